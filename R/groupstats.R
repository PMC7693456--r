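#' Pooled two-sample t-test
#'
#' Student's pooled-variance two-sample t-test (two-sided), the convention
#' under which the published effect sizes reproduce exactly from
#' \code{d = t * sqrt(1/n1 + 1/n2)}. Welch's unequal-variance test is
#' available via \code{welch = TRUE}.
#'
#' @param x,y numeric samples (each n >= 2).
#' @param welch use Welch's test instead of the pooled test.
#' @return list with \code{t}, \code{df}, \code{p}, per-group \code{mean}
#'   and \code{sd}, and \code{n1}, \code{n2}.
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6))$t   # -3.674
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) stopf("each sample needs n >= 2")
  if (!welch && stats::var(x) == 0 && stats::var(y) == 0)
    stopf("zero pooled variance")
  ht <- stats::t.test(x, y, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean = c(mean(x), mean(y)),
       sd = c(stats::sd(x), stats::sd(y)),
       n1 = length(x), n2 = length(y))
}

#' Cohen's d from a pooled t statistic
#'
#' For the pooled equal-variance test, \code{d = t * sqrt(1/n1 + 1/n2)};
#' this relation is exact and shares the sign of t.
#'
#' @param t pooled two-sample t statistic.
#' @param n1,n2 group sizes (>= 2).
#' @return Cohen's d.
#' @examples
#' cohens_d_from_t(3.927, 43, 43)   # 0.847
#' @export
cohens_d_from_t <- function(t, n1, n2) {
  if (any(c(n1, n2) < 2)) stopf("n1, n2 must be >= 2")
  t * sqrt(1 / n1 + 1 / n2)
}

#' Cohen's d from raw samples
#'
#' \code{(mean(x) - mean(y)) / s_pooled}; agrees exactly with
#' \code{cohens_d_from_t} applied to the pooled t on the same samples.
#'
#' @param x,y numeric samples.
#' @return Cohen's d.
#' @export
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stopf("each sample needs n >= 2")
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  if (sp == 0) stopf("zero pooled variance")
  (mean(x) - mean(y)) / sp
}

#' Normal-approximation confidence interval for Cohen's d
#'
#' \code{d +/- z * sqrt((n1 + n2)/(n1 n2) + d^2 / (2 (n1 + n2)))}.
#'
#' @param d effect size.
#' @param n1,n2 group sizes.
#' @param level confidence level in (0, 1).
#' @return length-2 numeric vector (lower, upper).
#' @export
cohens_d_ci <- function(d, n1, n2, level = 0.95) {
  if (level <= 0 || level >= 1) stopf("level must be in (0, 1)")
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  d + c(-1, 1) * stats::qnorm(1 - (1 - level) / 2) * se
}

#' Pearson chi-square test on a 2x2 count table
#'
#' Without continuity correction by default (switchable), matching the
#' group-comparison convention for categorical variables such as gender.
#'
#' @param counts 2x2 matrix of non-negative counts with positive margins.
#' @param correct apply Yates' continuity correction.
#' @return list with \code{chisq}, \code{df}, \code{p}.
#' @export
chi_square_counts <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stopf("zero margin in count table")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(chisq = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Demographic and behavioral group-comparison table
#'
#' Per continuous variable: per-group mean (SD), pooled t, df, Cohen's d
#' with normal-approximation 95% CI, and two-sided p; gender compared by
#' Pearson chi-square. Rows with p at or below \code{strict_alpha}
#' (0.001, the study's "obviously significant" convention) are flagged;
#' all raw p-values are always emitted.
#'
#' @param subjects data frame with a \code{group} column
#'   (\code{"patient"}/\code{"control"}) and the variables to compare.
#' @param variables character vector of continuous variable names; defaults
#'   to all numeric columns present in both groups.
#' @param gender_var name of the categorical gender column, or \code{NULL}.
#' @param strict_alpha flagging threshold.
#' @return an \code{sn_group_table}: data frame with one row per variable.
#' @export
group_table <- function(subjects, variables = NULL, gender_var = "gender",
                        strict_alpha = 0.001) {
  stopifnot(all(c("group") %in% names(subjects)))
  pat <- subjects[subjects$group == "patient", , drop = FALSE]
  con <- subjects[subjects$group == "control", , drop = FALSE]
  if (is.null(variables)) {
    num <- vapply(subjects, is.numeric, logical(1))
    variables <- names(subjects)[num]
    variables <- variables[vapply(variables, function(v)
      sum(!is.na(pat[[v]])) >= 2 && sum(!is.na(con[[v]])) >= 2, logical(1))]
  }
  rows <- lapply(variables, function(v) {
    tt <- two_sample_t(con[[v]], pat[[v]])  # control minus patient
    d <- cohens_d_from_t(tt$t, tt$n1, tt$n2)
    ci <- cohens_d_ci(d, tt$n1, tt$n2)
    data.frame(variable = v,
               control_mean = tt$mean[1], control_sd = tt$sd[1],
               patient_mean = tt$mean[2], patient_sd = tt$sd[2],
               t = tt$t, df = tt$df, cohens_d = d,
               d_ci_lower = ci[1], d_ci_upper = ci[2], p = tt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(gender_var) && gender_var %in% names(subjects)) {
    tab <- table(subjects$group, subjects[[gender_var]])
    if (all(dim(tab) == c(2L, 2L))) {
      cs <- chi_square_counts(tab)
      out <- rbind(out, data.frame(
        variable = gender_var, control_mean = NA, control_sd = NA,
        patient_mean = NA, patient_sd = NA, t = NA, df = cs$df,
        cohens_d = NA, d_ci_lower = NA, d_ci_upper = NA, p = cs$p,
        stringsAsFactors = FALSE))
      attr(out, "gender_chisq") <- cs$chisq
    }
  }
  out$flag <- ifelse(!is.na(out$p) & out$p <= strict_alpha, "***", "")
  structure(out, class = c("sn_group_table", "data.frame"),
            strict_alpha = strict_alpha)
}

#' @export
print.sn_group_table <- function(x, digits = 3, ...) {
  cat(sprintf("Group comparison (pooled t; *** marks p <= %g)\n",
              attr(x, "strict_alpha")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print.data.frame(df, row.names = FALSE, ...)
  invisible(x)
}
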