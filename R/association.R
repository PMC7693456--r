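#' Normality-gated choice of correlation method
#'
#' Shapiro-Wilk on each variable; Pearson is used only when both pass at
#' \code{normality_alpha}, otherwise Spearman's rank-order correlation.
#'
#' @param x,y numeric samples (n >= 4, non-constant).
#' @param normality_alpha Shapiro-Wilk rejection level (default 0.05).
#' @return list with \code{method} (\code{"pearson"}/\code{"spearman"})
#'   and the two Shapiro p-values \code{normality_p}.
#' @export
choose_method <- function(x, y, normality_alpha = 0.05) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stopf("need n >= 4 complete cases")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("constant variable")
  px <- stats::shapiro.test(x)$p.value
  py <- stats::shapiro.test(y)$p.value
  list(method = if (px > normality_alpha && py > normality_alpha)
    "pearson" else "spearman",
    normality_p = c(x = px, y = py))
}

#' Correlation between an edge's connectivity and a variable
#'
#' @param x,y numeric samples of equal length (n >= 4).
#' @param method \code{"pearson"} or \code{"spearman"} (ties handled by
#'   average ranks); if missing, chosen by \code{\link{choose_method}}.
#' @param normality_alpha passed to \code{\link{choose_method}}.
#' @return list with \code{method}, \code{r}, \code{p} (two-sided),
#'   \code{n}, and \code{normality_p} when the method was auto-chosen.
#' @examples
#' correlate(1:5, c(2, 1, 4, 3, 5), method = "spearman")$r  # 0.7
#' @export
correlate <- function(x, y, method = NULL, normality_alpha = 0.05) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stopf("need n >= 4 complete cases")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("constant variable")
  normality_p <- NULL
  if (is.null(method)) {
    ch <- choose_method(x, y, normality_alpha)
    method <- ch$method
    normality_p <- ch$normality_p
  }
  method <- match.arg(method, c("pearson", "spearman"))
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE))
  list(method = method, r = unname(ht$estimate), p = ht$p.value,
       n = length(x), normality_p = normality_p)
}

#' Edge-by-variable association table
#'
#' Correlates each significant-edge connectivity column against each
#' clinical/behavioral variable, with the correlation method gated per
#' pair by Shapiro-Wilk normality. Raw two-sided p-values are reported
#' uncorrected (the analysis convention) alongside Benjamini-Hochberg
#' q-values over all tested pairs.
#'
#' @param z_table data frame from \code{\link{extract_significant_z}}
#'   (\code{subject_id} plus edge columns).
#' @param subjects subject metadata data frame with \code{subject_id} and
#'   the variables.
#' @param variables character vector of variable names to test.
#' @param group restrict to this group (default \code{"patient"}, the
#'   study's convention); \code{NULL} uses all subjects.
#' @param normality_alpha Shapiro-Wilk level for the method gate.
#' @param flag_alpha reporting threshold for the \code{flag} column
#'   (default 0.01).
#' @return an \code{sn_assoc}: data frame with edge, variable, method,
#'   r, p, q (BH), n, the two normality p-values, and a significance flag.
#' @export
associate_edges <- function(z_table, subjects, variables,
                            group = "patient", normality_alpha = 0.05,
                            flag_alpha = 0.01) {
  stopifnot("subject_id" %in% names(z_table),
            "subject_id" %in% names(subjects))
  merged <- merge(z_table, subjects, by = "subject_id", sort = FALSE)
  if (!is.null(group)) merged <- merged[merged$group == group, ]
  edge_cols <- setdiff(names(z_table), "subject_id")
  missing_vars <- setdiff(variables, names(merged))
  if (length(missing_vars))
    stopf("variables not found: %s", paste(missing_vars, collapse = ", "))
  rows <- list()
  for (e in edge_cols) for (v in variables) {
    res <- correlate(merged[[e]], merged[[v]],
                     normality_alpha = normality_alpha)
    rows[[length(rows) + 1L]] <- data.frame(
      edge = e, variable = v, method = res$method, r = res$r, p = res$p,
      n = res$n, normality_p_edge = res$normality_p["x"],
      normality_p_var = res$normality_p["y"],
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(edge = character(),
                                      variable = character())
  if (nrow(out)) {
    out$q <- stats::p.adjust(out$p, method = "BH")
    out$flag <- ifelse(out$p < flag_alpha, "*", "")
  }
  structure(out, class = c("sn_assoc", "data.frame"),
            flag_alpha = flag_alpha)
}

#' @export
print.sn_assoc <- function(x, digits = 4, ...) {
  cat(sprintf("Edge-variable associations (* marks p < %g, uncorrected)\n",
              attr(x, "flag_alpha")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print.data.frame(df, row.names = FALSE, ...)
  invisible(x)
}
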