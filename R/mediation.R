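#' Single-mediator (model 4) point estimates
#'
#' Three ordinary-least-squares regressions on the complete cases:
#' \code{Y ~ X + covariates} (total effect c), \code{M ~ X + covariates}
#' (path a), and \code{Y ~ X + M + covariates} (paths c' and b). The
#' indirect effect is \code{a * b}, and the OLS decomposition
#' \code{c = c' + a b} holds to machine precision because all three fits
#' share the same sample and covariates.
#'
#' @param data data frame holding X, M, Y and the covariates.
#' @param x,m,y column names of the exposure, mediator and outcome.
#' @param covariates column names of covariates (default age, gender,
#'   education). A character \code{gender} column is recoded to a 0/1
#'   indicator (1 = "M").
#' @return an \code{sn_mediation_fit}: coefficients \code{a}, \code{b},
#'   \code{c}, \code{c_prime}, \code{indirect}; intercepts \code{i_M},
#'   \code{i_Y}; residual SDs \code{sigma_M}, \code{sigma_Y}; per-path
#'   standard errors \code{se} and two-sided p-values \code{p};
#'   \code{n} complete cases used and \code{n_dropped}.
#' @export
fit_model4 <- function(data, x, m, y,
                       covariates = c("age", "gender", "education")) {
  data <- recode_gender(as.data.frame(data), covariates)
  vars <- c(x, m, y, covariates)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stopf("columns not found: %s", paste(missing_vars, collapse = ", "))
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  n_dropped <- sum(!cc)
  d <- data[cc, vars, drop = FALSE]
  if (nrow(d) < length(covariates) + 3L)
    stopf("need at least %d complete cases, got %d",
          length(covariates) + 3L, nrow(d))

  rhs <- paste(c(sprintf("`%s`", x), sprintf("`%s`", covariates)),
               collapse = " + ")
  f_total <- stats::as.formula(sprintf("`%s` ~ %s", y, rhs))
  f_med   <- stats::as.formula(sprintf("`%s` ~ %s", m, rhs))
  f_full  <- stats::as.formula(sprintf("`%s` ~ `%s` + `%s` + %s",
                                       y, x, m,
                                       paste(sprintf("`%s`", covariates),
                                             collapse = " + ")))
  fit_c <- stats::lm(f_total, data = d)
  fit_a <- stats::lm(f_med, data = d)
  fit_b <- stats::lm(f_full, data = d)
  for (f in list(fit_c, fit_a, fit_b))
    if (f$rank < length(stats::coef(f)))
      stopf("rank-deficient design; collinear columns: %s",
            paste(names(stats::coef(f))[is.na(stats::coef(f))],
                  collapse = ", "))
  sc <- stats::coef(summary(fit_c)); sa <- stats::coef(summary(fit_a))
  sb <- stats::coef(summary(fit_b))
  xn <- sprintf("`%s`", x); mn <- sprintf("`%s`", m)
  xrow_c <- if (xn %in% rownames(sc)) xn else x
  coefs <- list(c = sc[xrow_c, ], a = sa[xrow_c, ],
                c_prime = sb[xrow_c, ],
                b = sb[if (mn %in% rownames(sb)) mn else m, ])
  est <- vapply(coefs, `[[`, numeric(1), 1L)
  se <- vapply(coefs, `[[`, numeric(1), 2L)
  pv <- vapply(coefs, `[[`, numeric(1), 4L)
  structure(list(
    a = est[["a"]], b = est[["b"]], c = est[["c"]],
    c_prime = est[["c_prime"]], indirect = est[["a"]] * est[["b"]],
    i_M = unname(stats::coef(fit_a)[1]),
    i_Y = unname(stats::coef(fit_b)[1]),
    sigma_M = stats::sigma(fit_a), sigma_Y = stats::sigma(fit_b),
    se = se, p = pv, n = nrow(d), n_dropped = n_dropped,
    x = x, m = m, y = y, covariates = covariates),
    class = "sn_mediation_fit")
}

recode_gender <- function(data, covariates) {
  if ("gender" %in% covariates && "gender" %in% names(data) &&
      !is.numeric(data$gender))
    data$gender <- as.numeric(data$gender == "M")
  data
}

#' Percentile-bootstrap confidence interval for the indirect effect
#'
#' Resamples subjects with replacement, refits paths a and b on each
#' resample and takes percentile quantiles of the \code{a * b} draws.
#' Rank-deficient resamples are redrawn (up to 100 retries each).
#'
#' @inheritParams fit_model4
#' @param n_bootstrap number of resamples (default 5000).
#' @param ci_level confidence level (default 0.95).
#' @param seed integer seed; identical seeds give identical intervals.
#' @return list with \code{ci} (lower, upper), \code{boot} (the resampled
#'   indirect effects) and \code{n_bootstrap}.
#' @export
bootstrap_indirect <- function(data, x, m, y,
                               covariates = c("age", "gender", "education"),
                               n_bootstrap = 5000L, ci_level = 0.95,
                               seed = 1L) {
  if (n_bootstrap < 1L) stopf("n_bootstrap must be >= 1")
  data <- recode_gender(as.data.frame(data), covariates)
  vars <- c(x, m, y, covariates)
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  d <- data[cc, vars, drop = FALSE]
  n <- nrow(d)
  Xa <- cbind(1, as.matrix(d[, c(x, covariates), drop = FALSE]))
  Xb <- cbind(1, as.matrix(d[, c(x, m, covariates), drop = FALSE]))
  storage.mode(Xa) <- storage.mode(Xb) <- "double"
  Mv <- as.numeric(d[[m]]); Yv <- as.numeric(d[[y]])
  pa <- ncol(Xa); pb <- ncol(Xb)
  boot <- with_seed(seed, vapply(seq_len(n_bootstrap), function(bb) {
    for (try in 1:100) {
      idx <- sample.int(n, n, replace = TRUE)
      fa <- stats::.lm.fit(Xa[idx, , drop = FALSE], Mv[idx])
      fb <- stats::.lm.fit(Xb[idx, , drop = FALSE], Yv[idx])
      if (fa$rank == pa && fb$rank == pb)
        return(fa$coefficients[2L] * fb$coefficients[3L])
    }
    stopf("bootstrap resample repeatedly rank-deficient")
  }, numeric(1)))
  alpha <- 1 - ci_level
  ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2)))
  list(ci = ci, boot = boot, n_bootstrap = as.integer(n_bootstrap))
}

#' Classify the mediation effect type
#'
#' Using the bootstrap CI for the indirect effect and the OLS p-values of
#' the total and direct paths: \emph{no_effect} when the indirect CI
#' contains 0; \emph{suppression} when the indirect CI excludes 0 while
#' both total and direct effects are non-significant; \emph{full_mediation}
#' when the indirect CI excludes 0, the total effect is significant and the
#' direct effect is not; \emph{partial_mediation} otherwise.
#'
#' @param indirect_ci length-2 numeric (lower, upper).
#' @param p_total,p_direct OLS two-sided p-values of c and c'.
#' @param alpha significance level for the total/direct paths.
#' @return one of \code{"no_effect"}, \code{"suppression"},
#'   \code{"full_mediation"}, \code{"partial_mediation"}.
#' @examples
#' classify_effect(c(0.0006, 0.015), p_total = 0.9048, p_direct = 0.3613)
#' @export
classify_effect <- function(indirect_ci, p_total, p_direct, alpha = 0.05) {
  if (indirect_ci[1] <= 0 && indirect_ci[2] >= 0) return("no_effect")
  tot_sig <- p_total < alpha
  dir_sig <- p_direct < alpha
  if (!tot_sig && !dir_sig) "suppression"
  else if (tot_sig && !dir_sig) "full_mediation"
  else "partial_mediation"
}

#' Mediation analysis with percentile-bootstrap inference
#'
#' Convenience wrapper: fits the single-mediator model
#' (\code{\link{fit_model4}}), bootstraps the indirect effect
#' (\code{\link{bootstrap_indirect}}) and classifies the effect type
#' (\code{\link{classify_effect}}).
#'
#' @inheritParams bootstrap_indirect
#' @param alpha significance level for the total/direct path tests.
#' @return an \code{sn_mediation}: the \code{fit}, \code{boot_ci},
#'   \code{boot} draws, \code{effect_class}, and the call parameters.
#' @export
mediate <- function(data, x, m, y,
                    covariates = c("age", "gender", "education"),
                    n_bootstrap = 5000L, ci_level = 0.95, alpha = 0.05,
                    seed = 1L) {
  fit <- fit_model4(data, x, m, y, covariates)
  bs <- bootstrap_indirect(data, x, m, y, covariates, n_bootstrap,
                           ci_level, seed)
  structure(list(fit = fit, boot_ci = bs$ci, boot = bs$boot,
                 effect_class = classify_effect(bs$ci, fit$p[["c"]],
                                                fit$p[["c_prime"]], alpha),
                 ci_level = ci_level, alpha = alpha,
                 n_bootstrap = bs$n_bootstrap, seed = as.integer(seed)),
            class = "sn_mediation")
}

#' @export
print.sn_mediation_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Mediation model 4: %s -> %s -> %s (covariates: %s), n = %d\n",
              x$x, x$m, x$y, paste(x$covariates, collapse = ", "), x$n))
  tab <- data.frame(
    path = c("a (X->M)", "b (M->Y|X)", "c (total)", "c' (direct)"),
    estimate = c(x$a, x$b, x$c, x$c_prime),
    se = x$se[c("a", "b", "c", "c_prime")],
    p = x$p[c("a", "b", "c", "c_prime")])
  tab$estimate <- signif(tab$estimate, digits)
  tab$se <- signif(tab$se, digits)
  tab$p <- signif(tab$p, digits)
  print.data.frame(tab, row.names = FALSE)
  cat(sprintf("indirect a*b = %s\n", signif(x$indirect, digits)))
  invisible(x)
}

#' @export
print.sn_mediation <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("%g%% percentile bootstrap CI (N = %d): [%s, %s]\n",
              100 * x$ci_level, x$n_bootstrap,
              signif(x$boot_ci[1], digits), signif(x$boot_ci[2], digits)))
  cat(sprintf("effect class: %s\n", x$effect_class))
  invisible(x)
}

#' @export
summary.sn_mediation <- function(object, ...) print(object, ...)

#' @export
plot.sn_mediation <- function(x, ...) {
  graphics::hist(x$boot, breaks = 40, main = "Bootstrap indirect effect",
                 xlab = "a * b", ...)
  graphics::abline(v = x$boot_ci, lty = 2)
  graphics::abline(v = 0, col = 2)
  invisible(x)
}
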