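make_med_data <- function(n = 120, a = 0.5, b = 0.4, cp = 0.1,
                          seed = 1) {
  set.seed(seed)
  X <- rnorm(n)
  M <- 0.2 + a * X + rnorm(n, 0, 0.3)
  Y <- 5 + cp * X + b * M + rnorm(n, 0, 0.5)
  data.frame(X = X, M = M, Y = Y, age = rnorm(n, 47, 10),
             gender = sample(c("M", "F"), n, TRUE),
             education = rnorm(n, 10, 3))
}

test_that("the OLS effect decomposition c = c' + a*b is exact", {
  for (s in 1:5) {
    d <- make_med_data(n = 40, seed = s)
    fit <- fit_model4(d, "X", "M", "Y")
    expect_lt(abs(fit$c - (fit$c_prime + fit$a * fit$b)), 1e-10)
  }
  # also with missing data (complete-case deletion)
  d <- make_med_data(60, seed = 9)
  d$M[c(3, 10)] <- NA
  fit <- fit_model4(d, "X", "M", "Y")
  expect_equal(fit$n_dropped, 2)
  expect_equal(fit$n, 58)
  expect_lt(abs(fit$c - (fit$c_prime + fit$indirect)), 1e-10)
})

test_that("a no-mediation dataset gives an indirect estimate near zero", {
  d <- make_med_data(n = 200, b = 0, seed = 2)
  fit <- fit_model4(d, "X", "M", "Y")
  se_ab <- sqrt(fit$b^2 * fit$se["a"]^2 + fit$a^2 * fit$se["b"]^2 +
                  fit$se["a"]^2 * fit$se["b"]^2)
  expect_lt(abs(fit$indirect), 3 * max(se_ab, fit$se["b"] * abs(fit$a)))
})

test_that("structural coefficients are recovered from a generated cohort", {
  co <- generate_cohort(cohort_config(
    n_per_group = 200, timeseries = FALSE, planted_edges = NULL,
    mediation = mediation_spec(a = 0.5, b = 0.4, c_prime = 0.1),
    seed = 77))
  pat <- co$subjects$group == "patient"
  d <- co$subjects[pat, ]
  d$M <- vapply(co$connectivity, function(m) m$values[1, 3],
                numeric(1))[pat]
  d$X <- as.numeric(scale(d$hemoglobin))
  fit <- fit_model4(d, "X", "M", "FDST")
  expect_lt(abs(fit$a - 0.5), 3 * fit$se["a"])
  expect_lt(abs(fit$b - 0.4), 3 * fit$se["b"])
  expect_lt(abs(fit$c_prime - 0.1), 3 * fit$se["c_prime"])
})

test_that("bootstrap CI is seed-deterministic and ordered", {
  d <- make_med_data(n = 80, seed = 3)
  b1 <- bootstrap_indirect(d, "X", "M", "Y", n_bootstrap = 300, seed = 4)
  b2 <- bootstrap_indirect(d, "X", "M", "Y", n_bootstrap = 300, seed = 4)
  expect_identical(b1$ci, b2$ci)
  expect_lte(b1$ci[1], b1$ci[2])
  expect_length(b1$boot, 300)
})

test_that("bootstrap CI width shrinks with sample size", {
  width <- vapply(c(50, 200), function(n) {
    d <- make_med_data(n = n, seed = 5)
    diff(bootstrap_indirect(d, "X", "M", "Y", n_bootstrap = 400,
                            seed = 6)$ci)
  }, numeric(1))
  expect_lt(width[2], width[1])
  # roughly root-n scaling: a 4x sample cuts the width near in half
  expect_lt(width[2] / width[1], 0.8)
})

test_that("pure-noise covariates leave the paths essentially unchanged", {
  d <- make_med_data(n = 300, seed = 7)
  with_cov <- fit_model4(d, "X", "M", "Y")
  no_cov <- lm(M ~ X, data = d)
  expect_lt(abs(with_cov$a - coef(no_cov)[["X"]]),
            2 * with_cov$se[["a"]])
})

test_that("effect classification covers all regimes", {
  expect_equal(classify_effect(c(0.0006, 0.015), p_total = 0.9048,
                               p_direct = 0.3613), "suppression")
  expect_equal(classify_effect(c(-0.01, 0.02), 0.5, 0.5), "no_effect")
  expect_equal(classify_effect(c(0.1, 0.3), p_total = 0.001,
                               p_direct = 0.4), "full_mediation")
  expect_equal(classify_effect(c(0.1, 0.3), p_total = 0.001,
                               p_direct = 0.01), "partial_mediation")
})

test_that("mediate() assembles fit, bootstrap CI and classification", {
  d <- make_med_data(n = 150, a = 0.8, b = 0.8, cp = 0, seed = 8)
  m <- mediate(d, "X", "M", "Y", n_bootstrap = 500, seed = 9)
  expect_s3_class(m, "sn_mediation")
  expect_gt(m$boot_ci[1], 0)          # strong mediation: CI excludes zero
  expect_true(m$effect_class %in% c("full_mediation", "partial_mediation"))
  expect_identical(m$boot_ci,
                   mediate(d, "X", "M", "Y", n_bootstrap = 500,
                           seed = 9)$boot_ci)
})

test_that("rank-deficient designs are refused with the offending column", {
  d <- make_med_data(n = 50, seed = 10)
  d$dup <- d$X
  expect_error(fit_model4(d, "X", "M", "Y",
                          covariates = c("age", "gender", "dup")),
               "rank|collinear")
  expect_error(fit_model4(d[1:4, ], "X", "M", "Y"), "complete cases")
})
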