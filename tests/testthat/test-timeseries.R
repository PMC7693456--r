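test_that("cleaning removes linear trends exactly", {
  t_idx <- 1:200
  ts <- cbind(ramp = 0.3 * t_idx + 5, noise = rnorm(200))
  out <- clean_timeseries(ts, tr_seconds = 2, cutoff_hz = NULL)
  slope <- coef(lm(out[, 1] ~ t_idx))[2]
  expect_lt(abs(slope), 1e-10)
  expect_lt(abs(mean(out[, 1])), 1e-10)
})

test_that("cleaned output is exactly orthogonal to nuisance regressors", {
  set.seed(4)
  t_sec <- (0:199) * 2
  sinus <- sin(2 * pi * 0.05 * t_sec)
  ts <- cbind(a = sinus + rnorm(200, 0, 0.5))
  out <- clean_timeseries(ts, tr_seconds = 2, nuisance = cbind(sinus),
                          cutoff_hz = 0.1)
  expect_lt(abs(cor(out[, 1], sinus)), 1e-10)
})

test_that("a supra-cutoff tone is attenuated by at least 20 dB", {
  t_sec <- (0:229) * 2
  tone <- sin(2 * pi * 0.2 * t_sec)           # 0.2 Hz, Nyquist 0.25
  out <- clean_timeseries(cbind(tone), tr_seconds = 2, cutoff_hz = 0.1)
  amp <- function(x) {
    fit <- lm(x ~ sin(2 * pi * 0.2 * t_sec) + cos(2 * pi * 0.2 * t_sec))
    sqrt(sum(coef(fit)[2:3]^2))
  }
  atten_db <- 20 * log10(amp(tone) / amp(out[, 1]))
  expect_gte(atten_db, 20)
})

test_that("cutoff at or above Nyquist is refused", {
  ts <- matrix(rnorm(100), 50, 2)
  expect_error(clean_timeseries(ts, tr_seconds = 2, cutoff_hz = 0.25),
               "Nyquist")
})

test_that("the projection stage is idempotent", {
  set.seed(5)
  ts <- matrix(rnorm(300), 100, 3)
  nuis <- cbind(rnorm(100))
  once <- clean_timeseries(ts, 2, nuisance = nuis, cutoff_hz = NULL)
  twice <- clean_timeseries(once, 2, nuisance = nuis, cutoff_hz = NULL)
  expect_lt(sqrt(mean((once - twice)^2)), 1e-8)
})

test_that("rank-deficient nuisance columns are dropped with a warning", {
  set.seed(6)
  ts <- matrix(rnorm(200), 100, 2)
  nuis <- cbind(a = rnorm(100))
  nuis <- cbind(nuis, b = 2 * nuis[, 1])
  expect_warning(out <- clean_timeseries(ts, 2, nuisance = nuis,
                                         cutoff_hz = NULL),
                 "rank-deficient")
  expect_lt(abs(cor(out[, 1], nuis[, 1])), 1e-10)
})

test_that("framewise displacement follows the closed form", {
  m <- matrix(1.5, 10, 6)
  fd0 <- framewise_displacement(m)
  expect_equal(fd0$fd, rep(0, 9))
  expect_equal(fd0$mean_fd, 0)

  m <- matrix(0, 5, 6); m[3:5, 1] <- 1      # single 1 mm translation step
  fd <- framewise_displacement(m)$fd
  expect_equal(fd, c(0, 1, 0, 0))

  m <- matrix(0, 5, 6); m[3:5, 5] <- 0.02   # 0.02 rad step, 50 mm radius
  fd <- framewise_displacement(m)$fd
  expect_equal(fd, c(0, 1, 0, 0))
  expect_equal(framewise_displacement(matrix(0, 5, 6) + m,
                                      head_radius_mm = 25)$fd,
               c(0, 0.5, 0, 0))

  m[2, 2] <- NA
  expect_error(framewise_displacement(m), "non-finite")
  expect_error(framewise_displacement(matrix(0, 1, 6)), "at least 2")
})

test_that("fc_matrix matches closed forms and clips perfect correlation", {
  set.seed(7)
  a <- as.numeric(scale(rnorm(60)))
  e <- as.numeric(scale(residuals(lm(rnorm(60) ~ a))))
  y <- 0.5 * a + sqrt(0.75) * e              # exact sample correlation 0.5
  cm <- fc_matrix(cbind(a = a, y = y))
  expect_equal(cm$values[1, 2], atanh(0.5), tolerance = 1e-10)
  expect_equal(diag(cm$values), c(a = 0, y = 0))

  dup <- fc_matrix(cbind(x = a, x2 = a))
  expect_true(is.finite(dup$values[1, 2]))
  expect_equal(dup$values[1, 2], atanh(1 - 1e-7))

  expect_error(fc_matrix(cbind(x = a, flat = rep(1, 60))), "flat")
})

test_that("white-noise connectivity is unbiased around zero", {
  zbar <- vapply(1:50, function(s) {
    set.seed(s)
    cm <- fc_matrix(matrix(rnorm(230 * 19), 230, 19))
    mean(cm$values[upper.tri(cm$values)])
  }, numeric(1))
  expect_lt(abs(mean(zbar)), 0.02)
})

test_that("fc_matrix is symmetric, deterministic and monotone in r", {
  set.seed(8)
  ts <- matrix(rnorm(100 * 6), 100, 6)
  z <- fc_matrix(ts, to_fisher_z = TRUE)
  r <- fc_matrix(ts, to_fisher_z = FALSE)
  expect_identical(z$values, t(z$values))
  expect_identical(z$values, fc_matrix(ts)$values)
  up <- upper.tri(z$values)
  expect_equal(order(r$values[up]), order(z$values[up]))
})
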