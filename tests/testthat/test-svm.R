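make_separable <- function(n_per_class = 10, p = 4, gap = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p, gap / 2), n_per_class, p),
             matrix(rnorm(n_per_class * p, -gap / 2), n_per_class, p))
  colnames(x) <- sprintf("f%d", seq_len(p))
  list(x = x, y = rep(c(1, -1), each = n_per_class))
}

test_that("widely separable classes are classified perfectly", {
  d <- make_separable()
  fit <- loocv_svm(d$x, d$y)
  expect_equal(fit$metrics$accuracy, 1)
  expect_equal(fit$metrics$auc, 1)
  expect_equal(unname(fit$confusion), c(10, 0, 10, 0))
})

test_that("metric identities hold from the confusion counts", {
  m <- classifier_metrics(35, 8, 27, 16)
  expect_equal(round(100 * m$accuracy, 2), 72.09)
  expect_equal(round(100 * m$sensitivity, 2), 81.40)
  expect_equal(round(100 * m$specificity, 2), 62.79)
  expect_equal(round(100 * m$ppv, 2), 68.63)
  expect_equal(round(100 * m$npv, 2), 77.14)

  d <- make_separable(8, 3, gap = 1.5, seed = 3)
  fit <- loocv_svm(d$x, d$y)
  cm <- fit$confusion
  expect_equal(cm[["tp"]] + cm[["fn"]], 8)
  expect_equal(cm[["tn"]] + cm[["fp"]], 8)
  expect_equal(fit$metrics$accuracy, (cm[["tp"]] + cm[["tn"]]) / 16)
})

test_that("AUC equals the pairwise-count oracle, including ties", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(6:20, 1)
    lab <- c(rep(1, ceiling(n / 2)), rep(-1, floor(n / 2)))
    dv <- round(rnorm(n), 1)                    # rounding induces ties
    expect_equal(snconn:::auc_score(dv, lab), auc_pairwise(dv, lab))
  }
})

test_that("label-permuted accuracy sits at chance level", {
  # LOOCV is pessimistically biased under the null at small n (the held-out
  # subject's class is under-represented in training), so a moderate n and
  # averaging over datasets are needed for the +/-5-point band around 50%
  acc <- unlist(lapply(1:3, function(ds) {
    d <- make_separable(30, 3, gap = 4, seed = ds)
    set.seed(100 + ds)
    vapply(1:30, function(b)
      loocv_svm(d$x, sample(d$y))$metrics$accuracy, numeric(1))
  }))
  expect_lt(abs(mean(acc) - 0.5), 0.05)
})

test_that("permutation p reaches its floor for a strong classifier", {
  d <- make_separable(6, 3, gap = 8, seed = 7)
  res <- svm_permutation_test(d$x, d$y, n_permutations = 49, seed = 8)
  expect_equal(unname(res$permutation_p["accuracy"]), 1 / 50)
  expect_equal(unname(res$permutation_p["auc"]), 1 / 50)
  expect_identical(res$permutation_p,
                   svm_permutation_test(d$x, d$y, n_permutations = 49,
                                        seed = 8)$permutation_p)
})

test_that("noise features rarely reach permutation significance", {
  set.seed(9)
  rej <- vapply(1:40, function(r) {
    x <- matrix(rnorm(16 * 6), 16, 6)
    y <- rep(c(1, -1), each = 8)
    p <- svm_permutation_test(x, y, n_permutations = 39,
                              seed = 100 + r)$permutation_p["accuracy"]
    p < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.10 + 2 * sqrt(0.05 * 0.95 / 40))
})

test_that("LOOCV predictions are invariant to subject ordering", {
  d <- make_separable(7, 4, gap = 2, seed = 10)
  fit <- loocv_svm(d$x, d$y)
  set.seed(11)
  ord <- sample(nrow(d$x))
  fit2 <- loocv_svm(d$x[ord, ], d$y[ord])
  expect_equal(fit2$predictions$predicted[order(ord)],
               fit$predictions$predicted)
  # decision values agree up to the LIBSVM solver's stopping tolerance
  expect_equal(fit2$predictions$decision_value[order(ord)],
               fit$predictions$decision_value, tolerance = 0.02)
})

test_that("published weight column reproduces its selection statistics", {
  W <- matrix(published_weights, nrow = 1)
  colnames(W) <- sprintf("edge%02d", seq_along(published_weights))
  wt <- aggregate_weights(W)
  expect_equal(round(attr(wt, "mean"), 3), 0.156)
  expect_equal(round(attr(wt, "sd"), 3), 0.106)
  sel <- wt$mean_abs_weight[wt$selected]
  expect_equal(sort(sel, decreasing = TRUE),
               c(0.461, 0.357, 0.286, 0.281, 0.264))
  expect_equal(sum(wt$selected), 5)
  expect_equal(sort(wt$rank), seq_along(published_weights))
})

test_that("weight aggregation handles degenerate and signed cases", {
  W <- matrix(0.2, 3, 4)
  wt <- aggregate_weights(W)
  expect_equal(attr(wt, "sd"), 0)
  expect_false(any(wt$selected))      # strict inequality at the threshold

  W2 <- matrix(c(1, -1, 0.1, 0.1), 2, 2)
  wt2 <- aggregate_weights(W2)
  expect_equal(wt2$mean_abs_weight[1], 1)
  expect_equal(wt2$mean_signed_weight[1], 0)

  Wna <- matrix(c(1, NA), 1, 2)
  expect_error(aggregate_weights(Wna), "inconsistent")
})

test_that("top-fraction selection keeps the five largest published t", {
  et <- data.frame(edge = sprintf("e%02d", seq_along(published_t_values)),
                   t = published_t_values)
  top <- top_fraction_edges(et, 0.20)
  expect_equal(nrow(top), 5)
  expect_equal(sort(top$t, decreasing = TRUE),
               c(4.59, 4.55, 4.22, 4.19, 4.15))

  expect_equal(nrow(top_fraction_edges(et, 1.0)), 28)
  small <- et[1:4, ]
  expect_equal(nrow(top_fraction_edges(small, 0.20)), 1)  # floor then min 1
  expect_equal(nrow(top_fraction_edges(et[0, ], 0.20)), 0)

  ties <- data.frame(i = c(2, 1, 1), j = c(3, 3, 2), t = c(4, 4, 4))
  picked <- top_fraction_edges(ties, 1 / 3)
  expect_equal(c(picked$i, picked$j), c(1, 2))   # lexicographic tie-break
})
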