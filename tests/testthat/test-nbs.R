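test_that("edgewise t is zero for identical groups and flips with labels", {
  g <- toy_groups(mu1 = rep(0.3, 6), mu2 = rep(0.3, 6), n1 = 5, n2 = 5,
                  n_nodes = 4, seed = 1)
  same <- lapply(g$g1, function(m) m)
  expect_lt(max(abs(edgewise_t(same, same))), 1e-10)
  t12 <- edgewise_t(g$g1, g$g2)
  t21 <- edgewise_t(g$g2, g$g1)
  expect_equal(t12, -t21)
  expect_equal(diag(t12), rep(0, 4))
})

test_that("each edge's t equals the scalar pooled t on its values", {
  mu2 <- rep(0.3, 6); mu1 <- mu2; mu1[2] <- -0.6    # shift edge (1,3)
  g <- toy_groups(mu1, mu2, n1 = 6, n2 = 7, n_nodes = 4, seed = 2)
  tm <- edgewise_t(g$g1, g$g2)
  v1 <- vapply(g$g1, function(m) m$values[1, 3], numeric(1))
  v2 <- vapply(g$g2, function(m) m$values[1, 3], numeric(1))
  expect_equal(tm[1, 3], two_sample_t(v1, v2)$t, tolerance = 1e-12)
  expect_equal(tm[2, 4], two_sample_t(
    vapply(g$g1, function(m) m$values[2, 4], numeric(1)),
    vapply(g$g2, function(m) m$values[2, 4], numeric(1)))$t,
    tolerance = 1e-12)
})

test_that("mixed scales or node orders are refused", {
  g <- toy_groups(rep(0.3, 6), rep(0.3, 6), 3, 3, 4)
  bad <- g$g2
  bad[[1]]$scale <- "pearson_r"
  expect_error(edgewise_t(g$g1, bad), "scale")
  expect_error(edgewise_t(g$g1[1], g$g2), "at least 2")
})

test_that("component extraction matches the toy example", {
  cfg <- nbs_config(t_threshold = 3.1, sidedness = "two_sided")
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 4.0
  m[2, 3] <- m[3, 2] <- 3.5
  comps <- threshold_components(m, cfg)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$n_edges, 2)
  expect_equal(comps[[1]]$nodes, c(1, 2, 3))

  expect_length(threshold_components(matrix(0, 4, 4), cfg), 0)

  iso <- matrix(0, 5, 5); iso[4, 5] <- iso[5, 4] <- 9
  comps <- threshold_components(iso, cfg)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$n_edges, 1)
})

test_that("components agree with a BFS oracle on 100 random 8-node graphs", {
  cfg <- nbs_config(t_threshold = 1, sidedness = "two_sided")
  set.seed(11)
  for (rep in 1:100) {
    m <- matrix(0, 8, 8)
    up <- upper.tri(m)
    vals <- ifelse(runif(sum(up)) < 0.25, runif(sum(up), 1.5, 5), 0)
    m[up] <- vals; m <- m + t(m)
    comps <- threshold_components(m, cfg)
    sizes <- sort(vapply(comps, `[[`, numeric(1), "n_edges"))
    et <- which(m > 1 & up, arr.ind = TRUE)
    oracle <- sort(bfs_component_sizes(et[, 1], et[, 2], 8))
    expect_equal(sizes, as.numeric(oracle))
  }
})

test_that("threshold limits and monotonicity behave as required", {
  set.seed(12)
  m <- matrix(rnorm(64, sd = 2), 8); m <- m + t(m); diag(m) <- 0
  high <- nbs_config(t_threshold = 1e6, sidedness = "two_sided")
  expect_length(threshold_components(m, high), 0)
  low <- nbs_config(t_threshold = 1e-9, sidedness = "two_sided")
  comps <- threshold_components(abs(m) + 0.1 - diag(rep(0.1, 8)), low)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$n_edges, choose(8, 2))   # complete graph

  for (thr in c(0.5, 1, 2, 3)) {
    big <- threshold_components(m, nbs_config(t_threshold = thr,
                                              sidedness = "two_sided"))
    small <- threshold_components(m, nbs_config(t_threshold = thr + 1,
                                                sidedness = "two_sided"))
    max_sz <- function(cc) if (length(cc)) max(vapply(cc, `[[`,
                                                      numeric(1),
                                                      "n_edges")) else 0
    expect_lte(max_sz(small), max_sz(big))
  }
})

test_that("a dominant observed component reaches the permutation floor", {
  pe <- default_planted_edges(0.8)
  co <- generate_cohort(cohort_config(n_per_group = 15, timeseries = FALSE,
                                      planted_edges = pe, seed = 31))
  ids <- split(co$subjects$subject_id, co$subjects$group)
  res <- nbs(co$connectivity[ids$patient], co$connectivity[ids$control],
             nbs_config(n_permutations = 99, seed = 5))
  expect_false(res$exact)
  expect_equal(min(vapply(res$components, `[[`, numeric(1), "fwer_p")),
               1 / 100)
  # every masked edge is supra-threshold in the right direction
  et <- res$edge_t[res$significant_mask == 1]
  expect_true(all(et < -3.1))
})

test_that("small cohorts trigger exact enumeration of label assignments", {
  g <- toy_groups(rep(-0.5, 6), rep(0.5, 6), 3, 3, 4, sd = 0.05, seed = 3)
  res <- nbs(g$g1, g$g2, nbs_config(t_threshold = 2,
                                    n_permutations = 500, seed = 1))
  expect_true(res$exact)
  expect_length(res$null_max_sizes, choose(6, 3))
  ps <- vapply(res$components, `[[`, numeric(1), "fwer_p")
  expect_true(all(ps >= 1 / choose(6, 3)))
})

test_that("fwer p-values are invariant to node relabeling", {
  pe <- data.frame(i = c(1L, 2L), j = c(2L, 3L), delta_z = 0.7)
  co <- generate_cohort(cohort_config(n_per_group = 12, n_nodes = 6,
                                      timeseries = FALSE,
                                      planted_edges = pe, seed = 17))
  ids <- split(co$subjects$subject_id, co$subjects$group)
  cfg <- nbs_config(n_permutations = 199, seed = 2, t_threshold = 2.5)
  res1 <- nbs(co$connectivity[ids$patient], co$connectivity[ids$control],
              cfg)
  perm <- c(6, 4, 1, 3, 2, 5)
  relabel <- lapply(co$connectivity, function(m) {
    v <- m$values[perm, perm]
    dimnames(v) <- NULL
    conn_matrix(v, m$scale, m$subject_id)
  })
  res2 <- nbs(relabel[ids$patient], relabel[ids$control], cfg)
  p1 <- sort(vapply(res1$components, `[[`, numeric(1), "fwer_p"))
  p2 <- sort(vapply(res2$components, `[[`, numeric(1), "fwer_p"))
  expect_equal(p1, p2)
})

test_that("extract_significant_z selects exactly the masked entries", {
  g <- toy_groups(rep(0.3, 3), rep(0.3, 3), 2, 2, 3, seed = 4)
  subs <- c(g$g1, g$g2)

  empty <- extract_significant_z(matrix(0, 3, 3), subs)
  expect_equal(ncol(empty), 1)          # subject_id only
  expect_equal(nrow(empty), 4)

  full <- matrix(1, 3, 3); diag(full) <- 0
  tab <- extract_significant_z(full, subs)
  expect_equal(names(tab)[-1], c("e1_2", "e1_3", "e2_3"))
  expect_equal(unname(unlist(tab[1, -1])),
               subs[[1]]$values[cbind(c(1, 1, 2), c(2, 3, 3))])

  one <- matrix(0, 3, 3); one[1, 2] <- one[2, 1] <- 1
  tab1 <- extract_significant_z(one, subs)
  expect_equal(tab1$e1_2,
               vapply(subs, function(m) m$values[1, 2], numeric(1)),
               ignore_attr = TRUE)
  expect_error(extract_significant_z(matrix(0, 4, 4), subs), "mismatch")
})
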