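#' Network-based statistic configuration
#'
#' @param t_threshold primary edge threshold on the two-sample t statistic
#'   (strictly exceeded; default 3.1).
#' @param n_permutations label permutations for the null of maximal
#'   component size (default 5000).
#' @param sidedness \code{"one_sided_group1_lt_group2"} (default: an edge is
#'   supra-threshold when group 1, the patients, show *lower* connectivity,
#'   i.e. \code{t < -t_threshold} for the group1-minus-group2 statistic) or
#'   \code{"two_sided"} (\code{|t| > t_threshold}).
#' @param alpha family-wise error level for declaring components
#'   significant (default 0.05).
#' @param seed integer seed for the permutation stream.
#' @return an \code{nbs_config} list.
#' @export
nbs_config <- function(t_threshold = 3.1, n_permutations = 5000L,
                       sidedness = c("one_sided_group1_lt_group2",
                                     "two_sided"),
                       alpha = 0.05, seed = 1L) {
  sidedness <- match.arg(sidedness)
  if (t_threshold <= 0) stopf("t_threshold must be positive")
  if (n_permutations < 1L) stopf("n_permutations must be >= 1")
  structure(list(t_threshold = t_threshold,
                 n_permutations = as.integer(n_permutations),
                 sidedness = sidedness, alpha = alpha,
                 seed = as.integer(seed)),
            class = "nbs_config")
}

# Stack a list of conn_matrix objects into a subjects x edges feature
# matrix (upper triangle, lexicographic edge order), validating agreement.
conn_features <- function(matrices, scale = "fisher_z") {
  stopifnot(length(matrices) >= 1L)
  first <- matrices[[1]]
  labels <- rownames(first$values)
  n_nodes <- nrow(first$values)
  edges <- edge_table(n_nodes, labels)
  feats <- t(vapply(matrices, function(m) {
    if (!inherits(m, "conn_matrix")) stopf("expected conn_matrix objects")
    if (m$scale != scale)
      stopf("mixed connectivity scales: expected %s, got %s", scale, m$scale)
    if (nrow(m$values) != n_nodes) stopf("mixed matrix sizes")
    if (!is.null(labels) && !is.null(rownames(m$values)) &&
        !identical(rownames(m$values), labels))
      stopf("node order differs between subjects")
    flatten_edges(m$values, edges)
  }, numeric(nrow(edges))))
  list(features = feats, edges = edges, n_nodes = n_nodes, labels = labels)
}

# Vectorized pooled two-sample t over columns of X for many group-1
# assignments at once. P: n_sub x B 0/1 indicator of group-1 membership.
pooled_t_block <- function(X, P, n1, n2) {
  Stot <- colSums(X); Qtot <- colSums(X^2)
  S1 <- crossprod(P, X)                     # B x E
  Q1 <- crossprod(P, X^2)
  m1 <- S1 / n1
  m2 <- sweep(-S1, 2L, Stot, "+") / n2
  ss1 <- Q1 - n1 * m1^2
  ss2 <- sweep(-Q1, 2L, Qtot, "+") - n2 * m2^2
  s2p <- (ss1 + ss2) / (n1 + n2 - 2)
  s2p[s2p < 0] <- 0                          # numerical guard
  diffm <- m1 - m2
  tt <- diffm / sqrt(s2p * (1 / n1 + 1 / n2))
  # edges constant within both groups: t = 0 when means agree too
  tt[s2p == 0 & diffm == 0] <- 0
  tt
}

supra_idx <- function(tvec, cfg) {
  if (cfg$sidedness == "two_sided") which(abs(tvec) > cfg$t_threshold)
  else which(tvec < -cfg$t_threshold)
}

# Edge counts of the connected components spanned by the given edges.
# Returns integer(0) when no edges. Components via igraph.
component_edge_counts <- function(edge_i, edge_j) {
  k <- length(edge_i)
  if (k == 0L) return(list(sizes = integer(0), membership = integer(0)))
  if (k == 1L) return(list(sizes = 1L, membership = 1L))
  g <- igraph::graph_from_edgelist(cbind(edge_i, edge_j), directed = FALSE)
  comp <- igraph::components(g)$membership
  memb <- comp[edge_i]                     # component of each edge
  memb <- match(memb, unique(memb))
  list(sizes = as.integer(tabulate(memb)), membership = as.integer(memb))
}

#' Supra-threshold connected components of an edge-statistic matrix
#'
#' Thresholds the edge-wise t matrix (strict inequality, direction per the
#' configured sidedness), builds the graph of surviving edges and returns
#' its connected components; a component's size is its edge count.
#'
#' @param edge_t symmetric nodes x nodes statistic matrix.
#' @param config an \code{nbs_config()}.
#' @return list of components, each a list with \code{edges} (data frame
#'   \code{i}, \code{j}, \code{t}), \code{n_edges}, \code{nodes}. Empty
#'   list when no edge survives.
#' @export
threshold_components <- function(edge_t, config = nbs_config()) {
  edge_t <- as.matrix(edge_t)
  if (max(abs(edge_t - t(edge_t))) > 1e-9) stopf("edge_t must be symmetric")
  edges <- edge_table(nrow(edge_t))
  tvec <- flatten_edges(edge_t, edges)
  sup <- supra_idx(tvec, config)
  cc <- component_edge_counts(edges$i[sup], edges$j[sup])
  lapply(seq_along(cc$sizes), function(ci) {
    sel <- sup[cc$membership == ci]
    list(edges = data.frame(i = edges$i[sel], j = edges$j[sel],
                            t = tvec[sel]),
         n_edges = length(sel),
         nodes = sort(unique(c(edges$i[sel], edges$j[sel]))))
  })
}

#' Edge-wise two-sample t matrix between two groups
#'
#' Pooled two-sample t computed independently on every upper-triangle edge
#' of the subjects' Fisher-z connectivity matrices; statistic is
#' group1 minus group2.
#'
#' @param group1,group2 lists of \code{conn_matrix} objects (>= 2 each),
#'   sharing node order and the \code{fisher_z} scale.
#' @return symmetric nodes x nodes t matrix with zero diagonal.
#' @export
edgewise_t <- function(group1, group2) {
  if (length(group1) < 2L || length(group2) < 2L)
    stopf("need at least 2 subjects per group")
  cf <- conn_features(c(group1, group2))
  n1 <- length(group1); n2 <- length(group2)
  P <- matrix(0, n1 + n2, 1); P[seq_len(n1), 1] <- 1
  tvec <- as.numeric(pooled_t_block(cf$features, P, n1, n2))
  m <- unflatten_edges(tvec, cf$n_nodes, cf$edges)
  dimnames(m) <- list(cf$labels, cf$labels)
  m
}

#' Network-based statistic with permutation FWER control
#'
#' The four-step NBS: (1) pooled two-sample t on every edge; (2) threshold
#' at the configured primary threshold; (3) connected components of the
#' supra-threshold graph, sized by edge count; (4) permutation null of the
#' maximal component size obtained by re-running steps 1-3 under random
#' group-label exchanges. Each observed component gets the family-wise
#' error corrected p-value \code{(1 + #\{null max >= size\}) / (N + 1)};
#' when the number of distinct label assignments is small (< 1e5 and not
#' above \code{n_permutations}) the null is enumerated exactly and
#' \code{p = #\{null max >= size\} / N_assignments}.
#'
#' @param group1 patient-group \code{conn_matrix} list (the "less than"
#'   side under the default one-sided mode).
#' @param group2 control-group \code{conn_matrix} list.
#' @param config an \code{nbs_config()}.
#' @return an \code{sn_nbs} object: \code{edge_t} (matrix),
#'   \code{components} (each with \code{fwer_p} added),
#'   \code{null_max_sizes}, \code{significant_mask} (0/1 matrix covering
#'   every edge of a component with \code{fwer_p < alpha}),
#'   \code{edge_table} of significant edges with t values, \code{config},
#'   \code{exact} (logical: enumerated null).
#' @export
nbs <- function(group1, group2, config = nbs_config()) {
  stopifnot(inherits(config, "nbs_config"))
  if (length(group1) < 2L || length(group2) < 2L)
    stopf("need at least 2 subjects per group")
  cf <- conn_features(c(group1, group2))
  X <- cf$features
  n1 <- length(group1); n2 <- length(group2); n <- n1 + n2
  edges <- cf$edges

  P_obs <- matrix(0, n, 1); P_obs[seq_len(n1), 1] <- 1
  t_obs <- as.numeric(pooled_t_block(X, P_obs, n1, n2))
  sup <- supra_idx(t_obs, config)
  cc <- component_edge_counts(edges$i[sup], edges$j[sup])

  n_assign <- choose(n, n1)
  exact <- is.finite(n_assign) && n_assign < 1e5 &&
    n_assign <= config$n_permutations
  assign_mat <- if (exact) {
    utils::combn(n, n1)
  } else {
    with_seed(config$seed,
              replicate(config$n_permutations, sample.int(n, n1)))
  }
  B <- ncol(assign_mat)
  null_max <- integer(B)
  chunk <- 1000L
  for (start in seq(1L, B, by = chunk)) {
    idx <- start:min(start + chunk - 1L, B)
    P <- matrix(0, n, length(idx))
    P[cbind(as.vector(assign_mat[, idx, drop = FALSE]),
            rep(seq_along(idx), each = n1))] <- 1
    Tb <- pooled_t_block(X, P, n1, n2)      # length(idx) x E
    for (bi in seq_along(idx)) {
      s <- supra_idx(Tb[bi, ], config)
      null_max[idx[bi]] <- if (length(s) == 0L) 0L else
        max(component_edge_counts(edges$i[s], edges$j[s])$sizes)
    }
  }

  comps <- lapply(seq_along(cc$sizes), function(ci) {
    sel <- sup[cc$membership == ci]
    size <- length(sel)
    p <- if (exact) sum(null_max >= size) / B
         else (1 + sum(null_max >= size)) / (B + 1)
    list(edges = data.frame(i = edges$i[sel], j = edges$j[sel],
                            t = t_obs[sel]),
         n_edges = size,
         nodes = sort(unique(c(edges$i[sel], edges$j[sel]))),
         fwer_p = p)
  })

  mask <- matrix(0L, cf$n_nodes, cf$n_nodes)
  sig_edges <- list()
  for (comp in comps) {
    if (comp$fwer_p < config$alpha) {
      mask[cbind(comp$edges$i, comp$edges$j)] <- 1L
      mask[cbind(comp$edges$j, comp$edges$i)] <- 1L
      sig_edges[[length(sig_edges) + 1L]] <- comp$edges
    }
  }
  dimnames(mask) <- list(cf$labels, cf$labels)
  sig <- if (length(sig_edges)) do.call(rbind, sig_edges) else
    data.frame(i = integer(), j = integer(), t = numeric())
  sig <- sig[order(sig$i, sig$j), , drop = FALSE]
  if (!is.null(cf$labels) && nrow(sig))
    sig$edge <- paste(cf$labels[sig$i], cf$labels[sig$j], sep = "--")

  edge_t <- unflatten_edges(t_obs, cf$n_nodes, edges)
  dimnames(edge_t) <- list(cf$labels, cf$labels)
  structure(list(edge_t = edge_t, components = comps,
                 null_max_sizes = null_max, significant_mask = mask,
                 edge_table = sig, config = config, exact = exact,
                 n1 = n1, n2 = n2),
            class = "sn_nbs")
}

#' Extract masked edge values from subject connectivity matrices
#'
#' Multiplies the significant-edge mask into each subject's matrix and
#' returns the surviving upper-triangle values, one column per edge in
#' stable (i, j) lexicographic order.
#'
#' @param mask 0/1 symmetric matrix (e.g. \code{significant_mask} of an
#'   \code{sn_nbs}).
#' @param subjects list of \code{conn_matrix} objects matching the mask's
#'   dimension.
#' @return data frame: \code{subject_id} plus one numeric column per
#'   masked edge (named \code{<label_i>--<label_j>}, or
#'   \code{e<i>_<j>} without labels). Zero edge columns when the mask is
#'   empty.
#' @export
extract_significant_z <- function(mask, subjects) {
  mask <- as.matrix(mask)
  if (max(abs(mask - t(mask))) > 0) stopf("mask must be symmetric")
  if (!all(mask %in% c(0, 1))) stopf("mask must be binary")
  n_nodes <- nrow(mask)
  edges <- edge_table(n_nodes)
  keep <- which(mask[cbind(edges$i, edges$j)] == 1)
  labels <- rownames(mask)
  nm <- if (!is.null(labels))
    paste(labels[edges$i[keep]], labels[edges$j[keep]], sep = "--")
  else sprintf("e%d_%d", edges$i[keep], edges$j[keep])
  vals <- lapply(subjects, function(m) {
    if (nrow(m$values) != n_nodes) stopf("mask/matrix size mismatch")
    (m$values * mask)[cbind(edges$i[keep], edges$j[keep])]
  })
  out <- as.data.frame(do.call(rbind, vals))
  names(out) <- nm
  ids <- vapply(subjects, function(m) m$subject_id, character(1))
  cbind(data.frame(subject_id = ids, stringsAsFactors = FALSE), out)
}

#' @export
print.sn_nbs <- function(x, ...) {
  cat(sprintf("Network-based statistic (threshold %g, %s, %d permutations%s)\n",
              x$config$t_threshold, x$config$sidedness,
              length(x$null_max_sizes),
              if (x$exact) ", exact enumeration" else ""))
  if (!length(x$components)) {
    cat("No supra-threshold components.\n")
  } else {
    for (k in seq_along(x$components)) {
      comp <- x$components[[k]]
      cat(sprintf("  component %d: %d edge(s), %d node(s), FWER p = %.4g%s\n",
                  k, comp$n_edges, length(comp$nodes), comp$fwer_p,
                  if (comp$fwer_p < x$config$alpha) " *" else ""))
    }
  }
  invisible(x)
}

#' @export
summary.sn_nbs <- function(object, ...) {
  print(object)
  if (nrow(object$edge_table)) {
    cat("Significant edges (FWER p < alpha):\n")
    df <- object$edge_table
    df$t <- round(df$t, 2)
    print.data.frame(df, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.sn_nbs <- function(x, ...) {
  n <- nrow(x$edge_t)
  graphics::image(seq_len(n), seq_len(n), t(x$edge_t[n:1, ]),
                  xlab = "node", ylab = "node",
                  main = "Edge-wise t (group1 - group2)",
                  col = grDevices::hcl.colors(64, "Blue-Red 2"), ...)
  invisible(x)
}
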