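# Independent brute-force oracles kept deliberately separate from the
# implementation paths they check.

# Connected components of an undirected edge list by breadth-first search;
# returns the edge count of each component.
bfs_component_sizes <- function(edge_i, edge_j, n_nodes) {
  if (length(edge_i) == 0L) return(integer(0))
  adj <- vector("list", n_nodes)
  for (k in seq_along(edge_i)) {
    adj[[edge_i[k]]] <- c(adj[[edge_i[k]]], edge_j[k])
    adj[[edge_j[k]]] <- c(adj[[edge_j[k]]], edge_i[k])
  }
  visited <- rep(FALSE, n_nodes)
  comp_of_node <- rep(NA_integer_, n_nodes)
  comp <- 0L
  for (start in unique(c(edge_i, edge_j))) {
    if (visited[start]) next
    comp <- comp + 1L
    queue <- start
    visited[start] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp_of_node[v] <- comp
      for (w in adj[[v]]) if (!visited[w]) {
        visited[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  as.integer(tabulate(comp_of_node[edge_i], nbins = comp))
}

# Pairwise-count AUC: fraction of (positive, negative) pairs ranked
# correctly, ties counted half.
auc_pairwise <- function(decision, labels) {
  dp <- decision[labels == 1]; dn <- decision[labels == -1]
  total <- 0
  for (a in dp) for (b in dn)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(dp) * length(dn))
}

# Pooled two-sample t evaluated directly from the textbook formula.
pooled_t_manual <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Build a conn_matrix with given upper-triangle values (lexicographic).
toy_conn <- function(vals, n_nodes, id = "s", scale = "fisher_z") {
  m <- matrix(0, n_nodes, n_nodes)
  k <- 1L
  for (i in seq_len(n_nodes - 1L)) for (j in (i + 1L):n_nodes) {
    m[i, j] <- m[j, i] <- vals[k]; k <- k + 1L
  }
  conn_matrix(m, scale = scale, subject_id = id)
}

# Two groups of conn_matrix objects around given population edge vectors.
toy_groups <- function(mu1, mu2, n1, n2, n_nodes, sd = 0.1, seed = 1) {
  set.seed(seed)
  g1 <- lapply(seq_len(n1), function(s)
    toy_conn(mu1 + rnorm(length(mu1), 0, sd), n_nodes, sprintf("p%02d", s)))
  g2 <- lapply(seq_len(n2), function(s)
    toy_conn(mu2 + rnorm(length(mu2), 0, sd), n_nodes, sprintf("c%02d", s)))
  list(g1 = g1, g2 = g2)
}

# The 28 published discriminative weights (signed) and t values used by the
# worked-example checks.
published_weights <- c(-0.461, -0.357, -0.286, -0.281, -0.264, -0.233,
                       -0.226, -0.216, -0.212, 0.178, -0.168, -0.157,
                       -0.142, -0.138, -0.133, -0.114, 0.104, -0.095,
                       0.092, -0.087, 0.085, 0.070, -0.067, 0.066,
                       0.059, 0.029, 0.028, -0.022)
published_t_values <- c(4.59, 4.55, 4.22, 4.19, 4.15, 4.09, 4.07, 4.06,
                        4.06, 4.00, 3.93, 3.72, 3.69, 3.69, 3.63, 3.59,
                        3.42, 3.41, 3.36, 3.31, 3.30, 3.29, 3.28, 3.26,
                        3.26, 3.23, 3.21, 3.16)
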