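# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage seed derived from a global seed, < 2^31.
stage_seed <- function(global_seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 1000003L
  as.integer((as.numeric(global_seed) %% 1000003 * 1000003 + h) %% 2147483647)
}

# Upper-triangle edge table in (i, j) lexicographic order, i < j.
edge_table <- function(n_nodes, labels = NULL) {
  i <- rep(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
  j <- unlist(lapply(seq_len(n_nodes - 1L), function(a) (a + 1L):n_nodes))
  out <- data.frame(i = i, j = j)
  if (!is.null(labels))
    out$edge <- paste(labels[i], labels[j], sep = "--")
  out
}

# Flatten a symmetric matrix to its upper triangle in edge_table order.
flatten_edges <- function(m, edges = edge_table(nrow(m))) {
  m[cbind(edges$i, edges$j)]
}

# Rebuild a symmetric matrix (zero diagonal) from an edge vector.
unflatten_edges <- function(x, n_nodes, edges = edge_table(n_nodes)) {
  m <- matrix(0, n_nodes, n_nodes)
  m[cbind(edges$i, edges$j)] <- x
  m[cbind(edges$j, edges$i)] <- x
  m
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stopf("%s contains non-finite values", what)
  invisible(x)
}
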