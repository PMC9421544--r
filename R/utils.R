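# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed; NULL seed uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer or NULL.")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 31-bit substream seed derived from a base seed and labels, so
# each pipeline stage (and each subject/density within it) is independently
# reproducible from the single top-level seed.
substream_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, character(1))),
               collapse = "/")
  hex <- substr(rlang::hash(key), 1, 7)
  (strtoi(hex, base = 16L) %% .Machine$integer.max) + 1L
}

# round() uses banker's rounding; edge counts need half-away-from-zero.
round_half_away <- function(x) {
  trunc(x + 0.5 * sign(x))
}

check_square_symmetric <- function(m, tol = 1e-9, arg = "matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  if (nrow(m) != ncol(m)) {
    abort(sprintf("`%s` must be square, got %d x %d.", arg, nrow(m), ncol(m)))
  }
  if (max(abs(m - t(m))) > tol) {
    abort(sprintf("`%s` is not symmetric within tolerance %g.", arg, tol))
  }
  invisible(m)
}

node_labels <- function(m, n = nrow(m)) {
  lb <- if (is.matrix(m)) rownames(m) else NULL
  if (is.null(lb)) sprintf("p%03d", seq_len(n)) else lb
}

# Upper-triangle edge list (1-based i < j) of a symmetric matrix.
edge_list <- function(adj, keep_zero = FALSE) {
  n <- nrow(adj)
  idx <- which(upper.tri(adj), arr.ind = TRUE)
  w <- adj[upper.tri(adj)]
  if (!keep_zero) {
    nz <- w != 0
    idx <- idx[nz, , drop = FALSE]
    w <- w[nz]
  }
  list(i = idx[, 1], j = idx[, 2], w = w, n = n)
}

edges_to_matrix <- function(i, j, w, n, labels = NULL) {
  adj <- matrix(0, n, n)
  adj[cbind(i, j)] <- w
  adj[cbind(j, i)] <- w
  if (!is.null(labels)) dimnames(adj) <- list(labels, labels)
  adj
}

as_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}
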