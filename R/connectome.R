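#' Pearson functional connectivity from parcellated time series
#'
#' Correlates every pair of parcel time courses, producing the subject's
#' symmetric weighted connectivity matrix (zero diagonal).
#'
#' @param ts Timepoints-by-nodes numeric matrix (columns are parcels).
#' @return Nodes-by-nodes correlation matrix, zero diagonal, with attribute
#'   `scale = "pearson_r"`.
#' @export
compute_fc <- function(ts) {
  if (!is.matrix(ts) || !is.numeric(ts)) abort("`ts` must be a numeric matrix.")
  if (nrow(ts) < 3) abort("Need at least 3 timepoints.")
  if (anyNA(ts)) abort("Time series contain missing values.")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- node_labels(t(ts))[sds == 0]
    abort(sprintf("Constant time series for parcel(s): %s",
                  paste(bad, collapse = ", ")))
  }
  r <- stats::cor(ts)
  diag(r) <- 0
  lb <- colnames(ts)
  if (is.null(lb)) lb <- sprintf("p%03d", seq_len(ncol(ts)))
  dimnames(r) <- list(lb, lb)
  attr(r, "scale") <- "pearson_r"
  r
}

fc_scale <- function(cm) {
  sc <- attr(cm, "scale")
  if (is.null(sc)) "pearson_r" else sc
}

#' Fisher r-to-z transform of a connectivity matrix
#'
#' Entrywise `atanh` with |r| clipped to `1 - 1e-7` so perfect correlations
#' stay finite; the diagonal stays zero. [fisher_z_inv()] is the entrywise
#' inverse (`tanh`).
#'
#' @param cm Pearson connectivity matrix.
#' @return Matrix on the Fisher-z scale (`scale = "fisher_z"`).
#' @export
fisher_z <- function(cm) {
  if (fc_scale(cm) != "pearson_r") abort("`cm` is not on the pearson_r scale.")
  z <- atanh(pmin(pmax(cm, -1 + 1e-7), 1 - 1e-7))
  diag(z) <- 0
  attributes(z) <- attributes(cm)
  attr(z, "scale") <- "fisher_z"
  z
}

#' @rdname fisher_z
#' @param z Fisher-z matrix.
#' @export
fisher_z_inv <- function(z) {
  r <- tanh(z)
  diag(r) <- 0
  attributes(r) <- attributes(z)
  attr(r, "scale") <- "pearson_r"
  r
}

#' Proportional (density) thresholding of a connectivity matrix
#'
#' Keeps the `k = round(density * N(N-1)/2)` largest off-diagonal entries by
#' signed value (half rounded away from zero; weight ties broken by
#' lexicographic node order for determinism) and zeroes the rest. Any negative
#' weights among the survivors are set to zero, since the weighted graph
#' metrics assume nonnegative weights; at the densities analyzed here (>= 10%)
#' retained functional-connectivity edges are almost always positive.
#'
#' @param cm Symmetric connectivity matrix.
#' @param density Fraction of possible edges to retain, in (0, 1].
#' @param mode `"weighted"` keeps surviving weights; `"binary"` sets them to 1.
#' @return Adjacency matrix with attributes `density` and `mode`.
#' @export
proportional_threshold <- function(cm, density, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  check_square_symmetric(cm, tol = 1e-9, arg = "cm")
  if (density <= 0 || density > 1) abort("`density` must be in (0, 1].")
  n <- nrow(cm)
  m_max <- n * (n - 1) / 2
  k <- round_half_away(density * m_max)
  if (k < 1) abort("`density` retains zero edges.")
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  w <- cm[upper.tri(cm)]
  ord <- order(-w, idx[, 1], idx[, 2])
  keep <- ord[seq_len(k)]
  wk <- if (mode == "binary") as.numeric(w[keep] > 0) else pmax(w[keep], 0)
  adj <- edges_to_matrix(idx[keep, 1], idx[keep, 2], wk, n, node_labels(cm))
  attr(adj, "density") <- density
  attr(adj, "mode") <- mode
  adj
}

#' Density grid for the sparsity sweep
#'
#' The analysis band defaults to 10--40% in 1% steps (31 densities); the lower
#' bound guards against graph fragmentation and the upper bound is a liberal
#' estimate of plausible cerebral connectivity. The full 1--40% sweep is
#' available via `from = 0.01`.
#'
#' @param from,to,by Grid bounds and step, all in (0, 1].
#' @return Strictly increasing numeric vector of densities.
#' @export
density_grid <- function(from = 0.10, to = 0.40, by = 0.01) {
  g <- seq(from, to, by = by)
  if (any(g <= 0 | g > 1) || is.unsorted(g, strictly = TRUE)) {
    abort("Densities must be strictly increasing within (0, 1].")
  }
  round(g, 10)
}

#' Threshold a connectivity matrix across a density grid
#'
#' One thresholded network per density. Because proportional thresholding is a
#' top-k selection, edge sets are nested: the network at density d is a
#' subgraph of the network at any d' > d.
#'
#' @param cm Symmetric connectivity matrix.
#' @param grid Densities from [density_grid()].
#' @param mode `"weighted"` or `"binary"`.
#' @return Named list of adjacency matrices (names are the densities).
#' @export
threshold_series <- function(cm, grid = density_grid(),
                             mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  nets <- lapply(grid, function(d) proportional_threshold(cm, d, mode))
  names(nets) <- format(grid, trim = TRUE)
  nets
}

#' Group-averaged connectome at a fixed density
#'
#' Averages subject matrices in Fisher-z space (the variance-stabilized
#' convention), back-transforms to correlation units, and keeps the top
#' `density` fraction of connections -- the network on which group-level
#' community detection and hub classification run.
#'
#' @param cms List of subject connectivity matrices (Pearson or Fisher-z; all
#'   the same dimension).
#' @param density Density retained (default the top 10% of connections).
#' @param mode `"weighted"` or `"binary"`.
#' @return Thresholded group-average adjacency matrix.
#' @export
group_average_fc <- function(cms, density = 0.10, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  if (length(cms) < 1) abort("Need at least one connectivity matrix.")
  dims <- vapply(cms, nrow, integer(1))
  if (length(unique(dims)) != 1 ||
      !all(vapply(cms, ncol, integer(1)) == dims[1])) {
    abort("All connectivity matrices must have the same dimensions.")
  }
  zs <- lapply(cms, function(m) if (fc_scale(m) == "fisher_z") m else fisher_z(m))
  zbar <- Reduce(`+`, zs) / length(zs)
  rbar <- tanh(zbar)
  diag(rbar) <- 0
  dimnames(rbar) <- dimnames(cms[[1]])
  attr(rbar, "scale") <- "pearson_r"
  proportional_threshold(rbar, density, mode)
}
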