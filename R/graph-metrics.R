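#' Shortest path lengths of a weighted network
#'
#' Path-based metrics treat strong connections as short: each edge's length is
#' the inverse of its weight (1 for binary graphs). Unreachable pairs get
#' `Inf`.
#'
#' @param net Nonnegative symmetric adjacency matrix.
#' @return Node-by-node distance matrix (zero diagonal).
#' @export
shortest_path_lengths <- function(net) {
  check_square_symmetric(net, arg = "net")
  if (any(net < 0)) abort("Edge weights must be nonnegative.")
  g <- as_igraph(net)
  if (igraph::ecount(g) == 0) {
    d <- matrix(Inf, nrow(net), ncol(net))
    diag(d) <- 0
    dimnames(d) <- dimnames(net)
    return(d)
  }
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

#' Characteristic path length
#'
#' Mean shortest path length over node pairs -- the network's primary
#' integration metric. Thresholded subject networks can fragment, so the mean
#' is taken over reachable pairs and a `disconnected` attribute flags when any
#' pair was unreachable.
#'
#' @param net Nonnegative symmetric adjacency matrix.
#' @return Scalar CPL with logical attribute `disconnected`.
#' @export
characteristic_path_length <- function(net) {
  d <- shortest_path_lengths(net)
  off <- d[upper.tri(d)]
  finite <- off[is.finite(off)]
  cpl <- if (length(finite)) mean(finite) else NA_real_
  attr(cpl, "disconnected") <- any(!is.finite(off))
  cpl
}

#' Global efficiency
#'
#' Mean inverse shortest path length over all pairs (`1/Inf = 0`), so it is
#' well-defined on disconnected graphs and bounded by 1.
#'
#' @param net Nonnegative symmetric adjacency matrix.
#' @return Scalar in `[0, 1]` for binary graphs.
#' @export
global_efficiency <- function(net) {
  d <- shortest_path_lengths(net)
  off <- d[upper.tri(d)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

#' Per-node clustering coefficient
#'
#' Binary graphs use the Watts-Strogatz triangle fraction; weighted graphs use
#' the Onnela geometric-mean triangle intensity (weights rescaled by the
#' maximum weight). Nodes with degree < 2 get 0.
#'
#' @param net Nonnegative symmetric adjacency matrix.
#' @return Named numeric vector of per-node clustering; summarize with
#'   `mean()`.
#' @export
clustering_coefficient <- function(net) {
  check_square_symmetric(net, arg = "net")
  if (any(net < 0)) abort("Edge weights must be nonnegative.")
  a <- (net != 0) * 1
  k <- rowSums(a)
  wmax <- max(net)
  if (wmax == 0) {
    return(setNames(rep(0, nrow(net)), node_labels(net)))
  }
  w3 <- (net / wmax)^(1 / 3)
  tri <- diag(w3 %*% w3 %*% w3)
  denom <- k * (k - 1)
  cc <- ifelse(denom > 0, tri / denom, 0)
  setNames(cc, node_labels(net))
}

#' Per-node local efficiency
#'
#' Global efficiency of the subgraph induced on each node's neighbors: how
#' well information would still flow locally if the node were removed. Nodes
#' with fewer than 2 neighbors get 0.
#'
#' @param net Nonnegative symmetric adjacency matrix.
#' @return Named numeric vector of per-node local efficiency.
#' @export
local_efficiency <- function(net) {
  check_square_symmetric(net, arg = "net")
  a <- net != 0
  eloc <- vapply(seq_len(nrow(net)), function(i) {
    nb <- which(a[i, ])
    if (length(nb) < 2) return(0)
    global_efficiency(net[nb, nb, drop = FALSE])
  }, numeric(1))
  setNames(eloc, node_labels(net))
}

#' Modularity of a partition
#'
#' Newman-Girvan Q generalized to weights:
#' `Q = sum_s (w_ss / W - (s_s / (2 W))^2)` with `W` the total edge weight,
#' `w_ss` module `s`'s internal weight and `s_s` its strength sum. Optionally
#' takes a resolution parameter multiplying the null term.
#'
#' @param net Nonnegative symmetric adjacency matrix.
#' @param membership Integer module label per node.
#' @param resolution Resolution parameter (default 1).
#' @return Scalar Q in `[-0.5, 1]`.
#' @export
modularity_q <- function(net, membership, resolution = 1) {
  check_square_symmetric(net, arg = "net")
  membership <- as.integer(membership)
  if (length(membership) != nrow(net) || anyNA(membership)) {
    abort("`membership` must label every node.")
  }
  w_tot <- sum(net) / 2
  if (w_tot <= 0) abort("Network has no edges.")
  strength <- rowSums(net)
  q <- 0
  for (s in unique(membership)) {
    in_s <- membership == s
    w_ss <- sum(net[in_s, in_s]) / 2
    s_s <- sum(strength[in_s])
    q <- q + w_ss / w_tot - resolution * (s_s / (2 * w_tot))^2
  }
  q
}

#' Maslov-Sneppen degree-preserving rewiring
#'
#' Randomizes topology by repeated double-edge swaps (a-b, c-d -> a-d, c-b),
#' rejecting self-loops and duplicate edges; weights travel with their edges.
#' The degree sequence is preserved exactly and the weight multiset is
#' untouched (node strengths are not preserved, matching the usual
#' connectome-null convention). About `iterations_per_edge * E` swaps are
#' attempted.
#'
#' @param net Nonnegative symmetric adjacency matrix with >= 2 edges.
#' @param iterations_per_edge Rewiring attempts per edge (default 20).
#' @param seed Optional seed.
#' @return Rewired adjacency matrix; attribute `rewired` is `FALSE` (with a
#'   warning) when no valid swap was found, in which case the input is
#'   returned unchanged.
#' @export
maslov_sneppen_rewire <- function(net, iterations_per_edge = 20, seed = NULL) {
  check_square_symmetric(net, arg = "net")
  el <- edge_list(net)
  if (length(el$w) < 2) abort("Rewiring needs at least 2 edges.")
  res <- with_seed(seed, .rewire_cpp(el$n, el$i - 1L, el$j - 1L, el$w,
                                     iterations_per_edge))
  if (res$n_swaps == 0) {
    warn("No valid degree-preserving swap found; returning the input network.")
    out <- net
    attr(out, "rewired") <- FALSE
    return(out)
  }
  out <- edges_to_matrix(res$edge_i + 1L, res$edge_j + 1L, res$edge_w,
                         el$n, node_labels(net))
  attr(out, "density") <- attr(net, "density")
  attr(out, "mode") <- attr(net, "mode")
  attr(out, "rewired") <- TRUE
  out
}

#' Small-worldness against degree-preserving nulls
#'
#' `sigma = (CC / <CC_null>) / (CPL / <CPL_null>)`, with the null means taken
#' over `n_null` Maslov-Sneppen rewirings. `sigma > 1` indicates the
#' lattice-like clustering / random-like path length regime.
#'
#' @param net Connected nonnegative symmetric adjacency matrix.
#' @param n_null Number of null networks (default 100).
#' @param iterations_per_edge Rewiring attempts per edge (default 20).
#' @param seed Optional seed (the whole ensemble is reproducible).
#' @return Scalar sigma.
#' @export
small_worldness <- function(net, n_null = 100, iterations_per_edge = 20,
                            seed = NULL) {
  cpl <- characteristic_path_length(net)
  if (isTRUE(attr(cpl, "disconnected"))) {
    abort("Small-worldness requires a connected network.")
  }
  cc <- mean(clustering_coefficient(net))
  with_seed(seed, {
    cc_null <- numeric(n_null)
    cpl_null <- numeric(n_null)
    any_fixed <- FALSE
    for (b in seq_len(n_null)) {
      rn <- withCallingHandlers(
        maslov_sneppen_rewire(net, iterations_per_edge = iterations_per_edge),
        warning = function(w) {
          any_fixed <<- TRUE
          invokeRestart("muffleWarning")
        }
      )
      cc_null[b] <- mean(clustering_coefficient(rn))
      cpl_null[b] <- as.numeric(characteristic_path_length(rn))
    }
    if (any_fixed) {
      warn("Null networks could not be rewired; sigma compares the network with itself.")
    }
    if (mean(cc_null) == 0) abort("Null clustering is zero; sigma undefined.")
    (cc / mean(cc_null)) / (as.numeric(cpl) / mean(cpl_null))
  })
}

#' Whole-brain global metrics of one thresholded network
#'
#' Convenience wrapper returning the integration/segregation summary used for
#' the density sweep: characteristic path length, global efficiency, mean
#' local efficiency, mean clustering, modularity (best of `n_louvain` Louvain
#' runs) and, optionally, small-worldness.
#'
#' @param net Nonnegative symmetric adjacency matrix.
#' @param n_louvain Louvain restarts for the modularity value.
#' @param sw_nulls Null networks for small-worldness; 0 skips it.
#' @param iterations_per_edge Rewiring attempts per edge for the nulls.
#' @param seed Optional seed.
#' @return One-row tibble: `cpl`, `e_glob`, `e_loc_mean`, `cc_mean`,
#'   `modularity_q`, `small_worldness` (NA when skipped), `disconnected`.
#' @export
global_metrics <- function(net, n_louvain = 100, sw_nulls = 0,
                           iterations_per_edge = 20, seed = NULL) {
  with_seed(seed, {
    cpl <- characteristic_path_length(net)
    best_q <- max(vapply(seq_len(n_louvain),
                         function(i) louvain(net)$q, numeric(1)))
    sw <- if (sw_nulls > 0) {
      small_worldness(net, n_null = sw_nulls,
                      iterations_per_edge = iterations_per_edge)
    } else {
      NA_real_
    }
    tibble::tibble(
      cpl = as.numeric(cpl),
      e_glob = global_efficiency(net),
      e_loc_mean = mean(local_efficiency(net)),
      cc_mean = mean(clustering_coefficient(net)),
      modularity_q = best_q,
      small_worldness = sw,
      disconnected = isTRUE(attr(cpl, "disconnected"))
    )
  })
}
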