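#' Louvain community detection
#'
#' Greedy two-phase Louvain maximizing weighted modularity at the given
#' resolution. The node sweep order is randomized from R's RNG, so results are
#' reproducible under `set.seed()` / `seed`. Modularity is asserted to be
#' non-decreasing across aggregation passes on every run.
#'
#' @param net Nonnegative symmetric adjacency matrix with at least one edge.
#' @param resolution Resolution parameter (1 recovers standard modularity).
#' @param seed Optional seed for the sweep order.
#' @return An `fcnet_partition`: `membership` (contiguous 1-based labels),
#'   `n_modules`, `q`, and the per-pass `q_trace`.
#' @export
louvain <- function(net, resolution = 1, seed = NULL) {
  check_square_symmetric(net, arg = "net")
  if (any(net < 0)) abort("Louvain requires nonnegative weights.")
  el <- edge_list(net)
  if (length(el$w) == 0) abort("Louvain requires a non-empty graph.")
  res <- with_seed(seed, .louvain_cpp(el$n, el$i - 1L, el$j - 1L, el$w,
                                      resolution))
  if (any(diff(res$q_trace) < -1e-9)) {
    abort("Internal error: modularity decreased across Louvain passes.")
  }
  new_partition(res$membership, q = res$q, q_trace = res$q_trace)
}

new_partition <- function(membership, q = NA_real_, q_trace = NULL) {
  membership <- as.integer(membership)
  structure(list(membership = membership,
                 n_modules = length(unique(membership)),
                 q = q, q_trace = q_trace),
            class = "fcnet_partition")
}

#' @export
print.fcnet_partition <- function(x, ...) {
  cat(sprintf("<fcnet_partition> %d nodes, %d modules, Q = %.4f\n",
              length(x$membership), x$n_modules, x$q))
  invisible(x)
}

#' @export
tidy.fcnet_partition <- function(x, ...) {
  tibble::tibble(node = seq_along(x$membership), module = x$membership)
}

#' Consensus Louvain partition
#'
#' Louvain is stochastic, so it is repeated `n_runs` times; the co-assignment
#' (agreement) matrix over runs is thresholded at `tau` and re-clustered
#' (again `n_runs` times), iterating until every run returns the same
#' partition. The returned Q is the modularity of the consensus partition on
#' the original network.
#'
#' @param net Nonnegative symmetric adjacency matrix.
#' @param n_runs Louvain repetitions per consensus iteration (study-scale
#'   default 1000).
#' @param tau Agreement threshold in (0, 1) (default 0.5).
#' @param resolution Louvain resolution.
#' @param seed Optional seed; the whole procedure is deterministic under it.
#' @param max_iter Consensus iterations allowed before erroring.
#' @return An `fcnet_consensus`: `partition` (an `fcnet_partition`) and
#'   `agreement` (the first-level co-assignment matrix).
#' @export
consensus_partition <- function(net, n_runs = 1000, tau = 0.5, resolution = 1,
                                seed = NULL, max_iter = 50) {
  if (n_runs < 1) abort("`n_runs` must be >= 1.")
  with_seed(seed, {
    run_once <- function(a) {
      # One edge-list extraction per consensus level, not per Louvain run.
      el <- edge_list(a)
      if (length(el$w) == 0) abort("Louvain requires a non-empty graph.")
      memb <- matrix(0L, nrow(a), n_runs)
      for (r in seq_len(n_runs)) {
        res <- .louvain_cpp(el$n, el$i - 1L, el$j - 1L, el$w, resolution)
        if (any(diff(res$q_trace) < -1e-9)) {
          abort("Internal error: modularity decreased across Louvain passes.")
        }
        memb[, r] <- res$membership
      }
      memb
    }
    agreement_of <- function(memb) {
      n <- nrow(memb)
      ag <- matrix(0, n, n)
      for (r in seq_len(ncol(memb))) {
        ind <- outer(memb[, r], memb[, r], "==")
        ag <- ag + ind
      }
      ag / ncol(memb)
    }
    all_identical <- function(memb) {
      all(apply(memb, 2, function(m) {
        isTRUE(all.equal(canonical_labels(m), canonical_labels(memb[, 1])))
      }))
    }

    a <- net
    first_agreement <- NULL
    for (iter in seq_len(max_iter)) {
      memb <- run_once(a)
      ag <- agreement_of(memb)
      if (is.null(first_agreement)) first_agreement <- ag
      if (all_identical(memb)) {
        final <- canonical_labels(memb[, 1])
        part <- new_partition(final, q = modularity_q(net, final, resolution))
        return(structure(list(partition = part, agreement = first_agreement),
                         class = "fcnet_consensus"))
      }
      a <- ag
      a[a < tau] <- 0
      diag(a) <- 0
      if (all(a == 0)) {
        abort("Consensus failed: thresholded agreement matrix is empty.")
      }
    }
    abort(sprintf("Consensus did not converge after %d iterations.", max_iter))
  })
}

# Relabel modules contiguously by first appearance, so partitions from
# different runs compare by value.
canonical_labels <- function(membership) {
  as.integer(factor(membership, levels = unique(membership)))
}

#' @export
print.fcnet_consensus <- function(x, ...) {
  cat("<fcnet_consensus>\n")
  print(x$partition)
  invisible(x)
}

#' @export
tidy.fcnet_consensus <- function(x, ...) tidy(x$partition)

#' @export
glance.fcnet_consensus <- function(x, ...) {
  tibble::tibble(n_modules = x$partition$n_modules, q = x$partition$q)
}
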