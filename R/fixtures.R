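#' Small analytic fixture graphs
#'
#' Deterministic (or seeded, for `planted_partition`) binary graphs with known
#' closed-form metric values, used as oracles for the graph-metric and
#' community modules.
#'
#' Families:
#' * `ring_lattice(n, k)`: each node linked to its `k` nearest neighbors
#'   (`k` even).
#' * `star(n)`: node 1 linked to the other `n - 1` nodes.
#' * `clique(n)`: complete graph.
#' * `two_cliques(n)`: two disconnected `n`-cliques (2n nodes).
#' * `planted_partition(n, n_modules, p_in, p_out)`: stochastic block model
#'   with equal-size blocks.
#' * `path(n)`: simple path.
#'
#' @param family One of `"ring_lattice"`, `"star"`, `"clique"`,
#'   `"two_cliques"`, `"planted_partition"`, `"path"`.
#' @param n Number of nodes (per clique for `two_cliques`).
#' @param k Neighborhood size for `ring_lattice` (even).
#' @param n_modules,p_in,p_out Planted-partition parameters.
#' @param seed Seed for the stochastic family.
#' @return A binary symmetric adjacency matrix (weights 1, zero diagonal) with
#'   a `density` attribute; `planted_partition` also carries a `membership`
#'   attribute with the planted block labels.
#' @export
fixture_graph <- function(family, n, k = 2L, n_modules = 2L,
                          p_in = 0.8, p_out = 0.1, seed = NULL) {
  adj <- switch(
    family,
    ring_lattice = {
      if (k %% 2 != 0 || k >= n) abort("ring_lattice needs even k < n.")
      a <- matrix(0, n, n)
      for (d in seq_len(k / 2)) {
        idx <- cbind(seq_len(n), (seq_len(n) + d - 1L) %% n + 1L)
        a[idx] <- 1
        a[idx[, 2:1]] <- 1
      }
      a
    },
    star = {
      if (n < 2) abort("star needs n >= 2.")
      a <- matrix(0, n, n)
      a[1, -1] <- 1
      a[-1, 1] <- 1
      a
    },
    clique = {
      a <- matrix(1, n, n)
      diag(a) <- 0
      a
    },
    two_cliques = {
      a <- matrix(0, 2 * n, 2 * n)
      a[seq_len(n), seq_len(n)] <- 1
      a[n + seq_len(n), n + seq_len(n)] <- 1
      diag(a) <- 0
      a
    },
    planted_partition = {
      if (n %% n_modules != 0) abort("planted_partition needs n divisible by n_modules.")
      memb <- rep(seq_len(n_modules), each = n / n_modules)
      same <- outer(memb, memb, "==")
      p <- ifelse(same, p_in, p_out)
      a <- with_seed(seed, {
        u <- matrix(0, n, n)
        u[upper.tri(u)] <- stats::runif(n * (n - 1) / 2)
        (u < p & upper.tri(u)) * 1
      })
      a <- a + t(a)
      attr(a, "membership") <- memb
      a
    },
    path = {
      a <- matrix(0, n, n)
      if (n > 1) {
        idx <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
        a[idx] <- 1
        a[idx[, 2:1]] <- 1
      }
      a
    },
    abort(sprintf("Unknown fixture family '%s'.", family))
  )
  nn <- nrow(adj)
  lb <- sprintf("p%03d", seq_len(nn))
  memb <- attr(adj, "membership")
  dimnames(adj) <- list(lb, lb)
  attr(adj, "density") <- sum(adj != 0) / (nn * (nn - 1))
  attr(adj, "mode") <- "binary"
  if (!is.null(memb)) attr(adj, "membership") <- memb
  adj
}
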