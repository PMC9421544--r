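# Brute-force oracles, independent of the package's implementation paths.

# All-pairs shortest paths by Floyd-Warshall with edge length 1/weight.
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && adj[i, j] > 0) d[i, j] <- 1 / adj[i, j]
    }
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_cpl <- function(adj) {
  d <- oracle_distances(adj)
  off <- d[upper.tri(d)]
  mean(off[is.finite(off)])
}

oracle_eglob <- function(adj) {
  d <- oracle_distances(adj)
  off <- d[upper.tri(d)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

# Per-node clustering: Watts-Strogatz for binary input, Onnela for weighted.
oracle_cc <- function(adj) {
  n <- nrow(adj)
  binary <- all(adj %in% c(0, 1))
  wmax <- max(adj)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    tot <- 0
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a == b) next
        ja <- nb[a]; jb <- nb[b]
        if (adj[ja, jb] > 0) {
          tot <- tot + if (binary) 1 else {
            ((adj[i, ja] / wmax) * (adj[i, jb] / wmax) * (adj[ja, jb] / wmax))^(1 / 3)
          }
        }
      }
    }
    cc[i] <- tot / (k * (k - 1))
  }
  cc
}

oracle_eloc <- function(adj) {
  n <- nrow(adj)
  el <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) next
    el[i] <- oracle_eglob(adj[nb, nb, drop = FALSE])
  }
  el
}

# Double-sum modularity: Q = (1/2W) sum_ij (A_ij - s_i s_j / (2W)) delta(c_i, c_j).
oracle_q <- function(adj, memb) {
  w2 <- sum(adj)
  s <- rowSums(adj)
  q <- 0
  n <- nrow(adj)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (memb[i] == memb[j]) q <- q + adj[i, j] - s[i] * s[j] / w2
    }
  }
  q / w2
}

# Benjamini-Hochberg step-up, written from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- val
    prev <- val
  }
  q
}

random_graph <- function(n, p = 0.5, weighted = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  on <- stats::runif(length(up)) < p
  a[up[on]] <- if (weighted) stats::runif(sum(on), 0.1, 1) else 1
  a + t(a)
}

nmi_of <- function(a, b) igraph::compare(a, b, method = "nmi")

as_igraph_test <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# Small cohort spec for structural pipeline tests (fast to simulate).
tiny_spec <- function(seed = 1, ...) {
  cohort_spec(n_per_group = c(6L, 6L), n_nodes = 30L, n_timepoints = 80L,
              n_modules = 3L, seed = seed, ...)
}

# Reduced-size analysis settings used by the simulation suites; the study-scale
# defaults are exercised structurally elsewhere.
sim_config <- function(seed = 1, ...) {
  pipeline_config(densities = c(0.10, 0.20, 0.30, 0.40),
                  subject_louvain_runs = 10, pcnorm_nulls = 0,
                  measures = c("pc", "wmz"), seed = seed, ...)
}

# Per-subject AUC table for a cohort under the reduced settings.
cohort_auc <- function(cohort, config, seed = 1) {
  purrr::map_dfr(names(cohort$ts), function(id) {
    cv <- nodal_curves(compute_fc(cohort$ts[[id]]), config,
                       seed = fcnet:::substream_seed(seed, "curves", id))
    dplyr::mutate(nodal_auc(cv), subject_id = id)
  })
}
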