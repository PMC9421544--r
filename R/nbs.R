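#' Network-based statistic (NBS)
#'
#' Connectome-wide two-sample inference with component-level family-wise error
#' control. Each edge's Fisher-z values are residualized on the (demeaned)
#' covariates, an unequal-variance t statistic is computed per edge, and the
#' two-tailed hypothesis is realized as two one-sided suprathreshold graphs
#' (`t > t_init` and `t < -t_init`). Connected components of suprathreshold
#' edges are the test statistics (size = edge count); their null distribution
#' is the maximal component size over `n_perm` group-label permutations of the
#' residuals, pooled over both directions, giving each observed component an
#' FWE-corrected p-value `(1 + #{max* >= size}) / (n_perm + 1)`.
#'
#' @param z_mats List of subject connectivity matrices on the Fisher-z scale
#'   (Pearson matrices are transformed automatically), in `design` row order.
#' @param design Tibble with `subject_id`, two-level `group`, and covariate
#'   columns.
#' @param covariates Covariate column names in `design` (default `"age"`).
#' @param t_init Initial edge threshold (> 0; study default 3.9856).
#' @param n_perm Permutations (study-scale default 10000).
#' @param seed Optional seed.
#' @param chunk_size Permutations processed per block (memory control).
#' @return An `fcnet_nbs` object: `components` tibble (id, direction,
#'   `n_edges`, `nodes`, `edges` list-column, `p_fwe`), the observed edgewise
#'   `t` matrix, and the null maximal-size distribution. `tidy()` returns the
#'   component table, `glance()` a one-row summary.
#' @export
nbs <- function(z_mats, design, covariates = "age", t_init = 3.9856,
                n_perm = 10000, seed = NULL, chunk_size = 250) {
  if (t_init <= 0) abort("`t_init` must be positive.")
  if (length(z_mats) != nrow(design)) {
    abort("`z_mats` must have one matrix per design row.")
  }
  n_nodes <- nrow(z_mats[[1]])
  labels <- node_labels(z_mats[[1]])
  ut <- upper.tri(matrix(0, n_nodes, n_nodes))
  edge_idx <- which(ut, arr.ind = TRUE)
  y <- t(vapply(z_mats, function(m) {
    if (fc_scale(m) == "pearson_r") m <- fisher_z(m)
    m[ut]
  }, numeric(sum(ut))))

  group <- as.factor(design$group)
  if (nlevels(group) != 2) abort("`group` must have exactly two levels.")
  g1 <- group == levels(group)[1]
  cov <- if (length(covariates)) design[, covariates, drop = FALSE] else NULL
  r <- residualize(y, cov)

  obs <- welch_t_perm(r, g1)$t_obs

  comp_sizes <- function(t_vec) {
    sup_pos <- which(t_vec > t_init)
    sup_neg <- which(t_vec < -t_init)
    size_of <- function(sup) {
      if (length(sup) == 0) return(integer(0))
      g <- igraph::graph_from_edgelist(edge_idx[sup, , drop = FALSE],
                                       directed = FALSE)
      memb <- igraph::components(g)$membership
      comp_e <- table(memb[edge_idx[sup, 1]])
      as.integer(comp_e)
    }
    max(c(0L, size_of(sup_pos), size_of(sup_neg)))
  }

  null_max <- with_seed(seed, {
    ind <- perm_schedule(length(g1), sum(g1), n_perm)
    out <- integer(n_perm)
    for (start in seq(1, n_perm, by = chunk_size)) {
      rows <- start:min(start + chunk_size - 1, n_perm)
      tp <- welch_t_perm(r, g1, ind[rows, , drop = FALSE])$t_perm
      out[rows] <- apply(tp, 1, comp_sizes)
    }
    out
  })

  observed_components <- function(direction) {
    sup <- if (direction == "positive") which(obs > t_init) else which(obs < -t_init)
    if (length(sup) == 0) return(NULL)
    g <- igraph::graph_from_edgelist(edge_idx[sup, , drop = FALSE],
                                     directed = FALSE)
    memb <- igraph::components(g)$membership
    comp_of_edge <- memb[edge_idx[sup, 1]]
    purrr::map(sort(unique(comp_of_edge)), function(cid) {
      e <- sup[comp_of_edge == cid]
      nodes <- sort(unique(as.integer(edge_idx[e, ])))
      edges <- tibble::tibble(from = edge_idx[e, 1], to = edge_idx[e, 2],
                              t = obs[e])
      list(direction = direction, n_edges = length(e), nodes = nodes,
           edges = edges)
    })
  }
  comps <- c(observed_components("positive"), observed_components("negative"))
  components <- if (length(comps) == 0) {
    tibble::tibble(component = integer(0), direction = character(0),
                   n_edges = integer(0), nodes = list(), edges = list(),
                   p_fwe = numeric(0))
  } else {
    tibble::tibble(
      component = seq_along(comps),
      direction = vapply(comps, `[[`, character(1), "direction"),
      n_edges = vapply(comps, `[[`, integer(1), "n_edges"),
      nodes = purrr::map(comps, "nodes"),
      edges = purrr::map(comps, "edges"),
      p_fwe = vapply(comps, function(cc) {
        (1 + sum(null_max >= cc$n_edges)) / (n_perm + 1)
      }, numeric(1))
    ) |>
      dplyr::arrange(dplyr::desc(n_edges))
  }
  t_mat <- matrix(0, n_nodes, n_nodes, dimnames = list(labels, labels))
  t_mat[ut] <- obs
  t_mat <- t_mat + t(t_mat)
  structure(list(components = components, t_matrix = t_mat,
                 null_max = null_max, t_init = t_init, n_perm = n_perm,
                 groups = levels(group)),
            class = "fcnet_nbs")
}

#' @export
print.fcnet_nbs <- function(x, ...) {
  cat(sprintf("<fcnet_nbs> t_init = %.4f, %d permutations, %d suprathreshold component(s)\n",
              x$t_init, x$n_perm, nrow(x$components)))
  if (nrow(x$components)) {
    print(dplyr::select(x$components, component, direction, n_edges, p_fwe))
  }
  invisible(x)
}

#' @export
tidy.fcnet_nbs <- function(x, ...) {
  dplyr::select(x$components, component, direction, n_edges, p_fwe)
}

#' @export
glance.fcnet_nbs <- function(x, ...) {
  tibble::tibble(
    n_components = nrow(x$components),
    n_significant = sum(x$components$p_fwe < 0.05),
    min_p_fwe = if (nrow(x$components)) min(x$components$p_fwe) else NA_real_,
    t_init = x$t_init,
    n_perm = x$n_perm
  )
}
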