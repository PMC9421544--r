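#' Within-module degree z-score (WMZ)
#'
#' How strongly a node connects inside its own module, standardized against
#' the other nodes of that module: `(k_i(s) - mean_s) / sd_s` with `k_i(s)`
#' node i's within-module strength and the sample mean/sd over module `s`.
#' Modules with zero spread (or singletons) give 0.
#'
#' @param net Nonnegative symmetric adjacency matrix.
#' @param membership Module label per node (e.g. from [consensus_partition()]).
#' @return Named numeric vector of z-scores.
#' @export
within_module_zscore <- function(net, membership) {
  check_square_symmetric(net, arg = "net")
  membership <- as.integer(membership)
  if (length(membership) != nrow(net) || anyNA(membership)) {
    abort("`membership` must label every node.")
  }
  wmz <- numeric(nrow(net))
  for (s in unique(membership)) {
    in_s <- which(membership == s)
    k_in <- rowSums(net[in_s, in_s, drop = FALSE])
    if (length(in_s) < 2) {
      wmz[in_s] <- 0
      next
    }
    s_s <- stats::sd(k_in)
    wmz[in_s] <- if (is.na(s_s) || s_s == 0) 0 else (k_in - mean(k_in)) / s_s
  }
  setNames(wmz, node_labels(net))
}

#' Participation coefficient (PC)
#'
#' Dispersion of a node's strength across modules:
#' `pc_i = 1 - sum_s (k_is / k_i)^2`. 0 means all edges stay inside one
#' module; the upper bound is `1 - 1/M` at a perfectly even split over the M
#' modules. Isolated nodes get 0.
#'
#' @inheritParams within_module_zscore
#' @return Named numeric vector in `[0, 1 - 1/M]`.
#' @export
participation_coefficient <- function(net, membership) {
  check_square_symmetric(net, arg = "net")
  membership <- as.integer(membership)
  if (length(membership) != nrow(net) || anyNA(membership)) {
    abort("`membership` must label every node.")
  }
  mods <- sort(unique(membership))
  ind <- outer(membership, mods, "==") * 1
  k_s <- net %*% ind
  k <- rowSums(net)
  pc <- ifelse(k > 0, 1 - rowSums((k_s / pmax(k, .Machine$double.eps))^2), 0)
  setNames(as.numeric(pc), node_labels(net))
}

#' Null-normalized participation coefficient (PC_norm)
#'
#' Raw PC is contaminated by within-module degree: a node with many
#' intramodular edges gets a low PC even when its between-module edges are
#' widely dispersed. PC_norm discounts that dependence by comparing each
#' node's PC with its PC distribution over `n_null` degree-preserving
#' randomizations in which only the between-module edges are rewired (the
#' within-module connections, and hence every node's within-module strength,
#' are preserved exactly):
#' `pc_norm_i = clip(pc_i / median_b pc_i^(b), 0, 1)`. A node whose
#' between-module edges are as dispersed as chance scores ~1; concentrated
#' (provincial) profiles score near 0; nodes with no between-module strength
#' score 0. Deterministic under `seed`.
#'
#' @inheritParams within_module_zscore
#' @param n_null Number of null networks (study-scale default 1000).
#' @param iterations_per_edge Rewiring attempts per between-module edge.
#' @param seed Optional seed.
#' @return Named numeric vector in `[0, 1]`. If the network admits no valid
#'   between-module rewiring, raw PC is returned with a warning.
#' @export
normalized_participation_coefficient <- function(net, membership,
                                                 n_null = 1000,
                                                 iterations_per_edge = 20,
                                                 seed = NULL) {
  if (n_null < 1) abort("`n_null` must be >= 1.")
  membership <- as.integer(membership)
  pc <- participation_coefficient(net, membership)
  with_seed(seed, {
    el <- edge_list(net)
    n_between <- sum(membership[el$i] != membership[el$j])
    if (n_between < 2) {
      warn("Too few between-module edges to rewire; returning raw participation coefficient.")
      return(pc)
    }
    pc_null <- matrix(NA_real_, nrow(net), n_null)
    any_rewired <- FALSE
    for (b in seq_len(n_null)) {
      res <- .rewire_between_cpp(el$n, el$i - 1L, el$j - 1L, el$w,
                                 membership - 1L, iterations_per_edge)
      if (res$n_swaps > 0) any_rewired <- TRUE
      rn <- edges_to_matrix(res$edge_i + 1L, res$edge_j + 1L, res$edge_w,
                            el$n)
      pc_null[, b] <- participation_coefficient(rn, membership)
    }
    if (!any_rewired) {
      warn("Network cannot be rewired; returning raw participation coefficient.")
      return(pc)
    }
    med <- apply(pc_null, 1, median)
    out <- ifelse(med > 0, pc / med, 0)
    setNames(pmin(pmax(out, 0), 1), names(pc))
  })
}

#' Classify nodes into hub roles
#'
#' Quadrant rule on WMZ and PC_norm: connector hub (`WMZ > 1` and
#' `PC_norm > 0.5`), provincial hub (`WMZ > 1` and `PC_norm < 0.5`), and the
#' corresponding non-hub roles for `WMZ <= 1`. Inequalities are strict; exact
#' boundary values fall to the non-hub / provincial side (conservative).
#'
#' @param wmz,pc_norm Numeric vectors of equal length.
#' @return Factor with levels `connector_hub`, `provincial_hub`,
#'   `connector_non_hub`, `provincial_non_hub`.
#' @export
classify_hubs <- function(wmz, pc_norm) {
  if (length(wmz) != length(pc_norm) || anyNA(wmz) || anyNA(pc_norm)) {
    abort("`wmz` and `pc_norm` must be complete vectors of equal length.")
  }
  role <- ifelse(wmz > 1,
                 ifelse(pc_norm > 0.5, "connector_hub", "provincial_hub"),
                 ifelse(pc_norm > 0.5, "connector_non_hub", "provincial_non_hub"))
  factor(role, levels = c("connector_hub", "provincial_hub",
                          "connector_non_hub", "provincial_non_hub"))
}

#' Per-node hub table for one network and partition
#'
#' Computes WMZ, PC and PC_norm under the given partition and assigns hub
#' roles -- the per-node summary behind hub reports and group comparisons.
#'
#' @inheritParams normalized_participation_coefficient
#' @param partition An `fcnet_partition`/`fcnet_consensus` or a membership
#'   vector.
#' @param parcel_table Optional tibble (`node_id`, `label`, `hemisphere`,
#'   `functional_network`) merged into the output.
#' @return Tibble: `node`, `label`, `module`, `wmz`, `pc`, `pc_norm`, `role`
#'   (plus parcel columns when supplied).
#' @export
hub_table <- function(net, partition, n_null = 1000, iterations_per_edge = 20,
                      seed = NULL, parcel_table = NULL) {
  membership <- partition_membership(partition)
  wmz <- within_module_zscore(net, membership)
  pc <- participation_coefficient(net, membership)
  pcn <- normalized_participation_coefficient(
    net, membership, n_null = n_null,
    iterations_per_edge = iterations_per_edge, seed = seed
  )
  out <- tibble::tibble(
    node = seq_len(nrow(net)),
    label = node_labels(net),
    module = as.integer(membership),
    wmz = as.numeric(wmz),
    pc = as.numeric(pc),
    pc_norm = as.numeric(pcn),
    role = classify_hubs(wmz, pcn)
  )
  if (!is.null(parcel_table)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(parcel_table, node_id, dplyr::any_of(c("hemisphere", "functional_network"))),
      by = c(node = "node_id")
    )
  }
  out
}

partition_membership <- function(partition) {
  if (inherits(partition, "fcnet_consensus")) return(partition$partition$membership)
  if (inherits(partition, "fcnet_partition")) return(partition$membership)
  as.integer(partition)
}

#' Per-module summary of size and hub roles
#'
#' One row per module: node count, connector/provincial hub counts and the
#' hemisphere-prefixed ROI lists (e.g. `"L 1,6,62; R 290,322"`), mirroring the
#' usual modular-properties report table.
#'
#' @param hub_tbl A [hub_table()] tibble.
#' @param parcel_table Optional parcel table supplying `hemisphere` when the
#'   hub table lacks it.
#' @return Tibble: `module`, `n_nodes`, `n_connector`, `n_provincial`,
#'   `connector_rois`, `provincial_rois`.
#' @export
module_summary <- function(hub_tbl, parcel_table = NULL) {
  tbl <- hub_tbl
  if (!"hemisphere" %in% names(tbl)) {
    if (!is.null(parcel_table)) {
      tbl <- dplyr::left_join(tbl,
                              dplyr::select(parcel_table, node_id, hemisphere),
                              by = c(node = "node_id"))
    } else {
      tbl$hemisphere <- NA_character_
    }
  }
  roi_string <- function(nodes, hemi) {
    if (length(nodes) == 0) return("")
    if (all(is.na(hemi))) return(paste(nodes, collapse = ","))
    parts <- vapply(c("L", "R"), function(h) {
      ns <- nodes[!is.na(hemi) & hemi == h]
      if (length(ns) == 0) "" else paste(h, paste(ns, collapse = ","))
    }, character(1))
    paste(parts[parts != ""], collapse = "; ")
  }
  tbl |>
    dplyr::group_by(module) |>
    dplyr::summarise(
      n_nodes = dplyr::n(),
      n_connector = sum(role == "connector_hub"),
      n_provincial = sum(role == "provincial_hub"),
      connector_rois = roi_string(node[role == "connector_hub"],
                                  hemisphere[role == "connector_hub"]),
      provincial_rois = roi_string(node[role == "provincial_hub"],
                                   hemisphere[role == "provincial_hub"]),
      .groups = "drop"
    )
}
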