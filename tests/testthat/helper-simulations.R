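# Shared replicate simulations, computed once per test run and reused by the
# blocks that assert different aspects of the same study conditions.

.sim_cache <- new.env(parent = emptyenv())

# 50 replicate cohorts at the default study conditions; for each one, nodal
# and behavior suites on PC/WMZ AUCs plus the group-average consensus NMI.
power_sim <- function(n_cohorts = 50) {
  key <- paste0("power_", n_cohorts)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  res <- purrr::map_dfr(seq_len(n_cohorts), function(r) {
    co <- generate_cohort(cohort_spec(seed = 20000 + r))
    cfg <- sim_config(seed = r)
    aucs <- cohort_auc(co, cfg, seed = r)
    ns <- nodal_test_suite(aucs, co$design, n_perm = 9999, seed = r)
    bs <- behavior_correlation_suite(aucs, co$design, n_perm = 19999, seed = r)
    grp <- group_average_fc(
      lapply(co$ts[co$design$subject_id[co$design$group == "control_like"]],
             compute_fc),
      density = 0.10
    )
    cp <- consensus_partition(grp, n_runs = 100, seed = r)
    beh <- bs[bs$node == co$truth$behavior_node & bs$measure == "pc", ]
    tibble::tibble(
      replicate = r,
      effect_hit = any(ns$significant & ns$node %in% co$truth$effect_nodes),
      false_nodes = sum(ns$significant & !ns$node %in% co$truth$effect_nodes),
      behavior_r = beh$estimate,
      behavior_hit = beh$significant && beh$estimate > 0,
      recovery_nmi = nmi_of(cp$partition$membership, co$truth$partition),
      n_modules = cp$partition$n_modules
    )
  })
  .sim_cache[[key]] <- res
  res
}

# Null cohorts: no planted effect, no behavior coupling.
null_cohort_sim <- function(n_cohorts = 10) {
  key <- paste0("null_", n_cohorts)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  res <- purrr::map_dfr(seq_len(n_cohorts), function(r) {
    co <- generate_cohort(cohort_spec(seed = 30000 + r, effect_delta = 0,
                                      rho_behavior = 0))
    cfg <- sim_config(seed = r)
    aucs <- cohort_auc(co, cfg, seed = r)
    ns <- nodal_test_suite(aucs, co$design, n_perm = 9999, seed = r)
    tibble::tibble(replicate = r,
                   n_significant = sum(ns$significant),
                   p_values = list(ns$p))
  })
  .sim_cache[[key]] <- res
  res
}

# Simple edge-level two-group generator for NBS checks: subject matrices are
# Gaussian noise on the Fisher-z scale, optionally with a planted connected
# component of shifted edges in one group.
nbs_sim_data <- function(n1, n2, n_nodes, effect_edges = NULL, delta = 0,
                         seed = 1) {
  set.seed(seed)
  lb <- sprintf("p%03d", seq_len(n_nodes))
  design <- tibble::tibble(
    subject_id = sprintf("s%02d", seq_len(n1 + n2)),
    group = rep(c("g1", "g2"), c(n1, n2)),
    age = rnorm(n1 + n2, 11, 1.5)
  )
  mats <- lapply(seq_len(n1 + n2), function(s) {
    m <- matrix(0, n_nodes, n_nodes, dimnames = list(lb, lb))
    z <- rnorm(n_nodes * (n_nodes - 1) / 2, 0.3, 0.15)
    m[upper.tri(m)] <- z
    m <- m + t(m)
    if (!is.null(effect_edges) && design$group[s] == "g2") {
      for (e in seq_len(nrow(effect_edges))) {
        i <- effect_edges[e, 1]; j <- effect_edges[e, 2]
        m[i, j] <- m[i, j] + delta
        m[j, i] <- m[i, j]
      }
    }
    attr(m, "scale") <- "fisher_z"
    m
  })
  list(mats = mats, design = design)
}
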