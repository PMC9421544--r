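#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with the study-scale
#' defaults: the 10--40% density grid, weighted networks, 100 small-world
#' nulls, 1000 PC_norm nulls, 1000 Louvain runs for the group consensus (a
#' lighter `subject_louvain_runs` for the per-subject-per-density partitions),
#' 20000 nodal and 10000 NBS permutations, and the NBS edge threshold
#' `t_init = 3.9856`. Smaller values are appropriate for demonstrations and
#' simulation studies; the statistical contracts do not change.
#'
#' @param densities Density grid for the nodal sweep.
#' @param mode `"weighted"` or `"binary"` networks.
#' @param group_density Density of the group-averaged network used for
#'   community detection and hub classification (default 0.10).
#' @param sw_nulls Null networks per small-worldness estimate (0 skips SW).
#' @param pcnorm_nulls Null networks for PC_norm.
#' @param louvain_runs Louvain repetitions for the group consensus partition.
#' @param subject_louvain_runs Louvain repetitions for each subject-density
#'   consensus partition.
#' @param tau Consensus agreement threshold.
#' @param resolution Louvain resolution.
#' @param nodal_perms,nbs_perms,behavior_perms Permutation counts.
#' @param t_init NBS initial edge threshold.
#' @param fdr_q FDR level for nodal and behavioral suites.
#' @param alpha FWE level for NBS reporting.
#' @param measures Nodal measures carried through AUC and group tests.
#' @param seed Top-level seed; all stage seeds are derived substreams.
#' @return A `pipeline_config` list with a `hash` attribute that changes iff
#'   any parameter changes.
#' @export
pipeline_config <- function(densities = density_grid(),
                            mode = "weighted",
                            group_density = 0.10,
                            sw_nulls = 100,
                            pcnorm_nulls = 1000,
                            louvain_runs = 1000,
                            subject_louvain_runs = 100,
                            tau = 0.5,
                            resolution = 1,
                            nodal_perms = 20000,
                            nbs_perms = 10000,
                            behavior_perms = 20000,
                            t_init = 3.9856,
                            fdr_q = 0.05,
                            alpha = 0.05,
                            measures = c("pc", "pc_norm", "wmz"),
                            seed = 1L) {
  cfg <- list(densities = densities, mode = mode, group_density = group_density,
              sw_nulls = sw_nulls, pcnorm_nulls = pcnorm_nulls,
              louvain_runs = louvain_runs,
              subject_louvain_runs = subject_louvain_runs, tau = tau,
              resolution = resolution, nodal_perms = nodal_perms,
              nbs_perms = nbs_perms, behavior_perms = behavior_perms,
              t_init = t_init, fdr_q = fdr_q, alpha = alpha,
              measures = measures, seed = as.integer(seed))
  counts <- unlist(cfg[c("sw_nulls", "pcnorm_nulls", "louvain_runs",
                         "subject_louvain_runs", "nodal_perms", "nbs_perms",
                         "behavior_perms")])
  if (any(counts < 0)) abort("Counts in the configuration must be nonnegative.")
  if (any(cfg$densities <= 0 | cfg$densities > 1)) {
    abort("Densities must lie in (0, 1].")
  }
  attr(cfg, "hash") <- rlang::hash(cfg)
  structure(cfg, class = "pipeline_config")
}

#' Nodal measure curves for one subject across the density grid
#'
#' Thresholds the subject's connectivity matrix at each density, finds that
#' network's consensus partition, and evaluates the requested nodal measures
#' under it (the AUC summaries therefore reflect subject-specific modular
#' structure at every density).
#'
#' @param cm Subject connectivity matrix (Pearson scale).
#' @param config A [pipeline_config()].
#' @param seed Seed for this subject's partitions and nulls.
#' @return Long tibble: `density`, `node`, `measure`, `value`.
#' @export
nodal_curves <- function(cm, config = pipeline_config(), seed = NULL) {
  purrr::map_dfr(config$densities, function(d) {
    net <- proportional_threshold(cm, d, mode = config$mode)
    d_seed <- substream_seed(seed %||% 0L, "partition", format(d))
    cp <- consensus_partition(net, n_runs = config$subject_louvain_runs,
                              tau = config$tau,
                              resolution = config$resolution, seed = d_seed)
    memb <- cp$partition$membership
    vals <- list()
    if ("pc" %in% config$measures) {
      vals$pc <- participation_coefficient(net, memb)
    }
    if ("pc_norm" %in% config$measures) {
      vals$pc_norm <- normalized_participation_coefficient(
        net, memb, n_null = config$pcnorm_nulls,
        seed = substream_seed(seed %||% 0L, "pcnorm", format(d))
      )
    }
    if ("wmz" %in% config$measures) {
      vals$wmz <- within_module_zscore(net, memb)
    }
    purrr::imap_dfr(vals, function(v, nm) {
      tibble::tibble(density = d, node = seq_along(v), measure = nm,
                     value = as.numeric(v))
    })
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Collapse nodal curves to per-node AUC summaries
#'
#' @param curves Output of [nodal_curves()] (optionally with a `subject_id`
#'   column).
#' @return Tibble with one AUC per (subject,) node and measure.
#' @export
nodal_auc <- function(curves) {
  grp <- intersect(c("subject_id", "node", "measure"), names(curves))
  curves |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::arrange(density, .by_group = TRUE) |>
    dplyr::summarise(auc = auc_over_densities(value, density),
                     .groups = "drop")
}

#' Run the full group-comparison pipeline
#'
#' Executes every stage in order on a cohort: subject connectomes (Pearson and
#' Fisher-z), group-averaged networks at `group_density` with consensus
#' partitions, hub tables and module summaries per group, per-subject nodal
#' measure curves across the density grid, AUC summaries, the nuisance-adjusted
#' nodal permutation suite with joint FDR, the network-based statistic, and
#' the behavior partial-correlation suite. Subjects are processed in
#' `subject_id` order and all randomness is derived from `config$seed` through
#' named substreams, so reruns (and subject-order permutations) reproduce the
#' same outputs.
#'
#' @param cohort A [generate_cohort()] result, or a list with elements `ts`
#'   (named list of time-series matrices) and `design` (tibble with
#'   `subject_id`, `group`, `age`, and optionally `score`).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, tables and matrices are
#'   written as tab-separated text with a provenance sidecar (config hash,
#'   seed, stage counts).
#' @param parcel_table Optional parcel table for reporting.
#' @return A `fcnet_pipeline` list: `fc`, `group_networks`,
#'   `group_partitions`, `hub_tables`, `module_summaries`, `auc`,
#'   `nodal_stats`, `nbs`, `behavior_stats`, `provenance`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL,
                         parcel_table = NULL) {
  if (!all(c("ts", "design") %in% names(cohort))) {
    abort("`cohort` must carry `ts` and `design`.")
  }
  design <- dplyr::arrange(cohort$design, subject_id)
  ids <- design$subject_id
  if (!all(ids %in% names(cohort$ts))) {
    abort("Every design subject needs a time-series matrix.")
  }
  seed <- config$seed

  fc <- lapply(ids, function(id) compute_fc(cohort$ts[[id]]))
  names(fc) <- ids
  zc <- lapply(fc, fisher_z)

  groups <- sort(unique(design$group))
  group_networks <- lapply(groups, function(g) {
    group_average_fc(zc[design$group == g], density = config$group_density,
                     mode = config$mode)
  })
  names(group_networks) <- groups
  group_partitions <- lapply(groups, function(g) {
    consensus_partition(group_networks[[g]], n_runs = config$louvain_runs,
                        tau = config$tau, resolution = config$resolution,
                        seed = substream_seed(seed, "consensus", g))
  })
  names(group_partitions) <- groups
  hub_tables <- lapply(groups, function(g) {
    hub_table(group_networks[[g]], group_partitions[[g]],
              n_null = config$pcnorm_nulls,
              seed = substream_seed(seed, "hubs", g),
              parcel_table = parcel_table)
  })
  names(hub_tables) <- groups
  module_summaries <- lapply(hub_tables, module_summary,
                             parcel_table = parcel_table)

  curves <- purrr::map_dfr(ids, function(id) {
    dplyr::mutate(
      nodal_curves(fc[[id]], config,
                   seed = substream_seed(seed, "nodal", id)),
      subject_id = id, .before = 1
    )
  })
  auc_tbl <- nodal_auc(curves)

  nodal_stats <- nodal_test_suite(auc_tbl, design, covariates = "age",
                                  n_perm = config$nodal_perms,
                                  q = config$fdr_q,
                                  seed = substream_seed(seed, "nodal_test"))

  nbs_res <- nbs(zc, design, covariates = "age", t_init = config$t_init,
                 n_perm = config$nbs_perms,
                 seed = substream_seed(seed, "nbs"))

  behavior_stats <- NULL
  if ("score" %in% names(design) && sum(!is.na(design$score)) >= 4) {
    behavior_stats <- behavior_correlation_suite(
      auc_tbl, design, score = "score", covariates = c("age", "group"),
      n_perm = config$behavior_perms, q = config$fdr_q,
      seed = substream_seed(seed, "behavior")
    )
  }

  provenance <- list(
    config_hash = attr(config, "hash"),
    seed = seed,
    n_subjects = length(ids),
    n_nodes = nrow(fc[[1]]),
    n_densities = length(config$densities),
    groups = as.list(table(design$group))
  )
  result <- structure(
    list(fc = fc, group_networks = group_networks,
         group_partitions = group_partitions, hub_tables = hub_tables,
         module_summaries = module_summaries, curves = curves, auc = auc_tbl,
         nodal_stats = nodal_stats, nbs = nbs_res,
         behavior_stats = behavior_stats, design = design,
         config = config, provenance = provenance),
    class = "fcnet_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline(result, out_dir)
  result
}

#' @export
print.fcnet_pipeline <- function(x, ...) {
  cat(sprintf("<fcnet_pipeline> %d subjects, %d nodes, %d densities\n",
              x$provenance$n_subjects, x$provenance$n_nodes,
              x$provenance$n_densities))
  cat(sprintf("  nodal tests: %d significant at q < %.2f\n",
              sum(x$nodal_stats$significant), x$config$fdr_q))
  cat(sprintf("  NBS: %d suprathreshold component(s)\n",
              nrow(x$nbs$components)))
  invisible(x)
}

# Write all tabular pipeline outputs plus a provenance sidecar.
write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(result$group_networks)) {
    write_matrix(result$group_networks[[g]],
                 file.path(out_dir, sprintf("group_%s_density%s_adjacency.tsv",
                                            g, format(result$config$group_density))))
    readr::write_tsv(result$hub_tables[[g]] |>
                       dplyr::mutate(role = as.character(role)),
                     file.path(out_dir, sprintf("hub_table_%s.tsv", g)))
    readr::write_tsv(result$module_summaries[[g]],
                     file.path(out_dir, sprintf("module_summary_%s.tsv", g)))
  }
  readr::write_tsv(result$auc, file.path(out_dir, "nodal_auc.tsv"))
  readr::write_tsv(result$nodal_stats, file.path(out_dir, "nodal_stats.tsv"))
  readr::write_tsv(tidy(result$nbs), file.path(out_dir, "nbs_components.tsv"))
  if (!is.null(result$behavior_stats)) {
    readr::write_tsv(result$behavior_stats,
                     file.path(out_dir, "behavior_stats.tsv"))
  }
  prov <- result$provenance
  writeLines(
    c(paste0("config_hash: ", prov$config_hash),
      paste0("seed: ", prov$seed),
      paste0("n_subjects: ", prov$n_subjects),
      paste0("n_nodes: ", prov$n_nodes),
      paste0("n_densities: ", prov$n_densities)),
    file.path(out_dir, "provenance.txt")
  )
  invisible(out_dir)
}

#' Write / read a pipeline configuration as structured text
#'
#' Key-value YAML serialization of a [pipeline_config()]; reading rebuilds the
#' config through the constructor, so validation reruns and the hash is
#' recomputed (identical parameters give an identical hash).
#'
#' @param config A [pipeline_config()].
#' @param path File path (YAML).
#' @return `write_config()` returns `path` invisibly; `read_config()` returns
#'   a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}
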