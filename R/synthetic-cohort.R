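#' Specify a synthetic two-group resting-state cohort
#'
#' Defines the generative conditions for a two-group cohort of parcellated
#' BOLD-like time series: a block-modular correlation structure, planted hub
#' nodes with elevated cross-module loading, a localized group difference in
#' between-module coupling, an age covariate offset between groups, and a
#' behavioral score coupled to one node's between-module loading. The defaults
#' emulate a 28 vs 29 child case-control study with 250 timepoints per subject
#' and five functional modules, at a desk-scale 90-node parcellation.
#'
#' @param n_per_group Integer vector of length 2: subjects in the effect
#'   ("apd_like") and reference ("control_like") groups.
#' @param n_nodes Number of parcels (network nodes).
#' @param n_timepoints Timepoints per subject (BOLD volumes).
#' @param n_modules Number of planted modules.
#' @param module_sizes Optional integer vector summing to `n_nodes`; defaults
#'   to an even split.
#' @param within_r Target mean within-module correlation, in (0, 1).
#' @param between_r Target between-module correlation, in `[0, within_r)`.
#' @param within_decay Distance decay of within-module correlation on the
#'   module's circular node order (`corr(d) = between_r + a * within_decay^(d-1)`
#'   with `a` set so the module mean equals `within_r`). The default 0.85
#'   emulates the spatial autocorrelation of parcellated BOLD -- neighboring
#'   parcels correlate more -- which grades edge weights so proportional
#'   thresholding keeps every node's strongest local edges instead of cutting
#'   uniformly into identical weights. `within_decay = 1` gives homogeneous
#'   blocks (all within-module entries exactly `within_r`).
#' @param hub_nodes Node ids given elevated cross-module loading (default: the
#'   first node of each module).
#' @param hub_boost Increment added to hub nodes' between-module correlations.
#'   The default (`within_r - between_r`) raises hub cross-module coupling to
#'   the within-module level -- the defining feature of connector hubs, and
#'   what keeps the top-density group network in one connected piece.
#' @param effect_nodes Node ids where the effect group's between-module
#'   coupling is shifted by `effect_delta` (default: the second node of the
#'   first three modules).
#' @param effect_base Baseline increment of the effect nodes' between-module
#'   coupling in both groups, so they carry measurable between-module
#'   connectivity for the shift to act on.
#' @param effect_delta Shift (correlation units) applied to `effect_nodes`'
#'   between-module entries in the effect group. Negative values emulate
#'   reduced between-module integration.
#' @param behavior_node Node whose between-module loading co-varies with the
#'   behavioral score (default: the second node of the fourth module).
#' @param behavior_base Baseline increment of the behavior node's
#'   between-module coupling (same rationale as `effect_base`).
#' @param rho_behavior Target correlation between the behavioral score and the
#'   planted per-subject loading jitter at `behavior_node`.
#' @param behavior_jitter_sd Standard deviation of the per-subject jitter of
#'   `behavior_node`'s between-module loading.
#' @param age_mean,age_sd Mean/SD of age (years) in the effect group.
#' @param age_shift Mean age difference added to the reference group (years).
#' @param seed Integer seed making the cohort fully reproducible.
#'
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = c(28L, 29L),
                        n_nodes = 90L,
                        n_timepoints = 250L,
                        n_modules = 5L,
                        module_sizes = NULL,
                        within_r = 0.5,
                        between_r = 0.1,
                        within_decay = 0.85,
                        hub_nodes = NULL,
                        hub_boost = NULL,
                        effect_nodes = NULL,
                        effect_base = 0.25,
                        effect_delta = -0.15,
                        behavior_node = NULL,
                        behavior_base = 0.22,
                        rho_behavior = 0.6,
                        behavior_jitter_sd = 0.10,
                        age_mean = 10.9,
                        age_sd = 1.5,
                        age_shift = 1.0,
                        seed = 1L) {
  if (length(n_per_group) != 2L || any(n_per_group < 1)) {
    abort("`n_per_group` must be two positive counts.")
  }
  if (is.null(module_sizes)) {
    base <- n_nodes %/% n_modules
    module_sizes <- rep(base, n_modules)
    extra <- n_nodes - sum(module_sizes)
    if (extra > 0) module_sizes[seq_len(extra)] <- module_sizes[seq_len(extra)] + 1L
  }
  if (length(module_sizes) != n_modules || sum(module_sizes) != n_nodes) {
    abort("`module_sizes` must have `n_modules` entries summing to `n_nodes`.")
  }
  if (!(between_r >= 0 && between_r < within_r && within_r < 1)) {
    abort("Require 0 <= between_r < within_r < 1.")
  }
  if (within_decay <= 0 || within_decay > 1) {
    abort("`within_decay` must lie in (0, 1].")
  }
  starts <- cumsum(c(1L, head(module_sizes, -1L)))
  if (is.null(hub_boost)) hub_boost <- within_r - between_r
  if (is.null(hub_nodes)) hub_nodes <- starts
  if (is.null(effect_nodes)) {
    effect_nodes <- starts[seq_len(min(3L, n_modules))] + 1L
  }
  if (is.null(behavior_node)) {
    behavior_node <- if (n_modules >= 4L) starts[4L] + 1L else starts[1L] + 2L
  }
  ids <- c(hub_nodes, effect_nodes, behavior_node)
  if (any(ids < 1L | ids > n_nodes)) {
    abort("Node ids must lie in [1, n_nodes].")
  }
  spec <- list(
    n_per_group = as.integer(n_per_group), n_nodes = as.integer(n_nodes),
    n_timepoints = as.integer(n_timepoints), n_modules = as.integer(n_modules),
    module_sizes = as.integer(module_sizes), within_r = within_r,
    between_r = between_r, within_decay = within_decay,
    hub_nodes = as.integer(hub_nodes),
    hub_boost = hub_boost, effect_nodes = as.integer(effect_nodes),
    effect_base = effect_base, effect_delta = effect_delta,
    behavior_node = as.integer(behavior_node), behavior_base = behavior_base,
    rho_behavior = rho_behavior, behavior_jitter_sd = behavior_jitter_sd,
    age_mean = age_mean, age_sd = age_sd, age_shift = age_shift,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  structure(spec, class = "cohort_spec")
}

# Module membership vector implied by a spec.
spec_partition <- function(spec) {
  rep(seq_len(spec$n_modules), spec$module_sizes)
}

#' Build the node-by-node correlation template for one group
#'
#' Assembles the correlation matrix implied by a [cohort_spec()]. Within each
#' module, correlation decays with circular node distance,
#' `corr(d) = between_r + a * within_decay^(d - 1)` with the amplitude `a`
#' chosen so the module's mean off-diagonal equals `within_r` (with
#' `within_decay = 1` every within-module entry is exactly `within_r`).
#' Between-module entries are `between_r`, except for the planted structure:
#' each hub couples to the whole next module at `between_r + hub_boost`,
#' effect nodes couple to their next two modules at `between_r + effect_base`
#' (shifted by `effect_delta` in the effect group), and the behavior node
#' couples to its next two modules at
#' `between_r + behavior_base + behavior_jitter`.
#' Where planted couplings overlap the strongest applies. The template is then
#' repaired to the nearest positive semi-definite correlation matrix (negative
#' eigenvalues clipped to zero, diagonal renormalized to one, tolerance 1e-8);
#' a spec whose repair would move any entry by more than 0.05, or that puts a
#' correlation outside (-1, 1), is rejected as infeasible.
#'
#' @param spec A [cohort_spec()].
#' @param group `"control_like"` (template) or `"apd_like"` (with
#'   `effect_delta` applied).
#' @param behavior_jitter Optional scalar added to `behavior_node`'s planted
#'   between-module correlation (used per subject by [generate_cohort()]).
#' @return An `n_nodes` x `n_nodes` PSD correlation matrix.
#' @export
build_covariance <- function(spec, group = c("control_like", "apd_like"),
                             behavior_jitter = 0) {
  stopifnot(inherits(spec, "cohort_spec"))
  group <- match.arg(group)
  part <- spec_partition(spec)
  n <- spec$n_nodes
  m_mod <- spec$n_modules

  sigma <- matrix(spec$between_r, n, n)

  # Within-module distance-decay profile with module mean pinned to within_r.
  offset <- 0L
  for (m in seq_len(m_mod)) {
    n_m <- spec$module_sizes[m]
    idx <- offset + seq_len(n_m)
    offset <- offset + n_m
    if (n_m < 2) next
    pos <- seq_len(n_m)
    d <- outer(pos, pos, function(i, j) pmin(abs(i - j), n_m - abs(i - j)))
    prof <- spec$within_decay^(pmax(d, 1) - 1)
    mean_prof <- mean(prof[upper.tri(prof)])
    a <- (spec$within_r - spec$between_r) / mean_prof
    blk <- spec$between_r + a * prof
    sigma[idx, idx] <- blk
  }

  # Planted cross-module couplings, graded with the same distance decay around
  # an anchor position (the special node acts like a virtual member of the
  # target module); overlaps resolved by the stronger value.
  module_pos <- sequence(spec$module_sizes)
  planted <- matrix(-Inf, n, n)
  plant <- function(v, targets, peak) {
    if (abs(peak) >= 1) {
      abort("Invalid spec: planted shift pushes correlations outside (-1, 1).")
    }
    for (tg in targets) {
      cols <- which(part == tg)
      n_t <- length(cols)
      d <- pmin(abs(module_pos[cols] - module_pos[v]),
                n_t - abs(module_pos[cols] - module_pos[v]))
      value <- spec$between_r +
        (peak - spec$between_r) * spec$within_decay^d
      planted[v, cols] <<- pmax(planted[v, cols], value)
      planted[cols, v] <<- pmax(planted[cols, v], value)
    }
  }
  next_mods <- function(v, k) {
    if (m_mod < 2) return(integer(0))
    (part[v] - 1L + seq_len(min(k, m_mod - 1L))) %% m_mod + 1L
  }
  for (v in spec$hub_nodes) {
    plant(v, next_mods(v, 1L), spec$between_r + spec$hub_boost)
  }
  eff <- spec$effect_base + if (group == "apd_like") spec$effect_delta else 0
  for (v in spec$effect_nodes) {
    plant(v, next_mods(v, 2L), spec$between_r + eff)
  }
  plant(spec$behavior_node, next_mods(spec$behavior_node, 2L),
        spec$between_r + spec$behavior_base + behavior_jitter)
  # Planted values override the baseline (not pmax against it), so negative
  # shifts/jitter act symmetrically; the graded profile decays back to
  # between_r away from the anchor, keeping the template smooth.
  keep <- is.finite(planted)
  sigma[keep] <- planted[keep]

  diag(sigma) <- 1
  if (any(abs(sigma[upper.tri(sigma)]) >= 1)) {
    abort("Invalid spec: planted shifts push correlations outside (-1, 1).")
  }
  repaired <- nearest_psd(sigma)
  if (max(abs(repaired - sigma)) > 0.05) {
    abort("Invalid spec: correlation template is not repairable to PSD within tolerance.")
  }
  labels <- sprintf("p%03d", seq_len(n))
  dimnames(repaired) <- list(labels, labels)
  repaired
}

# Clip negative eigenvalues to zero and renormalize the diagonal to 1.
nearest_psd <- function(sigma, tol = 1e-8) {
  eg <- eigen(sigma, symmetric = TRUE)
  if (min(eg$values) >= -tol && min(eg$values) > 0) {
    return(sigma)
  }
  vals <- pmax(eg$values, 0)
  rep_s <- eg$vectors %*% (vals * t(eg$vectors))
  rep_s <- (rep_s + t(rep_s)) / 2
  d <- sqrt(pmax(diag(rep_s), .Machine$double.eps))
  rep_s <- rep_s / tcrossprod(d)
  diag(rep_s) <- 1
  rep_s
}

#' Simulate one subject's parcellated time series
#'
#' Draws `n_timepoints` samples from a zero-mean multivariate normal with the
#' given covariance (stationary Gaussian signal model: downstream analysis
#' consumes only Pearson correlations, so no hemodynamic structure is added).
#'
#' @param sigma PSD covariance/correlation matrix (nodes x nodes).
#' @param n_timepoints Number of timepoints (>= 10).
#' @param seed Optional seed for an exact reproducible draw.
#' @return A `n_timepoints` x `n_nodes` matrix with parcel-label colnames.
#' @export
simulate_subject <- function(sigma, n_timepoints, seed = NULL) {
  check_square_symmetric(sigma, arg = "sigma")
  if (n_timepoints < 10) abort("`n_timepoints` must be at least 10.")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) abort("`sigma` is not positive semi-definite.")
  ts <- with_seed(seed, MASS::mvrnorm(n = n_timepoints,
                                      mu = rep(0, nrow(sigma)),
                                      Sigma = sigma, tol = 1e-7))
  colnames(ts) <- node_labels(sigma)
  ts
}

#' Generate a synthetic two-group cohort with known ground truth
#'
#' Produces per-subject time series, a design table and the planted ground
#' truth of a [cohort_spec()]. The effect group uses a covariance whose
#' between-module entries at the effect nodes are shifted by `effect_delta`.
#' Every subject additionally receives a jitter of the behavior node's
#' between-module loading (so subjects genuinely differ in that node's
#' coupling), and the behavioral score is built from the subject's *realized*
#' nodal coupling -- the mean Fisher-z connectivity between the behavior node
#' and its target modules, computed from the generated time series -- mixed
#' with noise to correlate with that nodal metric at `rho_behavior` in
#' expectation. Ages are Gaussian with the reference group shifted by
#' `age_shift` years.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional override of `spec$seed`.
#' @return A `synthetic_cohort` list: `ts` (named list of timepoint-by-node
#'   matrices), `design` (tibble: subject_id, group, age, score), `truth`
#'   (planted partition, hub/effect/behavior nodes), and `spec`.
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- if (is.null(seed)) spec$seed else as.integer(seed)
  with_seed(seed, {
    n_a <- spec$n_per_group[1]
    n_c <- spec$n_per_group[2]
    n <- n_a + n_c
    group <- rep(c("apd_like", "control_like"), c(n_a, n_c))
    subject_id <- sprintf("sub-%03d", seq_len(n))
    age <- rnorm(n, mean = spec$age_mean, sd = spec$age_sd) +
      ifelse(group == "control_like", spec$age_shift, 0)

    # Truncated at +/- 2 sd so every subject's loading stays inside the
    # feasible correlation range.
    jitter <- pmin(pmax(rnorm(n, 0, spec$behavior_jitter_sd),
                        -2 * spec$behavior_jitter_sd),
                   2 * spec$behavior_jitter_sd)

    ts <- vector("list", n)
    names(ts) <- subject_id
    for (s in seq_len(n)) {
      grp <- if (group[s] == "apd_like") "apd_like" else "control_like"
      sigma <- build_covariance(spec, group = grp, behavior_jitter = jitter[s])
      ts[[s]] <- simulate_subject(sigma, spec$n_timepoints)
    }

    # Realized nodal coupling at the behavior node: mean Fisher-z FC to its
    # target modules, measured from each subject's own time series.
    part <- spec_partition(spec)
    bnode <- spec$behavior_node
    m_mod <- spec$n_modules
    targets <- if (m_mod >= 2) {
      (part[bnode] - 1L + seq_len(min(2L, m_mod - 1L))) %% m_mod + 1L
    } else {
      integer(0)
    }
    cols <- which(part %in% targets)
    coupling <- vapply(ts, function(x) {
      r <- suppressWarnings(stats::cor(x[, bnode], x[, cols]))
      mean(atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)))
    }, numeric(1))
    zc <- if (stats::sd(coupling) > 0) as.numeric(scale(coupling)) else rep(0, n)
    rho <- spec$rho_behavior
    score <- rho * zc + sqrt(max(0, 1 - rho^2)) * rnorm(n)
    structure(list(
      ts = ts,
      design = tibble::tibble(subject_id = subject_id, group = group,
                              age = age, score = score),
      truth = list(partition = spec_partition(spec),
                   hub_nodes = spec$hub_nodes,
                   effect_nodes = spec$effect_nodes,
                   behavior_node = spec$behavior_node),
      spec = spec
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%d/%d), %d nodes x %d timepoints, %d modules\n",
              length(x$ts), x$spec$n_per_group[1], x$spec$n_per_group[2],
              x$spec$n_nodes, x$spec$n_timepoints, x$spec$n_modules))
  invisible(x)
}

#' Parcel-label table for a synthetic cohort
#'
#' Builds the node-id / label / hemisphere / functional-network table used by
#' reporting functions, mirroring atlas label tables (1-based ROI numbering;
#' odd nodes assigned to the left hemisphere, even to the right).
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `node_id`, `label`, `hemisphere`,
#'   `functional_network`.
#' @export
make_parcel_table <- function(spec) {
  part <- spec_partition(spec)
  tibble::tibble(
    node_id = seq_len(spec$n_nodes),
    label = sprintf("p%03d", seq_len(spec$n_nodes)),
    hemisphere = ifelse(seq_len(spec$n_nodes) %% 2 == 1, "L", "R"),
    functional_network = sprintf("module_%d", part)
  )
}

#' Write a synthetic cohort to delimited text files
#'
#' Writes one tab-separated time-series file per subject (timepoints x nodes,
#' header row of parcel labels), the design table, and a ground-truth table
#' (node_id, module, is_effect_node, is_hub_node, is_behavior_node).
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (id in names(cohort$ts)) {
    p <- file.path(dir, paste0(id, "_timeseries.tsv"))
    readr::write_tsv(tibble::as_tibble(cohort$ts[[id]]), p)
    paths <- c(paths, p)
  }
  p_design <- file.path(dir, "design.tsv")
  readr::write_tsv(cohort$design, p_design)
  truth <- tibble::tibble(
    node_id = seq_along(cohort$truth$partition),
    module = cohort$truth$partition,
    is_effect_node = seq_along(cohort$truth$partition) %in% cohort$truth$effect_nodes,
    is_hub_node = seq_along(cohort$truth$partition) %in% cohort$truth$hub_nodes,
    is_behavior_node = seq_along(cohort$truth$partition) == cohort$truth$behavior_node
  )
  p_truth <- file.path(dir, "ground_truth.tsv")
  readr::write_tsv(truth, p_truth)
  invisible(c(paths, p_design, p_truth))
}
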