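#' Area under a metric-versus-density curve
#'
#' Trapezoid integral of a nodal (or global) metric over the density grid,
#' the threshold-free summary carried into the group tests. The x-axis is in
#' density units, so a constant curve `c` over 10--40% integrates to `0.3 c`.
#'
#' @param values Metric values, one per density.
#' @param densities Strictly increasing densities (>= 2).
#' @return Scalar AUC.
#' @export
auc_over_densities <- function(values, densities) {
  if (length(values) != length(densities) || length(values) < 2) {
    abort("Need matching `values`/`densities` with at least 2 grid points.")
  }
  if (is.unsorted(densities, strictly = TRUE)) {
    abort("`densities` must be strictly increasing.")
  }
  if (any(!is.finite(values))) {
    bad <- densities[!is.finite(values)][1]
    abort(sprintf("Non-finite metric value at density %s.", format(bad)))
  }
  sum(diff(densities) * (head(values, -1) + tail(values, -1)) / 2)
}

# --- shared permutation machinery -------------------------------------------

# Freedman-Lane style nuisance removal: demean the covariates, regress Y on
# them, and carry the residuals into both the observed statistic and the
# permutation distribution.
residualize <- function(y, covariates = NULL) {
  y <- as.matrix(y)
  if (is.null(covariates) || NCOL(covariates) == 0) {
    return(scale(y, center = TRUE, scale = FALSE))
  }
  x <- as.matrix(covariates)
  x <- scale(x, center = TRUE, scale = FALSE)
  keep <- apply(x, 2, function(v) stats::sd(v) > 0)
  x <- x[, keep, drop = FALSE]
  if (ncol(x) == 0) {
    return(scale(y, center = TRUE, scale = FALSE))
  }
  x1 <- cbind(1, x)
  qr_x <- qr(x1)
  y - x1 %*% qr.coef(qr_x, y)
}

# Welch t statistics, one per column of Y, for an observed grouping plus a
# matrix of permuted group-1 indicators (n_perm x n_subjects, 0/1). Returns
# list(t_obs, t_perm). Zero variance in both groups gives t = 0.
welch_t_perm <- function(y, g1, perm_ind = NULL) {
  y <- as.matrix(y)
  n1 <- sum(g1)
  n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) abort("Each group needs at least 2 subjects.")
  tot_s <- colSums(y)
  tot_q <- colSums(y^2)
  t_of <- function(ind_mat) {
    s1 <- ind_mat %*% y
    q1 <- ind_mat %*% y^2
    m1 <- s1 / n1
    m2 <- sweep(-s1, 2, tot_s, `+`) / n2
    v1 <- (q1 - n1 * m1^2) / (n1 - 1)
    v2 <- (sweep(-q1, 2, tot_q, `+`) - n2 * m2^2) / (n2 - 1)
    v1 <- pmax(v1, 0)
    v2 <- pmax(v2, 0)
    se <- sqrt(v1 / n1 + v2 / n2)
    tt <- (m1 - m2) / se
    tt[se == 0] <- 0
    tt
  }
  obs <- t_of(matrix(as.numeric(g1), nrow = 1))
  perm <- if (is.null(perm_ind)) NULL else t_of(perm_ind)
  list(t_obs = as.numeric(obs), t_perm = perm)
}

# Shared permutation schedule: n_perm random reassignments of the group-1
# labels, as a 0/1 indicator matrix. Using one schedule across all nodes and
# measures keeps the joint FDR coherent.
perm_schedule <- function(n, n1, n_perm) {
  ind <- matrix(0, n_perm, n)
  for (b in seq_len(n_perm)) {
    ind[b, sample.int(n, n1)] <- 1
  }
  ind
}

#' Permutation two-sample test with nuisance covariates
#'
#' Welch (unequal-variance) t test assessed by group-label permutation.
#' Covariates (e.g. age) are demeaned and regressed out of the values first;
#' the observed statistic and all permuted statistics are computed on those
#' residuals (Freedman-Lane style randomization). The two-tailed p-value
#' includes the observed statistic: `p = (1 + #{|t*| >= |t|}) / (n_perm + 1)`.
#'
#' @param values Per-subject scalars (or a subjects-by-variables matrix; one
#'   test per column under a single shared permutation schedule).
#' @param group Two-level grouping vector.
#' @param covariates Optional per-subject nuisance data frame/matrix.
#' @param n_perm Number of permutations (study-scale default 20000).
#' @param seed Optional seed.
#' @return An `fcnet_permtest`: `statistic`, `p`, `n_perm`, plus the group
#'   labels compared. `tidy()` returns one row per variable.
#' @export
permutation_ttest <- function(values, group, covariates = NULL,
                              n_perm = 20000, seed = NULL) {
  y <- as.matrix(values)
  group <- as.factor(group)
  if (nlevels(group) != 2) abort("`group` must have exactly two levels.")
  g1 <- group == levels(group)[1]
  r <- residualize(y, covariates)
  res <- with_seed(seed, {
    ind <- perm_schedule(length(g1), sum(g1), n_perm)
    welch_t_perm(r, g1, ind)
  })
  p <- (1 + colSums(abs(res$t_perm) >= rep(abs(res$t_obs), each = n_perm) - 1e-12)) /
    (n_perm + 1)
  structure(list(statistic = res$t_obs, p = as.numeric(p), n_perm = n_perm,
                 groups = levels(group),
                 variable = colnames(y)),
            class = "fcnet_permtest")
}

#' @export
print.fcnet_permtest <- function(x, ...) {
  cat(sprintf("<fcnet_permtest> %s vs %s, %d permutation(s)\n",
              x$groups[1], x$groups[2], x$n_perm))
  print(tidy(x), ...)
  invisible(x)
}

#' @export
tidy.fcnet_permtest <- function(x, ...) {
  tibble::tibble(
    variable = if (is.null(x$variable)) paste0("v", seq_along(x$statistic)) else x$variable,
    statistic = x$statistic,
    p = x$p
  )
}

#' Joint Benjamini-Hochberg FDR correction
#'
#' One BH step-up pass over the pooled p-vector (all nodes and all measures
#' jointly), so discoveries are controlled across the whole nodal family.
#'
#' @param p P-values in (0, 1].
#' @param q FDR level for the `significant` flag (default 0.05).
#' @return Tibble: `p`, `q_value`, `significant`.
#' @export
fdr_correct_joint <- function(p, q = 0.05) {
  if (length(p) == 0) abort("Empty p-value vector.")
  if (any(!is.finite(p) | p <= 0 | p > 1)) abort("P-values must lie in (0, 1].")
  qv <- p.adjust(p, method = "BH")
  tibble::tibble(p = p, q_value = qv, significant = qv < q)
}

#' Nodal permutation test suite on AUC summaries
#'
#' One nuisance-adjusted permutation Welch t-test per node per measure, using
#' a single shared permutation schedule, followed by joint BH-FDR across all
#' nodes and measures.
#'
#' @param auc_tbl Long tibble with columns `subject_id`, `node`, `measure`,
#'   `auc` (one row per subject-node-measure).
#' @param design Tibble with `subject_id`, `group`, and the covariate columns.
#' @param covariates Covariate column names in `design` (default `"age"`).
#' @param n_perm Permutations (study-scale default 20000).
#' @param q FDR level.
#' @param seed Optional seed.
#' @return Tibble: `node`, `measure`, `statistic`, `p`, `q_value`,
#'   `significant`.
#' @export
nodal_test_suite <- function(auc_tbl, design, covariates = "age",
                             n_perm = 20000, q = 0.05, seed = NULL) {
  need <- c("subject_id", "node", "measure", "auc")
  if (!all(need %in% names(auc_tbl))) {
    abort("`auc_tbl` needs columns subject_id, node, measure, auc.")
  }
  wide <- auc_tbl |>
    dplyr::mutate(key = paste(measure, node, sep = "\r")) |>
    tidyr::pivot_wider(id_cols = "subject_id", names_from = "key",
                       values_from = "auc")
  wide <- dplyr::semi_join(wide, design, by = "subject_id")
  design <- design[match(wide$subject_id, design$subject_id), ]
  y <- as.matrix(wide[, -1])
  cov <- if (length(covariates)) design[, covariates, drop = FALSE] else NULL
  fit <- permutation_ttest(y, design$group, covariates = cov,
                           n_perm = n_perm, seed = seed)
  keys <- strsplit(colnames(y), "\r", fixed = TRUE)
  out <- tibble::tibble(
    node = vapply(keys, function(k) k[2], character(1)),
    measure = vapply(keys, function(k) k[1], character(1)),
    statistic = fit$statistic,
    p = fit$p
  )
  corr <- fdr_correct_joint(out$p, q = q)
  out$q_value <- corr$q_value
  out$significant <- corr$significant
  node_num <- suppressWarnings(as.integer(out$node))
  if (!anyNA(node_num)) out$node <- node_num
  dplyr::arrange(out, measure, node)
}

#' Permutation partial correlation
#'
#' Residualizes both variables on the covariates by least squares, computes
#' the Pearson correlation of the residuals, and assesses it by permuting one
#' residual vector (`p` two-tailed, observed statistic included).
#'
#' @param x,y Numeric vectors (same length, >= 4 after exclusions).
#' @param covariates Data frame/matrix of covariates (constant columns are
#'   dropped, so constant covariates recover the plain Pearson correlation).
#' @param n_perm Permutations (study-scale default 20000).
#' @param seed Optional seed.
#' @return Tibble: `estimate`, `p`, `n`, `n_perm`.
#' @export
partial_correlation_perm <- function(x, y, covariates = NULL,
                                     n_perm = 20000, seed = NULL) {
  ok <- stats::complete.cases(x, y)
  if (!is.null(covariates)) ok <- ok & stats::complete.cases(as.data.frame(covariates))
  x <- x[ok]
  y <- y[ok]
  cov <- if (is.null(covariates)) NULL else as.matrix(as.data.frame(covariates))[ok, , drop = FALSE]
  if (length(x) < 4) abort("Need at least 4 complete observations.")
  rx <- residualize(x, cov)[, 1]
  ry <- residualize(y, cov)[, 1]
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    abort("Constant residuals; partial correlation undefined.")
  }
  r_obs <- stats::cor(rx, ry)
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) stats::cor(rx[sample.int(length(rx))], ry),
           numeric(1))
  })
  p <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
  tibble::tibble(estimate = r_obs, p = p, n = length(x), n_perm = n_perm)
}

#' Behavior-metric association suite
#'
#' Permutation partial correlations between a behavioral score and each
#' node-by-measure AUC, controlling covariates (age and group by default),
#' with joint BH-FDR across nodes and measures. Subjects missing the score
#' are excluded. A single permutation schedule is shared across all columns.
#'
#' @param auc_tbl Long AUC tibble (`subject_id`, `node`, `measure`, `auc`).
#' @param design Tibble with `subject_id`, the `score` column, and covariates.
#' @param score Name of the behavioral score column in `design`.
#' @param covariates Covariate column names (default `c("age", "group")`;
#'   factors are expanded to numeric codes).
#' @param n_perm Permutations.
#' @param q FDR level.
#' @param seed Optional seed.
#' @return Tibble: `node`, `measure`, `estimate`, `p`, `q_value`,
#'   `significant`.
#' @export
behavior_correlation_suite <- function(auc_tbl, design, score = "score",
                                       covariates = c("age", "group"),
                                       n_perm = 20000, q = 0.05, seed = NULL) {
  design <- design[stats::complete.cases(design[[score]]), ]
  wide <- auc_tbl |>
    dplyr::mutate(key = paste(measure, node, sep = "\r")) |>
    tidyr::pivot_wider(id_cols = "subject_id", names_from = "key",
                       values_from = "auc") |>
    dplyr::semi_join(design, by = "subject_id")
  design <- design[match(wide$subject_id, design$subject_id), ]
  y <- as.matrix(wide[, -1])
  cov <- NULL
  if (length(covariates)) {
    cov <- as.matrix(data.frame(lapply(design[, covariates, drop = FALSE],
                                       function(v) as.numeric(as.factor(v)))))
  }
  score_v <- design[[score]]
  n <- length(score_v)
  if (n < 4) abort("Need at least 4 subjects after exclusions.")
  ry <- residualize(score_v, cov)[, 1]
  rx <- residualize(y, cov)
  if (stats::sd(ry) == 0) abort("Constant residuals; partial correlation undefined.")
  sx <- apply(rx, 2, stats::sd)
  rx_std <- sweep(rx, 2, ifelse(sx > 0, sx, 1), `/`)
  ry_std <- ry / stats::sd(ry)
  r_obs <- as.numeric(crossprod(ry_std, rx_std)) / (n - 1)
  r_obs[sx == 0] <- 0
  r_perm <- with_seed(seed, {
    perm <- matrix(0, n_perm, length(r_obs))
    for (b in seq_len(n_perm)) {
      perm[b, ] <- as.numeric(crossprod(ry_std[sample.int(n)], rx_std)) / (n - 1)
    }
    perm
  })
  p <- (1 + colSums(abs(r_perm) >= rep(abs(r_obs), each = n_perm) - 1e-12)) /
    (n_perm + 1)
  keys <- strsplit(colnames(y), "\r", fixed = TRUE)
  out <- tibble::tibble(
    node = vapply(keys, function(k) k[2], character(1)),
    measure = vapply(keys, function(k) k[1], character(1)),
    estimate = r_obs,
    p = as.numeric(p)
  )
  corr <- fdr_correct_joint(out$p, q = q)
  out$q_value <- corr$q_value
  out$significant <- corr$significant
  node_num <- suppressWarnings(as.integer(out$node))
  if (!anyNA(node_num)) out$node <- node_num
  dplyr::arrange(out, measure, node)
}

#' Demographic comparison tests
#'
#' Pooled-variance two-sample t tests for continuous variables and Pearson
#' chi-square tests (no continuity correction, df = 1) for 2 x 2 categorical
#' variables -- the standard participant-characteristics table.
#'
#' @param design Tibble with a two-level `group` column.
#' @param continuous Names of continuous columns to test.
#' @param categorical Names of two-level categorical columns to test.
#' @return Tibble: `variable`, `test`, `statistic`, `df`, `p`.
#' @export
demographic_tests <- function(design, continuous = character(0),
                              categorical = character(0)) {
  group <- as.factor(design$group)
  if (nlevels(group) != 2) abort("`group` must have exactly two levels.")
  if (min(table(group)) < 2) abort("Each group needs at least 2 subjects.")
  rows <- list()
  for (v in continuous) {
    x <- design[[v]][group == levels(group)[1]]
    y <- design[[v]][group == levels(group)[2]]
    tt <- pooled_t_from_summary(mean(x), stats::sd(x), length(x),
                                mean(y), stats::sd(y), length(y))
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = v, test = "pooled_t", statistic = tt$statistic,
      df = tt$df, p = tt$p
    )
  }
  for (v in categorical) {
    tab <- table(group, design[[v]])
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = v, test = "pearson_chisq",
      statistic = unname(ct$statistic), df = unname(ct$parameter),
      p = ct$p.value
    )
  }
  dplyr::bind_rows(rows)
}

#' Pooled two-sample t test from summary statistics
#'
#' Reconstructs the classic equal-variance two-sample t test from per-group
#' means, SDs and sizes, as printed in demographics tables.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Per-group summaries.
#' @return Tibble: `statistic` (sign of group2 - group1), `df`, `p`
#'   (two-tailed).
#' @export
pooled_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) abort("Each group needs at least 2 subjects.")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t_stat <- if (se == 0) 0 else (mean2 - mean1) / se
  tibble::tibble(statistic = t_stat, df = df,
                 p = 2 * stats::pt(-abs(t_stat), df))
}

#' Pearson chi-square test from 2 x 2 counts
#'
#' @param counts 2 x 2 integer matrix (groups x categories).
#' @return Tibble: `statistic`, `df`, `p` (no continuity correction).
#' @export
chisq_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) abort("`counts` must be a 2 x 2 matrix.")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value)
}
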