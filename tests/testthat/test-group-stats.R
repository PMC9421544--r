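test_that("AUC is the trapezoid integral over the density band", {
  grid <- density_grid()
  expect_equal(auc_over_densities(rep(2, 31), grid), 0.6)
  expect_equal(auc_over_densities(grid, grid), (0.4^2 - 0.1^2) / 2)
  expect_equal(auc_over_densities(c(0, 1), c(0.1, 0.4)), 0.15)
  expect_error(auc_over_densities(c(1, NaN, 3), c(0.1, 0.2, 0.3)), "0.2")
  expect_error(auc_over_densities(1, 0.1), "at least 2")
})

test_that("permutation t-test handles degenerate and exact cases", {
  g <- rep(c("a", "b"), each = 6)
  res <- permutation_ttest(rep(1, 12), g, n_perm = 99, seed = 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  # p includes the observed statistic: lower bound 1/(B+1)
  set.seed(2)
  y <- c(rnorm(6), rnorm(6) + 10)
  res2 <- permutation_ttest(y, g, n_perm = 199, seed = 2)
  expect_gte(res2$p, 1 / 200)
  expect_lt(res2$p, 0.05)
  # deterministic under seed
  res3 <- permutation_ttest(y, g, n_perm = 199, seed = 2)
  expect_identical(res2$p, res3$p)
})

test_that("permutation t-test is calibrated under the null and powered under a shift", {
  # 500 null replicates in seeded batches, two groups from one distribution
  n1 <- 28; n2 <- 29
  g <- rep(c("a", "b"), c(n1, n2))
  rejections <- unlist(lapply(1:10, function(b) {
    set.seed(100 + b)
    y <- matrix(rnorm((n1 + n2) * 50), n1 + n2, 50)
    age <- rnorm(n1 + n2, 11, 1.5)
    fit <- permutation_ttest(y, g, covariates = data.frame(age = age),
                             n_perm = 999, seed = b)
    fit$p <= 0.05
  }))
  rate <- mean(rejections)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)

  # 1-sd shift: power above 0.9 over 200 replicates
  hits <- unlist(lapply(1:4, function(b) {
    set.seed(200 + b)
    y <- matrix(rnorm((n1 + n2) * 50), n1 + n2, 50)
    y[g == "b", ] <- y[g == "b", ] + 1
    fit <- permutation_ttest(y, g, n_perm = 999, seed = b)
    fit$p <= 0.05
  }))
  expect_gt(mean(hits), 0.9)
})

test_that("joint BH-FDR matches the step-up oracle", {
  res <- fdr_correct_joint(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(res$significant))

  res1 <- fdr_correct_joint(rep(1, 5))
  expect_false(any(res1$significant))

  set.seed(3)
  for (rep in 1:100) {
    p <- stats::runif(sample(3:40, 1))^sample(1:3, 1)
    p <- pmin(pmax(p, 1e-12), 1)
    expect_equal(fdr_correct_joint(p)$q_value, oracle_bh(p), tolerance = 1e-12)
  }
  # monotone flags: anything significant at q = 0.01 is significant at q = 0.05
  p <- stats::runif(50)^3
  f1 <- fdr_correct_joint(p, q = 0.01)$significant
  f5 <- fdr_correct_joint(p, q = 0.05)$significant
  expect_true(all(f5[f1]))
  expect_error(fdr_correct_joint(numeric(0)), "Empty")
  expect_error(fdr_correct_joint(c(0.5, 0)), "in \\(0, 1]")
})

test_that("nodal suite has one row per node and measure with a shared schedule", {
  co <- generate_cohort(tiny_spec(seed = 13))
  cfg <- pipeline_config(densities = c(0.15, 0.30), subject_louvain_runs = 5,
                         pcnorm_nulls = 10, measures = c("pc", "pc_norm", "wmz"),
                         seed = 1)
  aucs <- suppressWarnings(cohort_auc(co, cfg, seed = 1))
  out <- nodal_test_suite(aucs, co$design, n_perm = 99, seed = 4)
  expect_equal(nrow(out), 30 * 3)
  expect_true(all(out$q_value >= out$p - 1e-12))
  # same seed, same schedule: identical p for identical input columns
  out2 <- nodal_test_suite(aucs, co$design, n_perm = 99, seed = 4)
  expect_identical(out$p, out2$p)
})

test_that("partial correlation matches the residualize-then-correlate oracle", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 3, 5)
  z <- c(1, 1, 2, 2)
  res <- partial_correlation_perm(x, y, covariates = data.frame(z = z),
                                  n_perm = 23, seed = 1)
  rx <- residuals(lm(x ~ z))
  ry <- residuals(lm(y ~ z))
  expect_equal(res$estimate, cor(rx, ry), tolerance = 1e-12)

  # constant covariate: plain Pearson correlation
  res2 <- partial_correlation_perm(x, y, covariates = data.frame(z = rep(2, 4)),
                                   n_perm = 23, seed = 1)
  expect_equal(res2$estimate, cor(x, y), tolerance = 1e-12)

  expect_error(partial_correlation_perm(c(1, 1, 1, 1), y, n_perm = 9),
               "Constant residuals")
  expect_error(partial_correlation_perm(x[1:3], y[1:3], n_perm = 9),
               "at least 4")
})

test_that("behavior suite excludes missing scores and reports joint FDR", {
  co <- generate_cohort(tiny_spec(seed = 17))
  co$design$score[c(1, 8, 12)] <- NA
  cfg <- sim_config(seed = 2)
  aucs <- cohort_auc(co, cfg, seed = 2)
  bs <- behavior_correlation_suite(aucs, co$design, n_perm = 199, seed = 2)
  expect_equal(nrow(bs), 30 * 2)
  expect_true(all(is.finite(bs$estimate)))
  expect_true(all(bs$q_value >= bs$p - 1e-12))
})

test_that("demographic tests reproduce the printed-table conventions", {
  # identical group proportions give chi-square exactly 0
  expect_equal(chisq_from_counts(matrix(c(10, 20, 10, 20), 2, byrow = TRUE))$statistic, 0)

  # raw-data path: pooled t equals the summary-statistic path
  set.seed(4)
  design <- tibble::tibble(
    group = rep(c("a", "b"), c(10, 12)),
    age = c(rnorm(10, 10), rnorm(12, 11)),
    sex = sample(c("m", "f"), 22, replace = TRUE)
  )
  out <- demographic_tests(design, continuous = "age", categorical = "sex")
  expect_equal(nrow(out), 2)
  x <- design$age[design$group == "a"]
  y <- design$age[design$group == "b"]
  ref <- t.test(y, x, var.equal = TRUE)
  expect_equal(out$statistic[out$variable == "age"], unname(ref$statistic),
               tolerance = 1e-12)
  expect_equal(out$p[out$variable == "age"], ref$p.value, tolerance = 1e-12)

  expect_error(demographic_tests(tibble::tibble(group = c("a", "a", "b"),
                                                age = 1:3),
                                 continuous = "age"),
               "at least 2")
})
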