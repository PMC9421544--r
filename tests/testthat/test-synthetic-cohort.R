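test_that("single-block and zero-between templates reduce to exact block values", {
  # Homogeneous sub-case: one module, no decay, no planted cross structure.
  spec1 <- cohort_spec(n_per_group = c(3, 3), n_nodes = 12, n_modules = 1,
                       within_r = 0.5, within_decay = 1,
                       hub_nodes = integer(0), effect_nodes = integer(0),
                       behavior_node = 2L, behavior_base = 0, seed = 1)
  s1 <- build_covariance(spec1)
  expect_equal(unname(s1[upper.tri(s1)]), rep(0.5, sum(upper.tri(s1))))
  expect_equal(unname(diag(s1)), rep(1, 12))

  # Zero between-module correlation, no planted structure: cross block zero.
  spec2 <- cohort_spec(n_per_group = c(3, 3), n_nodes = 12, n_modules = 2,
                       within_r = 0.5, between_r = 0, within_decay = 1,
                       hub_nodes = integer(0), effect_nodes = integer(0),
                       behavior_node = 2L, behavior_base = 0, seed = 1)
  s2 <- build_covariance(spec2)
  expect_true(all(s2[1:6, 7:12] == 0))
  expect_true(all(s2[1:6, 1:6][upper.tri(diag(6))] == 0.5))
})

test_that("default covariance template is PSD after repair, with bounded perturbation", {
  spec <- cohort_spec(seed = 3)
  for (grp in c("control_like", "apd_like")) {
    s <- build_covariance(spec, group = grp)
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
    expect_equal(unname(diag(s)), rep(1, spec$n_nodes))
    expect_lt(max(abs(s - t(s))), 1e-12)
  }
  # mean within-module correlation close to the within_r target
  part <- rep(1:5, each = 18)
  s <- build_covariance(spec)
  plain <- setdiff(seq_len(90), c(spec$hub_nodes, spec$effect_nodes, spec$behavior_node))
  blk <- s[intersect(which(part == 5), plain), intersect(which(part == 5), plain)]
  expect_equal(mean(blk[upper.tri(blk)]), spec$within_r, tolerance = 0.02)
})

test_that("infeasible correlation combinations are rejected", {
  spec <- cohort_spec(seed = 1, behavior_base = 0.95)
  expect_error(build_covariance(spec), "outside")
  spec2 <- cohort_spec(seed = 1, hub_boost = 0.88)
  expect_error(build_covariance(spec2), "Invalid spec")
  expect_error(cohort_spec(within_r = 0.3, between_r = 0.4), "between_r")
})

test_that("effect_delta = 0 makes the two group covariances identical", {
  spec <- cohort_spec(seed = 5, effect_delta = 0)
  expect_equal(build_covariance(spec, "control_like"),
               build_covariance(spec, "apd_like"))
  # a nonzero delta perturbs (essentially) only effect-node rows/columns; the
  # PSD repair may leak a tiny amount elsewhere
  spec2 <- cohort_spec(seed = 5)
  d <- build_covariance(spec2, "apd_like") - build_covariance(spec2, "control_like")
  eff <- spec2$effect_nodes
  expect_gt(max(abs(d[eff, ])), 0.1)
  expect_lt(max(abs(d[-eff, -eff])), 0.02)
})

test_that("simulate_subject draws match the requested covariance", {
  # identity covariance: sample correlations near zero at the 1.96/sqrt(T) scale
  ts <- simulate_subject(diag(8), n_timepoints = 10000, seed = 2)
  r <- compute_fc(ts)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)

  # strong planted pair lands inside its Fisher-z interval
  s <- diag(4)
  s[1, 2] <- s[2, 1] <- 0.9
  r2 <- compute_fc(simulate_subject(s, n_timepoints = 5000, seed = 3))
  expect_gt(r2[1, 2], 0.85)
  expect_lt(r2[1, 2], 0.95)

  expect_identical(simulate_subject(s, 50, seed = 9),
                   simulate_subject(s, 50, seed = 9))
  expect_error(simulate_subject(s, 5), "at least 10")
  s_bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(simulate_subject(s_bad, 50), "positive semi-definite")
})

test_that("generate_cohort is reproducible and carries coherent ground truth", {
  spec <- tiny_spec(seed = 11)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$ts, c2$ts)
  expect_identical(c1$design, c2$design)
  expect_equal(length(c1$ts), sum(spec$n_per_group))
  expect_equal(length(unique(c1$truth$partition)), spec$n_modules)
  expect_equal(table(c1$design$group)[["apd_like"]], spec$n_per_group[1])
  # age offset applied to the reference group
  expect_gt(mean(c1$design$age[c1$design$group == "control_like"]),
            mean(c1$design$age[c1$design$group == "apd_like"]) - 1)
})

test_that("rho_behavior = 0 leaves the score uncoupled from the planted jitter", {
  # With zero coupling the score is pure noise; correlations with every nodal
  # AUC stay at the sampling-error scale across a few replicates.
  rs <- vapply(1:4, function(r) {
    co <- generate_cohort(cohort_spec(seed = 40000 + r, rho_behavior = 0))
    cfg <- sim_config(seed = r)
    id_keep <- co$design$subject_id
    aucs <- vapply(id_keep, function(id) {
      cv <- nodal_curves(compute_fc(co$ts[[id]]), cfg,
                         seed = fcnet:::substream_seed(r, "b", id))
      av <- nodal_auc(cv)
      av$auc[av$node == co$truth$behavior_node & av$measure == "pc"]
    }, numeric(1))
    cor(co$design$score, aucs)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 2 / sqrt(4 * 57))
})

test_that("fixture graphs have their defining structure", {
  st <- fixture_graph("star", 5)
  expect_equal(sum(st) / 2, 4)
  expect_equal(rowSums(st)[[1]], 4)

  tc <- fixture_graph("two_cliques", 3)
  expect_equal(sum(tc) / 2, 6)
  expect_equal(igraph::components(as_igraph_test(tc))$no, 2)

  cl <- fixture_graph("clique", 4)
  expect_equal(sum(cl) / 2, 6)

  pa <- fixture_graph("path", 4)
  expect_equal(sum(pa) / 2, 3)

  rl <- fixture_graph("ring_lattice", 10, k = 4)
  expect_true(all(rowSums(rl) == 4))

  expect_error(fixture_graph("moebius", 5), "Unknown fixture family")
})

test_that("planted_partition edge counts sit inside the binomial interval", {
  pp <- fixture_graph("planted_partition", 60, n_modules = 3,
                      p_in = 0.9, p_out = 0.05, seed = 7)
  memb <- attr(pp, "membership")
  within_pairs <- sum(outer(memb, memb, "==")[upper.tri(pp)])
  within_edges <- sum((pp * outer(memb, memb, "=="))[upper.tri(pp)])
  mu <- within_pairs * 0.9
  sdv <- sqrt(within_pairs * 0.9 * 0.1)
  expect_gt(within_edges, mu - 4 * sdv)
  expect_lt(within_edges, mu + 4 * sdv)
})

test_that("write_cohort produces a readable on-disk layout", {
  co <- generate_cohort(tiny_spec(seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "design.tsv")))
  expect_true(file.exists(file.path(dir, "ground_truth.tsv")))
  ts_back <- read_timeseries(file.path(dir, "sub-001_timeseries.tsv"))
  expect_equal(ts_back, co$ts[["sub-001"]], tolerance = 1e-12)
  d <- read_design(file.path(dir, "design.tsv"))
  expect_equal(nrow(d), 12)
})
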