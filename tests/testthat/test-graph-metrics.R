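test_that("path lengths and CPL match closed forms on fixtures", {
  cl <- fixture_graph("clique", 4)
  d <- shortest_path_lengths(cl)
  expect_true(all(d[upper.tri(d)] == 1))
  expect_equal(as.numeric(characteristic_path_length(cl)), 1)

  pa <- fixture_graph("path", 3)
  expect_equal(shortest_path_lengths(pa)[1, 3], 2)

  # weighted triangle: direct route 1/0.2 = 5 vs two hops 1/0.5 + 1/0.5 = 4
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- 0.5
  w[1, 3] <- w[3, 1] <- 0.2
  expect_equal(shortest_path_lengths(w)[1, 3], 4)

  ring5 <- fixture_graph("ring_lattice", 5, k = 2)
  expect_equal(as.numeric(characteristic_path_length(ring5)), 1.5)

  tc <- fixture_graph("two_cliques", 3)
  cpl <- characteristic_path_length(tc)
  expect_equal(as.numeric(cpl), 1)
  expect_true(attr(cpl, "disconnected"))
})

test_that("global and local efficiency match pair-enumeration oracles", {
  expect_equal(global_efficiency(fixture_graph("clique", 5)), 1)
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
  expect_equal(global_efficiency(fixture_graph("path", 3)), (1 + 0.5 + 1) / 3)

  expect_equal(mean(local_efficiency(fixture_graph("clique", 4))), 1)
  expect_equal(mean(local_efficiency(fixture_graph("star", 5))), 0)
})

test_that("clustering matches triangle counting, including the pendant example", {
  expect_equal(unname(clustering_coefficient(fixture_graph("clique", 3))),
               rep(1, 3))
  expect_equal(unname(clustering_coefficient(fixture_graph("star", 5))),
               rep(0, 5))

  # triangle abc plus pendant d-a
  g <- matrix(0, 4, 4)
  g[1, 2] <- g[2, 1] <- 1
  g[1, 3] <- g[3, 1] <- 1
  g[2, 3] <- g[3, 2] <- 1
  g[1, 4] <- g[4, 1] <- 1
  cc <- clustering_coefficient(g)
  expect_equal(unname(cc), c(1 / 3, 1, 1, 0))
  expect_equal(mean(cc), 0.58333, tolerance = 1e-5)
  # local efficiency of the pendant-bearing vertex, against the oracle
  expect_equal(unname(local_efficiency(g)), oracle_eloc(g), tolerance = 1e-10)
})

test_that("modularity matches the closed form and the double-sum oracle", {
  tc <- fixture_graph("two_cliques", 3)
  expect_equal(modularity_q(tc, rep(1:2, each = 3)), 0.5)
  expect_equal(modularity_q(tc, rep(1, 6)), 0)

  set.seed(5)
  for (rep in 1:10) {
    g <- random_graph(8, 0.5, weighted = TRUE)
    if (sum(g) == 0) next
    memb <- sample(1:3, 8, replace = TRUE)
    expect_equal(modularity_q(g, memb), oracle_q(g, memb), tolerance = 1e-12)
  }
  expect_error(modularity_q(tc, c(1, 1, 1)), "label every node")
})

test_that("all metrics agree with brute-force oracles on random small graphs", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    g <- random_graph(n, stats::runif(1, 0.3, 0.8),
                      weighted = rep %% 2 == 0)
    if (sum(g) < 4) next
    expect_equal(as.numeric(characteristic_path_length(g)), oracle_cpl(g),
                 tolerance = 1e-10)
    expect_equal(global_efficiency(g), oracle_eglob(g), tolerance = 1e-10)
    expect_equal(unname(clustering_coefficient(g)), oracle_cc(g),
                 tolerance = 1e-10)
    expect_equal(unname(local_efficiency(g)), oracle_eloc(g), tolerance = 1e-10)
    expect_lte(global_efficiency(g), 1)
    if (all(g %in% c(0, 1)) && !attr(characteristic_path_length(g), "disconnected")) {
      expect_gte(as.numeric(characteristic_path_length(g)), 1)
    }
  }
})

test_that("adding an edge never increases binary CPL", {
  set.seed(6)
  for (rep in 1:10) {
    g <- random_graph(10, 0.4)
    if (isTRUE(attr(characteristic_path_length(g), "disconnected"))) next
    missing <- which(g == 0 & upper.tri(g), arr.ind = TRUE)
    if (nrow(missing) == 0) next
    pick <- missing[sample(nrow(missing), 1), ]
    g2 <- g
    g2[pick[1], pick[2]] <- g2[pick[2], pick[1]] <- 1
    expect_lte(as.numeric(characteristic_path_length(g2)),
               as.numeric(characteristic_path_length(g)) + 1e-12)
  }
})

test_that("rewiring preserves degrees, edge count and the weight multiset", {
  set.seed(7)
  for (rep in 1:10) {
    g <- random_graph(15, 0.3, weighted = TRUE)
    if (sum(g != 0) / 2 < 2) next
    rw <- maslov_sneppen_rewire(g, seed = rep)
    expect_identical(unname(rowSums(rw != 0)), unname(rowSums(g != 0)))
    expect_equal(sum(rw != 0), sum(g != 0))
    expect_equal(sort(rw[upper.tri(rw)][rw[upper.tri(rw)] != 0]),
                 sort(g[upper.tri(g)][g[upper.tri(g)] != 0]))
    expect_equal(sum(rw), sum(g))
  }

  # randomization destroys lattice clustering
  rl <- fixture_graph("ring_lattice", 20, k = 4)
  cc0 <- mean(clustering_coefficient(rl))
  cc_null <- vapply(1:100, function(s) {
    mean(clustering_coefficient(maslov_sneppen_rewire(rl, seed = s)))
  }, numeric(1))
  expect_lt(mean(cc_null), cc0)

  # a clique admits no valid swap and is returned unchanged with a warning
  cl <- fixture_graph("clique", 5)
  expect_warning(out <- maslov_sneppen_rewire(cl, seed = 1), "No valid")
  expect_false(attr(out, "rewired"))
})

test_that("small-worldness behaves across regimes", {
  # clique: nulls identical to the original, sigma exactly 1
  cl <- fixture_graph("clique", 6)
  expect_warning(sw_cl <- small_worldness(cl, n_null = 5, seed = 1))
  expect_equal(sw_cl, 1)

  # Watts-Strogatz regime: lattice with a few rewired edges
  rl <- fixture_graph("ring_lattice", 50, k = 6)
  ws <- maslov_sneppen_rewire(rl, iterations_per_edge = 0.05, seed = 2)
  expect_gt(small_worldness(ws, n_null = 30, seed = 3), 1)

  # dense random graph: null self-similarity
  set.seed(8)
  er <- random_graph(50, 0.5)
  sw_er <- small_worldness(er, n_null = 30, seed = 4)
  expect_gt(sw_er, 0.8)
  expect_lt(sw_er, 1.2)

  # relabeling invariance up to Monte Carlo noise of the null ensemble
  perm <- sample(50)
  sw_perm <- small_worldness(er[perm, perm], n_null = 30, seed = 5)
  expect_lt(abs(sw_perm - sw_er), 0.1)
})

test_that("global_metrics returns the full one-row summary", {
  co <- generate_cohort(tiny_spec(seed = 4))
  net <- proportional_threshold(compute_fc(co$ts[[1]]), 0.2)
  gm <- global_metrics(net, n_louvain = 20, sw_nulls = 10, seed = 1)
  expect_s3_class(gm, "tbl_df")
  expect_equal(nrow(gm), 1)
  expect_true(all(c("cpl", "e_glob", "e_loc_mean", "cc_mean",
                    "modularity_q", "small_worldness") %in% names(gm)))
  expect_true(gm$e_glob <= 1 && gm$e_glob >= 0)
  expect_true(gm$modularity_q >= -0.5 && gm$modularity_q <= 1)
})
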