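test_that("louvain separates disconnected cliques with the closed-form Q", {
  tc <- fixture_graph("two_cliques", 4)
  p <- louvain(tc, seed = 1)
  expect_equal(p$n_modules, 2)
  expect_equal(p$q, 0.5)
  expect_equal(p$q, modularity_q(tc, p$membership))
  expect_true(all(diff(p$q_trace) >= -1e-9))
})

test_that("louvain recovers planted partitions and agrees with an independent implementation", {
  nmis <- vapply(1:20, function(s) {
    pp <- fixture_graph("planted_partition", 60, n_modules = 3,
                        p_in = 0.9, p_out = 0.02, seed = s)
    p <- louvain(pp, seed = s)
    nmi_of(p$membership, attr(pp, "membership"))
  }, numeric(1))
  expect_equal(median(nmis), 1.0)

  # cross-check against igraph's Louvain on one instance
  pp <- fixture_graph("planted_partition", 60, n_modules = 3,
                      p_in = 0.9, p_out = 0.02, seed = 99)
  ours <- louvain(pp, seed = 1)
  theirs <- igraph::cluster_louvain(as_igraph_test(pp))
  expect_equal(nmi_of(ours$membership, igraph::membership(theirs)), 1.0)
  expect_equal(ours$q, igraph::modularity(as_igraph_test(pp),
                                          igraph::membership(theirs)),
               tolerance = 1e-6)

  expect_error(louvain(matrix(0, 3, 3)), "non-empty")
})

test_that("consensus is deterministic under seed, exact for stable graphs, idempotent", {
  tc <- fixture_graph("two_cliques", 4)
  cp <- consensus_partition(tc, n_runs = 20, seed = 3)
  expect_equal(cp$partition$n_modules, 2)
  expect_equal(cp$partition$q, 0.5)
  # all runs agree, so the agreement matrix is 0/1
  expect_true(all(cp$agreement %in% c(0, 1)))

  pp <- fixture_graph("planted_partition", 90, n_modules = 5,
                      p_in = 0.8, p_out = 0.05, seed = 5)
  c1 <- consensus_partition(pp, n_runs = 100, seed = 11)
  c2 <- consensus_partition(pp, n_runs = 100, seed = 11)
  expect_identical(c1$partition$membership, c2$partition$membership)
  expect_equal(c1$partition$n_modules, 5)
  expect_gte(nmi_of(c1$partition$membership, attr(pp, "membership")), 0.95)

  # idempotence: consensus of the converged agreement pattern is itself
  ag <- outer(c1$partition$membership, c1$partition$membership, "==") * 1
  diag(ag) <- 0
  c3 <- consensus_partition(ag, n_runs = 20, seed = 2)
  expect_equal(nmi_of(c3$partition$membership, c1$partition$membership), 1.0)
})

test_that("within-module z-scores use the per-module sample standardization", {
  # module of 3 nodes with within-degrees {2, 1, 1}: triangle missing one edge
  g <- matrix(0, 3, 3)
  g[1, 2] <- g[2, 1] <- 1
  g[1, 3] <- g[3, 1] <- 1
  wmz <- within_module_zscore(g, c(1, 1, 1))
  expect_equal(unname(wmz), c(1.1547, -0.5774, -0.5774), tolerance = 1e-4)

  # clique module: zero spread rule
  expect_equal(unname(within_module_zscore(fixture_graph("clique", 4), rep(1, 4))),
               rep(0, 4))

  # z-score identity: within-module mean is 0
  set.seed(9)
  g2 <- random_graph(12, 0.5, weighted = TRUE)
  memb <- rep(1:3, each = 4)
  w <- within_module_zscore(g2, memb)
  for (m in 1:3) expect_equal(mean(w[memb == m]), 0, tolerance = 1e-12)
})

test_that("participation coefficient matches its definition and bound", {
  # all edges inside own module
  tc <- fixture_graph("two_cliques", 3)
  expect_equal(unname(participation_coefficient(tc, rep(1:2, each = 3))),
               rep(0, 6))

  # node with strength split across modules
  g <- matrix(0, 5, 5)
  g[1, 2] <- g[2, 1] <- 1
  g[1, 3] <- g[3, 1] <- 1
  expect_equal(unname(participation_coefficient(g, c(1, 1, 2, 2, 2)))[1], 0.5)

  g4 <- matrix(0, 5, 5)
  g4[1, 2:5] <- 1
  g4[2:5, 1] <- 1
  expect_equal(unname(participation_coefficient(g4, c(1, 1, 2, 3, 4)))[1], 0.75)

  set.seed(10)
  for (rep in 1:10) {
    gr <- random_graph(10, 0.5, weighted = TRUE)
    memb <- sample(1:4, 10, replace = TRUE)
    m_count <- length(unique(memb))
    pc <- participation_coefficient(gr, memb)
    expect_true(all(pc <= 1 - 1 / m_count + 1e-12))
    expect_true(all(pc >= 0 - 1e-12))
  }
})

test_that("pc_norm is deterministic, bounded, and discounts within-module degree", {
  pp <- fixture_graph("planted_partition", 60, n_modules = 3,
                      p_in = 0.6, p_out = 0.12, seed = 21)
  memb <- attr(pp, "membership")
  # plant degree-heterogeneous structure: a few nodes get dense extra edges
  # inside their own module only (high within-degree, same between profile)
  g <- pp
  for (v in c(1, 21, 41)) {
    own <- setdiff(which(memb == memb[v]), v)
    g[v, own] <- 1
    g[own, v] <- 1
  }

  p1 <- normalized_participation_coefficient(g, memb, n_null = 100, seed = 5)
  p2 <- normalized_participation_coefficient(g, memb, n_null = 100, seed = 5)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))

  pc <- participation_coefficient(g, memb)
  win <- vapply(seq_len(nrow(g)), function(i) sum(g[i, memb == memb[i]]),
                numeric(1))
  expect_lt(abs(cor(p1, win)), abs(cor(pc, win)))
})

test_that("hub classification uses strict quadrant boundaries", {
  wmz <- c(1.5, 1.5, 0.2, 0.2, 1.0, 1.5, 2.0)
  pcn <- c(0.7, 0.3, 0.7, 0.3, 0.7, 0.5, 0.5000001)
  roles <- classify_hubs(wmz, pcn)
  expect_equal(as.character(roles),
               c("connector_hub", "provincial_hub", "connector_non_hub",
                 "provincial_non_hub",
                 "connector_non_hub",  # wmz == 1 exactly: not a hub
                 "provincial_hub",     # pc_norm == 0.5 exactly: provincial
                 "connector_hub"))
  expect_error(classify_hubs(c(1, NA), c(0.5, 0.5)), "complete")
})

test_that("hub_table and module_summary report coherent per-module structure", {
  co <- generate_cohort(tiny_spec(seed = 8))
  grp <- group_average_fc(lapply(co$ts, compute_fc), density = 0.10)
  cp <- consensus_partition(grp, n_runs = 50, seed = 2)
  pt <- make_parcel_table(co$spec)
  ht <- suppressWarnings(hub_table(grp, cp, n_null = 50, seed = 3, parcel_table = pt))
  expect_equal(nrow(ht), 30)
  expect_true(all(c("wmz", "pc", "pc_norm", "role", "hemisphere") %in% names(ht)))

  ms <- module_summary(ht)
  expect_equal(nrow(ms), cp$partition$n_modules)
  expect_equal(sum(ms$n_nodes), 30)
  expect_true(all(ms$n_connector + ms$n_provincial <=
                    ms$n_nodes))

  # single module, no hubs
  ht0 <- tibble::tibble(node = 1:4, label = letters[1:4], module = 1,
                        wmz = 0, pc = 0, pc_norm = 0,
                        role = classify_hubs(rep(0, 4), rep(0, 4)),
                        hemisphere = c("L", "R", "L", "R"))
  ms0 <- module_summary(ht0)
  expect_equal(nrow(ms0), 1)
  expect_equal(ms0$n_connector, 0)
  expect_equal(ms0$n_provincial, 0)
  expect_equal(ms0$connector_rois, "")
})
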