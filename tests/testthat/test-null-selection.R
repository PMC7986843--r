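test_that("degree-preserving rewiring conserves per-node degrees exactly", {
  # star K_{1,3}: the only simple graph on (3,1,1,1) is the star itself
  star <- toy_graph(4, rbind(c(1, 2), c(1, 3), c(1, 4)))
  r <- rewire_degree_preserving(star, seed = 2)
  expect_identical(igraph::degree(r), igraph::degree(star))
  expect_true(igraph::isomorphic(r, star))

  # 6-cycle: all degrees 2 afterwards, whatever the edge set
  cyc <- toy_graph(6, cbind(1:6, c(2:6, 1)))
  rc <- rewire_degree_preserving(cyc, seed = 3)
  expect_true(all(igraph::degree(rc) == 2))

  # random 30-node fixture: in-order degree tally is identical
  set.seed(59)
  adj <- matrix(0L, 30, 30)
  adj[upper.tri(adj)] <- rbinom(435, 1, 0.15)
  adj <- adj + t(adj)
  dimnames(adj) <- list(paste0("n", 1:30), paste0("n", 1:30))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  for (s in 1:5) {
    rg <- rewire_degree_preserving(g, seed = s)
    expect_identical(igraph::degree(rg), rowSums(adj)[igraph::V(g)$name])
    expect_false(igraph::any_multiple(rg))
    expect_false(any(igraph::which_loop(rg)))
  }
})

test_that("graphs with fewer than two edges are returned unchanged with a warning", {
  g1 <- toy_graph(3, rbind(c(1, 2)))
  expect_warning(r <- rewire_degree_preserving(g1, seed = 1), "unchanged")
  expect_identical(igraph::as_edgelist(r), igraph::as_edgelist(g1))
})

test_that("null expected stability is the mean pairwise agreement of null partitions", {
  expect_error(null_expected_stability(toy_graph(4, rbind(c(1, 2), c(3, 4))), m = 1),
               "m >= 2")

  # rigid graph: every randomization is the graph itself, stability 1
  star <- toy_graph(5, rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  expect_equal(null_expected_stability(star, m = 4, seed = 8), 1)

  # 20-node two-clique fixture: value equals a brute-force loop over the
  # unordered pairs of partitions generated from the same seeded stream
  k10 <- t(combn(1:10, 2))
  g <- toy_graph(20, rbind(k10, k10 + 10L))
  m <- 5
  v <- null_expected_stability(g, m = m, seed = 21)
  set.seed(21)
  parts <- lapply(seq_len(m), function(i)
    detect_modules(rewire_degree_preserving(g)))
  tot <- 0
  for (i in 1:(m - 1)) for (j in (i + 1):m)
    tot <- tot + bf_agreement(parts[[i]], parts[[j]])
  expect_equal(v, tot / choose(m, 2), tolerance = 1e-12)
  # m = 2 reduces to the single pairwise agreement
  v2 <- null_expected_stability(g, m = 2, seed = 22)
  set.seed(22)
  p1 <- detect_modules(rewire_degree_preserving(g))
  p2 <- detect_modules(rewire_degree_preserving(g))
  expect_equal(v2, partition_agreement(p1, p2), tolerance = 1e-12)
})

test_that("threshold selection maximizes S_delta with ties toward smaller t", {
  fake <- function(th, sd) {
    structure(list(profile = data.frame(threshold = th, s_delta = sd)),
              class = "stability_profile")
  }
  expect_equal(select_threshold(fake(c(0.3, 0.4, 0.5), c(0.1, 0.5, 0.2))), 0.4)
  expect_equal(select_threshold(fake(c(0.3, 0.4), c(0.5, 0.5))), 0.3)
})

test_that("the profile satisfies its arithmetic and structural invariants", {
  C <- block_correlation(24, 3, alpha = 0.8, beta = 0.1)
  x <- sample_gaussian(C, 40, seed = 5)
  fit <- stability_profile(x, thresholds = seq(0.3, 0.9, 0.15),
                           B = 12, m = 4, seed = 9)
  pr <- fit$profile
  expect_identical(pr$s_delta, pr$s_obs - pr$s_null)
  expect_true(fit$t_opt %in% pr$threshold)
  expect_equal(max(pr$s_delta), pr$s_delta[pr$threshold == fit$t_opt])
  expect_true(all(pr$s_obs > 0 & pr$s_obs <= 1))
  expect_true(all(pr$s_null > 0 & pr$s_null <= 1))
  expect_identical(select_threshold(fit), fit$t_opt)
  expect_identical(fit$modules_opt, fit$modules[[as.character(fit$t_opt)]])
  # conditional reports agree with their own decomposition identities
  for (rep in fit$reports) {
    expect_equal(rep$overall, mean(rep$node_stability), tolerance = 1e-12)
    expect_equal(unname(rep$module_stability),
                 unname(sapply(module_members(rep$reference), function(nn)
                   mean(rep$node_stability[nn]))), tolerance = 1e-12)
  }
  # a grid of one threshold trivially selects it; edgeless thresholds are legal
  one <- stability_profile(x, thresholds = 0.99, B = 5, m = 3, seed = 2)
  expect_equal(one$t_opt, 0.99)
  expect_true(all(one$profile$edgeless ==
                    (one$profile$n_edges == 0)))
})

test_that("seeded profiles are exactly reproducible and substreams are independent", {
  C <- block_correlation(15, 3, alpha = 0.7, beta = 0.1)
  x <- sample_gaussian(C, 30, seed = 77)
  f1 <- stability_profile(x, thresholds = c(0.4, 0.6), B = 8, m = 3, seed = 5)
  f2 <- stability_profile(x, thresholds = c(0.4, 0.6), B = 8, m = 3, seed = 5)
  expect_identical(f1$profile, f2$profile)
  expect_identical(f1$modules_opt, f2$modules_opt)
  # changing m leaves the bootstrap-driven S_obs untouched
  f3 <- stability_profile(x, thresholds = c(0.4, 0.6), B = 8, m = 5, seed = 5)
  expect_identical(f1$profile$s_obs, f3$profile$s_obs)
})

test_that("near-perfect correlation is perfectly stable at any interior threshold", {
  # every resample reproduces the complete graph, so the detected partition
  # is identical in every replicate and all stabilities are exactly 1
  set.seed(101)
  z <- rnorm(25)
  x <- sapply(1:6, function(i) z + rnorm(25, sd = 0.05))
  colnames(x) <- paste0("v", 1:6)
  fit <- stability_profile(x, thresholds = 0.5, B = 10, m = 3, seed = 1)
  expect_equal(fit$profile$s_obs, 1)
  expect_equal(fit$reports[[1]]$overall, 1)
  expect_true(all(fit$reports[[1]]$node_stability == 1))
})

test_that("block-model recovery selects a threshold in the separating band", {
  # alpha = 0.8, beta = 0.1: a valid threshold lies in [beta, alpha)
  ex <- run_block_experiment(p = 40, n_modules = 4, alpha = 0.8, beta = 0.1,
                             N = 50, thresholds = seq(0.3, 0.9, 0.1),
                             B = 20, m = 8, seed = 6)
  expect_gte(ex$t_opt, 0.1)
  expect_lt(ex$t_opt, 0.8)
  expect_gte(ex$ari_stability, 0.9)
})

test_that("structureless data never shows a positive stability gap", {
  # the trivial-solution guard: with independent variables no threshold may
  # look better than its degree-matched null. S_delta can go well below
  # zero where a few noise edges survive (rewiring a near-empty graph is
  # nearly rigid while the bootstrap resamples which noise edges exist),
  # but it must never rise meaningfully above it.
  C <- diag(20)
  dimnames(C) <- list(paste0("v", 1:20), paste0("v", 1:20))
  x <- sample_gaussian(C, 60, seed = 3)
  fit <- stability_profile(x, thresholds = seq(0.3, 0.6, 0.1),
                           B = 20, m = 10, seed = 4)
  expect_lt(max(fit$profile$s_delta), 0.1)
})
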