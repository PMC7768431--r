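test_that("planted-partition network generation and recovery", {
  # p_out = 0 with two blocks can never connect: parameter error
  expect_error(make_true_network(20, 2, p_in = 0.5, p_out = 0, seed = 1,
                                 max_tries = 20),
               "no connected graph")

  # p_in = p_out = 1 gives the complete graph
  full <- make_true_network(12, 3, p_in = 1, p_out = 1, seed = 2)
  expect_equal(igraph::ecount(full$graph), choose(12, 2))

  # Louvain recovers a well-separated planted partition
  net <- make_true_network(40, 4, p_in = 0.6, p_out = 0.05, seed = 3)
  memb <- modularity_louvain(net$graph, seed = 4)$membership
  expect_gte(mclust::adjustedRandIndex(memb, net$partition), 0.9)
})

test_that("censored walks emit each word at most once, at the target rate", {
  net <- make_true_network(seed = 10)
  for (eps in c(0, 0.3, 1)) {
    rec <- simulate_fluency(net$graph, n_participants = 29,
                            jump_prob = eps, seed = 20 + eps * 10)
    dup <- tapply(rec$response, rec$participant, anyDuplicated)
    expect_true(all(dup == 0))
  }
  rec <- simulate_fluency(net$graph, n_participants = 29, jump_prob = 0.2,
                          seed = 33)
  len <- tapply(rec$order, rec$participant, max)
  se <- sd(len) / sqrt(length(len))
  expect_lt(abs(mean(len) - 10), 3 * se + 1e-9)
})

test_that("full-teleport walks sample words uniformly", {
  net <- make_true_network(seed = 44)
  rec <- simulate_fluency(net$graph, n_participants = 100, jump_prob = 1,
                          seed = 45)
  counts <- table(factor(rec$response, levels = igraph::V(net$graph)$name))
  expect_gt(suppressWarnings(chisq.test(counts)$p.value), 0.01)
})

test_that("walks confined to one community stay in it", {
  # single-community graph restricted from a planted network: with eps = 0
  # and no between-community edges a walk cannot leave its start community
  net <- make_true_network(40, 4, p_in = 0.8, p_out = 0.1, seed = 50)
  g1 <- igraph::induced_subgraph(net$graph, which(net$partition == 1))
  rec <- simulate_fluency(g1, n_participants = 5, mean_responses = 6,
                          jump_prob = 0, seed = 51)
  expect_true(all(rec$response %in% igraph::V(g1)$name))
})

test_that("estimated-network modularity decreases with teleport probability", {
  qbar <- vapply(c(0, 0.2, 0.4, 0.8), function(eps) {
    qs <- vapply(1:20, function(s) {
      net <- make_true_network(seed = 600 + s)
      rec <- simulate_fluency(net$graph, n_participants = 29,
                              jump_prob = eps, seed = 700 + s)
      mat <- preprocess_responses(rec, min_producers = 2)
      g <- estimate_network(mat)
      modularity_louvain(g, seed = 800 + s)$q
    }, numeric(1))
    mean(qs)
  }, numeric(1))
  expect_true(all(diff(qbar) < 0))
})

test_that("the synthetic token universe matches the target study scale", {
  for (s in c(1, 2, 3)) {
    st <- simulate_study(seed = s)
    universe <- ncol(preprocess_responses(st$records, min_producers = 1))
    expect_gte(universe, 120)
    expect_lte(universe, 140)
  }
})

test_that("median split on the grouping score recovers generating groups", {
  st <- simulate_study(seed = 7)
  sp <- median_split(st$scores, "odt")
  expect_identical(
    as.character(sp$group[match(st$scores$participant, sp$participant)]),
    st$scores$group_true)
})

test_that("identical seeds reproduce the study byte for byte", {
  s1 <- simulate_study(seed = 99)
  s2 <- simulate_study(seed = 99)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$scores, s2$scores)
  expect_identical(igraph::as_edgelist(s1$true_network$graph),
                   igraph::as_edgelist(s2$true_network$graph))
})
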