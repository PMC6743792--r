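test_that("scale_to_unit divides each gene row by its maximum", {
  m <- rbind(g1 = c(2, 4, 8), g2 = c(5, 5, 5))
  s <- scale_to_unit(m)
  expect_equal(s["g1", ], c(0.25, 0.5, 1.0), ignore_attr = TRUE)
  expect_equal(s["g2", ], c(1, 1, 1), ignore_attr = TRUE)
  expect_warning(z <- scale_to_unit(rbind(g1 = c(0, 0))), "all-zero")
  expect_equal(unname(z[1, ]), c(0, 0))
  expect_error(scale_to_unit(rbind(g1 = c(-1, 2))), "negative")
})

test_that("ensemble activities match closed forms within Monte-Carlo error", {
  set.seed(101)
  runs <- 4000L
  se <- sqrt(0.25 / runs)
  # single source node holds its Bernoulli draw
  rs1 <- rule_set(list(S = hold_rule("S")))
  a <- simulate_ensemble(rs1, c(S = 0.3), sim_config(runs = runs))
  expect_lt(abs(a[["S"]] - 0.3), 4 * se)
  # chain copies the source; inhibition negates it
  rs2 <- chain_ruleset(2)
  a2 <- simulate_ensemble(rs2, c(A = 0.7, B = 0.1), sim_config(runs = runs))
  expect_lt(abs(a2[["B"]] - 0.7), 4 * se)
  rs3 <- chain_ruleset(2, sign = -1L)
  a3 <- simulate_ensemble(rs3, c(A = 0.7, B = 0.1), sim_config(runs = runs))
  expect_lt(abs(a3[["B"]] - 0.3), 4 * se)
})

test_that("clamped nodes are pinned exactly and activities stay in [0,1]", {
  rs <- chain_ruleset(3)
  a <- simulate_ensemble(rs, c(A = 0.3, B = 0.5, C = 0.5),
                         sim_config(runs = 500), clamps = c(A = 1L))
  expect_identical(unname(a[c("A", "B", "C")]), c(1, 1, 1))
  a0 <- simulate_ensemble(rs, c(A = 0.3, B = 0.5, C = 0.5),
                          sim_config(runs = 500), clamps = c(A = 0L))
  expect_identical(unname(a0[["A"]]), 0)
  set.seed(5)
  g <- generate_random_network(15, seed = 5)
  act <- generate_np_data(g, random_ruleset(g), 3, sim_config(runs = 200))
  expect_true(all(act >= 0 & act <= 1))
})

test_that("exact oracle reproduces closed forms", {
  rs1 <- rule_set(list(S = hold_rule("S")))
  expect_equal(exact_state_distribution(rs1, c(S = 0.3))[["S"]], 0.3)
  # 2-cycle of copy rules alternates; even tail averages to (pA + pB)/2
  cyc <- rule_set(list(A = copy_rule("A", "B"), B = copy_rule("B", "A")))
  ex <- exact_state_distribution(cyc, c(A = 0.2, B = 0.8))
  expect_equal(unname(ex), c(0.5, 0.5), tolerance = 1e-12)
  expect_error(exact_state_distribution(
    rule_set(stats::setNames(lapply(paste0("n", 1:13), hold_rule),
                             paste0("n", 1:13))),
    stats::setNames(rep(0.5, 13), paste0("n", 1:13))), "12 nodes")
})

test_that("ensemble simulator agrees with the exact oracle on random networks", {
  runs <- 2000L
  bound <- 4 * sqrt(0.25 / runs)
  for (seed in 1:10) {
    g <- generate_random_network(6, seed = seed, p_inhibitory = 0.3)
    rs <- random_ruleset(g, seed = seed)
    set.seed(seed + 1000)
    init <- stats::setNames(stats::runif(6), g$nodes)
    ex <- exact_state_distribution(rs, init, node_order = g$nodes)
    set.seed(seed + 2000)
    mc <- simulate_ensemble(rs, init, sim_config(runs = runs),
                            node_order = g$nodes)
    expect_true(all(abs(mc - ex) < bound),
                info = paste("seed", seed))
  }
})

test_that("ensemble estimate converges to the exact oracle as runs grow", {
  g <- generate_random_network(6, seed = 77)
  rs <- random_ruleset(g, seed = 77)
  init <- stats::setNames(rep(0.5, 6), g$nodes)
  ex <- exact_state_distribution(rs, init, node_order = g$nodes)
  err <- vapply(c(100L, 1000L, 10000L), function(r) {
    set.seed(42)
    mc <- simulate_ensemble(rs, init, sim_config(runs = r),
                            node_order = g$nodes)
    sqrt(mean((mc - ex)^2))
  }, numeric(1))
  expect_lt(err[3], err[1])
})

test_that("raising a source activator's probability never lowers downstream activity", {
  g <- chain_graph(4)
  rs <- chain_ruleset(4)
  acts <- vapply(seq(0, 1, by = 0.25), function(p) {
    exact_state_distribution(
      rs, c(A = p, B = 0.5, C = 0.5, D = 0.5))[["D"]]
  }, numeric(1))
  expect_true(all(diff(acts) >= 0))
})

test_that("activities are past the transient at 100 steps", {
  # 30-node networks: doubling the horizon changes activities no more than
  # rerunning the same horizon with fresh randomness
  for (seed in 1:2) {
    g <- generate_random_network(30, seed = seed)
    rs <- random_ruleset(g, seed = seed)
    set.seed(seed)
    init <- stats::setNames(stats::runif(30), g$nodes)
    a100 <- simulate_ensemble(rs, init, sim_config(runs = 3000),
                              node_order = g$nodes)
    a100b <- simulate_ensemble(rs, init, sim_config(runs = 3000),
                               node_order = g$nodes)
    a200 <- simulate_ensemble(rs, init, sim_config(runs = 3000, steps = 200),
                              node_order = g$nodes)
    mc_scale <- mean(abs(a100 - a100b))
    expect_lt(mean(abs(a100 - a200)), 2 * mc_scale + 0.01)
  }
})

test_that("defaults and contracts: missing genes, tail bounds, missing rules", {
  rs <- chain_ruleset(2)
  expect_message(a <- simulate_ensemble(rs, c(A = 1), sim_config(runs = 200)),
                 "0.5")
  expect_equal(unname(a[["B"]]), 1)  # B copies the always-on source A
  expect_error(sim_config(steps = 5, tail = 10), "tail")
  bad <- rule_set(list(A = hold_rule("A")))
  expect_error(simulate_ensemble(bad, c(A = 0.5, B = 0.5),
                                 node_order = c("A", "B")), "without rule")
})

test_that("asynchronous mode runs and respects bounds and clamps", {
  g <- generate_random_network(8, seed = 9)
  rs <- random_ruleset(g, seed = 9)
  set.seed(9)
  init <- stats::setNames(stats::runif(8), g$nodes)
  a <- simulate_ensemble(rs, init,
                         sim_config(runs = 200, mode = "asynchronous"),
                         clamps = stats::setNames(1L, g$nodes[1]),
                         node_order = g$nodes)
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(unname(a[[g$nodes[1]]]), 1)
})
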