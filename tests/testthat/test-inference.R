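test_that("global fitness implements the steady-state deviation", {
  D <- matrix(c(1, 0), nrow = 2, dimnames = list(c("A", "B"), "s1"))
  O <- matrix(c(0.5, 0.5), nrow = 2, dimnames = list(c("A", "B"), "s1"))
  expect_equal(global_fitness(D, D), 0)
  expect_equal(global_fitness(D, O), 0.25)
  expect_equal(global_fitness(cbind(D, D), cbind(O, O)), 0.5)  # additivity
  expect_error(global_fitness(D, O[, c(1, 1)]), "shapes differ")
})

test_that("node error sums squared deviations and averages to the global fitness", {
  D <- matrix(c(1, 1, 0, 1), 2, dimnames = list(c("A", "B"), NULL))
  O <- matrix(c(0, 1, 0, 1), 2, dimnames = list(c("A", "B"), NULL))
  expect_equal(node_error(D, O, "A"), 1)
  expect_equal(node_error(D, O, "B"), 0)
  expect_error(node_error(D, O, "Z"), "unknown node")
  set.seed(1)
  for (i in 1:5) {
    D <- matrix(stats::runif(20), 4, dimnames = list(letters[1:4], NULL))
    O <- matrix(stats::runif(20), 4, dimnames = list(letters[1:4], NULL))
    expect_equal(global_fitness(D, O),
                 mean(vapply(letters[1:4], node_error, numeric(1),
                             D = D, O = O)))
  }
})

test_that("sample_upstream keeps small regulator sets and weights by correlation", {
  cands <- data.frame(from = c("r1", "r2"), sign = c(1L, -1L))
  expect_identical(sample_upstream("y", cands, matrix(0, 0, 0)), cands)

  # equal weights: inclusion frequencies uniform (chi-square, alpha 0.01)
  set.seed(7)
  y <- stats::runif(30)
  expr_eq <- rbind(y = y, r1 = y, r2 = y, r3 = y, r4 = y)
  cands4 <- data.frame(from = paste0("r", 1:4), sign = 1L)
  draws <- table(unlist(replicate(2500, {
    sample_upstream("y", cands4, expr_eq)$from
  })))
  expect_gt(stats::chisq.test(draws)$p.value, 0.01)

  # a constant (correlation-free) regulator is almost never included
  expr_w <- rbind(y = y, r1 = y + 1e-3, r2 = 2 * y, r3 = y^2,
                  r4 = rep(1, 30))
  inc4 <- mean(replicate(2000, "r4" %in%
                           sample_upstream("y", cands4, expr_w)$from))
  expect_lt(inc4, 0.01)
})

test_that("the genetic algorithm is deterministic, elitist, and handles generations = 0", {
  g <- generate_random_network(8, seed = 21)
  D <- generate_np_data(g, random_ruleset(g, seed = 21), 3,
                        sim_config(runs = 300), seed = 1)
  cfg <- ga_config(generations = 0, fitness_runs = 50)
  ga0 <- run_genetic_algorithm(g, D, cfg, sim_config(runs = 50), seed = 4)
  expect_equal(nrow(ga0$trace), 1L)

  cfg10 <- ga_config(generations = 10, fitness_runs = 50)
  ga_a <- run_genetic_algorithm(g, D, cfg10, sim_config(runs = 50), seed = 4)
  ga_b <- run_genetic_algorithm(g, D, cfg10, sim_config(runs = 50), seed = 4)
  expect_identical(ga_a$trace, ga_b$trace)
  expect_identical(lapply(ga_a$best, rule_to_text),
                   lapply(ga_b$best, rule_to_text))
  expect_true(all(diff(ga_a$trace$best) <= 0))  # elitism: non-increasing
})

test_that("GA fitness improvement plateaus after the early generations", {
  # planted 10-node networks: most of the improvement happens early
  drops_early <- 0; drops_late <- 0
  for (seed in 1:3) {
    g <- generate_random_network(10, seed = seed)
    D <- generate_np_data(g, random_ruleset(g, seed = seed), 5,
                          sim_config(runs = 500), seed = seed)
    ga <- run_genetic_algorithm(g, D, ga_config(generations = 60,
                                                fitness_runs = 50),
                                sim_config(runs = 50), seed = seed)
    best <- ga$trace$best
    drops_early <- drops_early + (best[1] - best[21])
    drops_late <- drops_late + (best[21] - best[61])
  }
  expect_lt(drops_late, 0.5 * drops_early + 1e-9)
})

test_that("local search recovers planted rules exactly on noise-free DAG data", {
  # exact engine + data generated by the exact oracle: the planted rule's
  # node error is zero, so with tolerance 0 every ERS member fits perfectly
  for (seed in 1:3) {
    g <- generate_random_network(7, seed = seed)
    rs_true <- random_ruleset(g, seed = seed)
    set.seed(seed)
    init <- matrix(stats::runif(7 * 4), 7,
                   dimnames = list(g$nodes, paste0("s", 1:4)))
    D <- exact_state_distribution(rs_true, init, node_order = g$nodes)
    ers <- local_search(g, D, rs_true, tolerance = 0,
                        sim_cfg = exact_cfg())
    for (v in names(ers$nodes)) {
      expect_lt(ers$nodes[[v]]$min_error, 1e-9)
      expect_true(ers$nodes[[v]]$best_mask %in% ers$nodes[[v]]$masks)
    }
    acc <- rule_accuracy(ers, rs_true)
    expect_equal(acc[["ers_pct"]], 100)
  }
})

test_that("infinite tolerance admits the whole rule space", {
  g <- ffl_graph()
  rs <- rule_set(list(A = hold_rule("A"), B = copy_rule("B", "A"),
                      C = new_rule("C", c("A", "B"), c(1L, 1L), 2L)))
  D <- exact_state_distribution(rs, matrix(stats::runif(6), 3,
                                           dimnames = list(c("A", "B", "C"),
                                                           NULL)))
  ers <- local_search(g, D, rs, tolerance = 1e12, sim_cfg = exact_cfg())
  expect_length(ers$nodes$C$masks, 7L)  # full space for 2 regulators
  expect_length(ers$nodes$B$masks, 1L)
})

test_that("feed-forward motifs yield multi-member equivalent rule sets", {
  # planted C := B; since B mirrors A at steady state, C := A (and the
  # A/B combinations) are indistinguishable from cross-sectional data
  g <- ffl_graph()
  truth <- rule_set(list(A = hold_rule("A"), B = copy_rule("B", "A"),
                         C = new_rule("C", c("A", "B"), c(1L, 1L), 2L)))
  set.seed(33)
  init <- matrix(stats::runif(3 * 5), 3,
                 dimnames = list(c("A", "B", "C"), NULL))
  D <- exact_state_distribution(truth, init, node_order = g$nodes)
  ers <- local_search(g, D, truth, tolerance = 0, sim_cfg = exact_cfg())
  expect_gt(length(ers$nodes$C$masks), 1L)
  expect_true(1L %in% ers$nodes$C$masks)  # C := A alone fits too
})

test_that("infer_rules is deterministic and ERS accuracy dominates exact accuracy", {
  g <- generate_random_network(8, seed = 55)
  rs_true <- random_ruleset(g, seed = 55)
  D <- generate_np_data(g, rs_true, 4, sim_config(runs = 400), seed = 2)
  cfg <- ga_config(generations = 8, fitness_runs = 50, refine_runs = 200)
  f1 <- infer_rules(g, D, cfg, sim_config(runs = 50), seed = 11)
  f2 <- infer_rules(g, D, cfg, sim_config(runs = 50), seed = 11)
  expect_identical(lapply(f1$best, rule_to_text),
                   lapply(f2$best, rule_to_text))
  expect_identical(lapply(f1$ers$nodes, `[[`, "masks"),
                   lapply(f2$ers$nodes, `[[`, "masks"))
  acc <- rule_accuracy(f1$ers, rs_true)
  expect_gte(acc[["ers_pct"]], acc[["exact_pct"]])
  expect_error(infer_rules(g, D[, 1, drop = FALSE]), "2 samples")
  rownames(D) <- paste0("other", 1:8)
  expect_error(suppressMessages(infer_rules(g, D)), "no overlap")
})

test_that("shared-trajectory candidate scoring equals per-candidate resimulation", {
  # the exact engine is deterministic, so on a DAG both evaluation routes
  # must produce identical candidate errors, ERS members, and best rules
  for (seed in c(3, 9)) {
    g <- generate_random_network(8, seed = seed)
    rs <- random_ruleset(g, seed = seed)
    set.seed(seed)
    init <- matrix(stats::runif(8 * 3), 8, dimnames = list(g$nodes, NULL))
    D <- exact_state_distribution(rs, init, node_order = g$nodes)
    e1 <- local_search(g, D, rs, tolerance = 0.1, sim_cfg = exact_cfg(),
                       candidate_eval = "shared")
    e2 <- local_search(g, D, rs, tolerance = 0.1, sim_cfg = exact_cfg(),
                       candidate_eval = "resim")
    expect_equal(lapply(e1$nodes, `[[`, "masks"),
                 lapply(e2$nodes, `[[`, "masks"))
    expect_equal(lapply(e1$nodes, `[[`, "min_error"),
                 lapply(e2$nodes, `[[`, "min_error"))
    expect_identical(lapply(e1$best, rule_to_text),
                     lapply(e2$best, rule_to_text))
  }
  # Monte-Carlo route: shared scoring agrees with resimulation within noise
  g <- generate_random_network(7, seed = 4)
  rs <- random_ruleset(g, seed = 4)
  D <- generate_np_data(g, rs, 3, sim_config(runs = 1000), seed = 4)
  s1 <- local_search(g, D, rs, sim_cfg = sim_config(runs = 2000),
                     seed = 1, candidate_eval = "shared")
  s2 <- local_search(g, D, rs, sim_cfg = sim_config(runs = 2000),
                     seed = 2, candidate_eval = "resim")
  for (v in names(s1$nodes)) {
    expect_lt(abs(s1$nodes[[v]]$min_error - s2$nodes[[v]]$min_error), 0.05)
  }
})
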