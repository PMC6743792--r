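#' Desk-scale rule-recovery benchmark protocol
#'
#' The standard recovery experiment, scaled for a desktop run: each trial
#' draws a random signed network (15-25 nodes by default, in-degree at
#' most 3), plants a random rule set, generates the requested number of
#' cross-sectional samples by ensemble propagation from Uniform(0,1)
#' initial probabilities, optionally corrupts the data with multiplicative
#' noise, and runs the full inference (GA population 24 for
#' `generations` generations, then exhaustive local search with the
#' reporting ensemble of 1000 runs). Reported per trial: ERS and exact
#' recovery percentages.
#'
#' @param n_trials number of seeded trials (>= 10 for reporting).
#' @param n_samples simulated samples per trial.
#' @param noise multiplicative noise level applied to the generated data
#'   (0.1 = 10\%).
#' @param node_range candidate network sizes, sampled per trial.
#' @param seed master seed; all per-trial seeds derive from it.
#' @param generations GA generations (the reported setting is 120; the
#'   error plateaus well before 40, which is the desk-scale default).
#' @return data frame, one row per trial, with the columns of
#'   [run_recovery_experiment()].
#' @export
benchmark_rule_recovery <- function(n_trials = 10L, n_samples = 5L,
                                    noise = 0, node_range = 15:25,
                                    seed = 1L, generations = 40L) {
  set.seed(seed)
  seeds <- matrix(sample.int(2^31 - 1, 3L * n_trials), ncol = 3L)
  ga_cfg <- ga_config(generations = generations, fitness_runs = 100L,
                      refine_runs = 1000L)
  rows <- lapply(seq_len(n_trials), function(i) {
    set.seed(seeds[i, 1L])
    n <- if (length(node_range) > 1L) sample(node_range, 1L) else node_range
    g <- generate_random_network(n, seed = seeds[i, 2L])
    tab <- run_recovery_experiment(g, noise_levels = noise,
                                   sample_counts = n_samples,
                                   seeds = seeds[i, 3L], ga_cfg = ga_cfg)
    tab$trial <- i
    tab
  })
  do.call(rbind, rows)
}

#' Desk-scale source-attenuation ROC protocol
#'
#' The standard pathway-analysis discrimination benchmark: per network and
#' replicate, negative-binomial baseline counts are propagated through the
#' same planted random rules with source attenuation 0 (reference) and `a`
#' (treated); the full pathway analysis yields one p-value per cell; the
#' ROC treats `-log10 p` at attenuation 0 as the null class and at each
#' positive level as the alternative.
#'
#' @param levels log2 attenuation levels (0 must be included).
#' @param n_networks,n_nodes synthetic test networks.
#' @param n_replicates replicates per network and level.
#' @param n_samples samples per condition.
#' @param seed master seed.
#' @param n_perm permutations for each p-value.
#' @return list with `table` and `auc` as in
#'   [run_attenuation_experiment()].
#' @export
benchmark_attenuation_auc <- function(levels = c(0, 2), n_networks = 3L,
                                      n_nodes = 15L, n_replicates = 5L,
                                      n_samples = 5L, seed = 1L,
                                      n_perm = 500L) {
  set.seed(seed)
  net_seeds <- sample.int(2^31 - 1, n_networks + 1L)
  nets <- lapply(seq_len(n_networks), function(i)
    generate_random_network(n_nodes, seed = net_seeds[i]))
  ga_cfg <- ga_config(generations = 20L, fitness_runs = 100L,
                      refine_runs = 300L)
  run_attenuation_experiment(nets, levels = levels,
                             n_replicates = n_replicates,
                             n_samples = n_samples,
                             ga_cfg = ga_cfg,
                             sim_cfg = sim_config(runs = 500L),
                             n_perm = n_perm,
                             seed = net_seeds[n_networks + 1L])
}
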