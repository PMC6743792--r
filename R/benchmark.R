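#' Synthetic gene-wise negative-binomial parameters
#'
#' Stand-in for parameters estimated from real RNA-seq: log-normal means
#' (median ~100 counts, one log-unit spread) and Gamma-distributed
#' dispersions (mean 0.2), the typical magnitude for bulk RNA-seq.
#'
#' @param genes character vector of gene ids.
#' @param seed optional integer seed.
#' @param meanlog,sdlog log-normal parameters for the means.
#' @param disp_shape,disp_scale Gamma parameters for the dispersions.
#' @return list with named numeric vectors `means` and `dispersions`.
#' @export
nb_params <- function(genes, seed = NULL, meanlog = log(100), sdlog = 1,
                      disp_shape = 2, disp_scale = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  list(means = stats::setNames(stats::rlnorm(length(genes), meanlog, sdlog),
                               genes),
       dispersions = stats::setNames(
         stats::rgamma(length(genes), shape = disp_shape,
                       scale = disp_scale), genes))
}

#' Simulate negative-binomial counts
#'
#' Gene-wise NB draws parameterized by mean `mu` and dispersion `alpha`
#' with variance `mu + alpha * mu^2` (`size = 1/alpha`); the `alpha -> 0`
#' limit is Poisson.
#'
#' @param means positive gene-wise means (named).
#' @param dispersions positive gene-wise dispersions, aligned.
#' @param n_samples number of samples (columns).
#' @param seed optional integer seed.
#' @return genes x samples integer-valued matrix.
#' @export
simulate_counts <- function(means, dispersions, n_samples, seed = NULL) {
  if (length(means) != length(dispersions)) stop("parameter vectors differ in length")
  if (any(means <= 0) || any(dispersions <= 0))
    stop("means and dispersions must be positive")
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rnbinom(length(means) * n_samples,
                             mu = rep(means, n_samples),
                             size = rep(1 / dispersions, n_samples)),
              nrow = length(means), ncol = n_samples,
              dimnames = list(names(means),
                              paste0("s", seq_len(n_samples))))
  m
}

#' Multiplicative uniform noise on scaled data
#'
#' Each entry is multiplied by `(1 + u)`, `u ~ Uniform(-level, +level)`,
#' then clipped back to `[0, 1]`.
#'
#' @param mat matrix with entries in `[0, 1]`.
#' @param level noise level (0.1 = 10\% noise).
#' @param seed optional integer seed.
#' @return matrix of the same shape.
#' @export
add_noise <- function(mat, level, seed = NULL) {
  if (level < 0) stop("noise level must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  u <- matrix(stats::runif(length(mat), -level, level), nrow(mat))
  pmin(pmax(mat * (1 + u), 0), 1)
}

#' Generate cross-sectional data by network propagation
#'
#' The rule-recovery protocol's data generator: per sample, every node
#' gets an initial probability drawn from Uniform(0, 1); activities are
#' the propagated ensemble averages under the planted rules.
#'
#' @param graph a `signed_graph`.
#' @param ruleset planted `rule_set` (default: random).
#' @param n_samples number of samples.
#' @param sim_cfg a [sim_config()].
#' @param seed optional integer seed.
#' @return nodes x samples matrix of activities in `[0, 1]`.
#' @export
generate_np_data <- function(graph, ruleset = NULL, n_samples = 5L,
                             sim_cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ruleset)) ruleset <- random_ruleset(graph)
  init <- matrix(stats::runif(length(graph$nodes) * n_samples),
                 nrow = length(graph$nodes),
                 dimnames = list(graph$nodes, paste0("s", seq_len(n_samples))))
  simulate_ensemble(ruleset, init, sim_cfg, node_order = graph$nodes)
}

#' Attenuate source nodes and propagate through random rules
#'
#' Multiplies the expression of all source (in-degree-0) genes by
#' `2^(-a)` — `a` in log2 units, so `a = 0` leaves them unchanged and
#' `a = 2` quarters them — then scales the matrix to `[0, 1]` and
#' propagates it through the network under a (planted or supplied) rule
#' set, emulating inhibition of the whole pathway mediated through its
#' sources. Propagated activities are mapped back to the expression scale
#' by each gene's original row maximum; genes outside the network pass
#' through unchanged.
#'
#' @param graph a `signed_graph` with at least one source node.
#' @param expr raw genes x samples matrix covering the network genes.
#' @param a attenuation in log2 units (>= 0).
#' @param ruleset optional `rule_set`; random when NULL.
#' @param sim_cfg a [sim_config()].
#' @param seed optional integer seed.
#' @param propagate if FALSE, only the source rows are attenuated and no
#'   propagation is performed (the no-propagation benchmark variant).
#' @return matrix of the same shape as `expr`.
#' @export
attenuate_and_propagate <- function(graph, expr, a, ruleset = NULL,
                                    sim_cfg = sim_config(), seed = NULL,
                                    propagate = TRUE) {
  if (a < 0) stop("attenuation must be >= 0")
  src <- source_nodes(graph)
  if (!length(src)) stop("network has no source (in-degree 0) nodes")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ruleset)) ruleset <- random_ruleset(graph)
  map <- suppressMessages(match_genes(graph, expr))
  out <- expr
  src_rows <- stats::na.omit(map[src])
  if (!propagate) {
    out[src_rows, ] <- out[src_rows, , drop = FALSE] * 2^(-a)
    return(out)
  }
  # attenuation is applied in scaled (activity) space: scaling uses the
  # ORIGINAL row maxima, otherwise dividing an attenuated row by its own
  # (equally attenuated) maximum would cancel the attenuation exactly
  present <- !is.na(map)
  row_max <- apply(expr[map[present], , drop = FALSE], 1L, max)
  sc <- suppressWarnings(scale_to_unit(expr))
  sc[src_rows, ] <- sc[src_rows, , drop = FALSE] * 2^(-a)
  data_net <- sc[map[present], , drop = FALSE]
  rownames(data_net) <- names(map)[present]
  act <- simulate_ensemble(ruleset, data_net, sim_cfg,
                           node_order = graph$nodes)
  out[map[present], ] <- act[names(map)[present], , drop = FALSE] * row_max
  out
}

#' Mann-Whitney ROC AUC
#'
#' Probability that a randomly chosen alternative-class score exceeds a
#' randomly chosen null-class score, ties counted one half; equivalent to
#' the area under the empirical ROC curve.
#'
#' @param null_scores scores of the null class.
#' @param alt_scores scores of the alternative (positive) class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(null_scores, alt_scores) {
  n0 <- length(null_scores); n1 <- length(alt_scores)
  if (n0 == 0L || n1 == 0L) stop("both score lists must be nonempty")
  r <- rank(c(null_scores, alt_scores))
  (sum(r[n0 + seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

recover_once <- function(graph, n_samples, noise, ga_cfg, sim_cfg,
                         gen_cfg, seed) {
  set.seed(seed)
  rs_true <- random_ruleset(graph)
  D <- generate_np_data(graph, rs_true, n_samples, gen_cfg)
  if (noise > 0) D <- add_noise(D, noise)
  t0 <- proc.time()[["elapsed"]]
  fit <- infer_rules(graph, D, ga_cfg, sim_cfg)
  runtime <- proc.time()[["elapsed"]] - t0
  acc <- rule_accuracy(fit$ers, rs_true)
  list(exact_pct = acc[["exact_pct"]], ers_pct = acc[["ers_pct"]],
       median_ers = median_ers_size(fit$ers),
       structural_distance = structural_distance(fit$best, graph),
       runtime = runtime, fit = fit, truth = rs_true)
}

#' Rule-recovery experiment over noise levels and sample counts
#'
#' For each (network, noise level, sample count, seed) cell: plant a
#' random rule set, generate propagated data, corrupt it with
#' multiplicative noise, run the full inference, and record recovery
#' metrics.
#'
#' @param networks list of `signed_graph` (or a single one).
#' @param noise_levels numeric vector of noise levels.
#' @param sample_counts integer vector of sample numbers.
#' @param seeds integer vector of seeds (one trial per seed).
#' @param ga_cfg,sim_cfg inference configurations.
#' @param gen_cfg simulation configuration used to generate the data.
#' @return data frame with one row per cell: `network`, `n_nodes`,
#'   `noise`, `n_samples`, `seed`, `exact_pct`, `ers_pct`, `median_ers`,
#'   `structural_distance`, `runtime`.
#' @export
run_recovery_experiment <- function(networks, noise_levels = 0,
                                    sample_counts = 5L, seeds = 1:10,
                                    ga_cfg = ga_config(),
                                    sim_cfg = sim_config(),
                                    gen_cfg = sim_config()) {
  if (inherits(networks, "signed_graph")) networks <- list(networks)
  rows <- list()
  for (ni in seq_along(networks)) {
    for (noise in noise_levels) {
      for (ns in sample_counts) {
        for (seed in seeds) {
          r <- recover_once(networks[[ni]], ns, noise, ga_cfg, sim_cfg,
                            gen_cfg, seed)
          rows[[length(rows) + 1L]] <- data.frame(
            network = ni, n_nodes = length(networks[[ni]]$nodes),
            noise = noise, n_samples = ns, seed = seed,
            exact_pct = r$exact_pct, ers_pct = r$ers_pct,
            median_ers = r$median_ers,
            structural_distance = r$structural_distance,
            runtime = r$runtime)
        }
      }
    }
  }
  do.call(rbind, rows)
}

# minimum structural distance over ERS member combinations; exact because
# the distance decomposes over target nodes (every edge has one target)
min_structural_distance <- function(ers, reference) {
  ref_by_target <- split(edge_keys(reference$edges), reference$edges$to)
  covered <- names(ers$nodes)
  total <- 0L
  for (v in covered) {
    ent <- ers$nodes[[v]]
    ref_in <- ref_by_target[[v]]
    if (is.null(ref_in)) ref_in <- character()
    k <- length(ent$regulators)
    pow <- bitwShiftL(1L, seq_len(k) - 1L)
    best <- Inf
    for (msk in ent$masks) {
      used <- logical(k)
      for (t in seq_len(bitwShiftL(1L, k) - 1L)) {
        if (bitwAnd(msk, bitwShiftL(1L, t - 1L)) != 0L)
          used <- used | (bitwAnd(t, pow) != 0L)
      }
      eff <- paste(ent$regulators[used], v, ent$signs[used], sep = "\r")
      dist <- length(setdiff(eff, ref_in)) + length(setdiff(ref_in, eff))
      best <- min(best, dist)
    }
    total <- total + best
  }
  # reference edges into nodes the ERS does not cover are all missing
  uncovered <- setdiff(names(ref_by_target), covered)
  total + sum(lengths(ref_by_target[uncovered]))
}

#' False-positive-edge robustness experiment
#'
#' Generates data from the true network's planted rules, corrupts the
#' prior by adding spurious edges as a multiple of the edge count, runs
#' inference on the corrupted prior, and records the minimum structural
#' distance to the true network over equivalent-rule-set member
#' combinations (chosen per node, which is exact since the distance
#' decomposes over targets).
#'
#' @param true_graph the uncorrupted `signed_graph`.
#' @param multiples nonnegative multiples of the edge count to add.
#' @param seeds integer vector of seeds.
#' @param n_samples samples of generated data.
#' @param ga_cfg,sim_cfg,gen_cfg configurations as in
#'   [run_recovery_experiment()].
#' @return data frame with columns `multiple`, `seed`, `n_false_edges`,
#'   `min_structural_distance`, `ers_pct`.
#' @export
run_false_edge_experiment <- function(true_graph,
                                      multiples = c(0, 0.2, 0.5, 1, 1.5, 2, 4),
                                      seeds = 1:10, n_samples = 5L,
                                      ga_cfg = ga_config(),
                                      sim_cfg = sim_config(),
                                      gen_cfg = sim_config()) {
  rows <- list()
  for (mult in multiples) {
    for (seed in seeds) {
      set.seed(seed)
      rs_true <- random_ruleset(true_graph)
      D <- generate_np_data(true_graph, rs_true, n_samples, gen_cfg)
      g_corrupt <- add_false_edges(true_graph, mult)
      fit <- infer_rules(g_corrupt, D, ga_cfg, sim_cfg)
      acc <- rule_accuracy(fit$ers, rs_true)
      rows[[length(rows) + 1L]] <- data.frame(
        multiple = mult, seed = seed,
        n_false_edges = n_edges(g_corrupt) - n_edges(true_graph),
        min_structural_distance = min_structural_distance(fit$ers,
                                                          true_graph),
        ers_pct = acc[["ers_pct"]])
    }
  }
  do.call(rbind, rows)
}

#' Source-attenuation pathway-analysis benchmark
#'
#' Per (network, replicate, attenuation level): draws negative-binomial
#' baseline counts for the network genes plus a resampling pool, builds
#' the two contrast conditions by propagating the counts through the same
#' planted random rules with source attenuation 0 (reference condition)
#' and `a` (treated condition), runs the full pathway analysis on the
#' contrast, and records the p-value. The level-0 cells — two
#' independently propagated unattenuated conditions — form the null class
#' for ROC construction: `-log10 p` at level 0 versus `-log10 p` at each
#' positive level, pooled across networks and replicates.
#'
#' @param networks list of `signed_graph`.
#' @param levels attenuation levels in log2 units (must include 0 for the
#'   AUC table).
#' @param n_replicates replicates per network and level.
#' @param n_samples samples per condition.
#' @param pool_factor pool genes as a multiple of network genes.
#' @param ga_cfg,sim_cfg configurations for inference and scoring.
#' @param n_perm permutations for the p-value null.
#' @param propagate propagate the attenuated signal (FALSE = attenuate
#'   sources only).
#' @param seed optional integer seed.
#' @return list with `table` (per-cell p-values) and `auc`
#'   (per positive level, pooled AUC vs level 0).
#' @export
run_attenuation_experiment <- function(networks,
                                       levels = c(0, 0.5, 1, 1.5, 2),
                                       n_replicates = 10L, n_samples = 5L,
                                       pool_factor = 2,
                                       ga_cfg = ga_config(),
                                       sim_cfg = sim_config(),
                                       n_perm = 1000L, propagate = TRUE,
                                       seed = NULL) {
  if (inherits(networks, "signed_graph")) networks <- list(networks)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (ni in seq_along(networks)) {
    g <- networks[[ni]]
    n_pool <- ceiling(pool_factor * length(g$nodes))
    genes <- c(g$nodes, paste0("pool", seq_len(n_pool)))
    for (rep_i in seq_len(n_replicates)) {
      pars <- nb_params(genes)
      for (a in levels) {
        counts <- simulate_counts(pars$means, pars$dispersions,
                                  2L * n_samples)
        colnames(counts) <- paste0("s", seq_len(2L * n_samples))
        rs <- random_ruleset(g)
        idx_ref <- seq_len(n_samples)
        idx_trt <- n_samples + seq_len(n_samples)
        ref <- attenuate_and_propagate(g, counts[, idx_ref, drop = FALSE],
                                       0, rs, sim_cfg,
                                       propagate = propagate)
        trt <- attenuate_and_propagate(g, counts[, idx_trt, drop = FALSE],
                                       a, rs, sim_cfg,
                                       propagate = propagate)
        expr <- cbind(ref, trt)
        colnames(expr) <- paste0("s", seq_len(ncol(expr)))
        contrast <- rep(c("reference", "treated"), each = n_samples)
        res <- run_pathway_analysis(g, expr, contrast, ga_cfg, sim_cfg,
                                    n_perm)
        rows[[length(rows) + 1L]] <- data.frame(
          network = ni, replicate = rep_i, level = a,
          M_p = res$M_p[1], p_value = res$p_value[1])
      }
    }
  }
  tab <- do.call(rbind, rows)
  auc <- NULL
  if (0 %in% tab$level) {
    null_scores <- -log10(tab$p_value[tab$level == 0])
    pos <- sort(setdiff(unique(tab$level), 0))
    if (length(pos)) {
      auc <- data.frame(level = pos, auc = vapply(pos, function(a)
        roc_auc(null_scores, -log10(tab$p_value[tab$level == a])),
        numeric(1)))
    }
  }
  list(table = tab, auc = auc)
}
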