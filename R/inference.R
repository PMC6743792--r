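#' Genetic-algorithm configuration for rule inference
#'
#' Defaults reproduce the reported settings: constant population of 24
#' individuals run for 120 generations (errors plateau well before 40),
#' with at most 3 regulators per node. Crossover/mutation rates,
#' tournament size and elitism are not fixed by the method description;
#' the defaults are standard GA practice. `ers_tolerance` is the relative
#' tolerance defining the equivalent rule set during local search:
#' a rule belongs to the ERS when its node error is at most
#' `min_error * (1 + tolerance) + 0.001 * n_samples` (the absolute floor
#' absorbs Monte-Carlo noise when the minimum is near zero).
#'
#' @param population individuals per generation (>= 2).
#' @param generations number of generations (0 = score the random initial
#'   population only).
#' @param crossover_prob probability an offspring is produced by
#'   uniform-by-node crossover; otherwise it is a single-node mutation
#'   (the two operators are mutually exclusive per offspring).
#' @param tournament tournament size for parent selection.
#' @param elitism keep the best-so-far individual in every generation.
#' @param ers_tolerance relative ERS tolerance (default 0.1).
#' @param fitness_runs ensemble size used for GA fitness evaluations
#'   (reduced from the reporting default for speed).
#' @param refine_runs ensemble size used for local-search node errors.
#' @return a `ga_config` list.
#' @export
ga_config <- function(population = 24L, generations = 120L,
                      crossover_prob = 0.6, tournament = 3L,
                      elitism = TRUE, ers_tolerance = 0.1,
                      fitness_runs = 100L, refine_runs = 1000L) {
  if (population < 2L) stop("population must be >= 2")
  if (crossover_prob < 0 || crossover_prob > 1) stop("crossover_prob not in [0,1]")
  if (ers_tolerance < 0) stop("ers_tolerance must be >= 0")
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 tournament = as.integer(tournament),
                 elitism = isTRUE(elitism),
                 ers_tolerance = ers_tolerance,
                 fitness_runs = as.integer(fitness_runs),
                 refine_runs = as.integer(refine_runs)),
            class = "ga_config")
}

#' Global fitness: steady-state deviation after propagation
#'
#' `sum over samples of (1/n) sum over nodes of (D - O)^2`, where `D` is
#' the scaled data and `O` the propagated activities; zero iff the
#' simulation exactly reproduces the data.
#'
#' @param D,O nodes x samples matrices of the same shape.
#' @return nonnegative scalar.
#' @export
global_fitness <- function(D, O) {
  if (!all(dim(D) == dim(O))) stop("D and O shapes differ")
  sum((D - O)^2) / nrow(D)
}

#' Node-wise error
#'
#' `sum over samples of (D[j,] - O[j,])^2` for one node; the global
#' fitness equals the mean of the node errors over nodes.
#'
#' @inheritParams global_fitness
#' @param node node id (rowname) or row index.
#' @return nonnegative scalar.
#' @export
node_error <- function(D, O, node) {
  if (!all(dim(D) == dim(O))) stop("D and O shapes differ")
  if (is.character(node)) {
    if (!node %in% rownames(D)) stop("unknown node: ", node)
  } else if (node < 1 || node > nrow(D)) stop("unknown node index: ", node)
  sum((D[node, ] - O[node, ])^2)
}

#' Sample three regulators by correlation weight
#'
#' For nodes with more than three upstream regulators, three are drawn
#' without replacement with inclusion weight proportional to the absolute
#' Spearman correlation between regulator and target across samples
#' (inhibitors anticorrelate, so the magnitude is used); regulators or
#' targets without expression rows get a small floor weight.
#'
#' @param node target node id.
#' @param candidates data frame with columns `from`, `sign` (as returned
#'   by [in_neighbors()]).
#' @param scaled_expr genes x samples matrix used for correlations.
#' @param n number of regulators to keep (default 3).
#' @param epsilon floor weight for zero/undefined correlations.
#' @return a subset of `candidates` with `n` rows (all rows when the
#'   candidate set is already small enough).
#' @export
sample_upstream <- function(node, candidates, scaled_expr, n = 3L,
                            epsilon = 1e-6) {
  if (nrow(candidates) <= n) return(candidates)
  rows <- rownames(scaled_expr)
  w <- vapply(candidates$from, function(u) {
    if (!node %in% rows || !u %in% rows) return(epsilon)
    r <- suppressWarnings(stats::cor(scaled_expr[u, ], scaled_expr[node, ],
                                     method = "spearman"))
    if (is.na(r)) epsilon else max(abs(r), epsilon)
  }, numeric(1))
  candidates[sample.int(nrow(candidates), n, prob = w), , drop = FALSE]
}

# ---- internal GA machinery -------------------------------------------------

# memoized truth tables keyed by (k, mask, sign pattern)
.tt_cache <- new.env(parent = emptyenv())
tt_from_mask <- function(k, signs, mask) {
  key <- paste(k, mask, paste(signs, collapse = ""), sep = "|")
  v <- .tt_cache[[key]]
  if (!is.null(v)) return(v)
  v <- rule_truth_table(new_rule("x", paste0("r", seq_len(k)), signs, mask))
  .tt_cache[[key]] <- v
  v
}

# inference context: everything fitness evaluation needs, precomputed
make_ctx <- function(graph, scaled_data, sim_cfg) {
  node_order <- graph$nodes
  has_data <- node_order %in% rownames(scaled_data)
  if (!any(has_data)) stop("no overlap between network genes and expression genes")
  if (ncol(scaled_data) < 2L) stop("at least 2 samples are required")
  in_nb <- lapply(node_order, function(v) in_neighbors(graph, v))
  names(in_nb) <- node_order
  D <- prep_init(scaled_data[intersect(rownames(scaled_data), node_order),
                             , drop = FALSE], node_order)
  list(graph = graph, node_order = node_order, m = length(node_order),
       d = ncol(D), D = D, has_data = has_data, in_nb = in_nb,
       scaled_data = scaled_data,
       non_source = which(vapply(in_nb, nrow, 1L) > 0L),
       clamp_none = rep(-1L, length(node_order)),
       idx_of = stats::setNames(seq_along(node_order), node_order),
       sim_cfg = sim_cfg)
}

n_masks_for <- function(k) bitwShiftL(1L, bitwShiftL(1L, k) - 1L) - 1L

random_node_rule <- function(ctx, j) {
  nb <- ctx$in_nb[[j]]
  if (nrow(nb) == 0L) return(list(regs = integer(), signs = integer(), mask = 0L))
  if (nrow(nb) > 3L)
    nb <- sample_upstream(ctx$node_order[j], nb, ctx$scaled_data)
  k <- nrow(nb)
  list(regs = unname(ctx$idx_of[nb$from]), signs = nb$sign,
       mask = sample.int(n_masks_for(k), 1L))
}

random_individual <- function(ctx)
  lapply(seq_len(ctx$m), function(j) random_node_rule(ctx, j))

compile_individual <- function(ind, ctx) {
  m <- ctx$m
  k <- integer(m); regs <- matrix(0L, m, 3L); tt <- matrix(0L, m, 8L)
  for (j in seq_len(m)) {
    kk <- length(ind[[j]]$regs)
    k[j] <- kk
    if (kk > 0L) {
      regs[j, seq_len(kk)] <- ind[[j]]$regs
      ttv <- tt_from_mask(kk, ind[[j]]$signs, ind[[j]]$mask)
      tt[j, seq_along(ttv)] <- ttv
    }
  }
  list(k = k, regs = regs, tt = tt)
}

sim_from_comp <- function(comp, ctx, runs, clamp = ctx$clamp_none) {
  cfg <- ctx$sim_cfg
  if (cfg$engine == "exact") {
    exact_core(comp, ctx$D, cfg$steps, cfg$tail, clamp)
  } else {
    simulate_ensemble_cpp(comp$k, comp$regs, comp$tt, ctx$D, runs,
                          cfg$steps, cfg$tail, clamp,
                          cfg$mode == "asynchronous")
  }
}

eval_individual <- function(ind, ctx, runs) {
  O <- sim_from_comp(compile_individual(ind, ctx), ctx, runs)
  sel <- ctx$has_data
  sum((ctx$D[sel, , drop = FALSE] - O[sel, , drop = FALSE])^2) / sum(sel)
}

individual_to_ruleset <- function(ind, ctx) {
  rules <- lapply(seq_len(ctx$m), function(j) {
    nd <- ind[[j]]
    if (length(nd$regs) == 0L) hold_rule(ctx$node_order[j])
    else new_rule(ctx$node_order[j], ctx$node_order[nd$regs], nd$signs, nd$mask)
  })
  names(rules) <- ctx$node_order
  rule_set(rules)
}

ruleset_to_individual <- function(rs, ctx) {
  lapply(seq_len(ctx$m), function(j) {
    rule <- rs[[ctx$node_order[j]]]
    if (is.null(rule)) stop("node without rule: ", ctx$node_order[j])
    if (is_hold(rule)) list(regs = integer(), signs = integer(), mask = 0L)
    else list(regs = unname(ctx$idx_of[rule$regulators]),
              signs = rule$signs, mask = rule$mask)
  })
}

tournament_pick <- function(fitness, size) {
  cand <- sample.int(length(fitness), min(size, length(fitness)))
  cand[which.min(fitness[cand])]
}

#' Run the genetic algorithm over rule sets
#'
#' Global search minimizing [global_fitness()]: the initial population is
#' random (each node a random regulator subset and nonzero term mask);
#' each generation produces `population` offspring by uniform-by-node
#' crossover of two tournament-selected parents or by mutating one node's
#' regulators and mask; with elitism the best-so-far individual replaces
#' the worst offspring, so the best fitness trace is non-increasing.
#'
#' @param graph a `signed_graph`.
#' @param scaled_data genes x samples matrix in `[0, 1]`
#'   (see [scale_to_unit()]); rownames must overlap the network nodes.
#' @param cfg a [ga_config()].
#' @param sim_cfg a [sim_config()].
#' @param seed optional integer seed.
#' @return list with `best` (a `rule_set`), `trace` (data frame
#'   `generation`, `best`, `mean`), and the internal `best_ind`/`ctx`
#'   used by [local_search()].
#' @export
run_genetic_algorithm <- function(graph, scaled_data, cfg = ga_config(),
                                  sim_cfg = sim_config(), seed = NULL) {
  if (length(graph$nodes) == 0L) stop("empty network")
  if (!is.null(seed)) set.seed(seed)
  ctx <- make_ctx(graph, scaled_data, sim_cfg)
  pop <- replicate(cfg$population, random_individual(ctx), simplify = FALSE)
  fit <- vapply(pop, eval_individual, numeric(1), ctx = ctx,
                runs = cfg$fitness_runs)
  best_i <- which.min(fit)
  best_ind <- pop[[best_i]]; best_fit <- fit[best_i]
  trace <- data.frame(generation = 0L, best = best_fit, mean = mean(fit))
  if (cfg$generations > 0L) {
    for (gen in seq_len(cfg$generations)) {
      offspring <- vector("list", cfg$population)
      for (o in seq_len(cfg$population)) {
        if (stats::runif(1) < cfg$crossover_prob) {
          p1 <- pop[[tournament_pick(fit, cfg$tournament)]]
          p2 <- pop[[tournament_pick(fit, cfg$tournament)]]
          pick <- stats::runif(ctx$m) < 0.5
          offspring[[o]] <- lapply(seq_len(ctx$m), function(j)
            if (pick[j]) p1[[j]] else p2[[j]])
        } else {
          child <- pop[[tournament_pick(fit, cfg$tournament)]]
          j <- if (length(ctx$non_source) == 1L) ctx$non_source
               else sample(ctx$non_source, 1L)
          child[[j]] <- random_node_rule(ctx, j)
          offspring[[o]] <- child
        }
      }
      ofit <- vapply(offspring, eval_individual, numeric(1), ctx = ctx,
                     runs = cfg$fitness_runs)
      if (cfg$elitism) {
        worst <- which.max(ofit)
        offspring[[worst]] <- best_ind
        ofit[worst] <- best_fit
      }
      pop <- offspring; fit <- ofit
      if (min(fit) < best_fit) {
        best_fit <- min(fit)
        best_ind <- pop[[which.min(fit)]]
      }
      trace <- rbind(trace, data.frame(generation = gen, best = best_fit,
                                       mean = mean(fit)))
    }
  }
  list(best = individual_to_ruleset(best_ind, ctx), best_ind = best_ind,
       trace = trace, ctx = ctx)
}

# sources-first node visit order: BFS distance from any source, ties by
# position; nodes unreachable from any source (pure cycles) come last
topo_order <- function(graph) {
  succ <- adj_list(graph, "out")
  dist <- stats::setNames(rep(Inf, length(graph$nodes)), graph$nodes)
  queue <- source_nodes(graph)
  dist[queue] <- 0
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (w in succ[[v]]) {
      if (is.infinite(dist[[w]])) {
        dist[w] <- dist[[v]] + 1
        queue <- c(queue, w)
      }
    }
  }
  graph$nodes[order(dist[graph$nodes], seq_along(graph$nodes))]
}

#' Exhaustive node-wise local search and equivalent rule sets
#'
#' Visits nodes in a sources-first order; at each node, enumerates every
#' rule over the regulators chosen by the GA while holding all other
#' rules fixed, scores each candidate by its node error under fresh
#' propagation, keeps all rules within tolerance of the minimum as the
#' node's equivalent rule set (ERS), and installs the minimal-error rule
#' before moving on.
#'
#' @param graph a `signed_graph`.
#' @param scaled_data genes x samples matrix in `[0, 1]`.
#' @param ga_best a `rule_set` (typically the GA optimum) fixing each
#'   node's regulator choice and the off-node rules.
#' @param tolerance relative ERS tolerance; membership threshold is
#'   `min_error * (1 + tolerance) + 0.001 * n_samples`.
#' @param sim_cfg a [sim_config()].
#' @param runs ensemble size for node-error evaluation (default the
#'   reporting ensemble of `sim_cfg$runs`).
#' @param seed optional integer seed.
#' @param candidate_eval `"shared"` (default) scores all of a node's
#'   candidate rules against one shared simulation of its regulators'
#'   trajectories — exact whenever the node cannot influence its own
#'   regulators, and a paired comparison otherwise impossible with
#'   independent ensembles; `"resim"` re-simulates per candidate.
#'   Feedback nodes and asynchronous mode always fall back to `"resim"`.
#' @return an object of class `ers`: `$nodes` maps each non-source node to
#'   `regulators`, `signs`, `masks` (ERS member encodings), `errors`,
#'   `best_mask`, `min_error`; `$best` is the refined `rule_set`;
#'   `$tolerance` the tolerance used.
#' @export
local_search <- function(graph, scaled_data, ga_best, tolerance = 0.1,
                         sim_cfg = sim_config(), runs = sim_cfg$runs,
                         seed = NULL,
                         candidate_eval = c("shared", "resim")) {
  if (!is.null(seed)) set.seed(seed)
  if (tolerance < 0) stop("tolerance must be >= 0")
  candidate_eval <- match.arg(candidate_eval)
  ctx <- make_ctx(graph, scaled_data, sim_cfg)
  cur <- ruleset_to_individual(ga_best, ctx)
  order_nodes <- topo_order(graph)
  floor_abs <- 0.001 * ctx$d
  ers_nodes <- list()
  for (v in order_nodes) {
    j <- ctx$idx_of[[v]]
    nd <- cur[[j]]
    k <- length(nd$regs)
    if (k == 0L) next
    n_masks <- n_masks_for(k)
    errors <- numeric(n_masks)
    # the node's candidates can share one simulation of its regulators'
    # trajectories, unless the node can influence a regulator (feedback)
    regnames <- ctx$node_order[nd$regs]
    shareable <- candidate_eval == "shared" &&
      sim_cfg$mode == "synchronous" &&
      !any(vapply(regnames, function(u) v %in% ancestors(graph, u),
                  logical(1)))
    if (shareable) {
      comp <- compile_individual(cur, ctx)
      freq <- if (sim_cfg$engine == "exact") {
        exact_tail_pattern_freq(comp, ctx$D, sim_cfg$steps, sim_cfg$tail,
                                ctx$clamp_none, j)
      } else {
        tail_pattern_freq_cpp(comp$k, comp$regs, comp$tt, ctx$D, runs,
                              sim_cfg$steps, sim_cfg$tail, ctx$clamp_none,
                              j)
      }
      freq_k <- freq[seq_len(bitwShiftL(1L, k)), , drop = FALSE]
      for (msk in seq_len(n_masks)) {
        ttv <- tt_from_mask(k, nd$signs, msk)
        acts <- as.numeric(crossprod(freq_k, ttv))
        errors[msk] <- sum((ctx$D[j, ] - acts)^2)
      }
    } else {
      for (msk in seq_len(n_masks)) {
        cur[[j]]$mask <- msk
        O <- sim_from_comp(compile_individual(cur, ctx), ctx, runs)
        errors[msk] <- sum((ctx$D[j, ] - O[j, ])^2)
      }
    }
    min_err <- min(errors)
    best_mask <- which.min(errors)
    members <- which(errors <= min_err * (1 + tolerance) + floor_abs)
    cur[[j]]$mask <- best_mask
    ers_nodes[[v]] <- list(regulators = ctx$node_order[nd$regs],
                           signs = nd$signs, masks = members,
                           errors = errors[members],
                           best_mask = best_mask, min_error = min_err)
  }
  structure(list(nodes = ers_nodes, tolerance = tolerance,
                 best = individual_to_ruleset(cur, ctx)),
            class = "ers")
}

#' @export
print.ers <- function(x, ...) {
  sizes <- vapply(x$nodes, function(e) length(e$masks), integer(1))
  cat("equivalent rule sets for", length(x$nodes), "nodes",
      sprintf("(tolerance %g); median size %g\n", x$tolerance,
              stats::median(sizes)))
  invisible(x)
}

#' Infer logic rules from a network and expression data
#'
#' End-to-end rule determination: scales expression to `[0, 1]`, matches
#' network genes to expression rows (case-insensitively), runs the
#' genetic algorithm, then refines with the exhaustive node-wise local
#' search.
#'
#' @param graph a `signed_graph`.
#' @param expr nonnegative genes x samples matrix (counts or
#'   exponentiated intensities), >= 2 samples.
#' @param ga_cfg a [ga_config()].
#' @param sim_cfg a [sim_config()].
#' @param seed optional integer seed controlling the whole run.
#' @return list with `ers` (equivalent rule sets), `best` (refined
#'   `rule_set`), `trace` (GA fitness trace), `scaled` (the network-
#'   aligned scaled data) and `log` (seed and configurations).
#' @export
infer_rules <- function(graph, expr, ga_cfg = ga_config(),
                        sim_cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (ncol(expr) < 2L) stop("at least 2 samples are required")
  map <- match_genes(graph, expr)
  present <- !is.na(map)
  if (!any(present)) stop("no overlap between network genes and expression genes")
  sc <- scale_to_unit(expr)
  data_net <- sc[map[present], , drop = FALSE]
  rownames(data_net) <- names(map)[present]
  ga <- run_genetic_algorithm(graph, data_net, ga_cfg, sim_cfg)
  ers <- local_search(graph, data_net, ga$best,
                      tolerance = ga_cfg$ers_tolerance, sim_cfg = sim_cfg,
                      runs = ga_cfg$refine_runs)
  list(ers = ers, best = ers$best, trace = ga$trace, scaled = data_net,
       log = list(seed = seed, ga_cfg = unclass(ga_cfg),
                  sim_cfg = unclass(sim_cfg)))
}
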