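#' Simulation configuration
#'
#' Defaults follow the method's reported settings: ensembles of 1000 runs,
#' 100 synchronous update steps, activities averaged over the last 10
#' steps. The 100-step horizon comfortably exceeds the longest shortest
#' path of curated signaling networks (17), so trajectories are past their
#' transient; the 10-step tail averages over terminal cycles as well as
#' fixed points.
#'
#' @param runs ensemble size (trajectories per sample).
#' @param steps synchronous update steps per trajectory.
#' @param tail number of final steps averaged into the activity
#'   (`tail <= steps`).
#' @param mode `"synchronous"` (used for all reported results) or
#'   `"asynchronous"` (one random-order full sweep per step).
#' @param engine `"ensemble"` (Monte Carlo) or `"exact"` (full enumeration
#'   of initial states, networks of at most 12 nodes).
#' @return a `sim_config` list.
#' @export
sim_config <- function(runs = 1000L, steps = 100L, tail = 10L,
                       mode = c("synchronous", "asynchronous"),
                       engine = c("ensemble", "exact")) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  if (tail > steps) stop("tail must be <= steps")
  if (runs < 1L || steps < 1L || tail < 1L) stop("runs, steps, tail must be >= 1")
  structure(list(runs = as.integer(runs), steps = as.integer(steps),
                 tail = as.integer(tail), mode = mode, engine = engine),
            class = "sim_config")
}

#' Scale expression to the unit interval
#'
#' Divides each gene's row by that gene's maximum across samples, the
#' transform under which a value is read as the proportion of cells with
#' the gene "on" (and hence as a Bernoulli initialization probability).
#' Scaling is per gene so every gene's activity spans `[0, 1]`; all-zero
#' rows map to zero with a warning.
#'
#' @param expr nonnegative numeric matrix, genes x samples.
#' @return matrix of the same shape with entries in `[0, 1]`.
#' @export
#' @examples
#' scale_to_unit(rbind(g1 = c(2, 4, 8)))
scale_to_unit <- function(expr) {
  if (any(expr < 0)) stop("expression matrix contains negative entries")
  mx <- apply(expr, 1L, max)
  zero <- mx == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero gene row(s) left at zero")
    mx[zero] <- 1
  }
  out <- expr / mx
  attr(out, "provenance") <- "data-scaled"
  out
}

# compile a rule_set into the flat arrays the C++ core consumes
compile_ruleset <- function(rs, node_order) {
  m <- length(node_order)
  k <- integer(m)
  regs <- matrix(0L, m, 3L)
  tt <- matrix(0L, m, 8L)
  for (j in seq_len(m)) {
    rule <- rs[[node_order[j]]]
    if (is.null(rule)) stop("node without rule: ", node_order[j])
    kk <- length(rule$regulators)
    k[j] <- kk
    if (kk > 0L) {
      idx <- match(rule$regulators, node_order)
      if (anyNA(idx)) stop("rule regulator outside network at node ",
                           node_order[j])
      regs[j, seq_len(kk)] <- idx
      ttv <- rule_truth_table(rule)
      tt[j, seq_len(length(ttv))] <- ttv
    }
  }
  list(k = k, regs = regs, tt = tt)
}

prep_init <- function(init, node_order) {
  if (is.null(dim(init))) init <- matrix(init, ncol = 1L,
                                         dimnames = list(names(init), NULL))
  miss <- setdiff(node_order, rownames(init))
  if (length(miss)) {
    message(length(miss), " node(s) without data initialize at 0.5: ",
            paste(utils::head(miss, 10), collapse = ", "))
    fill <- matrix(0.5, length(miss), ncol(init),
                   dimnames = list(miss, colnames(init)))
    init <- rbind(init, fill)
  }
  init[node_order, , drop = FALSE]
}

prep_clamp <- function(clamps, node_order) {
  cl <- rep(-1L, length(node_order))
  if (!is.null(clamps)) {
    bad <- setdiff(names(clamps), node_order)
    if (length(bad)) stop("clamp on unknown node: ", paste(bad, collapse = ", "))
    cl[match(names(clamps), node_order)] <- as.integer(clamps)
  }
  cl
}

#' Ensemble network propagation
#'
#' Runs `cfg$runs` Boolean trajectories per sample, each started from
#' independent Bernoulli draws of the scaled data, and reports per-node
#' activities as the mean state over the last `cfg$tail` steps of all
#' trajectories. Source nodes hold their sampled initial bit for the whole
#' run (no decay), which is what makes cross-sectional steady states
#' reachable; clamped nodes are pinned to the clamp value at every step
#' including the initial one.
#'
#' @param rs a `rule_set` covering every network node.
#' @param init named vector or nodes x samples matrix of initial
#'   probabilities in `[0, 1]`; nodes absent from `init` start at 0.5.
#' @param cfg a [sim_config()].
#' @param clamps optional named vector of 0/1 clamp values.
#' @param node_order optional node ordering (defaults to `names(rs)`).
#' @return matrix (nodes x samples) of activities in `[0, 1]`; a plain
#'   named vector when `init` was a vector.
#' @export
simulate_ensemble <- function(rs, init, cfg = sim_config(), clamps = NULL,
                              node_order = names(rs)) {
  vec_in <- is.null(dim(init))
  init <- prep_init(init, node_order)
  if (any(init < 0 | init > 1)) stop("initial probabilities must lie in [0,1]")
  if (cfg$engine == "exact") {
    out <- exact_state_distribution(rs, init, cfg, clamps, node_order)
    return(if (vec_in) out[, 1L] else out)
  }
  comp <- compile_ruleset(rs, node_order)
  cl <- prep_clamp(clamps, node_order)
  out <- simulate_ensemble_cpp(comp$k, comp$regs, comp$tt, init,
                               cfg$runs, cfg$steps, cfg$tail, cl,
                               cfg$mode == "asynchronous")
  dimnames(out) <- dimnames(init)
  attr(out, "provenance") <- "simulated"
  if (vec_in) out[, 1L] else out
}

#' Exact ensemble activity by enumeration of initial states
#'
#' Brute-force oracle for [simulate_ensemble()]: enumerates all `2^m`
#' initial states with product-Bernoulli weights, propagates each
#' deterministically (synchronous update is deterministic given the start
#' state), and returns the exact expectation of the tail-averaged
#' activity. Refuses networks larger than 12 nodes.
#'
#' @inheritParams simulate_ensemble
#' @return matrix (nodes x samples) of exact expected activities.
#' @export
exact_state_distribution <- function(rs, init, cfg = sim_config(),
                                     clamps = NULL, node_order = names(rs)) {
  m <- length(node_order)
  if (m > 12L) stop("exact enumeration is limited to 12 nodes")
  vec_in <- is.null(dim(init))
  init <- prep_init(init, node_order)
  cl <- prep_clamp(clamps, node_order)
  comp <- compile_ruleset(rs, node_order)
  out <- exact_core(comp, init, cfg$steps, cfg$tail, cl)
  dimnames(out) <- dimnames(init)
  attr(out, "provenance") <- "simulated-exact"
  if (vec_in) out[, 1L, drop = TRUE] else out
}

# exact expectation of the tail-averaged activity from compiled rule arrays
exact_core <- function(comp, init, steps, tail, cl) {
  m <- length(comp$k)
  if (m > 12L) stop("exact enumeration is limited to 12 nodes")
  n_states <- bitwShiftL(1L, m)
  states <- matrix(0L, n_states, m)
  for (j in seq_len(m))
    states[, j] <- bitwAnd(bitwShiftR(0:(n_states - 1L), j - 1L), 1L)

  # trajectory is deterministic per start state: propagate all states once
  cur <- states
  for (j in seq_len(m)) if (cl[j] >= 0L) cur[, j] <- cl[j]
  tail_sum <- matrix(0, n_states, m)
  for (t in seq_len(steps)) {
    nw <- cur
    for (j in seq_len(m)) {
      if (cl[j] >= 0L) { nw[, j] <- cl[j]; next }
      if (comp$k[j] == 0L) next
      idx <- cur[, comp$regs[j, 1L]] + 1L
      if (comp$k[j] > 1L) idx <- idx + 2L * cur[, comp$regs[j, 2L]]
      if (comp$k[j] > 2L) idx <- idx + 4L * cur[, comp$regs[j, 3L]]
      nw[, j] <- comp$tt[j, idx]
    }
    cur <- nw
    if (t > steps - tail) tail_sum <- tail_sum + cur
  }
  tail_mean <- tail_sum / tail

  out <- matrix(0, m, ncol(init))
  for (col in seq_len(ncol(init))) {
    p <- init[, col]
    p[cl >= 0L] <- cl[cl >= 0L]  # clamped nodes start at the clamp value
    w <- rep(1, n_states)
    for (j in seq_len(m))
      w <- w * ifelse(states[, j] == 1L, p[j], 1 - p[j])
    out[, col] <- as.numeric(crossprod(tail_mean, w))
  }
  out
}

# exact analogue of tail_pattern_freq_cpp: expected frequency of node j's
# regulator bit patterns over the states feeding the tail window
exact_tail_pattern_freq <- function(comp, init, steps, tail, cl, j) {
  m <- length(comp$k)
  if (m > 12L) stop("exact enumeration is limited to 12 nodes")
  n_states <- bitwShiftL(1L, m)
  states <- matrix(0L, n_states, m)
  for (jj in seq_len(m))
    states[, jj] <- bitwAnd(bitwShiftR(0:(n_states - 1L), jj - 1L), 1L)
  cur <- states
  for (jj in seq_len(m)) if (cl[jj] >= 0L) cur[, jj] <- cl[jj]
  pat_sum <- matrix(0, n_states, 8L)
  pattern_of <- function(cur) {
    idx <- cur[, comp$regs[j, 1L]] + 1L
    if (comp$k[j] > 1L) idx <- idx + 2L * cur[, comp$regs[j, 2L]]
    if (comp$k[j] > 2L) idx <- idx + 4L * cur[, comp$regs[j, 3L]]
    idx
  }
  for (t in seq_len(steps)) {
    if (t > steps - tail) {
      idx <- pattern_of(cur)
      pat_sum[cbind(seq_len(n_states), idx)] <-
        pat_sum[cbind(seq_len(n_states), idx)] + 1
    }
    nw <- cur
    for (jj in seq_len(m)) {
      if (cl[jj] >= 0L) { nw[, jj] <- cl[jj]; next }
      if (comp$k[jj] == 0L) next
      idx <- cur[, comp$regs[jj, 1L]] + 1L
      if (comp$k[jj] > 1L) idx <- idx + 2L * cur[, comp$regs[jj, 2L]]
      if (comp$k[jj] > 2L) idx <- idx + 4L * cur[, comp$regs[jj, 3L]]
      nw[, jj] <- comp$tt[jj, idx]
    }
    cur <- nw
  }
  pat_mean <- pat_sum / tail
  out <- matrix(0, 8L, ncol(init))
  for (col in seq_len(ncol(init))) {
    p <- init[, col]
    p[cl >= 0L] <- cl[cl >= 0L]
    w <- rep(1, n_states)
    for (jj in seq_len(m))
      w <- w * ifelse(states[, jj] == 1L, p[jj], 1 - p[jj])
    out[, col] <- as.numeric(crossprod(pat_mean, w))
  }
  out
}
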