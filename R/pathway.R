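#' Node impact score by in-silico knockout/knock-in
#'
#' Propagates the network twice per sample — once with the gene clamped
#' off, once clamped on — and sums the squared activity differences over
#' all nodes and samples. Genes whose perturbation changes little of the
#' network score low; upstream regulators controlling signal flow score
#' high. By default the knockout/knock-in pair shares its initial-state
#' random draws (common random numbers), a pure variance-reduction device.
#'
#' @param rs a `rule_set`.
#' @param scaled_expr nodes x samples matrix of initial probabilities
#'   in `[0, 1]`.
#' @param gene gene (node) to perturb.
#' @param cfg a [sim_config()].
#' @param crn share random draws between the two clamped runs.
#' @param node_order node ordering (defaults to `names(rs)`).
#' @return nonnegative scalar. An isolated gene with no outgoing influence
#'   scores exactly `n_samples` (its own 0-vs-1 term in every sample).
#' @export
impact_score <- function(rs, scaled_expr, gene, cfg = sim_config(),
                         crn = TRUE, node_order = names(rs)) {
  if (!gene %in% node_order) stop("unknown gene: ", gene)
  use_crn <- crn && cfg$engine != "exact"
  if (use_crn) {
    if (!exists(".Random.seed", envir = .GlobalEnv)) stats::runif(1)
    st <- get(".Random.seed", envir = .GlobalEnv)
  }
  O <- simulate_ensemble(rs, scaled_expr, cfg,
                         clamps = stats::setNames(0L, gene),
                         node_order = node_order)
  if (use_crn) assign(".Random.seed", st, envir = .GlobalEnv)
  Z <- simulate_ensemble(rs, scaled_expr, cfg,
                         clamps = stats::setNames(1L, gene),
                         node_order = node_order)
  sum((O - Z)^2)
}

#' @rdname impact_score
#' @param genes genes to score (default all network nodes).
#' @return `impact_scores()`: named numeric vector of scores.
#' @export
impact_scores <- function(rs, scaled_expr, genes = names(rs),
                          cfg = sim_config(), crn = TRUE,
                          node_order = names(rs)) {
  vapply(genes, function(g)
    impact_score(rs, scaled_expr, g, cfg, crn, node_order), numeric(1))
}

#' Fold difference between two conditions
#'
#' Ratio of group means of the raw (unscaled) expression, with a
#' pseudocount of 1 added to both means so the ratio is always positive
#' and finite; swapping the groups maps `q -> 1/q`, leaving `|log q|`
#' unchanged.
#'
#' @param expr genes x samples matrix of raw expression.
#' @param gene gene id (rowname).
#' @param contrast character/factor of length `ncol(expr)` with exactly
#'   two levels assigning samples to conditions; `q` is
#'   first-level mean over second-level mean.
#' @return positive scalar.
#' @export
fold_difference <- function(expr, gene, contrast) {
  if (!gene %in% rownames(expr)) stop("gene absent from expression: ", gene)
  if (!is.factor(contrast))  # levels in order of appearance
    contrast <- factor(contrast, levels = unique(as.character(contrast)))
  if (nlevels(contrast) != 2L) stop("contrast must have exactly two levels")
  if (any(table(contrast) == 0L)) stop("both contrast groups must be nonempty")
  x <- expr[gene, ]
  (mean(x[contrast == levels(contrast)[1]]) + 1) /
    (mean(x[contrast == levels(contrast)[2]]) + 1)
}

#' Pathway modulation score
#'
#' `M_p = sum over genes of log2(1 + I_g) * |log2 q_g| * std(g)`, combining
#' topological influence (impact), differential expression magnitude and
#' per-gene variability. The `1 +` inside the log keeps zero-impact genes
#' at zero contribution and the score finite (a bare log would be
#' undefined at `I_g = 0` and negative below 1).
#'
#' @param impacts nonnegative impact scores, one per gene.
#' @param fold_diffs positive fold differences, aligned.
#' @param stds per-gene standard deviations of the scaled expression over
#'   all samples, aligned.
#' @return scalar; 0 when every fold difference is 1.
#' @export
modulation_score <- function(impacts, fold_diffs, stds) {
  if (length(impacts) != length(fold_diffs) ||
      length(impacts) != length(stds)) stop("input length mismatch")
  sum(log2(1 + impacts) * abs(log2(fold_diffs)) * stds)
}

#' Resampling p-value for a pathway modulation score
#'
#' Null distribution: keep the pathway's impact scores fixed (they encode
#' its topology and rules) and re-draw each pathway gene's
#' (fold difference, standard deviation) pair uniformly with replacement
#' from the gene-wise pairs of the full expression matrix. The pairs are
#' resampled jointly to preserve their dependence. The add-one estimator
#' `p = (1 + #{M_perm >= M_obs}) / (1 + n_perm)` never returns zero.
#'
#' @param m_obs observed modulation score.
#' @param impacts fixed impact scores of the pathway genes.
#' @param expr full genes x samples raw expression matrix (the
#'   resampling pool).
#' @param contrast two-level sample assignment (see [fold_difference()]).
#' @param n_perm number of permutations (>= 1).
#' @param seed optional integer seed.
#' @return p-value in `(0, 1]`.
#' @export
pathway_pvalue <- function(m_obs, impacts, expr, contrast, n_perm = 1000L,
                           seed = NULL) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pool <- rownames(expr)
  if (length(pool) < 2L * length(impacts))
    warning("resampling pool smaller than twice the pathway size")
  q_pool <- vapply(pool, function(g) fold_difference(expr, g, contrast),
                   numeric(1))
  sc <- scale_to_unit(expr)
  std_pool <- apply(sc, 1L, stats::sd)
  wts <- log2(1 + impacts)
  n_genes <- length(impacts)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    pick <- sample.int(length(pool), n_genes, replace = TRUE)
    m_perm <- sum(wts * abs(log2(q_pool[pick])) * std_pool[pick])
    if (m_perm >= m_obs) exceed <- exceed + 1L
  }
  (1 + exceed) / (1 + n_perm)
}

#' Topology-aware pathway analysis
#'
#' For each network: matches genes to the expression matrix
#' (case-insensitively), skips pathways with fewer than 4 matched genes,
#' infers rules on all samples pooled, computes per-gene impact scores
#' with the minimal-error rule set, fold differences and scaled standard
#' deviations on the contrast, the modulation score `M_p`, and its
#' resampling p-value. A Benjamini-Hochberg column is added for
#' convenience.
#'
#' @param networks a `signed_graph` or list of them.
#' @param expr raw genes x samples expression matrix.
#' @param contrast two-level sample assignment (see [fold_difference()]).
#' @param ga_cfg a [ga_config()].
#' @param sim_cfg a [sim_config()].
#' @param n_perm permutations for the null.
#' @param seed optional integer seed.
#' @return data frame (one row per analyzed pathway, sorted by p-value)
#'   with columns `pathway`, `n_genes`, `M_p`, `p_value`, `p_adjust`;
#'   per-pathway gene tables and inference artifacts are attached as
#'   `attr(, "details")`.
#' @export
run_pathway_analysis <- function(networks, expr, contrast,
                                 ga_cfg = ga_config(),
                                 sim_cfg = sim_config(),
                                 n_perm = 1000L, seed = NULL) {
  if (inherits(networks, "signed_graph")) networks <- list(networks)
  if (!is.null(seed)) set.seed(seed)
  contrast <- as.factor(contrast)
  if (any(table(contrast) < 2L)) stop("need >= 2 samples per condition")
  rows <- list(); details <- list()
  for (i in seq_along(networks)) {
    g <- networks[[i]]
    pid <- if (!is.null(g$name)) g$name else paste0("pathway_", i)
    map <- suppressMessages(match_genes(g, expr))
    matched <- names(map)[!is.na(map)]
    if (length(matched) < 4L) {
      message("skipping ", pid, ": only ", length(matched),
              " gene(s) matched (< 4 required)")
      next
    }
    fit <- infer_rules(g, expr, ga_cfg, sim_cfg)
    imp <- impact_scores(fit$best, fit$scaled, genes = matched,
                         cfg = sim_cfg)
    q <- vapply(matched, function(v)
      fold_difference(expr, map[[v]], contrast), numeric(1))
    stds <- apply(fit$scaled[matched, , drop = FALSE], 1L, stats::sd)
    m_p <- modulation_score(imp, q, stds)
    p <- pathway_pvalue(m_p, imp, expr, contrast, n_perm)
    rows[[pid]] <- data.frame(pathway = pid, n_genes = length(matched),
                              M_p = m_p, p_value = p,
                              stringsAsFactors = FALSE)
    details[[pid]] <- list(
      genes = data.frame(gene = matched, impact = imp, fold_difference = q,
                         std = stds, stringsAsFactors = FALSE),
      fit = fit)
  }
  if (!length(rows)) {
    warning("no pathway passed the >= 4 matched-gene filter")
    out <- data.frame(pathway = character(), n_genes = integer(),
                      M_p = numeric(), p_value = numeric(),
                      p_adjust = numeric(), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  attr(out, "details") <- details
  out
}

#' Export an annotated network as GraphML
#'
#' Writes the inferred logic structure in the viewer convention where an
#' AND-term with more than one literal becomes a small auxiliary connector
#' node feeding the target, while single-literal terms stay direct edges
#' (multiple incoming edges to a gene node therefore read as OR). Gene
#' nodes carry their impact score normalized by the pathway maximum, the
#' signed log2 fold difference, and the rule text.
#'
#' @param graph a `signed_graph`.
#' @param ruleset a `rule_set` on the graph's nodes.
#' @param impacts named impact scores (subset of nodes allowed).
#' @param fold_diffs named fold differences (subset of nodes allowed).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_annotated_network <- function(graph, ruleset, impacts, fold_diffs,
                                     path) {
  nodes <- graph$nodes
  imp_norm <- rep(NA_real_, length(nodes))
  names(imp_norm) <- nodes
  if (length(impacts)) {
    mx <- max(impacts)
    imp_norm[names(impacts)] <- if (mx > 0) impacts / mx else 0
  }
  lfc <- rep(NA_real_, length(nodes))
  names(lfc) <- nodes
  if (length(fold_diffs)) lfc[names(fold_diffs)] <- log2(fold_diffs)

  from <- character(); to <- character(); sign <- integer()
  aux_nodes <- character()
  for (v in nodes) {
    rule <- ruleset[[v]]
    if (is.null(rule) || is_hold(rule)) next
    k <- length(rule$regulators)
    pow <- bitwShiftL(1L, seq_len(k) - 1L)
    for (t in seq_len(bitwShiftL(1L, k) - 1L)) {
      if (bitwAnd(rule$mask, bitwShiftL(1L, t - 1L)) == 0L) next
      members <- which(bitwAnd(t, pow) != 0L)
      if (length(members) == 1L) {
        from <- c(from, rule$regulators[members])
        to <- c(to, v)
        sign <- c(sign, rule$signs[members])
      } else {
        aux <- paste0("AND_", v, "_", t)
        aux_nodes <- c(aux_nodes, aux)
        from <- c(from, rule$regulators[members], aux)
        to <- c(to, rep(aux, length(members)), v)
        sign <- c(sign, rule$signs[members], 1L)
      }
    }
  }
  all_nodes <- c(nodes, aux_nodes)
  edges <- unique(data.frame(from = from, to = to, sign = sign,
                             stringsAsFactors = FALSE))
  rule_txt <- vapply(all_nodes, function(v) {
    if (v %in% nodes && !is.null(ruleset[[v]])) rule_to_text(ruleset[[v]])
    else ""
  }, character(1))
  node_attrs <- data.frame(
    id = all_nodes,
    node_type = c(rep("gene", length(nodes)), rep("and", length(aux_nodes))),
    impact_norm = as.character(c(imp_norm, rep(NA_real_, length(aux_nodes)))),
    log2_fold_difference = as.character(c(lfc, rep(NA_real_,
                                                   length(aux_nodes)))),
    rule = rule_txt,
    stringsAsFactors = FALSE)
  g_out <- signed_graph(all_nodes, edges, name = graph$name, id = graph$id)
  write_graph(g_out, path, format = "graphml", node_attrs = node_attrs)
}
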