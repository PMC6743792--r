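# shared fixture builders and independent oracles

chain_graph <- function(n, sign = 1L) {
  nodes <- LETTERS[seq_len(n)]
  signed_graph(nodes, data.frame(from = nodes[-n], to = nodes[-1L],
                                 sign = sign, stringsAsFactors = FALSE))
}

# feed-forward loop A -> B, A -> C, B -> C (all activating)
ffl_graph <- function() {
  signed_graph(c("A", "B", "C"),
               data.frame(from = c("A", "A", "B"), to = c("B", "C", "C"),
                          sign = 1L, stringsAsFactors = FALSE))
}

copy_rule <- function(target, reg, sign = 1L) new_rule(target, reg, sign, 1L)

chain_ruleset <- function(n, sign = 1L) {
  nodes <- LETTERS[seq_len(n)]
  rules <- c(list(hold_rule(nodes[1L])),
             lapply(seq.int(2L, n), function(i)
               copy_rule(nodes[i], nodes[i - 1L], sign)))
  names(rules) <- nodes
  rule_set(rules)
}

# independent interpreter: expands the mask into explicit term subsets via
# utils::combn and evaluates with plain R logical operations
naive_eval_rule <- function(regulators, signs, mask, bits) {
  k <- length(regulators)
  subsets <- unlist(lapply(seq_len(k), function(sz)
    utils::combn(seq_len(k), sz, simplify = FALSE)), recursive = FALSE)
  term_index <- vapply(subsets, function(s) sum(2^(s - 1)), numeric(1))
  lit <- ifelse(signs > 0, bits == 1L, bits == 0L)
  any(vapply(seq_along(subsets), function(i) {
    included <- bitwAnd(mask, bitwShiftL(1L, as.integer(term_index[i]) - 1L)) != 0L
    included && all(lit[subsets[[i]]])
  }, logical(1)))
}

# O(n^2) pairwise AUC oracle
brute_auc <- function(null_scores, alt_scores) {
  tot <- 0
  for (a in alt_scores) for (b in null_scores)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(null_scores) * length(alt_scores))
}

fast_ga <- function(generations = 10L, ...)
  ga_config(generations = generations, fitness_runs = 50L,
            refine_runs = 200L, ...)

exact_cfg <- function() sim_config(engine = "exact")

kgml_fixture <- function() {
  system.file("extdata", "synthetic_pathway.kgml", package = "boolpath")
}

expect_same_graph <- function(g1, g2) {
  expect_setequal(g1$nodes, g2$nodes)
  expect_setequal(edge_keys_for_test(g1), edge_keys_for_test(g2))
}

edge_keys_for_test <- function(g)
  paste(g$edges$from, g$edges$to, g$edges$sign, sep = "|")
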