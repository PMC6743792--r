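#' Boolean rules as OR-of-ANDs over signed regulators
#'
#' A rule for a target node is an OR over a nonempty subset of the AND-terms
#' formed from its (at most three) regulators. Term `t` (an integer in
#' `1..2^k - 1`) denotes the conjunction of the regulators whose bit is set
#' in `t`; `mask` is the inclusion bitvector over terms (bit `t - 1` set
#' means term `t` participates in the OR). A literal's polarity is fixed by
#' its edge sign: activators appear plain, inhibitors negated, so every
#' representable function is unate (sign-compatible) in each input.
#'
#' Rule spaces are counted over *encodings* (masks), not distinct Boolean
#' functions: `2^(2^k - 1) - 1` rules for `k` regulators, i.e. 1, 7 and 127
#' for in-degree 1, 2 and 3. Functionally redundant encodings (e.g.
#' `A or (A and B)` vs `A`) are deliberately kept apart; equivalence is
#' established by truth-table comparison where it matters.
#'
#' @param target target node id.
#' @param regulators character vector of distinct regulator ids (length 0-3);
#'   length 0 creates the hold rule used for source nodes (state unchanged).
#' @param signs integer vector of `+1`/`-1` aligned with `regulators`.
#' @param mask term-inclusion bitvector, `1..2^(2^k) - 1` over the low
#'   `2^k - 1` bits; must be 0 for the hold rule.
#' @return an object of class `bool_rule`.
#' @export
new_rule <- function(target, regulators = character(), signs = integer(),
                     mask = 0L) {
  k <- length(regulators)
  if (k > 3L) stop("at most 3 regulators per rule")
  if (length(signs) != k) stop("signs must align with regulators")
  if (anyDuplicated(regulators)) stop("regulators must be distinct")
  mask <- as.integer(mask)
  if (k == 0L) {
    if (mask != 0L) stop("hold rule must have mask 0")
  } else {
    n_terms <- bitwShiftL(1L, k) - 1L
    if (mask < 1L || mask > bitwShiftL(1L, n_terms) - 1L)
      stop("mask out of range for ", k, " regulators")
  }
  structure(list(target = target, regulators = as.character(regulators),
                 signs = as.integer(signs), mask = mask),
            class = "bool_rule")
}

#' @rdname new_rule
#' @export
hold_rule <- function(target) new_rule(target)

is_hold <- function(rule) length(rule$regulators) == 0L

#' Enumerate the full rule space for a regulator set
#'
#' Every nonzero term-inclusion mask over the `2^k - 1` AND-terms, in
#' increasing mask order: 1 rule for one regulator, 7 for two, 127 for
#' three.
#'
#' @inheritParams new_rule
#' @return list of `bool_rule`; for `length(regulators) == 0` a list with
#'   the single hold rule.
#' @export
enumerate_rule_space <- function(regulators, signs, target = "y") {
  k <- length(regulators)
  if (k == 0L) return(list(hold_rule(target)))
  if (k > 3L) stop("rule spaces are only enumerated for <= 3 regulators; ",
                   "sample regulators first")
  n_masks <- bitwShiftL(1L, bitwShiftL(1L, k) - 1L) - 1L
  lapply(seq_len(n_masks), function(msk)
    new_rule(target, regulators, signs, msk))
}

# core semantics on a plain 0/1 vector aligned with rule$regulators
evaluate_rule_bits <- function(rule, bits) {
  k <- length(rule$regulators)
  if (k == 0L) stop("hold rule has no logic to evaluate")
  lits <- ifelse(rule$signs > 0L, bits, 1L - bits)
  pow <- bitwShiftL(1L, seq_len(k) - 1L)
  for (t in seq_len(bitwShiftL(1L, k) - 1L)) {
    if (bitwAnd(rule$mask, bitwShiftL(1L, t - 1L)) == 0L) next
    members <- which(bitwAnd(t, pow) != 0L)
    if (all(lits[members] == 1L)) return(1L)
  }
  0L
}

#' Evaluate a rule on a binary regulator state
#'
#' @param rule a `bool_rule`.
#' @param state named 0/1 vector supplying a bit for each regulator.
#' @return 0 or 1.
#' @export
evaluate_rule <- function(rule, state) {
  if (is_hold(rule)) stop("hold rule has no logic to evaluate")
  miss <- setdiff(rule$regulators, names(state))
  if (length(miss)) stop("missing regulator bit(s): ",
                         paste(miss, collapse = ", "))
  evaluate_rule_bits(rule, as.integer(state[rule$regulators]))
}

# truth table over the 2^k regulator states (state s: bit i of s is the
# value of regulator i); NULL for the hold rule
rule_truth_table <- function(rule) {
  k <- length(rule$regulators)
  if (k == 0L) return(NULL)
  vapply(0:(bitwShiftL(1L, k) - 1L), function(s) {
    bits <- bitwAnd(bitwShiftR(s, seq_len(k) - 1L), 1L)
    evaluate_rule_bits(rule, bits)
  }, integer(1))
}

#' Human-readable rule text
#'
#' @param rule a `bool_rule`.
#' @return a string such as `"C = A or (A and not B)"`.
#' @export
rule_to_text <- function(rule) {
  if (is_hold(rule)) return(paste(rule$target, "= (held)"))
  k <- length(rule$regulators)
  pow <- bitwShiftL(1L, seq_len(k) - 1L)
  terms <- character()
  for (t in seq_len(bitwShiftL(1L, k) - 1L)) {
    if (bitwAnd(rule$mask, bitwShiftL(1L, t - 1L)) == 0L) next
    members <- which(bitwAnd(t, pow) != 0L)
    lits <- ifelse(rule$signs[members] > 0L, rule$regulators[members],
                   paste("not", rule$regulators[members]))
    term <- paste(lits, collapse = " and ")
    if (length(members) > 1L) term <- paste0("(", term, ")")
    terms <- c(terms, term)
  }
  paste(rule$target, "=", paste(terms, collapse = " or "))
}

#' Functional equality of two rules
#'
#' Truth-table comparison over the union of both regulator sets: rules are
#' equal iff they compute the same output for every assignment. Redundant
#' encodings of the same function compare equal; this is the equality used
#' by recovery-accuracy scoring.
#'
#' @param a,b `bool_rule` objects.
#' @return TRUE/FALSE.
#' @export
rules_equal <- function(a, b) {
  if (is_hold(a) || is_hold(b)) return(is_hold(a) && is_hold(b))
  u <- union(a$regulators, b$regulators)
  for (s in 0:(bitwShiftL(1L, length(u)) - 1L)) {
    bits <- stats::setNames(bitwAnd(bitwShiftR(s, seq_along(u) - 1L), 1L), u)
    if (evaluate_rule(a, bits) != evaluate_rule(b, bits)) return(FALSE)
  }
  TRUE
}

#' Rule sets
#'
#' A rule set is one network-wide assignment: exactly one rule per node,
#' hold rules for source nodes.
#'
#' @param rules named list of `bool_rule`, names = node ids.
#' @return an object of class `rule_set` (a named list).
#' @export
rule_set <- function(rules) {
  stopifnot(length(names(rules)) == length(rules))
  structure(rules, class = "rule_set")
}

#' Random planted rule set for a network
#'
#' Each non-source node receives a uniformly random nonzero mask over a
#' regulator set of at most `max_regs` of its in-neighbors (a random subset
#' when in-degree exceeds `max_regs`); source nodes get hold rules.
#'
#' @param g a `signed_graph`.
#' @param seed optional integer seed.
#' @param max_regs maximum regulators per rule (default 3).
#' @return a `rule_set` covering every node of `g`.
#' @export
random_ruleset <- function(g, seed = NULL, max_regs = 3L) {
  if (!is.null(seed)) set.seed(seed)
  rules <- list()
  for (v in g$nodes) {
    nb <- in_neighbors(g, v)
    if (nrow(nb) == 0L) {
      rules[[v]] <- hold_rule(v)
      next
    }
    if (nrow(nb) > max_regs) nb <- nb[sample.int(nrow(nb), max_regs), ]
    k <- nrow(nb)
    n_masks <- bitwShiftL(1L, bitwShiftL(1L, k) - 1L) - 1L
    rules[[v]] <- new_rule(v, nb$from, nb$sign, sample.int(n_masks, 1L))
  }
  rule_set(rules)
}

#' Effective signed edges implied by a rule set
#'
#' The `(regulator, target, sign)` triples that appear in at least one
#' included AND-term of any rule; regulators carried by a rule but used in
#' no included term do not count.
#'
#' @param rs a `rule_set`.
#' @return data frame with columns `from`, `to`, `sign`.
#' @export
effective_edges <- function(rs) {
  from <- character(); to <- character(); sign <- integer()
  for (rule in rs) {
    if (is_hold(rule)) next
    k <- length(rule$regulators)
    pow <- bitwShiftL(1L, seq_len(k) - 1L)
    used <- logical(k)
    for (t in seq_len(bitwShiftL(1L, k) - 1L)) {
      if (bitwAnd(rule$mask, bitwShiftL(1L, t - 1L)) != 0L)
        used <- used | (bitwAnd(t, pow) != 0L)
    }
    from <- c(from, rule$regulators[used])
    to <- c(to, rep(rule$target, sum(used)))
    sign <- c(sign, rule$signs[used])
  }
  unique(data.frame(from = from, to = to, sign = sign,
                    stringsAsFactors = FALSE))
}

edge_keys <- function(edges) paste(edges$from, edges$to, edges$sign, sep = "\r")

#' Structural distance between inferred rules and a reference network
#'
#' Number of signed edges to add or remove to turn the effective network of
#' `rs` into `reference`: the symmetric difference of the two signed edge
#' sets. An edge present in both but with opposite sign therefore costs 2
#' (one removal plus one addition).
#'
#' @param rs a `rule_set`.
#' @param reference a `signed_graph` on the same node set.
#' @return nonnegative integer.
#' @export
structural_distance <- function(rs, reference) {
  if (!all(names(rs) %in% reference$nodes))
    stop("rule set and reference network node sets differ")
  eff <- edge_keys(effective_edges(rs))
  ref <- edge_keys(reference$edges)
  length(setdiff(eff, ref)) + length(setdiff(ref, eff))
}

#' Recovery accuracy of an equivalent rule set against planted truth
#'
#' `exact_pct` is the percentage of non-source nodes whose minimal-error
#' rule is functionally equal (truth-table equality over the union of
#' regulator sets) to the planted rule; `ers_pct` the percentage whose
#' planted rule is functionally matched by at least one ERS member.
#'
#' @param ers an `ers` object from [local_search()].
#' @param truth a `rule_set` of planted rules.
#' @return named numeric vector `c(exact_pct=, ers_pct=)`.
#' @export
rule_accuracy <- function(ers, truth) {
  nodes <- names(ers$nodes)
  nodes <- nodes[vapply(nodes, function(v) !is_hold(truth[[v]]), logical(1))]
  if (!length(nodes)) stop("no non-source nodes to score")
  n_exact <- 0L; n_ers <- 0L
  for (v in nodes) {
    ent <- ers$nodes[[v]]
    if (length(ent$masks) == 0L) stop("empty ERS at node ", v)
    mk <- function(msk) new_rule(v, ent$regulators, ent$signs, msk)
    if (rules_equal(mk(ent$best_mask), truth[[v]])) n_exact <- n_exact + 1L
    if (any(vapply(ent$masks, function(msk)
      rules_equal(mk(msk), truth[[v]]), logical(1)))) n_ers <- n_ers + 1L
  }
  c(exact_pct = 100 * n_exact / length(nodes),
    ers_pct = 100 * n_ers / length(nodes))
}

#' Median ERS size across non-source nodes
#' @param ers an `ers` object.
#' @return median number of rule encodings per node's equivalent set.
#' @export
median_ers_size <- function(ers) {
  sizes <- vapply(ers$nodes, function(e) length(e$masks), integer(1))
  stats::median(sizes)
}
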