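#' Signed directed network
#'
#' A `signed_graph` holds gene nodes plus directed edges, each carrying a
#' sign: `+1` for activation, `-1` for inhibition. It is the prior-knowledge
#' container on which rule inference and pathway scoring operate.
#'
#' @param nodes character vector of unique node identifiers.
#' @param edges data frame with columns `from`, `to`, `sign`
#'   (`sign %in% c(-1, 1)`); zero-row data frames are allowed.
#' @param name optional display name.
#' @param id optional pathway identifier.
#' @param aliases optional named list mapping node id -> character vector of
#'   alternative identifiers (used for case-insensitive expression matching).
#'
#' @return an object of class `signed_graph` with elements `nodes`,
#'   `edges`, `name`, `id`, `aliases`.
#' @export
#' @examples
#' g <- signed_graph(c("A", "B"), data.frame(from = "A", to = "B", sign = 1))
#' n_edges(g)
signed_graph <- function(nodes, edges = NULL, name = NULL, id = NULL,
                         aliases = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node identifiers")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        sign = integer(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = as.character(edges$from),
                        to = as.character(edges$to),
                        sign = as.integer(edges$sign),
                        stringsAsFactors = FALSE)
  }
  if (!all(edges$sign %in% c(-1L, 1L))) stop("edge signs must be +1 or -1")
  bad <- setdiff(unique(c(edges$from, edges$to)), nodes)
  if (length(bad)) {
    stop("edge endpoint(s) not declared as nodes: ", paste(bad, collapse = ", "))
  }
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (source, target) edge pairs")
  loops <- edges$from == edges$to
  if (any(loops)) {
    warning("graph contains ", sum(loops), " self-loop(s)")
  }
  structure(list(nodes = nodes, edges = edges, name = name, id = id,
                 aliases = aliases),
            class = "signed_graph")
}

#' @export
print.signed_graph <- function(x, ...) {
  cat("signed_graph", if (!is.null(x$name)) paste0("'", x$name, "'"), "with",
      length(x$nodes), "nodes and", nrow(x$edges), "edges\n")
  invisible(x)
}

#' @rdname signed_graph
#' @param g a `signed_graph`.
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname signed_graph
#' @export
n_edges <- function(g) nrow(g$edges)

check_node <- function(g, node) {
  if (!node %in% g$nodes) stop("unknown node: ", node)
  invisible(node)
}

#' In-neighbors of a node
#'
#' @param g a `signed_graph`.
#' @param node node identifier.
#' @return data frame with columns `from` and `sign`, one row per
#'   incoming edge (self-loops included).
#' @export
in_neighbors <- function(g, node) {
  check_node(g, node)
  sel <- g$edges$to == node
  data.frame(from = g$edges$from[sel], sign = g$edges$sign[sel],
             stringsAsFactors = FALSE)
}

#' Source nodes (in-degree zero)
#' @param g a `signed_graph`.
#' @return character vector of nodes with no incoming edges.
#' @export
source_nodes <- function(g) setdiff(g$nodes, unique(g$edges$to))

# adjacency list: for each node, character vector of predecessor (or
# successor) node ids
adj_list <- function(g, mode = c("in", "out")) {
  mode <- match.arg(mode)
  out <- stats::setNames(vector("list", length(g$nodes)), g$nodes)
  for (v in g$nodes) out[[v]] <- character()
  if (nrow(g$edges)) {
    sp <- if (mode == "in") split(g$edges$from, g$edges$to)
          else split(g$edges$to, g$edges$from)
    out[names(sp)] <- sp
  }
  out
}

#' Ancestor set of a node
#'
#' All nodes from which `node` is reachable by a directed path, including
#' `node` itself. Self-inclusion makes the shared-ancestry overlap of a
#' feed-forward motif nonzero, which is what ties ancestry overlap to rule
#' unidentifiability.
#'
#' @param g a `signed_graph`.
#' @param node node identifier.
#' @return character vector of ancestor node ids (always contains `node`).
#' @export
#' @examples
#' g <- signed_graph(c("A", "B", "C"),
#'                   data.frame(from = c("A", "B"), to = c("B", "C"),
#'                              sign = c(1, 1)))
#' ancestors(g, "C")  # A, B, C
ancestors <- function(g, node) {
  check_node(g, node)
  pred <- adj_list(g, "in")
  seen <- stats::setNames(logical(length(g$nodes)), g$nodes)
  queue <- node
  seen[node] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    for (u in pred[[v]]) {
      if (!seen[[u]]) {
        seen[u] <- TRUE
        queue <- c(queue, u)
      }
    }
  }
  g$nodes[seen[g$nodes]]
}

#' Total ancestor overlap of a node's regulators
#'
#' Sum over unordered pairs of distinct in-neighbors `U1 != U2` of
#' `|A(U1) intersect A(U2)|`, where `A(.)` is the self-inclusive ancestor
#' set. Large overlap means signal can reach the node along alternative
#' routes that cross-sectional data cannot distinguish, inflating the size
#' of the equivalent rule set.
#'
#' @param g a `signed_graph`.
#' @param node node identifier.
#' @return nonnegative integer; 0 for in-degree <= 1.
#' @export
total_ancestor_overlap <- function(g, node) {
  check_node(g, node)
  regs <- unique(in_neighbors(g, node)$from)
  if (length(regs) <= 1L) return(0L)
  anc <- lapply(regs, function(u) ancestors(g, u))
  tot <- 0L
  for (i in seq_len(length(regs) - 1L)) {
    for (j in seq.int(i + 1L, length(regs))) {
      tot <- tot + length(intersect(anc[[i]], anc[[j]]))
    }
  }
  tot
}

#' Longest shortest directed path
#'
#' Maximum over all ordered reachable pairs of the shortest directed path
#' length. For curated signaling networks this is small (17 across the
#' KEGG networks the method was developed on), which is what justifies a
#' fixed 100-step simulation horizon.
#'
#' @param g a nonempty `signed_graph`.
#' @return integer; 0 for an edgeless graph.
#' @export
longest_shortest_path <- function(g) {
  if (length(g$nodes) == 0L) stop("empty graph")
  succ <- adj_list(g, "out")
  best <- 0L
  for (s in g$nodes) {
    dist <- stats::setNames(rep(NA_integer_, length(g$nodes)), g$nodes)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      for (w in succ[[v]]) {
        if (is.na(dist[[w]])) {
          dist[w] <- dist[[v]] + 1L
          queue <- c(queue, w)
        }
      }
    }
    best <- max(best, max(dist, na.rm = TRUE))
  }
  best
}

#' Generate a random signed network
#'
#' Builds a connected layered graph: the first `n_sources` nodes are
#' sources (in-degree 0) and every later node draws 1..`max_indegree`
#' regulators uniformly from the nodes before it, so the result is a DAG
#' with at least one source. Optional feedback edges (respecting
#' `max_indegree`) can be added with probability `p_feedback` per node.
#' Edge signs are inhibitory with probability `p_inhibitory`.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param max_indegree maximum in-degree (>= 1; rules are only inferred
#'   over at most 3 regulators, larger in-degrees trigger regulator
#'   sampling during inference).
#' @param p_inhibitory probability an edge is inhibitory.
#' @param seed optional integer seed.
#' @param n_sources number of in-degree-0 nodes placed first
#'   (default ~15\% of nodes, at least 1).
#' @param p_feedback per-node probability of one extra feedback edge.
#' @return a `signed_graph` with nodes `n1..n<n>`.
#' @export
generate_random_network <- function(n_nodes, max_indegree = 3,
                                    p_inhibitory = 0.2, seed = NULL,
                                    n_sources = max(1L, round(0.15 * n_nodes)),
                                    p_feedback = 0) {
  if (n_nodes < 2L) stop("n_nodes must be >= 2")
  if (max_indegree < 1L) stop("max_indegree must be >= 1")
  if (p_inhibitory < 0 || p_inhibitory > 1) stop("p_inhibitory not in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  n_sources <- max(1L, min(as.integer(n_sources), n_nodes - 1L))
  nodes <- paste0("n", seq_len(n_nodes))
  from <- character(); to <- character()
  for (i in seq.int(n_sources + 1L, n_nodes)) {
    k <- sample.int(min(max_indegree, i - 1L), 1L)
    regs <- sample.int(i - 1L, k)
    from <- c(from, nodes[regs])
    to <- c(to, rep(nodes[i], k))
  }
  if (p_feedback > 0) {
    indeg <- table(factor(to, levels = nodes))
    for (i in seq_len(n_nodes - 1L)) {
      if (stats::runif(1) < p_feedback && indeg[[nodes[i]]] < max_indegree) {
        cand <- setdiff(nodes[seq.int(i + 1L, n_nodes)], from[to == nodes[i]])
        if (length(cand)) {
          u <- sample(cand, 1L)
          from <- c(from, u); to <- c(to, nodes[i])
          indeg[nodes[i]] <- indeg[[nodes[i]]] + 1L
        }
      }
    }
  }
  sign <- ifelse(stats::runif(length(from)) < p_inhibitory, -1L, 1L)
  signed_graph(nodes, data.frame(from = from, to = to, sign = sign,
                                 stringsAsFactors = FALSE))
}

#' Add false-positive edges
#'
#' Corrupts a prior-knowledge network by adding `round(multiple * |E|)`
#' edges drawn uniformly from the non-existing ordered pairs (no
#' self-loops, no duplicates), with random signs. Used to probe robustness
#' of rule inference to inaccurate priors.
#'
#' @param g a `signed_graph`.
#' @param multiple nonnegative multiple of the current edge count.
#' @param seed optional integer seed.
#' @param p_inhibitory probability a spurious edge is inhibitory.
#' @return a `signed_graph` containing all original edges plus the
#'   spurious ones.
#' @export
add_false_edges <- function(g, multiple, seed = NULL, p_inhibitory = 0.5) {
  if (multiple < 0) stop("multiple must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n_new <- round(multiple * n_edges(g))
  if (n_new == 0L) return(g)
  n <- length(g$nodes)
  all_pairs <- expand.grid(from = g$nodes, to = g$nodes,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  key <- paste(all_pairs$from, all_pairs$to, sep = "\r")
  have <- paste(g$edges$from, g$edges$to, sep = "\r")
  free <- which(!key %in% have)
  if (n_new > length(free)) stop("requested more false edges than available non-edges")
  pick <- free[sample.int(length(free), n_new)]
  new_edges <- data.frame(
    from = all_pairs$from[pick], to = all_pairs$to[pick],
    sign = ifelse(stats::runif(n_new) < p_inhibitory, -1L, 1L),
    stringsAsFactors = FALSE)
  signed_graph(g$nodes, rbind(g$edges, new_edges), name = g$name, id = g$id,
               aliases = g$aliases)
}
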