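test_that("signed_graph enforces its invariants", {
  expect_error(signed_graph(c("A", "A")), "duplicate node")
  expect_error(signed_graph("A", data.frame(from = "A", to = "B", sign = 1)),
               "not declared")
  expect_error(signed_graph(c("A", "B"),
                            data.frame(from = c("A", "A"), to = c("B", "B"),
                                       sign = c(1, -1))),
               "duplicate")
  expect_error(signed_graph(c("A", "B"),
                            data.frame(from = "A", to = "B", sign = 2)),
               "sign")
  expect_warning(signed_graph("A", data.frame(from = "A", to = "A", sign = 1)),
                 "self-loop")
})

test_that("parse_kgml maps entries and relation subtypes", {
  expect_warning(g <- parse_kgml(kgml_fixture()), "dropped")
  expect_setequal(g$nodes, c("GENEA", "GENEB", "GENEC", "GENEX", "GENEY",
                             "C00001"))
  keys <- edge_keys_for_test(g)
  expect_true("GENEA|GENEB|1" %in% keys)       # activation -> +1
  expect_true("GENEB|GENEC|-1" %in% keys)      # inhibition -> -1
  # group {GENEX, GENEY} targeted by activator GENEC expands to 2 edges
  expect_true(all(c("GENEC|GENEX|1", "GENEC|GENEY|1") %in% keys))
  # binding/association relation dropped entirely
  expect_false(any(grepl("^GENEA\\|GENEC", keys)))
  expect_equal(n_edges(g), 4L)
  expect_true("ALIASA" %in% g$aliases$GENEA)
  expect_identical(g$id, "path:syn00001")
  # compound entries removable
  g2 <- suppressWarnings(parse_kgml(kgml_fixture(), keep_compounds = FALSE))
  expect_false("C00001" %in% g2$nodes)
})

test_that("parse_kgml rejects malformed and gene-free documents", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<pathway><entry", bad)
  expect_error(parse_kgml(bad), "malformed")
  empty <- withr::local_tempfile(fileext = ".xml")
  writeLines('<pathway name="p"><entry id="1" name="x" type="compound"/></pathway>',
             empty)
  expect_error(parse_kgml(empty), "zero gene entries")
})

test_that("GraphML and SIF round-trip nodes, edges, and signs", {
  g <- generate_random_network(12, seed = 7, p_inhibitory = 0.4)
  for (fmt in c("graphml", "sif")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_graph(g, f, fmt)
    expect_same_graph(g, read_graph(f, fmt))
  }
})

test_that("GraphML undirected edges expand and missing signs default", {
  f <- withr::local_tempfile(fileext = ".graphml")
  writeLines('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">
    <key id="signal" for="edge" attr.name="signal" attr.type="string"/>
    <graph id="G" edgedefault="undirected">
      <node id="A"/><node id="B"/><node id="C"/>
      <edge source="A" target="B"><data key="signal">a</data></edge>
      <edge source="B" target="C" directed="true"/>
    </graph></graphml>', f)
  expect_warning(g <- read_graph(f, "graphml"), "default to activation")
  keys <- edge_keys_for_test(g)
  expect_setequal(keys, c("A|B|1", "B|A|1", "B|C|1"))
})

test_that("SIF parsing maps relations and catches malformed lines", {
  f <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A a B", "A i C"), f)
  g <- read_graph(f, "sif")
  expect_setequal(edge_keys_for_test(g), c("A|B|1", "A|C|-1"))
  writeLines("A B", f)
  expect_error(read_graph(f, "sif"), "malformed SIF")
})

test_that("ancestors are self-inclusive reachability sets", {
  g <- chain_graph(3)
  expect_setequal(ancestors(g, "C"), c("A", "B", "C"))
  gx <- signed_graph(c("A", "X"),
                     data.frame(from = "A", to = "A", sign = 1)[0, ])
  expect_setequal(ancestors(gx, "X"), "X")
  cyc <- signed_graph(c("A", "B"),
                      data.frame(from = c("A", "B"), to = c("B", "A"),
                                 sign = 1))
  expect_setequal(ancestors(cyc, "A"), c("A", "B"))
  expect_error(ancestors(g, "Z"), "unknown node")
})

test_that("total ancestor overlap matches hand enumeration", {
  # feed-forward: pair (A,B) shares only A under self-inclusive sets
  expect_equal(total_ancestor_overlap(ffl_graph(), "C"), 1L)
  g <- chain_graph(3)
  expect_equal(total_ancestor_overlap(g, "B"), 0L)  # single regulator
  dis <- signed_graph(c("A", "B", "C"),
                      data.frame(from = c("A", "B"), to = c("C", "C"),
                                 sign = 1))
  expect_equal(total_ancestor_overlap(dis, "C"), 0L)  # disjoint ancestries
})

test_that("total ancestor overlap is invariant under node relabeling", {
  for (seed in 1:5) {
    g <- generate_random_network(10, seed = seed)
    perm <- sample(LETTERS[1:10])
    names(perm) <- g$nodes
    g2 <- signed_graph(unname(perm[g$nodes]),
                       data.frame(from = unname(perm[g$edges$from]),
                                  to = unname(perm[g$edges$to]),
                                  sign = g$edges$sign))
    for (v in g$nodes) {
      expect_equal(total_ancestor_overlap(g, v),
                   total_ancestor_overlap(g2, perm[[v]]))
    }
  }
})

test_that("generate_random_network obeys its construction guarantees", {
  g1 <- generate_random_network(10, seed = 3)
  g2 <- generate_random_network(10, seed = 3)
  expect_identical(g1$edges, g2$edges)
  for (seed in 1:100) {
    g <- generate_random_network(10, max_indegree = 3, seed = seed)
    indeg <- table(factor(g$edges$to, levels = g$nodes))
    expect_true(all(indeg <= 3))
    expect_gte(length(source_nodes(g)), 1L)
  }
  g0 <- generate_random_network(15, p_inhibitory = 0, seed = 1)
  expect_true(all(g0$edges$sign == 1L))
  expect_error(generate_random_network(1), "n_nodes")
})

test_that("add_false_edges adds the requested disjoint edges", {
  g <- generate_random_network(8, seed = 11)
  expect_identical(add_false_edges(g, 0), g)
  g2 <- add_false_edges(g, 0.5, seed = 1)
  expect_equal(n_edges(g2), n_edges(g) + round(0.5 * n_edges(g)))
  new_keys <- setdiff(paste(g2$edges$from, g2$edges$to),
                      paste(g$edges$from, g$edges$to))
  expect_length(new_keys, round(0.5 * n_edges(g)))
  expect_error(add_false_edges(g, 1e6), "non-edges")
})

test_that("longest_shortest_path matches an igraph BFS oracle", {
  expect_equal(longest_shortest_path(chain_graph(5)), 4L)
  full <- expand.grid(from = LETTERS[1:4], to = LETTERS[1:4],
                      stringsAsFactors = FALSE)
  full <- full[full$from != full$to, ]
  full$sign <- 1L
  expect_equal(longest_shortest_path(signed_graph(LETTERS[1:4], full)), 1L)
  skip_if_not_installed("igraph")
  for (seed in 1:5) {
    g <- generate_random_network(20, seed = seed, p_feedback = 0.3)
    ig <- igraph::graph_from_data_frame(g$edges[, 1:2], vertices = g$nodes)
    d <- igraph::distances(ig, mode = "out")
    expect_equal(longest_shortest_path(g), max(d[is.finite(d)]))
  }
})
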