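#' Parse a KGML (KEGG XML) pathway into a signed network
#'
#' Gene entries become nodes identified by the first listed display symbol
#' (first token of the `graphics` name, falling back to the first token of
#' the entry `name`); the full identifier list is retained in
#' `$aliases` for case-insensitive matching against expression matrices.
#' Relation subtypes `activation`/`expression` map to sign `+1` and
#' `inhibition`/`repression` to `-1`; relations carrying neither
#' annotation (binding, state change, indirect, ...) are dropped with a
#' warning because the method is defined only for signed edges. Group
#' entries are expanded to their member genes, duplicating incident
#' edges to each member.
#'
#' @param path path to a KGML file.
#' @param keep_compounds keep `compound` entries as pass-through nodes
#'   (default TRUE); if FALSE they are removed together with their edges.
#' @return a `signed_graph` with `name` and `id` from the pathway element.
#' @export
parse_kgml <- function(path, keep_compounds = TRUE) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed KGML XML: ",
                                           conditionMessage(e)))
  entries <- xml2::xml_find_all(doc, ".//entry")
  ids <- xml2::xml_attr(entries, "id")
  types <- xml2::xml_attr(entries, "type")
  names_attr <- xml2::xml_attr(entries, "name")
  if (!any(types == "gene")) stop("KGML contains zero gene entries")

  entry_label <- function(i) {
    gnode <- xml2::xml_find_first(entries[[i]], "./graphics")
    gname <- if (!inherits(gnode, "xml_missing")) xml2::xml_attr(gnode, "name") else NA
    lab <- if (!is.na(gname) && nzchar(gname)) {
      strsplit(gname, ",\\s*")[[1]][1]
    } else {
      strsplit(names_attr[i], "\\s+")[[1]][1]
    }
    sub("\\.\\.\\.$", "", lab)
  }

  keep <- types %in% c("gene", if (keep_compounds) "compound")
  labels <- vapply(seq_along(entries), function(i)
    if (keep[i]) entry_label(i) else NA_character_, character(1))

  # group entries expand to their member entry ids
  members <- stats::setNames(as.list(ids), ids)
  for (i in which(types == "group")) {
    comp <- xml2::xml_find_all(entries[[i]], "./component")
    members[[ids[i]]] <- xml2::xml_attr(comp, "id")
  }

  aliases <- list()
  for (i in which(keep)) {
    al <- unique(c(strsplit(names_attr[i], "\\s+")[[1]],
                   {
                     gnode <- xml2::xml_find_first(entries[[i]], "./graphics")
                     gname <- if (!inherits(gnode, "xml_missing"))
                       xml2::xml_attr(gnode, "name") else NA
                     if (!is.na(gname)) sub("\\.\\.\\.$", "",
                                            strsplit(gname, ",\\s*")[[1]])
                     else character()
                   }))
    aliases[[labels[i]]] <- unique(c(aliases[[labels[i]]], al))
  }

  id_of <- stats::setNames(labels, ids)
  expand <- function(eid) {
    mids <- members[[eid]]
    if (is.null(mids)) mids <- eid
    labs <- id_of[mids]
    labs[!is.na(labs)]
  }

  rels <- xml2::xml_find_all(doc, ".//relation")
  from <- character(); to <- character(); sign <- integer()
  n_dropped <- 0L
  for (r in rels) {
    subtypes <- xml2::xml_attr(xml2::xml_find_all(r, "./subtype"), "name")
    s <- if (any(subtypes %in% c("activation", "expression"))) 1L
         else if (any(subtypes %in% c("inhibition", "repression"))) -1L
         else NA_integer_
    if (is.na(s)) { n_dropped <- n_dropped + 1L; next }
    src <- expand(xml2::xml_attr(r, "entry1"))
    tgt <- expand(xml2::xml_attr(r, "entry2"))
    for (a in src) for (b in tgt) {
      from <- c(from, a); to <- c(to, b); sign <- c(sign, s)
    }
  }
  if (n_dropped > 0L) {
    warning(n_dropped, " relation(s) without activation/inhibition ",
            "annotation dropped")
  }
  edges <- data.frame(from = from, to = to, sign = sign,
                      stringsAsFactors = FALSE)
  # entries can share a display symbol; deduplicate pairs (first sign wins)
  edges <- edges[!duplicated(paste(edges$from, edges$to, sep = "\r")), ]
  nodes <- unique(labels[keep & !is.na(labels)])
  signed_graph(nodes, edges,
               name = xml2::xml_attr(xml2::xml_root(doc), "title"),
               id = xml2::xml_attr(xml2::xml_root(doc), "name"),
               aliases = aliases)
}

#' Read a signed network from GraphML or SIF
#'
#' GraphML edges carry their sign in the `signal` attribute (`"a"` for
#' activation, `"i"` for inhibition); a missing attribute defaults to
#' activation with a warning. Undirected or bidirectional edges are
#' expanded into two directed edges, one in each direction — the standard
#' handling for de-novo inferred coexpression networks whose orientation
#' step leaves some edges unresolved. SIF lines are
#' `source <a|i> target`, whitespace separated.
#'
#' @param path input file path.
#' @param format `"graphml"` or `"sif"`.
#' @return a `signed_graph`. For GraphML, any further node attributes are
#'   attached as a data frame in `attr(g, "node_attrs")`.
#' @export
read_graph <- function(path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "sif") return(read_sif(path))
  read_graphml(path)
}

sig_to_sign <- function(x) ifelse(x == "i", -1L, 1L)

read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, ".//key")
  key_name <- stats::setNames(xml2::xml_attr(keys, "attr.name"),
                              xml2::xml_attr(keys, "id"))
  graph <- xml2::xml_find_first(doc, ".//graph")
  default_directed <-
    identical(xml2::xml_attr(graph, "edgedefault"), "directed")
  nodes_xml <- xml2::xml_find_all(graph, "./node")
  node_ids <- xml2::xml_attr(nodes_xml, "id")
  node_attrs <- list(id = node_ids)
  for (nd in seq_along(nodes_xml)) {
    data <- xml2::xml_find_all(nodes_xml[[nd]], "./data")
    for (dt in data) {
      nm <- key_name[[xml2::xml_attr(dt, "key")]]
      if (is.null(node_attrs[[nm]]))
        node_attrs[[nm]] <- rep(NA_character_, length(node_ids))
      node_attrs[[nm]][nd] <- xml2::xml_text(dt)
    }
  }
  edges_xml <- xml2::xml_find_all(graph, "./edge")
  from <- character(); to <- character(); sign <- integer()
  n_unsigned <- 0L
  for (e in edges_xml) {
    src <- xml2::xml_attr(e, "source"); tgt <- xml2::xml_attr(e, "target")
    if (!src %in% node_ids) stop("edge references undeclared node: ", src)
    if (!tgt %in% node_ids) stop("edge references undeclared node: ", tgt)
    data <- xml2::xml_find_all(e, "./data")
    sig <- NA_character_
    for (dt in data) {
      if (identical(key_name[[xml2::xml_attr(dt, "key")]], "signal"))
        sig <- xml2::xml_text(dt)
    }
    if (is.na(sig)) { n_unsigned <- n_unsigned + 1L; sig <- "a" }
    dir_attr <- xml2::xml_attr(e, "directed")
    directed <- if (is.na(dir_attr)) default_directed
                else identical(dir_attr, "true")
    from <- c(from, src); to <- c(to, tgt); sign <- c(sign, sig_to_sign(sig))
    if (!directed) {
      from <- c(from, tgt); to <- c(to, src); sign <- c(sign, sig_to_sign(sig))
    }
  }
  if (n_unsigned > 0L)
    warning(n_unsigned, " edge(s) without 'signal' attribute default to activation")
  edges <- data.frame(from = from, to = to, sign = sign,
                      stringsAsFactors = FALSE)
  edges <- edges[!duplicated(paste(edges$from, edges$to, sep = "\r")), ]
  g <- signed_graph(node_ids, edges,
                    name = xml2::xml_attr(graph, "id"))
  attr(g, "node_attrs") <- as.data.frame(node_attrs, stringsAsFactors = FALSE)
  g
}

read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad)) stop("malformed SIF line: ", lines[which(bad)[1]])
  from <- vapply(parts, `[[`, "", 1L)
  rel <- vapply(parts, `[[`, "", 2L)
  to <- vapply(parts, `[[`, "", 3L)
  if (!all(rel %in% c("a", "i")))
    stop("SIF relation must be 'a' or 'i', got: ",
         paste(unique(setdiff(rel, c("a", "i"))), collapse = ", "))
  signed_graph(unique(c(from, to)),
               data.frame(from = from, to = to, sign = sig_to_sign(rel),
                          stringsAsFactors = FALSE))
}

#' Write a signed network to GraphML or SIF
#'
#' @param g a `signed_graph`.
#' @param path output path.
#' @param format `"graphml"` or `"sif"`.
#' @param node_attrs optional data frame of extra node attributes; must
#'   contain an `id` column matching `g$nodes` (GraphML only).
#' @return `path`, invisibly.
#' @export
write_graph <- function(g, path, format = c("graphml", "sif"),
                        node_attrs = NULL) {
  format <- match.arg(format)
  if (format == "sif") {
    rel <- ifelse(g$edges$sign < 0L, "i", "a")
    writeLines(paste(g$edges$from, rel, g$edges$to), path)
    return(invisible(path))
  }
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  xml2::xml_add_child(doc, "key", id = "signal", `for` = "edge",
                      `attr.name` = "signal", `attr.type` = "string")
  extra <- character()
  if (!is.null(node_attrs)) {
    extra <- setdiff(names(node_attrs), "id")
    for (nm in extra) {
      xml2::xml_add_child(doc, "key", id = nm, `for` = "node",
                          `attr.name` = nm, `attr.type` = "string")
    }
  }
  graph <- xml2::xml_add_child(doc, "graph",
                               id = if (is.null(g$name)) "G" else g$name,
                               edgedefault = "directed")
  for (v in g$nodes) {
    nd <- xml2::xml_add_child(graph, "node", id = v)
    if (length(extra)) {
      row <- match(v, node_attrs$id)
      for (nm in extra) {
        dt <- xml2::xml_add_child(nd, "data", key = nm)
        xml2::xml_text(dt) <- as.character(node_attrs[[nm]][row])
      }
    }
  }
  for (i in seq_len(nrow(g$edges))) {
    e <- xml2::xml_add_child(graph, "edge",
                             source = g$edges$from[i],
                             target = g$edges$to[i])
    dt <- xml2::xml_add_child(e, "data", key = "signal")
    xml2::xml_text(dt) <- if (g$edges$sign[i] < 0L) "i" else "a"
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read an expression matrix from CSV/TSV
#'
#' Genes in rows (first column = gene id), samples in columns. Values must
#' be nonnegative (raw counts or exponentiated intensities).
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (`.csv` -> comma, otherwise tab).
#' @return numeric matrix with gene ids as rownames.
#' @export
read_expression <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers")
  if (any(m < 0)) stop("expression matrix contains negative entries")
  m
}

#' Match network genes to expression rows (case-insensitive)
#'
#' @param g a `signed_graph`.
#' @param expr numeric matrix with gene rownames.
#' @return named character vector mapping node id -> matched expression
#'   row name (NA when unmatched); unmatched nodes are reported via a
#'   message.
#' @export
match_genes <- function(g, expr) {
  rows <- rownames(expr)
  lower <- tolower(rows)
  hit <- function(v) {
    cand <- tolower(c(v, g$aliases[[v]]))
    i <- match(cand, lower)
    i <- i[!is.na(i)]
    if (length(i)) rows[i[1]] else NA_character_
  }
  map <- vapply(g$nodes, hit, character(1))
  if (anyNA(map)) {
    message(sum(is.na(map)), " network gene(s) not found in expression data: ",
            paste(utils::head(names(map)[is.na(map)], 10), collapse = ", "))
  }
  map
}
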