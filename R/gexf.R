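#' Export a semantic network and its partition as GEXF 1.3
#'
#' Writes an undirected, weighted GEXF 1.3 graph with node attributes
#' `size` (the lemma's seed co-occurrence frequency) and `modularity_class`
#' (the community id from [louvain()]), ready for layouting and rendering in
#' external network-visualization tools. Numbers are written at full double
#' precision; output is byte-identical across runs for identical inputs.
#'
#' @param network A `semnet`.
#' @param partition A `semnet_partition` covering every node of `network`.
#' @param path Output path; the parent directory must exist.
#' @return Invisibly, `path`.
#' @export
write_gexf <- function(network, partition, path) {
  stopifnot(inherits(network, "semnet"))
  if (is.null(partition) ||
      (inherits(partition, "semnet_partition") &&
       length(partition$membership) == 0L))
    stop("partition is empty", call. = FALSE)
  m <- as_membership(partition, network)

  doc <- xml2::xml_new_root("gexf", xmlns = "http://gexf.net/1.3",
                            version = "1.3")
  graph <- xml2::xml_add_child(doc, "graph",
                               defaultedgetype = "undirected",
                               mode = "static")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(attrs, "attribute", id = "size", title = "size",
                      type = "double")
  xml2::xml_add_child(attrs, "attribute", id = "modularity_class",
                      title = "modularity_class", type = "integer")
  nodes_el <- xml2::xml_add_child(graph, "nodes")
  nd <- network$nodes
  for (i in seq_len(nrow(nd))) {
    node <- xml2::xml_add_child(nodes_el, "node", id = nd$lemma[i],
                                label = nd$lemma[i])
    av <- xml2::xml_add_child(node, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "size",
                        value = sprintf("%.17g", nd$size[i]))
    xml2::xml_add_child(av, "attvalue", `for` = "modularity_class",
                        value = as.character(m[nd$lemma[i]]))
  }
  edges_el <- xml2::xml_add_child(graph, "edges")
  ed <- network$edges
  for (i in seq_len(nrow(ed))) {
    xml2::xml_add_child(edges_el, "edge", id = as.character(i - 1L),
                        source = ed$from[i], target = ed$to[i],
                        weight = sprintf("%.17g", ed$weight[i]))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(as.character(doc), con, useBytes = TRUE, sep = "")
  invisible(path)
}

#' Read a GEXF file written by [write_gexf()]
#'
#' @param path GEXF file path.
#' @return List with `nodes` (data.frame `lemma`, `size`,
#'   `modularity_class`) and `edges` (data.frame `from`, `to`, `weight`),
#'   both in file order.
#' @export
read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  node_els <- xml2::xml_find_all(doc, ".//nodes/node")
  get_att <- function(node, id) {
    av <- xml2::xml_find_first(
      node, sprintf(".//attvalue[@for='%s']", id))
    xml2::xml_attr(av, "value")
  }
  nodes <- data.frame(
    lemma = xml2::xml_attr(node_els, "id"),
    size = as.numeric(vapply(node_els, get_att, character(1), "size")),
    modularity_class = as.integer(
      vapply(node_els, get_att, character(1), "modularity_class")),
    stringsAsFactors = FALSE
  )
  edge_els <- xml2::xml_find_all(doc, ".//edges/edge")
  edges <- data.frame(
    from = xml2::xml_attr(edge_els, "source"),
    to = xml2::xml_attr(edge_els, "target"),
    weight = as.numeric(xml2::xml_attr(edge_els, "weight")),
    stringsAsFactors = FALSE
  )
  list(nodes = nodes, edges = edges)
}
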