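#' One-edge-difference graph over topological configurations
#'
#' Nodes are the admissible configurations; two nodes are joined when their
#' optional-edge masks differ in exactly one bit, i.e. when one configuration
#' can be turned into the other by gaining or losing a single reaction — a
#' minimal evolutionary event. Flips that land outside the admissible set are
#' simply absent edges; only admissible configurations are nodes.
#'
#' @param configs configuration table from [enumerate_configurations()].
#' @return An undirected [igraph::igraph] graph; vertices carry `name`
#'   (the letter label) and `mask` (the presence-bit string).
#' @examples
#' g <- build_topology_graph(enumerate_configurations())
#' igraph::degree(g)["S"]  # 0: channels-only is isolated
#' @export
build_topology_graph <- function(configs) {
  edge_cols <- setdiff(names(configs), c("label", "n_edges", "n_dependent"))
  bits <- as.matrix(configs[, edge_cols]) * 1
  keys <- apply(bits, 1, paste, collapse = "")
  if (anyDuplicated(keys)) stop("duplicate topological configurations")
  n <- nrow(bits)
  adj <- matrix(0L, n, n, dimnames = list(configs$label, configs$label))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (sum(bits[i, ] != bits[j, ]) == 1L) adj[i, j] <- adj[j, i] <- 1L
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$mask <- keys
  g
}

#' Connectivity of a configuration subset
#'
#' Tests whether the subgraph induced by `subset` (default: all nodes) is
#' connected, and returns its component decomposition.
#'
#' @param graph a [build_topology_graph()] graph.
#' @param subset character vector of configuration labels, or `NULL` for the
#'   full graph.
#' @return List with `connected` (logical), `n_components`, and `components`
#'   (list of label vectors).
#' @export
is_connected_subset <- function(graph, subset = NULL) {
  labels <- igraph::V(graph)$name
  if (is.null(subset)) subset <- labels
  unknown <- setdiff(subset, labels)
  if (length(unknown)) {
    stop("unknown configuration label: ", paste(unknown, collapse = ", "))
  }
  sg <- igraph::induced_subgraph(graph, subset)
  comp <- igraph::components(sg)
  members <- split(igraph::V(sg)$name, comp$membership)
  list(connected = comp$no == 1L,
       n_components = comp$no,
       components = unname(members))
}

#' Export the topology graph
#'
#' Writes a tab-separated edge list and, optionally, GraphML for
#' visualization tools.
#'
#' @param graph a [build_topology_graph()] graph.
#' @param edge_path TSV edge-list output path.
#' @param graphml_path optional GraphML output path.
#' @return `edge_path`, invisibly.
#' @export
write_topology_graph <- function(graph, edge_path, graphml_path = NULL) {
  el <- igraph::as_edgelist(graph)
  utils::write.table(data.frame(from = el[, 1], to = el[, 2]),
                     edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(graph, graphml_path, format = "graphml")
  }
  invisible(edge_path)
}
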