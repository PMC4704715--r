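#' Load an undirected interaction network from an edge-list TSV
#'
#' Accepts 2- or 3-column files (gene1, gene2, optional weight), with or
#' without a header. Self-loops are dropped (count reported via message) and
#' duplicate unordered pairs collapsed, keeping the maximum weight.
#'
#' @param path edge-list file.
#' @return an undirected [igraph::graph] with no loops or multi-edges;
#'   edge attribute `weight` if the file carried one.
#' @export
load_network <- function(path) {
  first <- utils::read.delim(path, header = FALSE, nrows = 1,
                             stringsAsFactors = FALSE)
  has_header <- ncol(first) >= 2 &&
    all(!is.na(first[1, 1:2])) &&
    any(tolower(as.character(first[1, ])) %in%
          c("gene1", "gene2", "source", "target", "weight"))
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("edge list needs at least 2 columns: ", path)
  edges <- data.frame(from = as.character(df[[1]]),
                      to = as.character(df[[2]]),
                      stringsAsFactors = FALSE)
  if (ncol(df) >= 3) edges$weight <- as.numeric(df[[3]])
  bad <- !nzchar(edges$from) | !nzchar(edges$to) |
    is.na(edges$from) | is.na(edges$to)
  if (any(bad)) stop("malformed edge row(s): ", paste(which(bad), collapse = ", "))
  loops <- edges$from == edges$to
  if (any(loops)) {
    message("dropped ", sum(loops), " self-loop(s)")
    edges <- edges[!loops, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if ("weight" %in% igraph::edge_attr_names(g)) {
    g <- igraph::simplify(g, edge.attr.comb = list(weight = "max"))
  } else {
    g <- igraph::simplify(g)
  }
  g
}

#' Induced subnetwork of a gene set
#'
#' Extracts the hit group's nodes from the full network keeping only their
#' direct interactions: edges with both endpoints in the group.
#'
#' @param network an [igraph::graph] (e.g. from [load_network()]).
#' @param genes character vector of gene identifiers.
#' @return list: `graph` (induced subgraph), `mapped` (genes present in the
#'   network), `unmapped` (genes absent from it).
#' @export
induced_subnetwork <- function(network, genes) {
  genes <- unique(as.character(genes))
  present <- intersect(genes, igraph::V(network)$name)
  sub <- igraph::induced_subgraph(network, present)
  list(graph = sub, mapped = present, unmapped = setdiff(genes, present))
}

#' Connectivity and module summary of an induced subnetwork
#'
#' Computes the connectivity statistics used to describe hit-group
#' subnetworks: mapped fraction, total edges, edges per node (edge count
#' divided by mapped node count, isolated nodes included by default),
#' connected components, and "modules" — components with more than
#' `min_nodes - 1` nodes (default: strictly more than 5). The share of
#' mapped genes inside the largest module is reported since it measures how
#' much of the group coheres into one connected piece.
#'
#' @param subnet result of [induced_subnetwork()].
#' @param n_input_genes size of the original gene group (for the mapped
#'   fraction); defaults to mapped + unmapped.
#' @param min_nodes minimum node count for a component to be a module.
#' @param denominator "mapped" (default; isolated mapped nodes count) or
#'   "non_isolated" for the alternative edges-per-node denominator.
#' @return list (SubnetworkSummary): n_input_genes, n_mapped,
#'   mapped_fraction, n_edges, edges_per_node, components (list of node
#'   vectors, largest first), modules (subset of components), module_stats
#'   (data.frame: size, n_edges, edges_per_node per module),
#'   largest_module_share.
#' @export
summarize_subnetwork <- function(subnet, n_input_genes = NULL, min_nodes = 6L,
                                 denominator = c("mapped", "non_isolated")) {
  denominator <- match.arg(denominator)
  g <- subnet$graph
  n_mapped <- igraph::vcount(g)
  if (is.null(n_input_genes)) {
    n_input_genes <- n_mapped + length(subnet$unmapped)
  }
  n_edges <- igraph::ecount(g)
  denom <- if (denominator == "mapped") {
    n_mapped
  } else {
    sum(igraph::degree(g) > 0)
  }
  epn <- if (denom > 0) n_edges / denom else 0
  comp <- igraph::components(g)
  members <- split(igraph::V(g)$name, comp$membership)
  members <- members[order(-vapply(members, length, integer(1)))]
  names(members) <- NULL
  sizes <- vapply(members, length, integer(1))
  is_module <- sizes > (min_nodes - 1L)
  modules <- members[is_module]
  module_stats <- do.call(rbind, lapply(modules, function(nodes) {
    sg <- igraph::induced_subgraph(g, nodes)
    data.frame(size = length(nodes), n_edges = igraph::ecount(sg),
               edges_per_node = igraph::ecount(sg) / length(nodes))
  }))
  if (is.null(module_stats)) {
    module_stats <- data.frame(size = integer(), n_edges = integer(),
                               edges_per_node = numeric())
  }
  list(n_input_genes = n_input_genes,
       n_mapped = n_mapped,
       mapped_fraction = if (n_input_genes > 0) n_mapped / n_input_genes else 0,
       n_edges = n_edges,
       edges_per_node = epn,
       components = members,
       modules = modules,
       module_stats = module_stats,
       largest_module_share =
         if (n_mapped > 0 && length(sizes)) max(sizes) / n_mapped else 0)
}

#' Connected modules of a gene group within a network
#'
#' Convenience wrapper: induce the group's subnetwork and return the
#' connected components larger than the module threshold.
#'
#' @inheritParams induced_subnetwork
#' @inheritParams summarize_subnetwork
#' @return list of character vectors (module node sets, largest first).
#' @export
find_modules <- function(network, genes, min_nodes = 6L) {
  sub <- induced_subnetwork(network, genes)
  summarize_subnetwork(sub, min_nodes = min_nodes)$modules
}

#' Write an interaction network as a 3-column TSV edge list
#'
#' @param network an [igraph::graph].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(network, path) {
  el <- igraph::as_data_frame(network, what = "edges")
  if (!"weight" %in% names(el)) el$weight <- 1
  names(el)[1:2] <- c("gene1", "gene2")
  utils::write.table(el[, c("gene1", "gene2", "weight")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
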