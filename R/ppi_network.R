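#' Extract a seed-gene subnetwork with linker genes
#'
#' Greedy Steiner-style extraction: starting from the seed genes present in
#' the interaction graph, the connected components of the current selection
#' are iteratively merged by the shortest path (of length at most
#' `maxLinkerPath` edges) between any two components in the full graph;
#' interior nodes of the chosen path join the selection as linkers. Ties
#' between equally short paths break lexicographically on the path's node
#' names. Seeds that cannot be reached within the path cap remain as
#' separate reported components rather than being dropped.
#'
#' @param graph an undirected [igraph::igraph] with gene-symbol vertex names.
#' @param seeds a [GeneSet-class]; at least 2 members must be in the graph.
#' @param maxLinkerPath maximum bridge path length in edges (default 2,
#'   i.e. at most one linker per bridge).
#' @return The induced subgraph over seeds and linkers, with vertex
#'   attribute `role` (`seed`/`linker`) and graph attributes `n_linkers`,
#'   `n_components`.
#' @export
extractSubnetwork <- function(graph, seeds, maxLinkerPath = 2) {
  seedGenes <- intersect(members(seeds), igraph::V(graph)$name)
  if (length(seedGenes) == 0) stop("no seed gene present in the graph")
  if (length(seedGenes) < 2) stop("need >= 2 seed genes in the graph")
  selected <- seedGenes
  repeat {
    sub <- igraph::induced_subgraph(graph, selected)
    comp <- igraph::components(sub)
    if (comp$no <= 1) break
    membership <- comp$membership[selected]
    # shortest path between any two distinct components, capped
    best <- NULL
    comps <- split(selected, membership)
    ord <- order(vapply(comps, function(g) min(g), character(1L)))
    comps <- comps[ord]
    for (i in seq_len(length(comps) - 1L)) {
      dists <- igraph::distances(graph, v = comps[[i]],
                                 to = unlist(comps[-seq_len(i)]))
      if (!any(is.finite(dists))) next
      dmin <- min(dists)
      if (dmin > maxLinkerPath) next
      if (!is.null(best) && dmin >= best$len) next
      hit <- which(dists == dmin, arr.ind = TRUE)
      # enumerate candidate endpoint pairs, take lexicographically least path
      for (h in seq_len(nrow(hit))) {
        from <- rownames(dists)[hit[h, 1L]]
        to <- colnames(dists)[hit[h, 2L]]
        paths <- igraph::all_shortest_paths(graph, from, to)$vpaths
        pathNames <- lapply(paths, function(p) igraph::V(graph)$name[p])
        keys <- vapply(pathNames, paste, character(1L), collapse = "\r")
        cand <- pathNames[[order(keys)[1L]]]
        if (is.null(best) || dmin < best$len ||
            paste(cand, collapse = "\r") < paste(best$path, collapse = "\r")) {
          best <- list(len = dmin, path = cand)
        }
      }
    }
    if (is.null(best)) break    # remaining components unreachable within cap
    selected <- union(selected, best$path)
  }
  out <- igraph::induced_subgraph(graph, selected)
  role <- ifelse(igraph::V(out)$name %in% seedGenes, "seed", "linker")
  out <- igraph::set_vertex_attr(out, "role", value = role)
  out <- igraph::set_graph_attr(out, "n_linkers", sum(role == "linker"))
  igraph::set_graph_attr(out, "n_components",
                         igraph::components(out)$no)
}

#' Network density
#'
#' `2E / (n (n - 1))` for an undirected simple graph with `n >= 2` nodes.
#' @param graph an igraph graph.
#' @return density in `[0, 1]`.
#' @export
graphDensity <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 2) stop("density needs >= 2 nodes")
  2 * igraph::ecount(graph) / (n * (n - 1))
}

#' Mean local clustering coefficient
#'
#' Average over all nodes of the local clustering coefficient, with nodes of
#' degree < 2 contributing 0.
#' @param graph an igraph graph with >= 1 node.
#' @return mean clustering coefficient in `[0, 1]`.
#' @export
avgClustering <- function(graph) {
  if (igraph::vcount(graph) < 1) stop("clustering needs >= 1 node")
  lc <- igraph::transitivity(graph, type = "local", isolates = "zero")
  mean(lc)
}

#' Node role table of an extracted subnetwork
#' @param graph a graph from [extractSubnetwork].
#' @return data.frame `gene`, `role`, `degree`.
#' @export
subnetworkRoles <- function(graph) {
  data.frame(gene = igraph::V(graph)$name, role = igraph::V(graph)$role,
             degree = igraph::degree(graph))
}
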