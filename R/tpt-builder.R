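#' One-mode TPT projection of a target-pathway map
#'
#' Projects the bipartite target-pathway relation onto its target mode:
#' two targets are joined by an edge exactly when they share at least one
#' pathway, and the edge records the full set of shared pathways. The
#' result is the targets-pathways-targets (TPT) network on which the
#' knockout perturbation operates. Edges are unweighted at baseline
#' (length 1); all weighting is perturbation-specific.
#'
#' @param map a [bipartite_map()].
#' @return An undirected igraph whose vertices are all targets in the map
#'   (targets whose pathways are all singletons remain as isolated nodes)
#'   and whose edges carry a `pathways` list attribute of shared pathway
#'   ids, each set sorted.
#' @export
#' @examples
#' g <- tpt_project(sample_network())
#' tpt_stats(g)
tpt_project <- function(map) {
  stopifnot(inherits(map, "bipartite_map"))
  nodes <- map_targets(map)
  if (length(nodes) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  prs <- map$pairs
  m <- merge(prs, prs, by = "pathway")
  m <- m[m$target.x < m$target.y, , drop = FALSE]
  if (nrow(m) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::add_vertices(g, length(nodes), name = nodes)
    return(g)
  }
  key <- paste(m$target.x, m$target.y, sep = "\r")
  sets <- lapply(split(m$pathway, key), function(p) sort(unique(p)))
  uv <- do.call(rbind, strsplit(names(sets), "\r", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = uv[, 1], to = uv[, 2], stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes)
  igraph::E(g)$pathways <- unname(sets)
  g
}

#' Basic TPT graph statistics
#'
#' @param graph an igraph, typically from [tpt_project()].
#' @return A list with `n_nodes`, `n_edges`, `n_components`.
#' @export
tpt_stats <- function(graph) {
  list(n_nodes = igraph::vcount(graph),
       n_edges = igraph::ecount(graph),
       n_components = if (igraph::vcount(graph) == 0) 0L else
         igraph::count_components(graph))
}
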