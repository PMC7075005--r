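#' Pathway efficacy under a single-target knockout
#'
#' Every member target of a pathway is assumed to contribute an equal share
#' of its efficacy, so setting off one member of a pathway with `N_j`
#' targets leaves it at efficacy `(N_j - 1)/N_j`; pathways not containing
#' the knocked target keep efficacy 1 exactly.
#'
#' @param pathway_size integer pathway size `N_j` (>= 1); vectorized.
#' @param is_member logical, whether the knocked target belongs to the
#'   pathway; vectorized.
#' @return Numeric efficacy in (0, 1].
#' @export
#' @examples
#' pathway_efficacy(3, TRUE)   # 2/3, displayed as 67%
#' pathway_efficacy(2, TRUE)   # 1/2, displayed as 50%
pathway_efficacy <- function(pathway_size, is_member) {
  if (any(is.na(pathway_size)) || any(pathway_size < 1)) {
    stop("pathway size must be a positive count", call. = FALSE)
  }
  n <- max(length(pathway_size), length(is_member))
  pathway_size <- rep_len(pathway_size, n)
  is_member <- rep_len(is_member, n)
  out <- rep(1, n)
  out[is_member] <- (pathway_size[is_member] - 1) / pathway_size[is_member]
  out
}

#' Edge efficacy and length under a knockout
#'
#' The efficacy of an edge is the product of the efficacies of the pathways
#' it carries; unaffected pathways contribute 1, so only the `t` affected
#' pathways matter: `EE = (N_1 - 1)/N_1 * ... * (N_t - 1)/N_t`. The edge
#' length is `1/EE` when affected and 1 otherwise. Both values are formed
#' from exact integer numerator/denominator products, so each is the
#' correctly rounded double of the underlying rational.
#'
#' @param edge_pathway_sizes integer sizes of the pathways the edge carries.
#' @param knocked_member_flags logical, aligned with `edge_pathway_sizes`:
#'   whether the knocked target is a member of each pathway.
#' @return List with `ee` (edge efficacy, (0, 1]), `length` (>= 1) and
#'   `n_affected` (the count `t`).
#' @export
edge_efficacy <- function(edge_pathway_sizes, knocked_member_flags) {
  stopifnot(length(edge_pathway_sizes) == length(knocked_member_flags))
  if (any(edge_pathway_sizes[knocked_member_flags] < 2)) {
    stop("an affected pathway on an edge must have >= 2 members",
         call. = FALSE)
  }
  N <- edge_pathway_sizes[knocked_member_flags]
  if (length(N) == 0) {
    return(list(ee = 1, length = 1, n_affected = 0L))
  }
  num <- prod(N - 1)
  den <- prod(N)
  if (num == 0) {                       # unreachable given the size guard
    return(list(ee = 0, length = Inf, n_affected = length(N)))
  }
  list(ee = num / den, length = den / num, n_affected = length(N))
}

#' Weighted network efficiency
#'
#' Sum over unordered node pairs of the reciprocal shortest-path length,
#' a measure of global network integrity. Unreachable pairs contribute 0.
#'
#' @param graph an undirected igraph.
#' @param lengths edge lengths (>= 1), in `igraph::E(graph)` order, or
#'   `NULL` for unit lengths.
#' @return The network efficiency NE (a non-negative number).
#' @export
network_efficiency <- function(graph, lengths = NULL) {
  n <- igraph::vcount(graph)
  if (n < 2) return(0)
  if (is.null(lengths)) lengths <- rep(1, igraph::ecount(graph))
  if (any(lengths < 1)) stop("edge lengths must be >= 1", call. = FALSE)
  d <- igraph::distances(graph, weights = lengths, algorithm = "dijkstra")
  sum(1 / d[upper.tri(d)])
}

#' Knock out one target and measure the efficiency decrease
#'
#' Implements the perturbation at the heart of the ranking: the knocked
#' target is assumed undruggable, each pathway containing it drops to
#' `(N_j - 1)/N_j` efficacy, every edge carrying an affected pathway is
#' lengthened to the reciprocal of its efficacy product, and the network
#' efficiency of the reweighted graph is compared with baseline. The node
#' itself is retained -- only edge lengths change -- so its incident pairs
#' still count.
#'
#' @param graph the TPT igraph from [tpt_project()].
#' @param map the [bipartite_map()] the graph was projected from.
#' @param target the target id to set off (must be a graph node).
#' @param ne_baseline baseline efficiency NE_0 at unit lengths; computed
#'   from `graph` when `NULL`. Pass it explicitly when ranking many targets
#'   so it is computed once.
#' @return An object of class `perturbation`: a list with `target`,
#'   `pathway_efficacies` (named numeric over all pathways, 1 where
#'   unaffected), `edge_states` (data frame `from`, `to`, `n_affected`,
#'   `ee`, `length`), `ne_baseline`, `ne`, `ned`.
#' @export
#' @examples
#' map <- sample_network()
#' g <- tpt_project(map)
#' k <- knockout(g, map, "C")
#' k$ned
knockout <- function(graph, map, target, ne_baseline = NULL) {
  stopifnot(inherits(map, "bipartite_map"))
  if (!(target %in% igraph::V(graph)$name)) {
    stop("unknown target: ", target, call. = FALSE)
  }
  if (is.null(ne_baseline)) ne_baseline <- network_efficiency(graph)
  sizes <- pathway_sizes(map)
  affected <- pathways_of(map, target)
  pe <- stats::setNames(rep(1, length(sizes)), names(sizes))
  pe[affected] <- pathway_efficacy(sizes[affected], TRUE)

  esets <- igraph::E(graph)$pathways
  if (is.null(esets)) esets <- rep(list(character()), igraph::ecount(graph))
  states <- lapply(esets, function(ps) {
    edge_efficacy(unname(sizes[ps]), ps %in% affected)
  })
  lens <- vapply(states, `[[`, numeric(1), "length")
  ne <- network_efficiency(graph, lengths = lens)
  el <- igraph::as_edgelist(graph, names = TRUE)
  edge_states <- data.frame(
    from = if (nrow(el)) el[, 1] else character(),
    to = if (nrow(el)) el[, 2] else character(),
    n_affected = vapply(states, `[[`, integer(1), "n_affected"),
    ee = vapply(states, `[[`, numeric(1), "ee"),
    length = lens,
    stringsAsFactors = FALSE)
  structure(list(target = target, pathway_efficacies = pe,
                 edge_states = edge_states,
                 ne_baseline = ne_baseline, ne = ne,
                 ned = ne_baseline - ne),
            class = "perturbation")
}

#' @export
print.perturbation <- function(x, ...) {
  cat("<perturbation> target ", x$target,
      ": NE_0 = ", format(x$ne_baseline),
      ", NE = ", format(x$ne),
      ", NED = ", format(x$ned), "\n", sep = "")
  invisible(x)
}

#' Rank all targets by network efficiency decrease
#'
#' Knocks out every node of the TPT graph in turn and ranks targets by
#' descending NED; ties break by ascending target id, so the ordering is
#' deterministic. The baseline NE_0 is computed once and shared.
#'
#' @inheritParams knockout
#' @return A data frame with columns `target`, `ne`, `ned`, `rank`, sorted
#'   by rank, with `ne_baseline` attached as an attribute `ne_baseline`.
#' @export
ned_rank <- function(graph, map) {
  ne0 <- network_efficiency(graph)
  targets <- igraph::V(graph)$name
  if (is.null(targets) || length(targets) == 0) {
    out <- data.frame(target = character(), ne = numeric(),
                      ned = numeric(), rank = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "ne_baseline") <- ne0
    return(out)
  }
  res <- lapply(targets, function(tg) knockout(graph, map, tg, ne0))
  out <- data.frame(target = targets,
                    ne = vapply(res, `[[`, numeric(1), "ne"),
                    ned = vapply(res, `[[`, numeric(1), "ned"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$ned, out$target), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "ne_baseline") <- ne0
  out
}

#' Select the top fraction of a ranking
#'
#' Takes the first `ceiling(fraction * n)` entries of a ranked table: the
#' "main targets". With 279 ranked targets and the default fraction 0.10
#' this selects 28.
#'
#' @param ranked data frame as returned by [ned_rank()] (or any ranked
#'   table).
#' @param fraction proportion in (0, 1], default 0.10.
#' @return The selected head of `ranked`.
#' @export
top_fraction <- function(ranked, fraction = 0.10) {
  stopifnot(is.data.frame(ranked))
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  utils::head(ranked, ceiling(fraction * nrow(ranked)))
}

#' Display an efficacy as a rounded percentage
#'
#' @param efficacy numeric efficacy in `[0, 1]`.
#' @return Integer percentage, rounded to the nearest whole percent
#'   (2/3 becomes 67).
#' @export
efficacy_percent <- function(efficacy) {
  as.integer(round(100 * efficacy))
}
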