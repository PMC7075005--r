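#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability \eqn{P(X \ge k)} for \eqn{X} hypergeometric: the
#' chance of drawing at least `k` pathway members when `n_query` targets are
#' drawn without replacement from a universe of `N_universe` targets of which
#' `K` belong to the pathway.
#'
#' @param k observed overlap between query and pathway.
#' @param K pathway size within the universe.
#' @param n_query query set size.
#' @param N_universe universe size.
#' @return p-value in (0, 1].
#' @export
hypergeometric_p <- function(k, K, n_query, N_universe) {
  stopifnot(length(k) == 1, length(K) == 1, length(n_query) == 1,
            length(N_universe) == 1)
  if (k < 0 || K < 0 || n_query < 0 || N_universe < 0 ||
      k > K || k > n_query || K > N_universe || n_query > N_universe) {
    stop("impossible counts: need 0 <= k <= min(K, n_query) and ",
         "K, n_query <= N_universe", call. = FALSE)
  }
  stats::phyper(k - 1, K, N_universe - K, n_query, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: sorted p-values are scaled by
#' m/rank and made monotone from the largest down, then mapped back to the
#' input order.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Pathway over-representation of a target set
#'
#' Tests every annotated pathway with an overlap of at least one query
#' target for over-representation using the one-sided hypergeometric upper
#' tail, controls the FDR with Benjamini-Hochberg across the tested
#' pathways, and retains pathways with q below `alpha`. Pathway membership
#' is intersected with the universe before testing.
#'
#' @param targets character vector: the query target set.
#' @param annotation a [bipartite_map()] of target-pathway membership.
#' @param universe character vector of background targets; defaults to all
#'   targets appearing in the annotation.
#' @param alpha FDR retention threshold (default 0.05).
#' @return A list with `results` (data frame over all tested pathways:
#'   `pathway_id`, `pathway_name`, `k`, `K`, `n_query`, `N_universe`,
#'   `p_value`, `q_value`, `retained`) and `retained` (the retained subset,
#'   sorted by q, then p, then pathway id).
#' @export
enrich <- function(targets, annotation, universe = NULL, alpha = 0.05) {
  stopifnot(inherits(annotation, "bipartite_map"))
  if (is.null(universe)) universe <- map_targets(annotation)
  universe <- unique(as.character(universe))
  if (length(universe) == 0) {
    stop("empty universe: supply a background target set or a non-empty ",
         "annotation", call. = FALSE)
  }
  targets <- unique(as.character(targets))
  if (!all(targets %in% universe)) {
    stop("query targets outside the universe: ",
         paste(utils::head(setdiff(targets, universe), 5), collapse = ", "),
         call. = FALSE)
  }
  N <- length(universe)
  n <- length(targets)
  empty <- data.frame(pathway_id = character(), pathway_name = character(),
                      k = integer(), K = integer(), n_query = integer(),
                      N_universe = integer(), p_value = numeric(),
                      q_value = numeric(), retained = logical(),
                      stringsAsFactors = FALSE)
  rows <- lapply(map_pathways(annotation), function(pw) {
    mem <- intersect(members_of(annotation, pw), universe)
    k <- length(intersect(mem, targets))
    if (k < 1) return(NULL)
    data.frame(pathway_id = pw,
               pathway_name = if (pw %in% names(annotation$pathway_names))
                 unname(annotation$pathway_names[pw]) else pw,
               k = k, K = length(mem), n_query = n, N_universe = N,
               p_value = hypergeometric_p(k, length(mem), n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(list(results = empty, retained = empty))
  res <- do.call(rbind, rows)
  res$q_value <- bh_fdr(res$p_value)
  res$retained <- res$q_value < alpha
  res <- res[order(res$q_value, res$p_value, res$pathway_id), , drop = FALSE]
  rownames(res) <- NULL
  list(results = res, retained = res[res$retained, , drop = FALSE])
}

#' Restrict a bipartite map to a set of pathways
#'
#' Helper to carry an enrichment result forward: keeps only the membership
#' pairs of the retained pathways.
#'
#' @param map a [bipartite_map()].
#' @param pathways character vector of pathway ids to keep.
#' @return A [bipartite_map()].
#' @export
restrict_pathways <- function(map, pathways) {
  stopifnot(inherits(map, "bipartite_map"))
  keep <- map$pairs$pathway %in% pathways
  bipartite_map(map$pairs$target[keep], map$pairs$pathway[keep],
                pathway_names = map$pathway_names[
                  names(map$pathway_names) %in% pathways])
}
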