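#' Build the targets-pathways-diseases (TPD) network
#'
#' Directed tripartite graph over the main-target set: an edge runs from
#' each main target to every pathway containing it, and from each pathway
#' so reached to the ICD-11 disease classes it maps to. Pathway and disease
#' importance is then read from indegree (number of main targets feeding a
#' pathway; number of distinct pathways feeding a disease class).
#'
#' @param main_targets character vector of main-target ids (must all appear
#'   in `map`).
#' @param map the [bipartite_map()] annotation.
#' @param disease_map data frame with columns `pathway_id`,
#'   `icd11_class_code`, `icd11_class_name` (see
#'   [read_pathway_disease_table()]). Rows naming a pathway absent from the
#'   annotation are skipped with a warning; duplicate (pathway, disease)
#'   rows collapse to a single edge.
#' @return A directed igraph with vertex attributes `category`
#'   (`"target"`, `"pathway"` or `"disease"`) and `label` (display name),
#'   of class also usable with [tpd_indegrees()].
#' @export
build_tpd <- function(main_targets, map, disease_map = NULL) {
  stopifnot(inherits(map, "bipartite_map"))
  main_targets <- unique(as.character(main_targets))
  unknown <- setdiff(main_targets, map_targets(map))
  if (length(unknown)) {
    stop("main target(s) not in the annotation: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  tp <- map$pairs[map$pairs$target %in% main_targets, , drop = FALSE]
  reached <- sort(unique(tp$pathway))

  pd <- data.frame(pathway_id = character(), icd11_class_code = character(),
                   icd11_class_name = character(), stringsAsFactors = FALSE)
  if (!is.null(disease_map) && nrow(disease_map)) {
    bad <- !(disease_map$pathway_id %in% map_pathways(map))
    if (any(bad)) {
      warning("skipping disease rows for unknown pathway(s): ",
              paste(unique(disease_map$pathway_id[bad]), collapse = ", "),
              call. = FALSE)
    }
    pd <- disease_map[!bad & disease_map$pathway_id %in% reached, ,
                      drop = FALSE]
    pd <- unique(pd[, c("pathway_id", "icd11_class_code",
                        "icd11_class_name")])
  }

  targets <- sort(main_targets[main_targets %in% tp$target])
  diseases <- sort(unique(pd$icd11_class_code))
  ids <- c(targets, reached, diseases)
  if (anyDuplicated(ids)) {
    stop("target, pathway and disease identifiers must be disjoint",
         call. = FALSE)
  }
  if (length(ids) == 0) {
    return(igraph::make_empty_graph(0, directed = TRUE))
  }
  category <- c(rep("target", length(targets)),
                rep("pathway", length(reached)),
                rep("disease", length(diseases)))
  label <- ids
  pw_named <- reached %in% names(map$pathway_names)
  label[length(targets) + which(pw_named)] <-
    unname(map$pathway_names[reached[pw_named]])
  dn <- pd$icd11_class_name[match(diseases, pd$icd11_class_code)]
  label[length(targets) + length(reached) + seq_along(diseases)] <-
    ifelse(is.na(dn), diseases, dn)

  edges <- rbind(
    data.frame(from = tp$target, to = tp$pathway,
               stringsAsFactors = FALSE),
    data.frame(from = pd$pathway_id, to = pd$icd11_class_code,
               stringsAsFactors = FALSE))
  igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = ids, category = category, label = label,
                          stringsAsFactors = FALSE))
}

#' Indegrees of a TPD network by node category
#'
#' @param tpd a graph from [build_tpd()].
#' @param category `"pathway"` or `"disease"`.
#' @return Named numeric vector of indegrees for the chosen category,
#'   sorted by decreasing indegree then id.
#' @export
tpd_indegrees <- function(tpd, category = c("pathway", "disease")) {
  category <- match.arg(category)
  if (igraph::vcount(tpd) == 0) return(stats::setNames(numeric(), character()))
  keep <- igraph::V(tpd)$category == category
  ind <- igraph::degree(tpd, mode = "in")[keep]
  ind[order(-ind, names(ind))]
}

#' Main pathways / diseases by indegree threshold
#'
#' Retains pathway (or disease) nodes whose indegree strictly exceeds the
#' threshold, the rule used to call a pathway "main" when more than 10 main
#' targets feed it and a disease class prominent when more than 20 pathways
#' feed it.
#'
#' @param tpd a graph from [build_tpd()].
#' @param threshold non-negative indegree cut; retention is strict (`>`).
#' @return Data frame with `id`, `label`, `indegree`, sorted by decreasing
#'   indegree then id.
#' @export
main_pathways <- function(tpd, threshold = 10) {
  tpd_threshold(tpd, "pathway", threshold)
}

#' @rdname main_pathways
#' @export
main_diseases <- function(tpd, threshold = 20) {
  tpd_threshold(tpd, "disease", threshold)
}

tpd_threshold <- function(tpd, category, threshold) {
  stopifnot(threshold >= 0)
  ind <- tpd_indegrees(tpd, category)
  ind <- ind[ind > threshold]
  lab <- if (length(ind))
    igraph::V(tpd)$label[match(names(ind), igraph::V(tpd)$name)]
  else character()
  data.frame(id = names(ind), label = lab, indegree = as.numeric(ind),
             stringsAsFactors = FALSE, row.names = NULL)
}
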