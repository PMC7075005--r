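#' Bipartite target-pathway map
#'
#' Container for the two-mode target-pathway membership relation that the
#' whole pipeline is built on: the output of a pathway enrichment (or a
#' pre-enriched annotation table) recording which protein targets belong to
#' which pathways. Pathway sizes taken from this map drive the knockout
#' perturbation model (a pathway of `N` targets retains efficacy
#' `(N - 1)/N` when one member is set off).
#'
#' @param target character vector of target identifiers (e.g. gene symbols).
#' @param pathway character vector of pathway identifiers, same length.
#' @param pathway_names optional named character vector mapping pathway id to
#'   a display name. If the same pathway id arrives with conflicting names,
#'   the first is kept with a warning.
#'
#' @details Identifiers are case-sensitive opaque strings; gene symbols are
#'   not normalized. Duplicate (target, pathway) pairs collapse silently.
#'
#' @return An object of class `bipartite_map`: a list with elements
#'   `pairs` (a data frame with columns `target`, `pathway`, deduplicated and
#'   sorted) and `pathway_names` (named character).
#' @export
#' @examples
#' m <- bipartite_map(c("A", "B", "B"), c("p1", "p1", "p2"))
#' pathway_sizes(m)
bipartite_map <- function(target = character(), pathway = character(),
                          pathway_names = NULL) {
  target <- as.character(target)
  pathway <- as.character(pathway)
  if (length(target) != length(pathway)) {
    stop("`target` and `pathway` must have the same length", call. = FALSE)
  }
  if (anyNA(target) || anyNA(pathway) ||
      any(!nzchar(target)) || any(!nzchar(pathway))) {
    stop("target and pathway identifiers must be non-missing, non-empty",
         call. = FALSE)
  }
  pairs <- unique(data.frame(target = target, pathway = pathway,
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$pathway, pairs$target), , drop = FALSE]
  rownames(pairs) <- NULL
  pn <- character()
  if (!is.null(pathway_names) && length(pathway_names)) {
    ids <- names(pathway_names)
    if (is.null(ids)) stop("`pathway_names` must be named", call. = FALSE)
    first <- !duplicated(ids)
    clash <- ids[duplicated(ids) &
                   pathway_names != pathway_names[match(ids, ids)]]
    if (length(clash)) {
      warning("conflicting names for pathway(s) ",
              paste(unique(clash), collapse = ", "),
              "; keeping the first", call. = FALSE)
    }
    pn <- pathway_names[first]
  }
  structure(list(pairs = pairs, pathway_names = pn),
            class = "bipartite_map")
}

#' @export
print.bipartite_map <- function(x, ...) {
  cat("<bipartite_map> ", length(map_targets(x)), " targets, ",
      length(map_pathways(x)), " pathways, ",
      nrow(x$pairs), " membership pairs\n", sep = "")
  invisible(x)
}

#' @rdname bipartite_map
#' @param map a `bipartite_map`.
#' @export
map_targets <- function(map) sort(unique(map$pairs$target))

#' @rdname bipartite_map
#' @export
map_pathways <- function(map) sort(unique(map$pairs$pathway))

#' Pathway sizes N_j
#'
#' Number of member targets per pathway, the `N_j` of the perturbation model.
#'
#' @param map a [bipartite_map()].
#' @return Named integer vector, one entry per pathway.
#' @export
pathway_sizes <- function(map) {
  stopifnot(inherits(map, "bipartite_map"))
  if (nrow(map$pairs) == 0) return(stats::setNames(integer(), character()))
  tab <- table(map$pairs$pathway)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(names(out))]
}

#' @rdname pathway_sizes
#' @param pathway a single pathway id.
#' @return `members_of`: character vector of member targets.
#' @export
members_of <- function(map, pathway) {
  stopifnot(inherits(map, "bipartite_map"), length(pathway) == 1)
  sort(map$pairs$target[map$pairs$pathway == pathway])
}

#' @rdname pathway_sizes
#' @param target a single target id.
#' @return `pathways_of`: character vector of pathways containing the target.
#' @export
pathways_of <- function(map, target) {
  stopifnot(inherits(map, "bipartite_map"), length(target) == 1)
  sort(map$pairs$pathway[map$pairs$target == target])
}

# --- tabular readers --------------------------------------------------------

read_table_checked <- function(path, required, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  df
}

guess_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

num_col <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop("non-numeric value in column '", col, "' of ", path,
         " at data row ", bad[1], " (\"", x[bad[1]], "\")", call. = FALSE)
  }
  out
}

#' Read a compound descriptor table
#'
#' Reads a CSV/TSV of compounds with the two Veber descriptors (rotatable
#' bond count and topological polar surface area). Rows sharing a
#' `compound_id` are merged into one record whose `herbs` is the union of
#' the source herbs -- the same compound is often listed under several herbs
#' by overlapping chemical databases.
#'
#' @param path file path. Extension `.csv` implies comma separation, anything
#'   else tab; override with `sep`.
#' @param sep field separator, or `NULL` to infer from the extension.
#' @return A data frame with columns `compound_id`, `name`, `smiles`,
#'   `herbs` (list column of character vectors), `rotatable_bonds`, `tpsa`;
#'   one row per unique compound, input order of first appearance preserved.
#' @export
read_compound_table <- function(path, sep = NULL) {
  sep <- guess_sep(path, sep)
  df <- read_table_checked(path, c("compound_id", "rotatable_bonds", "tpsa"),
                           sep = sep)
  if (nrow(df) == 0) {
    return(data.frame(compound_id = character(), name = character(),
                      smiles = character(),
                      herbs = I(list()),
                      rotatable_bonds = integer(), tpsa = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (any(!nzchar(df$compound_id))) {
    stop("empty compound_id in ", path, call. = FALSE)
  }
  rb <- num_col(df$rotatable_bonds, "rotatable_bonds", path)
  tp <- num_col(df$tpsa, "tpsa", path)
  name <- if ("name" %in% names(df)) df$name else df$compound_id
  smiles <- if ("smiles" %in% names(df)) df$smiles else
    rep(NA_character_, nrow(df))
  herb <- if ("herb" %in% names(df)) df$herb else rep("", nrow(df))

  ids <- unique(df$compound_id)
  idx <- match(ids, df$compound_id)
  herbs <- lapply(ids, function(id) {
    h <- herb[df$compound_id == id]
    sort(unique(h[nzchar(h)]))
  })
  out <- data.frame(compound_id = ids, name = name[idx],
                    smiles = smiles[idx],
                    rotatable_bonds = rb[idx], tpsa = tp[idx],
                    stringsAsFactors = FALSE)
  out$herbs <- herbs
  out[, c("compound_id", "name", "smiles", "herbs",
          "rotatable_bonds", "tpsa")]
}

#' Read a target-pathway membership table
#'
#' Two-column TSV (`target_id`, `pathway_id`), with an optional third column
#' `pathway_name`. Duplicate pairs collapse; if the same pathway id carries
#' two different names, the first is kept with a warning.
#'
#' @param path file path.
#' @param sep field separator, or `NULL` to infer from the extension.
#' @return A [bipartite_map()].
#' @export
read_bipartite_table <- function(path, sep = NULL) {
  sep <- guess_sep(path, sep)
  df <- read_table_checked(path, c("target_id", "pathway_id"), sep = sep)
  if (nrow(df) == 0) return(bipartite_map())
  pn <- NULL
  if ("pathway_name" %in% names(df)) {
    keep <- nzchar(df$pathway_name)
    pn <- df$pathway_name[keep]
    names(pn) <- df$pathway_id[keep]
    dup <- duplicated(names(pn)) & pn != pn[match(names(pn), names(pn))]
    if (any(dup)) {
      warning("conflicting names for pathway(s) ",
              paste(unique(names(pn)[dup]), collapse = ", "),
              "; keeping the first", call. = FALSE)
    }
    pn <- pn[!duplicated(names(pn))]
  }
  bipartite_map(df$target_id, df$pathway_id, pathway_names = pn)
}

#' Read a pathway-disease mapping table
#'
#' TSV with columns `pathway_id`, `icd11_class_code`, `icd11_class_name`,
#' mapping pathways to the ICD-11 disease classes used as disease nodes in
#' the TPD network.
#'
#' @inheritParams read_bipartite_table
#' @return Data frame with those three character columns, duplicates removed.
#' @export
read_pathway_disease_table <- function(path, sep = NULL) {
  sep <- guess_sep(path, sep)
  df <- read_table_checked(path,
                           c("pathway_id", "icd11_class_code",
                             "icd11_class_name"), sep = sep)
  unique(df[, c("pathway_id", "icd11_class_code", "icd11_class_name")])
}

#' Read a literature co-occurrence table
#'
#' TSV with columns `target_id`, `fulltext_count`, `abstract_count`: the
#' number of literature records co-mentioning the formula and each target,
#' from full-text and abstract-restricted searches.
#'
#' @inheritParams read_bipartite_table
#' @return Data frame with `target_id` (character) and the two non-negative
#'   integer count columns.
#' @export
read_cooccurrence_table <- function(path, sep = NULL) {
  sep <- guess_sep(path, sep)
  df <- read_table_checked(path,
                           c("target_id", "fulltext_count",
                             "abstract_count"), sep = sep)
  df$fulltext_count <- num_col(df$fulltext_count, "fulltext_count", path)
  df$abstract_count <- num_col(df$abstract_count, "abstract_count", path)
  if (any(df$fulltext_count < 0) || any(df$abstract_count < 0)) {
    stop("co-occurrence counts must be non-negative", call. = FALSE)
  }
  df
}

# --- graph I/O --------------------------------------------------------------

PATHWAY_SEP <- "|"

#' Write / read a pipeline graph
#'
#' Serializes a TPT or TPD graph so that a round-trip read reproduces the
#' node set, edge set and edge attributes exactly. GraphML is the primary
#' format (node/edge attributes included); a plain tab-separated edge list is
#' the fallback, in which the per-edge pathway set is joined with `"|"` and
#' isolated nodes are written as rows with an empty second column.
#'
#' @param graph an igraph object produced by [tpt_project()] or [build_tpd()].
#' @param path output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `write_graph_file`: the path, invisibly.
#' @export
write_graph_file <- function(graph, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  g <- graph
  if ("pathways" %in% igraph::edge_attr_names(g)) {
    ps <- igraph::E(g)$pathways
    if (is.list(ps)) {
      igraph::E(g)$pathways <-
        vapply(ps, paste, "", collapse = PATHWAY_SEP)
    }
  }
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g, names = TRUE)
    ps <- if ("pathways" %in% igraph::edge_attr_names(g))
      igraph::E(g)$pathways else rep("", nrow(el))
    iso <- setdiff(igraph::V(g)$name, as.vector(el))
    df <- data.frame(source = c(el[, 1], iso),
                     target = c(el[, 2], rep("", length(iso))),
                     pathways = c(ps, rep("", length(iso))),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_graph_file
#' @param directed for `format = "edgelist"`, whether to rebuild a directed
#'   graph (GraphML stores directedness itself).
#' @return `read_graph_file`: the igraph object, with `pathways` restored as
#'   a list-of-character edge attribute where present.
#' @export
read_graph_file <- function(path, format = c("graphml", "edgelist"),
                            directed = FALSE) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if ("id" %in% igraph::vertex_attr_names(g) &&
        !("name" %in% igraph::vertex_attr_names(g))) {
      igraph::V(g)$name <- igraph::V(g)$id
    }
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "",
                            colClasses = "character")
    iso <- !nzchar(df$target)
    g <- igraph::graph_from_data_frame(df[!iso, c("source", "target")],
                                       directed = directed,
                                       vertices = unique(c(df$source[iso],
                                                           df$source[!iso],
                                                           df$target[!iso])))
    igraph::E(g)$pathways <- df$pathways[!iso]
  }
  if ("pathways" %in% igraph::edge_attr_names(g) &&
      !is.list(igraph::E(g)$pathways)) {
    igraph::E(g)$pathways <- lapply(
      strsplit(igraph::E(g)$pathways, split = PATHWAY_SEP, fixed = TRUE),
      function(x) x[nzchar(x)])
  }
  g
}
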