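#' Run the full target-prioritization pipeline
#'
#' Orchestrates the stages in order -- compound screening (optional),
#' pathway enrichment (optional), TPT projection, NED ranking and
#' main-target selection, centrality baselines, TPD construction
#' (optional), and literature-co-occurrence validation (optional) -- and
#' writes each stage's output plus a run manifest into `out_dir`. A
#' pre-enriched target-pathway table may enter directly, in which case the
#' screening and enrichment stages are simply disabled.
#'
#' @param config a named list, or the path to a YAML/JSON file holding one.
#'   Recognised keys:
#'   \describe{
#'     \item{annotation}{path to a target-pathway TSV, or `"sample"` for the
#'       built-in worked-example network (required).}
#'     \item{out_dir}{output directory (required; created if absent).}
#'     \item{compounds}{optional compound table path; enables screening.}
#'     \item{targets}{optional path to a one-id-per-line query target list;
#'       enables enrichment, whose retained pathways then restrict the
#'       annotation.}
#'     \item{alpha}{enrichment FDR threshold (default 0.05).}
#'     \item{top_fraction}{main-target fraction (default 0.10).}
#'     \item{disease_map}{optional pathway-disease TSV; enables the TPD
#'       stage.}
#'     \item{pathway_indegree, disease_indegree}{TPD thresholds (defaults
#'       10 and 20, strict).}
#'     \item{cooccurrence}{optional co-occurrence TSV; enables validation.}
#'     \item{seed}{integer recorded in the manifest (the pipeline itself is
#'       deterministic; the seed feeds any synthetic inputs generated
#'       upstream).}
#'   }
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_config(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$annotation)) {
    stop("config error: `annotation` is required (path or \"sample\")",
         call. = FALSE)
  }
  if (is.null(config$out_dir)) {
    stop("config error: `out_dir` is required", call. = FALSE)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  alpha <- config$alpha %||% 0.05
  frac <- config$top_fraction %||% 0.10
  seed <- as.integer(config$seed %||% 1L)
  manifest <- list(inputs = config[intersect(names(config),
                                             c("annotation", "compounds",
                                               "targets", "disease_map",
                                               "cooccurrence"))],
                   parameters = list(alpha = alpha, top_fraction = frac,
                                     pathway_indegree =
                                       config$pathway_indegree %||% 10,
                                     disease_indegree =
                                       config$disease_indegree %||% 20),
                   seed = seed,
                   stages = character())

  # screening
  if (!is.null(config$compounds)) {
    cmp <- read_compound_table(config$compounds)
    scr <- screen_compounds(cmp)
    flat <- scr$passing
    flat$herbs <- vapply(flat$herbs, paste, "", collapse = ";")
    utils::write.table(flat, file.path(out_dir, "passing.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(n_input = scr$report$n_input,
                              n_pass = scr$report$n_pass),
                         file.path(out_dir, "screen_report.json"),
                         auto_unbox = TRUE)
    manifest$counts$n_compounds_in <- scr$report$n_input
    manifest$counts$n_compounds_pass <- scr$report$n_pass
    manifest$stages <- c(manifest$stages, "screen")
  }

  # annotation
  map <- if (identical(config$annotation, "sample")) sample_network()
         else read_bipartite_table(config$annotation)

  # enrichment
  if (!is.null(config$targets)) {
    q <- readLines(config$targets, warn = FALSE)
    q <- q[nzchar(q)]
    er <- enrich(q, map, alpha = alpha)
    utils::write.table(er$results, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    map <- restrict_pathways(map, er$retained$pathway_id)
    manifest$counts$n_pathways_retained <- nrow(er$retained)
    manifest$stages <- c(manifest$stages, "enrich")
  }
  if (nrow(map$pairs) == 0) {
    stop("no target-pathway pairs remain after the enrichment stage",
         call. = FALSE)
  }

  # TPT + NED
  g <- tpt_project(map)
  write_graph_file(g, file.path(out_dir, "tpt.graphml"), "graphml")
  st <- tpt_stats(g)
  ranked <- ned_rank(g, map)
  ne0 <- attr(ranked, "ne_baseline")
  main <- top_fraction(ranked, frac)
  ranked$is_main_target <- ranked$target %in% main$target
  ned_path <- file.path(out_dir, "ned.tsv")
  writeLines(sprintf("# NE_0 = %.10g", ne0), ned_path)
  suppressWarnings(
    utils::write.table(ranked, ned_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE))
  writeLines(main$target, file.path(out_dir, "main_targets.txt"))
  manifest$ne_0 <- ne0
  manifest$counts$n_nodes <- st$n_nodes
  manifest$counts$n_edges <- st$n_edges
  manifest$counts$n_components <- st$n_components
  manifest$counts$n_ranked <- nrow(ranked)
  manifest$counts$n_main_targets <- nrow(main)
  manifest$stages <- c(manifest$stages, "build-tpt", "ned")

  # centrality baselines
  cent <- centrality_table(g)
  utils::write.table(cent, file.path(out_dir, "centrality.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages <- c(manifest$stages, "centrality")

  # TPD
  if (!is.null(config$disease_map)) {
    dm <- read_pathway_disease_table(config$disease_map)
    tpd <- build_tpd(main$target, map, dm)
    write_graph_file(tpd, file.path(out_dir, "tpd.graphml"), "graphml")
    mp <- main_pathways(tpd, manifest$parameters$pathway_indegree)
    md <- main_diseases(tpd, manifest$parameters$disease_indegree)
    mp$category <- rep("pathway", nrow(mp))
    md$category <- rep("disease", nrow(md))
    summ <- rbind(mp, md)[, c("category", "id", "label", "indegree")]
    utils::write.table(summ, file.path(out_dir, "tpd_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$n_main_pathways <- nrow(mp)
    manifest$counts$n_main_diseases <- nrow(md)
    manifest$stages <- c(manifest$stages, "tpd")
  }

  # validation
  if (!is.null(config$cooccurrence)) {
    co <- read_cooccurrence_table(config$cooccurrence)
    tab <- merge(merge(ranked[, c("target", "ned")], cent, by = "target"),
                 co, by.x = "target", by.y = "target_id")
    val <- validate_scores(tab)
    jsonlite::write_json(val, file.path(out_dir, "validation.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    manifest$counts$n_validated <- nrow(tab)
    manifest$stages <- c(manifest$stages, "validate")
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
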