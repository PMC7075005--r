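#' Centrality baselines on the TPT network
#'
#' Degree centrality (raw incident-edge count) and unnormalized
#' shortest-path betweenness (Brandes semantics, fractional credit for
#' equal-length paths) on the unit-length TPT graph. These are the two
#' conventional node-importance scores the NED ranking is compared against;
#' since the comparison is rank-based, normalization is irrelevant and raw
#' values are reported.
#'
#' @param graph an undirected igraph.
#' @return `degree_centrality`: named numeric vector of degrees.
#' @export
degree_centrality <- function(graph) {
  igraph::degree(graph, loops = FALSE)
}

#' @rdname degree_centrality
#' @return `betweenness_centrality`: named numeric vector of unnormalized
#'   betweenness scores.
#' @export
betweenness_centrality <- function(graph) {
  igraph::betweenness(graph, directed = FALSE, weights = NA,
                      normalized = FALSE)
}

#' @rdname degree_centrality
#' @return `centrality_table`: data frame with `target`, `dc`, `bc`.
#' @export
centrality_table <- function(graph) {
  dc <- degree_centrality(graph)
  bc <- betweenness_centrality(graph)
  data.frame(target = names(dc), dc = as.numeric(dc),
             bc = as.numeric(bc[names(dc)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Spearman rank correlation with tie handling
#'
#' Correlation of mid-ranks: rho is the Pearson correlation of the
#' mid-ranked data, and the two-tailed p-value comes from the t
#' approximation with n - 2 degrees of freedom. Literature co-occurrence
#' counts are heavily tied (many zeros), so mid-ranks are essential. For
#' small samples an exact permutation p-value is available.
#'
#' @param x numeric score vector (length >= 3).
#' @param y numeric count vector, same length; ties and zeros allowed.
#' @param exact if `TRUE` and `length(x) <= 10`, compute the p-value by full
#'   enumeration of permutations of `y` (two-tailed on |rho|).
#' @return A list with `rho`, `p`, `n`, `method`, and `degenerate` (`TRUE`
#'   with `rho = NA` when either vector is constant, rather than an error).
#' @export
spearman_test <- function(x, y, exact = FALSE) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n,
                method = "degenerate", degenerate = TRUE))
  }
  rho <- stats::cor(rx, ry)
  if (exact && n <= 10) {
    perms <- permutations_of(n)
    obs <- abs(rho)
    null_rho <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(null_rho) >= obs - 1e-12)
    return(list(rho = rho, p = p, n = n, method = "exact-permutation",
                degenerate = FALSE))
  }
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, method = "t-approximation",
       degenerate = FALSE)
}

# all permutations of 1..n, one per row (n <= 10 guarded by the caller)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                 sub[, seq(pos, n - 1, length.out = n - pos),
                     drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Validate scores against literature co-occurrence counts
#'
#' Runs [spearman_test()] for each topological score (NED, DC, BC) against
#' both co-occurrence corpora (full text and abstract), reproducing the
#' validation design in which a good importance score should correlate with
#' how often a target is co-mentioned with the formula in the literature.
#'
#' @param table data frame with columns `target`, `ned`, `dc`, `bc`,
#'   `fulltext_count`, `abstract_count` and at least 3 rows.
#' @param exact passed to [spearman_test()].
#' @return Data frame with columns `score`, `corpus`, `rho`, `p`, `n`,
#'   `degenerate` (six rows).
#' @export
validate_scores <- function(table, exact = FALSE) {
  need <- c("target", "ned", "dc", "bc", "fulltext_count", "abstract_count")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("validation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(table) < 3) {
    stop("need at least 3 targets to run the correlation test",
         call. = FALSE)
  }
  grid <- expand.grid(score = c("ned", "dc", "bc"),
                      corpus = c("fulltext", "abstract"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- grid$score[i]
    cp <- paste0(grid$corpus[i], "_count")
    st <- spearman_test(table[[sc]], table[[cp]], exact = exact)
    data.frame(score = sc, corpus = grid$corpus[i], rho = st$rho,
               p = st$p, n = st$n, degenerate = st$degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
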