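# Independent oracles: deliberately naive implementations that share no code
# with the package (Floyd-Warshall instead of Dijkstra, explicit pair loops
# instead of joins, the textbook BH step-up formula instead of p.adjust).

# all-pairs shortest paths by Floyd-Warshall over an explicit edge list
fw_network_efficiency <- function(nodes, edges, lengths) {
  n <- length(nodes)
  if (n < 2) return(0)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1]; v <- edges[i, 2]
    d[u, v] <- d[v, u] <- min(d[u, v], lengths[i])
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  sum(1 / d[upper.tri(d)])
}

# brute-force one-mode projection: loop over every target pair
brute_projection <- function(map) {
  tg <- map_targets(map)
  out <- list()
  if (length(tg) >= 2) {
    for (i in seq_len(length(tg) - 1)) for (j in seq(i + 1, length(tg))) {
      shared <- intersect(pathways_of(map, tg[i]), pathways_of(map, tg[j]))
      if (length(shared)) {
        out[[paste(tg[i], tg[j])]] <- sort(shared)
      }
    }
  }
  out
}

# edge key/pathway-set normal form of a projected graph, for comparisons
projection_sets <- function(graph) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  if (nrow(el) == 0) return(list())
  a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
  sets <- lapply(igraph::E(graph)$pathways, sort)
  names(sets) <- paste(a, b)
  sets[order(names(sets))]
}

# full NED recomputation for one knockout, from the membership lists alone
brute_ned <- function(map, target) {
  sizes <- pathway_sizes(map)
  edges_list <- brute_projection(map)
  nodes <- map_targets(map)
  if (length(edges_list) == 0) return(0)
  el <- do.call(rbind, strsplit(names(edges_list), " ", fixed = TRUE))
  unit <- rep(1, nrow(el))
  affected <- pathways_of(map, target)
  lens <- vapply(edges_list, function(ps) {
    hit <- intersect(ps, affected)
    if (!length(hit)) 1 else prod(sizes[hit] / (sizes[hit] - 1))
  }, numeric(1))
  fw_network_efficiency(nodes, el, unit) -
    fw_network_efficiency(nodes, el, lens)
}

# textbook BH step-up: q_(i) = min_{j >= i} m p_(j) / j, capped at 1
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  run <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, run)
  q
}

# Pearson correlation of mid-ranks, written out longhand
midrank_pearson <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# upper-tail hypergeometric by direct enumeration of the overlap pmf
enum_hyper_upper <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
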