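test_that("pathway efficacy follows the equal-share rule", {
  expect_identical(pathway_efficacy(3, TRUE), 2 / 3)
  expect_identical(pathway_efficacy(2, TRUE), 1 / 2)
  expect_identical(pathway_efficacy(17, FALSE), 1)
  expect_equal(pathway_efficacy(c(3, 2, 5), c(TRUE, TRUE, FALSE)),
               c(2 / 3, 1 / 2, 1))
  expect_equal(pathway_efficacy(c(3, 2), TRUE), c(2 / 3, 1 / 2))
  expect_error(pathway_efficacy(0, TRUE), "positive")
  expect_equal(efficacy_percent(c(2 / 3, 1 / 2)), c(67L, 50L))
})

test_that("edge efficacy multiplies affected pathway efficacies", {
  both <- edge_efficacy(c(3, 3), c(TRUE, TRUE))
  expect_equal(both$ee, 4 / 9)
  expect_equal(both$length, 2.25)
  expect_equal(both$n_affected, 2L)
  one <- edge_efficacy(2, TRUE)
  expect_equal(one$ee, 1 / 2)
  expect_equal(one$length, 2)
  none <- edge_efficacy(2, FALSE)
  expect_identical(none$ee, 1)
  expect_identical(none$length, 1)
  expect_error(edge_efficacy(1, TRUE), ">= 2")
})

test_that("edge lengths are the correctly rounded rationals", {
  # single-pathway edge: L is bit-equal to the rational N/(N-1)
  for (N in 2:50) {
    expect_identical(edge_efficacy(N, TRUE)$length, N / (N - 1))
  }
  # at the fixture sizes the literal product identity also holds exactly
  expect_identical(edge_efficacy(2, TRUE)$length * (2 - 1) / 2, 1)
  expect_identical(edge_efficacy(3, TRUE)$length * (3 - 1) / 3, 1)
  # multi-pathway edges: products formed over integers first
  expect_identical(edge_efficacy(c(3, 3), c(TRUE, TRUE))$length, 9 / 4)
})

test_that("baseline network efficiency of the worked example is 83/6", {
  g <- tpt_project(sample_network())
  expect_equal(network_efficiency(g), 83 / 6, tolerance = 1e-12)
  # two nodes joined by one edge of length 2
  g2 <- igraph::make_graph(~ a - b)
  expect_equal(network_efficiency(g2, lengths = 2), 0.5)
  expect_equal(network_efficiency(igraph::make_empty_graph(0)), 0)
})

test_that("knocking out target C reproduces the printed edge lengths", {
  map <- sample_network()
  g <- tpt_project(map)
  k <- knockout(g, map, "C")
  expect_equal(unname(k$pathway_efficacies[c("a", "b", "c", "d", "e", "f")]),
               c(2 / 3, 2 / 3, 1, 1 / 2, 1 / 2, 1))
  lens <- with(k$edge_states, setNames(length, paste(from, to)))
  expect_identical(lens[["A B"]], 1.5)
  expect_identical(lens[["A C"]], 1.5)
  expect_identical(lens[["B C"]], 2.25)
  expect_identical(lens[["B E"]], 1.5)
  expect_identical(lens[["C D"]], 2)
  expect_identical(lens[["C E"]], 1.5)
  expect_identical(lens[["C F"]], 2)
  expect_identical(lens[["F G"]], 1)
  # the knocked node stays in the graph
  expect_equal(igraph::vcount(g), 7)
  # efficiency of the perturbed network, from the normative length matrix
  expect_equal(k$ne, 8.4761437908, tolerance = 1e-8)
  expect_equal(k$ned, 83 / 6 - 8.4761437908, tolerance = 1e-8)
})

test_that("a knockout that only stretches one leaf edge loses exactly 1", {
  map <- sample_network()
  g <- tpt_project(map)
  # G is only in pathway f = {F, G}: the single FG edge doubles in length
  expect_equal(knockout(g, map, "G")$ned, 1, tolerance = 1e-12)
  expect_error(knockout(g, map, "Q"), "unknown target")
})

test_that("a target with no shared pathway has NED exactly 0", {
  map <- bipartite_map(c("A", "B", "Z"), c("p", "p", "solo"))
  g <- tpt_project(map)
  expect_identical(knockout(g, map, "Z")$ned, 0)
})

test_that("ranking is NED-descending with deterministic tie-breaks", {
  map <- sample_network()
  ranked <- ned_rank(tpt_project(map), map)
  expect_equal(ranked$target, c("C", "B", "F", "E", "A", "D", "G"))
  expect_equal(ranked$rank, 1:7)
  expect_equal(attr(ranked, "ne_baseline"), 83 / 6, tolerance = 1e-12)
  # single clique from one pathway: full symmetry, alphabetical order
  clique <- bipartite_map(c("z", "y", "x", "w"), rep("p", 4))
  r2 <- ned_rank(tpt_project(clique), clique)
  expect_equal(length(unique(round(r2$ned, 12))), 1)
  expect_equal(r2$target, c("w", "x", "y", "z"))
})

test_that("ranking equals an independent full recomputation", {
  map <- random_bipartite(20, 6, 0.25, seed = 91)
  g <- tpt_project(map)
  ranked <- ned_rank(g, map)
  oracle <- vapply(ranked$target, function(tg) brute_ned(map, tg),
                   numeric(1))
  expect_equal(ranked$ned, unname(oracle), tolerance = 1e-9)
  expect_false(is.unsorted(rev(ranked$ned)))
})

test_that("network efficiency matches a Floyd-Warshall oracle", {
  for (seed in 1:12) {
    set.seed(300 + seed)
    n <- sample(4:12, 1)
    map <- random_bipartite(n, 4, 0.45, seed = seed)
    g <- tpt_project(map)
    el <- igraph::as_edgelist(g, names = TRUE)
    set.seed(400 + seed)
    lens <- 1 + runif(nrow(el), 0, 2)
    expect_equal(network_efficiency(g, lengths = lens),
                 fw_network_efficiency(igraph::V(g)$name, el, lens),
                 tolerance = 1e-9)
  }
})

test_that("NED is label-invariant", {
  map <- random_bipartite(10, 4, 0.4, seed = 17)
  relabel <- setNames(sprintf("G%02d", 10:1), sort(map_targets(map)))
  map2 <- bipartite_map(unname(relabel[map$pairs$target]),
                        map$pairs$pathway)
  r1 <- ned_rank(tpt_project(map), map)
  r2 <- ned_rank(tpt_project(map2), map2)
  expect_equal(setNames(r2$ned, r2$target)[unname(relabel[r1$target])],
               setNames(r1$ned, unname(relabel[r1$target])),
               tolerance = 1e-12)
})

test_that("top_fraction takes the ceiling of the requested share", {
  ranked279 <- data.frame(target = sprintf("T%03d", 1:279),
                          ned = rev(seq_len(279)), rank = 1:279)
  expect_equal(nrow(top_fraction(ranked279, 0.10)), 28)
  expect_equal(nrow(top_fraction(ranked279[1:10, ], 0.10)), 1)
  expect_equal(nrow(top_fraction(ranked279[1:7, ], 1.0)), 7)
  expect_equal(nrow(top_fraction(ranked279[0, ], 0.10)), 0)
  expect_error(top_fraction(ranked279, 0), "fraction")
  expect_error(top_fraction(ranked279, 1.5), "fraction")
})
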