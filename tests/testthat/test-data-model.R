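test_that("compound reader merges duplicate identifiers across herbs", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("compound_id,name,herb,rotatable_bonds,tpsa",
               "CID1,quercetin,herbA,5,131.4",
               "CID2,ferulic acid,herbA,3,66.8",
               "CID1,quercetin,herbB,5,131.4"), f)
  rec <- read_compound_table(f)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$herbs[[which(rec$compound_id == "CID1")]],
               c("herbA", "herbB"))
  expect_equal(rec$rotatable_bonds, c(5, 3))
})

test_that("compound reader handles header-only files and bad values", {
  f <- tempfile(fileext = ".csv")
  writeLines("compound_id,name,herb,rotatable_bonds,tpsa", f)
  expect_equal(nrow(read_compound_table(f)), 0)

  writeLines(c("compound_id,rotatable_bonds,tpsa",
               "CID1,5,100", "CID2,4,n/a"), f)
  expect_error(read_compound_table(f), "row 2")
  expect_error(read_compound_table(f), "tpsa")

  writeLines(c("compound_id,rotatable_bonds", "CID1,5"), f)
  expect_error(read_compound_table(f), "tpsa")
})

test_that("bipartite reader builds consistent lookups and collapses dups", {
  f <- tempfile(fileext = ".tsv")
  map0 <- sample_network()
  write_tsv(data.frame(target_id = map0$pairs$target,
                       pathway_id = map0$pairs$pathway), f)
  map <- read_bipartite_table(f)
  expect_length(map_pathways(map), 6)
  expect_length(map_targets(map), 7)
  expect_equal(nrow(map$pairs), 14)
  expect_equal(members_of(map, "a"), c("A", "B", "C"))
  expect_equal(pathways_of(map, "C"), c("a", "b", "d", "e"))

  # duplicated pair collapses; reading a doubled file equals reading once
  writeLines(c("target_id\tpathway_id", "X\tp1", "X\tp1", "Y\tp1"), f)
  map2 <- read_bipartite_table(f)
  expect_equal(nrow(map2$pairs), 2)
  doubled <- bipartite_map(rep(map0$pairs$target, 2),
                           rep(map0$pairs$pathway, 2))
  expect_identical(doubled, map0)

  writeLines("target_id\tpathway_id", f)
  expect_equal(nrow(read_bipartite_table(f)$pairs), 0)

  expect_error(read_bipartite_table(write_tsv(
    data.frame(target = "X", pathway = "p"), f)), "target_id")
})

test_that("conflicting pathway names keep the first with a warning", {
  expect_warning(
    m <- bipartite_map(c("X", "Y"), c("p1", "p1"),
                       pathway_names = c(p1 = "first", p1 = "second")),
    "conflicting")
  expect_equal(unname(m$pathway_names["p1"]), "first")
})

test_that("graph write/read round-trips both formats exactly", {
  g <- tpt_project(sample_network())
  for (fmt in c("graphml", "edgelist")) {
    path <- tempfile()
    write_graph_file(g, path, fmt)
    g2 <- read_graph_file(path, fmt)
    expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
    expect_identical(projection_sets(g2), projection_sets(g))
  }
  # edge list has one row per edge plus a header
  path <- tempfile()
  write_graph_file(g, path, "edgelist")
  expect_length(readLines(path), 8 + 1)
})

test_that("round-trip preserves isolated nodes and random seeded graphs", {
  map <- random_bipartite(12, 5, 0.3, seed = 11)
  # add an isolated target via a singleton pathway
  map <- bipartite_map(c(map$pairs$target, "ZZZ"),
                       c(map$pairs$pathway, "Psolo"))
  g <- tpt_project(map)
  expect_true("ZZZ" %in% igraph::V(g)$name)
  for (fmt in c("graphml", "edgelist")) {
    path <- tempfile()
    write_graph_file(g, path, fmt)
    g2 <- read_graph_file(path, fmt)
    expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
    expect_identical(projection_sets(g2), projection_sets(g))
  }
})

test_that("empty graph writes a valid header-only edge list", {
  g <- tpt_project(bipartite_map())
  path <- tempfile()
  write_graph_file(g, path, "edgelist")
  expect_length(readLines(path), 1)
})

test_that("pathway-disease and co-occurrence readers validate input", {
  f <- tempfile(fileext = ".tsv")
  write_tsv(data.frame(pathway_id = c("p1", "p1"),
                       icd11_class_code = c("02", "02"),
                       icd11_class_name = c("neoplasms", "neoplasms")), f)
  expect_equal(nrow(read_pathway_disease_table(f)), 1)

  write_tsv(data.frame(target_id = "AKT1", fulltext_count = 12,
                       abstract_count = 3), f)
  co <- read_cooccurrence_table(f)
  expect_equal(co$fulltext_count, 12)
  write_tsv(data.frame(target_id = "AKT1", fulltext_count = -1,
                       abstract_count = 3), f)
  expect_error(read_cooccurrence_table(f), "non-negative")
})
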