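test_that("parse_newick validates, reports malformed input, and round-trips", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(unname(depths), c(2, 2, 2))

  degen <- parse_newick("(A:0,B:0);")
  expect_equal(sort(degen$edge.length), c(0, 0))

  expect_error(parse_newick("((A:1,B:1):1,C:2"), "unclosed|position")
  expect_error(parse_newick("((A:1,B:1)):1,C:2);"), "position|malformed")
  expect_error(parse_newick("((A:1,B:-1):1,C:2);"), "negative")
  expect_error(parse_newick("((A:1,A:1):1,C:2);"), "duplicated")

  set.seed(42)
  for (i in 1:5) {
    tr0 <- ape::rtree(sample(4:20, 1))
    txt <- write_newick(tr0)
    tr1 <- parse_newick(txt)
    expect_true(ape::all.equal.phylo(tr0, tr1, use.edge.length = TRUE,
                                     tolerance = 1e-9))
    d0 <- ape::cophenetic.phylo(tr0)
    d1 <- ape::cophenetic.phylo(tr1)[tr0$tip.label, tr0$tip.label]
    expect_lt(max(abs(d0 - d1)), 1e-9)
  }
})

test_that("load_tree_sample downsamples reproducibly from NEXUS and newick files", {
  set.seed(7)
  trees <- lapply(1:12, function(i) {
    tr <- ape::rtree(6)
    tr$tip.label <- paste0("t", 1:6)
    tr
  })
  class(trees) <- "multiPhylo"

  nwk <- tempfile(fileext = ".nwk")
  writeLines(vapply(trees, write_newick, ""), nwk)
  ts1 <- load_tree_sample(nwk, n = 5, seed = 3)
  ts2 <- load_tree_sample(nwk, n = 5, seed = 3)
  expect_equal(ts1$indices, ts2$indices)
  expect_equal(ts1$sample_size, 5)
  expect_equal(ts1$source_size, 12)
  expect_equal(length(unique(ts1$indices)), 5)

  nex <- tempfile(fileext = ".nex")
  ape::write.nexus(trees, file = nex)
  ts3 <- load_tree_sample(nex, n = 12, seed = 1)
  expect_equal(ts3$sample_size, 12)

  expect_error(load_tree_sample(nwk, n = 50, seed = 1), "only 12 available")
})

test_that("phylo_covariance matches worked examples and the path-walk oracle", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  C <- phylo_covariance(tr)
  expect_equal(unname(diag(C)), c(2, 2, 2))
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0)

  star <- parse_newick("(A:1,B:1,C:1);")
  expect_equal(unname(phylo_covariance(star)), diag(3))

  expect_error(phylo_covariance(tr, c("A", "Z")), "Z")

  set.seed(11)
  for (i in 1:4) {
    tr <- ape::rtree(20)
    taxa <- sample(tr$tip.label, 8)
    expect_lt(max(abs(phylo_covariance(tr, taxa) -
                        path_walk_covariance(tr, taxa))), 1e-10)
  }
})

test_that("subsetting the covariance equals the submatrix and ultrametric diagonals are flat", {
  set.seed(5)
  for (i in 1:3) {
    tr <- simulate_tree(25, seed = i)
    Cfull <- phylo_covariance(tr)
    taxa <- sample(tr$tip.label, 10)
    expect_equal(phylo_covariance(tr, taxa), Cfull[taxa, taxa])
    expect_lt(diff(range(diag(Cfull))), 1e-8)  # ultrametric: height everywhere
  }
})

test_that("metadata reader enforces bounds and duplicates", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("taxon,longitude,latitude,macroarea,family",
               "abcd1234,10.0,50.0,Eurasia,FamA",
               "efgh5678,-120.5,-10.0,SouthAmerica,FamB"), f)
  md <- read_language_metadata(f)
  expect_equal(nrow(md), 2)
  expect_equal(md$latitude[1], 50)

  writeLines(c("taxon,longitude,latitude,macroarea,family",
               "abcd1234,10.0,95.0,Eurasia,FamA"), f)
  expect_error(read_language_metadata(f), "latitude")

  writeLines(c("taxon,longitude,latitude,macroarea,family",
               "abcd1234,10,50,Eurasia,FamA",
               "abcd1234,11,51,Eurasia,FamA"), f)
  expect_error(read_language_metadata(f), "duplicate")

  writeLines("taxon,longitude,latitude,macroarea,family", f)
  expect_warning(md0 <- read_language_metadata(f), "no rows")
  expect_equal(nrow(md0), 0)
})

test_that("trait matrix round-trips through CSV with missing entries", {
  m <- matrix(c(1L, 0L, NA, 1L, 0L, 0L), 3, 2,
              dimnames = list(c("a1", "b2", "c3"), c("F1", "F2")))
  f <- tempfile(fileext = ".csv")
  write_trait_matrix(m, f)
  m2 <- read_trait_matrix(f)
  expect_equal(m2, m)
})
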