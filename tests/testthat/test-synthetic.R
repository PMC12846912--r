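test_that("pure-birth trees have the expected shape, determinism and height scaling", {
  expect_error(simulate_tree(1), ">= 2")
  cherry <- simulate_tree(2, seed = 1)
  expect_equal(length(cherry$tip.label), 2)

  t1 <- simulate_tree(80, seed = 7)
  t2 <- simulate_tree(80, seed = 7)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))

  # Yule expectation: height grows like log(n) / lambda
  set.seed(91)
  h_small <- replicate(60, max(ape::node.depth.edgelength(
    ape::rphylo(20, birth = 1, death = 0))))
  h_large <- replicate(60, max(ape::node.depth.edgelength(
    ape::rphylo(80, birth = 1, death = 0))))
  expect_gt(mean(h_large), mean(h_small))
  expect_lt(abs(mean(h_large) - mean(h_small) - log(80 / 20)), 0.6)
})

test_that("metadata simulation respects degenerate limits and spatial signal", {
  tr <- simulate_tree(60, seed = 3)
  md0 <- simulate_metadata(tr, diffusion = 0, seed = 4, root_location = c(12, 34))
  expect_true(all(md0$longitude == 12))
  expect_true(all(md0$latitude == 34))

  H <- max(ape::node.depth.edgelength(tr))
  md1 <- simulate_metadata(tr, family_depth = H * 2, seed = 5)
  expect_equal(length(unique(md1$family)), 1)

  expect_error(simulate_metadata(tr, m_areas = 100), "exceed")

  # phylogenetically close tips are spatially close on average
  cors <- vapply(1:8, function(s) {
    md <- simulate_metadata(tr, diffusion = 150, seed = s)
    pat <- ape::cophenetic.phylo(tr)[md$taxon, md$taxon]
    geo <- geosphere::distm(cbind(md$longitude, md$latitude))
    cor(pat[lower.tri(pat)], geo[lower.tri(geo)], method = "spearman")
  }, 0)
  expect_gt(mean(cors), 0)
  expect_gt(mean(cors > 0), 0.7)
})

test_that("family assignment respects the age threshold", {
  tr <- simulate_tree(100, seed = 11, height = 1)
  md <- simulate_metadata(tr, family_depth = 0.4, seed = 12)
  fams <- split(md$taxon, md$family)
  # every family is a clade: its MRCA is younger than the threshold
  depths <- ape::node.depth.edgelength(tr)
  H <- max(depths)
  for (f in fams) {
    if (length(f) > 1) {
      mrca <- ape::getMRCA(tr, f)
      expect_gt(depths[mrca], H - 0.4 - 1e-8)
    }
  }
  expect_gt(length(fams), 1)
})

test_that("scenario generation produces compile-ready data with MCAR missingness", {
  sc <- scenario(
    n_tips = 400, n_trees = 3, missingness = 0.3, seed = 21,
    universals = list(
      list(id = "g1", utype = "hierarchy",
           model = list(type = "glmm", b = 2, intercept = -1)),
      list(id = "c1", utype = "narrow_word_order",
           model = list(type = "ctmc_dependent",
                        rates = c(q12 = 1, q13 = 1, q21 = 1, q24 = 5, q31 = 1,
                                  q34 = 5, q42 = 0.2, q43 = 0.2), root = 1))))
  gen <- generate_scenario(sc)
  expect_equal(dim(gen$traits), c(400, 4))
  miss_rate <- mean(is.na(gen$traits))
  expect_lt(abs(miss_rate - 0.3), 3 * sqrt(0.3 * 0.7 / length(gen$traits)) + 0.01)
  expect_equal(gen$trees$sample_size, 3)
  expect_equal(nrow(gen$meta), 400)
  expect_named(gen$truth, c("g1", "c1"))

  comp <- compile_universal(gen$specs[[1]], gen$traits, min_n = 50)
  expect_true(comp$n >= 0.4 * 400)  # ~ (1 - 0.3)^2 of taxa survive
  expect_true(!anyNA(comp$x))
})

test_that("null GLMM traits are independent and dependent CTMC enriches state 4", {
  # b = 0, no random fields: x and y independent (chi-square calibration)
  pvals <- vapply(1:20, function(s) {
    tr <- simulate_tree(200, seed = 100 + s)
    md <- simulate_metadata(tr, seed = 200 + s)
    sim <- simulate_glmm_traits(tr, md, b = 0, seed = 300 + s)
    suppressWarnings(stats::chisq.test(table(sim$x, sim$y))$p.value)
  }, 0)
  expect_lt(mean(pvals < 0.05), 0.25)
  expect_gt(mean(pvals), 0.25)  # roughly uniform, not collapsed near 0

  # dependent model with harmonic bias: more state 4 than independent
  # expectation built from the same marginal gain/loss intensities
  tr <- simulate_tree(500, height = 1, seed = 31)
  dep <- c(q12 = 1, q13 = 1, q21 = 1, q24 = 5, q31 = 1, q34 = 5,
           q42 = 0.2, q43 = 0.2)
  st_dep <- simulate_evolution(tr, build_q(dep), 1L, seed = 32)
  st_ind <- simulate_evolution(
    tr, build_q(rate_model("independent",
                           c(alpha1 = 1, beta1 = 1, alpha2 = 1, beta2 = 1))),
    1L, seed = 32)
  expect_gt(mean(st_dep == 4), mean(st_ind == 4))
})

test_that("generated datasets pass cleanly through the package readers", {
  sc <- scenario(n_tips = 60, n_trees = 2, seed = 41,
                 universals = list(list(id = "u1", utype = "other",
                                        model = list(type = "glmm", b = 1))))
  gen <- generate_scenario(sc)
  td <- tempfile(); dir.create(td)
  write_trait_matrix(gen$traits, file.path(td, "traits.csv"))
  utils::write.csv(gen$meta, file.path(td, "meta.csv"), row.names = FALSE)
  writeLines(vapply(gen$trees$trees, write_newick, ""),
             file.path(td, "trees.nwk"))
  expect_silent(suppressMessages({
    traits2 <- read_trait_matrix(file.path(td, "traits.csv"))
    meta2 <- read_language_metadata(file.path(td, "meta.csv"))
    trees2 <- load_tree_sample(file.path(td, "trees.nwk"), n = 2, seed = 1)
  }))
  expect_equal(traits2, gen$traits)
  expect_equal(meta2$taxon, gen$meta$taxon)
})
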