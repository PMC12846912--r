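test_that("spatial covariance matches haversine closed forms and is PSD", {
  meta <- data.frame(taxon = c("a", "b", "c"),
                     longitude = c(10, 10, 100), latitude = c(0, 0, 45),
                     macroarea = "x", family = "f")
  K <- spatial_covariance(meta, length_scale_km = 1000)
  expect_equal(K["a", "b"], 1)  # identical coordinates
  expect_equal(unname(diag(K)), rep(1, 3))

  # antipodal on the equator with length scale = half Earth circumference
  half_circ <- pi * 6378137 / 1000  # haversine default radius, km
  meta2 <- data.frame(taxon = c("p", "q"), longitude = c(0, 180),
                      latitude = c(0, 0), macroarea = "x", family = "f")
  K2 <- spatial_covariance(meta2, length_scale_km = half_circ)
  expect_equal(K2["p", "q"], exp(-1), tolerance = 1e-6)

  set.seed(8)
  meta3 <- data.frame(taxon = paste0("t", 1:15),
                      longitude = runif(15, -180, 180),
                      latitude = runif(15, -60, 60),
                      macroarea = "x", family = "f")
  K3 <- spatial_covariance(meta3, 2000)
  expect_equal(K3, t(K3))
  expect_gt(min(eigen(K3, symmetric = TRUE, only.values = TRUE)$values), -1e-10)

  meta3$latitude[1] <- 99
  expect_error(spatial_covariance(meta3, 2000), "latitude")
})

test_that("glmm_spec enforces variant requirements and binary inputs", {
  y <- c(0, 1, 0, 1); x <- c(1, 1, 0, 0)
  expect_error(glmm_spec("naive", response = c(0, 1, 2, 1), fixed = x), "binary")
  expect_error(glmm_spec("naive", response = y, fixed = x[-1]), "equal length")
  expect_error(glmm_spec("spatiophylo", response = y, fixed = x), "requires")
  expect_error(glmm_spec("family_control", response = y, fixed = x), "family")
  expect_s3_class(glmm_spec("naive", response = y, fixed = x), "glmm_spec")
})

test_that("degenerate responses are rejected at fit time", {
  spec <- glmm_spec("naive", response = rep(1, 50), fixed = rbinom(50, 1, 0.5))
  expect_error(fit_binary_glmm(spec), "degenerate response")
})

test_that("the family filter drops exactly the taxa in small families", {
  set.seed(12)
  fam <- rep(c("f7", "f5", "f4", "f1"), times = c(7, 5, 4, 1))
  n <- length(fam)
  y <- rbinom(n, 1, 0.5); y[1:2] <- c(0, 1)
  x <- rbinom(n, 1, 0.5)
  spec <- glmm_spec("family_control", response = y, fixed = x,
                    taxa = paste0("t", 1:n), family = fam)
  fit <- fit_binary_glmm(spec, mcmc_config(iterations = 300, burn_in = 100,
                                           thin = 2, seed = 1))
  expect_equal(fit$dropped_taxa, 5)      # the 4-member and 1-member families
  expect_equal(fit$dropped_families, 2)
  expect_equal(fit$n, 12)
})

test_that("naive fits recover a known effect and are permutation-equivariant", {
  set.seed(21)
  x <- rbinom(800, 1, 0.5)
  y <- rbinom(800, 1, plogis(-1 + 2 * x))
  cfg <- mcmc_config(iterations = 1500, burn_in = 500, thin = 2, seed = 3)
  fit <- fit_binary_glmm(glmm_spec("naive", response = y, fixed = x), cfg)
  expect_gt(fit$b_median, 1.4)
  expect_lt(fit$b_median, 2.6)
  expect_gt(fit$ci_low, 0)

  perm <- sample(800)
  fit_p <- fit_binary_glmm(glmm_spec("naive", response = y[perm],
                                     fixed = x[perm]), cfg)
  # sufficient statistics unchanged, same seed: identical chain
  expect_identical(fit$samples, fit_p$samples)
})

test_that("spatiophylo with all variance components fixed at zero matches the naive fit", {
  set.seed(33)
  tr <- simulate_tree(150, height = 1, seed = 5)
  meta <- simulate_metadata(tr, seed = 6)
  x <- rbinom(150, 1, 0.5)
  y <- rbinom(150, 1, plogis(-0.5 + 1.5 * x))
  names(x) <- names(y) <- tr$tip.label
  Cp <- phylo_covariance(tr, standardize = TRUE)
  Cs <- spatial_covariance(meta)
  cfg <- mcmc_config(iterations = 2500, burn_in = 800, thin = 2, seed = 9)
  f_naive <- fit_binary_glmm(glmm_spec("naive", response = y, fixed = x), cfg)
  f_sp0 <- fit_binary_glmm(
    glmm_spec("spatiophylo", response = y, fixed = x, phylo_cov = Cp,
              spatial_cov = Cs, macroarea = meta$macroarea),
    cfg, sigma_fixed = c(sigma_p = 0, sigma_s = 0, sigma_area = 0))
  expect_lt(abs(f_naive$b_median - f_sp0$b_median), 0.2)
  expect_lt(abs(f_naive$ci_low - f_sp0$ci_low), 0.35)
  expect_lt(abs(f_naive$ci_high - f_sp0$ci_high), 0.35)
})

test_that("support rules implement the three-stage decision criteria", {
  mk <- function(lo, hi, med = (lo + hi) / 2) {
    structure(list(samples = NULL, variant = "naive", b_median = med,
                   ci_low = lo, ci_high = hi, n = 100, dropped_taxa = 0,
                   dropped_families = 0, cfg = NULL),
              class = "glmm_posterior")
  }
  # single naive posterior
  expect_true(support_from_posteriors(mk(0.5, 1.5))$supported)
  expect_false(support_from_posteriors(mk(-0.2, 0.3))$supported)
  expect_false(support_from_posteriors(mk(0, 0.8))$supported)  # boundary tie
  # per-tree rule: median of bounds on the same side of zero
  all_pos <- lapply(1:5, function(i) mk(0.5, 1.5))
  expect_true(support_from_posteriors(all_pos)$supported)
  mixed <- list(mk(-0.3, 0.7), mk(-0.1, 0.9), mk(0.2, 1.1))
  s <- support_from_posteriors(mixed)
  expect_equal(s$ci_low, -0.1)
  expect_false(s$supported)
  all_neg <- lapply(1:5, function(i) mk(-1.5, -0.5))
  expect_true(support_from_posteriors(all_neg)$supported)
  expect_error(support_from_posteriors(list()), "no posteriors")
})

test_that("spatiophylogenetic and family-control estimates agree in rank across a battery", {
  tr <- simulate_tree(200, height = 1, seed = 71)
  meta <- simulate_metadata(tr, family_depth = 0.5, seed = 72)
  Cp <- phylo_covariance(tr, standardize = TRUE)
  Cs <- spatial_covariance(meta)
  bs <- c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5)
  med_sp <- med_fc <- numeric(length(bs))
  for (i in seq_along(bs)) {
    sim <- simulate_glmm_traits(tr, meta, b = bs[i], intercept = -0.5,
                                seed = 73 + i)
    cfg <- mcmc_config(iterations = 1000, burn_in = 400, thin = 2,
                       seed = 90 + i)
    med_sp[i] <- fit_binary_glmm(
      glmm_spec("spatiophylo", response = sim$x, fixed = sim$y,
                phylo_cov = Cp, spatial_cov = Cs,
                macroarea = meta$macroarea), cfg)$b_median
    med_fc[i] <- fit_binary_glmm(
      glmm_spec("family_control", response = sim$x, fixed = sim$y,
                family = meta$family), cfg)$b_median
  }
  expect_gt(compare_estimates(med_sp, med_fc)$spearman_r, 0.5)
})
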