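test_that("mcmc_config and prior_spec validate their fields", {
  expect_error(mcmc_config(iterations = 100, burn_in = 100), "burn_in")
  expect_error(mcmc_config(iterations = 100, burn_in = 10, thin = 0), "thin")
  expect_s3_class(mcmc_config(1000, 100, 10), "mcmc_config")
  expect_error(prior_spec(mean_max = 0), ">")
})

test_that("posterior sampling is deterministic under a fixed seed and cycles trees", {
  tr <- simulate_tree(40, height = 1, seed = 1)
  trees <- jitter_tree_sample(tr, 3, seed = 2)
  Q <- build_q(rate_model("independent",
                          c(alpha1 = 1, beta1 = 1, alpha2 = 1, beta2 = 1)))
  dat <- make_ctmc_dataset(tr, Q, 1L, seed = 3)
  cfg <- mcmc_config(iterations = 1500, burn_in = 300, thin = 10,
                     trees_per_block = 200, seed = 42)
  t1 <- sample_posterior("independent", dat, trees, cfg = cfg)
  t2 <- sample_posterior("independent", dat, trees, cfg = cfg)
  expect_identical(t1$rates, t2$rates)
  expect_identical(t1$loglik, t2$loglik)
  expect_equal(sort(unique(t1$tree_index)), 1:3)  # visited every tree
  expect_true(all(t1$rates > 0))
  expect_equal(nrow(t1$rates), (1500 - 300) %/% 10)
  diag_df <- trace_diagnostics(t1)
  expect_equal(nrow(diag_df), 4)
  expect_true(all(is.finite(diag_df$ess)))
})

test_that("hdi matches the brute-force shortest-window oracle", {
  expect_equal(unname(hdi(1:100)), c(1, 95))  # earliest of the tied windows
  expect_equal(unname(hdi(rep(3.5, 20))), c(3.5, 3.5))
  expect_error(hdi(1:5), "at least")

  set.seed(31)
  for (i in 1:20) {
    x <- switch(1 + i %% 3,
                rnorm(50),
                c(rnorm(40), rnorm(15, 8)),   # bimodal, heavier first mode
                rexp(30))
    expect_equal(unname(hdi(x, 0.9)), brute_hdi(x, 0.9))
  }
  # bimodal: interval anchors on the heavier mode
  x <- c(rnorm(80, 0, 0.5), rnorm(20, 50, 0.5))
  h <- hdi(x)
  expect_lt(h["low"], 5)
})

test_that("log Bayes factors follow the sign convention", {
  expect_equal(log_bayes_factor(-100, -110), 10)
  expect_equal(log_bayes_factor(-5, -5), 0)
  expect_equal(log_bayes_factor(-110, -100), -10)
  expect_error(log_bayes_factor(-Inf, 0), "finite")
})

test_that("stepping stone recovers conjugate and flat-likelihood marginals", {
  logprior <- function(u) plogis(u, log.p = TRUE) + plogis(-u, log.p = TRUE)
  # likelihood identically 1: logZ must be 0 whatever the ladder
  for (K in c(2, 5, 12)) {
    z <- stepping_stone(function(u) 0, logprior, init = 0.3, n_stones = K,
                        iters_per_stone = 50, seed = K)$logZ
    expect_lt(abs(z), 1e-6)
  }
  # Bernoulli toy: Beta(1,1) prior, 7/10 successes
  loglik <- function(u) {
    th <- plogis(u)
    7 * log(th) + 3 * log(1 - th)
  }
  exact <- lbeta(8, 4) - lbeta(1, 1)
  for (s in 1:3) {
    z <- stepping_stone(loglik, logprior, init = 0, n_stones = 10,
                        iters_per_stone = 2000, seed = s)$logZ
    expect_lt(abs(z - exact), 0.05)
  }
  expect_error(stepping_stone(loglik, logprior, 0, n_stones = 1), "n_stones")
})

test_that("the rate-model marginal likelihood is 0 for fully missing data", {
  tr <- simulate_tree(20, height = 1, seed = 4)
  dat <- list(taxa = tr$tip.label,
              x = setNames(rep(NA_integer_, 20), tr$tip.label),
              y = setNames(rep(NA_integer_, 20), tr$tip.label))
  z <- stepping_stone_logZ("independent", dat, tr,
                           ss_cfg = list(n_stones = 4, iters_per_stone = 100),
                           seed = 2)
  expect_lt(abs(z), 1e-8)
})

test_that("the BF support rule uses a strict HDI threshold", {
  high <- c(12, 14, 13, 15, 16, 12.5, 13.5, 14.5, 15.5, 12.2)
  expect_true(bf_support_rule(high)$supported)
  low <- high - 10
  expect_false(bf_support_rule(low)$supported)
  # boundary: lower bound exactly at the threshold is not support
  at <- rep(10, 12)
  expect_false(bf_support_rule(at)$supported)
})

test_that("stepping-stone logZ is stable across seeds on a 100-tip dataset", {
  tr <- simulate_tree(100, height = 1, seed = 55)
  Qi <- build_q(rate_model("independent",
                           c(alpha1 = 1, beta1 = 1, alpha2 = 1, beta2 = 1)))
  dat <- make_ctmc_dataset(tr, Qi, 1L, seed = 56)
  zs <- vapply(1:4, function(s) {
    stepping_stone_logZ("independent", dat, tr,
                        ss_cfg = list(n_stones = 10, iters_per_stone = 500),
                        seed = 60 + s)
  }, 0)
  expect_lt(sd(zs), 0.5)
})
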