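test_that("build_q lays out rates with forbidden dual transitions at zero", {
  Q <- build_q(rate_model("dependent", setNames(rep(1, 8), dep_names)))
  expect_equal(unname(rowSums(Q)), rep(0, 4))
  offdiag <- Q; diag(offdiag) <- 0
  expect_equal(unname(rowSums(offdiag > 0)), rep(2, 4))
  expect_equal(Q[1, 4], 0); expect_equal(Q[4, 1], 0)
  expect_equal(Q[2, 3], 0); expect_equal(Q[3, 2], 0)

  Qi <- build_q(rate_model("independent",
                           c(alpha1 = 1, beta1 = 2, alpha2 = 3, beta2 = 4)))
  expect_equal(Qi[1, 3], 1); expect_equal(Qi[2, 4], 1)
  expect_equal(Qi[3, 1], 2); expect_equal(Qi[4, 2], 2)
  expect_equal(Qi[1, 2], 3); expect_equal(Qi[3, 4], 3)
  expect_equal(Qi[2, 1], 4); expect_equal(Qi[4, 3], 4)

  bad <- setNames(rep(1, 8), dep_names); bad["q34"] <- 0
  expect_error(rate_model("dependent", bad), "positive")
})

test_that("transition_matrix is stochastic and matches a Taylor-series oracle", {
  Q <- build_q(rate_model("dependent", setNames(rep(1, 8), dep_names)))
  expect_equal(transition_matrix(Q, 0), diag(4), ignore_attr = TRUE)
  P_inf <- transition_matrix(Q, 500)
  expect_lt(max(abs(P_inf - 0.25)), 1e-8)  # uniform stationary by symmetry
  expect_error(transition_matrix(Q, -1), "non-negative")

  set.seed(3)
  for (i in 1:5) {
    Q <- build_q(random_dep_rates())
    P <- transition_matrix(Q, 0.7)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_lt(max(abs(P - taylor_expm(Q, 0.7))), 1e-8)
  }
})

test_that("pruning log-likelihood reproduces closed-form tiny cases", {
  Q <- build_q(random_dep_rates())
  # zero-length cherry, both tips in state 4, uniform root: log(1/4)
  tr <- parse_newick("(A:0,B:0);")
  tp <- tip_partials(c(A = 1, B = 1), c(A = 1, B = 1))
  expect_equal(pruning_loglik(tr, tp, Q), log(0.25))
  # fully missing single tip: total probability 1
  one <- ape::read.tree(text = "(A:1);")
  tp1 <- tip_partials(c(A = NA), c(A = NA))
  expect_equal(pruning_loglik(one, tp1, Q, "uniform"), 0)
})

test_that("the C++ pruning pass equals exhaustive enumeration (with missing data)", {
  set.seed(19)
  for (i in 1:10) {
    n <- sample(3:5, 1)
    tr <- ape::rtree(n)
    Q <- build_q(random_dep_rates())
    x <- sample(0:1, n, TRUE)
    y <- sample(0:1, n, TRUE)
    if (i %% 2 == 0) y[sample(n, 1)] <- NA
    tp <- tip_partials(setNames(x, tr$tip.label), setNames(y, tr$tip.label))
    a <- pruning_loglik(tr, tp, Q)
    b <- enum_loglik(tr, tp, Q)
    expect_lt(abs(a - b) / abs(b), 1e-10)
  }
})

test_that("independent model nests exactly in the dependent parameterization", {
  set.seed(23)
  tr <- ape::rtree(40)
  x <- sample(0:1, 40, TRUE)
  y <- sample(0:1, 40, TRUE)
  tp <- tip_partials(setNames(x, tr$tip.label), setNames(y, tr$tip.label))
  for (i in 1:5) {
    m_ind <- rate_model("independent",
                        setNames(rexp(4) + 0.1,
                                 c("alpha1", "beta1", "alpha2", "beta2")))
    Qi <- build_q(m_ind)
    Qd <- build_q(as_dependent_rates(m_ind))
    expect_identical(Qi, Qd)
    expect_equal(pruning_loglik(tr, tp, Qi), pruning_loglik(tr, tp, Qd),
                 tolerance = 1e-14)
  }
})

test_that("likelihood is invariant to tip ordering and decomposes on a star tree", {
  set.seed(29)
  star <- ape::read.tree(text = "(A:0.4,B:0.9,C:0.2,D:0.5,E:0.7);")
  Q <- build_q(random_dep_rates())
  x <- c(A = 1, B = 0, C = 1, D = 0, E = 1)
  y <- c(A = 1, B = 1, C = 0, D = 0, E = 1)
  tp <- tip_partials(x, y)
  ll <- pruning_loglik(star, tp, Q)
  # independent per-tip terms, summed over the uniform root state
  per_root <- vapply(1:4, function(s) {
    sum(log(vapply(seq_along(x), function(i) {
      P <- transition_matrix(Q, star$edge.length[i])
      sum(P[s, ] * tp[star$tip.label[i], ])
    }, 0)))
  }, 0)
  direct <- log(mean(exp(per_root)))
  expect_equal(ll, direct, tolerance = 1e-10)

  perm <- sample(5)
  tp2 <- tp[perm, , drop = FALSE]
  expect_equal(pruning_loglik(star, tp2, Q), ll, tolerance = 1e-12)
})

test_that("simulation is seed-deterministic and matches transition probabilities", {
  Q <- build_q(rate_model("dependent", setNames(rep(1, 8), dep_names)))
  tr <- simulate_tree(50, seed = 2)
  s1 <- simulate_evolution(tr, Q, 1L, seed = 9)
  s2 <- simulate_evolution(tr, Q, 1L, seed = 9)
  expect_identical(s1, s2)

  # near-zero rates: tips stay at the root state
  Qeps <- build_q(rate_model("dependent", setNames(rep(1e-12, 8), dep_names)))
  s0 <- simulate_evolution(tr, Qeps, 3L, seed = 1)
  expect_true(all(s0 == 3L))

  # many independent branches of length t: frequencies match exp(Qt) row
  t_len <- 0.6
  star <- ape::read.tree(text = paste0(
    "(", paste(sprintf("t%d:%g", 1:2000, t_len), collapse = ","), ");"))
  st <- simulate_evolution(star, Q, 1L, seed = 4)
  freq <- tabulate(st, 4) / 2000
  expected <- transition_matrix(Q, t_len)[1, ]
  expect_lt(max(abs(freq - expected)), 4 * sqrt(0.25 / 2000) + 0.01)
})

test_that("harmonic-biased rates inflate state-4 occupancy relative to symmetric rates", {
  tr <- simulate_tree(400, height = 1, seed = 6)
  biased <- setNames(c(1, 1, 1, 5, 1, 5, 0.2, 0.2), dep_names)
  sym <- setNames(rep(1, 8), dep_names)
  s_b <- simulate_evolution(tr, build_q(biased), 1L, seed = 7)
  s_s <- simulate_evolution(tr, build_q(sym), 1L, seed = 7)
  expect_gt(mean(s_b == 4), mean(s_s == 4))
})
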