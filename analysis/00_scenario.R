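# Shared study design for the analysis workflow: a synthetic battery of
# implicational universals with known generating truth, emulating the shape
# of a Grambank-style dataset (binary features, missing entries, posterior
# tree sample, geography, families). Sourced by the numbered drivers.

library(glottocoevo)

MASTER_SEED <- 20260925L
RESULTS_DIR <- "results"

battery_scenario <- function(seed = MASTER_SEED) {
  dep_rates <- c(q12 = 1, q13 = 1, q21 = 1, q24 = 5, q31 = 1, q34 = 5,
                 q42 = 0.2, q43 = 0.2)
  ind_rates <- c(alpha1 = 1, beta1 = 1, alpha2 = 1, beta2 = 1)
  scenario(
    n_tips = 300, n_trees = 5, missingness = 0.1, seed = seed,
    universals = list(
      # hierarchy: strong regression-style signal
      list(id = "hier1", utype = "hierarchy",
           model = list(type = "glmm", b = 2.5, intercept = -1)),
      list(id = "hier2", utype = "hierarchy",
           model = list(type = "glmm", b = 2, intercept = -0.5)),
      # narrow word order: genuine co-evolution toward the harmonic state
      list(id = "nwo1", utype = "narrow_word_order",
           model = list(type = "ctmc_dependent", rates = dep_rates, root = 1)),
      list(id = "nwo2", utype = "narrow_word_order",
           model = list(type = "ctmc_dependent", rates = dep_rates, root = 1)),
      # broad word order: no association at all
      list(id = "broad1", utype = "broad_word_order",
           model = list(type = "glmm", b = 0, intercept = 0)),
      list(id = "broad2", utype = "broad_word_order",
           model = list(type = "ctmc_independent", rates = ind_rates,
                        root = 1)),
      # other: one real effect, one phylogenetically confounded null
      list(id = "oth1", utype = "other",
           model = list(type = "glmm", b = 1.5, intercept = -0.5)),
      list(id = "oth2", utype = "other",
           model = list(type = "glmm", b = 0, sigma_p = 2, y_sigma_p = 2))))
}

battery_config <- function(seed = MASTER_SEED) {
  pipeline_config(
    "desk", seed = seed, min_n = 80,
    n_trees_glmm = 5L, n_trees_bf = 5L,
    glmm_iterations = 1500L, glmm_burn_in = 500L, glmm_thin = 2L,
    ss_cfg = list(n_stones = 6, iters_per_stone = 120, burn_frac = 0.25),
    posterior_cfg = list(iterations = 15000L, burn_in = 3000L, thin = 15L))
}
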