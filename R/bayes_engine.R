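#' Prior specification for CTMC rates
#'
#' Each transition rate gets a gamma prior whose mean and variance are
#' themselves uniform on (0, upper] and are resampled as part of the chain
#' (a hierarchical prior that lets the data pick the rate scale).
#'
#' @param mean_max,var_max upper bounds of the uniform hyperpriors
#'   (default 10 for both).
#' @return a `prior_spec` object.
#' @export
prior_spec <- function(mean_max = 10, var_max = 10) {
  stopifnot(mean_max > 0, var_max > 0)
  structure(list(mean_max = mean_max, var_max = var_max), class = "prior_spec")
}

gamma_pars <- function(m, v) list(shape = m^2 / v, rate = m / v)

log_rate_prior <- function(rates, m, v) {
  gp <- gamma_pars(m, v)
  sum(dgamma(rates, shape = gp$shape, rate = gp$rate, log = TRUE))
}

#' MCMC configuration
#'
#' @param iterations total iterations (default 200000, a desk-scale run).
#' @param burn_in iterations discarded (default 10% of `iterations`).
#' @param thin keep every `thin`-th post-burn-in sample (default 100).
#' @param trees_per_block iterations spent on each tree before cycling to
#'   the next (default `iterations / 100`, so a 100-tree sample gets equal
#'   time per tree within one chain).
#' @param seed integer seed.
#' @return an `mcmc_config` object.
#' @export
mcmc_config <- function(iterations = 200000, burn_in = iterations %/% 10,
                        thin = 100, trees_per_block = max(1, iterations %/% 100),
                        seed = 1) {
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  if (thin < 1) stop("thin must be >= 1")
  if (trees_per_block < 1) stop("trees_per_block must be >= 1")
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 trees_per_block = as.integer(trees_per_block),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

## tip partials + per-tree postorder structures for a compiled universal
ctmc_data_context <- function(data, trees, root_prior = "uniform") {
  trees <- as_tree_list(trees)
  taxa <- data$taxa
  tp <- tip_partials(data$x, data$y, taxa)
  rp <- root_mode_code(root_prior)
  structs <- lapply(trees, function(tr) {
    common <- intersect(tr$tip.label, taxa)
    if (length(common) < 3) stop("fewer than 3 taxa shared between tree and data")
    ps <- prune_structure(tr, common)
    ps$tp <- tp[ps$tree$tip.label, , drop = FALSE]
    ps
  })
  n_shared <- length(structs[[1]]$tree$tip.label)
  if (n_shared < length(taxa)) {
    gc_log("dropped %d data taxa absent from the trees", length(taxa) - n_shared)
  }
  list(structs = structs, rp = rp, n_trees = length(structs))
}

rate_names_for <- function(model_kind) {
  if (model_kind == "dependent") DEP_RATE_NAMES else INDEP_RATE_NAMES
}

## loglik closure over precomputed structures: f(rates, tree_idx)
make_rate_loglik <- function(model_kind, ctx) {
  force(ctx)
  function(rates, tree_idx = 1L) {
    model <- structure(list(kind = model_kind,
                            rates = setNames(rates, rate_names_for(model_kind))),
                       class = "rate_model")
    Q <- build_q(model)
    s <- ctx$structs[[tree_idx]]
    ctmc_loglik_cpp(s$edge, s$edge_length, s$tp, s$n_node_total, Q,
                    ctx$rp$mode, ctx$rp$vec)
  }
}

## reflect a proposal into (lo, hi]
reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  x <- (x - lo) %% (2 * span)
  x <- ifelse(x > span, 2 * span - x, x)
  pmax(x + lo, lo + 1e-12)
}

#' Posterior sampling for a rate model with tree cycling
#'
#' Component-wise Gaussian random walk on log rates (one component per
#' iteration, round robin) with Robbins-Monro adaptation toward 30%
#' acceptance during burn-in only, plus reflective uniform updates of the
#' gamma-prior mean and variance hyperparameters. The chain spends
#' `trees_per_block` consecutive iterations on each tree of the sample,
#' cycling deterministically, so posterior rate samples integrate over
#' phylogenetic uncertainty within one chain.
#'
#' @param model_kind `"dependent"` (8 rates) or `"independent"` (4 rates).
#' @param data a `compiled_universal` (or list with `taxa`, `x`, `y`).
#' @param trees a `tree_sample`, `phylo`, or list of `phylo`.
#' @param prior a `prior_spec`.
#' @param cfg an `mcmc_config`.
#' @param root_prior root treatment for the pruning likelihood
#'   (default `"uniform"`, the conventional default for this model family).
#' @return an `mcmc_trace`: matrix `rates` (one row per retained sample),
#'   vectors `loglik` and `tree_index`, matrix `hyper` (mean, var),
#'   `acceptance` per parameter, plus the config.
#' @export
sample_posterior <- function(model_kind = c("dependent", "independent"),
                             data, trees, prior = prior_spec(),
                             cfg = mcmc_config(), root_prior = "uniform") {
  model_kind <- match.arg(model_kind)
  ctx <- ctmc_data_context(data, trees, root_prior)
  llfun <- make_rate_loglik(model_kind, ctx)
  rn <- rate_names_for(model_kind)
  k <- length(rn)

  with_seed(cfg$seed, {
    m <- runif(1, 0.01, prior$mean_max)
    v <- runif(1, 0.01, prior$var_max)
    gp <- gamma_pars(m, v)
    lr <- log(pmax(rgamma(k, shape = gp$shape, rate = gp$rate), 1e-6))
    scales <- rep(0.6, k)
    hscale <- c(1, 1)
    n_keep <- (cfg$iterations - cfg$burn_in) %/% cfg$thin
    rates_out <- matrix(NA_real_, n_keep, k, dimnames = list(NULL, rn))
    ll_out <- numeric(n_keep)
    tree_out <- integer(n_keep)
    hyper_out <- matrix(NA_real_, n_keep, 2,
                        dimnames = list(NULL, c("mean", "var")))
    acc <- rep(0L, k + 2L)
    att <- rep(0L, k + 2L)
    adapt_n <- rep(0L, k)
    cur_tree <- 1L
    cur_ll <- llfun(exp(lr), cur_tree)
    kept <- 0L

    for (iter in seq_len(cfg$iterations)) {
      idx <- (((iter - 1L) %/% cfg$trees_per_block) %% ctx$n_trees) + 1L
      if (idx != cur_tree) {
        cur_tree <- idx
        cur_ll <- llfun(exp(lr), cur_tree)
      }
      burnin <- iter <= cfg$burn_in

      j <- ((iter - 1L) %% k) + 1L
      prop <- lr
      prop[j] <- lr[j] + rnorm(1) * scales[j]
      new_ll <- llfun(exp(prop), cur_tree)
      ## gamma prior on rates plus the log-scale Jacobian
      lpost_diff <- (new_ll + log_rate_prior(exp(prop), m, v) + prop[j]) -
        (cur_ll + log_rate_prior(exp(lr), m, v) + lr[j])
      accepted <- is.finite(lpost_diff) && log(runif(1)) < lpost_diff
      if (accepted) {
        lr <- prop
        cur_ll <- new_ll
      }
      if (!burnin) {
        att[j] <- att[j] + 1L
        acc[j] <- acc[j] + accepted
      } else {
        adapt_n[j] <- adapt_n[j] + 1L
        step <- min(0.25, 3 / sqrt(adapt_n[j]))
        scales[j] <- scales[j] * exp(step * ((accepted) - 0.3))
        scales[j] <- min(max(scales[j], 1e-3), 20)
      }

      ## hyperparameter moves: likelihood-free, only the rate prior changes
      rates_now <- exp(lr)
      for (h in 1:2) {
        cur_hp <- if (h == 1) m else v
        hi <- if (h == 1) prior$mean_max else prior$var_max
        prop_hp <- reflect_into(cur_hp + rnorm(1) * hscale[h], 0, hi)
        d <- if (h == 1) {
          log_rate_prior(rates_now, prop_hp, v) - log_rate_prior(rates_now, m, v)
        } else {
          log_rate_prior(rates_now, m, prop_hp) - log_rate_prior(rates_now, m, v)
        }
        h_acc <- is.finite(d) && log(runif(1)) < d
        if (h_acc) {
          if (h == 1) m <- prop_hp else v <- prop_hp
        }
        if (!burnin) {
          att[k + h] <- att[k + h] + 1L
          acc[k + h] <- acc[k + h] + h_acc
        }
      }

      if (!burnin && ((iter - cfg$burn_in) %% cfg$thin == 0L)) {
        kept <- kept + 1L
        if (kept <= n_keep) {
          rates_out[kept, ] <- exp(lr)
          ll_out[kept] <- cur_ll
          tree_out[kept] <- cur_tree
          hyper_out[kept, ] <- c(m, v)
        }
      }
    }
    acc_rate <- ifelse(att > 0, acc / att, NA_real_)
    names(acc_rate) <- c(rn, "hyper_mean", "hyper_var")
    if (any(att[seq_len(k)] > 20 & acc[seq_len(k)] == 0)) {
      stop("zero acceptance for at least one rate after burn-in; check the model")
    }
    structure(
      list(rates = rates_out[seq_len(kept), , drop = FALSE],
           loglik = ll_out[seq_len(kept)],
           tree_index = tree_out[seq_len(kept)],
           hyper = hyper_out[seq_len(kept), , drop = FALSE],
           acceptance = acc_rate, model_kind = model_kind, cfg = cfg),
      class = "mcmc_trace"
    )
  })
}

#' @export
print.mcmc_trace <- function(x, ...) {
  cat(sprintf("mcmc_trace (%s model): %d samples, %d rates; mean acceptance %.2f\n",
              x$model_kind, nrow(x$rates), ncol(x$rates),
              mean(x$acceptance[seq_len(ncol(x$rates))], na.rm = TRUE)))
  invisible(x)
}

#' Simple trace diagnostics: ESS and split R-hat per rate
#'
#' @param trace an `mcmc_trace`.
#' @return data.frame with `rate`, `ess`, `split_rhat`.
#' @export
trace_diagnostics <- function(trace) {
  S <- trace$rates
  one <- function(x) {
    n <- length(x)
    half <- n %/% 2
    a <- x[seq_len(half)]
    b <- x[(n - half + 1):n]
    W <- (stats::var(a) + stats::var(b)) / 2
    B <- half * (mean(a) - mean(b))^2 / 1  # 2 chains
    rhat <- if (W > 0) sqrt(((half - 1) / half * W + B / half) / W) else NA_real_
    ac <- stats::acf(x, lag.max = min(n - 1, 50), plot = FALSE)$acf[-1]
    pos <- ac[ac > 0.05]
    ess <- n / (1 + 2 * sum(pos))
    c(ess = ess, split_rhat = rhat)
  }
  out <- t(apply(S, 2, one))
  data.frame(rate = colnames(S), ess = out[, "ess"],
             split_rhat = out[, "split_rhat"], row.names = NULL)
}

#' Generic stepping-stone marginal likelihood estimator
#'
#' Runs component-wise random-walk MH chains along a ladder of power
#' posteriors `prior x likelihood^beta` with Beta-quantile spacing
#' `beta_k = (k/K)^(1/alpha)`, warm-starting each stone from the previous
#' one, and accumulates `sum_k log mean exp((beta_k - beta_{k-1}) logL)`
#' in log-sum-exp form over the samples drawn at stone k-1's temperature.
#'
#' The state is an unconstrained real vector; `logprior_fn` must include
#' any transform Jacobians.
#'
#' @param loglik_fn function(theta) -> log-likelihood.
#' @param logprior_fn function(theta) -> log prior density (with Jacobians).
#' @param init initial unconstrained state.
#' @param n_stones number of stones K (>= 2).
#' @param iters_per_stone recorded sweeps per stone after the per-stone
#'   burn-in (one sweep updates every component once).
#' @param burn_frac fraction of each stone's sweeps discarded (with
#'   continued proposal-scale adaptation).
#' @param alpha Beta-quantile spacing exponent (default 0.3).
#' @param scales initial proposal SDs (recycled over components).
#' @param seed integer seed.
#' @return list with `logZ`, `betas`, `contributions`, `final_state`.
#' @export
stepping_stone <- function(loglik_fn, logprior_fn, init, n_stones = 10,
                           iters_per_stone = 2000, burn_frac = 0.25,
                           alpha = 0.3, scales = 0.5, seed = 1) {
  if (n_stones < 2) stop("n_stones must be >= 2")
  d <- length(init)
  scales <- rep_len(scales, d)
  betas <- (seq(0, n_stones) / n_stones)^(1 / alpha)
  with_seed(seed, {
    theta <- init
    cur_lp <- logprior_fn(theta)
    cur_ll <- loglik_fn(theta)
    if (!is.finite(cur_lp) || !is.finite(cur_ll)) {
      stop("non-finite log density at the initial state")
    }
    contribs <- numeric(n_stones)
    burn <- ceiling(burn_frac * iters_per_stone)
    n_adapt <- rep(0L, d)
    for (k in seq_len(n_stones)) {
      beta_prev <- betas[k]
      beta_next <- betas[k + 1]
      ll_samples <- numeric(iters_per_stone)
      for (it in seq_len(burn + iters_per_stone)) {
        for (j in seq_len(d)) {
          prop <- theta
          prop[j] <- theta[j] + rnorm(1) * scales[j]
          lp <- logprior_fn(prop)
          accepted <- FALSE
          if (is.finite(lp)) {
            ll <- loglik_fn(prop)
            dpost <- (lp + beta_prev * ll) - (cur_lp + beta_prev * cur_ll)
            if (is.finite(dpost) && log(runif(1)) < dpost) {
              theta <- prop
              cur_lp <- lp
              cur_ll <- ll
              accepted <- TRUE
            }
          }
          if (it <= burn) {
            n_adapt[j] <- n_adapt[j] + 1L
            step <- min(0.25, 3 / sqrt(n_adapt[j]))
            scales[j] <- min(max(scales[j] * exp(step * (accepted - 0.3)), 1e-3), 20)
          }
        }
        if (it > burn) ll_samples[it - burn] <- cur_ll
      }
      contribs[k] <- logsumexp((beta_next - beta_prev) * ll_samples) -
        log(iters_per_stone)
      if (!is.finite(contribs[k])) {
        stop(sprintf("non-finite stepping-stone contribution at stone %d", k))
      }
    }
    list(logZ = sum(contribs), betas = betas, contributions = contribs,
         final_state = theta)
  })
}

## uniform-(0,hi] hyperparameter transform: u unconstrained -> m in (0,hi)
## log prior density in u-space (constant 1/hi times Jacobian hi*s*(1-s))
unif_from_raw <- function(u, hi) hi * plogis(u)
log_unif_raw_prior <- function(u) plogis(u, log.p = TRUE) + plogis(-u, log.p = TRUE)

#' Stepping-stone log marginal likelihood of a rate model on one tree
#'
#' The integrated state is (log rates, hyperprior mean, hyperprior
#' variance), so the marginal likelihood averages the pruning likelihood
#' over the full hierarchical prior.
#'
#' @inheritParams sample_posterior
#' @param ss_cfg list with `n_stones`, `iters_per_stone`, `burn_frac`,
#'   `alpha` (see [stepping_stone()]).
#' @param seed integer seed.
#' @param tree_index which tree of the sample to use (default 1).
#' @return the estimated log marginal likelihood (a single number).
#' @export
stepping_stone_logZ <- function(model_kind = c("dependent", "independent"),
                                data, trees, prior = prior_spec(),
                                ss_cfg = list(), seed = 1, tree_index = 1L,
                                root_prior = "uniform") {
  model_kind <- match.arg(model_kind)
  ss <- utils::modifyList(list(n_stones = 10, iters_per_stone = 2000,
                               burn_frac = 0.25, alpha = 0.3), ss_cfg)
  ctx <- ctmc_data_context(data, trees, root_prior)
  stopifnot(tree_index >= 1, tree_index <= ctx$n_trees)
  llfun_tree <- make_rate_loglik(model_kind, ctx)
  k <- length(rate_names_for(model_kind))

  loglik_fn <- function(theta) llfun_tree(exp(theta[seq_len(k)]), tree_index)
  logprior_fn <- function(theta) {
    lr <- theta[seq_len(k)]
    if (any(abs(lr) > 50)) return(-Inf)
    m <- unif_from_raw(theta[k + 1], prior$mean_max)
    v <- unif_from_raw(theta[k + 2], prior$var_max)
    log_rate_prior(exp(lr), m, v) + sum(lr) +
      log_unif_raw_prior(theta[k + 1]) + log_unif_raw_prior(theta[k + 2])
  }
  init <- with_seed(seed + 1L, {
    m0 <- runif(1, 1, prior$mean_max / 2)
    v0 <- runif(1, 1, prior$var_max / 2)
    gp <- gamma_pars(m0, v0)
    c(log(pmax(rgamma(k, gp$shape, gp$rate), 1e-4)),
      log(m0 / (prior$mean_max - m0)), log(v0 / (prior$var_max - v0)))
  })
  stepping_stone(loglik_fn, logprior_fn, init, n_stones = ss$n_stones,
                 iters_per_stone = ss$iters_per_stone,
                 burn_frac = ss$burn_frac, alpha = ss$alpha, seed = seed)$logZ
}

#' Natural-log Bayes factor of dependent over independent co-evolution
#'
#' The difference of log marginal likelihoods; positive values favour the
#' dependent (co-evolution) model.
#'
#' @param logZ_dep,logZ_indep finite log marginal likelihoods.
#' @return `logZ_dep - logZ_indep`.
#' @export
log_bayes_factor <- function(logZ_dep, logZ_indep) {
  if (!is.finite(logZ_dep) || !is.finite(logZ_indep)) {
    stop("log marginal likelihoods must be finite")
  }
  logZ_dep - logZ_indep
}

#' Highest density interval of a sample
#'
#' Shortest contiguous interval containing `ceiling(prob * n)` sorted
#' sample points; ties are broken toward the earliest window.
#'
#' @param samples numeric vector (>= `min_n` values).
#' @param prob probability mass (default 0.95).
#' @param min_n minimum sample size accepted (default 10).
#' @return named vector `c(low, high)`.
#' @export
hdi <- function(samples, prob = 0.95, min_n = 10) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < min_n) stop(sprintf("need at least %d samples for an HDI", min_n))
  s <- sort(samples)
  m <- ceiling(prob * n)
  if (m >= n) return(c(low = s[1], high = s[n]))
  widths <- s[seq(m, n)] - s[seq(1, n - m + 1)]
  i <- which.min(widths)  # which.min takes the earliest minimum
  c(low = s[i], high = s[i + m - 1])
}

#' Support rule on a distribution of log Bayes factors
#'
#' A universal's co-evolution is supported when the lower bound of the 95%
#' HDI of its log-BF distribution exceeds the threshold (strictly): a
#' conservative cut-off given the number of universals tested. A lower
#' bound exactly at the threshold does not count as support.
#'
#' @param per_tree_bf numeric vector of log Bayes factors (one per tree).
#' @param threshold support threshold (default 10).
#' @return list with `supported`, `median`, `hdi_low`, `hdi_high`.
#' @export
bf_support_rule <- function(per_tree_bf, threshold = 10) {
  h <- hdi(per_tree_bf, 0.95, min_n = min(10L, length(per_tree_bf)))
  list(supported = unname(h["low"]) > threshold,
       median = median(per_tree_bf),
       hdi_low = unname(h["low"]), hdi_high = unname(h["high"]))
}

#' Per-tree Bayes factors for co-evolution and their HDI summary
#'
#' Computes one (dependent, independent) stepping-stone log marginal
#' likelihood pair per tree over a subsample of the tree sample and
#' summarizes the distribution of log Bayes factors by its median and 95%
#' HDI. The support rule for co-evolution is `hdi_low > threshold`
#' (threshold 10 by default, a deliberately conservative cut-off given the
#' many universals tested).
#'
#' @inheritParams stepping_stone_logZ
#' @param n_trees number of trees to use (default `min(10, sample size)`).
#' @param bf_threshold support threshold on the HDI lower bound.
#' @return a `bf_summary`: per-tree log BFs, median, `hdi_low`, `hdi_high`,
#'   `supported`.
#' @export
coevolution_bf <- function(data, trees, prior = prior_spec(), ss_cfg = list(),
                           seed = 1, n_trees = NULL, bf_threshold = 10,
                           root_prior = "uniform") {
  tl <- as_tree_list(trees)
  n_trees <- n_trees %||% min(10L, length(tl))
  stopifnot(n_trees >= 1, n_trees <= length(tl))
  idx <- unique(round(seq(1, length(tl), length.out = n_trees)))
  bf <- vapply(seq_along(idx), function(i) {
    tr <- tl[[idx[i]]]
    zd <- stepping_stone_logZ("dependent", data, tr, prior, ss_cfg,
                              seed = split_seed(seed, paste0("tree", idx[i]), "dep"),
                              tree_index = 1L, root_prior = root_prior)
    zi <- stepping_stone_logZ("independent", data, tr, prior, ss_cfg,
                              seed = split_seed(seed, paste0("tree", idx[i]), "indep"),
                              tree_index = 1L, root_prior = root_prior)
    log_bayes_factor(zd, zi)
  }, 0)
  rule <- bf_support_rule(bf, bf_threshold)
  structure(
    list(per_tree_bf = bf, tree_indices = idx, median = rule$median,
         hdi_low = rule$hdi_low, hdi_high = rule$hdi_high,
         bf_threshold = bf_threshold,
         supported = rule$supported, mode = "per_tree"),
    class = "bf_summary"
  )
}

#' @export
print.bf_summary <- function(x, ...) {
  cat(sprintf("log BF over %d trees: median %.2f, 95%% HDI [%.2f, %.2f] -> %s\n",
              length(x$per_tree_bf), x$median, x$hdi_low, x$hdi_high,
              if (x$supported) "co-evolution supported" else "not supported"))
  invisible(x)
}

#' Write an MCMC trace as TSV
#'
#' One row per retained sample: sample index, tree index, rates,
#' log-likelihood and hyperparameters.
#'
#' @param trace an `mcmc_trace`.
#' @param path output path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "mcmc_trace"))
  df <- data.frame(sample = seq_len(nrow(trace$rates)),
                   tree_index = trace$tree_index, trace$rates,
                   loglik = trace$loglik,
                   hyper_mean = trace$hyper[, "mean"],
                   hyper_var = trace$hyper[, "var"], check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}
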