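#' Harmonic versus disharmonic rate comparison from a posterior trace
#'
#' Rates into the harmonic state 4 = (1,1) — `q34` (from (1,0)) and `q24`
#' (from (0,1)) — are compared against their disharmonic opposites `q43`
#' and `q42` in every retained MCMC draw: the indicator is 1 when the
#' harmonic rate is strictly larger (exact ties count as 0). Proportions
#' are reported per pair and pooled over both pairs.
#'
#' @param trace an `mcmc_trace` from a dependent-model fit.
#' @return a `rate_comparison`: `prop_q34_gt_q43`, `prop_q24_gt_q42`,
#'   `prop_pooled`, `n_draws`.
#' @export
harmonic_comparison <- function(trace) {
  stopifnot(inherits(trace, "mcmc_trace"))
  if (trace$model_kind != "dependent") {
    stop("harmonic/disharmonic pairs are undefined for an independent-model trace")
  }
  R <- trace$rates
  i34 <- R[, "q34"] > R[, "q43"]
  i24 <- R[, "q24"] > R[, "q42"]
  structure(
    list(prop_q34_gt_q43 = mean(i34), prop_q24_gt_q42 = mean(i24),
         prop_pooled = mean(c(i34, i24)), n_draws = nrow(R)),
    class = "rate_comparison"
  )
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat(sprintf(
    "harmonic > disharmonic: q34>q43 %.3f, q24>q42 %.3f, pooled %.3f (%d draws)\n",
    x$prop_q34_gt_q43, x$prop_q24_gt_q42, x$prop_pooled, x$n_draws))
  invisible(x)
}

## exact null distribution of the signed-rank statistic for possibly tied
## (average) ranks: each rank enters the positive sum independently with
## probability 1/2; ranks are doubled to integers and convolved.
signed_rank_exact_p <- function(ranks, V) {
  r2 <- as.integer(round(2 * ranks))
  tot <- sum(r2)
  f <- c(1)  # f[s+1] = number of sign patterns with doubled statistic s
  for (r in r2) {
    g <- c(f, numeric(r))
    g[(r + 1):(length(f) + r)] <- g[(r + 1):(length(f) + r)] + f
    f <- g
  }
  probs <- f / 2^length(r2)
  v2 <- as.integer(round(2 * V))
  p_le <- sum(probs[seq_len(v2 + 1)])
  p_ge <- sum(probs[(v2 + 1):(tot + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' Two-sided Wilcoxon signed-rank test against a location
#'
#' Values equal to `mu` are dropped; magnitudes are ranked with average
#' ranks for ties; `V` is the sum of ranks of values above `mu`. The
#' two-sided p-value uses the exact null distribution (a rank convolution,
#' valid with ties) for n <= 25 and a normal approximation with continuity
#' and tie corrections above.
#'
#' @param x numeric vector of per-universal proportions (or any values).
#' @param mu null location (default 0.5, chance for a rate comparison).
#' @param exact_max largest n for which the exact distribution is used.
#' @return list with `V`, `n`, `p`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, mu = 0.5, exact_max = 25) {
  x <- x[!is.na(x)]
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  if (n < 1) stop("no informative observations (all values equal mu)")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- signed_rank_exact_p(r, V)
    method <- "exact"
  } else {
    mu_v <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu_v - sign(V - mu_v) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(V = V, n = n, p = p, method = method)
}
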