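#' Spatial covariance from great-circle distances
#'
#' Exponential-decay kernel on haversine distance:
#' `K[i, j] = exp(-d_km(i, j) / length_scale_km)`, diagonal exactly 1.
#'
#' @param meta data.frame with columns `taxon`, `longitude`, `latitude`.
#' @param length_scale_km kernel length scale in kilometres (default 1000;
#'   roughly the scale at which language contact plausibly operates).
#' @return symmetric PSD matrix with taxon dimnames and attribute
#'   `length_scale_km`.
#' @export
spatial_covariance <- function(meta, length_scale_km = 1000) {
  stopifnot(length_scale_km > 0)
  validate_metadata(meta)
  if (anyNA(meta$longitude) || anyNA(meta$latitude)) {
    stop("missing coordinates in metadata")
  }
  coords <- cbind(meta$longitude, meta$latitude)
  d_km <- geosphere::distm(coords, fun = geosphere::distHaversine) / 1000
  K <- exp(-d_km / length_scale_km)
  diag(K) <- 1
  dimnames(K) <- list(meta$taxon, meta$taxon)
  attr(K, "length_scale_km") <- length_scale_km
  K
}

#' Specify a binary mixed model for one universal
#'
#' Variants mirror the three analysis stages: `naive` (fixed effect only),
#' `spatiophylo` (adds phylogenetic and spatial covariance random effects
#' plus macro-area intercepts), `family_control` (random intercepts and
#' slopes by language family, only families with >= 5 members retained at
#' fit time). The response is the condition part of the universal and the
#' fixed effect is the result part.
#'
#' @param variant `"naive"`, `"spatiophylo"`, or `"family_control"`.
#' @param response binary response vector.
#' @param fixed binary fixed-effect (predictor) vector.
#' @param taxa taxon names aligned with `response`.
#' @param phylo_cov,spatial_cov covariance matrices over (a superset of)
#'   `taxa` (required for `spatiophylo`).
#' @param macroarea,family grouping labels per taxon.
#' @return a `glmm_spec` object.
#' @export
glmm_spec <- function(variant = c("naive", "spatiophylo", "family_control"),
                      response, fixed, taxa = names(response),
                      phylo_cov = NULL, spatial_cov = NULL,
                      macroarea = NULL, family = NULL) {
  variant <- match.arg(variant)
  n <- length(response)
  if (length(fixed) != n) stop("response and fixed must have equal length")
  if (anyNA(response) || anyNA(fixed)) stop("missing values in model variables")
  if (!all(response %in% 0:1) || !all(fixed %in% 0:1)) {
    stop("response and fixed must be binary")
  }
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n))
  if (variant == "spatiophylo") {
    if (is.null(phylo_cov) || is.null(spatial_cov) || is.null(macroarea)) {
      stop("spatiophylo variant requires phylo_cov, spatial_cov and macroarea")
    }
  }
  if (variant == "family_control" && is.null(family)) {
    stop("family_control variant requires family labels")
  }
  align <- function(C) {
    if (is.null(C)) return(NULL)
    missing <- setdiff(taxa, rownames(C))
    if (length(missing)) stop(sprintf("covariance lacks taxa: %s",
                                      paste(head(missing, 5), collapse = ", ")))
    C[taxa, taxa, drop = FALSE]
  }
  structure(
    list(variant = variant, response = as.integer(response),
         fixed = as.integer(fixed), taxa = taxa,
         phylo_cov = align(phylo_cov), spatial_cov = align(spatial_cov),
         macroarea = macroarea, family = family),
    class = "glmm_spec"
  )
}

bernoulli_loglik <- function(y, eta) {
  sum(ifelse(y == 1L, plogis(eta, log.p = TRUE), plogis(-eta, log.p = TRUE)))
}

## Cholesky factor after PSD repair; adds a whisper of jitter for stability
safe_chol <- function(C) {
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) C <- nearest_psd(C)
  t(chol(C + diag(1e-8 * max(diag(C)), nrow(C))))
}

## one elliptical slice sampling update of z ~ N(0, I) given loglik(z)
ess_update <- function(z, loglik, cur_ll) {
  nu <- rnorm(length(z))
  logy <- cur_ll + log(runif(1))
  theta <- runif(1, 0, 2 * pi)
  lo <- theta - 2 * pi
  hi <- theta
  repeat {
    zp <- z * cos(theta) + nu * sin(theta)
    ll <- loglik(zp)
    if (ll > logy) return(list(z = zp, ll = ll))
    if (theta < 0) lo <- theta else hi <- theta
    theta <- runif(1, lo, hi)
    if (hi - lo < 1e-12) return(list(z = z, ll = cur_ll))
  }
}

#' Fit a Bayesian binary GLMM by MCMC
#'
#' Logit model `P(response = 1) = plogis(a + b fixed + u_phylo + u_spatial
#' + u_area)` (variant-dependent), with `u_phylo ~ N(0, sigma_p^2 C_phylo)`
#' and `u_spatial ~ N(0, sigma_s^2 C_spatial)`. Latent fields are whitened
#' through Cholesky factors and updated by elliptical slice sampling;
#' `(a, b)` and the log random-effect SDs use adaptive random-walk MH.
#' Priors: Normal(0, 5^2) on intercept and fixed effect, half-Normal(0,
#' 2^2) on the SDs. Covariance matrices are standardized by their maximum
#' diagonal entry so variance components are comparable across trees.
#'
#' @param spec a `glmm_spec`.
#' @param cfg an `mcmc_config`; `iterations` counts full sweeps
#'   (sensible GLMM scale: a few thousand).
#' @param sigma_fixed optional named vector fixing some SDs (e.g.
#'   `c(sigma_p = 0)`) instead of sampling them.
#' @return a `glmm_posterior`: samples of `a`, `b` and the SDs, the fixed
#'   effect's median and 95% equal-tailed CI, and bookkeeping about any
#'   family-filter drops.
#' @export
fit_binary_glmm <- function(spec, cfg = mcmc_config(iterations = 3000,
                                                    burn_in = 1000, thin = 2),
                            sigma_fixed = NULL) {
  stopifnot(inherits(spec, "glmm_spec"))
  y <- spec$response
  x <- spec$fixed
  taxa <- spec$taxa
  dropped_taxa <- 0L
  dropped_families <- 0L

  if (spec$variant == "family_control") {
    fam <- spec$family
    sizes <- table(fam)
    keep_fams <- names(sizes)[sizes >= 5]
    keep <- fam %in% keep_fams
    dropped_taxa <- sum(!keep)
    dropped_families <- length(sizes) - length(keep_fams)
    if (dropped_taxa) {
      gc_log("family filter (>=5 members): dropped %d taxa in %d families",
             dropped_taxa, dropped_families)
    }
    y <- y[keep]; x <- x[keep]; taxa <- taxa[keep]; fam <- fam[keep]
    fam_idx <- as.integer(factor(fam))
    n_fam <- max(fam_idx)
  }
  if (length(unique(y)) < 2) stop("degenerate response (all 0 or all 1)")
  n <- length(y)

  ## latent-field design: list of (map from whitened z to n-vector, dim)
  fields <- list()
  if (spec$variant == "spatiophylo") {
    Lp <- safe_chol(spec$phylo_cov / max(diag(spec$phylo_cov)))
    Ls <- safe_chol(spec$spatial_cov / max(diag(spec$spatial_cov)))
    area_idx <- as.integer(factor(spec$macroarea))
    n_area <- max(area_idx)
    fields <- list(
      sigma_p = list(map = function(z) drop(Lp %*% z), dim = n),
      sigma_s = list(map = function(z) drop(Ls %*% z), dim = n),
      sigma_area = list(map = function(z) z[area_idx], dim = n_area)
    )
  } else if (spec$variant == "family_control") {
    fields <- list(
      sigma_fam_int = list(map = function(z) z[fam_idx], dim = n_fam),
      sigma_fam_slope = list(map = function(z) z[fam_idx] * x, dim = n_fam)
    )
  }
  fnames <- names(fields)

  with_seed(cfg$seed, {
    a <- 0; b <- 0
    sig <- setNames(rep(0.5, length(fields)), fnames)
    for (nm in names(sigma_fixed %||% c())) {
      if (nm %in% fnames) sig[nm] <- sigma_fixed[[nm]]
    }
    is_fixed <- fnames %in% names(sigma_fixed %||% c())
    z <- lapply(fields, function(f) rnorm(f$dim) * 0.1)
    uvals <- lapply(fnames, function(nm) fields[[nm]]$map(z[[nm]]))
    names(uvals) <- fnames

    eta_of <- function(a, b, uvals, sig) {
      eta <- a + b * x
      for (nm in fnames) eta <- eta + sig[nm] * uvals[[nm]]
      eta
    }
    cur_eta <- eta_of(a, b, uvals, sig)
    cur_ll <- bernoulli_loglik(y, cur_eta)

    ab_scale <- c(0.3, 0.3)
    sig_scale <- setNames(rep(0.4, length(fields)), fnames)
    n_keep <- (cfg$iterations - cfg$burn_in) %/% cfg$thin
    out <- matrix(NA_real_, n_keep, 2 + length(fields),
                  dimnames = list(NULL, c("a", "b", fnames)))
    kept <- 0L
    adapt_ab <- 0L

    for (iter in seq_len(cfg$iterations)) {
      burnin <- iter <= cfg$burn_in
      ## (a, b) joint random walk
      ap <- a + rnorm(1) * ab_scale[1]
      bp <- b + rnorm(1) * ab_scale[2]
      eta_p <- cur_eta + (ap - a) + (bp - b) * x
      ll_p <- bernoulli_loglik(y, eta_p)
      dpost <- (ll_p + dnorm(ap, 0, 5, log = TRUE) + dnorm(bp, 0, 5, log = TRUE)) -
        (cur_ll + dnorm(a, 0, 5, log = TRUE) + dnorm(b, 0, 5, log = TRUE))
      acc <- is.finite(dpost) && log(runif(1)) < dpost
      if (acc) {
        a <- ap; b <- bp; cur_eta <- eta_p; cur_ll <- ll_p
      }
      if (burnin) {
        adapt_ab <- adapt_ab + 1L
        step <- min(0.25, 3 / sqrt(adapt_ab))
        ab_scale <- pmin(pmax(ab_scale * exp(step * (acc - 0.3)), 1e-3), 10)
      }

      ## latent fields by elliptical slice sampling on whitened z
      for (nm in fnames) {
        if (sig[nm] == 0) next
        base_eta <- cur_eta - sig[nm] * uvals[[nm]]
        up <- ess_update(z[[nm]], function(zz) {
          bernoulli_loglik(y, base_eta + sig[nm] * fields[[nm]]$map(zz))
        }, cur_ll)
        z[[nm]] <- up$z
        uvals[[nm]] <- fields[[nm]]$map(z[[nm]])
        cur_eta <- base_eta + sig[nm] * uvals[[nm]]
        cur_ll <- up$ll
      }

      ## SD updates on log scale (half-Normal(0, 2^2) prior + Jacobian)
      for (j in seq_along(fnames)) {
        nm <- fnames[j]
        if (is_fixed[j]) next
        ls <- log(sig[nm])
        lsp <- ls + rnorm(1) * sig_scale[nm]
        sp <- exp(lsp)
        base_eta <- cur_eta - sig[nm] * uvals[[nm]]
        eta_p <- base_eta + sp * uvals[[nm]]
        ll_p <- bernoulli_loglik(y, eta_p)
        dpost <- (ll_p + dnorm(sp, 0, 2, log = TRUE) + lsp) -
          (cur_ll + dnorm(sig[nm], 0, 2, log = TRUE) + ls)
        acc <- is.finite(dpost) && log(runif(1)) < dpost
        if (acc) {
          sig[nm] <- sp; cur_eta <- eta_p; cur_ll <- ll_p
        }
        if (burnin) {
          step <- min(0.25, 3 / sqrt(iter))
          sig_scale[nm] <- pmin(pmax(sig_scale[nm] * exp(step * (acc - 0.3)),
                                     1e-3), 10)
        }
      }

      if (!burnin && ((iter - cfg$burn_in) %% cfg$thin == 0L)) {
        kept <- kept + 1L
        if (kept <= n_keep) out[kept, ] <- c(a, b, sig)
      }
    }

    out <- out[seq_len(kept), , drop = FALSE]
    ci <- unname(quantile(out[, "b"], c(0.025, 0.975)))
    structure(
      list(samples = out, variant = spec$variant,
           b_median = median(out[, "b"]), ci_low = ci[1], ci_high = ci[2],
           n = n, dropped_taxa = dropped_taxa,
           dropped_families = dropped_families, cfg = cfg),
      class = "glmm_posterior"
    )
  })
}

#' @export
print.glmm_posterior <- function(x, ...) {
  cat(sprintf("glmm_posterior (%s, n=%d): b = %.3f [%.3f, %.3f]\n",
              x$variant, x$n, x$b_median, x$ci_low, x$ci_high))
  invisible(x)
}

#' Support classification from GLMM posteriors
#'
#' For a single (naive) posterior, the universal is supported when the
#' fixed effect's 95% CI excludes zero. For per-tree posteriors, the
#' medians of the per-tree CI lower and upper bounds must fall on the same
#' side of zero.
#'
#' @param posteriors a `glmm_posterior` or a list of them (one per tree).
#' @return list with `supported`, `ci_low`, `ci_high`, `b_median`,
#'   `n_posteriors`, `rule`.
#' @export
support_from_posteriors <- function(posteriors) {
  if (inherits(posteriors, "glmm_posterior")) posteriors <- list(posteriors)
  if (length(posteriors) == 0) stop("no posteriors supplied")
  lows <- vapply(posteriors, `[[`, 0, "ci_low")
  highs <- vapply(posteriors, `[[`, 0, "ci_high")
  meds <- vapply(posteriors, `[[`, 0, "b_median")
  lo <- median(lows)
  hi <- median(highs)
  supported <- (lo > 0 && hi > 0) || (lo < 0 && hi < 0)
  list(supported = supported, ci_low = lo, ci_high = hi,
       b_median = median(meds), n_posteriors = length(posteriors),
       rule = if (length(posteriors) == 1) "single_ci" else "median_of_bounds")
}
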