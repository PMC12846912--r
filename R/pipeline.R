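#' Pipeline configuration
#'
#' Bundles the stage-level knobs for a battery run. The `desk` profile is
#' sized for a single CPU (10 trees per stage, short chains); `full` uses
#' the settings large cross-linguistic studies run at (100 trees, long
#' chains) and is intended for cluster use.
#'
#' @param profile `"desk"` or `"full"`.
#' @param seed master seed; per-universal, per-stage seeds are split from
#'   it deterministically (see [split_seed()]).
#' @param min_n minimum sample size per universal (default 100).
#' @param ... overrides for any config element.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(profile = c("desk", "full"), seed = 1,
                            min_n = 100, ...) {
  profile <- match.arg(profile)
  base <- if (profile == "desk") {
    list(
      n_trees_glmm = 10L, n_trees_bf = 10L,
      glmm_iterations = 2000L, glmm_burn_in = 600L, glmm_thin = 2L,
      ss_cfg = list(n_stones = 10, iters_per_stone = 2000, burn_frac = 0.25,
                    alpha = 0.3),
      posterior_cfg = list(iterations = 200000L, burn_in = 20000L,
                           thin = 100L),
      bf_threshold = 10, length_scale_km = 1000
    )
  } else {
    list(
      n_trees_glmm = 100L, n_trees_bf = 100L,
      glmm_iterations = 8000L, glmm_burn_in = 2000L, glmm_thin = 2L,
      ss_cfg = list(n_stones = 100, iters_per_stone = 10000, burn_frac = 0.25,
                    alpha = 0.3),
      posterior_cfg = list(iterations = 30300000L, burn_in = 300000L,
                           thin = 30000L),
      bf_threshold = 10, length_scale_km = 1000
    )
  }
  cfg <- utils::modifyList(base, list(...))
  cfg$profile <- profile
  cfg$seed <- as.integer(seed)
  cfg$min_n <- min_n
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full three-stage analysis for one universal
#'
#' Stages: (1) compile the universal against the trait matrix (listwise
#' deletion); (2) naive GLMM; (3) spatiophylogenetic GLMM refit per tree
#' with the median-of-CI-bounds support rule; (4) only if stage 3 supports
#' the universal, dependent-vs-independent stepping-stone Bayes factors per
#' tree with the HDI > threshold rule, plus the harmonic/disharmonic rate
#' comparison from a dependent-model posterior. The final verdict is
#' "supported by stage 3 AND stage 4".
#'
#' @param spec a `universal_spec`.
#' @param traits binary trait matrix (taxa x features).
#' @param trees a `tree_sample`.
#' @param meta metadata data.frame (taxon, longitude, latitude, macroarea,
#'   family).
#' @param cfg a `pipeline_config`.
#' @param out_dir optional directory for per-stage TSV outputs.
#' @return a `support_decision` list.
#' @export
run_universal <- function(spec, traits, trees, meta, cfg = pipeline_config(),
                          out_dir = NULL) {
  tl <- as_tree_list(trees)
  comp <- compile_universal(spec, traits, min_n = cfg$min_n)
  meta_i <- meta[match(comp$taxa, meta$taxon), ]
  if (anyNA(meta_i$taxon)) stop(sprintf("universal %s: metadata missing taxa",
                                        spec$id))

  glmm_cfg <- function(seed) {
    mcmc_config(iterations = cfg$glmm_iterations, burn_in = cfg$glmm_burn_in,
                thin = cfg$glmm_thin, seed = seed)
  }

  ## response = condition part (x), fixed effect = result part (y)
  naive <- fit_binary_glmm(
    glmm_spec("naive", response = comp$x, fixed = comp$y, taxa = comp$taxa),
    glmm_cfg(split_seed(cfg$seed, spec$id, "naive"))
  )
  naive_support <- support_from_posteriors(naive)

  Cs <- spatial_covariance(meta_i, cfg$length_scale_km)
  n_tg <- min(cfg$n_trees_glmm, length(tl))
  tree_idx <- unique(round(seq(1, length(tl), length.out = n_tg)))
  per_tree <- lapply(seq_along(tree_idx), function(i) {
    Cp <- phylo_covariance(tl[[tree_idx[i]]], comp$taxa, standardize = TRUE)
    fit_binary_glmm(
      glmm_spec("spatiophylo", response = comp$x, fixed = comp$y,
                taxa = comp$taxa, phylo_cov = Cp, spatial_cov = Cs,
                macroarea = meta_i$macroarea),
      glmm_cfg(split_seed(cfg$seed, spec$id, paste0("spatiophylo", tree_idx[i])))
    )
  })
  sp_support <- support_from_posteriors(per_tree)

  bf <- NULL
  harm <- NULL
  coev_supported <- NA
  if (sp_support$supported) {
    bf <- coevolution_bf(comp, tl, prior_spec(), cfg$ss_cfg,
                         seed = split_seed(cfg$seed, spec$id, "bf"),
                         n_trees = min(cfg$n_trees_bf, length(tl)),
                         bf_threshold = cfg$bf_threshold)
    coev_supported <- bf$supported
    pc <- cfg$posterior_cfg
    trace <- sample_posterior(
      "dependent", comp, tl, prior_spec(),
      mcmc_config(iterations = pc$iterations, burn_in = pc$burn_in,
                  thin = pc$thin,
                  seed = split_seed(cfg$seed, spec$id, "harmonics"))
    )
    harm <- harmonic_comparison(trace)
  }

  decision <- structure(
    list(universal_id = spec$id, utype = spec$utype, n = comp$n,
         naive_supported = naive_support$supported,
         naive_b_median = naive_support$b_median,
         naive_ci_low = naive_support$ci_low,
         naive_ci_high = naive_support$ci_high,
         spatiophylo_supported = sp_support$supported,
         spatiophylo_b_median = sp_support$b_median,
         spatiophylo_ci_low = sp_support$ci_low,
         spatiophylo_ci_high = sp_support$ci_high,
         coevolution_supported = coev_supported,
         bf_median = if (is.null(bf)) NA_real_ else bf$median,
         bf_hdi_low = if (is.null(bf)) NA_real_ else bf$hdi_low,
         bf_hdi_high = if (is.null(bf)) NA_real_ else bf$hdi_high,
         prop_harmonic = if (is.null(harm)) NA_real_ else harm$prop_pooled,
         final_supported = isTRUE(sp_support$supported) && isTRUE(coev_supported),
         status = "ok"),
    class = "support_decision"
  )
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, spec$id), recursive = TRUE, showWarnings = FALSE)
    write_decision_tsv(list(decision), file.path(out_dir, spec$id, "decision.tsv"))
  }
  decision
}

#' @export
print.support_decision <- function(x, ...) {
  cat(sprintf(
    "universal %s [%s] n=%d: naive=%s spatiophylo=%s coevolution=%s -> final=%s\n",
    x$universal_id, x$utype, x$n, x$naive_supported, x$spatiophylo_supported,
    x$coevolution_supported, x$final_supported))
  invisible(x)
}

decision_fields <- c(
  "universal_id", "utype", "n", "naive_supported", "naive_b_median",
  "naive_ci_low", "naive_ci_high", "spatiophylo_supported",
  "spatiophylo_b_median", "spatiophylo_ci_low", "spatiophylo_ci_high",
  "coevolution_supported", "bf_median", "bf_hdi_low", "bf_hdi_high",
  "prop_harmonic", "final_supported", "status")

decisions_to_df <- function(decisions) {
  rows <- lapply(decisions, function(d) {
    vals <- lapply(decision_fields, function(f) {
      v <- d[[f]]
      if (is.null(v) || length(v) == 0) NA else v
    })
    names(vals) <- decision_fields
    as.data.frame(vals, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

write_decision_tsv <- function(decisions, path) {
  df <- decisions_to_df(decisions)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 10, format = "g"))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run a battery of universals
#'
#' Applies [run_universal()] to each spec; a failing universal is recorded
#' with status `"error"` rather than aborting the battery. Writes
#' `decisions.tsv` (stable formatting, so identical seeds give
#' byte-identical files) and a `battery_report.tsv` when `out_dir` is set.
#'
#' @param specs list of `universal_spec`.
#' @inheritParams run_universal
#' @return list with `decisions` (list of `support_decision`) and `report`
#'   (see [aggregate_battery()]).
#' @export
run_battery <- function(specs, traits, trees, meta, cfg = pipeline_config(),
                        out_dir = NULL) {
  decisions <- lapply(specs, function(sp) {
    tryCatch(
      run_universal(sp, traits, trees, meta, cfg),
      error = function(e) {
        gc_log("universal %s failed: %s", sp$id, conditionMessage(e))
        structure(list(universal_id = sp$id, utype = sp$utype, n = NA_integer_,
                       naive_supported = NA, spatiophylo_supported = NA,
                       coevolution_supported = NA, final_supported = NA,
                       status = paste0("error: ", conditionMessage(e))),
                  class = "support_decision")
      })
  })
  report <- aggregate_battery(decisions, specs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_decision_tsv(decisions, file.path(out_dir, "decisions.tsv"))
    rep_df <- report$per_type
    rep_df[] <- lapply(rep_df, function(v)
      if (is.numeric(v)) formatC(v, digits = 10, format = "g") else v)
    write.table(rep_df, file.path(out_dir, "battery_report.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  list(decisions = decisions, report = report)
}

#' Aggregate per-universal decisions into a battery report
#'
#' @param decisions list of `support_decision`.
#' @param specs the matching list of `universal_spec` (for the type of
#'   universals that errored).
#' @return a `battery_report`: data.frame `per_type` with counts and
#'   proportions supported at each stage (NA proportion for empty type
#'   buckets), plus overall counts.
#' @export
aggregate_battery <- function(decisions, specs = NULL) {
  if (!length(decisions)) stop("no decisions to aggregate")
  df <- decisions_to_df(decisions)
  stages <- c("naive_supported", "spatiophylo_supported", "final_supported")
  per_type <- do.call(rbind, lapply(UNIVERSAL_TYPES, function(tt) {
    sub <- df[df$utype == tt, , drop = FALSE]
    n <- nrow(sub)
    row <- data.frame(utype = tt, n = n)
    for (s in stages) {
      cnt <- if (n) sum(sub[[s]] %in% TRUE) else 0L
      row[[paste0(s, "_count")]] <- cnt
      row[[paste0(s, "_prop")]] <- if (n) cnt / n else NA_real_
    }
    row
  }))
  overall <- vapply(stages, function(s) sum(df[[s]] %in% TRUE), 0L)
  structure(list(per_type = per_type, overall = overall,
                 n_universals = nrow(df),
                 n_errors = sum(df$status != "ok")),
            class = "battery_report")
}

#' @export
print.battery_report <- function(x, ...) {
  cat(sprintf("battery_report: %d universals (%d errors)\n",
              x$n_universals, x$n_errors))
  print(x$per_type, row.names = FALSE)
  invisible(x)
}

#' Compare two sets of per-universal estimates by Spearman correlation
#'
#' Rank correlation with a Fisher-z 95% confidence interval (using the
#' Fieller-Hartley-Pearson standard error `1.03 / sqrt(n - 3)` appropriate
#' for Spearman's statistic) and a two-sided p-value.
#'
#' @param a,b paired numeric vectors (length >= 4).
#' @return list with `spearman_r`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
compare_estimates <- function(a, b) {
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 4) stop("need at least 4 complete pairs")
  if (sd(a) == 0 || sd(b) == 0) stop("constant vector: rank correlation undefined")
  ct <- suppressWarnings(cor.test(a, b, method = "spearman"))
  r <- unname(ct$estimate)
  z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
  se <- 1.03 / sqrt(n - 3)
  ci <- tanh(z + c(-1, 1) * qnorm(0.975) * se)
  list(spearman_r = r, ci_low = ci[1], ci_high = ci[2],
       p = ct$p.value, n = n)
}
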