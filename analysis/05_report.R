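#!/usr/bin/env Rscript
# Stage 5: cross-model comparisons and the final battery report. Compares
# naive against spatiophylogenetic effect estimates (Spearman), checks the
# decisions against the generating truth, and prints the per-type summary.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_scenario.R"))

decisions <- read.delim(file.path(RESULTS_DIR, "decisions.tsv"))
truth <- jsonlite::fromJSON(file.path(RESULTS_DIR, "data", "truth.json"),
                            simplifyVector = FALSE)

cmp <- compare_estimates(decisions$naive_b_median,
                         decisions$spatiophylo_b_median)
message(sprintf(
  "naive vs spatiophylogenetic effect medians: Spearman r = %.2f (95%% CI %.2f-%.2f, p = %.3g, n = %d)",
  cmp$spearman_r, cmp$ci_low, cmp$ci_high, cmp$p, cmp$n))

truth_has_signal <- vapply(names(truth), function(id) {
  m <- truth[[id]]
  (m$type == "ctmc_dependent") || (!is.null(m$b) && m$b != 0)
}, TRUE)
calls <- setNames(decisions$final_supported %in% TRUE, decisions$universal_id)
agree <- calls[names(truth_has_signal)] == truth_has_signal
message(sprintf("final verdicts agree with generating truth for %d/%d universals",
                sum(agree), length(agree)))
for (id in names(agree)[!agree]) {
  message(sprintf("  disagreement on %s (truth: %s)", id,
                  if (truth_has_signal[id]) "signal" else "null"))
}

tab <- read.delim(file.path(RESULTS_DIR, "battery_report.tsv"))
print(tab, row.names = FALSE)
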