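#!/usr/bin/env Rscript
# Stage 1: generate the synthetic battery and write it in the same formats
# a real study would read (trait CSV, metadata CSV, newick tree sample,
# universal specs as YAML, truth record as JSON).

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_scenario.R"))

data_dir <- file.path(RESULTS_DIR, "data")
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

gen <- generate_scenario(battery_scenario())

write_trait_matrix(gen$traits, file.path(data_dir, "traits.csv"))
write.csv(gen$meta, file.path(data_dir, "meta.csv"), row.names = FALSE)
writeLines(vapply(gen$trees$trees, write_newick, ""),
           file.path(data_dir, "trees.nwk"))
writeLines(write_newick(gen$base_tree), file.path(data_dir, "base_tree.nwk"))

specs_yaml <- lapply(gen$specs, function(s) {
  list(id = s$id, utype = s$utype,
       condition = lapply(s$condition, function(l)
         list(feature = l$feature, value = l$value)),
       result = list(feature = s$result$feature, value = s$result$value),
       description = s$description)
})
yaml::write_yaml(specs_yaml, file.path(data_dir, "universals.yaml"))
jsonlite::write_json(gen$truth, file.path(data_dir, "truth.json"),
                     auto_unbox = TRUE, pretty = TRUE)

message(sprintf(
  "simulated %d taxa x %d features (%.1f%% missing), %d trees, %d universals",
  nrow(gen$traits), ncol(gen$traits), 100 * mean(is.na(gen$traits)),
  gen$trees$sample_size, length(gen$specs)))
message(sprintf("macro-areas: %s; families: %d",
                paste(sort(unique(gen$meta$macroarea)), collapse = ", "),
                length(unique(gen$meta$family))))
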