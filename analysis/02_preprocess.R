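#!/usr/bin/env Rscript
# Stage 2: quality control and normalization of the raw miRNA counts.
#
# Probe-background subtraction (entries at or below background become
# missing), 95% feature then sample call-rate filters, removal of probes
# below 15 counts in at least half the samples, minimum-value imputation,
# log2 quantile normalization and ComBat adjustment across cartridges.

suppressMessages(library(mircortex))

out <- "results/analysis"
raw <- read_expression_tsv(file.path(out, "mirna_raw.tsv"))
bgt <- read.delim(file.path(out, "background.tsv"))
background <- setNames(bgt$background, bgt$feature_id)
cohort <- read_covariates_csv(file.path(out, "covariates.csv"))
raw$batch <- setNames(cohort$cartridge, cohort$sample_id)

pre <- preprocess_mirna(raw, background)
for (step in pre$report) {
  message(sprintf("%s: removed %d features, %d samples",
                  step$step, length(step$removed_features),
                  length(step$removed_samples)))
}
message(sprintf("retained %d features x %d samples (state %s)",
                nrow(pre$matrix$values), ncol(pre$matrix$values),
                pre$matrix$state))

write_expression_tsv(pre$matrix, file.path(out, "mirna_processed.tsv"))
jsonlite::write_json(
  lapply(unclass(pre$report), function(s) {
    list(step = s$step, n_features_removed = length(s$removed_features),
         n_samples_removed = length(s$removed_samples),
         thresholds = s$thresholds)
  }),
  file.path(out, "filter_report.json"), auto_unbox = TRUE, digits = NA)
message("stage 2 outputs written")
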