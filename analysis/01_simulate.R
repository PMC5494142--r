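#!/usr/bin/env Rscript
# Stage 1: simulate the study-condition cohort and raw expression data.
#
# Generates a 700-subject aging cohort (mean age 88, 64% female, 61%
# pathologic AD, RIN 2-9 with mean 6.5, correlated NP/NFT burdens), raw
# Nanostring-like miRNA counts for 340 probes (309 expressed + 31 near
# background, processed in cartridges of 96) with one miRNA planted at 6.7%
# of AD variance and AD-depleted, plus miRNA-coupled mRNA with target and
# pathway annotation. All downstream stages read these files.

suppressMessages(library(mircortex))

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20170701
seeds <- split_seed(seed, 3)

truth <- ground_truth(
  effects = data.frame(feature_id = "mir0001", outcome = "ad",
                       frac_var = 0.067, sign = -1),
  repression = data.frame(mirna_id = "mir0001", gene_id = sprintf("tg%02d", 1:5),
                          coef = -0.5)
)

cohort <- generate_cohort(700, seed = seeds[1])
message(sprintf("cohort: n=%d, mean age %.1f, %.0f%% female, %.0f%% pathologic AD, mean RIN %.2f",
                nrow(cohort), mean(cohort$age), 100 * mean(cohort$sex),
                100 * mean(cohort$ad), mean(cohort$rin)))
message(sprintf("NP/NFT correlation: %.2f", cor(cohort$np, cohort$nft)))
write_covariates_csv(cohort, file.path(out, "covariates.csv"))

mir <- generate_mirna_counts(cohort, truth, n_features = 309, seed = seeds[2],
                             params = {
                               p <- mirna_params()
                               p$n_low_features <- 31
                               p
                             })
write_expression_tsv(mir$matrix, file.path(out, "mirna_raw.tsv"))
write.table(data.frame(feature_id = names(mir$background),
                       background = mir$background),
            file.path(out, "background.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

# direct AD effect 0.6 alongside coupling -0.5: the miRNA mediates roughly
# a third of each member gene's AD association rather than all of it
ann <- generate_mrna_and_annotations(cohort, mir$matrix, truth,
                                     n_genes = 400, n_pathways = 200,
                                     seed = seeds[3],
                                     params = mrna_params(direct_ad_effect = 0.6))
write_expression_tsv(ann$mrna, file.path(out, "mrna.tsv"))
write_targets_tsv(ann$targets, file.path(out, "targets.tsv"))
write_gmt(ann$pathways, file.path(out, "pathways.gmt"))

jsonlite::write_json(
  list(seed = seed,
       planted = list(mirna = "mir0001", outcome = "ad", frac_var = 0.067,
                      sign = -1, repressed_genes = sprintf("tg%02d", 1:5),
                      coupling = -0.5)),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
message("stage 1 outputs written to ", out)
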