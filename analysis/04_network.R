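#!/usr/bin/env Rscript
# Stage 4: confounder-aware association network.
#
# Features pass a joint F-test on the three pathology terms (nominal
# p < 0.05), then forward-stepwise BIC selects which variable edges to
# keep; RIN is forced into every model but its edges are suppressed from
# the export. A correlation map over the significant features and the
# outcomes accompanies the edge list.

suppressMessages(library(mircortex))

out <- "results/analysis"
m <- read_expression_tsv(file.path(out, "mirna_processed.tsv"),
                         state = "batch_adjusted")
cohort <- read_covariates_csv(file.path(out, "covariates.csv"))
cohort <- cohort[cohort$sample_id %in% colnames(m$values), ]
assoc <- read.delim(file.path(out, "associations.tsv"))

net <- build_network(m, cohort, assoc = assoc)
message(sprintf("%d of %d features passed the pathology screen; %d edges",
                nrow(net$features), nrow(m$values), nrow(net$edges)))
print(net$edges[net$edges$feature %in%
                  net$features$feature[net$features$label == "significant"], ])
write_edge_list(net, file.path(out, "network_edges.tsv"))

sig_features <- unique(assoc$feature_id[assoc$significant])
if (length(sig_features) >= 2) {
  cm <- correlation_map(m, sig_features, cohort)
  write.table(round(cm, 4), file.path(out, "correlation_map.tsv"),
              sep = "\t", quote = FALSE)
}
message("stage 4 outputs written")
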