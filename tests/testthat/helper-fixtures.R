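# Small fixture builders shared across test files. Everything is generated
# in code; no stored data.

# tiny cohort with all covariate columns, deterministic
tiny_cohort <- function(n = 60, seed = 11, ...) {
  generate_cohort(n, seed = seed, params = cohort_params(...))
}

# plain numeric matrix with dimnames, for container-level tests
toy_matrix <- function(nr = 5, nc = 4, seed = 3, values = NULL) {
  set.seed(seed)
  v <- if (is.null(values)) matrix(rexp(nr * nc, rate = 0.01), nr, nc) else values
  nr <- nrow(v)
  nc <- ncol(v)
  dimnames(v) <- list(sprintf("f%02d", seq_len(nr)), sprintf("S%02d", seq_len(nc)))
  v
}

# raw ExpressionMatrix wrapper around toy_matrix
toy_em <- function(nr = 5, nc = 4, seed = 3, values = NULL, state = "raw",
                   feature_class = "miRNA", batch = NULL) {
  expression_matrix(toy_matrix(nr, nc, seed, values), feature_class = feature_class,
                    batch = batch, state = state)
}

# cohort + planted miRNA matrix + preprocessing in one call
planted_run <- function(n = 300, frac_var = 0.1, seed = 5, n_features = 50,
                        outcome = "ad", combat = TRUE, ...) {
  co <- generate_cohort(n, seed = seed)
  tr <- ground_truth(effects = data.frame(feature_id = "mir0001",
                                          outcome = outcome,
                                          frac_var = frac_var),
                     ...)
  g <- generate_mirna_counts(co, tr, n_features = n_features, seed = seed + 1)
  pre <- preprocess_mirna(g$matrix, g$background, combat = combat)
  co <- co[co$sample_id %in% colnames(pre$matrix$values), ]
  list(cohort = co, processed = pre$matrix, raw = g$matrix,
       background = g$background, report = pre$report, truth = tr)
}
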