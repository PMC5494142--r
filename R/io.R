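#' Read a feature-by-sample expression TSV
#'
#' First column holds feature ids, the header row sample ids; empty cells
#' are missing values. Ragged rows, duplicate ids and non-numeric cells are
#' rejected with the offending location named.
#'
#' @param path Input file.
#' @param feature_class Feature class tag for the container.
#' @param batch Optional per-sample batch labels.
#' @param state Processing-state tag of the stored values.
#' @return An `ExpressionMatrix`.
#' @export
read_expression_tsv <- function(path, feature_class = "miRNA", batch = NULL,
                                state = "raw") {
  lines <- readLines(path)
  if (length(lines) < 2) stop("expression TSV needs a header and >= 1 feature row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1]])
  ragged <- which(vapply(fields, length, integer(1)) != width)
  if (length(ragged) > 0) {
    stop("ragged row at line ", ragged[1], " of ", path)
  }
  header <- fields[[1]]
  sample_ids <- header[-1]
  body <- fields[-1]
  feature_ids <- vapply(body, `[[`, character(1), 1)
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids in ", path)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in ", path)
  cells <- lapply(body, function(f) f[-1])
  vals <- suppressWarnings(vapply(cells, as.numeric, numeric(width - 1)))
  vals <- matrix(vals, ncol = length(feature_ids))   # columns = features here
  bad <- which(is.na(vals) & matrix(unlist(cells) != "", ncol = length(feature_ids)))
  if (length(bad) > 0) {
    stop("non-numeric cell in ", path, " (feature ",
         feature_ids[ceiling(bad[1] / (width - 1))], ")")
  }
  m <- t(vals)
  dimnames(m) <- list(feature_ids, sample_ids)
  expression_matrix(m, feature_class = feature_class, batch = batch, state = state)
}

#' Write an expression matrix as TSV (missing entries as empty cells)
#' @param m `ExpressionMatrix` or plain matrix.
#' @param path Output file.
#' @export
write_expression_tsv <- function(m, path) {
  v <- if (inherits(m, "ExpressionMatrix")) m$values else m
  df <- data.frame(feature_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write / read the per-sample covariate and outcome table
#' @param cohort Cohort `data.frame`.
#' @param path CSV file.
#' @export
write_covariates_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_covariates_csv
#' @export
read_covariates_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a miRNA target table (columns mirna_id, gene_id)
#' @param targets Target `data.frame`.
#' @param path TSV file.
#' @export
write_targets_tsv <- function(targets, path) {
  utils::write.table(targets, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_targets_tsv
#' @export
read_targets_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "gene_id") %in% names(out))) {
    stop("target table must have columns mirna_id and gene_id")
  }
  out
}

#' Write pathway gene sets in GMT format
#'
#' Standard tab-separated layout: set name, description, then member gene
#' ids.
#'
#' @param pathways Named list of gene-id vectors.
#' @param path Output file.
#' @param descriptions Optional per-set description (defaults to `"na"`).
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(pathways))
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(pathways), descriptions, pathways)
  writeLines(lines, path)
  invisible(path)
}

#' Read pathway gene sets from a GMT file
#' @param path GMT file.
#' @return Named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3)
  if (length(short) > 0) stop("malformed GMT line ", short[1], " in ", path)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop("duplicate pathway names in ", path)
  sets
}

#' Write simplified RCC-like per-sample files
#'
#' One sectioned text file per sample: a header block with the sample id,
#' then a `Code_Summary` block of `CodeClass,Name,Count` lines covering the
#' endogenous probes and a set of negative-control probes. This dialect is
#' a documented simplification of vendor raw-count files, sufficient to
#' exercise the reader; it is not a bit-level clone.
#'
#' @param m Raw `ExpressionMatrix` of endogenous counts.
#' @param background Per-feature background levels; negative-control counts
#'   are written so their mean matches each sample's typical background.
#' @param dir Output directory (created if needed).
#' @param n_negatives Number of negative-control probes per file.
#' @return The directory, invisibly.
#' @export
write_rcc_like <- function(m, background, dir, n_negatives = 6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- m$values
  neg_mean <- mean(background)
  for (s in colnames(v)) {
    path <- file.path(dir, paste0(s, ".rcc"))
    con <- file(path, "w")
    writeLines(c("<Header>", paste0("sample_id,", s), "</Header>",
                 "<Code_Summary>", "CodeClass,Name,Count"), con)
    writeLines(sprintf("Endogenous,%s,%d", rownames(v), round(v[, s])), con)
    writeLines(sprintf("Negative,NEG_%s,%d", LETTERS[seq_len(n_negatives)],
                       round(neg_mean)), con)
    writeLines("</Code_Summary>", con)
    close(con)
  }
  invisible(dir)
}

#' Read a directory of simplified RCC-like files
#'
#' Assembles the endogenous counts into a raw feature-by-sample
#' `ExpressionMatrix` (columns ordered by sample id, so file order is
#' irrelevant) and derives a per-feature background level from the
#' negative-control summary (mean negative count across probes and
#' samples, applied to every feature).
#'
#' @param dir Directory of `.rcc` files.
#' @return List with `matrix` (raw `ExpressionMatrix`) and `background`.
#' @export
read_rcc_like <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.rcc$", full.names = TRUE))
  if (length(files) == 0) stop("no .rcc files in ", dir)
  per_sample <- lapply(files, function(path) {
    lines <- readLines(path)
    hdr <- grep("^sample_id,", lines, value = TRUE)
    if (length(hdr) != 1) stop("missing header section in ", path)
    sid <- sub("^sample_id,", "", hdr)
    start <- which(lines == "<Code_Summary>")
    end <- which(lines == "</Code_Summary>")
    if (length(start) != 1 || length(end) != 1) {
      stop("missing Code_Summary section in ", path)
    }
    body <- lines[(start + 2):(end - 1)]
    parts <- strsplit(body, ",", fixed = TRUE)
    cls <- vapply(parts, `[[`, character(1), 1)
    nm <- vapply(parts, `[[`, character(1), 2)
    cnt_chr <- vapply(parts, `[[`, character(1), 3)
    cnt <- suppressWarnings(as.integer(cnt_chr))
    if (anyNA(cnt)) stop("count not an integer in ", path)
    if (!any(cls == "Negative")) stop("no Negative class probes in ", path)
    list(sid = sid, endo = stats::setNames(cnt[cls == "Endogenous"], nm[cls == "Endogenous"]),
         neg = cnt[cls == "Negative"])
  })
  sids <- vapply(per_sample, `[[`, character(1), "sid")
  ord <- order(sids)
  per_sample <- per_sample[ord]
  features <- names(per_sample[[1]]$endo)
  v <- vapply(per_sample, function(s) unname(s$endo[features]), numeric(length(features)))
  v <- matrix(v, nrow = length(features),
              dimnames = list(features, sids[ord]))
  bg <- mean(unlist(lapply(per_sample, `[[`, "neg")))
  list(matrix = expression_matrix(v, feature_class = "miRNA", state = "raw"),
       background = stats::setNames(rep(bg, length(features)), features))
}

#' Pipeline configuration with documented defaults
#'
#' @param seed Master seed for every random stage.
#' @param n_samples,n_features,n_low_features Cohort and matrix dimensions.
#' @param n_genes,n_pathways mRNA/annotation dimensions.
#' @param call_rate,min_value,low_frac,lincrna_min_expected Filter settings.
#' @param screen_alpha,bonferroni_alpha Significance settings.
#' @param fixed_threshold Optional fixed per-test threshold reused across
#'   feature classes (mimics reusing one printed cutoff); `NULL` (default)
#'   uses the per-class Bonferroni computation.
#' @param direction_convention Passed to [rank_mir_pathways()].
#' @param top_k miR-pathways reported in the summary.
#' @param cohort,truth,mirna,mrna Parameter lists for the generators.
#' @return A `pipeline_config` list; round-trips through
#'   [jsonlite::toJSON()]-compatible serialization unchanged.
#' @export
pipeline_config <- function(seed = 1L, n_samples = 700, n_features = 309,
                            n_low_features = 31, n_genes = 300, n_pathways = 50,
                            call_rate = 0.95, min_value = 15, low_frac = 0.5,
                            lincrna_min_expected = 5,
                            screen_alpha = 0.05, bonferroni_alpha = 0.05,
                            fixed_threshold = NULL,
                            direction_convention = "opposite", top_k = 8,
                            cohort = cohort_params(), truth = NULL,
                            mirna = mirna_params(), mrna = mrna_params()) {
  stopifnot(call_rate > 0, call_rate <= 1, low_frac > 0, low_frac <= 1,
            screen_alpha > 0, screen_alpha < 1,
            bonferroni_alpha > 0, bonferroni_alpha < 1,
            min_value >= 0, lincrna_min_expected >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline: simulate, preprocess, associate, network, integrate
#'
#' Executes every stage in order on a synthetic cohort defined by the
#' config, writes each stage's table under `out_dir` and a versioned JSON
#' summary (`summary.json`) with the feature/sample counts at every step,
#' the significant features per outcome, the network edge list, the top-k
#' miR-pathways and every threshold used. A structured log records the
#' model formula of each fit family.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return The summary list, invisibly; all artifacts are on disk.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- split_seed(config$seed, 3)
  log_lines <- c(sprintf("seed: %d", config$seed))

  truth <- if (is.null(config$truth)) default_pipeline_truth(config) else config$truth
  cohort <- generate_cohort(config$n_samples, seeds[1], config$cohort)
  mp <- config$mirna
  mp$n_low_features <- config$n_low_features
  gen <- generate_mirna_counts(cohort, truth, config$n_features, seeds[2], mp)
  write_covariates_csv(cohort, file.path(out_dir, "covariates.csv"))
  write_expression_tsv(gen$matrix, file.path(out_dir, "mirna_raw.tsv"))

  pre <- preprocess_mirna(gen$matrix, gen$background,
                          call_rate = config$call_rate,
                          min_value = config$min_value,
                          low_frac = config$low_frac)
  cohort_kept <- cohort[cohort$sample_id %in% colnames(pre$matrix$values), ]
  write_expression_tsv(pre$matrix, file.path(out_dir, "mirna_processed.tsv"))
  log_lines <- c(log_lines,
                 sprintf("association formula: expression ~ outcome + %s",
                         paste(default_covariates(), collapse = " + ")))

  assoc <- associate_all(pre$matrix, cohort_kept,
                         alpha = config$bonferroni_alpha,
                         threshold = config$fixed_threshold)
  utils::write.table(assoc, file.path(out_dir, "associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sens <- covariate_sensitivity(pre$matrix, cohort_kept)
  utils::write.table(sens, file.path(out_dir, "sensitivity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  net <- build_network(pre$matrix, cohort_kept,
                       screen_alpha = config$screen_alpha, assoc = assoc)
  write_edge_list(net, file.path(out_dir, "network_edges.tsv"))
  log_lines <- c(log_lines,
                 "network formula: expression ~ age + nnls + sex + study + pmi + rin + np + nft + ad",
                 sprintf("network screen alpha: %g", config$screen_alpha))

  ann <- generate_mrna_and_annotations(cohort, gen$matrix, truth,
                                       n_genes = config$n_genes,
                                       n_pathways = config$n_pathways,
                                       seed = seeds[3], params = config$mrna)
  write_targets_tsv(ann$targets, file.path(out_dir, "targets.tsv"))
  write_gmt(ann$pathways, file.path(out_dir, "pathways.gmt"))
  mrna_kept <- ann$mrna
  mrna_kept$values <- mrna_kept$values[, cohort_kept$sample_id, drop = FALSE]
  gene_assoc <- associate_all(mrna_kept, cohort_kept, outcomes = "ad")
  mp_tab <- build_mir_pathways(ann$targets, ann$pathways)
  ranked <- rank_mir_pathways(assoc[assoc$outcome == "ad", ], gene_assoc, mp_tab,
                              direction_convention = config$direction_convention)
  utils::write.table(ranked, file.path(out_dir, "mir_pathways.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sig <- assoc[assoc$significant, c("feature_id", "outcome", "p")]
  summary <- list(
    schema_version = "1.0",
    seed = config$seed,
    counts = list(
      samples_simulated = config$n_samples,
      features_simulated = config$n_features + config$n_low_features,
      features_after_call_rate = length(pre$report$call_rate$retained_features),
      samples_after_call_rate = length(pre$report$call_rate$retained_samples),
      features_retained = nrow(pre$matrix$values),
      samples_retained = ncol(pre$matrix$values)
    ),
    thresholds = list(
      call_rate = config$call_rate, min_value = config$min_value,
      low_frac = config$low_frac, screen_alpha = config$screen_alpha,
      bonferroni_alpha = config$bonferroni_alpha,
      per_test_threshold = attr(assoc, "threshold")
    ),
    significant = split(sig$feature_id, sig$outcome),
    network_edges = net$edges,
    top_mir_pathways = utils::head(
      ranked[, c("mirna_id", "pathways", "direction", "score", "genes")],
      config$top_k)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(summary)
}

#' Default planted truth for the end-to-end pipeline run
#' @noRd
default_pipeline_truth <- function(config) {
  ground_truth(
    effects = data.frame(feature_id = "mir0001", outcome = "ad",
                         frac_var = 0.067, stringsAsFactors = FALSE),
    repression = data.frame(mirna_id = "mir0001",
                            gene_id = sprintf("tg%02d", 1:5),
                            coef = -0.5, stringsAsFactors = FALSE)
  )
}
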