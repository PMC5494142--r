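#' Subtract per-probe background levels
#'
#' Raw counts are adjusted by subtracting each probe's constant background;
#' measurements at or below their background are treated as not called
#' (missing). Thresholding instead of subtracting is available because
#' platform guidelines permit both conventions.
#'
#' @param raw Raw `ExpressionMatrix`.
#' @param background Named numeric vector of non-negative background levels,
#'   one per feature of `raw`.
#' @param mode `"subtract"` (default) replaces values by `value - background`
#'   where above background; `"threshold"` keeps values unchanged but still
#'   marks entries at or below background as missing.
#' @return Background-adjusted `ExpressionMatrix`.
#' @export
adjust_background <- function(raw, background, mode = c("subtract", "threshold")) {
  mode <- match.arg(mode)
  em_require_state(raw, "raw", "adjust_background")
  if (any(background < 0)) stop("negative background")
  missing_bg <- setdiff(rownames(raw$values), names(background))
  if (length(missing_bg) > 0) {
    stop("background undefined for features: ", paste(missing_bg, collapse = ", "))
  }
  bg <- background[rownames(raw$values)]
  v <- raw$values
  below <- !is.na(v) & v <= bg
  if (mode == "subtract") v <- v - bg
  v[below] <- NA_real_
  raw$values <- v
  em_set_state(raw, "background_adjusted")
}

#' Remove features, then samples, with call rate below threshold
#'
#' Call rate is the fraction of non-missing measurements. Features are
#' filtered first, then samples are re-assessed on the retained features;
#' the order matters and is fixed.
#'
#' @param m Background-adjusted `ExpressionMatrix`.
#' @param feature_rate,sample_rate Minimum retained call rate, in `(0, 1]`.
#' @return List with the filtered `matrix` and a `report` ([filter_report()]).
#' @export
filter_by_call_rate <- function(m, feature_rate = 0.95, sample_rate = 0.95) {
  em_require_state(m, c("background_adjusted", "filtered"), "filter_by_call_rate")
  if (feature_rate <= 0 || feature_rate > 1 || sample_rate <= 0 || sample_rate > 1) {
    stop("call rates must be in (0, 1]")
  }
  v <- m$values
  f_rate <- rowMeans(!is.na(v))
  keep_f <- f_rate >= feature_rate
  v <- v[keep_f, , drop = FALSE]
  s_rate <- colMeans(!is.na(v))
  keep_s <- s_rate >= sample_rate
  report <- filter_report(
    "call_rate",
    removed_features = rownames(m$values)[!keep_f],
    retained_features = rownames(m$values)[keep_f],
    removed_samples = colnames(v)[!keep_s],
    retained_samples = colnames(v)[keep_s],
    thresholds = list(feature_rate = feature_rate, sample_rate = sample_rate)
  )
  m$values <- v[, keep_s, drop = FALSE]
  if (!is.null(m$batch)) m$batch <- m$batch[colnames(m$values)]
  m <- em_set_state(m, "filtered")
  list(matrix = m, report = report)
}

#' Remove features with negligible expression
#'
#' A feature is removed when its value is below `min_value` in at least
#' `frac` of the samples. Missing entries (below background, hence
#' unexpressed) count as below `min_value`. The boundary is inclusive: a
#' feature low in exactly `frac` of samples is removed.
#'
#' @param m Call-rate-filtered `ExpressionMatrix`.
#' @param min_value Expression floor (default 15 counts).
#' @param frac Fraction of samples that must reach the floor.
#' @return List with the filtered `matrix` and a `report`.
#' @export
filter_low_expression <- function(m, min_value = 15, frac = 0.5) {
  em_require_state(m, "filtered", "filter_low_expression")
  if (min_value < 0) stop("min_value must be non-negative")
  v <- m$values
  low_frac <- rowMeans(is.na(v) | v < min_value)
  keep <- low_frac < frac
  report <- filter_report(
    "low_expression",
    removed_features = rownames(v)[!keep],
    retained_features = rownames(v)[keep],
    retained_samples = colnames(v),
    thresholds = list(min_value = min_value, frac = frac)
  )
  m$values <- v[keep, , drop = FALSE]
  list(matrix = m, report = report)
}

#' Remove lowly expressed lincRNA by mean expected count
#'
#' Features whose mean expected count is strictly below `min_expected` are
#' removed (a mean of exactly `min_expected` is retained).
#'
#' @param counts `ExpressionMatrix` of lincRNA expected counts.
#' @param min_expected Minimum mean expected count (default 5).
#' @return List with the filtered `matrix` (state `"filtered"`) and a
#'   `report`.
#' @export
filter_lincrna <- function(counts, min_expected = 5) {
  if (counts$feature_class != "lincRNA") stop("feature class must be lincRNA")
  if (min_expected < 0) stop("min_expected must be non-negative")
  v <- counts$values
  keep <- rowMeans(v, na.rm = TRUE) >= min_expected
  report <- filter_report(
    "lincrna_low_count",
    removed_features = rownames(v)[!keep],
    retained_features = rownames(v)[keep],
    retained_samples = colnames(v),
    thresholds = list(min_expected = min_expected)
  )
  counts$values <- v[keep, , drop = FALSE]
  counts$state <- "filtered"
  list(matrix = counts, report = report)
}

#' Impute remaining missing entries to the per-feature minimum
#'
#' After the call-rate and low-expression filters at most a small fraction
#' of entries remain missing; they are set to the smallest observed value of
#' their feature (an unexpressed-floor convention) so normalization can
#' operate on a complete grid.
#'
#' @param m Filtered `ExpressionMatrix`.
#' @return `ExpressionMatrix` with no missing entries.
#' @export
impute_feature_minimum <- function(m) {
  v <- m$values
  if (anyNA(v)) {
    mins <- apply(v, 1, min, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- mins[idx[, 1]]
    m$values <- v
  }
  m
}

#' Quantile-normalize samples on the log2 scale
#'
#' Values are log2(x + 1)-transformed (the working scale for all downstream
#' modeling) and each sample column is mapped to the across-sample mean of
#' order statistics, so every column shares the identical sorted vector.
#' Ties are resolved by averaging tied order statistics. Missing entries
#' must have been imputed first.
#'
#' @param m Filtered `ExpressionMatrix` with no missing entries.
#' @param log2_transform Apply the log2(x + 1) transform first (default
#'   `TRUE`; set `FALSE` if the input is already on the working scale).
#' @return Normalized `ExpressionMatrix`.
#' @export
quantile_normalize <- function(m, log2_transform = TRUE) {
  em_require_state(m, c("filtered", "normalized"), "quantile_normalize")
  if (ncol(m$values) < 2) stop("quantile normalization needs >= 2 samples")
  if (anyNA(m$values)) stop("impute missing entries before normalization")
  v <- m$values
  if (log2_transform) v <- log2(v + 1)
  out <- limma::normalizeQuantiles(v, ties = TRUE)
  dimnames(out) <- dimnames(v)
  m$values <- out
  em_set_state(m, "normalized")
}

#' Empirical-Bayes batch adjustment (ComBat)
#'
#' Parametric location/scale adjustment: per-feature standardization given
#' any supplied covariate design, batch location and scale estimated and
#' shrunk toward across-feature moment priors, then removed; covariate
#' effects are restored. Delegates to the reference parametric
#' implementation.
#'
#' @param m Normalized `ExpressionMatrix` with a batch label, or an explicit
#'   `batch` argument.
#' @param batch Optional per-sample batch labels (defaults to `m$batch`).
#' @param covariates Optional model matrix (without intercept) of biological
#'   covariates to protect during adjustment; default batch-only.
#' @return Batch-adjusted `ExpressionMatrix`.
#' @export
combat_adjust <- function(m, batch = NULL, covariates = NULL) {
  em_require_state(m, "normalized", "combat_adjust")
  if (is.null(batch)) batch <- m$batch
  if (is.null(batch)) stop("no batch labels available")
  batch <- as.character(batch)
  tab <- table(batch)
  if (length(tab) < 2) stop("combat_adjust needs >= 2 batches")
  if (any(tab < 2)) {
    stop("every batch needs >= 2 samples (offending: ",
         paste(names(tab)[tab < 2], collapse = ", "), ")")
  }
  mod <- NULL
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    mod <- stats::model.matrix(~., data = as.data.frame(covariates))
    if (qr(cbind(mod, stats::model.matrix(~batch)))$rank <
        (ncol(mod) + length(tab) - 1)) {
      stop("batch is confounded with the supplied covariates (singular design)")
    }
  }
  adj <- suppressMessages(sva::ComBat(dat = m$values, batch = batch, mod = mod,
                                      par.prior = TRUE, prior.plots = FALSE,
                                      BPPARAM = BiocParallel::SerialParam()))
  dimnames(adj) <- dimnames(m$values)
  m$values <- adj
  em_set_state(m, "batch_adjusted")
}

#' Run the full miRNA preprocessing chain
#'
#' Background adjustment, feature/sample call-rate filters, low-expression
#' filter, minimum-value imputation, log2 quantile normalization and
#' cartridge batch adjustment, collecting a step-by-step filter report.
#'
#' @param raw Raw miRNA `ExpressionMatrix` (with batch labels for the final
#'   step).
#' @param background Per-feature background levels.
#' @param call_rate Feature and sample call-rate threshold.
#' @param min_value,low_frac Low-expression filter settings.
#' @param combat Apply batch adjustment (default `TRUE`; set `FALSE` for
#'   batch-free data).
#' @param background_mode Passed to [adjust_background()].
#' @return List with `matrix` (processed) and `report` (all steps).
#' @export
preprocess_mirna <- function(raw, background, call_rate = 0.95,
                             min_value = 15, low_frac = 0.5, combat = TRUE,
                             background_mode = "subtract") {
  m <- adjust_background(raw, background, mode = background_mode)
  cr <- filter_by_call_rate(m, call_rate, call_rate)
  le <- filter_low_expression(cr$matrix, min_value, low_frac)
  m <- impute_feature_minimum(le$matrix)
  m <- quantile_normalize(m)
  if (combat) m <- combat_adjust(m)
  list(matrix = m, report = c(cr$report, le$report))
}

#' Run the lincRNA preprocessing chain
#'
#' Low-expected-count filter, then the same log2 quantile normalization and
#' (optional) batch adjustment as for miRNA.
#'
#' @inheritParams preprocess_mirna
#' @param counts Raw lincRNA expected-count `ExpressionMatrix`.
#' @param min_expected Minimum mean expected count.
#' @return List with `matrix` and `report`.
#' @export
preprocess_lincrna <- function(counts, min_expected = 5, combat = TRUE) {
  fl <- filter_lincrna(counts, min_expected)
  m <- impute_feature_minimum(fl$matrix)
  m <- quantile_normalize(m)
  if (combat) m <- combat_adjust(m)
  list(matrix = m, report = fl$report)
}
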