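#' Expression matrix container
#'
#' A lightweight container for a feature-by-sample expression grid with an
#' explicit missingness convention (`NA` entries), a feature-class label and
#' a per-sample batch (cartridge) label. A processing-state tag records how
#' far the matrix has moved through the preprocessing chain; operations
#' check it so stages can only be applied in pipeline order.
#'
#' @param values Numeric matrix, features as rows (rownames = feature ids),
#'   samples as columns (colnames = sample ids). `NA` marks a missing
#'   (e.g. below-background) measurement.
#' @param feature_class One of `"miRNA"`, `"lincRNA"`, `"mRNA"`.
#' @param batch Optional per-sample batch label (character/factor, length =
#'   number of samples), e.g. the Nanostring cartridge.
#' @param state Processing state, one of `"raw"`, `"background_adjusted"`,
#'   `"filtered"`, `"normalized"`, `"batch_adjusted"`.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, feature_class = c("miRNA", "lincRNA", "mRNA"),
                              batch = NULL, state = "raw") {
  feature_class <- match.arg(feature_class)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have rownames (feature ids) and colnames (sample ids)")
  }
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (!state %in% em_states()) stop("unknown state: ", state)
  if (!is.null(batch)) {
    batch <- as.character(batch)
    if (length(batch) != ncol(values)) stop("batch length must equal sample count")
    names(batch) <- colnames(values)
  }
  structure(
    list(values = values, feature_class = feature_class,
         batch = batch, state = state),
    class = "ExpressionMatrix"
  )
}

em_states <- function() {
  c("raw", "background_adjusted", "filtered", "normalized", "batch_adjusted")
}

#' @noRd
em_require_state <- function(m, allowed, op) {
  if (!m$state %in% allowed) {
    stop(sprintf("%s requires state in {%s}, got '%s'",
                 op, paste(allowed, collapse = ", "), m$state))
  }
  invisible(m)
}

#' Advance the processing-state tag; states only move forward
#' @noRd
em_set_state <- function(m, state) {
  states <- em_states()
  if (match(state, states) < match(m$state, states)) {
    stop("processing state can only advance (", m$state, " -> ", state, ")")
  }
  m$state <- state
  m
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d %s features x %d samples [state: %s]\n",
              nrow(x$values), x$feature_class, ncol(x$values), x$state))
  cat(sprintf("  missing entries: %d (%.2f%%)\n", sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  if (!is.null(x$batch)) {
    cat("  batches:", paste(names(table(x$batch)), table(x$batch),
                            sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Per-step record of what a filter removed and why
#'
#' @param step Name of the filtering step.
#' @param removed_features,retained_features Character vectors of feature ids.
#' @param removed_samples,retained_samples Character vectors of sample ids.
#' @param thresholds Named list of threshold values used.
#' @return A `FilterReport` object (one step). Reports from successive steps
#'   combine with [c()] into a multi-step report.
#' @export
filter_report <- function(step, removed_features = character(),
                          retained_features = character(),
                          removed_samples = character(),
                          retained_samples = character(),
                          thresholds = list()) {
  rep <- list(list(
    step = step,
    removed_features = removed_features,
    retained_features = retained_features,
    removed_samples = removed_samples,
    retained_samples = retained_samples,
    thresholds = thresholds
  ))
  names(rep) <- step
  structure(rep, class = "FilterReport")
}

#' @export
c.FilterReport <- function(...) {
  out <- NextMethod()
  structure(out, class = "FilterReport")
}

#' @export
print.FilterReport <- function(x, ...) {
  for (s in x) {
    cat(sprintf("%s: removed %d features, %d samples (retained %d x %d)\n",
                s$step, length(s$removed_features), length(s$removed_samples),
                length(s$retained_features), length(s$retained_samples)))
  }
  invisible(x)
}
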