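#' Variable sets used by the network models
#' @noRd
network_candidates <- function() {
  sort(c("age", "nnls", "sex", "study", "pmi", "np", "nft", "ad"))
}

#' Joint F-test screen for any pathology effect
#'
#' Fits expression on age, neuronal proportion, sex, study, PMI, RIN and
#' all three pathology terms (NP, NFT, AD) jointly, and tests the pathology
#' block with a partial F-test against the model without it. Features enter
#' the network only if this test is nominally significant.
#'
#' @param expr One feature's expression values.
#' @param cohort Cohort `data.frame`.
#' @param covariates Non-pathology covariates (default includes RIN).
#' @param pathology Pathology variable names (default `np`, `nft`, `ad`).
#' @return List with `F`, `p`, `df1`, `df2`.
#' @export
screen_pathology <- function(expr, cohort,
                             covariates = default_covariates(),
                             pathology = c("np", "nft", "ad")) {
  X_red <- cbind(1, as.matrix(cohort[covariates]))
  X_full <- cbind(X_red, as.matrix(cohort[pathology]))
  if (qr(X_full)$rank < ncol(X_full)) stop("singular design")
  rss <- function(X) {
    sum(stats::lm.fit(X, expr)$residuals^2)
  }
  rss_full <- rss(X_full)
  rss_red <- rss(X_red)
  df1 <- length(pathology)
  df2 <- length(expr) - ncol(X_full)
  Fstat <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Gaussian BIC of an OLS fit
#' @noRd
bic_ols <- function(y, X) {
  n <- length(y)
  rss <- sum(stats::lm.fit(X, y)$residuals^2)
  n * log(rss / n) + ncol(X) * log(n)
}

#' Forward-stepwise BIC variable selection with forced terms
#'
#' Starting from the forced model (intercept plus forced covariates, RIN by
#' default so every model stays RIN-adjusted), repeatedly adds the
#' candidate giving the largest BIC decrease and stops when no addition
#' decreases BIC. `BIC = n * ln(RSS / n) + k * ln(n)` with `k` the number
#' of estimated coefficients. Ties in BIC decrease are broken by candidate
#' order (alphabetical by default), deterministically.
#'
#' @param y Feature expression values.
#' @param data `data.frame` holding candidates and forced variables.
#' @param candidates Candidate variable names (default the eight
#'   demographic/technical/pathology variables).
#' @param forced Variables forced into every model (default `"rin"`).
#' @return List with `selected` (ordered as added), `coefficients` (named,
#'   from the final model, forced terms and intercept excluded), `sign`,
#'   `bic_path` (BIC after each accepted step, starting at the forced
#'   model) and `bic` (final).
#' @export
forward_stepwise_bic <- function(y, data, candidates = network_candidates(),
                                 forced = "rin") {
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (length(forced) > 0) X <- cbind(X, as.matrix(data[forced]))
  if (n < ncol(X) + 1) stop("too few observations for the forced model")
  remaining <- candidates
  selected <- character()
  bic_path <- bic_ols(y, X)
  repeat {
    if (length(remaining) == 0) break
    bics <- vapply(remaining, function(v) {
      bic_ols(y, cbind(X, as.matrix(data[v])))
    }, numeric(1))
    best <- which.min(bics)      # first minimum wins: candidate-order tie-break
    if (bics[best] >= bic_path[length(bic_path)]) break
    v <- remaining[best]
    X <- cbind(X, as.matrix(data[v]))
    selected <- c(selected, v)
    remaining <- setdiff(remaining, v)
    bic_path <- c(bic_path, unname(bics[best]))
  }
  coefs <- stats::lm.fit(X, y)$coefficients
  sel_coefs <- coefs[selected]
  list(selected = selected,
       coefficients = sel_coefs,
       sign = ifelse(sel_coefs >= 0, "+", "-"),
       bic_path = bic_path,
       bic = bic_path[length(bic_path)])
}

#' Exhaustive best-subset BIC search (oracle-scale inputs only)
#'
#' Evaluates every subset of the candidates on top of the forced model and
#' returns the subset with minimal BIC. Intended as an independent check of
#' forward selection on small candidate sets.
#'
#' @inheritParams forward_stepwise_bic
#' @return List with `selected` (sorted) and `bic`.
#' @export
best_subset_bic <- function(y, data, candidates = network_candidates(),
                            forced = "rin") {
  n <- length(y)
  base <- cbind(`(Intercept)` = rep(1, n))
  if (length(forced) > 0) base <- cbind(base, as.matrix(data[forced]))
  k <- length(candidates)
  best <- list(selected = character(), bic = bic_ols(y, base))
  for (mask in seq_len(2^k - 1)) {
    subset <- candidates[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
    b <- bic_ols(y, cbind(base, as.matrix(data[subset])))
    if (b < best$bic) best <- list(selected = sort(subset), bic = b)
  }
  best
}

#' Build the feature-variable association network
#'
#' Screens every feature with the joint pathology F-test, runs
#' forward-stepwise BIC selection for each screened feature, and assembles
#' the bipartite network of feature-variable edges. RIN is forced into
#' every model but its edges are suppressed from the exported network.
#' Features are annotated `significant` or `suggestive` from their marginal
#' Bonferroni-flagged associations.
#'
#' @inheritParams associate_all
#' @param screen_alpha Nominal F-test threshold for inclusion (default 0.05).
#' @param assoc Optional precomputed [associate_all()] table (recomputed if
#'   omitted).
#' @return An `ncrna_network`: list with `edges` (`data.frame`: `feature`,
#'   `variable`, `sign`, `beta`, `bic`), `features` (screen statistics and
#'   significance label) and `variables`.
#' @export
build_network <- function(m, cohort, screen_alpha = 0.05,
                          covariates = default_covariates(),
                          assoc = NULL, threshold = NULL) {
  Y <- if (inherits(m, "ExpressionMatrix")) m$values else m
  stopifnot(identical(colnames(Y), cohort$sample_id))
  if (is.null(assoc)) {
    assoc <- associate_all(m, cohort, covariates = covariates, threshold = threshold)
  }
  sig_features <- unique(assoc$feature_id[assoc$significant])

  screen <- lapply(rownames(Y), function(f) {
    s <- screen_pathology(Y[f, ], cohort, covariates)
    data.frame(feature = f, F = s$F, p_screen = s$p, stringsAsFactors = FALSE)
  })
  screen <- do.call(rbind, screen)
  screen$passed <- screen$p_screen < screen_alpha
  screen$label <- ifelse(screen$feature %in% sig_features, "significant", "suggestive")

  # candidate data on the same scale as association models
  data <- cohort
  data$np <- as.numeric(scale(data$np))
  data$nft <- as.numeric(scale(data$nft))

  edges <- list()
  for (f in screen$feature[screen$passed]) {
    sw <- forward_stepwise_bic(Y[f, ], data)
    keep <- setdiff(sw$selected, "rin")   # RIN in the model, not in the export
    if (length(keep) > 0) {
      edges[[f]] <- data.frame(
        feature = f, variable = keep,
        sign = sw$sign[keep], beta = unname(sw$coefficients[keep]),
        bic = sw$bic, stringsAsFactors = FALSE, row.names = NULL
      )
    }
  }
  edges <- if (length(edges) > 0) {
    do.call(rbind, c(edges, list(make.row.names = FALSE)))
  } else {
    data.frame(feature = character(), variable = character(),
               sign = character(), beta = numeric(), bic = numeric(),
               stringsAsFactors = FALSE)
  }
  structure(list(edges = edges,
                 features = screen[screen$passed, , drop = FALSE],
                 variables = network_candidates(),
                 screen_alpha = screen_alpha),
            class = "ncrna_network")
}

#' @export
print.ncrna_network <- function(x, ...) {
  cat(sprintf("ncrna_network: %d features passed the pathology screen, %d edges\n",
              nrow(x$features), nrow(x$edges)))
  invisible(x)
}

#' Export a network's edge list as TSV
#' @param net An `ncrna_network`.
#' @param path Output file.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Re-import an edge list written by [write_edge_list()]
#' @param path Edge-list TSV.
#' @return `data.frame` with the exported columns.
#' @export
read_edge_list <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(feature = "character", variable = "character",
                                   sign = "character", beta = "numeric",
                                   bic = "numeric"))
}

#' Pairwise correlation map of features and outcomes
#'
#' Pearson correlations over pairwise-complete observations between the
#' selected features' expression profiles and the outcome variables.
#'
#' @param m `ExpressionMatrix` or plain matrix.
#' @param features Feature ids to include (>= 2).
#' @param cohort Cohort `data.frame`.
#' @param outcomes Outcome columns to append (default `np`, `nft`, `ad`).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_map <- function(m, features, cohort, outcomes = c("np", "nft", "ad")) {
  Y <- if (inherits(m, "ExpressionMatrix")) m$values else m
  if (length(features) < 2) stop("need >= 2 features")
  block <- t(Y[features, , drop = FALSE])
  block <- cbind(block, as.matrix(cohort[outcomes]))
  sds <- apply(block, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0)) stop("zero-variance feature: ",
                          paste(colnames(block)[sds == 0], collapse = ", "))
  stats::cor(block, use = "pairwise.complete.obs")
}
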