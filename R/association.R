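#' Default covariate set for all adjusted models
#' @return Character vector of cohort column names.
#' @export
default_covariates <- function() c("age", "sex", "study", "nnls", "pmi", "rin")

#' Bonferroni per-test threshold
#'
#' @param n_tests Number of tests in the family (>= 1).
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  alpha / n_tests
}

#' Core OLS fit of expression on outcome plus covariates
#'
#' Expression is the response and the outcome the predictor of interest
#' (first non-intercept column); the partial variance explained is the
#' squared partial correlation `t^2 / (t^2 + df)`, which is symmetric in
#' response/predictor while the coefficient is not.
#'
#' @param expr Numeric vector of one feature's expression values.
#' @param outcome Numeric outcome vector (`ad` coded 0/1).
#' @param covariates Optional `data.frame`/matrix of adjustment covariates.
#' @param outcome_name Label stored in the result.
#' @param feature_id Label stored in the result.
#' @return One-row `data.frame`: `feature_id`, `outcome`, `beta`, `se`, `z`
#'   (= beta / se, t-distributed with residual df), `p` (two-sided), `r2`
#'   (partial variance explained), `n` (complete cases used).
#' @export
fit_association <- function(expr, outcome, covariates = NULL,
                            outcome_name = "ad", feature_id = NA_character_) {
  X <- cbind(`(Intercept)` = 1, outcome = outcome)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  cc <- stats::complete.cases(cbind(expr, X))
  y <- expr[cc]
  X <- X[cc, , drop = FALSE]
  if (nrow(X) < ncol(X) + 1) stop("too few complete cases for the model")
  if (stats::sd(y) == 0) stop("zero-variance expression")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("singular design")
  fit <- ols_stats(matrix(y, nrow = 1), X)
  data.frame(feature_id = feature_id, outcome = outcome_name,
             beta = fit$beta, se = fit$se, z = fit$z, p = fit$p,
             r2 = fit$r2, n = nrow(X), stringsAsFactors = FALSE)
}

#' Vectorized OLS of many features on a shared design
#'
#' @param Y Features-by-samples matrix with no missing entries.
#' @param X Design matrix (first column intercept, second the outcome).
#' @return List of per-feature vectors `beta`, `se`, `z`, `p`, `r2` for the
#'   outcome column, plus `df`.
#' @noRd
ols_stats <- function(Y, X) {
  C <- chol2inv(chol(crossprod(X)))
  B <- Y %*% X %*% C                      # features x k coefficients
  resid <- Y - B %*% t(X)
  df <- nrow(X) - ncol(X)
  sigma2 <- rowSums(resid^2) / df
  se <- sqrt(sigma2 * C[2, 2])
  beta <- B[, 2]
  z <- beta / se
  p <- 2 * stats::pt(-abs(z), df)
  r2 <- z^2 / (z^2 + df)
  list(beta = beta, se = se, z = z, p = p, r2 = r2, df = df)
}

#' @noRd
build_design <- function(cohort, outcome, covariates, standardize_outcomes) {
  y <- cohort[[outcome]]
  if (is.null(y)) stop("unknown outcome: ", outcome)
  if (standardize_outcomes && outcome %in% c("np", "nft")) y <- as.numeric(scale(y))
  X <- cbind(`(Intercept)` = 1, outcome = y)
  if (length(covariates) > 0) {
    missing_cov <- setdiff(covariates, names(cohort))
    if (length(missing_cov) > 0) stop("unknown covariates: ",
                                      paste(missing_cov, collapse = ", "))
    X <- cbind(X, as.matrix(cohort[covariates]))
  }
  X
}

#' Associate every feature with each pathology outcome
#'
#' Fits, for each feature and each requested outcome, an ordinary linear
#' model of expression on the outcome adjusted for the covariates, and
#' flags results against a Bonferroni threshold whose family is the set of
#' features of one class tested against one outcome. NP and NFT are
#' z-scaled by default so coefficients are comparable across outcomes; AD
#' stays 0/1.
#'
#' @param m `ExpressionMatrix` (preprocessed) or plain features-by-samples
#'   matrix on the working scale.
#' @param cohort Cohort `data.frame` aligned to the matrix columns by
#'   `sample_id`.
#' @param outcomes Outcomes to test (subset of `np`, `nft`, `ad`).
#' @param covariates Adjustment covariate names (default
#'   [default_covariates()]).
#' @param standardize_outcomes z-scale NP/NFT (default `TRUE`).
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @param threshold Optional fixed per-test threshold overriding the
#'   per-class Bonferroni computation (e.g. a study-specific printed
#'   cutoff reused across feature classes).
#' @return Long-format `data.frame` of [fit_association()] rows with a
#'   `significant` flag, one row per feature x outcome.
#' @export
associate_all <- function(m, cohort, outcomes = c("np", "nft", "ad"),
                          covariates = default_covariates(),
                          standardize_outcomes = TRUE,
                          alpha = 0.05, threshold = NULL) {
  Y <- if (inherits(m, "ExpressionMatrix")) m$values else m
  if (nrow(Y) == 0) stop("empty expression matrix")
  stopifnot(identical(colnames(Y), cohort$sample_id))
  thr <- if (is.null(threshold)) bonferroni_threshold(nrow(Y), alpha) else threshold
  res <- lapply(outcomes, function(oc) {
    X <- build_design(cohort, oc, covariates, standardize_outcomes)
    if (!anyNA(Y) && !anyNA(X)) {
      fit <- ols_stats(Y, X)
      data.frame(feature_id = rownames(Y), outcome = oc,
                 beta = fit$beta, se = fit$se, z = fit$z, p = fit$p,
                 r2 = fit$r2, n = nrow(X), stringsAsFactors = FALSE,
                 row.names = NULL)
    } else {
      do.call(rbind, lapply(rownames(Y), function(f) {
        fit_association(Y[f, ], X[, 2], X[, -c(1, 2), drop = FALSE],
                        outcome_name = oc, feature_id = f)
      }))
    }
  })
  out <- do.call(rbind, res)
  out$significant <- out$p < thr
  attr(out, "threshold") <- thr
  out
}

#' Leave-one-covariate-out sensitivity of the AD association
#'
#' Refits each feature's AD model dropping one covariate at a time, plus an
#' unadjusted model, exposing which associations depend on confounder
#' adjustment (RIN in particular).
#'
#' @inheritParams associate_all
#' @param outcome Outcome for the sensitivity analysis (default `"ad"`).
#' @return `data.frame` with `feature_id`, `p_full`, one `p_minus_<cov>`
#'   column per covariate, and `p_none`.
#' @export
covariate_sensitivity <- function(m, cohort, covariates = default_covariates(),
                                  outcome = "ad") {
  Y <- if (inherits(m, "ExpressionMatrix")) m$values else m
  stopifnot(identical(colnames(Y), cohort$sample_id))
  variants <- c(list(full = covariates),
                stats::setNames(lapply(covariates, function(cv) setdiff(covariates, cv)),
                                paste0("minus_", covariates)),
                list(none = character()))
  pmat <- sapply(variants, function(cv) {
    associate_all(m, cohort, outcomes = outcome, covariates = cv)$p
  })
  if (is.null(dim(pmat))) pmat <- matrix(pmat, nrow = 1, dimnames = list(NULL, names(variants)))
  out <- data.frame(feature_id = rownames(Y), stringsAsFactors = FALSE)
  colnames(pmat) <- paste0("p_", colnames(pmat))
  cbind(out, as.data.frame(pmat, row.names = NULL))
}

#' Partial variance in an outcome explained by one predictor
#'
#' Squared partial correlation of the predictor with the outcome given the
#' covariates, computed from the t statistic of the adjusted fit
#' (`t^2 / (t^2 + df)`), identical to `1 - SSR_full / SSR_reduced` of the
#' nested models.
#'
#' @param x Predictor vector (an expression profile, or a reference
#'   covariate such as an APOE-e4 indicator).
#' @param outcome Outcome vector.
#' @param covariates Optional adjustment `data.frame`.
#' @return Partial R-squared in `[0, 1]`.
#' @export
variance_explained <- function(x, outcome, covariates = NULL) {
  fit_association(x, outcome, covariates)$r2
}

#' Compare variance explained across features and reference covariates
#'
#' Puts expression features and reference covariates (e.g. a planted
#' APOE-e4-like indicator) on the same partial-R2 footing against one
#' outcome.
#'
#' @inheritParams associate_all
#' @param features Feature ids of `m` to include.
#' @param references Cohort column names to include as reference predictors.
#' @param outcome Outcome name (default `"ad"`).
#' @return `data.frame` with `predictor`, `type` and `r2`.
#' @export
variance_explained_comparison <- function(m, cohort, features,
                                          references = "apoe",
                                          outcome = "ad",
                                          covariates = default_covariates()) {
  Y <- if (inherits(m, "ExpressionMatrix")) m$values else m
  bad <- setdiff(features, rownames(Y))
  if (length(bad) > 0) stop("unknown feature ids: ", paste(bad, collapse = ", "))
  bad <- setdiff(references, names(cohort))
  if (length(bad) > 0) stop("unknown reference covariates: ",
                            paste(bad, collapse = ", "))
  y <- cohort[[outcome]]
  cov_df <- cohort[covariates]
  rows <- lapply(features, function(f) {
    data.frame(predictor = f, type = "feature",
               r2 = variance_explained(Y[f, ], y, cov_df),
               stringsAsFactors = FALSE)
  })
  ref_rows <- lapply(references, function(rf) {
    data.frame(predictor = rf, type = "reference",
               r2 = variance_explained(cohort[[rf]], y, cov_df),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, ref_rows))
}
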