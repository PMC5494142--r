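#' Derive reproducible child seeds from a single master seed
#'
#' All randomness in the package flows from one integer seed. Sub-generators
#' (cohort, miRNA counts, mRNA, null replicates) receive child seeds drawn
#' from a stream initialised with the master seed, so each sub-generator is
#' independently reproducible and adding a new consumer does not perturb
#' existing ones.
#'
#' @param seed Master integer seed.
#' @param n Number of child seeds to derive.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, n = 1L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.numeric(n), n >= 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Adjusted R-squared of a fitted linear model given its R-squared
#' @noRd
adj_r2 <- function(r2, n, p) {
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Mean of a normal distribution truncated to [lo, hi]
#' @noRd
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

#' Draw from a normal truncated to [lo, hi] by inverse-CDF
#' @noRd
rtruncnorm <- function(n, mu, sd, lo, hi) {
  pa <- stats::pnorm(lo, mu, sd)
  pb <- stats::pnorm(hi, mu, sd)
  stats::qnorm(stats::runif(n, pa, pb), mu, sd)
}
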