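#' Default cohort distribution settings
#'
#' Defaults emulate the demographic structure of a large community-based
#' autopsy cohort of aging: mean age at death 88, 64% female, 61% meeting
#' pathologic AD criteria, RNA integrity (RIN) truncated to \[2, 9\] with mean
#' 6.5, overdispersed and positively correlated plaque (NP) and tangle (NFT)
#' burdens, and samples processed in cartridges of 96.
#'
#' @param age_mean,age_sd Age at death, years.
#' @param frac_female Proportion of female subjects.
#' @param frac_map Proportion enrolled in the second of the two studies.
#' @param frac_ad Target proportion meeting pathologic AD criteria; the
#'   NP/NFT thresholds of the diagnosis rule are calibrated to hit it.
#' @param nnls_mean,nnls_conc Mean and concentration of the Beta-distributed
#'   neuronal proportion.
#' @param pmi_meanlog,pmi_sdlog Log-normal post-mortem interval, hours.
#' @param rin_mean Target mean RIN after truncation to `[rin_min, rin_max]`.
#' @param rin_sd Latent RIN standard deviation.
#' @param rin_min,rin_max RIN truncation bounds.
#' @param rin_ad_shift RIN decrease (units) for pathologic-AD subjects. The
#'   default 0 keeps RIN independent of outcome; positive values create the
#'   RIN-confounding scenario.
#' @param np_size,np_mu,nft_size,nft_mu Negative-binomial size and mean for
#'   the NP and NFT burdens.
#' @param latent_cor Correlation of the shared Gaussian latent factor that
#'   couples NP and NFT.
#' @param apoe_freq,apoe_r2 Carrier frequency and target variance in AD
#'   explained by the planted APOE-e4-like binary covariate.
#' @param cartridge_size Samples per cartridge (batch).
#' @param sqrt_transform If `TRUE`, NP and NFT are square-root transformed
#'   (variance-stabilizing) after diagnosis is assigned; the measurement
#'   scale of pathology summaries differs between studies, so this is
#'   exposed as a flag rather than asserted.
#' @return Named list of parameters for [generate_cohort()].
#' @export
cohort_params <- function(age_mean = 88, age_sd = 6.5,
                          frac_female = 0.64, frac_map = 0.5, frac_ad = 0.61,
                          nnls_mean = 0.35, nnls_conc = 30,
                          pmi_meanlog = log(6), pmi_sdlog = 0.5,
                          rin_mean = 6.5, rin_sd = 1.2,
                          rin_min = 2, rin_max = 9, rin_ad_shift = 0,
                          np_size = 2, np_mu = 10,
                          nft_size = 2, nft_mu = 10,
                          latent_cor = 0.5,
                          apoe_freq = 0.25, apoe_r2 = 0.061,
                          cartridge_size = 96,
                          sqrt_transform = FALSE) {
  p <- as.list(environment())
  for (nm in c("frac_female", "frac_map", "frac_ad", "apoe_freq")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must be in [0,1]")
  }
  if (p$rin_min >= p$rin_max) stop("RIN bounds inverted")
  p
}

#' Probability that both NB burdens reach their thresholds under the
#' Gaussian-copula coupling: P(NP >= t_np, NFT >= t_nft).
#' @noRd
ad_joint_prob <- function(t_np, t_nft, params) {
  # NP >= t  <=>  Phi(Z1) > F_NB(t - 1)
  z1 <- stats::qnorm(stats::pnbinom(t_np - 1, size = params$np_size, mu = params$np_mu))
  z2 <- stats::qnorm(stats::pnbinom(t_nft - 1, size = params$nft_size, mu = params$nft_mu))
  rho <- params$latent_cor
  if (is.infinite(z1) && z1 < 0 && is.infinite(z2) && z2 < 0) return(1)
  s <- sqrt(1 - rho^2)
  f <- function(z) stats::dnorm(z) * stats::pnorm((z2 - rho * z) / s, lower.tail = FALSE)
  stats::integrate(f, lower = z1, upper = Inf, rel.tol = 1e-10)$value
}

#' Calibrate the NP/NFT diagnosis thresholds to the target AD fraction
#'
#' The binary pathologic diagnosis follows an NIA-Reagan-like rule: AD = 1
#' iff NP reaches a moderate-plaque threshold AND NFT reaches a tangle
#' threshold. The integer threshold pair whose exact joint exceedance
#' probability (computed from the generative copula) is closest to
#' `frac_ad` is selected; ties prefer equal thresholds.
#'
#' @param params Output of [cohort_params()].
#' @return List with `t_np`, `t_nft` and the achieved probability `prob`.
#' @export
calibrate_ad_thresholds <- function(params = cohort_params()) {
  tmax_np <- stats::qnbinom(0.9, size = params$np_size, mu = params$np_mu)
  tmax_nft <- stats::qnbinom(0.9, size = params$nft_size, mu = params$nft_mu)
  grid <- expand.grid(t_np = 1:max(2L, tmax_np), t_nft = 1:max(2L, tmax_nft))
  grid$prob <- mapply(ad_joint_prob, grid$t_np, grid$t_nft,
                      MoreArgs = list(params = params))
  grid$err <- abs(grid$prob - params$frac_ad)
  grid <- grid[order(grid$err, abs(grid$t_np - grid$t_nft), grid$t_np + grid$t_nft), ]
  list(t_np = grid$t_np[1], t_nft = grid$t_nft[1], prob = grid$prob[1])
}

#' Generate a synthetic aging cohort with neuropathology outcomes
#'
#' Draws demographics, technical covariates and correlated plaque/tangle
#' burdens for `n` subjects, then assigns the binary pathologic AD diagnosis
#' deterministically from NP and NFT via calibrated thresholds. The latent
#' RIN mean is solved so the truncated RIN distribution attains the
#' requested mean. A binary APOE-e4-like covariate is planted with a chosen
#' AD variance share to serve as an effect-size reference.
#'
#' @param n Number of subjects (>= 2).
#' @param seed Integer seed; identical `(n, seed, params)` give identical
#'   output.
#' @param params Output of [cohort_params()].
#' @return A `data.frame` with columns `sample_id`, `age`, `sex` (1=female),
#'   `study` (0/1), `nnls`, `pmi`, `rin`, `cartridge`, `apoe`, `np`, `nft`,
#'   `ad`, carrying the calibrated thresholds as attribute `ad_thresholds`.
#' @export
generate_cohort <- function(n, seed = 1L, params = cohort_params()) {
  if (!is.numeric(n) || n < 2) stop("n must be >= 2")
  n <- as.integer(n)
  set.seed(as.integer(seed))

  age <- stats::rnorm(n, params$age_mean, params$age_sd)
  sex <- stats::rbinom(n, 1, params$frac_female)
  study <- stats::rbinom(n, 1, params$frac_map)
  nnls <- stats::rbeta(n, params$nnls_mean * params$nnls_conc,
                       (1 - params$nnls_mean) * params$nnls_conc)
  pmi <- stats::rlnorm(n, params$pmi_meanlog, params$pmi_sdlog)

  # latent RIN mean chosen so the truncated mean equals the target
  mu_rin <- stats::uniroot(
    function(mu) truncnorm_mean(mu, params$rin_sd, params$rin_min, params$rin_max) -
      params$rin_mean,
    interval = c(params$rin_min, params$rin_max), tol = 1e-8
  )$root
  rin <- rtruncnorm(n, mu_rin, params$rin_sd, params$rin_min, params$rin_max)

  # correlated overdispersed pathology burdens via a Gaussian copula
  z1 <- stats::rnorm(n)
  z2 <- params$latent_cor * z1 + sqrt(1 - params$latent_cor^2) * stats::rnorm(n)
  np <- stats::qnbinom(stats::pnorm(z1), size = params$np_size, mu = params$np_mu)
  nft <- stats::qnbinom(stats::pnorm(z2), size = params$nft_size, mu = params$nft_mu)

  thr <- calibrate_ad_thresholds(params)
  ad <- as.integer(np >= thr$t_np & nft >= thr$t_nft)

  if (params$rin_ad_shift != 0) {
    rin <- pmin(pmax(rin - params$rin_ad_shift * ad, params$rin_min), params$rin_max)
  }

  # APOE-like binary reference covariate with target AD variance share
  phi <- sqrt(params$apoe_r2)
  pa <- params$apoe_freq
  pd <- thr$prob
  p11 <- pd * pa + phi * sqrt(pa * (1 - pa) * pd * (1 - pd))
  p_apoe_ad <- min(1, p11 / pd)
  p_apoe_noad <- max(0, (pa - p11) / (1 - pd))
  apoe <- stats::rbinom(n, 1, ifelse(ad == 1, p_apoe_ad, p_apoe_noad))

  if (params$sqrt_transform) {
    np <- sqrt(np)
    nft <- sqrt(nft)
  }

  cartridge <- paste0("C", ceiling(seq_len(n) / params$cartridge_size))

  out <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    age = age, sex = sex, study = study, nnls = nnls, pmi = pmi, rin = rin,
    cartridge = cartridge, apoe = apoe, np = np, nft = nft, ad = ad,
    stringsAsFactors = FALSE
  )
  attr(out, "ad_thresholds") <- thr
  out
}

#' Planted ground truth for the expression generators
#'
#' Records which features carry real signal (and how much), the technical
#' coupling strengths, and the miRNA-to-gene repression coefficients, so
#' parameter-recovery tests can compare downstream estimates against known
#' truth. Features absent from `effects` are exact nulls.
#'
#' @param effects `data.frame` with columns `feature_id`, `outcome` (one of
#'   `"np"`, `"nft"`, `"ad"`) and `frac_var` (fraction of residual variance
#'   the feature's expression shares with the outcome, in `[0, 1)`); an
#'   optional `sign` column sets the effect direction (default positive).
#' @param batch_sd SD of per-feature, per-cartridge log2 shifts.
#' @param rin_slope Mean slope of log2 expression on centered RIN.
#' @param rin_slope_sd Across-feature SD of the RIN slope (default half the
#'   mean). RNA degradation hits probes unevenly, so the slope is
#'   feature-specific; a purely common slope would be an across-feature
#'   sample shift that quantile normalization removes entirely.
#' @param repression `data.frame` with columns `mirna_id`, `gene_id`, `coef`
#'   (slope of gene expression on the standardized miRNA; negative =
#'   repression).
#' @return A `GroundTruth` object.
#' @export
ground_truth <- function(effects = NULL, batch_sd = 0.3, rin_slope = 0.15,
                         rin_slope_sd = rin_slope / 2, repression = NULL) {
  if (is.null(effects)) {
    effects <- data.frame(feature_id = character(), outcome = character(),
                          frac_var = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("feature_id", "outcome", "frac_var") %in% names(effects)))
  if (any(!effects$outcome %in% c("np", "nft", "ad"))) {
    stop("effect outcomes must be np, nft or ad")
  }
  if (any(effects$frac_var >= 1 | effects$frac_var < 0)) {
    stop("requested variance fractions must be in [0, 1)")
  }
  if (is.null(repression)) {
    repression <- data.frame(mirna_id = character(), gene_id = character(),
                             coef = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(effects = effects, batch_sd = batch_sd,
                 rin_slope = rin_slope, rin_slope_sd = rin_slope_sd,
                 repression = repression),
            class = "GroundTruth")
}

#' Default settings for the Nanostring-like miRNA count generator
#'
#' @param base_log2_mean,base_log2_sd Distribution of per-feature baseline
#'   log2 expression for expressed features.
#' @param noise_sd Per-entry biological/technical log2 noise SD; planted
#'   effect sizes are calibrated against this residual scale.
#' @param n_low_features Number of additional essentially unexpressed
#'   features (counts near the probe background) appended to exercise the
#'   call-rate and low-expression filters.
#' @param low_log2_mean Baseline log2 expression of the unexpressed features.
#' @param background_meanlog,background_sdlog Log-normal distribution of the
#'   per-probe constant background level.
#' @param count_noise `"poisson"` for Poisson count noise around the mean
#'   count (default), `"none"` for noise-free expected counts.
#' @return Named list of parameters for [generate_mirna_counts()].
#' @export
mirna_params <- function(base_log2_mean = 8, base_log2_sd = 1, noise_sd = 0.5,
                         n_low_features = 0, low_log2_mean = 0.5,
                         background_meanlog = log(25), background_sdlog = 0.3,
                         count_noise = c("poisson", "none")) {
  p <- as.list(environment())
  p$count_noise <- match.arg(count_noise)
  p
}

#' Generate Nanostring-like raw miRNA counts with planted effects
#'
#' On the log2 scale each feature receives a baseline, a per-cartridge batch
#' shift, a slope on centered RIN, any planted outcome effect and Gaussian
#' noise; the implied mean count plus a per-probe constant background is
#' then observed with Poisson count noise. A feature planted at variance
#' fraction `v` gets slope `sqrt(v / (1 - v)) * noise_sd` on the
#' standardized outcome, so after preprocessing its squared partial
#' correlation with the outcome is `v` in expectation.
#'
#' @param cohort Output of [generate_cohort()].
#' @param truth A [ground_truth()] object; effect feature ids must be among
#'   the generated ids (`mir0001`, ...).
#' @param n_features Number of expressed features.
#' @param seed Integer seed.
#' @param params Output of [mirna_params()].
#' @return List with `matrix` (raw `ExpressionMatrix`, cartridge batch
#'   labels attached) and `background` (named per-feature background level).
#' @export
generate_mirna_counts <- function(cohort, truth = ground_truth(),
                                  n_features = 309, seed = 1L,
                                  params = mirna_params()) {
  if (nrow(cohort) == 0) stop("cohort is empty")
  if (n_features < 1) stop("n_features must be >= 1")
  set.seed(as.integer(seed))
  n <- nrow(cohort)
  ids <- sprintf("mir%04d", seq_len(n_features + params$n_low_features))
  unknown <- setdiff(truth$effects$feature_id, ids)
  if (length(unknown) > 0) {
    stop("unknown feature ids in truth: ", paste(unknown, collapse = ", "))
  }

  base <- c(stats::rnorm(n_features, params$base_log2_mean, params$base_log2_sd),
            rep(params$low_log2_mean, params$n_low_features))
  background <- stats::rlnorm(length(ids), params$background_meanlog,
                              params$background_sdlog)
  names(background) <- ids

  batches <- unique(cohort$cartridge)
  gamma <- matrix(stats::rnorm(length(ids) * length(batches), 0, truth$batch_sd),
                  nrow = length(ids), dimnames = list(ids, batches))

  rin_c <- cohort$rin - mean(cohort$rin)
  rin_slopes <- stats::rnorm(length(ids), truth$rin_slope, truth$rin_slope_sd)
  L <- matrix(base, nrow = length(ids), ncol = n) +
    gamma[, cohort$cartridge, drop = FALSE] +
    rin_slopes %o% rin_c

  if (nrow(truth$effects) > 0) {
    for (i in seq_len(nrow(truth$effects))) {
      fid <- truth$effects$feature_id[i]
      v <- truth$effects$frac_var[i]
      y <- cohort[[truth$effects$outcome[i]]]
      y_std <- (y - mean(y)) / stats::sd(y)
      # residual log2 variance the effect must stand against: Gaussian noise
      # plus (delta-method) Poisson count noise at the feature's mean count
      resid_var <- params$noise_sd^2
      if (params$count_noise == "poisson") {
        lambda <- 2^base[match(fid, ids)] + background[fid]
        resid_var <- resid_var + 1 / (lambda * log(2)^2)
      }
      beta <- sqrt(v / (1 - v) * resid_var)
      if (!is.null(truth$effects$sign)) beta <- beta * sign(truth$effects$sign[i])
      L[fid, ] <- L[fid, ] + beta * y_std
    }
  }
  L <- L + matrix(stats::rnorm(length(L), 0, params$noise_sd), nrow = nrow(L))

  mu <- 2^L + background
  counts <- if (params$count_noise == "poisson") {
    matrix(stats::rpois(length(mu), mu), nrow = nrow(mu))
  } else {
    mu
  }
  dimnames(counts) <- list(ids, cohort$sample_id)

  list(
    matrix = expression_matrix(counts, feature_class = "miRNA",
                               batch = cohort$cartridge, state = "raw"),
    background = background
  )
}

#' Default settings for the miRNA-coupled mRNA generator
#'
#' @param noise_sd Per-gene residual SD on the abundance scale.
#' @param targets_per_mirna Predicted targets per planted miRNA (repressed
#'   genes plus decoy targets).
#' @param planted_extra_genes Non-targeted filler genes added to each
#'   planted pathway.
#' @param null_pathway_size Genes per null pathway.
#' @param null_targets_per_pathway Size of the (miRNA, pathway) overlap
#'   arranged for each null miR-pathway.
#' @param direct_ad_effect Direct (non-miRNA-mediated) slope of repressed
#'   genes on the 0/1 AD diagnosis.
#' @return Named list of parameters for [generate_mrna_and_annotations()].
#' @export
mrna_params <- function(noise_sd = 1, targets_per_mirna = 20,
                        planted_extra_genes = 3,
                        null_pathway_size = 8, null_targets_per_pathway = 5,
                        direct_ad_effect = 0) {
  as.list(environment())
}

#' Generate mRNA abundances, a target table and pathway sets
#'
#' Genes repressed by a planted miRNA (per `truth$repression`) are coupled
#' to that miRNA's standardized log2 expression with the recorded
#' coefficient, optionally plus a direct AD effect; all other genes are pure
#' noise. Annotation output plants one coherent miR-pathway per repressing
#' miRNA (its repressed genes plus filler) and `n_pathways` null pathways,
#' each arranged to overlap the target set of some null miRNA so that null
#' miR-pathways exist for calibration.
#'
#' @param cohort Output of [generate_cohort()].
#' @param mirna Raw miRNA `ExpressionMatrix` from [generate_mirna_counts()];
#'   coupling uses its log2(count + 1) values.
#' @param truth A [ground_truth()] object; `repression` rows must name
#'   miRNA ids present in `mirna`.
#' @param n_genes Total number of genes (must cover all annotated sets).
#' @param n_pathways Number of null pathways.
#' @param seed Integer seed.
#' @param params Output of [mrna_params()].
#' @return List with `mrna` (an `ExpressionMatrix`, class `"mRNA"`),
#'   `targets` (`data.frame`: `mirna_id`, `gene_id`) and `pathways` (named
#'   list of gene-id vectors).
#' @export
generate_mrna_and_annotations <- function(cohort, mirna, truth,
                                          n_genes = 300, n_pathways = 50,
                                          seed = 1L, params = mrna_params()) {
  set.seed(as.integer(seed))
  n <- nrow(cohort)
  stopifnot(identical(colnames(mirna$values), cohort$sample_id))
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  mir_ids <- rownames(mirna$values)
  bad <- setdiff(truth$repression$mirna_id, mir_ids)
  if (length(bad) > 0) stop("repression names unknown miRNA ids: ",
                            paste(bad, collapse = ", "))
  planted_mirs <- unique(truth$repression$mirna_id)
  planted_genes <- unique(truth$repression$gene_id)
  if (length(planted_genes) > n_genes) stop("n_genes too small for planted sets")
  if (params$null_pathway_size > n_genes) {
    stop("pathway size exceeds n_genes")
  }
  # planted repression targets occupy the head of the gene id space
  gene_map <- stats::setNames(gene_ids[seq_along(planted_genes)], planted_genes)

  expr <- matrix(stats::rnorm(n_genes * n, 0, params$noise_sd),
                 nrow = n_genes, dimnames = list(gene_ids, cohort$sample_id))
  mir_log2 <- log2(mirna$values + 1)
  ad_c <- cohort$ad - mean(cohort$ad)
  if (nrow(truth$repression) > 0) {
    for (i in seq_len(nrow(truth$repression))) {
      g <- gene_map[[truth$repression$gene_id[i]]]
      m <- truth$repression$mirna_id[i]
      zmir <- as.numeric(scale(mir_log2[m, ]))
      expr[g, ] <- expr[g, ] + truth$repression$coef[i] * zmir +
        params$direct_ad_effect * ad_c
    }
  }

  null_genes <- setdiff(gene_ids, unname(gene_map))
  null_mirs <- setdiff(mir_ids, planted_mirs)

  # target table: planted miRNAs target their repressed genes plus decoys
  targets <- list()
  for (m in planted_mirs) {
    own <- unname(gene_map[truth$repression$gene_id[truth$repression$mirna_id == m]])
    decoys <- sample(null_genes, max(0, params$targets_per_mirna - length(own)))
    targets[[m]] <- data.frame(mirna_id = m, gene_id = c(own, decoys),
                               stringsAsFactors = FALSE)
  }

  # pathways: one coherent set per planted miRNA, plus nulls with arranged
  # overlap so (null miRNA, null pathway) pairs survive the size filter
  pathways <- list()
  for (m in planted_mirs) {
    own <- unname(gene_map[truth$repression$gene_id[truth$repression$mirna_id == m]])
    filler <- sample(null_genes, params$planted_extra_genes)
    pathways[[paste0("planted_", m)]] <- c(own, filler)
  }
  if (n_pathways > 0) {
    if (length(null_mirs) == 0) stop("no null miRNAs available for null pathways")
    for (j in seq_len(n_pathways)) {
      pw <- sample(null_genes, params$null_pathway_size)
      m <- null_mirs[((j - 1) %% length(null_mirs)) + 1]
      hit <- sample(pw, min(params$null_targets_per_pathway, length(pw)))
      targets[[paste0(m, "_pw", j)]] <- data.frame(mirna_id = m, gene_id = hit,
                                                   stringsAsFactors = FALSE)
      pathways[[sprintf("null_pw%03d", j)]] <- pw
    }
  }
  if (anyDuplicated(names(pathways))) stop("duplicate pathway names")
  targets <- unique(do.call(rbind, c(targets, list(make.row.names = FALSE))))

  list(
    mrna = expression_matrix(expr, feature_class = "mRNA", state = "normalized"),
    targets = targets,
    pathways = pathways,
    gene_map = gene_map
  )
}
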