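#' Construct miR-pathways from a target table and pathway sets
#'
#' A miR-pathway is the intersection of one miRNA's predicted target genes
#' with one annotated pathway's gene set. Pairs whose intersection is
#' smaller than `min_size` are dropped, and pathway aliases yielding an
#' identical member set for the same miRNA are merged with their names
#' concatenated by `"; "`.
#'
#' @param targets `data.frame` with columns `mirna_id`, `gene_id`.
#' @param pathways Named list of gene-id vectors (as read by [read_gmt()]).
#' @param min_size Minimum member-set size (default 3).
#' @return `data.frame` with `mirna_id`, `pathways` (merged names), `genes`
#'   (`";"`-joined member ids) and `n_genes`.
#' @export
build_mir_pathways <- function(targets, pathways, min_size = 3) {
  if (nrow(targets) == 0) stop("empty target table")
  stopifnot(all(c("mirna_id", "gene_id") %in% names(targets)))
  if (is.null(names(pathways)) || any(names(pathways) == "")) {
    stop("pathways must be named")
  }
  target_sets <- split(targets$gene_id, targets$mirna_id)
  rows <- list()
  for (m in names(target_sets)) {
    tg <- unique(target_sets[[m]])
    for (pw in names(pathways)) {
      member <- sort(intersect(tg, unique(pathways[[pw]])))
      if (length(member) >= min_size) {
        key <- paste(m, paste(member, collapse = ";"), sep = "|")
        if (is.null(rows[[key]])) {
          rows[[key]] <- list(mirna_id = m, pathways = pw, genes = member)
        } else {
          rows[[key]]$pathways <- paste(rows[[key]]$pathways, pw, sep = "; ")
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(mirna_id = character(), pathways = character(),
                      genes = character(), n_genes = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(mirna_id = r$mirna_id, pathways = r$pathways,
               genes = paste(r$genes, collapse = ";"),
               n_genes = length(r$genes), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Stouffer combination of signed z statistics
#'
#' @param z Numeric vector of gene-level z statistics (finite, length >= 1).
#' @return Combined statistic `sum(z) / sqrt(length(z))`.
#' @export
stouffer_combine <- function(z) {
  if (length(z) == 0) stop("empty z list")
  if (any(!is.finite(z))) stop("non-finite z values")
  sum(z) / sqrt(length(z))
}

#' One-sided normal tail probability of a statistic in an expected direction
#'
#' @param z Statistic.
#' @param direction `"+"` (evidence = large positive z) or `"-"`.
#' @return Upper-tail probability of `z * direction`.
#' @export
one_sided_p <- function(z, direction = c("+", "-")) {
  direction <- match.arg(direction)
  s <- if (direction == "+") 1 else -1
  stats::pnorm(s * z, lower.tail = FALSE)
}

#' Joint score from two one-sided p-values
#'
#' Fisher-family product statistic `X = -2 (ln p1 + ln p2)` referred to a
#' chi-square with 4 df. Because member genes of an annotated pathway are
#' correlated, this score is strongly anti-conservative under the null and
#' is used for ranking only, never reported as a p-value.
#'
#' @param p_mirna,p_pathway One-sided p-values in (0, 1].
#' @return Upper-tail chi-square(4) probability of `X`.
#' @export
combine_joint <- function(p_mirna, p_pathway) {
  if (any(c(p_mirna, p_pathway) > 1) || any(c(p_mirna, p_pathway) < 0)) {
    stop("p-values must be in [0, 1]")
  }
  if (p_mirna == 0 || p_pathway == 0) {
    warning("zero p-value floored at machine minimum")
    p_mirna <- max(p_mirna, .Machine$double.xmin)
    p_pathway <- max(p_pathway, .Machine$double.xmin)
  }
  X <- -2 * (log(p_mirna) + log(p_pathway))
  stats::pchisq(X, df = 4, lower.tail = FALSE)
}

#' Rank miR-pathways by joint miRNA + target-pathway evidence
#'
#' For each miR-pathway, gene-level z statistics (from the association
#' module, same covariates and samples as the miRNA models) are combined
#' by Stouffer's method; the miRNA's one-sided p uses its own association
#' sign, and the pathway's one-sided p uses by default the opposite sign
#' (repression logic: an AD-depleted miRNA de-represses its targets). The
#' two one-sided p-values are combined into the chi-square(4) joint score
#' and rows are ranked ascending by it, ties broken by larger absolute
#' Stouffer z.
#'
#' @param mirna_assoc [associate_all()] rows for the miRNAs (one outcome).
#' @param gene_assoc [associate_all()] rows for the genes (same outcome and
#'   samples).
#' @param mir_pathways Output of [build_mir_pathways()].
#' @param direction_convention `"opposite"` (default, repression logic) or
#'   `"same"`.
#' @return `data.frame` sorted by rank: `mirna_id`, `pathways`, `direction`
#'   (`Up`/`Down` from the miRNA association sign), `score`, `genes`,
#'   `n_genes`, `stouffer_z`, `p_mirna`, `p_pathway`, `rank`. The score is
#'   a ranking statistic, not a p-value.
#' @export
rank_mir_pathways <- function(mirna_assoc, gene_assoc, mir_pathways,
                              direction_convention = c("opposite", "same")) {
  direction_convention <- match.arg(direction_convention)
  if (nrow(mir_pathways) == 0) stop("no miR-pathways to rank")
  gene_z <- stats::setNames(gene_assoc$z, gene_assoc$feature_id)
  mir_z <- stats::setNames(mirna_assoc$z, mirna_assoc$feature_id)
  rows <- lapply(seq_len(nrow(mir_pathways)), function(i) {
    m <- mir_pathways$mirna_id[i]
    genes <- strsplit(mir_pathways$genes[i], ";", fixed = TRUE)[[1]]
    genes <- genes[genes %in% names(gene_z)]
    if (length(genes) == 0 || !m %in% names(mir_z)) return(NULL)
    zm <- mir_z[[m]]
    mir_dir <- if (zm >= 0) "+" else "-"
    path_dir <- if (direction_convention == "opposite") {
      if (mir_dir == "+") "-" else "+"
    } else mir_dir
    Zs <- stouffer_combine(gene_z[genes])
    p_m <- one_sided_p(zm, mir_dir)
    p_p <- one_sided_p(Zs, path_dir)
    data.frame(mirna_id = m, pathways = mir_pathways$pathways[i],
               direction = if (mir_dir == "+") "Up" else "Down",
               score = combine_joint(p_m, p_p),
               genes = paste(genes, collapse = ";"),
               n_genes = length(genes), stouffer_z = Zs,
               p_mirna = p_m, p_pathway = p_p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no overlapping features between associations and miR-pathways")
  out <- out[order(out$score, -abs(out$stouffer_z)), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Decompose a gene-outcome effect into miRNA-explained and residual parts
#'
#' Fits `gene ~ outcome + covariates` (total effect) and
#' `gene ~ outcome + miRNA(s) + covariates` (adjusted effect). The
#' explained fraction is `1 - beta_adjusted / beta_total`; it is reported
#' unclipped with a flag when outside `[0, 1]`, and flagged missing when
#' the total effect is numerically zero. The incremental adjusted
#' R-squared of the miRNA block supports joint multi-miRNA fits.
#'
#' @param gene Gene expression values.
#' @param outcome Outcome vector.
#' @param mirnas Numeric vector or samples-in-columns matrix of one or more
#'   miRNA expression profiles (rows = miRNAs).
#' @param covariates Optional adjustment `data.frame`.
#' @return List with `beta_total`, `se_total`, `beta_adjusted`,
#'   `se_adjusted`, `explained_fraction`, `fraction_flag` (`"ok"`,
#'   `"outside_unit"`, `"undefined"`), `incremental_adj_r2`.
#' @export
decompose_effect <- function(gene, outcome, mirnas, covariates = NULL) {
  if (is.null(dim(mirnas))) mirnas <- matrix(mirnas, nrow = 1)
  M <- t(mirnas)                          # samples x miRNAs
  base <- fit_association(gene, outcome, covariates)
  covs_aug <- if (is.null(covariates)) as.data.frame(M) else cbind(as.data.frame(M), covariates)
  adj <- fit_association(gene, outcome, covs_aug)

  n <- length(gene)
  r2_of <- function(covs) {
    X <- cbind(1, outcome)
    if (!is.null(covs)) X <- cbind(X, as.matrix(covs))
    fit <- stats::lm.fit(X, gene)
    r2 <- 1 - sum(fit$residuals^2) / sum((gene - mean(gene))^2)
    adj_r2(r2, n, ncol(X) - 1)
  }
  inc_adj_r2 <- r2_of(covs_aug) - r2_of(covariates)

  frac <- 1 - adj$beta / base$beta
  flag <- "ok"
  if (abs(base$beta) < 1e-12) {
    frac <- NA_real_
    flag <- "undefined"
  } else if (frac < 0 || frac > 1) {
    flag <- "outside_unit"
  }
  list(beta_total = base$beta, se_total = base$se,
       beta_adjusted = adj$beta, se_adjusted = adj$se,
       explained_fraction = frac, fraction_flag = flag,
       incremental_adj_r2 = inc_adj_r2)
}

#' Closed-form mediated fraction implied by generative path coefficients
#'
#' For a gene generated as `direct * outcome + coupling * z(miRNA) + noise`
#' where the standardized miRNA carries slope `a` on the outcome, the
#' population total effect is `direct + coupling * a` and the
#' miRNA-adjusted effect is `direct`, so the mediated (explained) fraction
#' is `coupling * a / (direct + coupling * a)`.
#'
#' @param a Slope of the standardized miRNA on the outcome.
#' @param coupling Gene-on-miRNA coefficient.
#' @param direct Direct gene-on-outcome coefficient.
#' @return Expected explained fraction.
#' @export
mediated_fraction <- function(a, coupling, direct) {
  (coupling * a) / (direct + coupling * a)
}
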