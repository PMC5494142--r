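test_that("miR-pathways are intersections above the size floor, aliases merged", {
  targets <- data.frame(mirna_id = "m1", gene_id = c("A", "B", "C"))
  pathways <- list(pw1 = c("B", "C", "D"), pw2 = c("B", "C", "D", "E"),
                   alias = c("X", "B", "C", "D"))
  mp <- build_mir_pathways(targets, pathways, min_size = 2)
  expect_equal(nrow(mp), 1)           # identical member sets merged
  expect_equal(mp$genes, "B;C")
  expect_match(mp$pathways, "pw1; pw2; alias")

  # below the floor the pair is dropped
  mp3 <- build_mir_pathways(targets, list(pw = c("C", "Z")), min_size = 3)
  expect_equal(nrow(mp3), 0)

  expect_error(build_mir_pathways(targets[0, ], pathways), "empty")
})

test_that("miR-pathway construction matches a brute-force double-loop oracle", {
  set.seed(50)
  genes <- sprintf("g%02d", 1:40)
  targets <- do.call(rbind, lapply(paste0("m", 1:5), function(m) {
    data.frame(mirna_id = m, gene_id = sample(genes, 12))
  }))
  pathways <- setNames(lapply(1:8, function(i) sample(genes, 10)),
                       paste0("pw", 1:8))
  mp <- build_mir_pathways(targets, pathways, min_size = 3)
  # oracle: enumerate every (miRNA, pathway) pair independently
  oracle <- list()
  for (m in paste0("m", 1:5)) for (pw in names(pathways)) {
    inter <- sort(intersect(targets$gene_id[targets$mirna_id == m], pathways[[pw]]))
    if (length(inter) >= 3) {
      oracle[[paste(m, paste(inter, collapse = ";"))]] <- TRUE
    }
  }
  expect_equal(nrow(mp), length(oracle))
  expect_setequal(paste(mp$mirna_id, mp$genes), names(oracle))
})

test_that("Stouffer combination matches its closed form exactly", {
  expect_equal(stouffer_combine(c(2, 2, 2, 2)), 4, tolerance = 1e-15)
  expect_equal(stouffer_combine(1.3), 1.3, tolerance = 1e-15)
  expect_equal(stouffer_combine(c(1, -1)), 0, tolerance = 1e-15)
  set.seed(51)
  z <- rnorm(17)
  expect_equal(stouffer_combine(z), sum(z) / sqrt(17), tolerance = 1e-12)
  expect_equal(stouffer_combine(z), stouffer_combine(sample(z)), tolerance = 1e-12)
  expect_error(stouffer_combine(numeric()), "empty")
  expect_error(stouffer_combine(c(1, Inf)), "finite")
})

test_that("one-sided p-values follow the normal tail in the expected direction", {
  expect_equal(one_sided_p(0, "+"), 0.5)
  expect_equal(one_sided_p(1.959964, "+"), pnorm(1.959964, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(one_sided_p(1.959964, "+"), 0.025, tolerance = 1e-6)
  expect_equal(one_sided_p(1.959964, "-"), 0.975, tolerance = 1e-6)
})

test_that("joint score matches the chi-square(4) oracle and is monotone", {
  expect_equal(combine_joint(1, 1), 1)
  X <- -2 * (log(0.05) + log(0.05))
  expect_equal(combine_joint(0.05, 0.05), pchisq(X, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(combine_joint(0.05, 0.05), 0.0175, tolerance = 5e-3)
  grid <- seq(0.01, 1, by = 0.07)
  for (p2 in c(0.05, 0.5, 1)) {
    scores <- sapply(grid, combine_joint, p_pathway = p2)
    expect_true(all(diff(scores) > 0))
  }
  expect_warning(combine_joint(0, 0.5), "floored")
})

# shared fixture: cohort with one planted coherent miR-pathway
integration_fixture <- function(seed, n = 700, n_pathways = 30,
                                coupling = -0.5, direct = 0) {
  co <- generate_cohort(n, seed = seed)
  tr <- ground_truth(
    effects = data.frame(feature_id = "mir0001", outcome = "ad", frac_var = 0.067,
                         sign = -1),
    batch_sd = 0,
    repression = data.frame(mirna_id = "mir0001", gene_id = paste0("t", 1:5),
                            coef = coupling)
  )
  g <- generate_mirna_counts(co, tr, n_features = 20, seed = seed + 1)
  ann <- generate_mrna_and_annotations(co, g$matrix, tr, n_genes = 300,
                                       n_pathways = n_pathways, seed = seed + 2,
                                       params = mrna_params(direct_ad_effect = direct))
  l2 <- log2(g$matrix$values + 1)
  mir_assoc <- associate_all(l2, co, outcomes = "ad")
  gene_assoc <- associate_all(ann$mrna$values, co, outcomes = "ad")
  list(co = co, tr = tr, g = g, ann = ann, l2 = l2,
       mir_assoc = mir_assoc, gene_assoc = gene_assoc)
}

test_that("the planted coherent miR-pathway outranks null miR-pathways", {
  fx <- integration_fixture(60)
  mp <- build_mir_pathways(fx$ann$targets, fx$ann$pathways)
  ranked <- rank_mir_pathways(fx$mir_assoc, fx$gene_assoc, mp)
  top <- ranked[1, ]
  expect_equal(top$mirna_id, "mir0001")
  expect_match(top$pathways, "planted")
  expect_equal(top$direction, "Down")   # planted miRNA is AD-depleted
  expect_true(all(ranked$score >= 0 & ranked$score <= 1))
  expect_equal(ranked$rank, seq_len(nrow(ranked)))
})

test_that("direction labels follow the miRNA association sign", {
  fx <- integration_fixture(61)
  mp <- build_mir_pathways(fx$ann$targets, fx$ann$pathways)
  ranked <- rank_mir_pathways(fx$mir_assoc, fx$gene_assoc, mp)
  z1 <- fx$mir_assoc$z[fx$mir_assoc$feature_id == "mir0001"]
  lab <- ranked$direction[ranked$mirna_id == "mir0001"][1]
  expect_equal(lab, if (z1 >= 0) "Up" else "Down")
})

test_that("under all-null annotations no pair systematically wins", {
  winners <- c()
  for (s in 1:8) {
    co <- generate_cohort(200, seed = 80 + s)
    tr <- ground_truth(batch_sd = 0)
    g <- generate_mirna_counts(co, tr, n_features = 10, seed = 90 + s)
    ann <- generate_mrna_and_annotations(co, g$matrix, tr, n_genes = 100,
                                         n_pathways = 10, seed = 95 + s)
    mir_assoc <- associate_all(log2(g$matrix$values + 1), co, outcomes = "ad")
    gene_assoc <- associate_all(ann$mrna$values, co, outcomes = "ad")
    mp <- build_mir_pathways(ann$targets, ann$pathways)
    ranked <- rank_mir_pathways(mir_assoc, gene_assoc, mp)
    winners <- c(winners, ranked$pathways[1])
  }
  expect_gt(length(unique(winners)), 1)
})

test_that("correlated member genes make null joint scores anti-conservative", {
  # the documented caveat: under the null with correlated genes the score
  # distribution is stochastically smaller than uniform
  set.seed(70)
  n <- 300
  scores <- replicate(300, {
    shared <- rnorm(n)
    zg <- sapply(1:5, function(i) {
      g <- 0.8 * shared + 0.6 * rnorm(n)
      y <- rbinom(n, 1, 0.5)
      f <- fit_association(g, y)
      f$z
    })
    zm <- rnorm(1)
    p_m <- one_sided_p(zm, if (zm >= 0) "+" else "-")
    Zs <- stouffer_combine(zg)
    p_p <- one_sided_p(Zs, if (Zs >= 0) "+" else "-")
    combine_joint(p_m, p_p)
  })
  expect_lt(median(scores), 0.5)
  expect_gt(mean(scores < 0.05), 0.05)
})

test_that("effect decomposition recovers the closed-form mediated fraction", {
  # fully synthetic paths with known coefficients
  set.seed(71)
  n <- 5000
  fracs <- c()
  for (r in 1:20) {
    ad <- rbinom(n, 1, 0.6)
    mir <- -0.8 * ad + rnorm(n)   # AD-depleted miRNA, repressed targets up in AD
    zmir <- as.numeric(scale(mir))
    direct <- 0.3
    coupling <- -0.5
    gene <- direct * ad + coupling * zmir + rnorm(n, sd = 0.8)
    d <- decompose_effect(gene, ad, zmir)
    a_hat <- lm.fit(cbind(1, ad), zmir)$coefficients[2]
    fracs <- c(fracs, d$explained_fraction -
                 mediated_fraction(a_hat, coupling, direct))
  }
  expect_lt(abs(mean(fracs)), 0.02)
})

test_that("decomposition limits: full mediation tends to 1, null coupling to 0", {
  set.seed(72)
  n <- 2000
  ad <- rbinom(n, 1, 0.6)
  mir <- ad + rnorm(n, sd = 0.3)
  gene_full <- -0.7 * mir + rnorm(n, sd = 1e-4)   # noise -> 0, no direct path
  d_full <- decompose_effect(gene_full, ad, mir)
  expect_equal(d_full$explained_fraction, 1, tolerance = 0.01)

  gene_null <- 0.5 * ad + rnorm(n)
  indep_mir <- rnorm(n)
  d_null <- decompose_effect(gene_null, ad, indep_mir)
  expect_lt(abs(d_null$explained_fraction), 0.15)

  # beta_total exactly 0 by construction -> flagged undefined
  y <- rbinom(n, 1, 0.5)
  gene_orth <- residuals(lm(rnorm(n) ~ y))
  d_und <- decompose_effect(gene_orth, y, rnorm(n))
  expect_identical(d_und$fraction_flag, "undefined")
  expect_true(is.na(d_und$explained_fraction))
})

test_that("joint multi-miRNA fits raise incremental adjusted R2 above singles", {
  set.seed(73)
  n <- 1500
  ad <- rbinom(n, 1, 0.6)
  mirA <- 0.6 * ad + rnorm(n)
  mirB <- 0.6 * ad + rnorm(n)          # independent signal channels
  gene <- -0.4 * scale(mirA)[, 1] - 0.4 * scale(mirB)[, 1] + 0.2 * ad + rnorm(n)
  dA <- decompose_effect(gene, ad, scale(mirA)[, 1])
  dB <- decompose_effect(gene, ad, scale(mirB)[, 1])
  dAB <- decompose_effect(gene, ad, rbind(scale(mirA)[, 1], scale(mirB)[, 1]))
  expect_gte(dAB$incremental_adj_r2, max(dA$incremental_adj_r2, dB$incremental_adj_r2))

  # incremental adjusted R2 equals the nested summary.lm oracle
  oracle <- summary(lm(gene ~ ad + scale(mirA)[, 1]))$adj.r.squared -
    summary(lm(gene ~ ad))$adj.r.squared
  expect_equal(dA$incremental_adj_r2, oracle, tolerance = 1e-10)
})

test_that("mediated fraction flows through the generator's planted pathway", {
  # recovered fraction for a planted member gene matches the generative
  # closed form within Monte-Carlo tolerance
  fracs <- exp_fracs <- c()
  for (s in 1:10) {
    fx <- integration_fixture(100 + s, n = 700, n_pathways = 5, direct = 0.3)
    gene <- fx$ann$mrna$values[fx$ann$gene_map[["t1"]], ]
    zmir <- as.numeric(scale(fx$l2["mir0001", ]))
    d <- decompose_effect(gene, fx$co$ad, zmir)
    a_hat <- lm.fit(cbind(1, fx$co$ad), zmir)$coefficients[2]
    fracs <- c(fracs, d$explained_fraction)
    exp_fracs <- c(exp_fracs, mediated_fraction(a_hat, -0.5, 0.3))
  }
  expect_lt(abs(mean(fracs) - mean(exp_fracs)), 0.1)
})
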