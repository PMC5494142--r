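test_that("background adjustment subtracts and marks below-background as missing", {
  v <- toy_matrix(values = matrix(c(100, 20, 50, 31,
                                    40, 10, 70, 35), 2, 4, byrow = TRUE))
  m <- expression_matrix(v, state = "raw")
  bg <- setNames(c(30, 30), rownames(v))
  out <- adjust_background(m, bg)
  expect_equal(out$values["f01", 1], 70)
  expect_true(is.na(out$values["f01", 2]))   # 20 <= 30
  expect_equal(out$state, "background_adjusted")

  # thresholding variant keeps values but still masks
  out2 <- adjust_background(m, bg, mode = "threshold")
  expect_equal(out2$values["f01", 1], 100)
  expect_true(is.na(out2$values["f01", 2]))

  expect_error(adjust_background(m, setNames(c(-1, 30), rownames(v))), "negative")
  expect_error(adjust_background(m, setNames(30, "f01")), "undefined")
})

test_that("background adjustment matches an elementwise oracle on random input", {
  m <- toy_em(50, 20, seed = 8)
  bg <- setNames(runif(50, 10, 60), rownames(m$values))
  out <- adjust_background(m, bg)
  oracle <- m$values
  for (i in 1:50) for (j in 1:20) {
    oracle[i, j] <- if (m$values[i, j] > bg[i]) m$values[i, j] - bg[i] else NA_real_
  }
  expect_identical(out$values, oracle)
})

test_that("call-rate filter removes features first, then samples, and reconciles", {
  set.seed(2)
  v <- toy_matrix(100, 50, seed = 2)
  # plant missingness: features 1-10 miss 6% of samples; sample 1 misses many
  v[1:10, 1:3] <- NA
  v[11, ] <- v[11, ]  # fully observed
  v[15:90, 1] <- NA
  m <- expression_matrix(v, state = "background_adjusted")
  out <- filter_by_call_rate(m, 0.95, 0.95)

  # oracle: brute-force recount of the same two-stage rule
  keep_f <- rowMeans(!is.na(v)) >= 0.95
  v2 <- v[keep_f, , drop = FALSE]
  keep_s <- colMeans(!is.na(v2)) >= 0.95
  expect_identical(rownames(out$matrix$values), rownames(v)[keep_f])
  expect_identical(colnames(out$matrix$values), colnames(v2)[keep_s])

  # report reconciles at every step
  rep <- out$report$call_rate
  expect_equal(length(rep$removed_features) + length(rep$retained_features), 100)
  expect_equal(length(rep$removed_samples) + length(rep$retained_samples), 50)

  expect_error(filter_by_call_rate(m, 0, 0.95), "in \\(0, 1\\]")
})

test_that("boundary behavior: 96% call rate retained, 94% removed", {
  n <- 50
  v <- matrix(100, 2, n, dimnames = list(c("hi", "lo"), sprintf("S%02d", 1:n)))
  v["hi", 1:2] <- NA    # 96% non-missing -> retained
  v["lo", 1:3] <- NA    # 94% non-missing -> removed
  m <- expression_matrix(v, state = "background_adjusted")
  out <- filter_by_call_rate(m, 0.95, 0.95)
  expect_identical(rownames(out$matrix$values), "hi")
})

test_that("low-expression filter counts missing as low and is boundary-inclusive", {
  n <- 10
  v <- matrix(20, 3, n, dimnames = list(c("keep", "half", "miss"), sprintf("S%02d", 1:n)))
  v["half", 1:5] <- 14          # exactly 50% below 15 -> removed
  v["miss", 1:3] <- NA          # 3 missing + 2 low = 50% -> removed
  v["miss", 4:5] <- 10
  m <- expression_matrix(v, state = "background_adjusted")
  m <- filter_by_call_rate(m, 0.5, 0.1)$matrix
  out <- filter_low_expression(m, 15, 0.5)
  expect_identical(rownames(out$matrix$values), "keep")
  expect_setequal(out$report$low_expression$removed_features, c("half", "miss"))
})

test_that("low-expression removal set matches a brute-force oracle", {
  set.seed(9)
  v <- toy_matrix(80, 30, seed = 9, values = matrix(rexp(80 * 30, 1 / 30), 80, 30))
  v[sample(length(v), 100)] <- NA
  m <- expression_matrix(v, state = "background_adjusted")
  m <- filter_by_call_rate(m, 0.01, 0.01)$matrix
  out <- filter_low_expression(m, 15, 0.5)
  oracle_removed <- rownames(v)[sapply(seq_len(nrow(v)), function(i) {
    mean(is.na(v[i, ]) | v[i, ] < 15) >= 0.5
  })]
  expect_setequal(out$report$low_expression$removed_features, oracle_removed)
  # filters are idempotent on their own output
  again <- filter_low_expression(out$matrix, 15, 0.5)
  expect_identical(again$matrix$values, out$matrix$values)
})

test_that("lincRNA filter uses a strict mean-expected-count threshold", {
  v <- matrix(c(rep(4.9, 4), rep(5.0, 4), rep(80, 4)), 3, 4, byrow = TRUE,
              dimnames = list(c("low", "edge", "hi"), paste0("S", 1:4)))
  m <- expression_matrix(v, feature_class = "lincRNA")
  out <- filter_lincrna(m, 5)
  expect_setequal(rownames(out$matrix$values), c("edge", "hi"))
  expect_error(filter_lincrna(toy_em(feature_class = "miRNA")), "lincRNA")

  # brute-force oracle on a random toy matrix
  set.seed(4)
  v2 <- matrix(rexp(40 * 6, 1 / 6), 40, 6,
               dimnames = list(sprintf("l%02d", 1:40), paste0("S", 1:6)))
  m2 <- expression_matrix(v2, feature_class = "lincRNA")
  out2 <- filter_lincrna(m2, 5)
  expect_setequal(rownames(out2$matrix$values),
                  rownames(v2)[rowMeans(v2) >= 5])
})

test_that("quantile normalization equalizes column distributions", {
  v <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(paste0("f", 1:3), paste0("S", 1:2)))
  m <- expression_matrix(v, state = "filtered")
  out <- quantile_normalize(m, log2_transform = FALSE)
  expect_equal(unname(out$values), matrix(c(2.5, 3.5, 4.5, 2.5, 3.5, 4.5), 3, 2))

  # defining property on arbitrary input: identical sorted columns
  m2 <- toy_em(30, 8, seed = 5, state = "filtered")
  out2 <- quantile_normalize(m2)
  sorted <- apply(out2$values, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))

  # fixed point: identical columns are unchanged; re-running is a no-op
  v3 <- matrix(rep(c(1, 5, 9), 4), 3, 4,
               dimnames = list(paste0("f", 1:3), paste0("S", 1:4)))
  m3 <- expression_matrix(v3, state = "filtered")
  out3 <- quantile_normalize(m3, log2_transform = FALSE)
  expect_equal(out3$values, v3)
  again <- quantile_normalize(out2, log2_transform = FALSE)
  expect_equal(again$values, out2$values, tolerance = 1e-12)

  expect_error(quantile_normalize(expression_matrix(
    matrix(1:3, 3, 1, dimnames = list(paste0("f", 1:3), "S1")), state = "filtered")),
    ">= 2 samples")
})

test_that("ComBat removes a pure batch mean shift and refuses one batch", {
  set.seed(6)
  n <- 200
  batch <- rep(c("A", "B"), each = n / 2)
  v <- matrix(rnorm(100 * n, 8, 0.1), 100, n,
              dimnames = list(sprintf("f%03d", 1:100), sprintf("S%03d", 1:n)))
  v[, batch == "B"] <- v[, batch == "B"] + 3
  m <- expression_matrix(v, batch = batch, state = "normalized")
  out <- combat_adjust(m)
  delta <- rowMeans(out$values[, batch == "A"]) - rowMeans(out$values[, batch == "B"])
  expect_lt(max(abs(delta)), 0.05)

  one <- expression_matrix(v, batch = rep("A", n), state = "normalized")
  expect_error(combat_adjust(one), ">= 2 batches")
  tiny <- expression_matrix(v, batch = c("B", rep("A", n - 1)), state = "normalized")
  expect_error(combat_adjust(tiny), ">= 2 samples")
})

test_that("ComBat preserves an outcome effect orthogonal to batch", {
  set.seed(7)
  n <- 200
  batch <- rep(c("A", "B"), each = n / 2)
  y <- rep(c(0, 1), n / 2)                     # orthogonal to batch
  v <- matrix(rnorm(100 * n, 8, 0.5), 100, n,
              dimnames = list(sprintf("f%03d", 1:100), sprintf("S%03d", 1:n)))
  v[1, ] <- v[1, ] + 0.6 * y
  v[, batch == "B"] <- v[, batch == "B"] + 2
  m <- expression_matrix(v, batch = batch, state = "normalized")
  out <- combat_adjust(m)
  before <- lm.fit(cbind(1, y), v[1, ])$coefficients[2]
  after <- lm.fit(cbind(1, y), out$values[1, ])$coefficients[2]
  expect_lt(abs(after - before) / abs(before), 0.05)
})

test_that("processing states advance in pipeline order only", {
  m <- toy_em(state = "raw")
  expect_error(filter_by_call_rate(m), "requires state")
  expect_error(quantile_normalize(m), "requires state")
  bg <- setNames(rep(0.1, 5), rownames(m$values))
  chain <- preprocess_mirna(m, bg, combat = FALSE)
  expect_equal(chain$matrix$state, "normalized")
})

test_that("batch adjustment leaves downstream association close to batch-free truth", {
  # same seed with and without batch effects; no batch-outcome confounding
  co <- generate_cohort(300, seed = 77)
  tr_b <- ground_truth(effects = data.frame(feature_id = "mir0001", outcome = "ad",
                                            frac_var = 0.1), batch_sd = 0.4)
  tr_0 <- ground_truth(effects = tr_b$effects, batch_sd = 0)
  g_b <- generate_mirna_counts(co, tr_b, n_features = 40, seed = 78)
  g_0 <- generate_mirna_counts(co, tr_0, n_features = 40, seed = 78)
  p_b <- preprocess_mirna(g_b$matrix, g_b$background)
  p_0 <- preprocess_mirna(g_0$matrix, g_0$background, combat = FALSE)
  a_b <- associate_all(p_b$matrix, co, outcomes = "ad")
  a_0 <- associate_all(p_0$matrix, co, outcomes = "ad")
  z_b <- a_b$z[a_b$feature_id == "mir0001"]
  z_0 <- a_0$z[a_0$feature_id == "mir0001"]
  expect_lt(abs(z_b - z_0) / abs(z_0), 0.25)
})
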