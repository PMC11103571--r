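test_that("compute_ratios covers the three modes and exclusion rules", {
  expect_equal(compute_ratios(c(4, 6), r = c(2, 3), mode = "reference")$xr, c(2, 2))
  # one PSM with channel intensities {2, 2, 4}: target 4 over channel sum 8
  expect_equal(compute_ratios(4, channel_sum = 8, mode = "channel_sum")$xr, 0.5)
  expect_equal(compute_ratios(c(1, 3), mode = "psm_sum")$xr, c(0.25, 0.75))
  # missing target or missing/zero reference excludes the PSM
  res <- compute_ratios(c(4, NA, 6), r = c(2, 5, NA), mode = "reference")
  expect_equal(res$keep, c(TRUE, FALSE, FALSE))
  expect_equal(res$xr, 2)
  expect_error(compute_ratios(c(1, 2), mode = "reference"), "reference")
})

test_that("compute_weights matches the closed form and normalizes", {
  w <- compute_weights(16, 1)
  expect_equal(w$f, 8)                 # (16*1)^0.75 = 8 exactly
  expect_equal(w$fr, 1)
  expect_equal(compute_weights(c(16, 16), c(1, 1))$fr, c(0.5, 0.5))
  # direct evaluation oracle: F = (P*T)^0.75 normalized
  f_direct <- c(1, 3)^0.75
  expect_equal(compute_weights(c(1, 3), c(1, 1))$fr, f_direct / sum(f_direct),
               tolerance = 1e-12)
  expect_warning(w0 <- compute_weights(c(0, 0), c(1, 1)), "uniform")
  expect_equal(w0$fr, c(0.5, 0.5))
  expect_warning(wna <- compute_weights(c(4, 9), c(1, NA)), "fill time")
  expect_equal(wna$f, c(4^0.75, 9^0.75))
})

test_that("weighted_median reproduces worked examples and validates input", {
  expect_equal(weighted_median(c(1, 2, 3), rep(1 / 3, 3)), 2)
  expect_equal(weighted_median(c(3, 1, 2), c(0.2, 0.6, 0.2)), 1)
  expect_equal(weighted_median(7, 1), 7)
  # two PSMs, equal weights: lower weighted median by the smallest-k tie-break
  expect_equal(weighted_median(c(1.5, 0.5), c(0.5, 0.5)), 0.5)
  expect_identical(weighted_median(numeric(0), numeric(0)), NA_real_)
  expect_error(weighted_median(c(1, 2), c(0.9, 0.3)), "sum")
})

test_that("weighted_median agrees with the brute-force selection oracle", {
  set.seed(101)
  for (i in 1:500) {
    n <- sample(1:6, 1)
    x <- round(stats::runif(n, 0, 10), 2)
    w <- if (i %% 2 == 0) rep(1 / n, n) else {
      raw <- stats::runif(n)
      raw / sum(raw)
    }
    expect_equal(weighted_median(x, w), wmed_oracle(x, w))
  }
})

test_that("weighted_median properties: bounds, permutation and scale invariance, classic median", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    x <- stats::rexp(n)
    w <- stats::runif(n)
    w <- w / sum(w)
    m <- weighted_median(x, w)
    expect_gte(m, min(x))
    expect_lte(m, max(x))
    p <- sample(n)
    expect_equal(weighted_median(x[p], w[p]), m)
    expect_equal(weighted_median(7.5 * x, w), 7.5 * m)
  }
  # equal weights: classic median for odd n, lower median for even n
  expect_equal(weighted_median(c(5, 1, 9), rep(1 / 3, 3)), 5)
  expect_equal(weighted_median(c(5, 1, 9, 7), rep(0.25, 4)), 5)
})

test_that("normalize_protein_table rolls up single-PSM proteins as plain ratios", {
  # one protein, one PSM, C = 6 channels; reference in channel 2
  reporters <- matrix(c(1000, 50, 5, 100, 150, 200), nrow = 1)
  psms <- make_psms(reporters, protein_id = "P001")
  qm <- normalize_protein_table(psms, make_ann(C = 6), mode = "reference")
  expect_identical(qm$scale, "linear")
  # output columns: control + three single cells (carrier/reference dropped)
  expect_setequal(qm$samples$role, c("control", "single_cell"))
  sc_cols <- qm$samples$sample_id[qm$samples$role == "single_cell"]
  expect_equal(unname(qm$values["P001", sc_cols]), c(100, 150, 200) / 50)
  # control channels dropped when keep_control = FALSE
  qm2 <- normalize_protein_table(psms, make_ann(C = 6), keep_control = FALSE)
  expect_true(all(qm2$samples$role == "single_cell"))
})

test_that("two equal-weight PSMs give the lower ratio and missing batches stay missing", {
  reporters <- rbind(c(NA, 10, NA, 20, 40, NA),
                     c(NA, 10, NA, 30, 60, NA))
  psms <- make_psms(reporters, protein_id = "P001")
  ann2 <- rbind(make_ann("b1", 6), make_ann("b2", 6))
  qm <- normalize_protein_table(psms, ann2, mode = "reference")
  b1_sc <- qm$samples$sample_id[qm$samples$batch_id == "b1" &
                                  qm$samples$role == "single_cell"]
  # channel 4: ratios {2, 3} with equal weights -> lower weighted median 2
  expect_equal(unname(qm$values["P001", b1_sc]), c(2, 4, NA))
  # protein absent from batch 2 of 2 -> all batch-2 columns missing
  b2_cols <- qm$samples$sample_id[qm$samples$batch_id == "b2"]
  expect_true(all(is.na(qm$values["P001", b2_cols])))
  # 6 of 8 columns missing: the NA control/ch6 in batch 1 plus all of batch 2
  expect_equal(mean(is.na(qm$values)), 6 / 8)
})

test_that("reference-mode rollup is invariant to joint rescaling and PSM order", {
  set.seed(33)
  C <- 6
  reporters <- matrix(stats::runif(5 * C, 10, 100), 5, C)
  psms <- make_psms(reporters, protein_id = rep("P001", 5),
                    precursor = stats::runif(5, 1e4, 1e6),
                    fill_time = stats::runif(5, 5, 50))
  ann <- make_ann(C = C)
  base <- normalize_protein_table(psms, ann)
  scaled <- make_psms(reporters * 37, protein_id = rep("P001", 5),
                      precursor = psms$precursor_intensity,
                      fill_time = psms$fill_time)
  expect_equal(normalize_protein_table(scaled, ann)$values, base$values,
               tolerance = 1e-12)
  p <- sample(5)
  perm <- make_psms(reporters[p, ], protein_id = rep("P001", 5),
                    precursor = psms$precursor_intensity[p],
                    fill_time = psms$fill_time[p])
  expect_equal(normalize_protein_table(perm, ann)$values, base$values,
               tolerance = 1e-12)
})

test_that("log2_transform maps values, keeps the mask and flips the scale flag", {
  v <- matrix(c(8, 1, NA, 0.5), 2, 2)
  qm <- make_qm(v, scale = "linear", roles = rep("single_cell", 2))
  lg <- log2_transform(qm)
  expect_equal(lg$values[!is.na(lg$values)], c(3, 0, -1))
  expect_identical(is.na(lg$values), is.na(qm$values))
  expect_identical(lg$scale, "log2")
  expect_error(log2_transform(lg), "already")
  bad <- make_qm(matrix(c(-1, 2), 1, 2), scale = "linear")
  expect_error(log2_transform(bad), "positive")
})
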