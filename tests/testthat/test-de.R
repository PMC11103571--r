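make_de_matrix <- function(n_prot, n1, n2, delta = 0, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(n_prot * (n1 + n2)), n_prot, n1 + n2)
  v[, seq_len(n1)] <- v[, seq_len(n1)] + delta
  rownames(v) <- sprintf("P%04d", seq_len(n_prot))
  colnames(v) <- sprintf("s%02d", seq_len(n1 + n2))
  list(v = v, labels = rep(c("A", "B"), c(n1, n2)))
}

test_that("bh_adjust matches the step-up definition and base oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(12)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("d0 = 0 reduces to the ordinary pooled two-sample t", {
  d <- make_de_matrix(5, 3, 3, delta = 0.8, seed = 3)
  res <- moderated_t_test(d$v, d$labels, prior = list(d0 = 0, s0_2 = 1))
  for (i in 1:5) {
    tt <- stats::t.test(d$v[i, 1:3], d$v[i, 4:6], var.equal = TRUE)
    expect_equal(res$t_mod[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-10)
    expect_equal(res$log2_fc[i], unname(diff(rev(tt$estimate))), tolerance = 1e-10)
  }
})

test_that("d0 = Inf orders |t| exactly like |log2_fc|", {
  d <- make_de_matrix(50, 4, 4, seed = 4)
  res <- moderated_t_test(d$v, d$labels, prior = list(d0 = Inf, s0_2 = 0.7))
  expect_equal(order(abs(res$t_mod)), order(abs(res$log2_fc)))
  expect_true(all(res$s2_post == 0.7))
})

test_that("identical group means give t = 0 and p = 1", {
  v <- matrix(rnorm(40), 10, 4)
  v <- cbind(v, v)    # group B duplicates group A -> identical means
  rownames(v) <- sprintf("P%02d", 1:10)
  colnames(v) <- sprintf("s%02d", 1:8)
  res <- moderated_t_test(v, rep(c("A", "B"), each = 4))
  expect_true(all(res$t_mod == 0))
  expect_true(all(res$p_value == 1))
})

test_that("estimated prior and moderated t agree with the limma oracle", {
  skip_if_not_installed("limma")
  d <- make_de_matrix(300, 5, 5, seed = 8)
  d$v <- d$v * rep(sqrt(stats::rchisq(300, 5) / 5), 10)  # heterogeneous variances
  res <- moderated_t_test(d$v, d$labels)
  design <- cbind(1, as.integer(d$labels == "A"))
  fit <- limma::eBayes(limma::lmFit(d$v, design))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s0_2"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_mod, fit$t[, 2], ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(res$p_value, fit$p.value[, 2], ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(res$q_value, stats::p.adjust(fit$p.value[, 2], "BH"),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("shrinkage reduces variance spread and permutation flips signs only", {
  d <- make_de_matrix(200, 4, 4, seed = 9)
  d$v <- d$v * rep(sqrt(stats::rchisq(200, 4) / 4), 8)  # spread true variances
  res <- moderated_t_test(d$v, d$labels)
  expect_lt(stats::var(res$s2_post), stats::var(res$s2))

  relev <- moderated_t_test(d$v, factor(d$labels, levels = c("B", "A")))
  expect_equal(relev$log2_fc, -res$log2_fc)
  expect_equal(relev$t_mod, -res$t_mod)
  expect_equal(relev$p_value, res$p_value)
  expect_equal(relev$q_value, res$q_value)
})

test_that("homogeneous variances trigger the infinite-prior fallback with a warning", {
  set.seed(77)
  v <- matrix(rnorm(30 * 8), 30, 8)
  v <- v / sqrt(rowSums((v - rowMeans(v))^2) / 7)   # force near-equal variances
  rownames(v) <- sprintf("P%02d", 1:30)
  colnames(v) <- sprintf("s%d", 1:8)
  expect_warning(res <- moderated_t_test(v, rep(c("A", "B"), each = 4)),
                 "infinite prior")
  expect_true(is.infinite(attr(res, "d0")))
  expect_true(all(res$df_total == Inf))
})

test_that("null data yields near-uniform p-values", {
  d <- make_de_matrix(2000, 10, 10, seed = 10)
  # homogeneous true variances may trip the (correct) d0 = Inf fallback
  res <- suppressWarnings(moderated_t_test(d$v, d$labels))
  expect_equal(mean(res$p_value <= 0.05), 0.05, tolerance = 0.4)
  expect_equal(mean(res$p_value <= 0.5), 0.5, tolerance = 0.1)
})

test_that("input validation catches bad designs", {
  d <- make_de_matrix(10, 2, 2)
  expect_error(moderated_t_test(d$v, rep("A", 4)), "two levels")
  expect_error(moderated_t_test(d$v, c("A", "A", "A", "B")), "at least 2")
  d$v[1, 1] <- NA
  expect_error(moderated_t_test(d$v, d$labels), "complete")
})

test_that("volcano_table sorts by q and applies the boundary inclusively", {
  res <- data.frame(protein_id = c("a", "b", "c"),
                    log2_fc = c(1, -2, 0.5),
                    q_value = c(0.2, 0.049, 0.05))
  out <- volcano_table(res, q_cutoff = 0.05)
  expect_equal(out$protein_id, c("b", "c", "a"))
  expect_identical(out$significant, c(TRUE, TRUE, FALSE))
  expect_equal(out$neg_log10_q[out$protein_id == "c"], -log10(0.05))
  empty <- volcano_table(res[0, ])
  expect_equal(nrow(empty), 0L)
})
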