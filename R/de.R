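#' Invert the trigamma function
#'
#' Newton iteration on `1/trigamma`, which is nearly linear; used by the
#' moment-matching estimator of the variance prior.
#'
#' @param x positive values.
#' @return `y` with `trigamma(y) = x`; `Inf` maps to 0-variance prior limit.
#' @keywords internal
trigamma_inverse <- function(x) {
  out <- x
  large <- x > 1e7
  out[large] <- 1 / sqrt(x[large])
  small <- x < 1e-6
  out[small] <- 1 / x[small]
  mid <- !large & !small
  if (any(mid)) {
    y <- 0.5 + 1 / x[mid]
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / x[mid]) / psigamma(y, 2)
      y <- y + dif
      if (max(abs(dif / y)) < 1e-8) break
    }
    out[mid] <- y
  }
  out
}

# Moment-matching estimate of the variance prior (d0, s0^2) from per-protein
# sample variances s2 with common residual df dg: the log variances follow a
# scaled log-F, so their spread above trigamma(dg/2) identifies d0 and their
# location identifies s0^2.
estimate_variance_prior <- function(s2, dg) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(dg / 2) + log(dg / 2)
  ev <- stats::var(z) - trigamma(dg / 2)
  if (!is.finite(ev) || ev <= 0) {
    warning("log-variance spread not above sampling noise; using an infinite prior df")
    return(list(d0 = Inf, s0_2 = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(ev)
  s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1, returned in the
#' original order.
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no NA")
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Two-group moderated t-test with empirical-Bayes variance shrinkage
#'
#' For each protein the pooled within-group variance `s_g^2` (residual df
#' `d_g = n1 + n2 - 2`) is shrunk toward a prior `(d0, s0^2)` estimated by
#' moment matching on the log variances (or supplied): the posterior
#' variance is `(d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)`, the moderated t is
#' `log2_fc / (s_tilde * sqrt(1/n1 + 1/n2))` with `d0 + d_g` degrees of
#' freedom, and q-values are Benjamini-Hochberg over all tested proteins.
#' `log2_fc` is `mean(group A) - mean(group B)` where A is the first factor
#' level of `labels`.
#'
#' @param x complete (imputed) log2 matrix or [quant_matrix()], proteins in
#'   rows.
#' @param labels two-level factor (or coercible) over the columns; each
#'   level needs at least 2 samples.
#' @param prior optional list `list(d0 =, s0_2 =)` to bypass estimation;
#'   `d0 = 0` yields the ordinary pooled t, `d0 = Inf` a fully shrunk t.
#' @param q_cutoff significance cutoff on the q-value (default 0.05).
#' @return `data.frame` of class `de_result`: `protein_id`, `log2_fc`, `s2`,
#'   `s2_post`, `t_mod`, `df_total`, `p_value`, `q_value`, `significant`;
#'   attributes `d0`, `s0_2`, and counts under both the q and raw-p rules.
#' @export
moderated_t_test <- function(x, labels, prior = NULL, q_cutoff = 0.05) {
  v <- if (inherits(x, "quant_matrix")) x$values else x
  stopifnot(is.matrix(v), is.numeric(v))
  if (anyNA(v)) stop("moderated_t_test expects a complete (imputed) matrix")
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("labels must have exactly two levels, got ", nlevels(labels))
  if (length(labels) != ncol(v)) stop("one label per column required")
  n1 <- sum(labels == levels(labels)[1])
  n2 <- sum(labels == levels(labels)[2])
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")

  g1 <- v[, labels == levels(labels)[1], drop = FALSE]
  g2 <- v[, labels == levels(labels)[2], drop = FALSE]
  m1 <- rowMeans(g1)
  m2 <- rowMeans(g2)
  lfc <- m1 - m2
  ss1 <- rowSums((g1 - m1)^2)
  ss2 <- rowSums((g2 - m2)^2)
  dg <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / dg

  if (is.null(prior)) prior <- estimate_variance_prior(s2, dg)
  d0 <- prior$d0
  s0_2 <- prior$s0_2
  if (is.infinite(d0)) {
    s2_post <- rep(s0_2, length(s2))
    df_total <- rep(Inf, length(s2))
  } else {
    s2_post <- (d0 * s0_2 + dg * s2) / (d0 + dg)
    df_total <- rep(d0 + dg, length(s2))
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  p <- 2 * stats::pt(abs(t_mod), df = df_total, lower.tail = FALSE)
  q <- bh_adjust(p)

  out <- data.frame(protein_id = rownames(v), log2_fc = lfc, s2 = s2,
                    s2_post = s2_post, t_mod = t_mod, df_total = df_total,
                    p_value = p, q_value = q,
                    significant = q <= q_cutoff,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  attr(out, "groups") <- levels(labels)
  attr(out, "n_significant_q") <- sum(q <= q_cutoff)
  attr(out, "n_significant_p") <- sum(p <= q_cutoff)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Volcano table from differential-expression results
#'
#' @param results [moderated_t_test()] output.
#' @param q_cutoff significance cutoff (default 0.05; `-log10` of it is the
#'   usual dashed line on the plot).
#' @return `data.frame` with `protein_id`, `log2_fc`, `neg_log10_q`,
#'   `significant`, sorted by q-value.
#' @export
volcano_table <- function(results, q_cutoff = 0.05) {
  if (!nrow(results)) {
    return(data.frame(protein_id = character(0), log2_fc = numeric(0),
                      neg_log10_q = numeric(0), significant = logical(0)))
  }
  out <- data.frame(protein_id = results$protein_id,
                    log2_fc = results$log2_fc,
                    neg_log10_q = -log10(results$q_value),
                    significant = results$q_value <= q_cutoff,
                    stringsAsFactors = FALSE)
  out[order(results$q_value), , drop = FALSE]
}
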