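#' @importFrom data.table := .N .SD
NULL

# Fast weighted-median kernel without argument validation; callers guarantee
# length(x) == length(w) >= 1 and w >= 0 with sum(w) > 0. Returns the lower
# weighted median: the smallest sorted index k whose flanking cumulative
# weights both stay at or below half the total weight.
wmed_fast <- function(x, w, tol = 1e-9) {
  o <- order(x)
  xs <- x[o]
  ws <- w[o]
  cs <- cumsum(ws)
  tot <- cs[length(cs)]
  left <- cs - ws          # sum of weights strictly below k
  right <- tot - cs        # sum of weights strictly above k
  half <- tot / 2 + tol * tot
  k <- which(left <= half & right <= half)[1L]
  xs[k]
}

#' Weighted median of normalized PSM ratios
#'
#' The protein value is the sorted ratio at the smallest index `k` whose
#' cumulative weight strictly below `k` and strictly above `k` are both at
#' most one half. When a cumulative weight hits exactly one half two adjacent
#' `k` qualify; the smaller (lower weighted median) is returned for
#' determinism. With equal weights this reduces to the classic median for odd
#' `n` and the lower median for even `n`.
#'
#' @param x numeric vector of ratios (length `n >= 1`).
#' @param w numeric vector of normalized weights, same length, summing to 1.
#' @param tol tolerance on the weight-sum check.
#' @return the weighted median, or `NA_real_` for empty input.
#' @export
weighted_median <- function(x, w, tol = 1e-6) {
  if (length(x) == 0L) return(NA_real_)
  if (length(x) != length(w))
    stop("'x' and 'w' must have the same length")
  if (anyNA(x) || anyNA(w)) stop("'x' and 'w' must not contain NA")
  if (any(w < 0)) stop("weights must be non-negative")
  if (abs(sum(w) - 1) > tol)
    stop(sprintf("internal error: weights sum to %.8f, expected 1", sum(w)))
  wmed_fast(x, w)
}

#' PSM weighting factors from precursor intensity and fill time
#'
#' The raw weight of a PSM is `(precursor intensity x MS/MS fill time)^e`
#' with exponent `e = 0.75` by default; the product is a proxy for the ion
#' population that was fragmented. Weights are then normalized to sum to 1.
#' A PSM with missing fill time falls back to `precursor^e` (with a
#' warning); if every product is zero or missing, uniform weights are used.
#'
#' @param p precursor intensities (>= 0).
#' @param t fill times in ms (>= 0); may contain `NA`.
#' @param exponent weight exponent, default 0.75.
#' @return list with `f` (raw weights) and `fr` (normalized, sum 1).
#' @export
compute_weights <- function(p, t, exponent = 0.75) {
  n <- length(p)
  if (length(t) != n) stop("'p' and 't' must have the same length")
  if (n == 0L) return(list(f = numeric(0), fr = numeric(0)))
  prod <- p * t
  fallback <- is.na(t) & !is.na(p)
  if (any(fallback)) {
    warning(sprintf("%d PSM(s) with missing fill time: weighting by precursor intensity alone",
                    sum(fallback)))
    prod[fallback] <- p[fallback]
  }
  f <- prod^exponent
  s <- sum(f, na.rm = TRUE)
  if (!is.finite(s) || s <= 0 || all(is.na(f))) {
    warning("all PSM weight products are zero or missing; using uniform weights")
    f[] <- ifelse(is.na(f), 0, f)
    fr <- rep(1 / n, n)
  } else {
    f[is.na(f)] <- 0
    fr <- f / sum(f)
  }
  list(f = f, fr = fr)
}

#' Normalized PSM ratios for one protein/channel group
#'
#' In `reference` mode each PSM's target-channel intensity is divided by the
#' same PSM's reference-channel intensity, cancelling PSM- and batch-level
#' effects. Without a reference channel, `channel_sum` mode divides by the
#' PSM's total reporter signal across all non-missing channels (the reading
#' under which a median across PSMs is meaningful), while `psm_sum` divides
#' by the sum of the group's target-channel intensities across PSMs.
#'
#' @param x target-channel intensities, one per PSM (may contain `NA`).
#' @param r reference-channel intensities, same order (reference mode).
#' @param channel_sum per-PSM sum of reporter intensities over non-missing
#'   channels (channel_sum mode).
#' @param mode one of `"reference"`, `"channel_sum"`, `"psm_sum"`.
#' @return list with `xr` (ratios, finite and positive) and `keep` (logical
#'   index of the PSMs retained). PSMs with missing `x`, or missing/zero
#'   denominator, are excluded; if none remain, `xr` is empty.
#' @export
compute_ratios <- function(x, r = NULL, channel_sum = NULL,
                           mode = c("reference", "channel_sum", "psm_sum")) {
  mode <- match.arg(mode)
  keep <- !is.na(x) & x > 0
  if (mode == "reference") {
    if (is.null(r)) stop("reference mode requires reference-channel intensities")
    keep <- keep & !is.na(r) & r > 0
    xr <- x[keep] / r[keep]
  } else if (mode == "channel_sum") {
    if (is.null(channel_sum)) stop("channel_sum mode requires per-PSM channel sums")
    keep <- keep & !is.na(channel_sum) & channel_sum > 0
    xr <- x[keep] / channel_sum[keep]
  } else {
    xr <- x[keep]
    xr <- xr / sum(xr)
  }
  list(xr = xr, keep = keep)
}

#' Roll PSM-level reporter intensities up to protein values
#'
#' For every protein and sample channel within each batch, the retained PSM
#' ratios (see [compute_ratios()]) are combined by a weighted median with
#' weights from [compute_weights()]. Carrier, reference and unused channels
#' never appear in the output; control and empty channels are retained by
#' default for QC diagnostics and should be dropped before differential
#' expression. Batches are processed independently: it is the reference
#' ratio that makes values comparable across batches.
#'
#' @param psms filtered PSM table ([read_psm_table()] then
#'   [filter_identifications()]).
#' @param annotation channel annotation ([read_annotation()]).
#' @param mode ratio mode, see [compute_ratios()]; default `"reference"`.
#' @param weight_exponent exponent of the PSM weight product, default 0.75.
#' @param keep_control keep control/empty channels as output columns
#'   (default `TRUE`).
#' @return a linear-scale [quant_matrix()] of ratios; `NA` where a protein
#'   has no usable PSM for a channel.
#' @export
normalize_protein_table <- function(psms, annotation,
                                    mode = c("reference", "channel_sum", "psm_sum"),
                                    weight_exponent = 0.75,
                                    keep_control = TRUE) {
  mode <- match.arg(mode)
  psms <- data.table::as.data.table(psms)
  ann <- validate_annotation(annotation)
  rep_cols <- grep("^reporter_[0-9]+$", names(psms), value = TRUE)
  n_channels <- length(rep_cols)
  if (n_channels == 0L) stop("PSM table has no reporter_* columns")

  out_roles <- if (keep_control) c("single_cell", "control", "empty") else "single_cell"
  out_ann <- ann[ann$role %in% out_roles, ]
  if (nrow(out_ann) == 0L) stop("annotation yields no output channels")

  batches <- unique(psms$batch_id)
  missing_ann <- setdiff(batches, unique(ann$batch_id))
  if (length(missing_ann))
    stop("no channel annotation for batch(es): ", paste(missing_ann, collapse = ", "))

  # per-PSM raw weight (constant across channels of the PSM)
  p <- psms$precursor_intensity
  t <- psms$fill_time
  prod <- p * t
  fb <- is.na(t) & !is.na(p)
  if (any(fb)) {
    warning(sprintf("%d PSM(s) with missing fill time: weighting by precursor intensity alone",
                    sum(fb)))
    prod[fb] <- p[fb]
  }
  fw <- prod^weight_exponent
  fw[!is.finite(fw)] <- NA_real_

  rep_mat <- as.matrix(psms[, rep_cols, with = FALSE])
  chan_sum <- rowSums(rep_mat, na.rm = TRUE)
  chan_sum[chan_sum == 0] <- NA_real_

  # reference intensity per PSM, by batch
  refs <- ann[ann$role == "reference", ]
  ref_by_batch <- stats::setNames(as.list(refs$channel), refs$batch_id)
  ref_int <- rep(NA_real_, nrow(psms))
  if (mode == "reference") {
    if (length(ref_by_batch) == 0L)
      stop("reference mode requires a reference channel in the annotation")
    for (b in batches) {
      rc <- ref_by_batch[[b]]
      if (is.null(rc))
        stop("reference mode: batch '", b, "' has no reference channel annotated")
      idx <- psms$batch_id == b
      ref_int[idx] <- rep_mat[idx, rc]
    }
  }

  # long table restricted to output channels present in each batch
  long_list <- vector("list", nrow(out_ann))
  for (i in seq_len(nrow(out_ann))) {
    b <- out_ann$batch_id[i]
    ch <- out_ann$channel[i]
    idx <- which(psms$batch_id == b)
    if (!length(idx)) next
    long_list[[i]] <- data.table::data.table(
      protein_id = psms$protein_id[idx],
      sample_id = sprintf("%s_ch%02d", b, ch),
      x = rep_mat[idx, ch],
      r = ref_int[idx],
      cs = chan_sum[idx],
      f = fw[idx]
    )
  }
  long <- data.table::rbindlist(long_list)

  x <- r <- cs <- f <- sample_id <- protein_id <- NULL # R CMD check NSE
  keep <- !is.na(long$x) & long$x > 0
  keep <- switch(mode,
    reference = keep & !is.na(long$r) & long$r > 0,
    channel_sum = keep & !is.na(long$cs),
    psm_sum = keep)
  long <- long[keep]

  group_value <- switch(mode,
    reference = function(d) {
      w <- d$f
      if (all(is.na(w)) || sum(w, na.rm = TRUE) <= 0) w <- rep(1, nrow(d))
      w[is.na(w)] <- 0
      wmed_fast(d$x / d$r, w)
    },
    channel_sum = function(d) {
      w <- d$f
      if (all(is.na(w)) || sum(w, na.rm = TRUE) <= 0) w <- rep(1, nrow(d))
      w[is.na(w)] <- 0
      wmed_fast(d$x / d$cs, w)
    },
    psm_sum = function(d) {
      w <- d$f
      if (all(is.na(w)) || sum(w, na.rm = TRUE) <= 0) w <- rep(1, nrow(d))
      w[is.na(w)] <- 0
      wmed_fast(d$x / sum(d$x), w)
    })

  vals <- long[, list(value = group_value(.SD)), by = c("protein_id", "sample_id"),
               .SDcols = c("x", "r", "cs", "f")]

  proteins <- sort(unique(psms$protein_id))
  sample_ids <- sprintf("%s_ch%02d", out_ann$batch_id, out_ann$channel)
  m <- matrix(NA_real_, nrow = length(proteins), ncol = length(sample_ids),
              dimnames = list(proteins, sample_ids))
  m[cbind(match(vals$protein_id, proteins), match(vals$sample_id, sample_ids))] <-
    vals$value

  samples <- data.frame(sample_id = sample_ids,
                        batch_id = out_ann$batch_id,
                        channel = out_ann$channel,
                        role = out_ann$role,
                        cell_type = out_ann$cell_type,
                        stringsAsFactors = FALSE)
  quant_matrix(m, samples, scale = "linear")
}

#' Log2-transform a linear-scale quant_matrix
#'
#' @param x a linear-scale [quant_matrix()] with positive or missing entries.
#' @return the matrix on log2 scale; the missing mask is unchanged.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "quant_matrix"))
  if (x$scale != "linear") stop("matrix is already on log2 scale")
  v <- x$values
  if (any(!is.na(v) & v <= 0))
    stop("log2_transform: non-missing values must be positive")
  x$values <- log2(v)
  x$scale <- "log2"
  x
}
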