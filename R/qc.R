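#' Filter samples (cells) by valid-value percentage
#'
#' Retains the sample columns whose percentage of valid (non-missing)
#' protein values is at least `min_valid_within_cell`. The valid fraction is
#' computed over the full post-identification-filter protein universe, not
#' after any protein-level filtering, to avoid circularity between the two
#' axes. Thresholds are inclusive.
#'
#' @param x log2-scale [quant_matrix()].
#' @param min_valid_within_cell percent in `[0, 100]`.
#' @return the filtered `quant_matrix` with attribute `removed_samples`.
#' @export
cell_filter <- function(x, min_valid_within_cell) {
  stopifnot(inherits(x, "quant_matrix"))
  if (nrow(x$values) == 0L || ncol(x$values) == 0L)
    stop("cell_filter: empty matrix")
  stopifnot(min_valid_within_cell >= 0, min_valid_within_cell <= 100)
  pct <- 100 * valid_fraction_by_sample(x)
  keep <- pct >= min_valid_within_cell - 1e-9
  out <- qm_subset(x, samples = which(keep))
  attr(out, "removed_samples") <- colnames(x$values)[!keep]
  out
}

#' Filter proteins by valid-value percentage across retained samples
#'
#' Retains protein rows whose percentage of valid values across the current
#' sample columns is at least `min_valid_across_samples` (inclusive). Run
#' after [cell_filter()]: cell retention depends only on the cell threshold.
#'
#' @param x log2-scale [quant_matrix()] (after [cell_filter()]).
#' @param min_valid_across_samples percent in `[0, 100]`.
#' @return the filtered `quant_matrix` with attribute `removed_proteins`.
#' @export
protein_filter <- function(x, min_valid_across_samples) {
  stopifnot(inherits(x, "quant_matrix"))
  stopifnot(min_valid_across_samples >= 0, min_valid_across_samples <= 100)
  pct <- 100 * valid_fraction_by_protein(x)
  keep <- pct >= min_valid_across_samples - 1e-9
  out <- qm_subset(x, proteins = which(keep))
  attr(out, "removed_proteins") <- rownames(x$values)[!keep]
  out
}

# median across proteins of the per-protein sample variance (n-1 denominator)
# over one cell type's columns; proteins with < 2 observed values skipped.
median_protein_variance <- function(values) {
  if (ncol(values) < 2L) return(NA_real_)
  nv <- rowSums(!is.na(values))
  v <- apply(values[nv >= 2L, , drop = FALSE], 1L, stats::var, na.rm = TRUE)
  if (!length(v)) return(NA_real_)
  stats::median(v)
}

#' Quantification-quality threshold grid
#'
#' Evaluates the full cross-product of cell-level and protein-level
#' valid-value thresholds. For each pair it applies [cell_filter()] then
#' [protein_filter()] and records the retained protein and cell counts and,
#' per cell type, the median of per-protein sample variances computed on
#' observed (pre-imputation) values. Retained cell counts depend only on the
#' cell threshold, mirroring the table layout used to choose thresholds by
#' inspection.
#'
#' @param x log2-scale [quant_matrix()].
#' @param cell_thresholds,protein_thresholds percent vectors
#'   (default `c(0, 10, 30, 50, 70, 90)` each).
#' @return `data.frame` of class `qc_grid` with columns `cell_threshold`,
#'   `protein_threshold`, `retained_proteins`, `retained_cells`, and one
#'   `median_variance_<type>` column per cell type.
#' @export
qc_grid <- function(x,
                    cell_thresholds = c(0, 10, 30, 50, 70, 90),
                    protein_thresholds = c(0, 10, 30, 50, 70, 90)) {
  stopifnot(inherits(x, "quant_matrix"))
  types <- sort(unique(stats::na.omit(
    x$samples$cell_type[x$samples$role == "single_cell"])))
  rows <- list()
  i <- 0L
  for (ct in cell_thresholds) {
    xc <- cell_filter(x, ct)
    for (pt in protein_thresholds) {
      xp <- protein_filter(xc, pt)
      i <- i + 1L
      row <- data.frame(cell_threshold = ct, protein_threshold = pt,
                        retained_proteins = nrow(xp$values),
                        retained_cells = ncol(xc$values))
      for (ty in types) {
        cols <- which(xp$samples$role == "single_cell" &
                        !is.na(xp$samples$cell_type) & xp$samples$cell_type == ty)
        row[[paste0("median_variance_", ty)]] <-
          median_protein_variance(xp$values[, cols, drop = FALSE])
      }
      rows[[i]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("qc_grid", "data.frame")
  out
}

#' Reshape a qc_grid into the wide threshold-table layout
#'
#' One row per cell threshold; protein-count columns per protein threshold,
#' plus the cell count (which varies only with the cell threshold).
#'
#' @param grid result of [qc_grid()].
#' @return wide `data.frame`.
#' @export
qc_grid_table <- function(grid) {
  stopifnot(inherits(grid, "qc_grid"))
  cts <- unique(grid$cell_threshold)
  pts <- unique(grid$protein_threshold)
  out <- data.frame(cell_threshold = cts)
  for (pt in pts) {
    out[[sprintf("proteins_at_%g", pt)]] <-
      grid$retained_proteins[match(paste(cts, pt),
                                   paste(grid$cell_threshold, grid$protein_threshold))]
  }
  out$cells <- grid$retained_cells[match(paste(cts, pts[1]),
                                         paste(grid$cell_threshold, grid$protein_threshold))]
  out
}

#' Per-sample missing-value profile
#'
#' Percentage of missing protein values per sample column, tagged with the
#' channel role and cell type, with a flag for samples whose missingness
#' exceeds a cutoff (default 30 percent). Run before any filtering; control
#' and empty channels participate so that their dropout is visible.
#'
#' @param x [quant_matrix()].
#' @param cutoff percent missing above which a sample is flagged.
#' @return `data.frame` with `sample_id`, `batch_id`, `role`, `cell_type`,
#'   `missing_pct`, `above_cutoff`.
#' @export
missingness_profile <- function(x, cutoff = 30) {
  stopifnot(inherits(x, "quant_matrix"))
  miss <- 100 * colMeans(is.na(x$values))
  data.frame(sample_id = x$samples$sample_id,
             batch_id = x$samples$batch_id,
             role = x$samples$role,
             cell_type = x$samples$cell_type,
             missing_pct = unname(miss),
             above_cutoff = unname(miss > cutoff),
             stringsAsFactors = FALSE)
}

#' Exclude proteins with too few supporting PSMs
#'
#' Proteins quantified from a single PSM carry substantial missingness and
#' are excluded from differential expression by default (`min_psm_count =
#' 2`). A protein absent from the count table is treated as count 0, with a
#' warning.
#'
#' @param x [quant_matrix()].
#' @param psm_counts named integer vector (names = protein ids) of total PSM
#'   counts, or a protein-group table with `protein_id` and `psm_count`.
#' @param min_psm_count minimum PSM count to retain (default 2).
#' @return filtered `quant_matrix`.
#' @export
min_psm_filter <- function(x, psm_counts, min_psm_count = 2L) {
  stopifnot(inherits(x, "quant_matrix"), min_psm_count >= 1)
  if (is.data.frame(psm_counts)) {
    psm_counts <- stats::setNames(as.integer(psm_counts$psm_count),
                                  psm_counts$protein_id)
  }
  counts <- psm_counts[rownames(x$values)]
  if (anyNA(counts)) {
    warning(sprintf("%d protein(s) missing from the PSM count table; treated as count 0",
                    sum(is.na(counts))))
    counts[is.na(counts)] <- 0L
  }
  qm_subset(x, proteins = which(counts >= min_psm_count))
}

#' Tally PSMs per protein from a PSM table
#' @param psms PSM table ([read_psm_table()]).
#' @return named integer vector of PSM counts per protein id.
#' @export
psm_counts_by_protein <- function(psms) {
  tab <- table(psms$protein_id)
  stats::setNames(as.integer(tab), names(tab))
}
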