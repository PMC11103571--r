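#' Protein-by-sample quantification matrix
#'
#' A `quant_matrix` is the central container of the package: a numeric
#' proteins x samples matrix in which missing values are `NA` (never 0 --
#' a reporter-ion signal of zero is a detection failure, not a true zero),
#' together with a per-sample annotation table and a scale flag.
#'
#' @param values numeric matrix, proteins in rows (rownames = protein ids),
#'   samples in columns (colnames = sample ids). Missing entries are `NA`.
#' @param samples `data.frame` with one row per column of `values`, columns
#'   `sample_id`, `batch_id`, `channel`, `role`, `cell_type`. Row order must
#'   match the column order of `values`.
#' @param scale `"linear"` or `"log2"`.
#'
#' @return An object of class `quant_matrix`.
#' @export
quant_matrix <- function(values, samples, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  # R drops zero-length dimnames to NULL on subsetting; treat NULL names of
  # an empty dimension as empty
  if (is.null(rownames(values)) && nrow(values) > 0)
    stop("'values' must have row names")
  if (is.null(colnames(values)) && ncol(values) > 0)
    stop("'values' must have column names")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  needed <- c("sample_id", "batch_id", "channel", "role", "cell_type")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols))
    stop("sample annotation lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stop("nrow(samples) must equal ncol(values)")
  cn <- colnames(values)
  if (is.null(cn)) cn <- character(0)
  if (!identical(as.character(samples$sample_id), cn))
    stop("samples$sample_id must match colnames(values) in order")
  structure(list(values = values, samples = samples, scale = scale),
            class = "quant_matrix")
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' @export
print.quant_matrix <- function(x, ...) {
  d <- dim(x$values)
  miss <- mean(is.na(x$values))
  cat(sprintf("quant_matrix: %d proteins x %d samples [%s scale, %.1f%% missing]\n",
              d[1], d[2], x$scale, 100 * miss))
  roles <- table(x$samples$role)
  cat("  roles:", paste(sprintf("%s=%d", names(roles), roles), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a quant_matrix keeping values and sample annotation in sync
#'
#' @param x a `quant_matrix`.
#' @param proteins row index (names, integers or logical); `NULL` keeps all.
#' @param samples column index; `NULL` keeps all.
#' @return the subsetted `quant_matrix`.
#' @export
qm_subset <- function(x, proteins = NULL, samples = NULL) {
  stopifnot(inherits(x, "quant_matrix"))
  v <- x$values
  ann <- x$samples
  if (!is.null(proteins)) v <- v[proteins, , drop = FALSE]
  if (!is.null(samples)) {
    v <- v[, samples, drop = FALSE]
    ann <- ann[match(colnames(v), ann$sample_id), , drop = FALSE]
    rownames(ann) <- NULL
  }
  quant_matrix(v, ann, scale = x$scale)
}

#' Fraction of valid (non-missing) entries per sample column
#' @param x a `quant_matrix`.
#' @return named numeric vector in `[0, 1]`.
#' @export
valid_fraction_by_sample <- function(x) {
  stopifnot(inherits(x, "quant_matrix"))
  colMeans(!is.na(x$values))
}

#' Fraction of valid (non-missing) entries per protein row
#' @param x a `quant_matrix`.
#' @return named numeric vector in `[0, 1]`.
#' @export
valid_fraction_by_protein <- function(x) {
  stopifnot(inherits(x, "quant_matrix"))
  rowMeans(!is.na(x$values))
}
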