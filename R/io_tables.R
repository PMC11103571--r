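#' Column dialects for search-engine tables
#'
#' A dialect maps the columns of a vendor PSM (evidence-style) table onto the
#' fields this package needs. The default dialect matches MaxQuant
#' `evidence.txt` column names; nothing else about the search engine is
#' assumed. Boolean flag columns follow the MaxQuant convention of `"+"` for
#' TRUE and blank for FALSE.
#'
#' @param reporter_prefix prefix of the per-channel reporter columns; the
#'   channel number (1-based) is appended.
#' @param n_channels number of reporter channels (18 for TMTpro-18plex).
#' @param protein_col column holding the protein-group identifier.
#' @param batch_col column holding the batch/run identifier; `NA` means use
#'   the file name stem.
#' @param precursor_col precursor (MS1) intensity column.
#' @param fill_time_col MS/MS ion injection (fill) time column, in ms.
#' @param reverse_col,contaminant_col decoy / contaminant flag columns.
#' @param id_col PSM identifier column; `NA` means use the row number.
#'
#' @return a list of class `psm_dialect`.
#' @export
psm_dialect <- function(reporter_prefix = "Reporter intensity corrected ",
                        n_channels = 18,
                        protein_col = "Leading razor protein",
                        batch_col = "Raw file",
                        precursor_col = "Intensity",
                        fill_time_col = "Ion injection time",
                        reverse_col = "Reverse",
                        contaminant_col = "Potential contaminant",
                        id_col = NA_character_) {
  structure(list(reporter_prefix = reporter_prefix, n_channels = n_channels,
                 protein_col = protein_col, batch_col = batch_col,
                 precursor_col = precursor_col, fill_time_col = fill_time_col,
                 reverse_col = reverse_col, contaminant_col = contaminant_col,
                 id_col = id_col),
            class = "psm_dialect")
}

#' Dialect for protein-group tables (proteinGroups.txt style)
#' @param protein_col,gene_col,reverse_col,contaminant_col,site_col,psm_count_col
#'   column names in the vendor table.
#' @return a list of class `pg_dialect`.
#' @export
pg_dialect <- function(protein_col = "Protein IDs",
                       gene_col = "Gene names",
                       reverse_col = "Reverse",
                       contaminant_col = "Potential contaminant",
                       site_col = "Only identified by site",
                       psm_count_col = "MS/MS count") {
  structure(list(protein_col = protein_col, gene_col = gene_col,
                 reverse_col = reverse_col, contaminant_col = contaminant_col,
                 site_col = site_col, psm_count_col = psm_count_col),
            class = "pg_dialect")
}

flag_to_logical <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  x <- trimws(as.character(x))
  !is.na(x) & x %in% c("+", "TRUE", "True", "true", "1", "yes")
}

require_columns <- function(tab, cols, what) {
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    stop(sprintf("%s: mandatory column(s) not found: %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
}

#' Read a PSM-level quantification table
#'
#' Reads a tab-delimited evidence-style table and standardizes it. Reporter
#' intensities of 0 or blank are recorded as missing (`NA`): a zero reporter
#' signal indicates a detection failure, never a true zero.
#'
#' @param path file path to the tab-delimited table.
#' @param dialect a [psm_dialect()].
#' @return a `data.table` with columns `psm_id`, `protein_id`, `batch_id`,
#'   `reporter_1` .. `reporter_C` (NA = missing), `precursor_intensity`,
#'   `fill_time`, `is_reverse`, `is_contaminant`. Row order of the file is
#'   preserved.
#' @export
read_psm_table <- function(path, dialect = psm_dialect()) {
  stopifnot(inherits(dialect, "psm_dialect"))
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           na.strings = c("", "NA", "NaN"),
                           check.names = FALSE, data.table = TRUE)
  rep_cols <- paste0(dialect$reporter_prefix, seq_len(dialect$n_channels))
  mandatory <- c(rep_cols, dialect$protein_col, dialect$precursor_col,
                 dialect$fill_time_col)
  require_columns(tab, mandatory, sprintf("PSM table '%s'", basename(path)))

  num_or_die <- function(col) {
    v <- tab[[col]]
    if (is.character(v)) {
      out <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(out))
      if (length(bad))
        stop(sprintf("PSM table '%s': non-numeric value '%s' in column '%s' at row %d",
                     basename(path), v[bad[1]], col, bad[1]), call. = FALSE)
      out
    } else as.numeric(v)
  }

  reporters <- vapply(rep_cols, num_or_die, numeric(nrow(tab)))
  if (!is.matrix(reporters)) reporters <- matrix(reporters, nrow = nrow(tab))
  reporters[!is.na(reporters) & reporters == 0] <- NA_real_

  batch_id <- if (!is.na(dialect$batch_col) && dialect$batch_col %in% names(tab)) {
    as.character(tab[[dialect$batch_col]])
  } else {
    rep(tools::file_path_sans_ext(basename(path)), nrow(tab))
  }
  psm_id <- if (!is.na(dialect$id_col) && dialect$id_col %in% names(tab)) {
    as.character(tab[[dialect$id_col]])
  } else {
    sprintf("%s:%d", tools::file_path_sans_ext(basename(path)), seq_len(nrow(tab)))
  }

  out <- data.table::data.table(
    psm_id = psm_id,
    protein_id = as.character(tab[[dialect$protein_col]]),
    batch_id = batch_id,
    precursor_intensity = num_or_die(dialect$precursor_col),
    fill_time = num_or_die(dialect$fill_time_col),
    is_reverse = if (dialect$reverse_col %in% names(tab))
      flag_to_logical(tab[[dialect$reverse_col]]) else rep(FALSE, nrow(tab)),
    is_contaminant = if (dialect$contaminant_col %in% names(tab))
      flag_to_logical(tab[[dialect$contaminant_col]]) else rep(FALSE, nrow(tab))
  )
  rep_std <- data.table::as.data.table(reporters)
  data.table::setnames(rep_std, paste0("reporter_", seq_len(dialect$n_channels)))
  out <- cbind(out, rep_std)
  attr(out, "n_channels") <- dialect$n_channels
  out[]
}

#' Read a protein-group table
#'
#' @param path tab-delimited protein-group table.
#' @param dialect a [pg_dialect()].
#' @return `data.table` with `protein_id`, `gene_name`, `is_reverse`,
#'   `is_contaminant`, `is_site_only`, `psm_count`.
#' @export
read_protein_groups <- function(path, dialect = pg_dialect()) {
  stopifnot(inherits(dialect, "pg_dialect"))
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           na.strings = c("", "NA"), check.names = FALSE)
  require_columns(tab, dialect$protein_col,
                  sprintf("protein-group table '%s'", basename(path)))
  getcol <- function(col, default) {
    if (col %in% names(tab)) tab[[col]] else rep(default, nrow(tab))
  }
  data.table::data.table(
    protein_id = as.character(tab[[dialect$protein_col]]),
    gene_name = as.character(getcol(dialect$gene_col, NA_character_)),
    is_reverse = flag_to_logical(getcol(dialect$reverse_col, FALSE)),
    is_contaminant = flag_to_logical(getcol(dialect$contaminant_col, FALSE)),
    is_site_only = flag_to_logical(getcol(dialect$site_col, FALSE)),
    psm_count = as.integer(getcol(dialect$psm_count_col, NA_integer_))
  )
}

VALID_ROLES <- c("carrier", "reference", "control", "unused", "empty", "single_cell")

#' Read and validate a channel-annotation table
#'
#' Maps (batch, channel index) to a channel role and, for single cells, a
#' cell type. Roles decide which channels act as ratio denominators
#' (reference), which are diagnostics (control), and which are samples.
#'
#' @param path delimited file (TSV or CSV) with columns `batch`, `channel`,
#'   `role`, `cell_type`.
#' @return `data.table` with `batch_id`, `channel` (1-based integer), `role`,
#'   `cell_type`, one row per (batch, channel).
#' @export
read_annotation <- function(path) {
  tab <- data.table::fread(path, header = TRUE, na.strings = c("", "NA"),
                           check.names = FALSE)
  require_columns(tab, c("batch", "channel", "role"),
                  sprintf("annotation '%s'", basename(path)))
  ann <- data.table::data.table(
    batch_id = as.character(tab$batch),
    channel = as.integer(tab$channel),
    role = as.character(tab$role),
    cell_type = if ("cell_type" %in% names(tab))
      as.character(tab$cell_type) else NA_character_
  )
  validate_annotation(ann)
}

#' Validate a channel annotation
#'
#' Checks role vocabulary, uniqueness of (batch, channel), at most one
#' reference channel per batch, and that single-cell channels carry a cell
#' type.
#'
#' @param ann `data.frame`/`data.table` with `batch_id`, `channel`, `role`,
#'   `cell_type`.
#' @return the validated annotation as a `data.table`.
#' @export
validate_annotation <- function(ann) {
  ann <- data.table::as.data.table(ann)
  bad <- setdiff(unique(ann$role), VALID_ROLES)
  if (length(bad))
    stop("unknown channel role(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(VALID_ROLES, collapse = ", "), ")", call. = FALSE)
  key <- paste(ann$batch_id, ann$channel)
  if (anyDuplicated(key))
    stop("duplicated (batch, channel) annotation: ",
         key[duplicated(key)][1], call. = FALSE)
  nref <- ann[ann$role == "reference", .N, by = "batch_id"]
  if (nrow(nref) && any(nref$N > 1))
    stop("more than one reference channel in batch ",
         nref$batch_id[which(nref$N > 1)[1]], call. = FALSE)
  sc <- ann[ann$role == "single_cell", ]
  if (nrow(sc) && anyNA(sc$cell_type))
    stop("single_cell channels must carry a cell_type", call. = FALSE)
  ann[]
}

#' Remove unreliable identifications before quantification
#'
#' Drops protein groups flagged as reverse (decoy), potential contaminant or
#' only-identified-by-site, and all PSMs that either carry such a flag
#' themselves or map to a removed protein. Identification-level FDR control
#' is assumed done upstream.
#'
#' @param psms PSM table from [read_psm_table()].
#' @param protein_groups protein-group table from [read_protein_groups()].
#' @return list with `psms`, `protein_groups` (both filtered) and `removed`,
#'   a named count summary.
#' @export
filter_identifications <- function(psms, protein_groups) {
  psms <- data.table::as.data.table(psms)
  pg <- data.table::as.data.table(protein_groups)
  bad_pg <- pg$is_reverse | pg$is_contaminant | pg$is_site_only
  removed_proteins <- pg$protein_id[bad_pg]
  pg_keep <- pg[!bad_pg]
  drop_psm <- psms$is_reverse | psms$is_contaminant |
    psms$protein_id %in% removed_proteins
  psm_keep <- psms[!drop_psm]
  removed <- c(proteins_removed = sum(bad_pg),
               proteins_kept = nrow(pg_keep),
               psms_removed = sum(drop_psm),
               psms_kept = nrow(psm_keep))
  list(psms = psm_keep, protein_groups = pg_keep, removed = removed)
}

#' Write a quant_matrix to a tab-delimited file
#'
#' Missing values are written as `NA`; the scale flag is persisted in a
#' `# scale:` header comment, and the sample annotation in `# sample:`
#' comment lines, so [read_quant_matrix()] round-trips losslessly.
#'
#' @param x a [quant_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_quant_matrix <- function(x, path) {
  stopifnot(inherits(x, "quant_matrix"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# scale: %s", x$scale), con)
  ann_lines <- sprintf("# sample: %s\t%s\t%d\t%s\t%s",
                       x$samples$sample_id, x$samples$batch_id,
                       x$samples$channel, x$samples$role,
                       ifelse(is.na(x$samples$cell_type), "NA", x$samples$cell_type))
  writeLines(ann_lines, con)
  df <- data.frame(protein_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a quant_matrix written by [write_quant_matrix()]
#' @param path file path.
#' @return a [quant_matrix()].
#' @export
read_quant_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  scale_line <- grep("^# scale:", lines, value = TRUE)
  scale <- if (length(scale_line)) sub("^# scale:\\s*", "", scale_line[1]) else "linear"
  ann_lines <- grep("^# sample:", lines, value = TRUE)
  ann <- NULL
  if (length(ann_lines)) {
    parts <- strsplit(sub("^# sample:\\s*", "", ann_lines), "\t", fixed = TRUE)
    ann <- data.frame(
      sample_id = vapply(parts, `[`, "", 1),
      batch_id = vapply(parts, `[`, "", 2),
      channel = as.integer(vapply(parts, `[`, "", 3)),
      role = vapply(parts, `[`, "", 4),
      cell_type = vapply(parts, `[`, "", 5),
      stringsAsFactors = FALSE
    )
    ann$cell_type[ann$cell_type == "NA"] <- NA_character_
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  tab <- utils::read.delim(text = body, check.names = FALSE,
                           stringsAsFactors = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- tab[[1]]
  if (is.null(ann)) {
    ann <- data.frame(sample_id = colnames(vals), batch_id = NA_character_,
                      channel = NA_integer_, role = "single_cell",
                      cell_type = NA_character_, stringsAsFactors = FALSE)
  }
  quant_matrix(vals, ann, scale = scale)
}
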