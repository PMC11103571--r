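#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. Defaults are the settings
#' chosen for single-cell TMT data throughout this package: 70 percent
#' minimum valid values within a cell, 50 percent across samples, at least
#' 2 PSMs per protein for differential expression, a down-shift of 1.0 (the
#' largest value at which imputed values no longer deform the observed
#' distribution; the desktop-tool default of 1.8 remains available), ratio
#' normalization against the reference channel, and a q cutoff of 0.05.
#'
#' @param psm_path,protein_groups_path,annotation_path input files; leave
#'   `NULL` when passing a `synth_dataset` to [run_pipeline()] directly.
#' @param n_channels reporter channels per batch (default 18).
#' @param ratio_mode see [compute_ratios()].
#' @param min_valid_within_cell,min_valid_across_samples QC thresholds in
#'   percent (defaults 70, 50).
#' @param min_psm_count minimum PSMs per protein for DE (default 2).
#' @param down_shift,width,impute_scope imputation parameters (defaults
#'   1.0, 0.3, `"per_sample"`).
#' @param q_cutoff DE significance cutoff (default 0.05).
#' @param keep_control keep control/empty channels through QC diagnostics
#'   (they are always excluded from DE).
#' @param seed top-level seed; stage seeds are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(psm_path = NULL, protein_groups_path = NULL,
                            annotation_path = NULL, n_channels = 18,
                            ratio_mode = "reference",
                            min_valid_within_cell = 70,
                            min_valid_across_samples = 50,
                            min_psm_count = 2,
                            down_shift = 1.0, width = 0.3,
                            impute_scope = "per_sample",
                            q_cutoff = 0.05, keep_control = TRUE,
                            seed = 1) {
  cfg <- as.list(environment())
  validate_pipeline_config(cfg)
}

#' Validate a pipeline configuration list
#' @param cfg named list of configuration values.
#' @return the validated config, classed `pipeline_config`.
#' @export
validate_pipeline_config <- function(cfg) {
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults <- formals(pipeline_config)
  full <- stats::setNames(vector("list", length(known)), known)
  for (k in known) {
    full[k] <- if (k %in% names(cfg)) cfg[k] else list(eval(defaults[[k]]))
  }
  cfg <- full
  with(cfg, {
    stopifnot(min_valid_within_cell >= 0, min_valid_within_cell <= 100,
              min_valid_across_samples >= 0, min_valid_across_samples <= 100,
              min_psm_count >= 1, down_shift >= 0, width > 0,
              q_cutoff > 0, q_cutoff <= 1)
    if (!ratio_mode %in% c("reference", "channel_sum", "psm_sum"))
      stop("ratio_mode must be reference, channel_sum or psm_sum")
    if (!impute_scope %in% c("per_sample", "global"))
      stop("impute_scope must be per_sample or global")
  })
  for (p in c("psm_path", "protein_groups_path", "annotation_path")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("configured file does not exist: ", cfg[[p]])
  }
  structure(cfg[known], class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' The configuration file is a flat JSON object whose keys are the
#' arguments of [pipeline_config()]; unknown keys are rejected.
#'
#' @param path JSON file.
#' @return validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_pipeline_config(cfg)
}

stage_seed <- function(seed, offset) (as.integer(seed) + offset) %% .Machine$integer.max

#' Run the full quantification pipeline
#'
#' Stage order: read, identification filter, PSM-level normalization, log2,
#' missingness profile, cell filter, protein filter, minimum-PSM filter,
#' imputation, differential expression, volcano table and PCA/cluster
#' evaluation. Every stage writes its output under `out_dir` and logs
#' protein/cell counts; counts reconcile (in = out + removed) at each
#' filtering stage.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created); `NULL` for a temporary one.
#' @param dataset optional `synth_dataset` used instead of the configured
#'   input paths.
#' @return list with the final objects (`ratios`, `log2`, `qc`, `imputed`,
#'   `de`, `volcano`, `evaluation`, `log`, `out_dir`), invisibly classed
#'   `pipeline_run`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(out_dir)) out_dir <- tempfile("scpquant_run_")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_rows <- list()
  note <- function(stage, ...) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(stage = stage, ...,
                                                     stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  # 1: read ------------------------------------------------------------
  if (!is.null(dataset)) {
    psms <- run_stage("read", standardize_psms(dataset))
    pg <- standardize_protein_groups(dataset)
    ann <- standardize_annotation(dataset)
  } else {
    if (is.null(config$psm_path) || is.null(config$annotation_path) ||
        is.null(config$protein_groups_path))
      stop("pipeline stage 'read' failed: input paths not configured")
    psms <- run_stage("read", read_psm_table(
      config$psm_path, psm_dialect(n_channels = config$n_channels)))
    pg <- run_stage("read", read_protein_groups(config$protein_groups_path))
    ann <- run_stage("read", read_annotation(config$annotation_path))
  }
  note("read", psms_in = nrow(psms), proteins_in = nrow(pg))

  # 2: identification filter -------------------------------------------
  idf <- run_stage("identification_filter", filter_identifications(psms, pg))
  note("identification_filter",
       psms_in = nrow(psms), psms_out = nrow(idf$psms),
       psms_removed = unname(idf$removed["psms_removed"]),
       proteins_in = nrow(pg), proteins_out = nrow(idf$protein_groups),
       proteins_removed = unname(idf$removed["proteins_removed"]))
  data.table::fwrite(idf$psms, file.path(out_dir, "01_psms_filtered.tsv"),
                     sep = "\t")

  # 3: PSM normalization -------------------------------------------------
  ratios <- run_stage("normalize", normalize_protein_table(
    idf$psms, ann, mode = config$ratio_mode,
    keep_control = config$keep_control))
  write_quant_matrix(ratios, file.path(out_dir, "02_protein_ratios.tsv"))
  note("normalize", proteins_out = nrow(ratios$values),
       samples_out = ncol(ratios$values))

  # 4: log2 --------------------------------------------------------------
  lg <- run_stage("log2", log2_transform(ratios))
  write_quant_matrix(lg, file.path(out_dir, "03_log2.tsv"))
  note("log2", proteins_out = nrow(lg$values), samples_out = ncol(lg$values))

  # 5: missingness profile ----------------------------------------------
  prof <- run_stage("missingness_profile", missingness_profile(lg))
  data.table::fwrite(prof, file.path(out_dir, "04_missingness.tsv"), sep = "\t")
  note("missingness_profile", samples_above_cutoff = sum(prof$above_cutoff))

  # 6: cell filter -------------------------------------------------------
  cf <- run_stage("cell_filter", cell_filter(lg, config$min_valid_within_cell))
  write_quant_matrix(cf, file.path(out_dir, "05_cell_filter.tsv"))
  note("cell_filter", samples_in = ncol(lg$values),
       samples_out = ncol(cf$values),
       samples_removed = ncol(lg$values) - ncol(cf$values))

  # 7: protein filter ----------------------------------------------------
  pf <- run_stage("protein_filter",
                  protein_filter(cf, config$min_valid_across_samples))
  write_quant_matrix(pf, file.path(out_dir, "06_protein_filter.tsv"))
  note("protein_filter", proteins_in = nrow(cf$values),
       proteins_out = nrow(pf$values),
       proteins_removed = nrow(cf$values) - nrow(pf$values))

  # 8: minimum-PSM filter ------------------------------------------------
  counts <- psm_counts_by_protein(idf$psms)
  mp <- run_stage("min_psm_filter",
                  min_psm_filter(pf, counts, config$min_psm_count))
  write_quant_matrix(mp, file.path(out_dir, "07_min_psm.tsv"))
  note("min_psm_filter", proteins_in = nrow(pf$values),
       proteins_out = nrow(mp$values),
       proteins_removed = nrow(pf$values) - nrow(mp$values))

  # 9: imputation (single cells only from here on) -----------------------
  sc <- qm_subset(mp, samples = which(mp$samples$role == "single_cell"))
  imp <- run_stage("imputation", downshift_impute(
    sc, down_shift = config$down_shift, width = config$width,
    scope = config$impute_scope, seed = stage_seed(config$seed, 101L)))
  write_quant_matrix(imp$matrix, file.path(out_dir, "08_imputed.tsv"))
  report <- distribution_report(imp$matrix, imp$imputed_mask)
  note("imputation", values_imputed = sum(imp$imputed_mask),
       bimodal_flag = report$bimodal,
       mode_gap_sd = round(report$mode_gap_sd, 3))

  # 10: differential expression -----------------------------------------
  labels <- imp$matrix$samples$cell_type
  de <- run_stage("de", moderated_t_test(imp$matrix, labels,
                                         q_cutoff = config$q_cutoff))
  data.table::fwrite(de, file.path(out_dir, "09_de.tsv"), sep = "\t")
  volc <- volcano_table(de, config$q_cutoff)
  data.table::fwrite(volc, file.path(out_dir, "10_volcano.tsv"), sep = "\t")
  note("de", proteins_tested = nrow(de),
       significant_q = attr(de, "n_significant_q"),
       significant_p = attr(de, "n_significant_p"))

  # evaluation -----------------------------------------------------------
  emb <- run_stage("evaluation", pca_embed(imp$matrix))
  acc <- cluster_accuracy(emb, labels, k = 2,
                          seed = stage_seed(config$seed, 202L))
  eval_tab <- data.frame(sample_id = imp$matrix$samples$sample_id,
                         cell_type = labels,
                         PC1 = emb$coords[, 1], PC2 = emb$coords[, 2])
  data.table::fwrite(eval_tab, file.path(out_dir, "evaluation.tsv"), sep = "\t")
  note("evaluation", cluster_accuracy = round(acc, 4),
       pc1_var = round(emb$explained_variance[1], 4))

  log_df <- data.table::rbindlist(log_rows, fill = TRUE)
  data.table::fwrite(log_df, file.path(out_dir, "summary.tsv"), sep = "\t")

  invisible(structure(list(ratios = ratios, log2 = lg, qc = mp, imputed = imp,
                           distribution = report, de = de, volcano = volc,
                           evaluation = list(embedding = emb, accuracy = acc),
                           log = log_df, out_dir = out_dir),
                      class = "pipeline_run"))
}
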