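#' Configuration for the synthetic TMT-SCP generator
#'
#' Describes a multiplexed single-cell proteomics experiment of the pSCoPE
#' type at reduced scale: TMTpro-18plex batches each carrying one carrier
#' channel (many cells' worth of peptide), one pooled reference channel
#' (the ratio denominator), one control channel (reagents but no cell) and
#' single cells of two types; per-protein PSM counts of at least one;
#' planted fold-changes; batch-level intensity shifts; and left-censored
#' (MNAR) missingness whose logistic detection curve is calibrated to a
#' target overall rate, with a subset of low-quality cells censored harder.
#'
#' @param n_batches number of TMT batches (default 8).
#' @param channels_per_batch reporter channels per batch (default 18).
#' @param n_proteins number of (non-decoy) proteins (default 1000).
#' @param carrier_factor carrier boost factor beta (default 100).
#' @param reference_factor peptide amount of the pooled reference channel in
#'   single-cell equivalents (default 5, the usual multi-cell reference of
#'   carrier-based designs); keeps the ratio denominator mostly detected.
#' @param psm_lambda PSM count per protein-batch is `1 + Poisson(lambda)`
#'   (default 2).
#' @param base_mu,base_sd log2 base-abundance distribution (default 20, 2).
#' @param fraction_dep fraction of proteins with a planted fold-change
#'   (default 0.2).
#' @param fc_choices absolute log2 fold-changes sampled for planted
#'   proteins, sign random (default `c(0.5, 1, 2)`).
#' @param batch_sd SD of the per-batch log2 shift (default 0.5).
#' @param psm_noise_sd per-PSM-channel measurement noise, log2 (default 0.3).
#' @param psm_offset_sd per-PSM (peptide ionization) spread, log2 (default 1).
#' @param cell_offset_sd per-cell efficiency spread, log2 (default 0.2).
#' @param missing_target overall missing fraction of emitted single-cell
#'   reporter values (default 0.4).
#' @param detection_slope slope of the logistic detection curve per log2
#'   unit (default 1).
#' @param lowq_fraction fraction of single-cell channels that are
#'   low-quality cells (default 0.1).
#' @param lowq_missing_target missing fraction targeted for low-quality
#'   cells (default 0.7).
#' @param control_offset log2 offset of the control channel below the
#'   pooled signal (default -6).
#' @param decoy_fraction,contaminant_fraction extra flagged protein groups
#'   added to exercise identification filtering (defaults 0.03, 0.02).
#' @param fill_time_range MS/MS fill time range in ms (default `c(5, 50)`).
#' @param cell_types the two cell-type names.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_batches = 8, channels_per_batch = 18,
                         n_proteins = 1000, carrier_factor = 100,
                         reference_factor = 5,
                         psm_lambda = 2, base_mu = 20, base_sd = 2,
                         fraction_dep = 0.2, fc_choices = c(0.5, 1, 2),
                         batch_sd = 0.5, psm_noise_sd = 0.3,
                         psm_offset_sd = 1, cell_offset_sd = 0.2,
                         missing_target = 0.4, detection_slope = 1,
                         lowq_fraction = 0.1, lowq_missing_target = 0.7,
                         control_offset = -6,
                         decoy_fraction = 0.03, contaminant_fraction = 0.02,
                         fill_time_range = c(5, 50),
                         cell_types = c("typeA", "typeB")) {
  stopifnot(n_batches >= 1, channels_per_batch >= 5, n_proteins >= 2,
            carrier_factor >= 1, missing_target >= 0, missing_target <= 0.99,
            lowq_missing_target >= 0, lowq_missing_target <= 0.99,
            fraction_dep >= 0, fraction_dep <= 1, length(cell_types) == 2)
  structure(as.list(environment()), class = "synth_config")
}

# Calibrate the logistic detection location gamma so that the expected
# missing fraction over the realized log2 intensities `y` equals `target`:
# solves mean(1 - plogis(slope * (y - gamma))) = target by root finding.
# Calibrating on the realized values (rather than the theoretical marginal)
# absorbs finite-sample fluctuations of the batch shifts, leaving only
# negligible Bernoulli noise in the emitted missingness. Uses no RNG.
calibrate_detection <- function(y, slope, target) {
  if (target <= 0) return(-Inf)
  miss_rate <- function(gamma) mean(1 - stats::plogis(slope * (y - gamma)))
  rng <- range(y)
  stats::uniroot(function(g) miss_rate(g) - target,
                 lower = rng[1] - 50, upper = rng[2] + 50, tol = 1e-8)$root
}

#' Generate a synthetic TMT-SCP dataset
#'
#' Emits a PSM table in the MaxQuant `evidence.txt` dialect (censored
#' reporter values written as 0), a matching protein-group table, a channel
#' annotation, and the ground truth (planted fold-changes, cell types,
#' low-quality cells). The same `(config, seed)` always reproduces the same
#' dataset.
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return list of class `synth_dataset` with elements `psms`,
#'   `protein_groups` (vendor-dialect `data.table`s), `annotation`,
#'   `ground_truth` (list: `proteins`, `cells`, `detection`), `config`.
#' @export
generate_dataset <- function(config = synth_config(), seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  set.seed(as.integer(seed))

  C <- cf$channels_per_batch
  n_cells_per_batch <- C - 3L # carrier, reference, control occupy 1..3
  batches <- sprintf("batch%02d", seq_len(cf$n_batches))

  # --- proteins and planted effects -------------------------------------
  n_real <- cf$n_proteins
  ids <- sprintf("P%04d", seq_len(n_real))
  mu_p <- stats::rnorm(n_real, cf$base_mu, cf$base_sd)
  is_dep <- rep(FALSE, n_real)
  n_dep <- round(cf$fraction_dep * n_real)
  if (n_dep > 0) is_dep[sample.int(n_real, n_dep)] <- TRUE
  fc <- numeric(n_real)
  if (n_dep > 0) {
    fc[is_dep] <- sample(cf$fc_choices, n_dep, replace = TRUE) *
      sample(c(-1, 1), n_dep, replace = TRUE)
  }

  n_decoy <- round(cf$decoy_fraction * n_real)
  n_cont <- round(cf$contaminant_fraction * n_real)
  decoy_ids <- if (n_decoy) sprintf("REV__P%04d", seq_len(n_decoy)) else character(0)
  cont_ids <- if (n_cont) sprintf("CON__P%04d", seq_len(n_cont)) else character(0)
  all_ids <- c(ids, decoy_ids, cont_ids)
  n_all <- length(all_ids)
  mu_all <- c(mu_p, stats::rnorm(n_decoy + n_cont, cf$base_mu, cf$base_sd))
  fc_all <- c(fc, numeric(n_decoy + n_cont))

  # --- channel annotation ----------------------------------------------
  ann_list <- vector("list", cf$n_batches)
  for (b in seq_len(cf$n_batches)) {
    types <- sample(rep(cf$cell_types, length.out = n_cells_per_batch))
    ann_list[[b]] <- data.table::data.table(
      batch = batches[b],
      channel = seq_len(C),
      role = c("carrier", "reference", "control",
               rep("single_cell", n_cells_per_batch)),
      cell_type = c(NA, NA, NA, types))
  }
  annotation <- data.table::rbindlist(ann_list)

  cells <- annotation[annotation$role == "single_cell", ]
  n_cells <- nrow(cells)
  n_lowq <- round(cf$lowq_fraction * n_cells)
  lowq_idx <- if (n_lowq) sample.int(n_cells, n_lowq) else integer(0)
  cells$is_low_quality <- FALSE
  cells$is_low_quality[lowq_idx] <- TRUE
  cells$sample_id <- sprintf("%s_ch%02d", cells$batch, cells$channel)
  cells$cell_offset <- stats::rnorm(n_cells, 0, cf$cell_offset_sd)

  # --- pass 1: uncensored log2 signal per batch -------------------------
  batch_shift <- stats::rnorm(cf$n_batches, 0, cf$batch_sd)
  sim <- vector("list", cf$n_batches)
  for (b in seq_len(cf$n_batches)) {
    n_psm_per_prot <- 1L + stats::rpois(n_all, cf$psm_lambda)
    prot_idx <- rep(seq_len(n_all), n_psm_per_prot)
    n_psm <- length(prot_idx)
    a_psm <- stats::rnorm(n_psm, 0, cf$psm_offset_sd)
    base_log2 <- mu_all[prot_idx] + a_psm + batch_shift[b]

    ann_b <- ann_list[[b]]
    cells_b <- cells[cells$batch == batches[b], ]
    ch_type <- ann_b$cell_type[match(seq_len(C), ann_b$channel)]
    ch_role <- ann_b$role[match(seq_len(C), ann_b$channel)]

    log2_mat <- matrix(NA_real_, n_psm, C)
    ch_lowq <- rep(FALSE, C)
    for (ch in seq_len(C)) {
      role <- ch_role[ch]
      shift <- switch(role,
        carrier = log2(cf$carrier_factor),
        reference = log2(cf$reference_factor),
        control = cf$control_offset,
        single_cell = {
          sgn <- if (ch_type[ch] == cf$cell_types[1]) 0.5 else -0.5
          ci <- match(sprintf("%s_ch%02d", batches[b], ch), cells_b$sample_id)
          ch_lowq[ch] <- cells_b$is_low_quality[ci]
          sgn * fc_all[prot_idx] + cells_b$cell_offset[ci]
        })
      log2_mat[, ch] <- base_log2 + shift + stats::rnorm(n_psm, 0, cf$psm_noise_sd)
    }
    precursor <- round(2^(mu_all[prot_idx] + a_psm + batch_shift[b] + 5 +
                            stats::rnorm(n_psm, 0, 0.5)), 2)
    fill_time <- round(stats::runif(n_psm, cf$fill_time_range[1],
                                    cf$fill_time_range[2]), 2)
    sim[[b]] <- list(prot_idx = prot_idx, log2_mat = log2_mat,
                     precursor = precursor, fill_time = fill_time,
                     ch_role = ch_role, ch_lowq = ch_lowq)
  }

  # --- detection-curve calibration on the realized signal ---------------
  # Overall single-cell missingness is targeted at `missing_target` with
  # low-quality cells at `lowq_missing_target`; the normal-cell rate is the
  # remainder.
  y_norm <- unlist(lapply(sim, function(s)
    s$log2_mat[, s$ch_role == "single_cell" & !s$ch_lowq, drop = FALSE]))
  y_lowq <- unlist(lapply(sim, function(s)
    s$log2_mat[, s$ch_role == "single_cell" & s$ch_lowq, drop = FALSE]))
  n_n <- length(y_norm)
  n_l <- length(y_lowq)
  t_norm <- if (n_l > 0) {
    ((n_n + n_l) * cf$missing_target - n_l * cf$lowq_missing_target) / n_n
  } else cf$missing_target
  if (t_norm < 0)
    stop("infeasible missingness targets: low-quality cells alone exceed the overall target")
  gamma <- calibrate_detection(y_norm, cf$detection_slope, t_norm)
  gamma_lq <- if (n_l > 0)
    calibrate_detection(y_lowq, cf$detection_slope, cf$lowq_missing_target)
  else gamma

  # --- pass 2: MNAR censoring and vendor-dialect tables -----------------
  psm_tabs <- vector("list", cf$n_batches)
  for (b in seq_len(cf$n_batches)) {
    s <- sim[[b]]
    n_psm <- length(s$prot_idx)
    gamma_ch <- ifelse(s$ch_role == "single_cell" & s$ch_lowq, gamma_lq, gamma)
    p_det <- stats::plogis(cf$detection_slope *
                             sweep(s$log2_mat, 2, gamma_ch, "-"))
    detected <- matrix(stats::runif(n_psm * C), n_psm, C) < p_det
    reporters <- round(2^s$log2_mat, 4)
    reporters[!detected] <- 0

    tab <- data.table::data.table(
      `Raw file` = batches[b],
      `Leading razor protein` = all_ids[s$prot_idx],
      Intensity = s$precursor,
      `Ion injection time` = s$fill_time,
      Reverse = ifelse(grepl("^REV__", all_ids[s$prot_idx]), "+", ""),
      `Potential contaminant` = ifelse(grepl("^CON__", all_ids[s$prot_idx]), "+", ""))
    rep_dt <- data.table::as.data.table(reporters)
    data.table::setnames(rep_dt, paste0("Reporter intensity corrected ", seq_len(C)))
    psm_tabs[[b]] <- cbind(tab, rep_dt)
  }
  psms <- data.table::rbindlist(psm_tabs)

  pg <- data.table::data.table(
    `Protein IDs` = all_ids,
    `Gene names` = sub("^(REV__|CON__)", "", all_ids),
    Reverse = ifelse(grepl("^REV__", all_ids), "+", ""),
    `Potential contaminant` = ifelse(grepl("^CON__", all_ids), "+", ""),
    `Only identified by site` = "",
    `MS/MS count` = as.integer(table(factor(psms$`Leading razor protein`,
                                            levels = all_ids))))

  ground_truth <- list(
    proteins = data.table::data.table(protein_id = ids, base_log2 = mu_p,
                                      is_dep = is_dep, log2_fc = fc),
    cells = cells[, c("sample_id", "batch", "channel", "cell_type",
                      "is_low_quality"), with = FALSE],
    detection = list(gamma = gamma, gamma_lowq = gamma_lq,
                     slope = cf$detection_slope,
                     normal_cell_target = t_norm))

  structure(list(psms = psms, protein_groups = pg, annotation = annotation,
                 ground_truth = ground_truth, config = cf),
            class = "synth_dataset")
}

#' Simulate the loss of matching-between-runs
#'
#' Without identification transfer across runs, a peptide not selected for
#' MS/MS in a given run contributes no PSMs there. Each (protein, batch)
#' block of the PSM table is dropped entirely with probability
#' `dropout_rate`, raising cross-batch missingness.
#'
#' @param dataset a `synth_dataset` (or its vendor-dialect PSM table).
#' @param dropout_rate probability in `[0, 1]`.
#' @param seed integer seed.
#' @return object of the same type with the reduced PSM table.
#' @export
emulate_mbr_off <- function(dataset, dropout_rate, seed = 1) {
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("dropout_rate must lie in [0, 1]")
  is_ds <- inherits(dataset, "synth_dataset")
  psms <- if (is_ds) dataset$psms else data.table::as.data.table(dataset)
  set.seed(as.integer(seed))
  key <- paste(psms$`Leading razor protein`, psms$`Raw file`)
  blocks <- unique(key)
  dropped <- blocks[stats::runif(length(blocks)) < dropout_rate]
  out <- psms[!key %in% dropped]
  if (is_ds) {
    dataset$psms <- out
    cnt <- table(factor(out$`Leading razor protein`,
                        levels = dataset$protein_groups$`Protein IDs`))
    dataset$protein_groups$`MS/MS count` <- as.integer(cnt)
    dataset
  } else out
}

#' Write a synthetic dataset to disk in the vendor dialects
#'
#' @param dataset a `synth_dataset`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(evidence = file.path(dir, "evidence.txt"),
             protein_groups = file.path(dir, "proteinGroups.txt"),
             annotation = file.path(dir, "annotation.tsv"),
             truth_proteins = file.path(dir, "truth_proteins.tsv"),
             truth_cells = file.path(dir, "truth_cells.tsv"))
  data.table::fwrite(dataset$psms, paths["evidence"], sep = "\t", quote = FALSE)
  data.table::fwrite(dataset$protein_groups, paths["protein_groups"],
                     sep = "\t", quote = FALSE)
  data.table::fwrite(dataset$annotation, paths["annotation"], sep = "\t",
                     quote = FALSE)
  data.table::fwrite(dataset$ground_truth$proteins, paths["truth_proteins"],
                     sep = "\t", quote = FALSE)
  data.table::fwrite(dataset$ground_truth$cells, paths["truth_cells"],
                     sep = "\t", quote = FALSE)
  invisible(paths)
}

#' Standardize an in-memory synthetic PSM table
#'
#' Convenience for tests and the pipeline: converts the vendor-dialect
#' table of a `synth_dataset` to the standardized layout of
#' [read_psm_table()] without a round-trip through disk.
#'
#' @param dataset a `synth_dataset`.
#' @return standardized PSM `data.table` (zero reporters recoded to `NA`).
#' @export
standardize_psms <- function(dataset) {
  stopifnot(inherits(dataset, "synth_dataset"))
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  data.table::fwrite(dataset$psms, tmp, sep = "\t", quote = FALSE)
  read_psm_table(tmp, psm_dialect(n_channels = dataset$config$channels_per_batch))
}

#' Standardize the annotation of a synthetic dataset
#' @param dataset a `synth_dataset`.
#' @return validated annotation `data.table` as from [read_annotation()].
#' @export
standardize_annotation <- function(dataset) {
  stopifnot(inherits(dataset, "synth_dataset"))
  ann <- data.table::data.table(batch_id = dataset$annotation$batch,
                                channel = as.integer(dataset$annotation$channel),
                                role = dataset$annotation$role,
                                cell_type = dataset$annotation$cell_type)
  validate_annotation(ann)
}

#' Standardize the protein-group table of a synthetic dataset
#' @param dataset a `synth_dataset`.
#' @return standardized `data.table` as from [read_protein_groups()].
#' @export
standardize_protein_groups <- function(dataset) {
  stopifnot(inherits(dataset, "synth_dataset"))
  pg <- dataset$protein_groups
  data.table::data.table(
    protein_id = pg$`Protein IDs`,
    gene_name = pg$`Gene names`,
    is_reverse = pg$Reverse == "+",
    is_contaminant = pg$`Potential contaminant` == "+",
    is_site_only = pg$`Only identified by site` == "+",
    psm_count = pg$`MS/MS count`)
}
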