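# Independent brute-force oracle for the weighted median: try every index k
# of the sorted ratios and return the first whose flanking cumulative
# weights both stay at or below half the total.
wmed_oracle <- function(x, w) {
  o <- order(x)
  xs <- x[o]
  ws <- w[o]
  n <- length(xs)
  tot <- sum(ws)
  tol <- 1e-9 * tot
  for (k in seq_len(n)) {
    left <- if (k > 1) sum(ws[1:(k - 1)]) else 0
    right <- if (k < n) sum(ws[(k + 1):n]) else 0
    if (left <= tot / 2 + tol && right <= tot / 2 + tol) return(xs[k])
  }
  NA_real_
}

# quant_matrix with an all-single-cell annotation, two alternating cell types
make_qm <- function(values, scale = "log2", roles = NULL, types = NULL,
                    batch = "b1") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  n <- ncol(values)
  if (is.null(roles)) roles <- rep("single_cell", n)
  if (is.null(types))
    types <- ifelse(roles == "single_cell",
                    rep(c("typeA", "typeB"), length.out = n), NA_character_)
  ids <- sprintf("%s_ch%02d", batch, seq_len(n))
  colnames(values) <- ids
  quant_matrix(values,
               data.frame(sample_id = ids, batch_id = batch,
                          channel = seq_len(n), role = roles,
                          cell_type = types, stringsAsFactors = FALSE),
               scale = scale)
}

# standardized PSM table (the layout read_psm_table produces) for small
# hand-built normalization cases; `reporters` is a PSM x channel matrix with
# NA for missing
make_psms <- function(reporters, protein_id, batch_id = "b1",
                      precursor = NULL, fill_time = NULL) {
  n <- nrow(reporters)
  if (is.null(precursor)) precursor <- rep(16, n)
  if (is.null(fill_time)) fill_time <- rep(1, n)
  out <- data.table::data.table(
    psm_id = sprintf("psm%d", seq_len(n)),
    protein_id = protein_id,
    batch_id = batch_id,
    precursor_intensity = precursor,
    fill_time = fill_time,
    is_reverse = FALSE,
    is_contaminant = FALSE)
  rep_dt <- data.table::as.data.table(reporters)
  data.table::setnames(rep_dt, paste0("reporter_", seq_len(ncol(reporters))))
  cbind(out, rep_dt)
}

# annotation for one batch with C channels: carrier, reference, control,
# then single cells with alternating types
make_ann <- function(batch = "b1", C = 6) {
  n_sc <- C - 3L
  data.table::data.table(
    batch_id = batch,
    channel = seq_len(C),
    role = c("carrier", "reference", "control", rep("single_cell", n_sc)),
    cell_type = c(NA, NA, NA, rep(c("typeA", "typeB"), length.out = n_sc)))
}

# triangular 6x6 validity mask used for the QC-grid hand fixture: column j
# is valid in proteins 1..(7-j), so the six columns have valid fractions
# 100, 83.3, 66.7, 50, 33.3 and 16.7 percent
triangular_qm <- function() {
  v <- matrix(NA_real_, 6, 6)
  for (j in 1:6) v[seq_len(7 - j), j] <- seq_len(7 - j) + j / 10
  make_qm(v)
}

# small synthetic dataset shared by slower tests (cached per session)
small_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(synth_config(n_batches = 3, n_proteins = 150),
                                 seed = 421)
    cache
  }
})
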