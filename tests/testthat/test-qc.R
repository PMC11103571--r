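test_that("cell_filter keeps columns at or above the inclusive threshold", {
  v <- matrix(NA_real_, 4, 3)
  v[1:3, 1] <- 1          # 75 % valid
  v[1:2, 2] <- 1          # 50 % valid
  v[1:4, 3] <- 1          # 100 % valid
  qm <- make_qm(v)
  kept <- cell_filter(qm, 70)
  expect_equal(ncol(kept$values), 2L)
  expect_identical(attr(kept, "removed_samples"), colnames(qm$values)[2])
  expect_equal(ncol(cell_filter(qm, 0)$values), 3L)   # identity at 0
  expect_equal(ncol(cell_filter(qm, 75)$values), 2L)  # boundary inclusive
  expect_error(cell_filter(qm_subset(qm, proteins = integer(0)), 50), "empty")
})

test_that("protein_filter keeps rows at or above the inclusive threshold", {
  v <- matrix(NA_real_, 2, 10)
  v[1, 1:5] <- 1          # 50 % valid
  v[2, 1:4] <- 1          # 40 % valid
  qm <- make_qm(v)
  kept <- protein_filter(qm, 50)
  expect_equal(rownames(kept$values), "P001")
  expect_equal(nrow(protein_filter(qm, 0)$values), 2L)
})

test_that("qc_grid matches an independent brute-force enumeration on the triangular fixture", {
  qm <- triangular_qm()
  ths <- c(0, 10, 30, 50, 70, 90)
  grid <- qc_grid(qm, ths, ths)

  # independent enumeration straight from the validity mask
  mask <- !is.na(qm$values)
  for (i in seq_len(nrow(grid))) {
    ct <- grid$cell_threshold[i]
    pt <- grid$protein_threshold[i]
    cells_kept <- which(100 * colMeans(mask) >= ct - 1e-9)
    prot_kept <- which(100 * rowMeans(mask[, cells_kept, drop = FALSE]) >= pt - 1e-9)
    expect_equal(grid$retained_cells[i], length(cells_kept))
    expect_equal(grid$retained_proteins[i], length(prot_kept))
  }

  # spot-frozen hand computations: columns have 100/83.3/66.7/50/33.3/16.7 %
  at <- function(ct, pt) grid[grid$cell_threshold == ct & grid$protein_threshold == pt, ]
  expect_equal(at(70, 0)$retained_cells, 2L)
  expect_equal(at(90, 0)$retained_cells, 1L)
  expect_equal(at(0, 0)$retained_proteins, 6L)
  expect_equal(at(70, 70)$retained_proteins, 5L)   # P6 valid in 1 of 2 kept cells
  expect_equal(at(70, 50)$retained_proteins, 6L)
})

test_that("qc_grid is monotone and its cell counts depend only on the cell threshold", {
  ds <- small_synth()
  psms <- standardize_psms(ds)
  idf <- filter_identifications(psms, standardize_protein_groups(ds))
  qm <- log2_transform(normalize_protein_table(idf$psms, standardize_annotation(ds)))
  ths <- c(0, 30, 50, 70, 90)
  grid <- qc_grid(qm, ths, ths)
  for (ct in ths) {
    sub <- grid[grid$cell_threshold == ct, ]
    # protein counts fall as the protein threshold rises; the cell count is
    # a function of the cell threshold alone
    expect_true(all(diff(sub$retained_proteins) <= 0))
    expect_equal(length(unique(sub$retained_cells)), 1L)
  }
  for (pt in ths) {
    sub <- grid[grid$protein_threshold == pt, ]
    expect_true(all(diff(sub$retained_cells) <= 0))
  }
  # note: protein counts need not fall as the CELL threshold rises --
  # dropping sparse cells raises the remaining valid fractions
  # (0, 0) is the identity
  expect_equal(grid$retained_proteins[grid$cell_threshold == 0 &
                                        grid$protein_threshold == 0],
               nrow(qm$values))
  all_valid <- make_qm(matrix(1, 4, 4))
  g2 <- qc_grid(all_valid, c(0, 50, 90), c(0, 50, 90))
  expect_true(all(g2$retained_proteins == 4L & g2$retained_cells == 4L))
})

test_that("per-cell-type median variance uses observed values with n-1 denominator", {
  v <- rbind(c(1, 3, 2, 6), c(2, 2, 4, 8), c(NA, 5, 1, NA))
  qm <- make_qm(v, types = c("typeA", "typeA", "typeB", "typeB"))
  grid <- qc_grid(qm, 0, 0)
  # typeA columns 1:2 -> per-protein variances var(c(1,3)) = 2, var(c(2,2)) = 0,
  # row 3 has one observed value in typeA and is skipped -> median 1
  expect_equal(grid$median_variance_typeA, 1)
  expect_equal(grid$median_variance_typeB,
               stats::median(c(var(c(2, 6)), var(c(4, 8)))))
})

test_that("missingness_profile reports per-sample percentages with the 30 % flag", {
  v <- matrix(NA_real_, 10, 3)
  v[1:7, 1] <- 1                 # 30 % missing
  v[, 2] <- 1                    # fully valid
  qm <- make_qm(v, roles = c("single_cell", "single_cell", "control"))
  prof <- missingness_profile(qm)
  expect_equal(prof$missing_pct, c(30, 0, 100))
  expect_identical(prof$above_cutoff, c(FALSE, FALSE, TRUE))
  expect_identical(prof$role, c("single_cell", "single_cell", "control"))
})

test_that("min_psm_filter removes under-supported proteins inclusively", {
  v <- matrix(1, 3, 4)
  qm <- make_qm(v)
  counts <- c(P001 = 1L, P002 = 2L, P003 = 5L)
  expect_identical(rownames(min_psm_filter(qm, counts, 2)$values), c("P002", "P003"))
  expect_equal(nrow(min_psm_filter(qm, counts, 1)$values), 3L)
  expect_warning(out <- min_psm_filter(qm, counts[-1], 2), "count 0")
  expect_false("P001" %in% rownames(out$values))
})

test_that("qc_grid_table lays the grid out wide with a single cell-count column", {
  grid <- qc_grid(triangular_qm(), c(0, 70), c(0, 50))
  wide <- qc_grid_table(grid)
  expect_equal(dim(wide), c(2L, 4L))
  expect_equal(wide$cells, c(6L, 2L))
  expect_equal(wide$proteins_at_0, c(6L, 6L))
})
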