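#' PCA embedding of samples
#'
#' Samples are observations and proteins features; features are centered
#' (unit-variance scaling optional) and the principal components come from
#' the singular value decomposition of the centered matrix.
#'
#' @param x complete [quant_matrix()] or numeric matrix (proteins x
#'   samples).
#' @param n_components number of components to keep (default 2).
#' @param scale. also scale features to unit variance (default `FALSE`).
#' @return list of class `pca_embedding`: `coords` (samples x components),
#'   `explained_variance` (fractions, non-increasing), `labels` (cell types
#'   if available).
#' @export
pca_embed <- function(x, n_components = 2, scale. = FALSE) {
  is_qm <- inherits(x, "quant_matrix")
  v <- if (is_qm) x$values else x
  stopifnot(is.matrix(v))
  if (anyNA(v)) stop("pca_embed expects a complete matrix")
  if (ncol(v) < 2L) stop("need at least 2 samples")
  obs <- t(v)
  keep <- apply(obs, 2, stats::sd) > 0 | !scale.
  pc <- stats::prcomp(obs[, keep, drop = FALSE], center = TRUE, scale. = scale.)
  k <- min(n_components, ncol(pc$x))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(coords = pc$x[, seq_len(k), drop = FALSE],
                 explained_variance = ev[seq_len(k)],
                 labels = if (is_qm) x$samples$cell_type else NULL),
            class = "pca_embedding")
}

# all permutations of seq_len(n); n is small (number of clusters)
permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in permutations(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[p])
    }
  }
  out
}

#' Cluster-label accuracy of an embedding
#'
#' Runs k-means (fixed seed, multiple restarts) on the embedding
#' coordinates and scores the best agreement with the true labels over all
#' assignments of clusters to label values. By construction the result is
#' at least the majority-class fraction.
#'
#' @param embedding [pca_embed()] result or a samples x features matrix.
#' @param true_labels vector of true group labels, one per sample.
#' @param k number of clusters (default 2).
#' @param seed RNG seed for k-means (default 1).
#' @param nstart k-means restarts (default 10).
#' @return accuracy in `[0, 1]`.
#' @export
cluster_accuracy <- function(embedding, true_labels, k = 2, seed = 1,
                             nstart = 10) {
  coords <- if (inherits(embedding, "pca_embedding")) embedding$coords else embedding
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(true_labels) != n) stop("one true label per sample required")
  if (k > n) stop("k must not exceed the number of samples")
  true_labels <- factor(true_labels)
  if (k == 1L) return(max(table(true_labels)) / n)
  set.seed(as.integer(seed))
  km <- stats::kmeans(coords, centers = k, nstart = nstart)
  lev <- levels(true_labels)
  tab <- table(km$cluster, true_labels)
  if (k == length(lev)) {
    # bijective cluster-to-label assignment: best permutation wins, ties
    # broken toward the first enumerated permutation
    best <- 0
    for (p in permutations(k)) {
      acc <- sum(tab[cbind(seq_len(k), p)]) / n
      if (acc > best) best <- acc
    }
    best
  } else {
    # cluster count differs from label count: each cluster takes its best
    # label independently
    sum(apply(tab, 1, max)) / n
  }
}
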