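# S-phase cluster seeding: seed clusters on mid-S replication trends,
# derive A-score-profile bin clusters, expand seeds to all non-M cells by
# nearest-centroid assignment, and split off the erythrocyte-like cluster
# with a linear separator.

#' Seed cell clusters on mid-S replication trends
#'
#' Normalizes each mid-S cell's bin coverage by the G1 mean per bin, orders
#' cells by their fraction of short-range contacts, removes the residual
#' cell-cycle gradient by subtracting per bin the running mean over a
#' window of cells along that ordering, and clusters the corrected
#' profiles (correlation distance, average linkage).
#'
#' @param dsn_s mid-S cells x bins coverage matrix.
#' @param g1_mean per-bin mean coverage over G1 cells (same bin columns).
#' @param frac_near named per-cell fraction of short-range contacts, used
#'   as the ordering key.
#' @param k_seeds number of seed clusters.
#' @param window running-mean window in cells (default 20).
#' @return list with \code{seeds} (named integer cluster per cell) and the
#'   corrected matrix \code{corrected}.
#' @export
seed_midS_clusters <- function(dsn_s, g1_mean, frac_near, k_seeds,
                               window = 20L) {
  stopifnot(nrow(dsn_s) >= 2 * k_seeds)
  ok <- g1_mean > 0
  m <- sweep(dsn_s[, ok, drop = FALSE], 2, g1_mean[ok], "/")
  m <- m / rowMeans(m)
  ord <- order(frac_near[rownames(dsn_s)])
  m_ord <- m[ord, , drop = FALSE]
  run <- apply(m_ord, 2, function(x) {
    k <- min(window, length(x))
    stats::filter(x, rep(1 / k, k), sides = 2)
  })
  # fill filter NAs at the edges with the column mean
  cm <- colMeans(m_ord)
  na <- is.na(run)
  run[na] <- cm[col(run)[na]]
  corrected <- m_ord - run
  cc <- suppressWarnings(cor(t(corrected)))
  cc[is.na(cc)] <- 0
  hc <- hclust(as.dist(1 - cc), method = "average")
  seeds <- cutree(hc, k = k_seeds)
  names(seeds) <- rownames(m_ord)
  list(seeds = seeds[rownames(dsn_s)], corrected = corrected)
}

#' Cluster genomic bins by their A-score profile across seeds
#'
#' k-means (fixed seed) over per-bin vectors of seed A-scores; clusters are
#' relabelled in decreasing order of differential A-score (max - min of the
#' cluster centre), so cluster 1 is the most seed-differential.
#'
#' @param a_seed bins x seeds A-score matrix (rows with NA dropped).
#' @param n_clusters number of bin clusters (default 11).
#' @param seed RNG seed for k-means.
#' @return named integer vector bin -> cluster (1 = most differential).
#' @export
derive_bin_clusters <- function(a_seed, n_clusters = 11L, seed = 1L) {
  keep <- stats::complete.cases(a_seed)
  m <- a_seed[keep, , drop = FALSE]
  set.seed(seed)
  km <- kmeans(m, centers = n_clusters, nstart = 5, iter.max = 50)
  spread <- apply(km$centers, 1, function(x) max(x) - min(x))
  relabel <- match(seq_len(n_clusters), order(spread, decreasing = TRUE))
  out <- relabel[km$cluster]
  names(out) <- rownames(a_seed)[keep]
  out
}

#' Per-cell pooled A-scores over bin clusters
#'
#' @param cA,cB matrices from [ab_contact_counts()].
#' @param bin_clusters named vector bin -> cluster from
#'   [derive_bin_clusters()].
#' @return cells x clusters matrix of pooled A-scores.
#' @export
cell_ascore_matrix <- function(cA, cB, bin_clusters) {
  cl <- sort(unique(bin_clusters))
  out <- sapply(cl, function(k)
    cell_pooled_ascore(cA, cB, names(bin_clusters)[bin_clusters == k]))
  rownames(out) <- rownames(cA)
  colnames(out) <- as.character(cl)
  out
}

#' Expand seed clusters to all non-mitotic cells
#'
#' Each cell is assigned to the seed with the nearest centroid (Euclidean
#' after centring each profile on its own mean) in pooled-A-score space;
#' ties resolve to the lowest cluster index. Centring removes the per-cell
#' global A-level, which tracks replication progression rather than
#' identity and would otherwise pull cells across cluster boundaries.
#' Cells listed as mitotic are flagged unassignable (NA).
#'
#' @param cell_A cells x bin-cluster pooled A-score matrix.
#' @param centroids seeds x bin-cluster centroid matrix (e.g. seed means of
#'   cell_A rows).
#' @param mitotic_cells cell ids to leave unassigned.
#' @return named integer cluster per cell (NA for mitotic cells).
#' @export
assign_cells <- function(cell_A, centroids, mitotic_cells = character()) {
  out <- rep(NA_integer_, nrow(cell_A))
  names(out) <- rownames(cell_A)
  ok <- stats::complete.cases(cell_A) & !(rownames(cell_A) %in% mitotic_cells)
  if (any(ok)) {
    prof <- cell_A[ok, , drop = FALSE]
    prof <- prof - rowMeans(prof)
    cen <- centroids - rowMeans(centroids)
    d2 <- sapply(seq_len(nrow(cen)), function(k)
      rowSums(sweep(prof, 2, cen[k, ])^2))
    if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
    out[ok] <- apply(d2, 1, which.min)  # which.min takes the lowest index on ties
  }
  out
}

#' Split a target population with a linear separator in A-score space
#'
#' Classifies cells on two pooled A-scores (a seed-differential "high" bin
#' cluster and a "low" one). A separator line can be supplied as
#' c(a, b, c), labelling cells with a*high + b*low + c > 0 as the target;
#' otherwise a two-class linear discriminant is fitted on the given labels.
#'
#' @param high,low named per-cell pooled A-scores.
#' @param line optional numeric c(a, b, c).
#' @param labels logical per cell (TRUE = target), required when fitting.
#' @return named logical, TRUE for target (erythrocyte-like) cells.
#' @export
split_linear <- function(high, low, line = NULL, labels = NULL) {
  ok <- !is.na(high) & !is.na(low)
  out <- rep(NA, length(high))
  names(out) <- names(high)
  if (is.null(line)) {
    stopifnot(!is.null(labels))
    df <- data.frame(h = high[ok], l = low[ok], y = factor(labels[ok]))
    ld <- MASS::lda(y ~ h + l, data = df)
    pred <- stats::predict(ld, df)$class
    out[ok] <- pred == "TRUE"
  } else {
    out[ok] <- line[1] * high[ok] + line[2] * low[ok] + line[3] > 0
  }
  out
}

#' 2-D PCA projection of pooled A-scores
#'
#' @param cell_A cells x bin-cluster matrix (rows with NA dropped).
#' @return matrix with columns PC1, PC2.
#' @export
pca_project <- function(cell_A) {
  keep <- stats::complete.cases(cell_A)
  m <- cell_A[keep, , drop = FALSE]
  sds <- apply(m, 2, sd)
  m <- m[, sds > 0, drop = FALSE]
  p <- prcomp(m, center = TRUE, scale. = TRUE)
  k <- min(2, ncol(p$x))
  out <- p$x[, seq_len(k), drop = FALSE]
  if (k == 1) out <- cbind(out, PC2 = 0)
  colnames(out) <- c("PC1", "PC2")
  out
}
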