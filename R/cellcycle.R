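# Cell-cycle phasing from contact-distance statistics, early/late coverage
# ratios, and derivation of the strict-early / strict-late reference sets.

#' Per-cell cell-cycle features
#'
#' Computes, per cell, the fraction of "near" contacts (cis < 2 Mb), the
#' fraction of "mitotic" contacts (cis 2-12 Mb), the mean contact distance
#' over cis contacts of at least 4.5 Mb (NA when no such contact exists),
#' the fraction of fragment ends falling in the strict-early reference, and
#' far tightness (the fraction of cis contacts in the modal log-spaced
#' distance bin). Fractions are over all contacts (cis + trans), so
#' frac_near + frac_mitotic + frac_far_cis + frac_trans = 1.
#'
#' @param contacts contact data.table.
#' @param reference a list with \code{early_strict} / \code{late_strict} bin
#'   id vectors (see [derive_strict_sets()]).
#' @param bins bin table used by the reference.
#' @param tight_factor log-spacing factor of the far-tightness distance bins
#'   (distance bin = floor(log(d)/log(factor)); default sqrt(2)).
#' @return data.table with one row per cell.
#' @export
phase_features <- function(contacts, reference, bins,
                           tight_factor = sqrt(2)) {
  ct <- as.data.table(contacts)
  d <- contact_distance(ct)
  dt <- data.table(cell = ct$cell, d = d)
  feats <- dt[, {
    cis <- !is.na(d)
    stopifnot(any(cis))
    far <- cis & d >= 4.5e6
    dc <- d[cis & d >= 1]
    tight <- if (length(dc)) {
      b <- floor(log(dc) / log(tight_factor))
      max(tabulate(b - min(b) + 1L)) / length(dc)
    } else NA_real_
    .(frac_near = mean(cis & d < 2e6),
      frac_mitotic = mean(cis & d >= 2e6 & d < 1.2e7),
      mean_far_dist = if (any(far)) mean(d[far]) else NA_real_,
      far_tightness = tight)
  }, by = cell]

  ends <- data.table(cell = rep(ct$cell, 2),
                     chrom = c(ct$chr1, ct$chr2),
                     pos = c(ct$pos1, ct$pos2))
  ends[, bin := assign_bin(chrom, pos, bins)]
  ec <- ends[, .(frac_early_cov = mean(bin %in% reference$early_strict,
                                       na.rm = TRUE)), by = cell]
  merge(feats, ec, by = "cell")
}

#' Phase classification rules
#'
#' @param mitotic_thresh frac_mitotic above which a cell is pre/post-mitotic.
#' @param postm_near_thresh within the mitotic branch, frac_near above which
#'   the cell is post-mitotic (decondensing) rather than pre-mitotic.
#' @param g1_near_thresh frac_near below which a non-mitotic cell is G1.
#' @param early_cov_split frac_early_cov separating early-S from mid-S/G2;
#'   NULL (default) splits adaptively by 1-D 2-means over the S-branch cells.
#' @return list of rules for [classify_phase()].
#' @export
phase_rules <- function(mitotic_thresh = 0.3, postm_near_thresh = 0.15,
                        g1_near_thresh = 0.5, early_cov_split = NULL) {
  list(mitotic_thresh = mitotic_thresh, postm_near_thresh = postm_near_thresh,
       g1_near_thresh = g1_near_thresh, early_cov_split = early_cov_split)
}

#' Classify cells into cell-cycle phases and order them within phases
#'
#' Labels are post-M, G1, early-S, mid-S (mid-S to G2) and pre-M. Cells
#' with frac_mitotic above the mitotic threshold branch to pre/post-mitotic
#' (split on frac_near); remaining cells are G1 when frac_near is low, and
#' otherwise split into early-S vs mid-S on the early-coverage fraction.
#' The within-phase ordering key is frac_near for S-phase cells (replication
#' progresses with short-range contact enrichment) and mean_far_dist for
#' G1/mitotic cells.
#'
#' @param features data.table from [phase_features()].
#' @param rules list from [phase_rules()].
#' @return the features table with added \code{phase} and \code{order}
#'   (within-phase rank) columns.
#' @export
classify_phase <- function(features, rules = phase_rules()) {
  f <- data.table::copy(as.data.table(features))
  mitotic <- f$frac_mitotic > rules$mitotic_thresh
  phase <- character(nrow(f))
  phase[mitotic] <- ifelse(f$frac_near[mitotic] > rules$postm_near_thresh,
                           "post-M", "pre-M")
  g1 <- !mitotic & f$frac_near < rules$g1_near_thresh
  phase[g1] <- "G1"
  sbr <- !mitotic & !g1
  if (any(sbr)) {
    split <- rules$early_cov_split
    if (is.null(split)) {
      x <- f$frac_early_cov[sbr]
      if (length(unique(x)) >= 2) {
        km <- kmeans(x, centers = quantile(x, c(0.25, 0.75)))
        split <- mean(km$centers)
      } else split <- -Inf
    }
    phase[sbr] <- ifelse(f$frac_early_cov[sbr] > split, "mid-S", "early-S")
  }
  f[, phase := phase]
  key <- ifelse(phase %in% c("early-S", "mid-S"), f$frac_near, f$mean_far_dist)
  key[is.na(key)] <- Inf
  f[, .ordkey := key]
  f[, order := rank(.ordkey, ties.method = "first"), by = phase]
  f[, .ordkey := NULL]
  f[]
}

#' Derive strict-early and strict-late reference bin sets
#'
#' Clusters genomic bins by their coverage profile across cells
#' (correlation distance, average-linkage hierarchical clustering) into
#' \code{n_groups} groups; among groups holding at least \code{min_frac}
#' of the clustered bins, the one with the highest mean downsampled
#' coverage is the strict-early (A-proxy) set and the lowest the
#' strict-late (B-proxy) set. The size floor keeps singleton outlier
#' bins (which average linkage tends to isolate) from becoming a
#' reference set. Bins with (near-)constant coverage are dropped before
#' clustering.
#'
#' @param dsn cells x bins coverage matrix (downsampled; see
#'   [bin_coverage()] / [downsample_cells()]).
#' @param n_groups number of bin clusters (default 4).
#' @param min_frac minimum fraction of clustered bins a group needs to be
#'   eligible as a reference set (default 0.05).
#' @return list with \code{early_strict}, \code{late_strict} (integer bin
#'   ids = column names of dsn) and the full \code{groups} assignment.
#' @export
derive_strict_sets <- function(dsn, n_groups = 4L, min_frac = 0.05) {
  sds <- apply(dsn, 2, sd)
  keep <- which(sds > 0)
  m <- dsn[, keep, drop = FALSE]
  cc <- suppressWarnings(cor(m))
  cc[is.na(cc)] <- 0
  hc <- hclust(as.dist(1 - cc), method = "average")
  grp <- cutree(hc, k = n_groups)
  mu <- tapply(colMeans(m), grp, mean)
  sizes <- table(grp)
  big <- names(sizes)[sizes >= min_frac * length(grp)]
  if (length(big) >= 2) mu <- mu[big]
  bin_ids <- as.integer(colnames(dsn))[keep]
  early <- bin_ids[grp == names(mu)[which.max(mu)]]
  late <- bin_ids[grp == names(mu)[which.min(mu)]]
  groups <- setNames(grp, bin_ids)
  list(early_strict = early, late_strict = late, groups = groups)
}

#' Early/late coverage ratio and mid-S classification
#'
#' el = log2 of the ratio of pooled downsampled coverage in the
#' strict-early vs strict-late reference bins; cells with el above the
#' threshold (default 1.8) are classified mid-S (the K^S set). Cells with
#' zero strict-late coverage get NA and are excluded from K^S.
#'
#' @param dsn cells x bins coverage matrix (columns named by bin id).
#' @param reference from [derive_strict_sets()].
#' @param threshold mid-S threshold on el.
#' @return data.table with cell, el, mid_s.
#' @export
el_ratio <- function(dsn, reference, threshold = 1.8) {
  bin_ids <- as.integer(colnames(dsn))
  ei <- which(bin_ids %in% reference$early_strict)
  li <- which(bin_ids %in% reference$late_strict)
  e <- rowSums(dsn[, ei, drop = FALSE])
  l <- rowSums(dsn[, li, drop = FALSE])
  el <- ifelse(l > 0, log2(e / l), NA_real_)
  data.table(cell = rownames(dsn), el = el,
             mid_s = !is.na(el) & el > threshold)
}
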