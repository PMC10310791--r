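# Enhancer and Polycomb calling from occupancy tracks, promoter pairing,
# three-way differential-contact support, empirical contact tests, and
# ATAC peak clustering with TAD-proximity enrichment.

#' Call peaks from a percentile-score track
#'
#' Peaks are contiguous runs of track bins with score above the threshold
#' (default 7, i.e. the top 1/128 of bins), merged into intervals.
#'
#' @param score numeric score vector (see [chip_bin_score()]).
#' @param starts bin start coordinates (bp); \code{step} resolution.
#' @param step track resolution (bp).
#' @param threshold minimum score (default 7).
#' @return data.table of peak intervals with the per-peak max score.
#' @export
call_peaks <- function(score, starts, step = 20L, threshold = 7) {
  ok <- which(score > threshold)
  if (!length(ok)) return(data.table(start = numeric(), end = numeric(),
                                     score = numeric()))
  run <- cumsum(c(TRUE, diff(ok) != 1))
  data.table::rbindlist(lapply(split(ok, run), function(ii)
    data.table(start = starts[ii[1]], end = starts[tail(ii, 1)] + step,
               score = max(score[ii]))))
}

#' Classify a peak as tissue-set specific
#'
#' Specific when one tissue-set score is at least \code{min_score} and
#' exceeds the other set's score by at least \code{min_diff}.
#'
#' @param score_x,score_y peak scores in the two tissue sets (vectors).
#' @param min_score minimum score in the winning set (default 9).
#' @param min_diff minimum difference between the sets (default 3).
#' @return character vector: "x", "y" or "none".
#' @export
classify_specific <- function(score_x, score_y, min_score = 9, min_diff = 3) {
  out <- rep("none", length(score_x))
  out[score_x >= min_score & score_x - score_y >= min_diff] <- "x"
  out[score_y >= min_score & score_y - score_x >= min_diff] <- "y"
  out
}

#' Pair peaks with their closest TSSs within a distance window
#'
#' For each peak, the nearest TSS 50-500 kb upstream and the nearest
#' 50-500 kb downstream (at most one per side) are linked; TSSs closer
#' than the lower bound are skipped (scHi-C resolution is limited there).
#'
#' @param peaks data.table with start, end (and any id columns).
#' @param tss data.table with gene, pos.
#' @param window c(min, max) distance from the peak centre (default
#'   5e4, 5e5).
#' @return data.table of peak-TSS pairs with distance and side.
#' @export
pair_with_tss <- function(peaks, tss, window = c(5e4, 5e5)) {
  peaks <- as.data.table(peaks)
  tss <- as.data.table(tss)
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    centre <- (peaks$start[i] + peaks$end[i]) / 2
    d <- tss$pos - centre
    for (side in c(-1, 1)) {
      sel <- which(sign(d) == side & abs(d) >= window[1] &
                     abs(d) <= window[2])
      if (!length(sel)) next
      j <- sel[which.min(abs(d[sel]))]
      out[[length(out) + 1]] <- cbind(
        peaks[i], data.table(gene = tss$gene[j], tss_pos = tss$pos[j],
                             distance = abs(d[j]),
                             side = if (side < 0) "up" else "down"))
    }
  }
  if (!length(out)) return(NULL)
  data.table::rbindlist(out)
}

#' Three-way support of an enhancer-promoter pair
#'
#' The pair's contact score in each cluster map is the score of the contact
#' nearest (Euclidean) to the (enhancer, promoter) point. A pair is
#' supported when the expected cluster's score exceeds the other cluster's
#' by at least \code{margin}, or is at least \code{margin} in absolute
#' value while the other score is negative.
#'
#' @param enh_pos,prom_pos coordinates (vectors); \code{chrom} chromosome.
#' @param chrom chromosome (scalar or vector).
#' @param map_expected,map_other scored contact maps.
#' @param margin score margin (default 15).
#' @return data.table with score_expected, score_other, supported.
#' @export
three_way_support <- function(enh_pos, prom_pos, chrom, map_expected,
                              map_other, margin = 15) {
  chrom <- rep_len(chrom, length(enh_pos))
  qx <- pmin(enh_pos, prom_pos); qy <- pmax(enh_pos, prom_pos)
  get_score <- function(map) {
    map <- as.data.table(map)
    out <- rep(NA_real_, length(qx))
    for (ch in unique(chrom)) {
      sel <- which(chrom == ch)
      mm <- map[chr1 == ch & chr2 == ch]
      if (!nrow(mm)) next
      nn <- nn1_cpp(as.numeric(qx[sel]), as.numeric(qy[sel]),
                    as.numeric(mm$pos1), as.numeric(mm$pos2))
      out[sel] <- mm$score[nn]
    }
    out
  }
  se <- get_score(map_expected)
  so <- get_score(map_other)
  data.table(score_expected = se, score_other = so,
             supported = !is.na(se) & !is.na(so) &
               (se - so >= margin | (se >= margin & so < 0)))
}

#' Count pooled contacts in a window around enhancer-promoter points
#'
#' @param pool contact data.table.
#' @param chrom,enh_pos,prom_pos pair coordinates.
#' @param half_window half window around each end (default 25 kb).
#' @return integer counts.
#' @export
count_pair_contacts <- function(pool, chrom, enh_pos, prom_pos,
                                half_window = 2.5e4) {
  pool <- as.data.table(pool)
  chrom <- rep_len(chrom, length(enh_pos))
  qx <- pmin(enh_pos, prom_pos); qy <- pmax(enh_pos, prom_pos)
  vapply(seq_along(qx), function(i) {
    nrow(pool[chr1 == chrom[i] & chr2 == chrom[i] &
                abs(pos1 - qx[i]) <= half_window &
                abs(pos2 - qy[i]) <= half_window])
  }, 0L)
}

#' Empirical one-sided contact-difference test
#'
#' For a pair with counts (x, o) in the two pools, the statistic x - o is
#' compared to the empirical distribution of the same statistic over all
#' background pairs with the same x + o total. p = (r + 1) / (N + 1) with
#' r the number of background differences at least as large. Pairs with
#' total below \code{min_total} or with at most \code{min_background}
#' matched background pairs are flagged untested (NA).
#'
#' @param x,o counts in the tested condition and the other condition.
#' @param bg_x,bg_o background pair counts.
#' @param min_total minimum x + o (default 80).
#' @param min_background minimum matched background pairs (default 100).
#' @return numeric p-values (NA = untested).
#' @export
empirical_contact_test <- function(x, o, bg_x, bg_o, min_total = 80,
                                   min_background = 100) {
  bg_tot <- bg_x + bg_o
  bg_diff <- bg_x - bg_o
  vapply(seq_along(x), function(i) {
    tot <- x[i] + o[i]
    if (tot < min_total) return(NA_real_)
    sel <- bg_tot == tot
    if (sum(sel) <= min_background) return(NA_real_)
    r <- sum(bg_diff[sel] >= x[i] - o[i])
    (r + 1) / (sum(sel) + 1)
  }, 0)
}

#' Screen for repressive (Polycomb) domain - silent gene pairs
#'
#' Selects track regions with score above \code{score_min} and a
#' cross-tissue difference above \code{diff_min}, and pairs them with
#' proximal lowly expressed genes (below the \code{low_quantile} of
#' expression) whose repressive signal is higher in the tissue where the
#' gene is silent.
#'
#' @param score_x,score_y per-bin repressive-mark scores in two tissues.
#' @param starts track bin starts; \code{step} resolution.
#' @param step track resolution (bp).
#' @param tss data.table with gene, pos.
#' @param expr_x,expr_y named gene expression in the two tissues.
#' @param score_min region threshold (default 7); \code{diff_min}
#'   specificity threshold (default 3).
#' @param diff_min specificity threshold (default 3).
#' @param low_quantile expression quantile defining "lowly expressed".
#' @param max_dist max region-TSS distance (default 100 kb).
#' @return data.table of candidate region-gene pairs.
#' @export
repressive_screen <- function(score_x, score_y, starts, step, tss,
                              expr_x, expr_y, score_min = 7, diff_min = 3,
                              low_quantile = 0.25, max_dist = 1e5) {
  cand <- list()
  for (which_t in c("x", "y")) {
    s_hi <- if (which_t == "x") score_x else score_y
    s_lo <- if (which_t == "x") score_y else score_x
    e_hi <- if (which_t == "x") expr_x else expr_y
    regions <- call_peaks(pmin(s_hi, ifelse(s_hi - s_lo > diff_min, s_hi,
                                            -Inf)),
                          starts, step, threshold = score_min)
    if (!nrow(regions)) next
    low_cut <- quantile(e_hi, low_quantile)
    silent <- names(e_hi)[e_hi <= low_cut]
    tt <- as.data.table(tss)[gene %in% silent]
    for (i in seq_len(nrow(regions))) {
      centre <- (regions$start[i] + regions$end[i]) / 2
      sel <- which(abs(tt$pos - centre) <= max_dist)
      if (!length(sel)) next
      cand[[length(cand) + 1]] <- data.table(
        tissue = which_t, region_start = regions$start[i],
        region_end = regions$end[i], score = regions$score[i],
        gene = tt$gene[sel], tss_pos = tt$pos[sel])
    }
  }
  if (!length(cand)) return(NULL)
  data.table::rbindlist(cand)
}

# kmeans++ seeding over rows of m
.kmeanspp_centers <- function(m, k) {
  n <- nrow(m)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(m, 2, m[centers[1], ])^2)
  for (i in seq_len(k - 1)) {
    pr <- d2 / sum(d2)
    centers[i + 1] <- sample.int(n, 1, prob = pr)
    d2 <- pmin(d2, rowSums(sweep(m, 2, m[centers[i + 1], ])^2))
  }
  m[centers, , drop = FALSE]
}

#' Call ATAC peaks and cluster their accessibility profiles
#'
#' Peaks are intervals whose total (over metacell clusters) coverage
#' exceeds \code{min_total}; per metacell cluster the counts are
#' normalized to frequencies and transformed log2(1e-5 + p); profiles are
#' clustered with kmeans++ (default K = 120); clusters with fewer than
#' \code{min_peaks} peaks are dropped; a cluster is "variable" when at
#' least \code{var_low_n} metacell clusters have mean value below
#' \code{var_low} and the min-max range of the cluster mean profile
#' exceeds \code{var_range}.
#'
#' @param counts peaks x metacell-cluster ATAC count matrix.
#' @param K number of peak clusters (default 120).
#' @param min_total minimum total peak coverage (default 300).
#' @param min_peaks minimum cluster size (default 100).
#' @param var_low,var_low_n,var_range variability rule parameters
#'   (defaults -16, 4, 0.7).
#' @param eps frequency pseudocount (default 1e-5).
#' @param seed RNG seed.
#' @return list with cluster (per kept peak), profiles (cluster means),
#'   variable (per cluster flag), kept peaks, normalized matrix.
#' @export
atac_call_and_cluster <- function(counts, K = 120L, min_total = 300,
                                  min_peaks = 100L, var_low = -16,
                                  var_low_n = 4L, var_range = 0.7,
                                  eps = 1e-5, seed = 1L) {
  keep <- rowSums(counts) > min_total
  m <- counts[keep, , drop = FALSE]
  freq <- sweep(m, 2, pmax(colSums(m), 1), "/")
  lm <- log2(eps + freq)
  set.seed(seed)
  K <- min(K, nrow(lm))
  km <- kmeans(lm, centers = .kmeanspp_centers(lm, K), iter.max = 100)
  sizes <- tabulate(km$cluster, K)
  kept_cl <- which(sizes >= min_peaks)
  prof <- km$centers
  variable <- vapply(seq_len(K), function(k) {
    pr <- prof[k, ]
    sum(pr < var_low) >= var_low_n && (max(pr) - min(pr)) > var_range
  }, TRUE)
  list(cluster = km$cluster, profiles = prof,
       kept_clusters = kept_cl, variable = variable,
       peaks_kept = which(keep), normalized = lm)
}

#' TAD-proximity enrichment between peak clusters
#'
#' Counts peak pairs lying in the same TAD within \code{max_dist} of each
#' other, per ordered cluster pair; enrichment = observed * total /
#' (row total * column total), log2-transformed; entries with a zero
#' marginal are NA.
#'
#' @param peaks data.table with chrom, start, cluster, tad_id.
#' @param max_dist maximum pair distance (default 200 kb).
#' @return list with counts, log2 enrichment matrix.
#' @export
proximity_enrichment <- function(peaks, max_dist = 2e5) {
  pk <- as.data.table(peaks)
  cls <- sort(unique(pk$cluster))
  nc <- length(cls)
  obs <- matrix(0, nc, nc, dimnames = list(cls, cls))
  for (td in unique(pk$tad_id)) {
    sub <- pk[tad_id == td]
    if (nrow(sub) < 2) next
    cmb <- utils::combn(nrow(sub), 2)
    d <- abs(sub$start[cmb[1, ]] - sub$start[cmb[2, ]])
    okp <- d <= max_dist
    if (!any(okp)) next
    a <- match(sub$cluster[cmb[1, okp]], cls)
    b <- match(sub$cluster[cmb[2, okp]], cls)
    for (t in seq_along(a)) {
      obs[a[t], b[t]] <- obs[a[t], b[t]] + 1
      if (a[t] != b[t]) obs[b[t], a[t]] <- obs[b[t], a[t]] + 1
    }
  }
  tot <- sum(obs)
  rs <- rowSums(obs); csm <- colSums(obs)
  enr <- obs * tot / outer(rs, csm)
  enr[!is.finite(enr)] <- NA
  list(counts = obs, log2_enrichment = log2(enr))
}
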