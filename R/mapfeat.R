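# Locus-level map statistics: insulation, virtual 4C and differential
# screens, iterative hotspot scanning, funnel anchors and profile
# clustering, pooled locus maps, and ChIP percentile scoring.

#' Insulation score along a chromosome
#'
#' At each position x (every \code{step} bp), counts "cross" contacts (one
#' end within \code{window} upstream of x, the other within \code{window}
#' downstream) and "within" contacts (both ends within \code{window} of x),
#' and reports log(cross / within) (natural log). Positions with a zero
#' denominator are NA.
#'
#' @param pool contact data.table (cis contacts of one chromosome are used).
#' @param chrom chromosome to scan.
#' @param chrom_size scan end (bp).
#' @param window half-window (default 200 kb).
#' @param step scan step (default 40 kb).
#' @return data.table with chrom, pos, cross, within, insulation.
#' @export
insulation <- function(pool, chrom, chrom_size, window = 2e5, step = 4e4) {
  ct <- as.data.table(pool)
  ct <- ct[chr1 == chrom & chr2 == chrom]
  x1 <- pmin(ct$pos1, ct$pos2); x2 <- pmax(ct$pos1, ct$pos2)
  o <- order(x1); x1 <- x1[o]; x2 <- x2[o]
  xs <- seq(step, chrom_size - step, by = step)
  res <- lapply(xs, function(x) {
    # cross: pos1 in [x - w, x], pos2 in [x, x + w]
    lo <- findInterval(x - window - 1, x1) + 1L
    hi <- findInterval(x, x1)
    cross <- if (hi >= lo) {
      s2 <- x2[lo:hi]
      sum(s2 >= x & s2 <= x + window)
    } else 0L
    # within: both ends in [x - w, x + w]
    hi2 <- findInterval(x + window, x1)
    within <- if (hi2 >= lo) sum(x2[lo:hi2] <= x + window) else 0L
    c(cross, within)
  })
  m <- do.call(rbind, res)
  data.table(chrom = chrom, pos = xs, cross = m[, 1], within = m[, 2],
             insulation = ifelse(m[, 2] > 0, log(m[, 1] / m[, 2]), NA_real_))
}

#' Virtual 4C trace at a viewpoint
#'
#' A contact enters the trace iff one fragment end is within 3 kb of the
#' viewpoint and the span is below 100 kb, or within 10 kb with span in
#' [100 kb, 500 kb), or within 30 kb with span in [500 kb, 1 Mb]. Span
#' boundaries are assigned to the longer-range condition (lower edge
#' inclusive).
#'
#' @param pool contact data.table (optionally with a \code{score} column).
#' @param chrom,x viewpoint.
#' @return data.table of included contacts with side ("5p"/"3p" by the
#'   distal end), span, and score (NA when absent).
#' @export
virtual_4c <- function(pool, chrom, x) {
  ct <- as.data.table(pool)
  ct <- ct[chr1 == chrom & chr2 == chrom]
  span <- abs(ct$pos2 - ct$pos1)
  d1 <- abs(ct$pos1 - x); d2 <- abs(ct$pos2 - x)
  dmin <- pmin(d1, d2)
  keep <- (dmin < 3e3 & span < 1e5) |
          (dmin < 1e4 & span >= 1e5 & span < 5e5) |
          (dmin < 3e4 & span >= 5e5 & span <= 1e6)
  ct <- ct[keep]
  if (!("score" %in% names(ct))) ct[, score := NA_real_]
  distal <- ifelse(d1[keep] <= d2[keep], ct$pos2, ct$pos1)
  data.table(chrom = chrom, viewpoint = x,
             side = ifelse(distal < x, "5p", "3p"),
             span = span[keep], pos = distal, score = ct$score)
}

#' Maximum binned difference between two virtual 4C traces
#'
#' Scores are averaged per (side, span-bin) over the stated span-bin edges
#' (half-open, lower edge inclusive); the distance between the traces is
#' the maximum absolute difference of bin means; bins empty in either trace
#' are skipped.
#'
#' @param v4c_a,v4c_b traces from [virtual_4c()].
#' @param edges span-bin edges (bp).
#' @return list with \code{distance} and the per-bin table.
#' @export
v4c_difference <- function(v4c_a, v4c_b,
                           edges = c(0, 2.5e4, 5e4, 1e5, 2e5, 3e5, 5e5,
                                     7.5e5, 1e6)) {
  binm <- function(v) {
    v <- as.data.table(v)
    v[, bin := findInterval(span, edges)]
    v[, .(m = mean(score, na.rm = TRUE)), by = .(side, bin)]
  }
  ma <- binm(v4c_a); mb <- binm(v4c_b)
  j <- merge(ma, mb, by = c("side", "bin"), suffixes = c("_a", "_b"))
  j <- j[is.finite(m_a) & is.finite(m_b)]
  list(distance = if (nrow(j)) max(abs(j$m_a - j$m_b)) else NA_real_,
       bins = j[])
}

#' Greedy hotspot scan over differential contact scores
#'
#' Repeatedly takes the contact with the maximal score difference, emits it
#' as a hotspot, and removes all contacts whose both ends lie within
#' \code{radius} of the emitted contact's ends; stops when no contact above
#' \code{threshold} remains. Ties at the maximum resolve to the earlier
#' genomic coordinate.
#'
#' @param diffs data.table with chr1, pos1, chr2, pos2, diff.
#' @param dist_range cis span range considered (default 1e4 to 1e6).
#' @param radius removal radius around each hotspot (default 5e4).
#' @param threshold minimum difference (default 40).
#' @return data.table of hotspots in emission order.
#' @export
hotspot_scan <- function(diffs, dist_range = c(1e4, 1e6), radius = 5e4,
                         threshold = 40) {
  dd <- as.data.table(diffs)
  span <- ifelse(dd$chr1 == dd$chr2, abs(dd$pos2 - dd$pos1), NA_real_)
  dd <- dd[!is.na(diff) & !is.na(span) & span >= dist_range[1] &
             span <= dist_range[2]]
  setorder(dd, chr1, pos1, pos2)
  out <- list()
  alive <- rep(TRUE, nrow(dd))
  while (any(alive)) {
    cand <- which(alive)
    mx <- max(dd$diff[cand])
    if (mx <= threshold) break
    top <- cand[dd$diff[cand] == mx][1]   # earlier coordinate wins ties
    out[[length(out) + 1]] <- dd[top]
    near <- alive & dd$chr1 == dd$chr1[top] & dd$chr2 == dd$chr2[top] &
      abs(dd$pos1 - dd$pos1[top]) < radius &
      abs(dd$pos2 - dd$pos2[top]) < radius
    alive[near] <- FALSE
    alive[top] <- FALSE
  }
  if (!length(out)) return(dd[0])
  data.table::rbindlist(out)
}

#' Funnel anchor bins from differential A-scores
#'
#' Thresholds the A-score difference (x - y >= delta), merges adjacent
#' qualifying bins (consecutive bin ids on one chromosome), and keeps the
#' argmax-difference bin of every merged run.
#'
#' @param a_x,a_y named per-bin A-score vectors (names = bin ids).
#' @param bins bin table.
#' @param delta minimum difference (default 0.35).
#' @return data.table of anchors (bin_id, chrom, start, end, delta).
#' @export
funnel_anchors <- function(a_x, a_y, bins, delta = 0.35) {
  bins <- as.data.table(bins)
  dd <- a_x - a_y
  ok <- which(!is.na(dd) & dd >= delta)
  if (!length(ok)) {
    empty <- bins[0]
    empty$delta <- numeric(0)
    return(empty)
  }
  ids <- as.integer(names(dd)[ok])
  b <- bins[match(ids, bin_id)]
  o <- order(b$chrom, b$start)
  ids <- ids[o]; dvals <- dd[ok][o]; b <- b[o]
  run <- cumsum(c(TRUE, !(diff(ids) == 1 &
                            b$chrom[-1] == b$chrom[-nrow(b)])))
  keep <- unlist(lapply(split(seq_along(ids), run), function(ii)
    ii[which.max(dvals[ii])]))
  out <- b[keep]
  out[, delta := dvals[keep]]
  out[]
}

#' Oriented A-score traces around anchors, clustered
#'
#' Extracts per anchor the A-score traces +/- \code{flank} in two
#' conditions, flips each anchor's orientation so the 5' mean is at least
#' the 3' mean (judged on the first condition), concatenates the two
#' condition traces and k-means clusters them.
#'
#' @param anchors from [funnel_anchors()].
#' @param a_x,a_y per-bin A-score vectors of the two conditions.
#' @param bins bin table.
#' @param flank flank size (default 400 kb).
#' @param k clusters (default 8); \code{seed} RNG seed.
#' @param seed RNG seed.
#' @return list with traces (anchors x positions), cluster, flipped.
#' @export
funnel_cluster <- function(anchors, a_x, a_y, bins, flank = 4e5, k = 8L,
                           seed = 1L) {
  bins <- as.data.table(bins)
  bw <- max(bins$end - bins$start)
  nb <- as.integer(flank / bw)
  tr <- function(track, bin0) {
    idx <- (bin0 - nb):(bin0 + nb)
    v <- rep(NA_real_, length(idx))
    ok <- idx >= 1 & idx <= length(track) &
      bins$chrom[pmin(pmax(idx, 1), nrow(bins))] == bins$chrom[bin0]
    v[ok] <- track[idx[ok]]
    v
  }
  tx <- t(vapply(anchors$bin_id, function(b0)
    tr(a_x[as.character(bins$bin_id)], which(bins$bin_id == b0)),
    numeric(2 * nb + 1)))
  ty <- t(vapply(anchors$bin_id, function(b0)
    tr(a_y[as.character(bins$bin_id)], which(bins$bin_id == b0)),
    numeric(2 * nb + 1)))
  mid <- nb + 1
  flip <- rowMeans(tx[, 1:nb, drop = FALSE], na.rm = TRUE) <
    rowMeans(tx[, (mid + 1):(2 * nb + 1), drop = FALSE], na.rm = TRUE)
  flip[is.na(flip)] <- FALSE
  for (i in which(flip)) {
    tx[i, ] <- rev(tx[i, ]); ty[i, ] <- rev(ty[i, ])
  }
  traces <- cbind(tx, ty)
  filled <- traces
  filled[is.na(filled)] <- mean(traces, na.rm = TRUE)
  set.seed(seed)
  kk <- min(k, nrow(traces))
  if (kk >= nrow(traces)) {
    # kmeans needs strictly fewer centres than rows
    cluster <- seq_len(nrow(traces))
    centers <- filled
  } else {
    km <- kmeans(filled, centers = kk, nstart = 5, iter.max = 50)
    cluster <- km$cluster
    centers <- km$centers
  }
  list(traces = traces, cluster = cluster, flipped = flip,
       centers = centers)
}

#' Pooled mean-score locus maps
#'
#' Partitions the contact plane around each locus into pixel x pixel bins
#' over +/- flank, averages contact scores per pixel, aligns orientation
#' (mirrors flipped loci), and averages the per-locus matrices within each
#' locus cluster.
#'
#' @param scored scored contact data.table (with \code{score}).
#' @param loci data.table with chrom, pos, and optionally cluster, flipped.
#' @param flank half-window (default 1 Mb); \code{pixel} bin size (20 kb).
#' @param pixel pixel size (bp).
#' @return named list cluster -> mean-score matrix.
#' @export
pooled_locus_map <- function(scored, loci, flank = 1e6, pixel = 2e4) {
  sc <- as.data.table(scored)
  loci <- as.data.table(loci)
  if (!("cluster" %in% names(loci))) loci[, cluster := 1L]
  if (!("flipped" %in% names(loci))) loci[, flipped := FALSE]
  npix <- as.integer(2 * flank / pixel)
  per_locus <- lapply(seq_len(nrow(loci)), function(i) {
    x <- loci$pos[i]; ch <- loci$chrom[i]
    s <- sc[chr1 == ch & chr2 == ch &
              pos1 >= x - flank & pos1 < x + flank &
              pos2 >= x - flank & pos2 < x + flank]
    m <- matrix(NA_real_, npix, npix)
    if (nrow(s)) {
      i1 <- pmin(npix, 1L + as.integer((s$pos1 - (x - flank)) / pixel))
      i2 <- pmin(npix, 1L + as.integer((s$pos2 - (x - flank)) / pixel))
      lo <- pmin(i1, i2); hi <- pmax(i1, i2)
      sums <- tapply(s$score, list(factor(lo, 1:npix), factor(hi, 1:npix)),
                     mean)
      m[!is.na(sums)] <- sums[!is.na(sums)]
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
    }
    if (isTRUE(loci$flipped[i])) m <- m[npix:1, npix:1]
    m
  })
  out <- list()
  for (cl in sort(unique(loci$cluster))) {
    ms <- per_locus[loci$cluster == cl]
    arr <- array(unlist(ms), dim = c(npix, npix, length(ms)))
    out[[as.character(cl)]] <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  }
  out
}

#' ChIP percentile score, binding sites and per-bin maxima
#'
#' The score of a track bin with coverage percentile p is -log2(1 - p);
#' percentiles use p = (rank - 1) / n so the top bin of n = 128 scores
#' exactly 7. \code{chip_binding_sites} thresholds scores; a coarse bin's
#' binding score is the maximum site score it contains.
#'
#' @param coverage numeric coverage vector (20 bp bins).
#' @return numeric score vector.
#' @export
chip_bin_score <- function(coverage) {
  n <- length(coverage)
  p <- (rank(coverage, ties.method = "average") - 1) / n
  -log2(1 - p)
}

#' @rdname chip_bin_score
#' @param score score vector; \code{starts} bin start coordinates;
#'   \code{step} track resolution; \code{threshold} site threshold.
#' @param starts track bin start coordinates (bp).
#' @param step track resolution (bp).
#' @param threshold minimum site score (default 8).
#' @return data.table of merged binding-site intervals with max score.
#' @export
chip_binding_sites <- function(score, starts, step = 20L, threshold = 8) {
  ok <- which(score > threshold)
  if (!length(ok)) return(data.table(start = integer(), end = integer(),
                                     score = numeric()))
  run <- cumsum(c(TRUE, diff(ok) != 1))
  data.table::rbindlist(lapply(split(ok, run), function(ii)
    data.table(start = starts[ii[1]], end = starts[tail(ii, 1)] + step,
               score = max(score[ii]))))
}

#' @rdname chip_bin_score
#' @param sites from [chip_binding_sites()]; \code{bins} coarse bin table;
#'   \code{chrom} the track's chromosome.
#' @param sites binding-site table.
#' @param bins coarse bin table.
#' @param chrom chromosome of the track.
#' @return named per-bin max site score (NA when no site).
#' @export
chip_bin_max <- function(sites, bins, chrom) {
  bins <- as.data.table(bins)[chrom, on = "chrom"]
  out <- rep(NA_real_, nrow(bins))
  names(out) <- as.character(bins$bin_id)
  for (i in seq_len(nrow(sites))) {
    sel <- which(bins$start < sites$end[i] & bins$end > sites$start[i])
    out[sel] <- pmax(out[sel], sites$score[i], na.rm = TRUE)
  }
  out
}
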