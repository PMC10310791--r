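# Pooling, degree- and distance-preserving contact shuffling, and
# KNN/KS enrichment scoring of contact maps.

#' Pool cluster contacts and downsample to equal size
#'
#' @param contacts contact data.table.
#' @param assignment named cluster label per cell (NA cells dropped).
#' @param seed RNG seed.
#' @return named list cluster -> contact data.table, all of the minimal
#'   pool size.
#' @export
pool_and_downsample <- function(contacts, assignment, seed = 1L) {
  ct <- as.data.table(contacts)
  lab <- assignment[ct$cell]
  pools <- split(ct[!is.na(lab)], lab[!is.na(lab)])
  m <- min(vapply(pools, nrow, 0L))
  set.seed(seed)
  lapply(pools, function(p) if (nrow(p) > m) p[sample(.N, m)] else p)
}

#' Shuffle a contact pool preserving degrees and distances
#'
#' Runs partner-swap MCMC: a proposal exchanges the second fragment ends of
#' two contacts (drawn from the same chromosome for cis, from the trans
#' pool for trans) and is accepted by Metropolis on the change of the
#' distance-histogram mismatch sum_b |h_b - H_b| against the input
#' histogram (log2-spaced bins from 1 kb; one trans bin). Per-end degrees
#' are preserved exactly by construction.
#'
#' @param pool contact data.table.
#' @param sweeps proposals per contact (default 20).
#' @param beta Metropolis inverse temperature on the histogram mismatch
#'   (default 20). The number of scrambled configurations grows roughly
#'   like exp(log(n) * mismatch), so beta must exceed log(n) or the chain
#'   drifts to long distances; at the default, proposals that damage the
#'   histogram are effectively rejected and accepted swaps preserve the
#'   distance histogram (near-)exactly.
#' @param seed RNG seed.
#' @param tv_warn warn if the final total-variation distance between the
#'   shuffled and target distance histograms exceeds this (default 0.01).
#' @return shuffled contact data.table with attributes \code{tv},
#'   \code{n_proposals}, \code{n_accepted}.
#' @export
shaman_shuffle <- function(pool, sweeps = 20L, beta = 20, seed = 1L,
                           tv_warn = 0.01) {
  pool <- as.data.table(pool)
  stopifnot(nrow(pool) >= 2)
  chroms <- sort(unique(c(pool$chr1, pool$chr2)))
  res <- shuffle_cpp(match(pool$chr1, chroms), as.numeric(pool$pos1),
                     match(pool$chr2, chroms), as.numeric(pool$pos2),
                     as.integer(sweeps), beta, as.integer(seed %% .Machine$integer.max))
  out <- data.table(cell = pool$cell,
                    chr1 = chroms[res$chr1], pos1 = as.integer(res$pos1),
                    chr2 = chroms[res$chr2], pos2 = as.integer(res$pos2))
  out <- canonicalize_contacts(out, chroms)
  if (res$tv > tv_warn) {
    warning(sprintf("shuffle did not converge: distance-histogram TV %.4g > %.4g",
                    res$tv, tv_warn))
  }
  attr(out, "tv") <- res$tv
  attr(out, "n_proposals") <- res$n_proposals
  attr(out, "n_accepted") <- res$n_accepted
  out
}

#' Distance-histogram total variation between two pools
#'
#' log2-spaced cis distance bins from 1 kb plus one trans bin.
#' @param a,b contact data.tables.
#' @return numeric in [0, 1].
#' @export
contact_dist_tv <- function(a, b) {
  binz <- function(ct) {
    d <- contact_distance(ct)
    ifelse(is.na(d), 0L, 1L + floor(log2(pmax(d, 1000) / 1000)))
  }
  ba <- binz(a); bb <- binz(b)
  lev <- sort(unique(c(ba, bb)))
  ha <- tabulate(match(ba, lev), length(lev)) / length(ba)
  hb <- tabulate(match(bb, lev), length(lev)) / length(bb)
  sum(abs(ha - hb)) / 2
}

#' Per-end degree table of a pool (for exact preservation checks)
#' @param pool contact data.table.
#' @return data.table (chrom, pos, degree) sorted.
#' @export
end_degrees <- function(pool) {
  ends <- data.table(chrom = c(pool$chr1, pool$chr2),
                     pos = c(pool$pos1, pool$pos2))
  out <- ends[, .(degree = .N), by = .(chrom, pos)]
  setorder(out, chrom, pos)
  out[]
}

#' KNN/KS enrichment scores for observed contacts
#'
#' For every observed contact, the distances to its k nearest neighbours in
#' the observed pool (the contact itself excluded) and in the shuffled pool
#' are compared with a two-sample KS statistic; the signed score is
#' 100 * D, positive when observed neighbours are nearer (enrichment),
#' clipped to [-100, 100]. Chromosome pairs with fewer than k + 1 contacts
#' are scored with the reduced neighbour count.
#'
#' @param observed,shuffled contact data.tables (canonical).
#' @param k neighbours (default 100).
#' @return the observed table with a \code{score} column.
#' @export
shaman_score <- function(observed, shuffled, k = 100L) {
  obs <- as.data.table(observed)
  shuf <- as.data.table(shuffled)
  stopifnot(nrow(obs) > 0, nrow(shuf) > 0)
  obs[, score := NA_real_]
  obs[, pair := paste(chr1, chr2, sep = "|")]
  shuf[, pair := paste(chr1, chr2, sep = "|")]
  for (pp in unique(obs$pair)) {
    oi <- which(obs$pair == pp)
    si <- which(shuf$pair == pp)
    if (length(si) == 0) next
    kk <- min(k, length(oi) - 1L, length(si))
    if (kk < 1) next
    sc <- knn_score_cpp(as.numeric(obs$pos1[oi]), as.numeric(obs$pos2[oi]),
                        as.numeric(obs$pos1[oi]), as.numeric(obs$pos2[oi]),
                        as.numeric(shuf$pos1[si]), as.numeric(shuf$pos2[si]),
                        as.integer(kk), TRUE, seq_along(oi) - 1L)
    obs[oi, score := sc]
  }
  obs[, pair := NULL]
  obs[]
}

#' Differential score between two scored maps
#'
#' For every contact of map A, the difference between its score and the
#' score of the nearest contact in map B (Euclidean on the contact plane,
#' same chromosome pair). Mode "both_positive" keeps only contacts whose
#' own score and nearest-B score are both positive; "unrestricted" keeps
#' all. Contacts with no B contact on their chromosome pair are flagged by
#' an NA difference.
#'
#' @param mapA,mapB scored contact data.tables (with \code{score}).
#' @param mode filtering mode.
#' @return mapA with columns \code{score_other} and \code{diff}.
#' @export
score_difference <- function(mapA, mapB,
                             mode = c("unrestricted", "both_positive")) {
  mode <- match.arg(mode)
  a <- data.table::copy(as.data.table(mapA))
  b <- as.data.table(mapB)
  a[, score_other := NA_real_]
  a[, pairk := paste(chr1, chr2, sep = "|")]
  bp <- paste(b$chr1, b$chr2, sep = "|")
  for (pp in unique(a$pairk)) {
    ai <- which(a$pairk == pp)
    bi <- which(bp == pp)
    if (!length(bi)) next
    nn <- nn1_cpp(as.numeric(a$pos1[ai]), as.numeric(a$pos2[ai]),
                  as.numeric(b$pos1[bi]), as.numeric(b$pos2[bi]))
    a[ai, score_other := b$score[bi[nn]]]
  }
  a[, diff := score - score_other]
  a[, pairk := NULL]
  if (mode == "both_positive") a <- a[!is.na(diff) & score > 0 & score_other > 0]
  a[]
}
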