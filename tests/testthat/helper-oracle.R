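# Independent brute-force oracles used by the equivalence tests. These are
# deliberately written in the most literal way possible (per-element loops,
# no shared helpers with the package) so that agreement with the package
# functions is meaningful.

oracle_assign_bin <- function(chrom, pos, bins) {
  out <- rep(NA_integer_, length(pos))
  for (i in seq_along(pos)) {
    for (j in seq_len(nrow(bins))) {
      if (bins$chrom[j] == chrom[i] &&
          pos[i] >= bins$start[j] && pos[i] < bins$end[j]) {
        out[i] <- bins$bin_id[j]
        break
      }
    }
  }
  out
}

oracle_a_score <- function(cA, cB, cells) {
  num <- 0 * cA[1, ]; den <- num
  for (cl in cells) {
    num <- num + cA[cl, ]
    den <- den + cA[cl, ] + cB[cl, ]
  }
  res <- num / den
  res[den == 0] <- NA_real_
  res
}

oracle_early_score <- function(dsn, cells, g1) {
  out <- numeric(ncol(dsn))
  for (j in seq_len(ncol(dsn))) {
    a <- sum(dsn[cells, j]); b <- sum(dsn[g1, j])
    out[j] <- log((length(g1) / length(cells)) * a / b)
  }
  out
}

oracle_el <- function(row, early, late) {
  log2(sum(row[early]) / sum(row[late]))
}

oracle_insulation <- function(contacts, x, w) {
  cross <- 0; within <- 0
  for (i in seq_len(nrow(contacts))) {
    p1 <- contacts$pos1[i]; p2 <- contacts$pos2[i]
    if (p1 >= x - w && p1 <= x && p2 >= x && p2 <= x + w) cross <- cross + 1
    if (p1 >= x - w && p1 <= x + w && p2 >= x - w && p2 <= x + w)
      within <- within + 1
  }
  log(cross / within)
}

oracle_v4c_included <- function(dmin, span) {
  (dmin < 3e3 && span < 1e5) ||
    (dmin < 1e4 && span >= 1e5 && span < 5e5) ||
    (dmin < 3e4 && span >= 5e5 && span <= 1e6)
}

oracle_v4c_difference <- function(pa, sa, pb, sb, edges) {
  best <- 0
  for (b in seq_len(length(edges) - 1)) {
    ia <- pa >= edges[b] & pa < edges[b + 1]
    ib <- pb >= edges[b] & pb < edges[b + 1]
    ma <- mean(sa[ia]); mb <- mean(sb[ib])
    if (is.finite(ma) && is.finite(mb) && abs(ma - mb) > best)
      best <- abs(ma - mb)
  }
  best
}

oracle_hotspots <- function(pos1, pos2, score, threshold, radius) {
  keep <- which(score > threshold)
  keep <- keep[order(-score[keep], pos1[keep], pos2[keep])]
  chosen <- integer(0)
  while (length(keep)) {
    i <- keep[1]
    chosen <- c(chosen, i)
    near <- abs(pos1[keep] - pos1[i]) < radius &
      abs(pos2[keep] - pos2[i]) < radius
    keep <- keep[!near]
  }
  chosen
}

# literal oracle for distinct values: rank_i = 1 + #(v < v_i)
oracle_chip_score <- function(v) {
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    p <- sum(v < v[i]) / n
    out[i] <- -log2(1 - p)
  }
  out
}

oracle_proximity <- function(cl1, cl2, tad1, tad2, pos1, pos2, max_dist) {
  ks <- sort(unique(c(cl1, cl2)))
  obs <- matrix(0, length(ks), length(ks), dimnames = list(ks, ks))
  n <- length(cl1)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_tad <- !is.na(tad1[i]) && !is.na(tad1[j]) && tad1[i] == tad1[j]
      if (!same_tad) next
      if (abs(pos1[i] - pos1[j]) > max_dist) next
      a <- as.character(cl1[i]); b <- as.character(cl1[j])
      if (a == b) {
        obs[a, b] <- obs[a, b] + 1
      } else {
        obs[a, b] <- obs[a, b] + 1
        obs[b, a] <- obs[b, a] + 1
      }
    }
  }
  obs
}

# simple adjusted Rand index for recovery tests
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  e <- sa * sb / choose(n, 2)
  (si - e) / ((sa + sb) / 2 - e)
}
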