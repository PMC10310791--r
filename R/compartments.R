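# A-score and early-score tracks, per-cell pooled A-scores, mapping
# expression onto genomic bins, and threshold classification of bins.

#' Long-range contact counts against the strict references
#'
#' For every cell i and bin j, cA(i,j) / cB(i,j) count the cis contacts
#' longer than \code{min_dist} with one end in bin j and the other end in a
#' strict-early / strict-late reference bin. Each contact contributes once
#' per (bin, reference-class) incidence: a contact whose two ends fall in
#' bins j1 and j2 with the j2 end inside the early reference increments
#' cA(i, j1); if the j1 end is also inside the early reference it
#' additionally increments cA(i, j2).
#'
#' @param contacts contact data.table.
#' @param bins bin table (typically 40 kb).
#' @param reference list with early_strict / late_strict bin ids on the same
#'   bin table.
#' @param min_dist minimum cis distance (default 1 Mb).
#' @return list of two cells x bins sparse-pattern integer matrices cA, cB.
#' @export
ab_contact_counts <- function(contacts, bins, reference, min_dist = 1e6) {
  ct <- as.data.table(contacts)
  d <- contact_distance(ct)
  ct <- ct[!is.na(d) & d > min_dist]
  cells <- sort(unique(as.data.table(contacts)$cell))
  bins <- as.data.table(bins)
  b1 <- assign_bin(ct$chr1, ct$pos1, bins)
  b2 <- assign_bin(ct$chr2, ct$pos2, bins)
  mk <- function(ref) {
    # counts at bin of one end when the partner end is in the reference
    inc <- data.table(cell = c(ct$cell, ct$cell), bin = c(b1, b2),
                      partner = c(b2, b1))
    inc <- inc[!is.na(bin) & partner %in% ref]
    m <- matrix(0L, length(cells), nrow(bins),
                dimnames = list(cells, as.character(bins$bin_id)))
    if (nrow(inc)) {
      tab <- inc[, .N, by = .(cell, bin)]
      m[cbind(match(tab$cell, cells), match(tab$bin, bins$bin_id))] <- tab$N
    }
    m
  }
  list(cA = mk(reference$early_strict), cB = mk(reference$late_strict))
}

#' A-score track for a set of cells
#'
#' scoreA_j = sum_i cA(i,j) / (sum_i cA(i,j) + sum_i cB(i,j)) over cells i
#' in the set; NA where the denominator is zero (never 0/0 -> 0).
#'
#' @param cA,cB matrices from [ab_contact_counts()].
#' @param cells character vector of cell ids (default: all rows).
#' @return named numeric vector per bin.
#' @export
a_score <- function(cA, cB, cells = rownames(cA)) {
  stopifnot(length(cells) > 0)
  a <- colSums(cA[cells, , drop = FALSE])
  b <- colSums(cB[cells, , drop = FALSE])
  out <- ifelse(a + b > 0, a / (a + b), NA_real_)
  setNames(out, colnames(cA))
}

#' Early-replication score track
#'
#' scoreE_j = log((|G1|/|C|) * sum_C dsn_j / sum_G1 dsn_j) (natural log):
#' the relative coverage of bin j in the cell set C versus G1 cells. NA
#' where pooled G1 coverage is zero.
#'
#' @param dsn cells x bins coverage matrix.
#' @param cells cell ids of the set C.
#' @param g1_cells cell ids of the G1 reference set.
#' @return named numeric vector per bin.
#' @export
early_score <- function(dsn, cells, g1_cells) {
  stopifnot(length(cells) > 0, length(g1_cells) > 0)
  sc <- colSums(dsn[cells, , drop = FALSE])
  sg <- colSums(dsn[g1_cells, , drop = FALSE])
  out <- ifelse(sg > 0, log((length(g1_cells) / length(cells)) * sc / sg),
                NA_real_)
  setNames(out, colnames(dsn))
}

#' Per-cell pooled A-score over a bin group
#'
#' cell_A_m(i) = sum_{j in m} cA(i,j) / sum_{j in m} (cA + cB)(i,j);
#' NA when the cell has no qualifying contact in the group.
#'
#' @param cA,cB matrices from [ab_contact_counts()].
#' @param bin_group bin ids of the group m.
#' @return named numeric vector per cell.
#' @export
cell_pooled_ascore <- function(cA, cB, bin_group) {
  sel <- colnames(cA) %in% as.character(bin_group)
  a <- rowSums(cA[, sel, drop = FALSE])
  b <- rowSums(cB[, sel, drop = FALSE])
  ifelse(a + b > 0, a / (a + b), NA_real_)
}

#' Map an expression profile onto genomic bins
#'
#' The bin value is the maximal expression over all genes whose TSS falls in
#' the bin; bins with no TSS get NA.
#'
#' @param expr named numeric vector (per gene) or gene x set matrix.
#' @param tss data.table with gene, bin_id.
#' @param bins bin table.
#' @return numeric vector per bin (or matrix bins x sets).
#' @export
map_expression_to_bins <- function(expr, tss, bins) {
  bins <- as.data.table(bins)
  if (is.matrix(expr)) {
    out <- sapply(colnames(expr), function(cn)
      map_expression_to_bins(expr[, cn], tss, bins))
    rownames(out) <- as.character(bins$bin_id)
    return(out)
  }
  tss <- as.data.table(tss)[gene %in% names(expr)]
  v <- rep(NA_real_, nrow(bins))
  names(v) <- as.character(bins$bin_id)
  if (nrow(tss)) {
    agg <- tss[, .(e = max(expr[gene])), by = bin_id]
    v[as.character(agg$bin_id)] <- agg$e
  }
  v
}

#' Classify bins by differential expression or scores
#'
#' kind "induced": bins with at least \code{fold}-fold expression change
#' between the two tracks (both directions reported). kind "a_specific" or
#' "funnel_seed": bins whose score difference exceeds \code{delta}.
#'
#' @param x,y per-bin values of the two conditions (same length, named).
#' @param kind one of "induced", "a_specific", "funnel_seed".
#' @param fold fold-change threshold (induced; default 4).
#' @param delta score-difference threshold (a_specific default 0.2;
#'   funnel_seed default 0.35).
#' @param pseudo pseudocount added to expression before fold change.
#' @return list with x_specific and y_specific bin-name vectors.
#' @export
classify_bins <- function(x, y, kind = c("induced", "a_specific", "funnel_seed"),
                          fold = 4, delta = NULL, pseudo = 0) {
  kind <- match.arg(kind)
  stopifnot(length(x) == length(y))
  nm <- names(x)
  if (kind == "induced") {
    fc <- (x + pseudo) / (y + pseudo)
    xs <- which(!is.na(fc) & fc >= fold)
    ys <- which(!is.na(fc) & fc <= 1 / fold)
  } else {
    if (is.null(delta)) delta <- if (kind == "funnel_seed") 0.35 else 0.2
    dd <- x - y
    xs <- which(!is.na(dd) & dd >= delta)
    ys <- which(!is.na(dd) & dd <= -delta)
  }
  list(x_specific = nm[xs], y_specific = nm[ys])
}

#' TSS bin sets of enriched genes per metacell
#'
#' Normalizes log expression by subtracting each gene's mean over
#' metacells, then selects per metacell the top \code{top_n} enriched genes
#' with enrichment above \code{min_enrich}, and maps them to bins.
#'
#' @param expr gene x metacell expression matrix (UMI fractions).
#' @param tss data.table with gene, bin_id.
#' @param top_n cap on genes per metacell (default 50).
#' @param min_enrich minimum log2 enrichment (default 0.5).
#' @param eps pseudo-fraction before log.
#' @return named list metacell -> integer bin ids.
#' @export
tss_bin_sets <- function(expr, tss, top_n = 50, min_enrich = 0.5,
                         eps = 1e-5) {
  le <- log2(expr + eps)
  enr <- le - rowMeans(le)
  tss <- as.data.table(tss)
  lapply(setNames(colnames(expr), colnames(expr)), function(mc) {
    e <- enr[, mc]
    sel <- names(sort(e[e > min_enrich], decreasing = TRUE))
    sel <- head(sel, top_n)
    sort(unique(tss$bin_id[match(sel, tss$gene)]))
  })
}

#' Project a cell's UMI vector onto an expression atlas
#'
#' Assigns the annotation of the atlas metacell maximizing
#' cor(log(u+1), log(eps + e)); ties resolve to the lowest metacell index.
#'
#' @param u named UMI count vector.
#' @param profiles gene x metacell expression-fraction matrix.
#' @param annotations named character, per-metacell cell-type labels.
#' @param eps regularization (default 1e-5).
#' @return list with metacell (column name) and type.
#' @export
project_to_atlas <- function(u, profiles, annotations = NULL, eps = 1e-5) {
  g <- intersect(names(u), rownames(profiles))
  cc <- cor(log(u[g] + 1), log(eps + profiles[g, , drop = FALSE]))
  best <- which(cc == max(cc))[1]
  mc <- colnames(profiles)[best]
  list(metacell = mc,
       type = if (!is.null(annotations)) annotations[[mc]] else NA_character_,
       correlation = max(cc))
}
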