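# Contact-table IO, canonicalization, per-cell QC, downsampling and binning.
#
# A contact table is a data.table with columns
#   cell (character), chr1, pos1, chr2, pos2
# holding one ligated fragment-end pair per row. Coordinates are 0-based bp.
# Records are canonical when (chr1, pos1) <= (chr2, pos2) under (chromosome
# order, position) ordering; chromosome order is the lexicographic order of
# the chromosome names unless a factor level order is supplied.

#' Canonicalize a contact table
#'
#' Reorders the two fragment ends of every record so that
#' (chr1, pos1) <= (chr2, pos2) under (chromosome order, position) ordering.
#'
#' @param contacts data.table with columns cell, chr1, pos1, chr2, pos2.
#' @param chrom_levels optional character vector fixing the chromosome order;
#'   defaults to sorted unique names.
#' @return the canonicalized data.table (a copy).
#' @export
canonicalize_contacts <- function(contacts, chrom_levels = NULL) {
  ct <- as.data.table(contacts)
  if (is.null(chrom_levels)) {
    chrom_levels <- sort(unique(c(ct$chr1, ct$chr2)))
  }
  o1 <- match(ct$chr1, chrom_levels)
  o2 <- match(ct$chr2, chrom_levels)
  swap <- (o2 < o1) | (o1 == o2 & ct$pos2 < ct$pos1)
  if (any(swap)) {
    tmp_c <- ct$chr1[swap]; tmp_p <- ct$pos1[swap]
    ct[swap, `:=`(chr1 = chr2, pos1 = pos2)]
    ct[swap, `:=`(chr2 = tmp_c, pos2 = tmp_p)]
  }
  ct[]
}

#' Read a contact table from a pairs-like TSV
#'
#' Expects five tab-separated columns: cell, chr1, pos1, chr2, pos2. A header
#' row is detected (first line whose position fields are non-numeric) and
#' skipped. Records are canonicalized on read.
#'
#' @param path file path.
#' @param chrom_levels optional chromosome ordering for canonicalization.
#' @return canonical contact data.table.
#' @export
read_contacts <- function(path, chrom_levels = NULL) {
  if (!file.exists(path)) stop("contact file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.table(cell = character(), chr1 = character(), pos1 = integer(),
                      chr2 = character(), pos2 = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  skip <- 0L
  f1 <- fields[[1]]
  if (length(f1) == 5 && (is.na(suppressWarnings(as.numeric(f1[3]))) ||
                          is.na(suppressWarnings(as.numeric(f1[5]))))) {
    skip <- 1L
  }
  body_idx <- seq.int(skip + 1L, length(lines))
  bad <- body_idx[nf[body_idx] != 5L]
  if (length(bad)) {
    stop("malformed contact line(s) (expected 5 tab-separated fields) at line ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  }
  m <- matrix(unlist(fields[body_idx]), ncol = 5, byrow = TRUE)
  pos1 <- suppressWarnings(as.numeric(m[, 3]))
  pos2 <- suppressWarnings(as.numeric(m[, 5]))
  nonnum <- which(is.na(pos1) | is.na(pos2))
  if (length(nonnum)) {
    stop("non-numeric position at line ",
         paste(head(body_idx[nonnum], 5), collapse = ", "))
  }
  neg <- which(pos1 < 0 | pos2 < 0)
  if (length(neg)) {
    stop("negative position at line ",
         paste(head(body_idx[neg], 5), collapse = ", "))
  }
  ct <- data.table(cell = m[, 1], chr1 = m[, 2], pos1 = as.integer(round(pos1)),
                   chr2 = m[, 4], pos2 = as.integer(round(pos2)))
  canonicalize_contacts(ct, chrom_levels)
}

#' Write a contact table as TSV
#'
#' @param contacts contact data.table.
#' @param path output file path.
#' @param header write a header row (default TRUE).
#' @export
write_contacts <- function(contacts, path, header = TRUE) {
  write.table(as.data.table(contacts)[, .(cell, chr1, pos1, chr2, pos2)],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = header)
  invisible(path)
}

#' Cis contact distances
#'
#' @param contacts contact data.table.
#' @return numeric vector, |pos2 - pos1| for cis records and NA for trans.
#' @export
contact_distance <- function(contacts) {
  ifelse(contacts$chr1 == contacts$chr2,
         abs(contacts$pos2 - contacts$pos1), NA_real_)
}

#' Uniform genomic bins
#'
#' Builds a table of half-open, uniform-width bins covering the given
#' chromosomes, with 0-based coordinates and consecutive integer bin ids.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param width bin width in bp.
#' @return data.table with columns chrom, start, end, bin_id.
#' @export
make_bins <- function(chrom_sizes, width) {
  stopifnot(width > 0, length(chrom_sizes) > 0, !is.null(names(chrom_sizes)))
  out <- lapply(names(chrom_sizes), function(cn) {
    len <- chrom_sizes[[cn]]
    starts <- seq(0, len - 1, by = width)
    data.table(chrom = cn, start = starts, end = pmin(starts + width, len))
  })
  bins <- data.table::rbindlist(out)
  bins[, bin_id := seq_len(.N)]
  bins[]
}

#' Read / write bin tables as BED3+id
#' @param path file path.
#' @return data.table with chrom, start, end, bin_id.
#' @export
read_bins <- function(path) {
  b <- data.table::fread(path, header = FALSE,
                         col.names = c("chrom", "start", "end", "bin_id"))
  b[, `:=`(start = as.numeric(start), end = as.numeric(end),
           bin_id = as.integer(bin_id))]
  b[]
}

#' @rdname read_bins
#' @param bins bin table.
#' @export
write_bins <- function(bins, path) {
  write.table(as.data.table(bins)[, .(chrom, start, end, bin_id)], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Map genomic positions to bin ids
#'
#' @param chrom,pos position vectors.
#' @param bins bin table from [make_bins()].
#' @return integer bin ids (NA where the position falls outside all bins).
#' @export
assign_bin <- function(chrom, pos, bins) {
  bins <- as.data.table(bins)
  out <- rep(NA_integer_, length(pos))
  for (cn in unique(chrom)) {
    sel <- chrom == cn
    cb <- bins[bins$chrom == cn]
    if (nrow(cb) == 0) next
    idx <- findInterval(pos[sel], cb$start)
    ok <- idx >= 1 & pos[sel] < cb$end[pmax(idx, 1)]
    out[sel][ok] <- cb$bin_id[idx[ok]]
  }
  out
}

#' QC thresholds for single cells
#'
#' @param min_contacts minimum contact count per cell.
#' @param max_trans maximum fraction of trans (inter-chromosomal) contacts.
#' @param max_nondigested maximum fraction of cis contacts with distance
#'   below \code{nondigested_dist} (a proxy for non-digested fragments).
#' @param max_chrom_aberration maximum over chromosomes of
#'   |log2(observed / expected coverage)|.
#' @param nondigested_dist distance below which a cis contact is counted as
#'   non-digested (bp).
#' @return a list of thresholds, used by [qc_cells()].
#' @export
qc_config <- function(min_contacts = 20000, max_trans = 0.35,
                      max_nondigested = 0.35, max_chrom_aberration = 1.0,
                      nondigested_dist = 1000) {
  list(min_contacts = min_contacts, max_trans = max_trans,
       max_nondigested = max_nondigested,
       max_chrom_aberration = max_chrom_aberration,
       nondigested_dist = nondigested_dist)
}

#' Per-cell quality control
#'
#' Computes, per cell, the total contact count, trans fraction, the fraction
#' of short (non-digested proxy) cis contacts, the maximal chromosomal
#' coverage aberration (max over chromosomes of |log2 observed/expected
#' fragment-end coverage|, expected taken from the pooled cohort), and the
#' modal contact-distance bin, and filters cells on configurable thresholds.
#'
#' @param contacts contact data.table.
#' @param thresholds from [qc_config()].
#' @return list with elements \code{qc} (per-cell statistics and pass flag)
#'   and \code{pass} (character vector of passing cell ids).
#' @export
qc_cells <- function(contacts, thresholds = qc_config()) {
  ct <- as.data.table(contacts)
  stopifnot(nrow(ct) > 0)
  d <- contact_distance(ct)
  ct2 <- data.table(cell = ct$cell, trans = is.na(d), d = d)
  per <- ct2[, .(
    n_contacts = .N,
    frac_trans = mean(trans),
    frac_nondigested = {
      cis <- !trans
      if (any(cis)) mean(d[cis] < thresholds$nondigested_dist) else 0
    },
    modal_distance_bin = {
      cis <- !trans & d >= 1000
      if (any(cis)) {
        b <- floor(log2(d[cis]) / 0.5)
        names(sort(table(b), decreasing = TRUE))[1]
      } else NA_character_
    }), by = cell]

  # chromosomal coverage aberration: per-cell chromosome end fractions vs
  # pooled cohort fractions
  ends <- data.table(cell = rep(ct$cell, 2), chrom = c(ct$chr1, ct$chr2))
  cc <- ends[, .N, by = .(cell, chrom)]
  pooled <- ends[, .N, by = chrom]
  pooled[, frac := N / sum(N)]
  tot <- cc[, .(tot = sum(N)), by = cell]
  cc <- merge(cc, tot, by = "cell")
  cc <- merge(cc, pooled[, .(chrom, frac)], by = "chrom")
  ab <- cc[, .(max_chrom_aberration = max(abs(log2((N / tot) / frac)))),
           by = cell]
  per <- merge(per, ab, by = "cell", all.x = TRUE)
  per[is.na(max_chrom_aberration), max_chrom_aberration := 0]

  per[, pass := n_contacts >= thresholds$min_contacts &
        frac_trans <= thresholds$max_trans &
        frac_nondigested <= thresholds$max_nondigested &
        max_chrom_aberration <= thresholds$max_chrom_aberration]
  list(qc = per[], pass = per$cell[per$pass])
}

#' Downsample every cell to a fixed contact count
#'
#' Samples, without replacement, exactly \code{target} contacts from every
#' cell with at least that many; cells below the target are kept whole or
#' dropped according to \code{drop_below}.
#'
#' @param contacts contact data.table.
#' @param target contact count per cell after downsampling.
#' @param seed RNG seed (sampling is reproducible for a fixed seed).
#' @param drop_below drop cells with fewer than \code{target} contacts.
#' @return downsampled contact data.table.
#' @export
downsample_cells <- function(contacts, target, seed = 1L, drop_below = FALSE) {
  stopifnot(target > 0)
  ct <- as.data.table(contacts)
  set.seed(seed)
  keep <- logical(nrow(ct))
  idx_by_cell <- split(seq_len(nrow(ct)), ct$cell)
  for (cn in sort(names(idx_by_cell))) {
    idx <- idx_by_cell[[cn]]
    if (length(idx) > target) {
      keep[sample(idx, target)] <- TRUE
    } else if (length(idx) == target || !drop_below) {
      keep[idx] <- TRUE
    }
  }
  ct[keep]
}

#' Fragment-end coverage per cell and bin
#'
#' Entry (i, j) counts the fragment ends of cell i that fall in bin j; every
#' contact contributes two ends (possibly to the same bin). Ends outside all
#' bins are dropped with a warning.
#'
#' @param contacts contact data.table.
#' @param bins bin table from [make_bins()].
#' @return integer matrix cells x bins with attributes \code{bin_width}; row
#'   names are cell ids, column names bin ids.
#' @export
bin_coverage <- function(contacts, bins) {
  ct <- as.data.table(contacts)
  bins <- as.data.table(bins)
  cells <- sort(unique(ct$cell))
  ends <- data.table(cell = rep(ct$cell, 2),
                     chrom = c(ct$chr1, ct$chr2),
                     pos = c(ct$pos1, ct$pos2))
  ends[, bin := assign_bin(chrom, pos, bins)]
  n_out <- sum(is.na(ends$bin))
  if (n_out > 0) {
    warning(n_out, " fragment end(s) outside the bin table were dropped")
    ends <- ends[!is.na(bin)]
  }
  m <- matrix(0L, nrow = length(cells), ncol = nrow(bins),
              dimnames = list(cells, as.character(bins$bin_id)))
  tab <- ends[, .N, by = .(cell, bin)]
  m[cbind(match(tab$cell, cells), match(tab$bin, bins$bin_id))] <- tab$N
  w <- unique(bins$end - bins$start)
  attr(m, "bin_width") <- max(w)
  m
}
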