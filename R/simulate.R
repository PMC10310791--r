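# Synthetic scHi-C cohort generator with planted ground truth.
#
# The generator emulates the features of embryonic scHi-C data that the
# analysis modules consume: cell-cycle-dependent contact-distance
# distributions (short <2 Mb contacts rising through S phase, a 2-12 Mb
# "mitotic" band dominating pre/post-mitotic cells), bin-wise S-phase copy
# number ramping 1 -> 2 with bin-specific timing regimes, A/B-compartment-
# biased contact partners (with an extra-strong, funnel-bearing
# erythrocyte-like type), trans-contact rates, tissue occupancy tracks,
# metacell expression profiles, and TAD-clustered ATAC peaks.

#' Genome specification for simulation
#'
#' Bins are tiered per cell type into four coverage/timing classes
#' (strong-A, weak-A, weak-B, strong-B) with base coverage weights and
#' replication regimes; a configurable fraction of bins is flipped per type
#' (type-specific compartments) and a second fraction carries type-specific
#' early replication timing (differential regimes).
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param bin_width bin width (bp).
#' @param cell_types character vector of cell-type names; the first name
#'   matching "pEry" (case-insensitive) gets the strong-compartment,
#'   funnel-bearing profile.
#' @param L number of replication regimes.
#' @param frac_flip fraction of bins with type-specific compartment flips.
#' @param frac_diff_regime fraction of bins with type-specific early timing.
#' @param n_funnels number of funnel anchors planted for the
#'   erythrocyte-like type.
#' @param seed RNG seed.
#' @return list with bins, per-type compartment labels, weights, regimes,
#'   funnel anchors, and a per-bin compartment-bias multiplier (anchors get
#'   a sharper compartment identity than the type-level bias); class
#'   "genome_spec".
#' @export
genome_spec <- function(chrom_sizes = c(chr1 = 100e6, chr2 = 100e6),
                        bin_width = 200e3,
                        cell_types = c("embryo", "esc", "pEry"),
                        L = 12L, frac_flip = 0.08, frac_diff_regime = 0.05,
                        flip_weight_mult = 2, n_signature = 80L,
                        sig_weight_mult = 1.5, n_funnels = 8L, seed = 1L) {
  set.seed(seed)
  bins <- make_bins(chrom_sizes, bin_width)
  J <- nrow(bins)
  # tiers in contiguous blocks of ~10 bins so compartments are blocky
  block <- 10L
  n_blocks <- ceiling(J / block)
  tier_of_block <- sample(rep_len(1:4, n_blocks))
  tier <- rep(tier_of_block, each = block)[seq_len(J)]
  tier_weight <- c(2.3, 1.25, 0.30, 0.50)
  # regime ranges separated so the earliest tier is fully replicated well
  # before mid-S and the two latest tiers do not start within it
  tier_regime <- list(1:2, 4:6, 8:10, 11:12)

  base_regime <- vapply(tier, function(t)
    sample(tier_regime[[t]], 1L), integer(1))
  base_regime <- pmin(base_regime, L)
  base_comp <- ifelse(tier <= 2, "A", "B")
  base_weight <- tier_weight[tier]

  comp <- list(); weight <- list(); regime <- list(); flips <- list()
  diff_bins <- list(); sig_bins <- list()
  for (ty in cell_types) {
    cmp <- base_comp; wt <- base_weight; rg <- base_regime
    # compartment flips are drawn from the facultative-late tier: in this
    # type the bin becomes A with doubled weight while keeping its late
    # replication regime. Flips plant type-specific compartment
    # differences; replication-timing differences are planted
    # independently through the differential-regime bins below.
    n_flip <- round(frac_flip * J)
    fl <- sample(which(tier == 3L), min(n_flip, sum(tier == 3L)))
    cmp[fl] <- "A"; wt[fl] <- wt[fl] * flip_weight_mult
    # type-signature domains: facultative-tier bins with elevated coverage
    # in this type only (active-domain differences between cell types);
    # drawn from tier 3 (late replication, low weight) so that their
    # cluster placement cannot distort the early/late coverage contrast
    sg <- sample(setdiff(which(tier == 3L), fl),
                 min(n_signature, sum(tier == 3L) - length(fl)))
    wt[sg] <- wt[sg] * sig_weight_mult
    n_diff <- round(frac_diff_regime * J)
    db <- sample(setdiff(seq_len(J), fl), n_diff)
    rg[db] <- 2L   # early in this type; base regime elsewhere is mid/late
    comp[[ty]] <- cmp; weight[[ty]] <- wt; regime[[ty]] <- rg
    flips[[ty]] <- fl; diff_bins[[ty]] <- db; sig_bins[[ty]] <- sg
  }

  ery <- grep("pery", cell_types, ignore.case = TRUE, value = TRUE)
  funnels <- NULL
  anchor_bias_mult <- rep(1, J)
  if (length(ery) && n_funnels > 0) {
    # anchors need >=400 kb flank inside their chromosome, and live inside
    # otherwise-B (late-tier) regions: the funnel is an erythroid-specific
    # A locus within a region that is repressed in every other type
    flank_bins <- ceiling(400e3 / bin_width)
    ok <- bins[, .I[seq_len(.N) > flank_bins + 1 &
                      seq_len(.N) < .N - flank_bins], by = chrom]$V1
    ok <- ok[tier[ok] >= 3L]
    # anchors must not collide with planted flips, signature domains or
    # differential-regime bins of any type: those carry their own planted
    # semantics (A in one type, elevated coverage, early regime) that would
    # contradict the anchor's B-everywhere-but-erythroid identity
    ok <- setdiff(ok, unique(c(unlist(flips), unlist(sig_bins),
                               unlist(diff_bins))))
    anchors <- sample(ok, n_funnels)
    funnels <- data.table(bin_id = bins$bin_id[anchors],
                          chrom = bins$chrom[anchors],
                          pos = floor((bins$start[anchors] + bins$end[anchors]) / 2),
                          cell_type = ery[1])
    # a funnel anchor is a strongly A, early locus in the erythroid type
    # and a firmly repressed B locus in every other type; its compartment
    # identity is sharper than the type-level contact bias (see
    # anchor_bias_mult in the contact samplers), so the anchors are
    # genuinely differential between the erythroid type and the rest
    comp[[ery[1]]][anchors] <- "A"
    weight[[ery[1]]][anchors] <- 2.3
    regime[[ery[1]]][anchors] <- 1L
    for (ty in setdiff(cell_types, ery[1])) comp[[ty]][anchors] <- "B"
    anchor_bias_mult[anchors] <- 6
  }

  structure(list(chrom_sizes = chrom_sizes, bin_width = bin_width,
                 bins = bins, cell_types = cell_types, L = L,
                 tier = tier,
                 compartment = comp, weight = weight, regime = regime,
                 flipped_bins = flips, diff_regime_bins = diff_bins,
                 signature_bins = sig_bins,
                 funnel_anchors = funnels,
                 anchor_bias_mult = anchor_bias_mult),
            class = "genome_spec")
}

#' Simulation parameters
#'
#' Distance-band weights are per cell-cycle phase over three cis bands
#' (<2 Mb, 2-12 Mb "mitotic", >12 Mb). Compartment bias is the
#' acceptance-rejection odds favouring same-compartment partners; the
#' erythrocyte-like type defaults to 3x the embryo strength.
#'
#' @param band_weights named list phase -> length-3 numeric weights.
#' @param comp_bias named numeric, same-compartment odds per cell type
#'   (unlisted types fall back to \code{comp_bias[["default"]]}).
#' @param trans_rate default trans-contact fraction.
#' @param funnel_rate fraction of an anchor-bearing cell's contacts emitted
#'   per funnel anchor.
#' @param near_s_slope increase of the short-band weight per unit s.
#' @param tier_jitter_sd per-tier standard deviations of the per-cell
#'   coverage jitter: each cell multiplies the weights of every coverage
#'   tier by its own lognormal factor exp(eta_t), eta_t ~ N(0,
#'   tier_jitter_sd[t]). The extreme tiers are constitutive (small sd)
#'   while the middle tiers are facultative (large sd), emulating the
#'   stable extreme early/late replication domains versus variable
#'   intermediate domains seen across single cells.
#' @return list of parameters; class "sim_config".
#' @export
sim_config <- function(band_weights = list(
                         "post-M" = c(0.25, 0.65, 0.10),
                         "G1"      = c(0.40, 0.25, 0.35),
                         "early-S" = c(0.55, 0.15, 0.30),
                         "mid-S"   = c(0.55, 0.12, 0.33),
                         "pre-M"   = c(0.10, 0.80, 0.10)),
                       comp_bias = c(default = 1.8, esc = 2.8, pEry = 5.4),
                       trans_rate = 0.10,
                       funnel_rate = 0.004,
                       near_s_slope = 0.20,
                       tier_jitter_sd = c(0.08, 0.18, 0.08, 0.06),
                       late_jitter_sd = 0.12) {
  list(band_weights = band_weights, comp_bias = comp_bias,
       trans_rate = trans_rate, funnel_rate = funnel_rate,
       near_s_slope = near_s_slope, tier_jitter_sd = tier_jitter_sd,
       late_jitter_sd = late_jitter_sd)
}

#' Build a cohort of cell specifications
#'
#' Phases are assigned in the given proportions; s_true is 1 for post-M/G1,
#' 2 for pre-M, and uniform in phase-specific S ranges (early-S in
#' (1.005, 1.03), mid-S in (1.32, 1.60)) so that the early/late coverage
#' ratio separates the phases.
#'
#' @param n_per_type named integer vector, cells per type.
#' @param phase_props named numeric, proportions per phase.
#' @param n_contacts contacts per cell (single value or per-type named).
#' @param trans_rate trans fraction (scalar or per-type named).
#' @param seed RNG seed.
#' @return data.table of cell specifications.
#' @export
make_cells <- function(n_per_type = c(embryo = 120, esc = 60, pEry = 40),
                       phase_props = c("post-M" = 0.05, "G1" = 0.25,
                                       "early-S" = 0.15, "mid-S" = 0.45,
                                       "pre-M" = 0.10),
                       n_contacts = 6000, trans_rate = 0.10, seed = 1L) {
  set.seed(seed)
  out <- list()
  for (ty in names(n_per_type)) {
    n <- n_per_type[[ty]]
    ph <- sample(names(phase_props), n, replace = TRUE, prob = phase_props)
    s <- numeric(n)
    s[ph %in% c("post-M", "G1")] <- 1
    s[ph == "pre-M"] <- 2
    s[ph == "early-S"] <- runif(sum(ph == "early-S"), 1.005, 1.03)
    s[ph == "mid-S"] <- runif(sum(ph == "mid-S"), 1.32, 1.60)
    nc <- if (!is.null(names(n_contacts))) n_contacts[[ty]] else n_contacts
    tr <- if (!is.null(names(trans_rate))) trans_rate[[ty]] else trans_rate
    out[[ty]] <- data.table(
      cell_id = sprintf("%s_%03d", ty, seq_len(n)), cell_type = ty,
      phase = ph, s_true = s, n_contacts = nc, trans_rate = tr)
  }
  data.table::rbindlist(out)
}

#' Piecewise-linear replication copy number
#'
#' Regime l replicates linearly over s in [1+(l-1)/L, 1+l/L]: copy number is
#' 1 before the window, 2 after, linear inside.
#'
#' @param s S-phase coordinate(s) in [1,2].
#' @param l regime(s) in 1..L (recycled against s).
#' @param L number of regimes.
#' @return copy number in [1,2].
#' @export
copy_number <- function(s, l, L = 12L) {
  lo <- 1 + (l - 1) / L
  pmin(2, pmax(1, 1 + (s - lo) * L))
}

# sample cis partner positions with compartment bias and copy-number
# acceptance; vectorized with resampling rounds
.sim_cis <- function(n, s, genome, type, params, band_w,
                     eta = numeric(4)) {
  bins <- genome$bins
  comp <- genome$compartment[[type]]
  wbase <- genome$weight[[type]] * exp(eta[genome$tier])
  wt <- wbase * copy_number(s, genome$regime[[type]], genome$L)
  bias <- params$comp_bias
  strength <- if (type %in% names(bias)) bias[[type]] else bias[["default"]]
  # per-bin bias multiplier: funnel anchors hold their compartment identity
  # more strongly than the type-level bias, at whichever end of the
  # contact they appear
  abm <- genome$anchor_bias_mult
  if (is.null(abm)) abm <- rep(1, nrow(bins))

  band <- sample.int(3L, n, replace = TRUE, prob = band_w)
  b1 <- sample.int(nrow(bins), n, replace = TRUE, prob = wt)
  pos1 <- floor(bins$start[b1] + runif(n) * (bins$end[b1] - bins$start[b1]))
  chrom <- bins$chrom[b1]
  chrlen <- genome$chrom_sizes[chrom]
  lo <- c(1e3, 2e6, 1.2e7)[band]
  hi <- pmin(c(2e6, 1.2e7, 4e7)[band], chrlen / 2)

  pos2 <- rep(NA_real_, n)
  todo <- seq_len(n)
  # acceptance normalized to the best achievable value at this s so that
  # rejection sampling stays efficient without flattening the relative bias
  cmax <- max(copy_number(s, genome$regime[[type]], genome$L))
  for (round in 1:15) {
    if (!length(todo)) break
    d <- 10^runif(length(todo), log10(lo[todo]), log10(hi[todo]))
    sgn <- sample(c(-1, 1), length(todo), replace = TRUE)
    p2 <- pos1[todo] + sgn * d
    out <- p2 < 0 | p2 >= chrlen[todo]
    p2[out] <- pos1[todo][out] - (sgn * d)[out]
    p2 <- pmin(pmax(p2, 0), chrlen[todo] - 1)
    b2 <- assign_bin(chrom[todo], p2, bins)
    c2 <- copy_number(s, genome$regime[[type]][b2], genome$L)
    same <- comp[b1[todo]] == comp[b2]
    w2 <- wbase[b2] / max(wbase)
    p_acc <- ifelse(same, 1, 1 / (strength * pmax(abm[b1[todo]], abm[b2]))) *
      (c2 / cmax) * w2
    acc <- runif(length(todo)) < p_acc
    pos2[todo[acc]] <- p2[acc]
    todo <- todo[!acc]
  }
  # the few pairs never accepted are dropped rather than force-accepted,
  # which would dilute the planted coverage/compartment structure
  keep <- !is.na(pos2)
  data.table(chr1 = chrom[keep], pos1 = as.integer(pos1[keep]),
             chr2 = chrom[keep], pos2 = as.integer(round(pos2[keep])))
}

.sim_trans <- function(n, s, genome, type, params, eta = numeric(4)) {
  if (n == 0) return(NULL)
  bins <- genome$bins
  comp <- genome$compartment[[type]]
  wt <- genome$weight[[type]] * exp(eta[genome$tier]) *
    copy_number(s, genome$regime[[type]], genome$L)
  bias <- params$comp_bias
  strength <- if (type %in% names(bias)) bias[[type]] else bias[["default"]]
  abm <- genome$anchor_bias_mult
  if (is.null(abm)) abm <- rep(1, nrow(bins))
  b1 <- sample.int(nrow(bins), n, replace = TRUE, prob = wt)
  b2 <- rep(NA_integer_, n)
  todo <- seq_len(n)
  for (round in 1:15) {
    if (!length(todo)) break
    cand <- sample.int(nrow(bins), length(todo), replace = TRUE, prob = wt)
    ok_chrom <- bins$chrom[cand] != bins$chrom[b1[todo]]
    same <- comp[b1[todo]] == comp[cand]
    p_acc <- ifelse(same, 1, 1 / (strength * pmax(abm[b1[todo]], abm[cand])))
    acc <- ok_chrom & runif(length(todo)) < p_acc
    b2[todo[acc]] <- cand[acc]
    todo <- todo[!acc]
  }
  drop <- is.na(b2)
  if (any(drop)) { b1 <- b1[!drop]; b2 <- b2[!drop] }
  u1 <- runif(length(b1)); u2 <- runif(length(b2))
  data.table(
    chr1 = bins$chrom[b1],
    pos1 = as.integer(floor(bins$start[b1] + u1 * (bins$end[b1] - bins$start[b1]))),
    chr2 = bins$chrom[b2],
    pos2 = as.integer(floor(bins$start[b2] + u2 * (bins$end[b2] - bins$start[b2]))))
}

#' Simulate a scHi-C cohort with planted ground truth
#'
#' @param genome a [genome_spec()].
#' @param cells a cell table from [make_cells()].
#' @param params a [sim_config()].
#' @param seed RNG seed; the same seed reproduces the cohort exactly.
#' @return list with \code{contacts} (canonical contact table) and
#'   \code{truth} (cells, per-type bin annotations, funnel anchors).
#' @export
simulate_cohort <- function(genome, cells, params = sim_config(), seed = 1L) {
  stopifnot(inherits(genome, "genome_spec"))
  cells <- as.data.table(cells)
  bad <- setdiff(cells$cell_type, genome$cell_types)
  if (length(bad)) stop("unknown cell type(s): ", paste(bad, collapse = ", "))
  max_band <- max(vapply(genome$chrom_sizes, function(x) x / 2, 0))
  if (max_band < 2e6) stop("chromosomes too short for the mitotic band")
  set.seed(seed)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cs <- cells[i]
    bw <- params$band_weights[[cs$phase]]
    if (cs$phase %in% c("early-S", "mid-S")) {
      bw[1] <- bw[1] + params$near_s_slope * (cs$s_true - 1)
    }
    bw <- bw / sum(bw)
    n_tr <- rbinom(1, cs$n_contacts, cs$trans_rate)
    n_cis <- cs$n_contacts - n_tr
    # funnel contacts for anchor-bearing types
    fun <- NULL
    fa <- genome$funnel_anchors
    if (!is.null(fa) && cs$cell_type %in% fa$cell_type) {
      n_fun_tot <- 0L
      pieces <- list()
      for (a in seq_len(nrow(fa))) {
        n_f <- rbinom(1, n_cis, params$funnel_rate)
        if (n_f == 0) next
        p2 <- fa$pos[a] + as.integer(round(runif(n_f, -400e3, 400e3)))
        pieces[[length(pieces) + 1]] <- data.table(
          chr1 = fa$chrom[a],
          pos1 = as.integer(fa$pos[a] + round(runif(n_f, -5e3, 5e3))),
          chr2 = fa$chrom[a], pos2 = p2)
        n_fun_tot <- n_fun_tot + n_f
      }
      if (length(pieces)) fun <- data.table::rbindlist(pieces)
      n_cis <- max(0L, n_cis - n_fun_tot)
    }
    eta <- rnorm(4, 0, params$tier_jitter_sd)
    # shared late-domain factor binds the two late tiers' covariation
    eta[3:4] <- eta[3:4] + rnorm(1, 0, params$late_jitter_sd)
    cis <- .sim_cis(n_cis, cs$s_true, genome, cs$cell_type, params, bw, eta)
    tr <- .sim_trans(n_tr, cs$s_true, genome, cs$cell_type, params, eta)
    ctc <- data.table::rbindlist(list(cis, tr, fun), use.names = TRUE)
    ctc[, cell := cs$cell_id]
    out[[i]] <- ctc
  }
  ct <- data.table::rbindlist(out)
  data.table::setcolorder(ct, c("cell", "chr1", "pos1", "chr2", "pos2"))
  ct <- canonicalize_contacts(ct, names(genome$chrom_sizes))
  bins_truth <- data.table::copy(genome$bins)
  for (ty in genome$cell_types) {
    bins_truth[[paste0("comp_", ty)]] <- genome$compartment[[ty]]
    bins_truth[[paste0("regime_", ty)]] <- genome$regime[[ty]]
  }
  list(contacts = ct,
       truth = list(cells = cells, bins = bins_truth,
                    funnel_anchors = genome$funnel_anchors))
}

#' Simulate tissue occupancy tracks with planted peaks
#'
#' Generates per-tissue occupancy at 20 bp resolution over a region, with a
#' heavy-tailed (gamma) background and planted elements whose coverage is
#' drawn from a high quantile of the background.
#'
#' @param region list(chrom, start, end).
#' @param tissues character vector of track names.
#' @param planted data.table with columns start, end, tissue ("all" for
#'   shared elements), class (free-form, e.g. "enhancer", "k27"); may be NULL.
#' @param enrichment multiple of the background 99.9th percentile given to
#'   planted elements.
#' @param step track resolution (bp).
#' @param seed RNG seed.
#' @return list with \code{tracks} (named list of numeric coverage vectors),
#'   \code{starts} (bin start coordinates) and \code{planted}.
#' @export
simulate_tracks <- function(region = list(chrom = "chr1", start = 0, end = 2e6),
                            tissues = c("ecto", "meso"),
                            planted = NULL, enrichment = 3, step = 20L,
                            seed = 1L) {
  set.seed(seed)
  starts <- seq(region$start, region$end - step, by = step)
  nb <- length(starts)
  if (!is.null(planted)) {
    planted <- as.data.table(planted)
    if (nrow(planted) > 1) {
      po <- planted[order(start)]
      ov <- which(po$start[-1] < po$end[-nrow(po)])
      if (length(ov) && any(po$class[ov] != po$class[ov + 1])) {
        stop("overlapping planted elements of conflicting class")
      }
    }
  }
  tracks <- list()
  for (ti in tissues) {
    cov <- rgamma(nb, shape = 0.8, scale = 5)
    if (!is.null(planted)) {
      sel <- planted[planted$tissue %in% c(ti, "all")]
      hi <- quantile(cov, 0.999) * enrichment
      for (r in seq_len(nrow(sel))) {
        idx <- which(starts >= sel$start[r] & starts < sel$end[r])
        cov[idx] <- hi * runif(length(idx), 0.8, 1.2)
      }
    }
    tracks[[ti]] <- cov
  }
  list(tracks = tracks, starts = starts, step = step, region = region,
       planted = planted)
}

#' Simulate metacell expression profiles and clustered ATAC peaks
#'
#' Expression: genes x metacells UMI-fraction profiles with planted
#' cell-type-enriched modules. ATAC: peaks x metacell-cluster count matrix
#' organized in planted peak clusters; peaks of a cluster pair flagged
#' "co-TAD" are placed inside shared TADs so their within-200 kb pair count
#' is enriched.
#'
#' @param genome a [genome_spec()] (TSSs and TADs are laid on its bins).
#' @param metacell_types named integer, metacells per type.
#' @param n_genes total genes; module_size genes per planted module.
#' @param n_peaks,n_peak_clusters ATAC peaks and planted clusters.
#' @param seed RNG seed.
#' @return list with expression matrix, tss table, atac counts, peak table
#'   (with planted cluster), tads, and planted module table.
#' @export
simulate_expression_and_atac <- function(genome,
                                         metacell_types = c(embryo = 6, esc = 4, pEry = 3),
                                         n_genes = 400, module_size = 25,
                                         n_peaks = 600, n_peak_clusters = 6,
                                         seed = 1L) {
  set.seed(seed)
  bins <- genome$bins
  gene <- sprintf("g%04d", seq_len(n_genes))
  tss_bin <- sample(bins$bin_id, n_genes, replace = TRUE)
  tss <- data.table(gene = gene, chrom = bins$chrom[tss_bin],
                    pos = floor((bins$start[tss_bin] + bins$end[tss_bin]) / 2),
                    bin_id = tss_bin)
  mcs <- unlist(lapply(names(metacell_types), function(ty)
    sprintf("%s_mc%02d", ty, seq_len(metacell_types[[ty]]))))
  mc_type <- rep(names(metacell_types), metacell_types)
  expr <- matrix(rgamma(n_genes * length(mcs), 2, 2), n_genes,
                 dimnames = list(gene, mcs))
  modules <- list()
  gi <- 1
  for (ty in names(metacell_types)) {
    mod <- gene[gi:(gi + module_size - 1)]
    expr[mod, mc_type == ty] <- expr[mod, mc_type == ty] * 8
    modules[[ty]] <- mod
    gi <- gi + module_size
  }
  expr <- sweep(expr, 2, colSums(expr), "/")  # UMI fractions

  # TADs: contiguous runs of 5 bins
  tad_size <- 5L
  tads <- bins[, .(start = start[seq(1, .N, by = tad_size)],
                   end = end[pmin(seq(1, .N, by = tad_size) + tad_size - 1, .N)]),
               by = chrom]
  tads[, tad_id := seq_len(.N)]

  # ATAC peaks: clusters 1..n; clusters 1 and 2 are "co-TAD" (share TADs)
  n_cl <- n_peak_clusters
  cl <- sort(rep_len(seq_len(n_cl), n_peaks))
  shared_tads <- sample(tads$tad_id, max(4, round(nrow(tads) * 0.05)))
  peak_tad <- integer(n_peaks)
  for (k in seq_len(n_cl)) {
    idx <- which(cl == k)
    peak_tad[idx] <- if (k <= 2) sample(shared_tads, length(idx), TRUE)
                     else sample(setdiff(tads$tad_id, shared_tads), length(idx), TRUE)
  }
  tpos <- tads[match(peak_tad, tad_id)]
  ppos <- floor(tpos$start + runif(n_peaks) * (tpos$end - tpos$start - 300))
  peaks <- data.table(peak = sprintf("p%04d", seq_len(n_peaks)),
                      chrom = tpos$chrom, start = ppos, end = ppos + 300L,
                      cluster_true = cl, tad_id = peak_tad)
  # accessibility: cluster-specific profiles over metacell clusters
  n_mc_cl <- length(mcs)
  prof <- matrix(rnorm(n_cl * n_mc_cl, 0, 0.3), n_cl)
  hot <- cbind(seq_len(n_cl), sample(n_mc_cl, n_cl, replace = TRUE))
  prof[hot] <- prof[hot] + 2.5
  atac <- matrix(rpois(n_peaks * n_mc_cl,
                       lambda = exp(1.5 + prof[cl, , drop = FALSE])),
                 n_peaks, dimnames = list(peaks$peak, mcs))
  list(expression = expr, tss = tss, metacell_type = setNames(mc_type, mcs),
       atac = atac, peaks = peaks, tads = tads, modules = modules)
}

#' Simulate counts from the replication mixture model
#'
#' Draws cells x bins contact counts directly from the generative model of
#' [repmix_fit()]: multinomial over bins with probabilities proportional to
#' a background rate times the copy number of the bin's regime at the cell's
#' S-phase coordinate. A fraction of bins is differentially timed (early in
#' exactly one cluster).
#'
#' @param n_cells_per_cluster integer vector of cluster sizes.
#' @param n_bins number of genomic bins.
#' @param L regimes; \code{frac_diff} fraction of differential bins.
#' @param n_per_cell contacts per cell.
#' @param s_range range of the true s-score (uniform).
#' @param seed RNG seed.
#' @return list with counts n, background p, true clusters, s_true, regimes.
#' @export
simulate_repmix_counts <- function(n_cells_per_cluster = c(150, 100, 50),
                                   n_bins = 1000, L = 12L, frac_diff = 0.05,
                                   n_per_cell = 10000,
                                   s_range = c(1.2, 1.8), seed = 1L) {
  set.seed(seed)
  K <- length(n_cells_per_cluster)
  n_cells <- sum(n_cells_per_cluster)
  k_true <- rep(seq_len(K), n_cells_per_cluster)
  s_true <- runif(n_cells, s_range[1], s_range[2])
  base <- sample.int(L, n_bins, replace = TRUE)
  # background coverage correlates with replication timing (early bins are
  # more covered), as observed in real maps; this also lets the model's
  # default initialization orient its cell ordering
  p <- rgamma(n_bins, 8, 8) * (1.6 - 0.9 * (base - 1) / (L - 1))
  p <- p / sum(p)
  r <- matrix(rep(base, each = K), K, n_bins)
  n_diff <- round(frac_diff * n_bins)
  db <- sample(n_bins, n_diff)
  owner <- rep_len(seq_len(K), n_diff)
  # differential bins: early (regime 2) in their owner cluster, clearly late
  # in all other clusters
  for (j in seq_len(n_diff)) {
    r[owner[j], db[j]] <- 2L
    others <- setdiff(seq_len(K), owner[j])
    r[others, db[j]] <- sample(8:L, length(others), replace = TRUE)
  }
  n <- matrix(0L, n_cells, n_bins,
              dimnames = list(sprintf("c%04d", seq_len(n_cells)), NULL))
  for (i in seq_len(n_cells)) {
    q <- p * copy_number(s_true[i], r[k_true[i], ], L)
    n[i, ] <- as.integer(stats::rmultinom(1, n_per_cell, q))
  }
  list(n = n, p = p, k_true = k_true, s_true = s_true, r_true = r,
       diff_bins = db, diff_owner = owner, L = L)
}
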