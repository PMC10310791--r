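# End-to-end orchestration: configuration, staged execution with
# provenance-stamped reports.

#' Pipeline configuration
#'
#' All thresholds default to the values used throughout the analysis:
#' 75k-contact downsampling, el > 1.8 mid-S classification, mixture model
#' L = 12 / R = 11 / lambda = 40, A-score difference thresholds 0.2 / 0.35,
#' contact-score margins 15 / 40 / 50, enhancer calling 7 / 9 / 3,
#' promoter pairing 50-500 kb, ATAC 300 / -16 / 0.7 / K = 120, proximity
#' 200 kb. Every value is configurable; none is hard-coded downstream.
#'
#' @param ... overrides of the defaults.
#' @return a named list of class "run_config".
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    outdir = NULL,
    # synthetic cohort (used when no contacts are supplied)
    sim = list(n_per_type = c(embryo = 90, esc = 45, pEry = 35),
               n_contacts = 20000, bin_width_coverage = 200e3),
    downsample_target = 75000, downsample_enabled = FALSE,
    qc = qc_config(min_contacts = 1000),
    el_threshold = 1.8,
    k_seeds = 3L, n_bin_clusters = 11L,
    repmix = list(K = 2L, L = 12L, R = 11L, lambda = 40),
    shaman = list(sweeps = 20L, k = 50L, max_pool = 150000L),
    a_specific_delta = 0.2, funnel_delta = 0.35,
    support_margin = 15, hotspot_threshold = 40, diff_threshold = 50,
    enhancer = list(call = 7, min = 9, diff = 3),
    pairing_window = c(5e4, 5e5),
    atac = list(min_total = 300, var_low = -16, var_range = 0.7, K = 120L),
    proximity_max_dist = 2e5,
    stages = c(simulate = TRUE, qc = TRUE, phase = TRUE, scores = TRUE,
               seeding = TRUE, repmix = TRUE, shaman = TRUE,
               features = TRUE))
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  class(cfg) <- "run_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg a [run_config()].
#' @return invisibly TRUE; stops with an informative error when invalid.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (cfg$repmix$lambda < 0) stop("lambda must be non-negative")
  if (cfg$repmix$L < 1 || cfg$repmix$R < 2) stop("invalid L or R")
  if (cfg$downsample_target <= 0) stop("downsample target must be positive")
  if (cfg$el_threshold <= 0) stop("el threshold must be positive")
  if (cfg$pairing_window[1] >= cfg$pairing_window[2])
    stop("pairing window must be an increasing range")
  invisible(TRUE)
}

# config hash for provenance stamping (md5 of the deparsed config)
.config_hash <- function(cfg) {
  tf <- tempfile()
  writeLines(deparse(cfg[setdiff(names(cfg), "outdir")]), tf)
  h <- unname(tools::md5sum(tf))
  unlink(tf)
  h
}

.stamp <- function(path, cfg, stage, counts = NULL) {
  lines <- c(sprintf("# stage: %s", stage),
             sprintf("# config_hash: %s", .config_hash(cfg)),
             sprintf("# seed: %d", cfg$seed))
  if (!is.null(counts)) {
    lines <- c(lines, sprintf("# %s: %s", names(counts), counts))
  }
  writeLines(lines, path)
  invisible(path)
}

.write_report <- function(dt, path, cfg, stage, counts = NULL) {
  .stamp(path, cfg, stage, counts)
  suppressWarnings(write.table(dt, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Run the staged pipeline on a contact cohort
#'
#' Executes qc -> phasing -> strict reference sets -> A/early scores ->
#' S-phase seeding -> replication mixture model -> contact shuffling and
#' scoring -> locus features, writing a provenance-stamped TSV report per
#' stage into \code{cfg$outdir}. When no contacts are supplied the bundled
#' synthetic cohort generator provides them (stage "simulate").
#'
#' @param cfg a [run_config()] (with \code{outdir} set).
#' @param contacts optional contact data.table; if NULL the synthetic
#'   generator runs with \code{cfg$sim} and \code{cfg$seed}.
#' @param genome optional [genome_spec()] matching the contacts.
#' @return invisibly, a list with the main intermediate objects.
#' @export
run_pipeline <- function(cfg = run_config(), contacts = NULL, genome = NULL) {
  validate_config(cfg)
  if (is.null(cfg$outdir)) stop("cfg$outdir must be set")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config_hash = .config_hash(cfg))

  if (is.null(contacts)) {
    if (!cfg$stages[["simulate"]])
      stop("stage 'qc' needs contacts: supply them or enable the 'simulate' stage")
    if (is.null(genome)) genome <- genome_spec(seed = cfg$seed)
    cells <- make_cells(n_per_type = cfg$sim$n_per_type,
                        n_contacts = cfg$sim$n_contacts, seed = cfg$seed)
    sim <- simulate_cohort(genome, cells, sim_config(), seed = cfg$seed)
    contacts <- sim$contacts
    res$truth <- sim$truth
    .write_report(sim$truth$cells, file.path(cfg$outdir, "simulate.tsv"),
                  cfg, "simulate",
                  c(n_cells = nrow(cells), n_contacts = nrow(contacts)))
  }
  if (is.null(genome)) stop("genome spec required with user-supplied contacts")
  bins <- genome$bins

  if (!cfg$stages[["qc"]]) stop("the qc stage cannot be skipped")
  qc <- qc_cells(contacts, cfg$qc)
  ct <- contacts[contacts$cell %in% qc$pass]
  if (cfg$downsample_enabled) {
    ct <- downsample_cells(ct, cfg$downsample_target, seed = cfg$seed,
                           drop_below = TRUE)
  }
  .write_report(qc$qc, file.path(cfg$outdir, "qc.tsv"), cfg, "qc",
                c(cells_in = nrow(qc$qc), cells_pass = length(qc$pass)))
  res$qc <- qc

  dsn <- bin_coverage(ct, bins)
  ref <- derive_strict_sets(dsn)
  el <- el_ratio(dsn, ref, cfg$el_threshold)
  feats <- phase_features(ct, ref, bins)
  phases <- classify_phase(feats)
  .write_report(merge(phases, el, by = "cell"),
                file.path(cfg$outdir, "phase.tsv"), cfg, "phase",
                c(mid_s = sum(el$mid_s)))
  res$reference <- ref; res$phases <- phases; res$el <- el; res$dsn <- dsn

  if (!cfg$stages[["scores"]]) {
    warning("stage 'scores' disabled; skipping dependent stages")
    return(invisible(res))
  }
  ab <- ab_contact_counts(ct, bins, ref)
  g1 <- phases$cell[phases$phase == "G1"]
  all_cells <- rownames(dsn)
  scoreA <- a_score(ab$cA, ab$cB, all_cells)
  scoreE <- early_score(dsn, setdiff(all_cells, g1), g1)
  .write_report(data.table(bin_id = bins$bin_id, a_score = scoreA,
                           early_score = scoreE),
                file.path(cfg$outdir, "scores.tsv"), cfg, "scores")
  res$ab <- ab; res$a_score <- scoreA; res$early_score <- scoreE

  if (!cfg$stages[["seeding"]]) {
    warning("stage 'seeding' disabled; skipping dependent stages")
    return(invisible(res))
  }
  midS <- el$cell[el$mid_s]
  g1_mean <- colMeans(dsn[intersect(g1, rownames(dsn)), , drop = FALSE])
  fn <- setNames(phases$frac_near, phases$cell)
  sd_res <- seed_midS_clusters(dsn[midS, , drop = FALSE], g1_mean,
                               fn, cfg$k_seeds)
  a_seed <- sapply(sort(unique(sd_res$seeds)), function(k)
    a_score(ab$cA, ab$cB, names(sd_res$seeds)[sd_res$seeds == k]))
  rownames(a_seed) <- colnames(ab$cA)
  bc <- derive_bin_clusters(a_seed, cfg$n_bin_clusters, seed = cfg$seed)
  cell_A <- cell_ascore_matrix(ab$cA, ab$cB, bc)
  centroids <- do.call(rbind, lapply(sort(unique(sd_res$seeds)), function(k)
    colMeans(cell_A[names(sd_res$seeds)[sd_res$seeds == k], , drop = FALSE],
             na.rm = TRUE)))
  mit <- phases$cell[phases$phase %in% c("pre-M", "post-M")]
  assignment <- assign_cells(cell_A, centroids, mitotic_cells = mit)
  .write_report(data.table(cell = names(assignment), cluster = assignment),
                file.path(cfg$outdir, "seeding.tsv"), cfg, "seeding",
                c(n_clusters = length(unique(stats::na.omit(assignment)))))
  res$seeds <- sd_res$seeds; res$bin_clusters <- bc
  res$cell_A <- cell_A; res$assignment <- assignment

  if (cfg$stages[["repmix"]]) {
    prep <- prepare_repmix_inputs(dsn, bins, midS, g1,
                                  min_mean = 1)
    fit <- repmix_fit(prep$n, prep$p, K = cfg$repmix$K, L = cfg$repmix$L,
                      R = cfg$repmix$R, lambda = cfg$repmix$lambda,
                      init = list(order = fn), seed = cfg$seed)
    .write_report(data.table(cell = names(fit$cluster),
                             cluster = fit$cluster, s = fit$s),
                  file.path(cfg$outdir, "repmix.tsv"), cfg, "repmix",
                  c(K_active = sum(fit$active)))
    res$repmix <- fit
  }

  if (cfg$stages[["shaman"]]) {
    pools <- pool_and_downsample(ct, assignment, seed = cfg$seed)
    # cap the scored pool size: KNN scoring cost grows superlinearly with
    # pool size, and enrichment scores are relative within a pool
    mp <- cfg$shaman$max_pool
    if (!is.null(mp) && is.finite(mp)) {
      set.seed(cfg$seed)
      pools <- lapply(pools, function(p)
        if (nrow(p) > mp) p[sample(nrow(p), mp)] else p)
    }
    scored <- lapply(pools, function(p) {
      sh <- shaman_shuffle(p, sweeps = cfg$shaman$sweeps, seed = cfg$seed)
      shaman_score(p, sh, k = cfg$shaman$k)
    })
    for (nm in names(scored)) {
      .write_report(scored[[nm]],
                    file.path(cfg$outdir, sprintf("shaman_%s.tsv", nm)),
                    cfg, "shaman", c(pool_size = nrow(scored[[nm]])))
    }
    res$scored <- scored
  }

  if (cfg$stages[["features"]] && !is.null(res$scored) &&
      length(res$scored) >= 1) {
    pool1 <- res$scored[[1]]
    ch <- names(genome$chrom_sizes)[1]
    ins <- insulation(pool1, ch, genome$chrom_sizes[[1]])
    .write_report(ins, file.path(cfg$outdir, "insulation.tsv"), cfg,
                  "features")
    res$insulation <- ins
  }
  invisible(res)
}
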