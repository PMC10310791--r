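# Synthetic cohort generator: planted structure, determinism, marginals.

test_that("copy_number is the piecewise-linear ramp", {
  L <- 12L
  # regime l replicates over [1+(l-1)/L, 1+l/L]
  expect_equal(copy_number(1, 1, L), 1)
  expect_equal(copy_number(2, 12, L), 2)
  expect_equal(copy_number(1 + 0.5 / L, 1, L), 1.5)
  expect_equal(copy_number(1 + 1 / L, 1, L), 2)     # just finished
  expect_equal(copy_number(1 + 1 / L, 2, L), 1)     # just starting
  expect_equal(copy_number(1.5, 6, L), 1 + (1.5 - (1 + 5 / 12)) * 12)
  # recycling over vector l
  expect_equal(copy_number(1.5, c(1, 12), L), c(2, 1))
})

test_that("genome_spec plants tiers, flips, signatures and funnels", {
  g <- genome_spec(seed = 3)
  J <- nrow(g$bins)
  expect_s3_class(g$bins, "data.table")
  expect_equal(sort(unique(g$tier)), 1:4)
  for (ty in g$cell_types) {
    expect_equal(length(g$compartment[[ty]]), J)
    # base rule: tiers 1-2 are A, 3-4 B, except flipped / funnel bins
    fl <- g$flipped_bins[[ty]]
    expect_true(all(g$tier[fl] == 3L))
    expect_true(all(g$compartment[[ty]][fl] == "A"))
    # flips change compartment and weight but keep their tier's late
    # replication regime (diff-regime bins and funnel anchors are drawn
    # to exclude flips), so strict-set derivation stays consistent
    expect_true(all(g$regime[[ty]][fl] %in% 8:10))
    # differential-regime bins are early (regime 2) in this type
    expect_true(all(g$regime[[ty]][g$diff_regime_bins[[ty]]] == 2L))
    # signature bins live in tier 3 and do not overlap flips
    sg <- g$signature_bins[[ty]]
    expect_true(all(g$tier[sg] == 3L))
    expect_length(intersect(sg, fl), 0)
  }
  # funnel anchors: erythroid-only, strong-A, earliest regime, with flank
  fa <- g$funnel_anchors
  expect_equal(nrow(fa), 8L)
  expect_true(all(fa$cell_type == "pEry"))
  idx <- match(fa$bin_id, g$bins$bin_id)
  expect_true(all(g$compartment$pEry[idx] == "A"))
  expect_true(all(g$regime$pEry[idx] == 1L))
  expect_true(all(fa$pos - 4e5 >= 0))
  expect_true(all(fa$pos + 4e5 <= g$chrom_sizes[fa$chrom]))
  # deterministic given the seed
  expect_equal(genome_spec(seed = 3)$regime, g$regime)
})

test_that("make_cells draws phases and s ranges as documented", {
  cells <- make_cells(n_per_type = c(embryo = 300, esc = 100, pEry = 50),
                      seed = 2)
  expect_equal(nrow(cells), 450L)
  expect_true(all(cells$s_true[cells$phase %in% c("post-M", "G1")] == 1))
  expect_true(all(cells$s_true[cells$phase == "pre-M"] == 2))
  es <- cells$s_true[cells$phase == "early-S"]
  ms <- cells$s_true[cells$phase == "mid-S"]
  expect_true(all(es > 1 & es < 1.05))
  expect_true(all(ms >= 1.32 & ms <= 1.60))
  # mid-S is the most common phase under the default proportions
  expect_equal(names(which.max(table(cells$phase))), "mid-S")
  expect_equal(make_cells(seed = 2)$phase, make_cells(seed = 2)$phase)
})

test_that("simulate_cohort emits canonical contacts with planted marginals", {
  g <- genome_spec(chrom_sizes = c(chr1 = 50e6, chr2 = 50e6), seed = 1)
  cells <- make_cells(n_per_type = c(embryo = 4, esc = 2, pEry = 2),
                      phase_props = c("G1" = 0.5, "pre-M" = 0.25,
                                      "mid-S" = 0.25),
                      n_contacts = 3000, seed = 5)
  sim <- simulate_cohort(g, cells, seed = 9)
  ct <- sim$contacts
  expect_setequal(unique(ct$cell), cells$cell_id)
  # canonical: no record with (chr2, pos2) before (chr1, pos1)
  o1 <- match(ct$chr1, names(g$chrom_sizes))
  o2 <- match(ct$chr2, names(g$chrom_sizes))
  expect_true(all(o1 < o2 | (o1 == o2 & ct$pos1 <= ct$pos2)))
  # per-cell counts close to the request (rejection drops a few pairs)
  nn <- table(ct$cell)
  expect_true(all(nn <= 3000 & nn > 2000))
  # trans fraction near the configured 10% (absolute band: rejection
  # drops shift the realized rate slightly in both directions)
  expect_lt(abs(mean(ct$chr1 != ct$chr2) - 0.10), 0.035)
  # pre-M cells dominated by the 2-12 Mb band; G1 cells are not
  d <- contact_distance(ct)
  ph <- cells$phase[match(ct$cell, cells$cell_id)]
  band_mit <- !is.na(d) & d >= 2e6 & d < 1.2e7
  expect_gt(mean(band_mit[ph == "pre-M"]), 0.55)
  expect_lt(mean(band_mit[ph == "G1"]), 0.45)
  # identical seed reproduces the cohort exactly
  sim2 <- simulate_cohort(g, cells, seed = 9)
  expect_equal(as.data.frame(sim2$contacts), as.data.frame(ct))
  # unknown cell types are rejected
  bad <- data.table::copy(cells)[1, cell_type := "mystery"]
  expect_error(simulate_cohort(g, bad, seed = 1), "unknown cell type")
})

test_that("planted coverage weights shape the sampled bins", {
  g <- genome_spec(chrom_sizes = c(chr1 = 50e6), seed = 2)
  cells <- make_cells(n_per_type = c(embryo = 6, esc = 0, pEry = 0),
                      phase_props = c("G1" = 1), n_contacts = 5000,
                      trans_rate = 0, seed = 3)
  sim <- simulate_cohort(g, cells[cell_type == "embryo"], seed = 4)
  cov <- bin_coverage(sim$contacts, g$bins)
  mean_cov <- colMeans(cov)
  # strong-A bins (tier 1) accumulate far more coverage than strong-B
  # (tier 4): weight ratio 2.3 / 0.5
  t1 <- mean(mean_cov[g$tier == 1])
  t4 <- mean(mean_cov[g$tier == 4])
  expect_gt(t1 / t4, 2)
})

test_that("funnel anchors receive focal contacts in the erythroid type", {
  g <- genome_spec(seed = 6)
  cells <- make_cells(n_per_type = c(embryo = 2, esc = 0, pEry = 2),
                      phase_props = c("G1" = 1), n_contacts = 20000,
                      seed = 7)
  sim <- simulate_cohort(g, cells, seed = 8)
  ct <- sim$contacts
  near_anchor <- function(cellset) {
    sub <- ct[ct$cell %in% cellset & ct$chr1 == ct$chr2]
    hits <- 0
    for (a in seq_len(nrow(g$funnel_anchors))) {
      fa <- g$funnel_anchors[a]
      hits <- hits + sum(sub$chr1 == fa$chrom &
                           (abs(sub$pos1 - fa$pos) < 6e3 |
                              abs(sub$pos2 - fa$pos) < 6e3))
    }
    hits / nrow(sub)
  }
  ery <- cells$cell_id[cells$cell_type == "pEry"]
  emb <- cells$cell_id[cells$cell_type == "embryo"]
  expect_gt(near_anchor(ery), 4 * near_anchor(emb))
})

test_that("simulate_tracks plants enriched elements and rejects conflicts", {
  planted <- data.table::data.table(
    start = c(1e5, 5e5), end = c(1.01e5, 5.01e5),
    tissue = c("ecto", "all"), class = c("enhancer", "enhancer"))
  tr <- simulate_tracks(planted = planted, seed = 11)
  expect_setequal(names(tr$tracks), c("ecto", "meso"))
  ecto <- tr$tracks$ecto; meso <- tr$tracks$meso
  in_el <- tr$starts >= 1e5 & tr$starts < 1.01e5
  in_shared <- tr$starts >= 5e5 & tr$starts < 5.01e5
  # ecto-only element high in ecto, background-level in meso
  expect_gt(min(ecto[in_el]), quantile(ecto[!in_el & !in_shared], 0.99))
  expect_lt(mean(meso[in_el]), quantile(meso[!in_el & !in_shared], 0.999))
  # shared element high in both
  expect_gt(min(meso[in_shared]), quantile(meso[!in_el & !in_shared], 0.99))
  # conflicting overlap is an error
  bad <- data.table::data.table(start = c(1e5, 1.005e5),
                                end = c(1.01e5, 1.02e5),
                                tissue = "all", class = c("enhancer", "k27"))
  expect_error(simulate_tracks(planted = bad, seed = 1), "conflicting")
})

test_that("simulate_expression_and_atac plants modules and co-TAD clusters", {
  g <- genome_spec(seed = 1)
  ea <- simulate_expression_and_atac(g, seed = 13)
  expect_equal(dim(ea$expression), c(400L, 13L))
  expect_equal(colSums(ea$expression), rep(1, 13), ignore_attr = TRUE,
               tolerance = 1e-12)
  # planted module genes enriched in their own type's metacells
  for (ty in names(ea$modules)) {
    own <- ea$metacell_type == ty
    mod <- ea$modules[[ty]]
    enr <- rowMeans(ea$expression[mod, own, drop = FALSE]) /
      rowMeans(ea$expression[mod, !own, drop = FALSE])
    expect_gt(median(enr), 3)
  }
  # clusters 1 and 2 share TADs; higher clusters do not use those TADs
  pk <- ea$peaks
  shared <- intersect(pk$tad_id[pk$cluster_true == 1],
                      pk$tad_id[pk$cluster_true == 2])
  expect_gt(length(shared), 0)
  expect_length(intersect(pk$tad_id[pk$cluster_true > 2], shared), 0)
  # tss bins are consistent with the bin table
  expect_true(all(ea$tss$bin_id %in% g$bins$bin_id))
})

test_that("simulate_repmix_counts draws from the stated generative model", {
  sim <- simulate_repmix_counts(n_cells_per_cluster = c(30, 20),
                                n_bins = 200, n_per_cell = 5000, seed = 17)
  expect_equal(dim(sim$n), c(50L, 200L))
  expect_true(all(rowSums(sim$n) == 5000))
  expect_equal(sum(sim$p), 1)
  expect_equal(sim$k_true, rep(1:2, c(30, 20)))
  # differential bins: regime 2 in the owner, late (>= 8) elsewhere
  for (j in seq_along(sim$diff_bins)) {
    b <- sim$diff_bins[j]; ow <- sim$diff_owner[j]
    expect_equal(sim$r_true[ow, b], 2L)
    expect_true(all(sim$r_true[-ow, b] >= 8L))
  }
  # expected counts match the multinomial mean for a random cell
  i <- 7
  q <- sim$p * copy_number(sim$s_true[i], sim$r_true[sim$k_true[i], ], sim$L)
  q <- q / sum(q)
  # chi-square-ish sanity: correlation of observed vs expected is high
  expect_gt(cor(as.numeric(sim$n[i, ]), q), 0.9)
  # background correlates negatively with regime (early bins more covered)
  expect_lt(cor(sim$p, sim$r_true[1, ]), -0.2)
})
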