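# plastichic

Cell-cycle-aware analysis of single-cell Hi-C (scHi-C) contact maps.

In proliferating tissues most of the cell-to-cell variation in scHi-C maps
comes from the cell cycle and DNA replication, not from cell identity.
`plastichic` measures that signal, classifies cells by cycle phase,
conditions on it, and only then asks which compartment and locus-level
differences separate cell types. It provides:

- per-cell QC and cell-cycle phasing from contact-distance statistics
  (`qc_cells`, `phase_features`, `classify_phase`)
- strict-early / strict-late reference bin sets derived from coverage
  (`derive_strict_sets`), A-compartment and early-replication scores
  (`a_score`, `early_score`, `el_ratio`)
- S-phase-seeded clustering of cells and centroid expansion
  (`seed_midS_clusters`, `derive_bin_clusters`, `assign_cells`,
  `split_linear`)
- a replication-trend mixture model inferring cell clusters, a latent
  S-progression coordinate and per-bin replication regimes
  (`repmix_fit`, `sensitivity_harness`)
- a degree-preserving MCMC contact shuffler and a k-nearest-neighbour
  enrichment scorer (`shaman_shuffle`, `shaman_score`), plus locus map
  statistics: `insulation`, `virtual_4c`, `v4c_difference`,
  `hotspot_scan`, `funnel_anchors`, `funnel_cluster`, `pooled_locus_map`
- regulatory integration: enhancer/promoter pairing, three-way contact
  support, exact empirical contact tests, ATAC clustering, proximity
  enrichment (`three_way_support`, `empirical_contact_test`,
  `atac_call_and_cluster`, `proximity_enrichment`)
- a staged pipeline writing provenance-stamped reports (`run_pipeline`)
- a synthetic-cohort generator with planted ground truth
  (`genome_spec`, `make_cells`, `simulate_cohort`,
  `simulate_repmix_counts`) so every stage is testable offline

## Worked example

Simulate a small cohort, QC it, and phase the cells:

```r
library(plastichic)
library(data.table)

genome <- genome_spec(seed = 1)
cells  <- make_cells(n_per_type = c(embryo = 40, esc = 20, pEry = 20),
                     n_contacts = 8000, seed = 1)
sim    <- simulate_cohort(genome, cells, sim_config(), seed = 1)
head(sim$contacts, 3)
#>          cell   chr1     pos1   chr2     pos2
#> 1: embryo_001   chr2  9758711   chr2 37829710
#> 2: embryo_001   chr2 12039728   chr2 12051826
#> 3: embryo_001   chr2 80750343   chr2 94777453

qc  <- qc_cells(sim$contacts, qc_config(min_contacts = 1000))
ct  <- sim$contacts[cell %in% qc$pass]      # all 80 cells pass here
dsn <- bin_coverage(ct, genome$bins)
ref <- derive_strict_sets(dsn)
ph  <- classify_phase(phase_features(ct, ref, genome$bins))
table(ph$phase)
#> early-S      G1   mid-S  post-M   pre-M
#>      24      28      15       4       9
```

Fit the replication mixture model on planted copy-number counts
(300 cells in clusters of 150/100/50, 1,000 bins; runs in a few seconds):

```r
simc <- simulate_repmix_counts(c(150, 100, 50), n_bins = 1000, L = 12,
                               frac_diff = 0.05, seed = 1)
fit  <- repmix_fit(simc$n, simc$p, K = 3, L = 12, seed = 1)
fit
#> Replication mixture model: K = 3 active clusters, 1000 bins, L = 12
#> cluster sizes: 49, 101, 150
#> penalized log-likelihood: -20148443
cor(fit$s, simc$s_true, method = "spearman")   # 0.999
# adjusted Rand index vs planted clusters: 0.993
```

Recover the planted erythroid "funnel" anchors — bins that are
A-compartment and early-replicating in pEry but repressed everywhere
else — from per-group A-scores:

```r
tt   <- setNames(sim$truth$cells$cell_type, sim$truth$cells$cell_id)
ab   <- ab_contact_counts(ct, genome$bins, ref)
pres <- rownames(ab$cA)
a_x  <- a_score(ab$cA, ab$cB, intersect(names(tt)[tt == "pEry"], pres))
a_y  <- a_score(ab$cA, ab$cB, intersect(names(tt)[tt == "embryo"], pres))
funnel_anchors(a_x, a_y, genome$bins, delta = 0.35)
#>      chrom    start      end bin_id     delta
#>  1:   chr1 40000000 40200000    201 0.6631258
#>  2:   chr1 62600000 62800000    314 0.8104223
#>  3:   chr1 93600000 93800000    469 0.7685881
#>  4:   chr2 62800000 63000000    815 0.6796992
#>  5:   chr2 83200000 83400000    917 0.6179818
#>  6:   chr2 86200000 86400000    932 0.6549034
#>  ...
genome$funnel_anchors$bin_id
#> [1] 469 470 932 917 201 815 314 931
```

At this shallow depth (20 pEry cells, 8,000 contacts each) six of the
eight planted anchors clear the 0.35 threshold, along with a few
borderline bins; the full-depth cohorts used in the test suite recover
all eight with deltas of 0.56–0.78.

Run the whole staged pipeline; every report carries a provenance stamp
(stage, config hash, seed):

```r
cfg <- run_config(outdir = tempfile("plastichic"), seed = 1,
                  sim = list(n_per_type = c(embryo = 40, esc = 20, pEry = 20),
                             n_contacts = 8000, bin_width_coverage = 200e3))
res <- run_pipeline(cfg)                     # ~2.3 minutes
list.files(cfg$outdir)
#>  [1] "insulation.tsv" "phase.tsv"      "qc.tsv"         "repmix.tsv"
#>  [5] "scores.tsv"     "seeding.tsv"    "shaman_1.tsv"   "shaman_2.tsv"
#>  [9] "shaman_3.tsv"   "simulate.tsv"
readLines(file.path(cfg$outdir, "scores.tsv"), n = 3)
#> [1] "# stage: scores"
#> [2] "# config_hash: 88cc2f1c3cbe7417ca2163542eaac712"
#> [3] "# seed: 1"
```

## Testing

```r
testthat::test_dir("tests/testthat", package = "plastichic",
                   load_package = "installed")
```

The suite checks every operator against independent brute-force oracles
and runs end-to-end recovery scenarios on planted synthetic data
(`tests/testthat/test-acceptance.R`). A standalone report of the main
computed quantities:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

See `vignettes/cellcycle-aware-schic.Rmd` for a walk-through of the full
workflow.
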