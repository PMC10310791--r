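# Insulation, virtual 4C, hotspot scan, funnel anchors, pooled maps, ChIP.

test_that("insulation matches the literal cross/within oracle", {
  set.seed(71)
  n <- 400
  p1 <- sample(1e6, n)
  pool <- canonicalize_contacts(data.table::data.table(
    cell = "p", chr1 = "chr1", pos1 = p1, chr2 = "chr1",
    pos2 = p1 + sample(1e3:4e5, n, replace = TRUE)))
  ins <- insulation(pool, "chr1", 1e6, window = 2e5, step = 4e4)
  for (i in c(3, 10, 17)) {
    x <- ins$pos[i]
    expect_equal(ins$insulation[i], oracle_insulation(pool, x, 2e5))
  }
  # zero within -> NA insulation
  lone <- data.table::data.table(cell = "p", chr1 = "chr1", pos1 = 1e5,
                                 chr2 = "chr1", pos2 = 9e5)
  ins2 <- insulation(lone, "chr1", 1e6, window = 2e4, step = 4e4)
  expect_true(all(is.na(ins2$insulation)))
})

test_that("virtual_4c applies the span-dependent inclusion rule", {
  set.seed(72)
  n <- 500
  x <- 5e6
  p1 <- x + sample(-4e4:4e4, n, replace = TRUE)
  span <- sample(c(1e3:9e4, 1e5:9e5), n, replace = TRUE)
  side <- sample(c(-1, 1), n, replace = TRUE)
  pool <- data.table::data.table(cell = "p", chr1 = "chr1", pos1 = p1,
                                 chr2 = "chr1", pos2 = p1 + side * span)
  v <- virtual_4c(pool, "chr1", x)
  dmin <- pmin(abs(pool$pos1 - x), abs(pool$pos2 - x))
  # the inclusion count is exactly the literal rule's
  expect_equal(nrow(v), sum(mapply(oracle_v4c_included, dmin, span)))
  # sides: distal end below the viewpoint is 5p
  expect_true(all((v$pos < x) == (v$side == "5p")))
  expect_true(all(v$span <= 1e6))
  # a tie (both ends equidistant) treats pos2 as distal
  tie <- data.table::data.table(cell = "p", chr1 = "chr1", pos1 = x - 1e3,
                                chr2 = "chr1", pos2 = x + 1e3)
  vt <- virtual_4c(tie, "chr1", x)
  expect_equal(vt$pos, x + 1e3)
  expect_equal(vt$side, "3p")
})

test_that("v4c_difference equals the per-side binned-mean oracle", {
  set.seed(73)
  mk <- function(n) data.table::data.table(
    chrom = "chr1", viewpoint = 0,
    side = sample(c("5p", "3p"), n, replace = TRUE),
    span = runif(n, 1e3, 9.9e5), pos = 0, score = rnorm(n, 0, 30))
  a <- mk(300); b <- mk(250)
  edges <- c(0, 2.5e4, 5e4, 1e5, 2e5, 3e5, 5e5, 7.5e5, 1e6)
  got <- v4c_difference(a, b, edges)$distance
  want <- max(sapply(c("5p", "3p"), function(sd)
    oracle_v4c_difference(a$span[a$side == sd], a$score[a$side == sd],
                          b$span[b$side == sd], b$score[b$side == sd],
                          edges)))
  expect_equal(got, want, tolerance = 1e-12)
  # empty overlap -> NA distance
  expect_true(is.na(v4c_difference(a[0], b, edges)$distance))
})

test_that("hotspot_scan reproduces the greedy removal oracle", {
  set.seed(74)
  n <- 200
  p1 <- sample(1e6, n)
  span <- sample(1e4:9e5, n, replace = TRUE)
  diffs <- data.table::data.table(chr1 = "chr1", pos1 = p1, chr2 = "chr1",
                                  pos2 = p1 + span,
                                  diff = runif(n, 0, 100))
  got <- hotspot_scan(diffs, threshold = 40, radius = 5e4)
  ora <- oracle_hotspots(diffs$pos1, diffs$pos2, diffs$diff,
                         threshold = 40, radius = 5e4)
  expect_equal(got$pos1, diffs$pos1[ora])
  expect_equal(got$pos2, diffs$pos2[ora])
  expect_equal(got$diff, diffs$diff[ora])
  # spans outside dist_range and sub-threshold scores are excluded
  expect_true(all(got$diff > 40))
  none <- hotspot_scan(diffs, threshold = 101)
  expect_equal(nrow(none), 0L)
})

test_that("funnel_anchors merges adjacent runs and keeps the argmax", {
  bins <- make_bins(c(chr1 = 5e5, chr2 = 2e5), width = 1e5)
  nm <- as.character(bins$bin_id)   # 1..5 chr1, 6..7 chr2
  a_x <- setNames(c(0.9, 0.95, 0.9, 0.2, 0.2, 0.9, 0.2), nm)
  a_y <- setNames(rep(0.2, 7), nm)
  out <- funnel_anchors(a_x, a_y, bins, delta = 0.35)
  # run 1-3 on chr1 collapses to bin 2 (max delta 0.75); chr2 bin 6 alone
  expect_equal(out$bin_id, c(2L, 6L))
  expect_equal(out$delta, c(0.75, 0.7), ignore_attr = TRUE)
  # a run must not span the chromosome boundary
  a_x2 <- setNames(c(0.2, 0.2, 0.2, 0.9, 0.8, 0.9, 0.2), nm)
  out2 <- funnel_anchors(a_x2, a_y, bins, delta = 0.35)
  expect_equal(out2$bin_id, c(4L, 6L))
  # nothing above delta -> empty table
  expect_equal(nrow(funnel_anchors(a_y, a_y, bins)), 0L)
})

test_that("funnel_cluster orients traces 5'-high and clusters them", {
  bins <- make_bins(c(chr1 = 1e5), width = 1e3)
  nm <- as.character(bins$bin_id)
  ramp_up <- seq(0, 1, length.out = 100)
  a_x <- setNames(ramp_up, nm)          # rising: anchors flip
  a_y <- setNames(rev(ramp_up), nm)
  anchors <- data.table::data.table(bin_id = c(20L, 60L))
  fc <- funnel_cluster(anchors, a_x, a_y, bins, flank = 4e3, k = 2, seed = 1)
  expect_equal(dim(fc$traces), c(2L, 2L * (2L * 4L + 1L)))
  expect_true(all(fc$flipped))
  # after flipping, the x-condition trace decreases left to right
  expect_true(all(fc$traces[1, 1:9] == rev(a_x[(20 - 4):(20 + 4)])))
  expect_length(fc$cluster, 2L)
  # positions beyond the chromosome are NA-masked
  fc2 <- funnel_cluster(data.table::data.table(bin_id = 2L), a_x, a_y,
                        bins, flank = 4e3, k = 1, seed = 1)
  expect_true(any(is.na(fc2$traces)))
})

test_that("pooled_locus_map averages scores per pixel and mirrors flips", {
  sc <- data.table::data.table(
    cell = "p", chr1 = "chr1",
    pos1 = c(920, 925, 1090), chr2 = "chr1",
    pos2 = c(960, 955, 1095), score = c(10, 20, 40))
  loci <- data.table::data.table(chrom = "chr1", pos = 1000)
  m <- pooled_locus_map(sc, loci, flank = 100, pixel = 50)[["1"]]
  expect_equal(dim(m), c(4L, 4L))
  expect_equal(m[1, 2], 15)          # mean of the two 10/20 contacts
  expect_equal(m[2, 1], 15)          # symmetric fill
  expect_equal(m[4, 4], 40)
  expect_true(is.na(m[1, 3]))
  # flipped locus mirrors the matrix
  loci2 <- data.table::data.table(chrom = "chr1", pos = 1000, flipped = TRUE)
  m2 <- pooled_locus_map(sc, loci2, flank = 100, pixel = 50)[["1"]]
  expect_equal(m2, m[4:1, 4:1])
})

test_that("chip scores, binding sites and bin maxima behave as stated", {
  set.seed(75)
  v <- sample(1000)[1:128]           # distinct values
  sc <- chip_bin_score(v)
  expect_equal(sc, oracle_chip_score(v))
  expect_equal(max(sc), 7)           # top of n = 128 scores exactly 7
  # ties share the averaged-rank score
  expect_equal(chip_bin_score(c(1, 1, 2))[1], chip_bin_score(c(1, 1, 2))[2])
  # binding sites: adjacent above-threshold track bins merge
  score <- c(1, 9, 10, 2, 12, 1)
  starts <- seq(0, by = 20, length.out = 6)
  sites <- chip_binding_sites(score, starts, step = 20, threshold = 8)
  expect_equal(nrow(sites), 2L)
  expect_equal(sites$start, c(20L, 80L))
  expect_equal(sites$end, c(60L, 100L))
  expect_equal(sites$score, c(10, 12))
  # per-coarse-bin maximum over overlapping sites
  bins <- make_bins(c(chr1 = 200), width = 50)
  mx <- chip_bin_max(sites, bins, "chr1")
  expect_equal(unname(mx), c(10, 12, NA, NA))
  expect_equal(nrow(chip_binding_sites(score, starts, threshold = 20)), 0L)
})
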