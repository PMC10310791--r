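# Contact IO, canonicalization, binning, QC, downsampling.

test_that("canonicalize_contacts orders ends by (chrom, pos)", {
  ct <- data.table::data.table(
    cell = c("a", "a", "a", "a"),
    chr1 = c("chr2", "chr1", "chr1", "chr1"),
    pos1 = c(100L, 500L, 100L, 100L),
    chr2 = c("chr1", "chr1", "chr2", "chr1"),
    pos2 = c(200L, 100L, 50L, 100L))
  cc <- canonicalize_contacts(ct)
  # trans record swapped to chr1 first
  expect_equal(cc$chr1[1], "chr1"); expect_equal(cc$pos1[1], 200L)
  expect_equal(cc$chr2[1], "chr2"); expect_equal(cc$pos2[1], 100L)
  # cis record with pos2 < pos1 swapped
  expect_equal(cc$pos1[2], 100L); expect_equal(cc$pos2[2], 500L)
  # already canonical trans untouched
  expect_equal(cc$chr1[3], "chr1"); expect_equal(cc$chr2[3], "chr2")
  # self-contact untouched
  expect_equal(cc$pos1[4], 100L); expect_equal(cc$pos2[4], 100L)
  # custom chromosome order reverses the trans swap
  cc2 <- canonicalize_contacts(ct[3], chrom_levels = c("chr2", "chr1"))
  expect_equal(cc2$chr1, "chr2")
})

test_that("read/write round-trips and rejects malformed input", {
  ct <- data.table::data.table(
    cell = c("c1", "c2"), chr1 = c("chr1", "chr1"), pos1 = c(10L, 30L),
    chr2 = c("chr1", "chr2"), pos2 = c(20L, 40L))
  tf <- tempfile(fileext = ".tsv")
  write_contacts(ct, tf)
  back <- read_contacts(tf)
  expect_equal(as.data.frame(back), as.data.frame(ct))
  # headerless files work too
  write_contacts(ct, tf, header = FALSE)
  expect_equal(nrow(read_contacts(tf)), 2L)
  # malformed: wrong field count
  writeLines(c("c1\tchr1\t10\tchr1"), tf)
  expect_error(read_contacts(tf), "5 tab-separated")
  # malformed: non-numeric position in the body
  writeLines(c("cell\tchr1\tpos1\tchr2\tpos2",
               "c1\tchr1\tzz\tchr1\t20"), tf)
  expect_error(read_contacts(tf), "non-numeric")
  # malformed: negative position
  writeLines(c("c1\tchr1\t-5\tchr1\t20"), tf)
  expect_error(read_contacts(tf), "negative")
  # missing file
  expect_error(read_contacts(tempfile()), "not found")
  # empty file gives an empty table
  writeLines(character(), tf)
  expect_equal(nrow(read_contacts(tf)), 0L)
})

test_that("contact_distance is |pos2 - pos1| for cis and NA for trans", {
  ct <- data.table::data.table(cell = "c", chr1 = c("chr1", "chr1"),
                               pos1 = c(100, 5), chr2 = c("chr1", "chr2"),
                               pos2 = c(350, 10))
  expect_equal(contact_distance(ct), c(250, NA))
})

test_that("make_bins tiles chromosomes with half-open uniform bins", {
  b <- make_bins(c(chrA = 1000, chrB = 250), width = 100)
  expect_equal(nrow(b), 10 + 3)
  expect_equal(b$bin_id, 1:13)
  expect_equal(b$start[1:3], c(0, 100, 200))
  # last bin of chrB truncated at the chromosome end
  expect_equal(b[chrom == "chrB"]$end, c(100, 200, 250))
  # round trip through BED
  tf <- tempfile()
  write_bins(b, tf)
  expect_equal(as.data.frame(read_bins(tf)), as.data.frame(b))
})

test_that("assign_bin matches a brute-force scan and handles edges", {
  set.seed(42)
  bins <- make_bins(c(chr1 = 1e4, chr2 = 5e3), width = 1e3)
  chrom <- sample(c("chr1", "chr2", "chrX"), 200, replace = TRUE)
  pos <- sample(0:12000, 200, replace = TRUE)
  expect_equal(assign_bin(chrom, pos, bins),
               oracle_assign_bin(chrom, pos, bins))
  # half-open edges: start included, end excluded
  expect_equal(assign_bin("chr1", 0, bins), 1L)
  expect_equal(assign_bin("chr1", 999, bins), 1L)
  expect_equal(assign_bin("chr1", 1000, bins), 2L)
  expect_true(is.na(assign_bin("chr1", 10000, bins)))
  expect_true(is.na(assign_bin("chr9", 10, bins)))
})

test_that("qc_cells computes per-cell statistics and filters", {
  # cell "good": 10 cis contacts at 5 kb; cell "transy": mostly trans;
  # cell "shorty": mostly sub-1kb cis; cell "tiny": too few contacts
  mk <- function(cell, n, chr2 = "chr1", d = 5000) {
    data.table::data.table(cell = cell, chr1 = "chr1",
                           pos1 = seq(1e4, by = 1e4, length.out = n),
                           chr2 = chr2,
                           pos2 = seq(1e4, by = 1e4, length.out = n) + d)
  }
  ct <- rbind(mk("good", 10),
              rbind(mk("transy", 2), mk("transy", 8, chr2 = "chr2")),
              mk("shorty", 10, d = 500),
              mk("tiny", 2))
  th <- qc_config(min_contacts = 5, max_trans = 0.5, max_nondigested = 0.5,
                  max_chrom_aberration = 10)
  res <- qc_cells(ct, th)
  qc <- res$qc[match(c("good", "transy", "shorty", "tiny"), cell)]
  expect_equal(qc$n_contacts, c(10L, 10L, 10L, 2L))
  expect_equal(qc$frac_trans, c(0, 0.8, 0, 0))
  expect_equal(qc$frac_nondigested, c(0, 0, 1, 0))
  expect_setequal(res$pass, "good")
  # chromosomal aberration: a cell with all ends on chr1 vs a pooled
  # cohort split between chr1/chr2 has |log2(1/pooled_frac)| > 0
  ct2 <- rbind(mk("allchr1", 50), mk("mixed", 50, chr2 = "chr2"))
  res2 <- qc_cells(ct2, qc_config(min_contacts = 1, max_trans = 1,
                                  max_nondigested = 1,
                                  max_chrom_aberration = 0.3))
  q2 <- res2$qc[match(c("allchr1", "mixed"), cell)]
  # pooled chr1 fraction = 150/200; allchr1 cell has chr1 fraction 1
  expect_equal(q2$max_chrom_aberration[1],
               abs(log2(1 / (150 / 200))), tolerance = 1e-12)
  expect_false("allchr1" %in% res2$pass && q2$max_chrom_aberration[1] > 0.3)
})

test_that("downsample_cells samples exactly and reproducibly", {
  set.seed(7)
  ct <- data.table::data.table(
    cell = rep(c("a", "b"), c(100, 30)), chr1 = "chr1",
    pos1 = sample(1e6, 130), chr2 = "chr1", pos2 = sample(1e6, 130))
  d1 <- downsample_cells(ct, 50, seed = 3)
  expect_equal(as.integer(table(d1$cell)[c("a", "b")]), c(50L, 30L))
  # sampled without replacement from the original rows
  expect_true(all(d1[cell == "a"]$pos1 %in% ct[cell == "a"]$pos1))
  expect_equal(anyDuplicated(d1[cell == "a"]$pos1), 0L)
  # reproducible; different seed differs
  d2 <- downsample_cells(ct, 50, seed = 3)
  expect_equal(as.data.frame(d1), as.data.frame(d2))
  # drop_below removes short cells
  d3 <- downsample_cells(ct, 50, seed = 3, drop_below = TRUE)
  expect_setequal(unique(d3$cell), "a")
})

test_that("bin_coverage counts two ends per contact", {
  bins <- make_bins(c(chr1 = 3000), width = 1000)
  ct <- data.table::data.table(
    cell = c("a", "a", "b"), chr1 = "chr1", pos1 = c(100, 1100, 100),
    chr2 = "chr1", pos2 = c(150, 2500, 1500))
  m <- bin_coverage(ct, bins)
  expect_equal(dim(m), c(2L, 3L))
  # cell a: contact1 both ends bin1, contact2 ends bins 2 and 3
  expect_equal(unname(m["a", ]), c(2L, 1L, 1L))
  expect_equal(unname(m["b", ]), c(1L, 1L, 0L))
  expect_equal(attr(m, "bin_width"), 1000)
  # out-of-range ends warn and are dropped
  ct2 <- rbind(ct, data.table::data.table(cell = "a", chr1 = "chr1",
                                          pos1 = 100, chr2 = "chr1",
                                          pos2 = 5000))
  expect_warning(m2 <- bin_coverage(ct2, bins), "dropped")
  expect_equal(unname(m2["a", ]), c(3L, 1L, 1L))
})
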