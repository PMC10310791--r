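# Replication-trend mixture model: input preparation, fit recovery,
# likelihood, s-normalization, cluster expansion and annotation.

test_that("prepare_repmix_inputs filters cells, chroms and shallow bins", {
  bins <- data.table::data.table(
    bin_id = 1:6, chrom = c("chr1", "chr1", "chr1", "chr1", "chrX", "chrX"),
    start = 0, end = 1)
  dsn <- matrix(10L, 6, 6,
                dimnames = list(c("m1", "m2", "m3", "g1", "g2", "ery"),
                                as.character(1:6)))
  dsn[, 3] <- c(30L, 30L, 30L, 60L, 20L, 10L)  # uneven background bin
  dsn[, 4] <- 2L                               # below min_mean
  prep <- prepare_repmix_inputs(dsn, bins, mid_s_cells = c("m1", "m2", "m3",
                                                           "ery"),
                                g1_cells = c("g1", "g2"),
                                exclude_cells = "ery", min_mean = 8)
  expect_setequal(prep$cells, c("m1", "m2", "m3"))
  # chrX bins 5-6 and shallow bin 4 dropped
  expect_equal(prep$bin_ids, c(1L, 2L, 3L))
  # background from pooled G1 coverage of the kept bins
  expect_equal(unname(prep$p), c(20, 20, 80) / 120)
  expect_equal(sum(prep$p), 1)
  expect_error(prepare_repmix_inputs(dsn, bins, "nope", "g1"))
})

test_that("repmix_fit recovers planted clusters, s and regimes", {
  sim <- simulate_repmix_counts(n_cells_per_cluster = c(40, 30),
                                n_bins = 300, n_per_cell = 8000, seed = 5)
  fit <- suppressWarnings(repmix_fit(sim$n, sim$p, K = 2, seed = 1))
  expect_s3_class(fit, "repmix")
  expect_gt(oracle_ari(fit$cluster, sim$k_true), 0.8)
  expect_gt(cor(fit$s, sim$s_true, method = "spearman"), 0.9)
  # fitted regimes separate the planted differential bins: early in the
  # owner cluster, late in the other
  map <- sapply(1:2, function(k)
    as.integer(names(which.max(table(sim$k_true[fit$cluster == k])))))
  for (j in seq_along(sim$diff_bins)) {
    b <- sim$diff_bins[j]
    fk <- which(map == sim$diff_owner[j])
    if (length(fk) == 1) {
      expect_lte(fit$r[fk, b], 4L)
      expect_gte(fit$r[3 - fk, b], 6L)
    }
  }
  # penalized log-likelihood is non-decreasing once the penalty is active
  tr <- fit$loglik
  if (length(tr) > 3) expect_true(all(diff(tr[-(1:2)]) > -1e-6 * abs(tr[3])))
  # identical seed reproduces the fit
  fit2 <- suppressWarnings(repmix_fit(sim$n, sim$p, K = 2, seed = 1))
  expect_equal(fit2$cluster, fit$cluster)
  expect_equal(fit2$s, fit$s)
})

test_that("repmix_loglik equals the literal multinomial mixture loglik", {
  sim <- simulate_repmix_counts(n_cells_per_cluster = c(15, 10),
                                n_bins = 80, n_per_cell = 2000, seed = 9)
  fit <- suppressWarnings(repmix_fit(sim$n, sim$p, K = 2, seed = 2,
                                     max_iter = 6))
  ll <- repmix_loglik(fit, sim$n, per_cell = TRUE)
  # oracle: log sum_k pi_k * prod_j q_kj^n_ij (up to the multinomial
  # coefficient, which repmix_loglik also omits)
  for (i in c(1, 12, 25)) {
    terms <- sapply(which(fit$active), function(k) {
      cc <- copy_number(fit$s_ik[i, k], fit$r[k, ], fit$L)
      q <- fit$p * cc / sum(fit$p * cc)
      log(fit$pi[k]) + sum(sim$n[i, ] * log(q))
    })
    m <- max(terms)
    expect_equal(ll[i], m + log(sum(exp(terms - m))), tolerance = 1e-8)
  }
  expect_equal(repmix_loglik(fit, sim$n), sum(ll))
})

test_that("normalize_by_s divides out the fitted expectation exactly", {
  L <- 12L
  p <- c(0.4, 0.3, 0.2, 0.1)
  r <- rbind(c(1L, 3L, 8L, 12L))
  s <- c(a = 1.4, b = 1.7)
  model <- list(cluster = c(a = 1L, b = 1L), s = s, r = r, L = L, p = p)
  n <- t(sapply(names(s), function(i) {
    cc <- copy_number(s[[i]], r[1, ], L)
    5000 * p * cc / sum(p * cc)
  }))
  out <- normalize_by_s(n, model)
  expect_equal(unname(out), matrix(1, 2, 4), tolerance = 1e-12)
})

test_that("early_regime_bins intersects own-early with others-late", {
  model <- list(r = rbind(c(1L, 2L, 2L, 7L), c(9L, 3L, 10L, 1L)),
                active = c(TRUE, TRUE), bin_ids = c("10", "20", "30", "40"))
  expect_equal(early_regime_bins(model, 1), c("10", "30"))
  expect_equal(early_regime_bins(model, 2), "40")
  # with a single active cluster only the own-early bound applies
  model$active <- c(TRUE, FALSE)
  expect_equal(early_regime_bins(model, 1), c("10", "20", "30"))
})

test_that("expand_clusters thresholds the best group score", {
  gs <- rbind(a = c(0.9, 0.1), b = c(0.2, 0.6), c = c(0.3, 0.35),
              d = c(NA, 0.9))
  out <- expand_clusters(gs, thresholds = c(0.5, 0.5))
  expect_equal(unname(out[c("a", "b")]), c(1L, 2L))
  expect_true(is.na(out[["c"]]))      # best score below threshold
  expect_true(is.na(out[["d"]]))      # incomplete scores
  # per-group thresholds are respected
  out2 <- expand_clusters(gs, thresholds = c(0.5, 0.3))
  expect_equal(unname(out2[["c"]]), 2L)
})

test_that("annotate_clusters recovers a planted module enrichment", {
  set.seed(51)
  n_bins <- 600
  grad <- sort(rnorm(n_bins))
  scoreE <- cbind(c1 = grad + rnorm(n_bins, sd = 0.05),
                  c2 = grad + rnorm(n_bins, sd = 0.05))
  rownames(scoreE) <- as.character(seq_len(n_bins))
  mod_bins <- sample(n_bins, 30)
  scoreE[mod_bins, "c2"] <- scoreE[mod_bins, "c2"] + 0.6
  out <- annotate_clusters(scoreE, modules = list(m = mod_bins,
                                                  bg = setdiff(1:n_bins,
                                                               mod_bins)))
  expect_equal(dim(out), c(2L, 2L))
  expect_equal(rowMeans(out), c(m = 0, bg = 0), tolerance = 1e-12)
  expect_gt(out["m", "c2"], out["m", "c1"] + 0.3)
})

test_that("subcluster_annotate links coverage folds to expression", {
  set.seed(52)
  n_bins <- 40
  cov <- matrix(rgamma(20 * n_bins, 20, 20), 20, n_bins,
                dimnames = list(sprintf("c%02d", 1:20),
                                as.character(1:n_bins)))
  cov[1:10, 1:10] <- cov[1:10, 1:10] * 3     # subgroup-elevated bins
  genes <- sprintf("g%02d", 1:n_bins)
  tss <- data.table::data.table(gene = genes, bin_id = 1:n_bins)
  expr_diff <- cbind(X = ifelse(1:n_bins <= 10, 2, -2),
                     Y = ifelse(1:n_bins <= 10, -2, 2))
  rownames(expr_diff) <- genes
  out <- subcluster_annotate(cov, n_sub = 2, expr_diff, tss)
  grp <- out$subcluster[sprintf("c%02d", 1:10)]
  expect_equal(length(unique(grp)), 1L)
  expect_equal(out$annotation[unique(grp)], "X")
})

test_that("repmix_cross_validate scores hyperparameters on held-out bins", {
  sim <- simulate_repmix_counts(n_cells_per_cluster = c(15, 10),
                                n_bins = 120, n_per_cell = 3000, seed = 12)
  cv <- suppressWarnings(
    repmix_cross_validate(sim$n, sim$p, K = 2, L_grid = c(6L, 12L),
                          folds = 2L, seed = 3, max_iter = 5))
  expect_equal(nrow(cv$table), 2L)
  expect_true(all(is.finite(cv$table$score)))
  expect_true(cv$best[["L"]] %in% c(6, 12))
  expect_equal(cv$best[["lambda"]], 40)
})
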