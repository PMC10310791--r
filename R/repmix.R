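# Replication-trend mixture model.
#
# Cells are modelled as multinomial draws over genomic bins: a cell i in
# cluster k at S-phase coordinate s has bin probabilities
#   q_j(k, s) = p_j * c(s; r_kj) / sum_j' p_j' * c(s; r_kj')
# where p_j is the background contact fraction of bin j (from G1 cells) and
# c(s; l) is the piecewise-linear copy-number ramp of replication regime
# l in 1..L (see copy_number()). EM alternates: (E) per cell x cluster,
# maximize the multinomial log-likelihood over s on an R-point grid with
# parabolic refinement, and update soft cluster responsibilities; (M) per
# bin and cluster, update regimes by exact coordinate ascent with a fused
# penalty lambda toward the cross-cluster consensus regime, and update
# cluster priors. The penalized observed-data log-likelihood is checked to
# be non-decreasing every iteration.

#' Prepare inputs for the replication mixture model
#'
#' Restricts to mid-S, QC-passed, non-erythroid cells; drops X-chromosome
#' bins and bins with mean coverage below \code{min_mean}; and computes the
#' background bin distribution p from pooled G1 (non-erythroid) coverage.
#'
#' @param dsn cells x bins coverage matrix (columns named by bin id).
#' @param bins bin table (for chromosome exclusion).
#' @param mid_s_cells,g1_cells,exclude_cells cell id vectors.
#' @param min_mean minimum mean per-bin coverage (default 8).
#' @param exclude_chroms chromosomes to drop (default "chrX").
#' @return list with n (cells x bins), p (background), bin_ids, cells.
#' @export
prepare_repmix_inputs <- function(dsn, bins, mid_s_cells, g1_cells,
                                  exclude_cells = character(),
                                  min_mean = 8, exclude_chroms = "chrX") {
  bins <- as.data.table(bins)
  cells <- setdiff(intersect(mid_s_cells, rownames(dsn)), exclude_cells)
  g1 <- setdiff(intersect(g1_cells, rownames(dsn)), exclude_cells)
  stopifnot(length(cells) > 0, length(g1) > 0)
  bad_chrom <- bins$bin_id[bins$chrom %in% exclude_chroms]
  keep <- !(as.integer(colnames(dsn)) %in% bad_chrom)
  n <- dsn[cells, keep, drop = FALSE]
  keep2 <- colMeans(n) >= min_mean
  n <- n[, keep2, drop = FALSE]
  g1_cov <- colSums(dsn[g1, keep, drop = FALSE][, keep2, drop = FALSE])
  if (any(g1_cov == 0)) g1_cov <- g1_cov + 1  # guard empty background bins
  p <- g1_cov / sum(g1_cov)
  list(n = n, p = p, bin_ids = as.integer(colnames(n)), cells = cells)
}

# log-likelihood of all cells against one cluster's regimes on an s grid;
# returns cells x R matrix
.ll_grid <- function(n, N, logp, p, r_k, sgrid, L) {
  sapply(sgrid, function(s) {
    cc <- copy_number(s, r_k, L)
    as.numeric(n %*% (logp + log(cc))) - N * log(sum(p * cc))
  })
}

.ll_at <- function(ni, Ni, logp, p, r_k, s, L) {
  cc <- copy_number(s, r_k, L)
  sum(ni * (logp + log(cc))) - Ni * log(sum(p * cc))
}

#' Fit the replication mixture model
#'
#' @param n cells x bins count matrix.
#' @param p background bin fractions (sums to 1).
#' @param K number of clusters.
#' @param L replication regimes (default 12).
#' @param R s-grid resolution in the E-step (default 11).
#' @param lambda fused-penalty weight toward the cross-cluster consensus
#'   regime (default 40); lambda = 0 gives per-cluster independent
#'   maximum-likelihood regimes, lambda -> Inf forces identical rows.
#' @param init optional list with \code{clusters} (named integer per cell)
#'   and/or \code{order} (cell ordering proxy for initial s, e.g. fraction
#'   of short-range contacts); defaults are derived from the counts.
#' @param seed RNG seed (initial clustering).
#' @param max_iter,tol EM stopping rule: stop when the penalized
#'   log-likelihood improves by less than \code{tol} (absolute). The fused
#'   penalty is warmed up (lambda = 0 for the first two iterations) so that
#'   cluster-specific regimes can differentiate from the soft initial
#'   responsibilities before being fused toward the consensus.
#' @return object of class "repmix" with r (K x bins regimes), s (per-cell),
#'   s_ik, resp, pi, cluster (hard assignment), consensus, loglik trace.
#' @export
repmix_fit <- function(n, p, K, L = 12L, R = 11L, lambda = 40,
                       init = NULL, seed = 1L, max_iter = 40L, tol = 1e-3) {
  stopifnot(K >= 1, nrow(n) >= K, length(p) == ncol(n))
  set.seed(seed)
  nc <- nrow(n); J <- ncol(n)
  N <- rowSums(n)
  p <- p / sum(p)
  logp <- log(p)
  sgrid <- seq(1, 2, length.out = R)

  # --- initialization (order cells, rank-spread s in [1.2, 1.8]) ---
  ord_key <- if (!is.null(init$order)) init$order[rownames(n)] else {
    m <- log1p(sweep(n, 1, N, "/") * J)
    pc <- prcomp(m, center = TRUE)$x[, 1]
    # orient the component against an early/late coverage proxy: early
    # (high-background) bins saturate at two copies first, so as s advances
    # the cell's coverage shifts from high-p toward low-p (late) bins and
    # the proxy falls with s
    hi <- p >= quantile(p, 0.75); lo <- p <= quantile(p, 0.25)
    el_proxy <- log1p(rowSums(n[, hi, drop = FALSE])) -
      log1p(rowSums(n[, lo, drop = FALSE]))
    anchor <- if (sd(el_proxy) > 0) el_proxy else N
    al <- suppressWarnings(cor(pc, anchor))
    if (!is.na(al) && al > 0) pc <- -pc
    pc
  }
  s_init <- 1.2 + 0.6 * (rank(ord_key, ties.method = "first") - 1) /
    max(1, nc - 1)
  cl_init <- if (!is.null(init$clusters)) init$clusters[rownames(n)] else {
    m <- sweep(n, 1, N, "/")
    m <- sweep(m, 2, colMeans(m), "/")
    o <- order(ord_key)
    w <- min(20L, nc)
    run <- apply(m[o, , drop = FALSE], 2, function(x)
      stats::filter(x, rep(1 / w, w), sides = 2))
    cmn <- colMeans(m[o, , drop = FALSE])
    nas <- is.na(run)
    run[nas] <- cmn[col(run)[nas]]
    corrected <- m[o, , drop = FALSE] - run
    cc <- suppressWarnings(cor(t(corrected)))
    cc[is.na(cc)] <- 0
    cl <- cutree(hclust(as.dist(1 - cc), method = "average"), k = K)
    cl[match(rownames(n), rownames(m)[o])]
  }
  own <- if (K == 2) 2 / 3 else 0.5
  resp <- matrix((1 - own) / max(1, K - 1), nc, K)
  resp[cbind(seq_len(nc), cl_init)] <- if (K > 1) own else 1
  s_ik <- matrix(s_init, nc, K)
  r <- matrix(as.integer(ceiling(L / 2)), K, J)
  consensus <- r[1, ]
  pi_k <- colMeans(resp)
  active <- rep(TRUE, K)

  pen_ll <- -Inf
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    # penalty warm-up: with the soft 0.5 initial responsibilities every
    # cluster sees nearly the same weighted data, so under the full fused
    # penalty all clusters make identical regime choices and the first
    # E-step has no between-cluster contrast. Two unpenalized iterations
    # let cluster-specific regimes differentiate before fusion kicks in;
    # the monotonicity check restarts when the penalty switches on.
    lambda_eff <- if (iter <= 2L && max_iter > 2L) 0 else lambda
    if (iter == 3L) pen_ll <- -Inf
    ## ----- M-step: regimes by exact coordinate ascent, then consensus -----
    for (k in which(active)) {
      w <- resp[, k]
      if (sum(w) < .Machine$double.eps) next
      C <- sapply(seq_len(L), function(l) copy_number(s_ik[, k], l, L)) # nc x L
      logC <- log(C)
      T1 <- crossprod(n * w, logC)                    # J x L
      # current per-cell copy numbers and normalizers under r[k, ]
      Ck <- matrix(0, nc, J)
      for (l in seq_len(L)) {
        sel <- r[k, ] == l
        if (any(sel)) Ck[, sel] <- C[, l]
      }
      Z <- as.numeric(Ck %*% p)
      wN <- w * N
      for (j in seq_len(J)) {
        Zmj <- Z - p[j] * Ck[, j]
        obj <- T1[j, ] - colSums(wN * log(Zmj + p[j] * C))
        obj <- obj - lambda_eff * (seq_len(L) != consensus[j])
        best <- which(obj == max(obj))
        l_new <- if (consensus[j] %in% best) consensus[j] else best[1]
        if (l_new != r[k, j]) {
          r[k, j] <- l_new
          Ck[, j] <- C[, l_new]
          Z <- Zmj + p[j] * Ck[, j]
        }
      }
    }
    # consensus = per-bin median regime across active clusters (regimes
    # are ordinal; a modal consensus would resolve all-distinct ties to
    # the earliest regime and so reward early deviations), ties kept at
    # the previous consensus for stability
    consensus <- vapply(seq_len(J), function(j) {
      x <- r[active, j]
      cost <- vapply(seq_len(L), function(l) sum(abs(x - l)), 0)
      best <- which(cost == min(cost))
      if (consensus[j] %in% best) consensus[j] else as.integer(best[1])
    }, 0L)
    pi_k <- pmax(colSums(resp), 1e-12)
    pi_k <- pi_k / sum(pi_k)

    ## ----- E-step: optimal s per cell x cluster, responsibilities -----
    ll <- matrix(-Inf, nc, K)
    for (k in which(active)) {
      g <- .ll_grid(n, N, logp, p, r[k, ], sgrid, L)
      bi <- max.col(g, ties.method = "first")
      s_best <- sgrid[bi]
      ll_best <- g[cbind(seq_len(nc), bi)]
      # parabolic refinement around interior grid maxima
      h <- sgrid[2] - sgrid[1]
      interior <- which(bi > 1 & bi < R)
      for (i in interior) {
        lm <- g[i, bi[i] - 1]; l0 <- g[i, bi[i]]; lp <- g[i, bi[i] + 1]
        den <- lm - 2 * l0 + lp
        if (den < 0) {
          s_star <- sgrid[bi[i]] - 0.5 * h * (lp - lm) / den
          s_star <- min(2, max(1, s_star))
          l_star <- .ll_at(n[i, ], N[i], logp, p, r[k, ], s_star, L)
          if (l_star > ll_best[i]) { ll_best[i] <- l_star; s_best[i] <- s_star }
        }
      }
      ll[, k] <- ll_best
      s_ik[, k] <- s_best
    }
    lmax <- apply(ll[, active, drop = FALSE], 1, max)
    num <- sweep(exp(sweep(ll[, active, drop = FALSE], 1, lmax)), 2,
                 pi_k[active], "*")
    resp_act <- num / rowSums(num)
    resp[, active] <- resp_act
    resp[, !active] <- 0

    # drop empty clusters (less than one cell-equivalent of mass)
    mass <- colSums(resp)
    newly_empty <- active & mass < 1
    if (any(newly_empty)) {
      warning("dropping empty cluster(s): ",
              paste(which(newly_empty), collapse = ", "))
      active[newly_empty] <- FALSE
      resp[, !active] <- 0
      resp <- resp / rowSums(resp)
      pi_k <- pmax(colSums(resp), 1e-12); pi_k <- pi_k / sum(pi_k)
    }

    pen <- lambda_eff * sum(r[active, , drop = FALSE] !=
                              matrix(consensus, sum(active), J, byrow = TRUE))
    new_ll <- sum(lmax + log(rowSums(sweep(
      exp(sweep(ll[, active, drop = FALSE], 1, lmax)), 2, pi_k[active],
      "*")))) - pen
    trace <- c(trace, new_ll)
    if (is.finite(pen_ll) && new_ll < pen_ll - 1e-6 * abs(pen_ll)) {
      warning(sprintf("penalized log-likelihood decreased at iteration %d (%.6g -> %.6g)",
                      iter, pen_ll, new_ll))
    }
    # absolute improvement test (the log-likelihood magnitude scales with
    # the total count mass, so a relative test would stop immediately);
    # never converge inside the warm-up phase
    if (iter > 3L && is.finite(pen_ll) && abs(new_ll - pen_ll) < tol) {
      pen_ll <- new_ll
      break
    }
    pen_ll <- new_ll
  }

  hard <- apply(resp, 1, which.max)
  s <- s_ik[cbind(seq_len(nc), hard)]
  structure(list(K = K, L = L, R = R, lambda = lambda,
                 r = r, consensus = consensus, s = setNames(s, rownames(n)),
                 s_ik = s_ik, resp = resp, pi = pi_k,
                 cluster = setNames(hard, rownames(n)),
                 active = active, loglik = trace, p = p,
                 bin_ids = colnames(n)),
            class = "repmix")
}

#' @export
print.repmix <- function(x, ...) {
  cat("Replication mixture model: K =", sum(x$active), "active clusters,",
      length(x$consensus), "bins, L =", x$L, "\n")
  cat("cluster sizes:", paste(tabulate(x$cluster, x$K), collapse = ", "), "\n")
  cat("penalized log-likelihood:", tail(x$loglik, 1), "\n")
  invisible(x)
}

#' Observed-data log-likelihood of counts under a fitted model
#' @param model repmix fit; \code{n} counts; cells matched by row.
#' @param n counts matrix.
#' @param per_cell return the per-cell vector instead of the sum.
#' @return numeric.
#' @export
repmix_loglik <- function(model, n, per_cell = FALSE) {
  N <- rowSums(n)
  logp <- log(model$p)
  ll <- sapply(which(model$active), function(k)
    vapply(seq_len(nrow(n)), function(i)
      .ll_at(n[i, ], N[i], logp, model$p, model$r[k, ],
             model$s_ik[i, k], model$L), 0))
  lmax <- apply(ll, 1, max)
  out <- lmax + log(rowSums(sweep(exp(sweep(ll, 1, lmax)), 2,
                                  model$pi[model$active], "*")))
  if (per_cell) out else sum(out)
}

#' Cross-validate mixture-model hyperparameters over bin folds
#'
#' Bins are split into folds; for every (L, R, lambda) tuple the model is
#' fitted on training bins, and with s and responsibilities fixed from that
#' fit, held-out bin regimes are set by a single M-step and the held-out
#' per-cell multinomial log-likelihood is averaged. The best tuple (highest
#' mean held-out score) is returned.
#'
#' @param n,p counts and background.
#' @param K clusters; grids of L, R, lambda values; folds; seed.
#' @param L_grid,R_grid,lambda_grid hyperparameter grids.
#' @param folds number of bin folds.
#' @param seed RNG seed (fold split is deterministic given the seed).
#' @param ... passed to [repmix_fit()].
#' @return list with \code{best} (named vector) and \code{table}.
#' @export
repmix_cross_validate <- function(n, p, K, L_grid = c(6L, 12L),
                                  R_grid = 11L, lambda_grid = 40,
                                  folds = 3L, seed = 1L, ...) {
  set.seed(seed)
  J <- ncol(n)
  fold <- sample(rep_len(seq_len(folds), J))
  grid <- expand.grid(L = L_grid, R = R_grid, lambda = lambda_grid)
  scores <- matrix(NA_real_, nrow(grid), folds)
  for (g in seq_len(nrow(grid))) {
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- !tr
      fit <- repmix_fit(n[, tr, drop = FALSE], p[tr] / sum(p[tr]), K,
                        L = grid$L[g], R = grid$R[g],
                        lambda = grid$lambda[g], seed = seed, ...)
      # held-out regimes from one hard M-step with training s / resp
      s_hat <- fit$s
      cl_hat <- fit$cluster
      L <- grid$L[g]
      nte <- n[, te, drop = FALSE]
      pte <- p[te] / sum(p[te])
      ll_cells <- 0
      r_te <- matrix(0L, fit$K, ncol(nte))
      for (k in which(fit$active)) {
        sel <- cl_hat == k
        if (!any(sel)) next
        C <- sapply(seq_len(L), function(l) copy_number(s_hat[sel], l, L))
        if (is.null(dim(C))) C <- matrix(C, nrow = 1)
        T1 <- crossprod(nte[sel, , drop = FALSE], log(C))
        r_te[k, ] <- max.col(T1, ties.method = "first")
      }
      for (k in which(fit$active)) {
        sel <- cl_hat == k
        if (!any(sel)) next
        for (i in which(sel)) {
          cc <- copy_number(s_hat[i], r_te[k, ], L)
          q <- pte * cc / sum(pte * cc)
          ll_cells <- ll_cells + sum(nte[i, ] * log(q))
        }
      }
      scores[g, f] <- ll_cells / nrow(n)
    }
  }
  grid$score <- rowMeans(scores)
  best <- grid[which.max(grid$score), ]
  list(best = c(L = best$L, R = best$R, lambda = best$lambda),
       table = grid)
}

#' Coverage normalized by inferred S-phase progression
#'
#' Entry (i, j) = n_ij / (N_i * p_j * c(s_i; r_kj) / Z_i): observed counts
#' over model-expected counts given the cell's cluster, s-score and the
#' bin's regime. A model-perfect cell gives a row of ~1.
#'
#' @param n counts matrix; \code{model} a repmix fit.
#' @param model repmix fit (rows of n matched by order).
#' @return numeric matrix like n.
#' @export
normalize_by_s <- function(n, model) {
  N <- rowSums(n)
  out <- matrix(NA_real_, nrow(n), ncol(n), dimnames = dimnames(n))
  for (i in seq_len(nrow(n))) {
    k <- model$cluster[i]
    cc <- copy_number(model$s[i], model$r[k, ], model$L)
    q <- model$p * cc / sum(model$p * cc)
    out[i, ] <- n[i, ] / (N[i] * q)
  }
  out
}

#' Bins replicated early in one cluster only
#'
#' Bins in a regime at most \code{own_max} (early) in the target cluster
#' and at least \code{others_min} (late) in every other active cluster.
#'
#' @param model repmix fit; \code{k} target cluster.
#' @param k target cluster index.
#' @param own_max,others_min regime bounds (defaults 2 and 4).
#' @return character vector of bin ids.
#' @export
early_regime_bins <- function(model, k, own_max = 2L, others_min = 4L) {
  others <- setdiff(which(model$active), k)
  sel <- model$r[k, ] <= own_max
  if (length(others)) {
    sel <- sel & apply(model$r[others, , drop = FALSE] >= others_min, 2, all)
  }
  model$bin_ids[sel]
}

#' Expand clusters to held-out cells on cluster-specific bin groups
#'
#' Scores every cell by its mean value over each cluster-specific bin
#' group (e.g. pooled A-score or normalized coverage on the groups from
#' [early_regime_bins()]); a cell joins the cluster of its best group when
#' that score passes the group threshold, else stays unassigned.
#'
#' @param group_scores cells x groups matrix.
#' @param thresholds per-group numeric thresholds (recycled).
#' @return named integer cluster (NA = unassigned).
#' @export
expand_clusters <- function(group_scores, thresholds) {
  thresholds <- rep_len(thresholds, ncol(group_scores))
  out <- rep(NA_integer_, nrow(group_scores))
  names(out) <- rownames(group_scores)
  ok <- stats::complete.cases(group_scores)
  best <- max.col(group_scores[ok, , drop = FALSE], ties.method = "first")
  pass <- group_scores[ok, , drop = FALSE][cbind(seq_along(best), best)] >=
    thresholds[best]
  out[which(ok)[pass]] <- best[pass]
  out
}

#' Minority-cluster detection sensitivity
#'
#' Subsamples the minority cluster to each target size, refits the model on
#' the reduced cohort, and reports whether a cluster with majority overlap
#' to the planted minority emerges (>50% of the fitted cluster's cells are
#' minority cells and it captures >50% of them).
#'
#' @param n,p counts and background.
#' @param truth named integer vector of planted clusters.
#' @param minority planted cluster id to subsample.
#' @param sizes minority sizes to test (default 100, 75, 50, 25).
#' @param reps replicates per size.
#' @param seed RNG seed.
#' @param ... passed to [repmix_fit()].
#' @return data.table with size, rep, detected.
#' @export
sensitivity_harness <- function(n, p, truth, minority,
                                sizes = c(100L, 75L, 50L, 25L), reps = 2L,
                                seed = 1L, ...) {
  K <- length(unique(truth))
  out <- list()
  for (sz in sizes) {
    for (rp in seq_len(reps)) {
      set.seed(seed + 1000L * sz + rp)
      min_cells <- names(truth)[truth == minority]
      sz_eff <- min(sz, length(min_cells))
      keep <- c(names(truth)[truth != minority], sample(min_cells, sz_eff))
      nk <- n[keep, , drop = FALSE]
      fit <- repmix_fit(nk, p, K, seed = seed + rp, ...)
      mn <- intersect(keep, min_cells)
      detected <- FALSE
      for (k in which(fit$active)) {
        memb <- names(fit$cluster)[fit$cluster == k]
        if (length(memb) &&
            mean(memb %in% mn) > 0.5 &&
            sum(memb %in% mn) > 0.5 * length(mn)) detected <- TRUE
      }
      out[[length(out) + 1]] <- data.table(size = sz, rep = rp,
                                           detected = detected)
    }
  }
  data.table::rbindlist(out)
}

#' Annotate clusters with expression-derived bin modules
#'
#' Orders bins by their mean early-score across clusters, detrends each
#' cluster's early-score by subtracting the running mean over a window of
#' bins along that ordering, averages the detrended score per module, and
#' centres rows.
#'
#' @param scoreE bins x clusters early-score matrix (rownames = bin ids).
#' @param modules named list module -> bin ids.
#' @param window running-mean window in bins (default 200).
#' @return modules x clusters matrix, rows centred.
#' @export
annotate_clusters <- function(scoreE, modules, window = 200L) {
  keep <- stats::complete.cases(scoreE)
  m <- scoreE[keep, , drop = FALSE]
  ord <- order(rowMeans(m))
  m <- m[ord, , drop = FALSE]
  w <- min(window, nrow(m))
  det <- apply(m, 2, function(x) {
    rm <- stats::filter(x, rep(1 / w, w), sides = 2)
    rm[is.na(rm)] <- mean(x)
    x - rm
  })
  rownames(det) <- rownames(m)
  out <- t(sapply(names(modules), function(md) {
    sel <- rownames(det) %in% as.character(modules[[md]])
    if (!any(sel)) rep(NA_real_, ncol(det))
    else colMeans(det[sel, , drop = FALSE])
  }))
  colnames(out) <- colnames(scoreE)
  sweep(out, 1, rowMeans(out, na.rm = TRUE))
}

#' Subcluster a cell cluster and annotate against differential expression
#'
#' Hierarchically subclusters s-normalized coverage profiles, computes per
#' subcluster the log2 coverage fold change (pooled subcluster vs the
#' rest), and correlates it, over the bins holding the TSSs of
#' fold-filtered genes, with per-cell-type differential expression.
#'
#' @param norm_cov cells x bins s-normalized coverage (cluster cells only).
#' @param n_sub number of subclusters.
#' @param expr_diff genes x cell-types differential (log2, centred)
#'   expression matrix.
#' @param tss data.table with gene, bin_id.
#' @param fold minimum fold change (on 2^expr_diff range) for a gene to
#'   enter the correlation (default 2).
#' @return list with subcluster (per cell), cor (subclusters x cell types),
#'   annotation (per subcluster argmax type).
#' @export
subcluster_annotate <- function(norm_cov, n_sub, expr_diff, tss, fold = 2) {
  cc <- suppressWarnings(cor(t(norm_cov)))
  cc[is.na(cc)] <- 0
  sub <- cutree(hclust(as.dist(1 - cc), method = "average"), k = n_sub)
  names(sub) <- rownames(norm_cov)
  genes <- rownames(expr_diff)[apply(abs(expr_diff), 1, max) >= log2(fold)]
  tss <- as.data.table(tss)[gene %in% genes]
  bin_cols <- match(as.character(tss$bin_id), colnames(norm_cov))
  ok <- !is.na(bin_cols)
  tss <- tss[ok]; bin_cols <- bin_cols[ok]
  cmat <- matrix(NA_real_, n_sub, ncol(expr_diff),
                 dimnames = list(seq_len(n_sub), colnames(expr_diff)))
  for (k in seq_len(n_sub)) {
    inm <- sub == k
    if (sum(inm) == 0 || sum(!inm) == 0) next
    fc <- log2((colMeans(norm_cov[inm, , drop = FALSE]) + 1e-9) /
                 (colMeans(norm_cov[!inm, , drop = FALSE]) + 1e-9))
    fc_g <- fc[bin_cols]
    for (ty in colnames(expr_diff)) {
      e <- expr_diff[tss$gene, ty]
      if (sd(fc_g) > 0 && sd(e) > 0) cmat[k, ty] <- cor(fc_g, e)
    }
  }
  ann <- colnames(expr_diff)[apply(cmat, 1, function(x)
    if (all(is.na(x))) NA_integer_ else which.max(x))]
  list(subcluster = sub, cor = cmat, annotation = ann)
}
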