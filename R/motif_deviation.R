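#' Sample GC/accessibility-matched background peaks
#'
#' For every peak, draws `n_iter` background peaks (with replacement, never
#' the peak itself) from its `k` nearest neighbors in the standardized 2-D
#' space of GC fraction and log1p mean accessibility. These matched sets
#' supply the null used to bias-correct motif deviations.
#'
#' @param peaks data.frame with a `gc` column, aligned with `colnames(atac)`.
#' @param atac sparse counts, cells x peaks.
#' @param n_iter background draws per peak (default 50).
#' @param k neighborhood size (default 50).
#' @param seed integer seed.
#' @return integer matrix, peaks x n_iter, of background peak indices.
#' @export
sample_background_peaks <- function(peaks, atac, n_iter = 50, k = 50, seed = 1L) {
  stopifnot(n_iter >= 1, identical(nrow(peaks), ncol(atac)))
  np <- nrow(peaks)
  if (np < k + 1)
    .stopf("need at least k + 1 = %d peaks for background matching (got %d)",
           k + 1, np)
  zs <- function(x) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  feat <- cbind(zs(peaks$gc), zs(log1p(Matrix::colSums(atac) / nrow(atac))))
  d <- as.matrix(dist(feat))
  diag(d) <- Inf
  .with_seed(seed, {
    out <- matrix(0L, np, n_iter)
    for (p in seq_len(np)) {
      nn <- order(d[p, ])[seq_len(k)]
      out[p, ] <- sample(nn, n_iter, replace = TRUE)
    }
    rownames(out) <- peaks$peak
    out
  })
}

#' Bias-corrected per-cell motif accessibility deviations
#'
#' For motif m and cell j, the observed count is `X = sum of counts over the
#' motif's peaks`; the depth-normalized expectation is `E = f_m * t_j`, with
#' `f_m` the motif peaks' share of the grand count total and `t_j` the cell
#' total. The raw deviation is `(X - E) / E`. The same statistic is computed
#' for each background iteration over the matched background peak set; the
#' bias-corrected deviation subtracts the background mean and the deviation
#' Z-score additionally divides by the background SD. Entries with `E = 0`
#' are reported as `NA`.
#'
#' @param atac sparse counts, cells x peaks.
#' @param motifs binary peaks x motifs hit matrix.
#' @param backgrounds integer matrix from [sample_background_peaks()]; when
#'   `NULL` only raw deviations are meaningful (background mean/SD of zero
#'   iterations are undefined).
#' @return list of class `deviation_matrix`: `deviations` (bias-corrected),
#'   `z`, `raw`, `n_iter`.
#' @export
compute_deviations <- function(atac, motifs, backgrounds) {
  atac <- .as_sparse(atac)
  motifs <- .as_sparse(motifs)
  stopifnot(ncol(atac) == nrow(motifs), nrow(backgrounds) == nrow(motifs))
  n_iter <- ncol(backgrounds)
  total <- sum(atac)
  t_j <- Matrix::rowSums(atac)

  raw_dev <- function(hit_mat) {
    X <- as.matrix(atac %*% hit_mat)
    f_m <- colSums(X) / total
    E <- outer(t_j, f_m)
    out <- (X - E) / E
    out[E == 0] <- NA_real_
    out
  }

  raw <- raw_dev(motifs)
  acc <- matrix(0, nrow(atac), ncol(motifs))
  acc2 <- matrix(0, nrow(atac), ncol(motifs))
  np <- nrow(motifs)
  for (i in seq_len(n_iter)) {
    S_i <- sparseMatrix(i = backgrounds[, i], j = seq_len(np), x = 1,
                        dims = c(np, np))
    bg <- raw_dev(S_i %*% motifs)
    acc <- acc + bg
    acc2 <- acc2 + bg^2
  }
  bg_mean <- acc / n_iter
  bg_sd <- sqrt(pmax(acc2 - n_iter * bg_mean^2, 0) / (n_iter - 1))
  dev <- raw - bg_mean
  z <- dev / bg_sd
  z[!is.na(bg_sd) & bg_sd == 0] <- NA_real_
  dn <- list(rownames(atac), colnames(motifs))
  dimnames(raw) <- dimnames(dev) <- dimnames(z) <- dn
  structure(list(deviations = dev, z = z, raw = raw, n_iter = n_iter),
            class = "deviation_matrix")
}

#' Differential TF activity between cell types
#'
#' One-vs-rest comparison of per-cell motif deviation scores. The reported
#' effect, `activity_delta`, is the difference of group means (deviation
#' scores are signed, so a ratio-based fold change is ill-defined); the test
#' is a two-sided Wilcoxon rank-sum, Bonferroni-corrected over motifs x
#' groups. A motif is flagged significant in a group when
#' `activity_delta > delta_cut` and `p_adj < alpha`.
#'
#' By default the comparison runs on the background-standardized Z-scores
#' (`scale = "z"`); `scale = "deviation"` switches to the bias-corrected
#' deviations (see the methods vignette for why the Z scale carries the
#' effect-size gates).
#'
#' @param dev a `deviation_matrix` from [compute_deviations()].
#' @param labels cell group labels.
#' @param scale `"z"` or `"deviation"`.
#' @param delta_cut,alpha significance gates (defaults 1 and 0.05).
#' @param min_cells groups smaller than this are skipped with a warning.
#' @return data.frame: `motif`, `group`, `activity_delta`, `p`, `p_adj`,
#'   `significant`; attribute `scale` records the score scale used.
#' @export
differential_tf_activity <- function(dev, labels, scale = c("z", "deviation"),
                                     delta_cut = 1, alpha = 0.05,
                                     min_cells = 3) {
  scale <- match.arg(scale)
  mat <- if (scale == "z") dev$z else dev$deviations
  stopifnot(length(labels) == nrow(mat))
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2) .stopf("need at least two groups")
  small <- groups[table(factor(labels, levels = groups)) < min_cells]
  if (length(small) > 0) {
    warning("skipping groups with fewer than ", min_cells, " cells: ",
            paste(small, collapse = ", "))
    groups <- setdiff(groups, small)
  }
  res <- do.call(rbind, lapply(groups, function(g) {
    ing <- labels == g
    rows <- lapply(colnames(mat), function(m) {
      v <- mat[, m]
      ok <- !is.na(v)
      data.frame(
        motif = m, group = g,
        activity_delta = mean(v[ok & ing]) - mean(v[ok & !ing]),
        p = .ranksum_p(matrix(v[ok], ncol = 1), ing[ok]),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  }))
  res$p_adj <- pmin(res$p * nrow(res), 1)
  res$significant <- res$activity_delta > delta_cut & res$p_adj < alpha
  rownames(res) <- NULL
  attr(res, "scale") <- scale
  res
}
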