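#' Pool cells into metacells within each cell type
#'
#' Cells of each type are shuffled (seeded) and split into pools of
#' `group_size`; a remainder smaller than `group_size` is merged into the
#' last pool. Metacell counts are pooled sums, so total counts are conserved.
#' Densifying sparse accessibility this way preserves the covariance
#' structure the co-accessibility estimator needs without requiring an
#' embedding.
#'
#' @param atac sparse counts, cells x peaks.
#' @param labels cell type labels.
#' @param group_size cells per pool (>= 2).
#' @param seed integer seed.
#' @return list: `counts` (metacells x peaks), `cell_type` (per metacell).
#' @export
aggregate_to_metacells <- function(atac, labels, group_size = 10, seed = 1L) {
  stopifnot(group_size >= 2, length(labels) == nrow(atac))
  labels <- as.character(labels)
  .with_seed(seed, {
    rows <- list()
    types <- character(0)
    for (g in sort(unique(labels))) {
      idx <- sample(which(labels == g))
      n_pool <- max(1L, floor(length(idx) / group_size))
      pool <- pmin(ceiling(seq_along(idx) / group_size), n_pool)
      for (k in seq_len(n_pool)) {
        rows[[length(rows) + 1L]] <- idx[pool == k]
        types <- c(types, g)
      }
    }
    ind <- sparseMatrix(
      i = rep(seq_along(rows), lengths(rows)), j = unlist(rows), x = 1,
      dims = c(length(rows), nrow(atac))
    )
    counts <- .as_sparse(ind %*% atac)
    rownames(counts) <- sprintf("mc%04d", seq_along(rows))
    colnames(counts) <- colnames(atac)
    list(counts = counts, cell_type = types)
  })
}

# Graphical lasso by block coordinate descent (Friedman/Hastie/Tibshirani
# scheme) with an element-wise penalty matrix. Small dense problems only:
# window sizes here are tens of peaks.
.glasso <- function(S, Rho, maxit = 50, tol = 1e-4) {
  p <- nrow(S)
  W <- S + diag(diag(Rho), p)
  B <- matrix(0, p, p)
  if (p == 1) return(matrix(1 / W[1, 1], 1, 1))
  for (it in seq_len(maxit)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      r12 <- Rho[idx, j]
      beta <- B[idx, j]
      for (sweep in seq_len(100)) {
        beta_old <- beta
        for (k in seq_along(idx)) {
          resid <- s12[k] - sum(W11[k, -k] * beta[-k])
          beta[k] <- sign(resid) * max(abs(resid) - r12[k], 0) / W11[k, k]
        }
        if (max(abs(beta - beta_old)) < tol * 1e-2) break
      }
      w12 <- as.numeric(W11 %*% beta)
      W[idx, j] <- w12
      W[j, idx] <- w12
      B[idx, j] <- beta
    }
    if (mean(abs(W - W_old)) < tol * mean(abs(diag(S)))) break
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    denom <- W[j, j] - sum(W[idx, j] * B[idx, j])
    Theta[j, j] <- 1 / denom
    Theta[idx, j] <- -B[idx, j] / denom
  }
  (Theta + t(Theta)) / 2
}

#' Peak-peak co-accessibility by windowed graphical lasso
#'
#' Standardized log1p metacell accessibility is analyzed in overlapping
#' genomic windows (width `window`, advancing by `window / 2`). In each
#' window a sparse inverse covariance is estimated by the graphical lasso
#' with a distance-increasing penalty
#' `rho_ij = lambda * (1 + (d_ij / window)^2)`; the co-accessibility score of
#' a peak pair is the partial correlation `-Theta_ij / sqrt(Theta_ii
#' Theta_jj)`, averaged over all windows containing the pair. Pairs are
#' retained when the averaged score reaches `coaccess_cutoff`.
#'
#' @param metacells list from [aggregate_to_metacells()] (or any matrix-like
#'   with metacells in rows and peaks in columns).
#' @param peaks peak annotation data.frame aligned with the matrix columns.
#' @param window window width in bp (default 500000).
#' @param coaccess_cutoff retention threshold on the score (default 0.2).
#' @param lambda base graphical-lasso penalty (default 0.2).
#' @return data.frame of class-free pairs: `peak_a`, `peak_b`, `score`,
#'   `distance` (bp); `peak_a < peak_b` lexicographically, each unordered
#'   pair reported once.
#' @export
compute_coaccessibility <- function(metacells, peaks, window = 500000,
                                    coaccess_cutoff = 0.2, lambda = 0.2) {
  mat <- if (is.list(metacells) && !is.null(metacells$counts)) metacells$counts else metacells
  if (nrow(mat) < 5) .stopf("need at least 5 metacells")
  stopifnot(identical(colnames(mat), peaks$peak))
  x <- as.matrix(log1p(mat))
  x <- scale(x)
  mid <- floor((peaks$start + peaks$end) / 2)
  sum_s <- matrix(0, nrow(peaks), nrow(peaks))
  n_s <- matrix(0L, nrow(peaks), nrow(peaks))
  for (chr in unique(peaks$chrom)) {
    on_chr <- which(peaks$chrom == chr)
    if (length(on_chr) < 2) next
    lo <- min(mid[on_chr])
    hi <- max(mid[on_chr])
    starts <- seq(floor(lo / (window / 2)) * (window / 2), hi, by = window / 2)
    for (ws in starts) {
      sel <- on_chr[mid[on_chr] >= ws & mid[on_chr] < ws + window]
      xs <- x[, sel, drop = FALSE]
      ok <- apply(xs, 2, function(v) all(is.finite(v)) && sd(v) > 0)
      sel <- sel[ok]
      if (length(sel) < 2) next
      xs <- x[, sel, drop = FALSE]
      S <- crossprod(xs) / (nrow(xs) - 1)
      d <- abs(outer(mid[sel], mid[sel], "-"))
      Rho <- lambda * (1 + (d / window)^2)
      Theta <- tryCatch(.glasso(S, Rho), error = function(e) {
        warning("skipping singular window ", chr, ":", ws, ": ",
                conditionMessage(e))
        NULL
      })
      if (is.null(Theta)) next
      pc <- -Theta / sqrt(outer(diag(Theta), diag(Theta)))
      sum_s[sel, sel] <- sum_s[sel, sel] + pc
      n_s[sel, sel] <- n_s[sel, sel] + 1L
    }
  }
  keep <- which(upper.tri(n_s) & n_s > 0, arr.ind = TRUE)
  if (nrow(keep) == 0)
    return(data.frame(peak_a = character(0), peak_b = character(0),
                      score = numeric(0), distance = integer(0)))
  score <- sum_s[keep] / n_s[keep]
  out <- data.frame(
    peak_a = peaks$peak[keep[, 1]], peak_b = peaks$peak[keep[, 2]],
    score = score,
    distance = abs(mid[keep[, 1]] - mid[keep[, 2]]),
    stringsAsFactors = FALSE
  )
  out <- out[out$score >= coaccess_cutoff, , drop = FALSE]
  out <- out[order(out$peak_a, out$peak_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Link distal peaks to genes (candidate cis-regulatory elements)
#'
#' From co-accessible peak pairs in which exactly one peak overlaps a gene's
#' promoter (midpoint within `promoter_dist` of the TSS), computes the
#' Pearson correlation between the OTHER peak's mean accessibility and the
#' gene's mean expression across cell types (log-normalized means), with a
#' two-sided p from the t distribution on `n_types - 2` df,
#' Benjamini-Hochberg corrected across all candidate links. Links with
#' `q < q_cut` are the candidate cCREs.
#'
#' @param pairs data.frame from [compute_coaccessibility()].
#' @param peaks,genes annotations as elsewhere.
#' @param atac_type_means,rna_type_means cell type x feature matrices of
#'   log-normalized means (see [type_means()]); rows must agree.
#' @param q_cut BH-significance gate (default 0.05).
#' @param promoter_dist promoter window around the TSS in bp.
#' @return data.frame: `peak` (distal side), `gene`, `promoter_peak`,
#'   `coaccess`, `r`, `p`, `q`.
#' @export
link_ccres <- function(pairs, peaks, genes, atac_type_means, rna_type_means,
                       q_cut = 0.05, promoter_dist = 1000) {
  if (!identical(rownames(atac_type_means), rownames(rna_type_means)))
    .stopf("modalities must share the same cell-type set")
  n_types <- nrow(atac_type_means)
  if (n_types < 3)
    .stopf("cross-cell-type correlation needs at least 3 cell types (got %d)",
           n_types)
  ctx <- .peak_gene_context(peaks, genes, promoter_dist)
  is_prom <- peaks$peak %in% names(ctx$promoter)
  names(is_prom) <- peaks$peak
  cand <- NULL
  if (nrow(pairs) > 0) {
    pa <- is_prom[pairs$peak_a]
    pb <- is_prom[pairs$peak_b]
    one_sided <- xor(pa, pb)
    px <- ifelse(pa, pairs$peak_a, pairs$peak_b)[one_sided]
    dx <- ifelse(pa, pairs$peak_b, pairs$peak_a)[one_sided]
    sc <- pairs$score[one_sided]
    cand <- do.call(rbind, lapply(seq_along(px), function(i) {
      gs <- ctx$promoter[[px[i]]]
      data.frame(peak = dx[i], gene = gs, promoter_peak = px[i],
                 coaccess = sc[i], stringsAsFactors = FALSE)
    }))
  }
  if (is.null(cand) || nrow(cand) == 0)
    return(data.frame(peak = character(0), gene = character(0),
                      promoter_peak = character(0), coaccess = numeric(0),
                      r = numeric(0), p = numeric(0), q = numeric(0)))
  rp <- t(vapply(seq_len(nrow(cand)), function(i) {
    a <- atac_type_means[, cand$peak[i]]
    e <- rna_type_means[, cand$gene[i]]
    if (sd(a) == 0 || sd(e) == 0) return(c(NA_real_, 1))
    r <- cor(a, e)
    tt <- r * sqrt(n_types - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    c(r, 2 * pt(-abs(tt), df = n_types - 2))
  }, numeric(2)))
  cand$r <- rp[, 1]
  cand$p <- rp[, 2]
  cand$q <- p.adjust(cand$p, method = "BH")
  out <- cand[!is.na(cand$q) & cand$q < q_cut, , drop = FALSE]
  out <- out[order(out$q, out$peak), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Fraction of a type's cells in which each peak is detected (count > 0)
.detection_fraction <- function(atac, labels, cell_type) {
  idx <- which(as.character(labels) == cell_type)
  if (length(idx) == 0) .stopf("cell type '%s' has no cells", cell_type)
  Matrix::colSums(atac[idx, , drop = FALSE] > 0) / length(idx)
}

#' Identify candidate target genes of a TF in one cell type
#'
#' A gene is a candidate target of the TF (motif) in a cell type when either
#' (a) a promoter peak of the gene is accessible in that type and carries the
#' motif (`promoter_motif` evidence), or (b) a cCRE linked to the gene is
#' accessible in that type and carries the motif (`linked_ccre` evidence).
#' "Accessible" means detected (count > 0) in at least `min_detect_frac` of
#' the type's cells.
#'
#' @param motif motif id (column of `motifs`).
#' @param motifs binary peaks x motifs matrix.
#' @param links cCRE links from [link_ccres()].
#' @param peaks,genes annotations as elsewhere.
#' @param atac sparse counts, cells x peaks.
#' @param labels cell type labels.
#' @param cell_type the type whose accessibility gates the evidence.
#' @param min_detect_frac detection-fraction gate (default 0.05).
#' @param promoter_dist promoter window in bp.
#' @return data.frame: `tf` (motif id), `gene`, `evidence`
#'   (`promoter_motif` / `linked_ccre`), `peak` (the evidencing peak).
#' @export
identify_tf_targets <- function(motif, motifs, links, peaks, genes, atac,
                                labels, cell_type, min_detect_frac = 0.05,
                                promoter_dist = 1000) {
  if (!motif %in% colnames(motifs))
    .stopf("unknown motif '%s'", motif)
  det <- .detection_fraction(atac, labels, cell_type)
  accessible <- names(det)[det >= min_detect_frac]
  hit_peaks <- rownames(motifs)[motifs[, motif] > 0]
  ctx <- .peak_gene_context(peaks, genes, promoter_dist)
  ev <- list()
  prom_ok <- intersect(intersect(hit_peaks, accessible), names(ctx$promoter))
  for (p in prom_ok)
    ev[[length(ev) + 1L]] <- data.frame(tf = motif, gene = ctx$promoter[[p]],
                                        evidence = "promoter_motif", peak = p,
                                        stringsAsFactors = FALSE)
  if (!is.null(links) && nrow(links) > 0) {
    lk <- links[links$peak %in% intersect(hit_peaks, accessible), , drop = FALSE]
    if (nrow(lk) > 0)
      ev[[length(ev) + 1L]] <- data.frame(tf = motif, gene = lk$gene,
                                          evidence = "linked_ccre",
                                          peak = lk$peak,
                                          stringsAsFactors = FALSE)
  }
  if (length(ev) == 0)
    return(data.frame(tf = character(0), gene = character(0),
                      evidence = character(0), peak = character(0)))
  out <- unique(do.call(rbind, ev))
  out <- out[order(out$gene, out$evidence, out$peak), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a TF regulatory network
#'
#' Deduplicates TF-to-target edges into a directed igraph, keeping every
#' evidence record on the edge and flagging differentially expressed target
#' genes on the nodes.
#'
#' @param tf_targets data.frame with columns `tf`, `gene`, `evidence` (e.g.
#'   rbind of [identify_tf_targets()] outputs).
#' @param deg_genes character vector of DEG gene ids (may be empty).
#' @return a directed `igraph` object; edge attribute `evidence` is a
#'   comma-separated, sorted evidence-class list, node attribute `is_deg`
#'   flags DEGs, node attribute `role` is `"tf"` or `"target"` (TFs that are
#'   also targets keep `"tf"`).
#' @export
build_network <- function(tf_targets, deg_genes = character(0)) {
  if (is.null(tf_targets) || nrow(tf_targets) == 0) {
    return(igraph::make_empty_graph(directed = TRUE))
  }
  key <- paste(tf_targets$tf, tf_targets$gene, sep = "\r")
  ev <- vapply(split(tf_targets$evidence, key), function(e)
    paste(sort(unique(e)), collapse = ","), character(1))
  uk <- strsplit(names(ev), "\r", fixed = TRUE)
  edges <- data.frame(from = vapply(uk, `[`, character(1), 1),
                      to = vapply(uk, `[`, character(1), 2),
                      evidence = unname(ev), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  igraph::V(g)$is_deg <- igraph::V(g)$name %in% deg_genes
  igraph::V(g)$role <- ifelse(igraph::V(g)$name %in% tf_targets$tf, "tf", "target")
  g
}

#' Expression-bin-matched gene module score
#'
#' Per-cell score of a gene set: mean log-normalized expression of the set
#' minus the mean of `n_ctrl` control genes drawn (seeded) from the same
#' mean-expression bins as each set gene. Genes are binned into `n_bins`
#' equal-frequency bins of their mean expression across all cells.
#'
#' @param expr raw counts, cells x genes.
#' @param gene_set character vector of genes (subset of `colnames(expr)`).
#' @param n_bins expression bins (default 24).
#' @param n_ctrl control genes per set gene (default 100, with replacement).
#' @param seed integer seed.
#' @return numeric vector, one score per cell.
#' @export
score_gene_module <- function(expr, gene_set, n_bins = 24, n_ctrl = 100,
                              seed = 1L) {
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0) .stopf("gene set is empty")
  missing <- setdiff(gene_set, colnames(expr))
  if (length(missing) > 0)
    .stopf("genes absent from the matrix: %s",
           paste(head(missing, 5), collapse = ", "))
  norm <- normalize_counts(expr)
  avg <- Matrix::colMeans(norm)
  n_bins <- min(n_bins, length(avg))
  bins <- cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bins) <- colnames(expr)
  .with_seed(seed, {
    ctrl <- unlist(lapply(gene_set, function(g) {
      pool <- names(bins)[bins == bins[[g]]]
      sample(pool, n_ctrl, replace = TRUE)
    }))
    set_mean <- Matrix::rowMeans(norm[, gene_set, drop = FALSE])
    ctrl_mean <- Matrix::rowMeans(norm[, ctrl, drop = FALSE])
    as.numeric(set_mean - ctrl_mean)
  })
}
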