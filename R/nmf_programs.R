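#' Relative expression matrix for intratumoral program discovery
#'
#' Log-normalizes one sample's tumor-cell counts, centers each gene on its
#' mean across those cells ("relative" expression), and clamps negative
#' values to zero so the result is a valid NMF input. Genes that end up
#' all-zero (constant across cells) are retained.
#'
#' @param expr raw counts, cells x genes, tumor cells of one sample.
#' @param min_cells smallest usable cell number (default 20).
#' @return dense non-negative matrix, genes x cells.
#' @export
prepare_relative_expression <- function(expr, min_cells = 20) {
  if (nrow(expr) < min_cells)
    .stopf("need at least %d tumor cells (got %d)", min_cells, nrow(expr))
  norm <- as.matrix(normalize_counts(expr))
  centered <- sweep(norm, 2, colMeans(norm))
  centered[centered < 0] <- 0
  t(centered)
}

# One NMF fit (Frobenius objective, multiplicative updates, random init)
.nmf_fit <- function(V, k, seed, maxit = 300, tol = 1e-5) {
  n <- nrow(V)
  m <- ncol(V)
  eps <- .Machine$double.eps
  .with_seed(seed, {
    W <- matrix(runif(n * k, 0, max(V)), n, k)
    H <- matrix(runif(k * m, 0, 1), k, m)
    err_old <- Inf
    for (it in seq_len(maxit)) {
      H <- H * (crossprod(W, V) / (crossprod(W) %*% H + eps))
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
      if (it %% 10 == 0 || it == maxit) {
        err <- sqrt(sum((V - W %*% H)^2))
        if (is.finite(err_old) && abs(err_old - err) < tol * max(err_old, eps)) break
        err_old <- err
      }
    }
    err <- sqrt(sum((V - W %*% H)^2))
    rownames(W) <- rownames(V)
    colnames(H) <- colnames(V)
    list(W = W, H = H, error = err, seed = seed)
  })
}

#' Consensus NMF over a range of ranks
#'
#' For every rank `k` in `k_min:k_max`, runs `nrun` seeded random-init
#' factorizations (Frobenius multiplicative updates). Cells are assigned to
#' their highest-loading program; the consensus matrix is the mean
#' co-assignment indicator over runs, and the cophenetic coefficient is the
#' correlation between the consensus dissimilarity and the cophenetic
#' distances of its average-linkage hierarchical clustering. The run with
#' the lowest reconstruction error is retained per rank.
#'
#' @param mat non-negative matrix, genes x cells
#'   (see [prepare_relative_expression()]).
#' @param k_min,k_max rank range (defaults 2 and 6).
#' @param nrun factorizations per rank (default 30).
#' @param seed integer seed; per-run seeds are derived deterministically.
#' @param maxit,tol solver controls.
#' @return list: `fits` (per retained rank: `W`, `H`, `error`, `seed`),
#'   `cophenetic` (named numeric by rank), `ranks`.
#' @export
run_nmf_range <- function(mat, k_min = 2, k_max = 6, nrun = 30, seed = 1L,
                          maxit = 300, tol = 1e-5) {
  if (any(mat < 0)) .stopf("NMF input must be non-negative")
  ranks <- k_min:k_max
  usable <- ranks[ranks < min(dim(mat))]
  if (length(usable) < length(ranks))
    warning("skipping ranks >= min(dim): ",
            paste(setdiff(ranks, usable), collapse = ", "))
  fits <- list()
  coph <- numeric(0)
  m <- ncol(mat)
  for (k in usable) {
    best <- NULL
    co <- matrix(0, m, m)
    for (run in seq_len(nrun)) {
      f <- .nmf_fit(mat, k, seed = (seed %% 100000L) * 10000L + k * 100L + run,
                    maxit = maxit, tol = tol)
      if (is.null(best) || f$error < best$error) best <- f
      assign <- apply(f$H, 2, which.max)
      co <- co + outer(assign, assign, "==")
    }
    consensus <- co / nrun
    d <- as.dist(1 - consensus)
    coph_k <- if (var(as.numeric(d)) == 0) 1 else {
      hc <- hclust(d, method = "average")
      cor(as.numeric(d), as.numeric(cophenetic(hc)))
    }
    fits[[as.character(k)]] <- best
    coph[as.character(k)] <- coph_k
  }
  list(fits = fits, cophenetic = coph, ranks = usable)
}

#' Rank selection by the largest cophenetic drop
#'
#' Chooses the rank immediately before the largest decrease of the
#' cophenetic coefficient: `k* = argmax_k [coph(k) - coph(k+1)]` over
#' consecutive ranks with a positive drop. If no drop is positive, falls
#' back to the rank with the maximal coefficient.
#'
#' @param coph named numeric vector, names are ranks.
#' @return the selected rank (integer).
#' @export
select_k_by_cophenetic_drop <- function(coph) {
  ks <- as.integer(names(coph))
  if (length(ks) < 2) return(ks[1])
  ord <- order(ks)
  ks <- ks[ord]
  v <- as.numeric(coph)[ord]
  drops <- v[-length(v)] - v[-1]
  if (all(drops <= 0)) return(ks[which.max(v)])
  ks[which.max(drops)]
}

#' Extract per-sample NMF programs
#'
#' For each factor of the retained factorization, ranks genes by loading
#' (ties broken lexicographically by gene id for determinism) and records
#' the `top_n` highest-loading genes as the program signature.
#'
#' @param fit a retained factorization (list with `W`, `H`) from
#'   [run_nmf_range()].
#' @param sample_id sample label attached to the programs.
#' @param top_n signature size (default 30).
#' @return list of programs; each is a list with `sample`, `k`, `program`,
#'   `loadings` (named, full), `top_genes`, `degenerate` (TRUE when fewer
#'   than `top_n` loadings are nonzero).
#' @export
extract_programs <- function(fit, sample_id, top_n = 30) {
  W <- fit$W
  k <- ncol(W)
  lapply(seq_len(k), function(j) {
    lo <- W[, j]
    ord <- order(-lo, names(lo))
    top <- names(lo)[ord][seq_len(min(top_n, length(lo)))]
    list(sample = sample_id, k = k, program = j,
         loadings = lo, top_genes = top,
         degenerate = sum(lo > 0) < top_n)
  })
}

# Cut a dendrogram into maximal subtrees whose mean pairwise similarity
# (from `sim`) is >= threshold; remaining leaves become singleton clusters.
.coherent_subtree_cut <- function(hc, sim, threshold) {
  n <- nrow(sim)
  n_merge <- nrow(hc$merge)
  members <- vector("list", n_merge)
  valid <- logical(n_merge)
  parent <- integer(n_merge)
  for (i in seq_len(n_merge)) {
    get <- function(x) if (x < 0) -x else members[[x]]
    a <- hc$merge[i, 1]
    b <- hc$merge[i, 2]
    members[[i]] <- c(get(a), get(b))
    children_ok <- (a < 0 || valid[a]) && (b < 0 || valid[b])
    sub <- sim[members[[i]], members[[i]]]
    valid[i] <- children_ok && mean(sub[upper.tri(sub)]) >= threshold
    if (a > 0) parent[a] <- i
    if (b > 0) parent[b] <- i
  }
  cl <- rep(NA_integer_, n)
  cid <- 0L
  for (i in which(valid)) {
    if (parent[i] == 0 || !valid[parent[i]]) {
      cid <- cid + 1L
      cl[members[[i]]] <- cid
    }
  }
  for (l in which(is.na(cl))) {
    cid <- cid + 1L
    cl[l] <- cid
  }
  cl
}

#' Consolidate per-sample programs into meta-programs
#'
#' Scores every program's signature on every sample's tumor cells
#' ([score_gene_module()]), correlates program scores within each sample,
#' averages the correlation matrices element-wise across samples (over the
#' samples where both programs are scoreable), and clusters programs by Ward
#' linkage on `1 - average correlation`. The dendrogram is cut into highly
#' correlated program sets: clusters are the maximal subtrees whose mean
#' pairwise averaged correlation is at least `min_within_cor` (programs in
#' no such subtree stay singletons). Retained clusters must additionally
#' span at least `min_coverage_fraction` of the samples. Each retained
#' cluster is a meta-program represented by the `sig_size` genes with the
#' highest average (L2-normalized) loading over its members.
#'
#' @param programs flat list of programs from [extract_programs()] across
#'   samples.
#' @param expr_by_sample named list, per sample: raw counts (cells x genes)
#'   of that sample's tumor cells.
#' @param min_coverage_fraction coverage gate (default 0.5).
#' @param min_within_cor coherence threshold defining a highly correlated
#'   program set (default 0.5).
#' @param sig_size meta-program signature size (default 30).
#' @param n_bins,n_ctrl,seed passed to [score_gene_module()].
#' @return list of meta-programs, each a list with `members` (data.frame
#'   `sample`, `program`), `samples_covered`, `signature`; attributes
#'   `avg_correlation` and `clusters` expose the clustering audit trail.
#' @export
derive_meta_programs <- function(programs, expr_by_sample,
                                 min_coverage_fraction = 0.5,
                                 min_within_cor = 0.5, sig_size = 30,
                                 n_bins = 24, n_ctrl = 100, seed = 1L) {
  n_prog <- length(programs)
  samples <- sort(unique(vapply(programs, `[[`, character(1), "sample")))
  if (length(samples) < 2) .stopf("need programs from at least 2 samples")
  prog_id <- vapply(programs, function(p)
    paste0(p$sample, ".P", p$program), character(1))

  cor_sum <- matrix(0, n_prog, n_prog, dimnames = list(prog_id, prog_id))
  cor_n <- matrix(0L, n_prog, n_prog)
  for (s in samples) {
    expr <- expr_by_sample[[s]]
    scores <- vapply(seq_len(n_prog), function(i) {
      gs <- intersect(programs[[i]]$top_genes, colnames(expr))
      if (length(gs) == 0) return(rep(NA_real_, nrow(expr)))
      score_gene_module(expr, gs, n_bins = n_bins, n_ctrl = n_ctrl,
                        seed = seed + i)
    }, numeric(nrow(expr)))
    ok <- which(apply(scores, 2, function(x) !anyNA(x) && sd(x) > 0))
    if (length(ok) < 2) next
    cm <- cor(scores[, ok, drop = FALSE])
    cor_sum[ok, ok] <- cor_sum[ok, ok] + cm
    cor_n[ok, ok] <- cor_n[ok, ok] + 1L
  }
  avg <- cor_sum / pmax(cor_n, 1L)
  avg[cor_n == 0] <- 0
  diag(avg) <- 1

  if (n_prog == 1) {
    cl <- setNames(1L, prog_id)
  } else {
    hc <- hclust(as.dist(1 - avg), method = "ward.D2")
    cl <- .coherent_subtree_cut(hc, avg, min_within_cor)
    names(cl) <- prog_id
  }

  metas <- list()
  for (cid in sort(unique(cl))) {
    members <- which(cl == cid)
    mem_samples <- unique(vapply(programs[members], `[[`, character(1), "sample"))
    if (length(mem_samples) < min_coverage_fraction * length(samples)) next
    load_sum <- NULL
    for (i in members) {
      lo <- programs[[i]]$loadings
      lo <- lo / sqrt(sum(lo^2) + .Machine$double.eps)
      if (is.null(load_sum)) load_sum <- lo else {
        all_g <- union(names(load_sum), names(lo))
        a <- setNames(numeric(length(all_g)), all_g)
        a[names(load_sum)] <- load_sum
        a[names(lo)] <- a[names(lo)] + lo
        load_sum <- a
      }
    }
    avg_load <- load_sum / length(members)
    ord <- order(-avg_load, names(avg_load))
    metas[[length(metas) + 1L]] <- list(
      members = data.frame(
        sample = vapply(programs[members], `[[`, character(1), "sample"),
        program = vapply(programs[members], `[[`, numeric(1), "program"),
        stringsAsFactors = FALSE),
      samples_covered = length(mem_samples),
      signature = names(avg_load)[ord][seq_len(min(sig_size, length(avg_load)))]
    )
  }
  structure(metas, avg_correlation = avg, clusters = cl)
}
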