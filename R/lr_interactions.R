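#' Interaction strength of ligand-receptor pairs between clusters
#'
#' For every ligand-receptor pair and ordered (source, target) cluster pair,
#' the triple is testable when the ligand is expressed (count > 0) in at
#' least `min_frac` of source cells AND the receptor in at least `min_frac`
#' of target cells. Its strength is the average of the mean log-normalized
#' ligand expression in the source and the mean log-normalized receptor
#' expression in the target.
#'
#' @param expr raw counts, cells x genes.
#' @param labels cluster labels.
#' @param pairs data.frame with columns `ligand`, `receptor` (and optionally
#'   `pair`); pairs with genes absent from `expr` are skipped with a warning.
#' @param min_frac expression-fraction gate (default 0.1).
#' @param min_cells clusters smaller than this are excluded (default 10).
#' @param log whether strengths use log1p-normalized expression (default)
#'   or the un-logged normalized scale; [permutation_test()] must be called
#'   with the same setting.
#' @return data.frame of testable triples: `pair`, `ligand`, `receptor`,
#'   `source`, `target`, `mean`.
#' @export
compute_interaction_means <- function(expr, labels, pairs, min_frac = 0.1,
                                      min_cells = 10, log = TRUE) {
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(expr))
  if (is.null(pairs$pair))
    pairs$pair <- paste(pairs$ligand, pairs$receptor, sep = "_")
  present <- pairs$ligand %in% colnames(expr) & pairs$receptor %in% colnames(expr)
  if (any(!present)) {
    warning("skipping ", sum(!present), " pair(s) with genes absent from the matrix")
    pairs <- pairs[present, , drop = FALSE]
  }
  clusters <- names(which(table(labels) >= min_cells))
  clusters <- sort(clusters)
  if (length(clusters) == 0) .stopf("no cluster has >= %d cells", min_cells)
  norm <- normalize_counts(expr, log = log)
  genes <- unique(c(pairs$ligand, pairs$receptor))
  frac <- t(group_means((expr[, genes, drop = FALSE] > 0) * 1, labels))
  mu <- t(group_means(norm[, genes, drop = FALSE], labels))

  grid <- expand.grid(i = seq_len(nrow(pairs)), source = clusters,
                      target = clusters, stringsAsFactors = FALSE)
  lig <- pairs$ligand[grid$i]
  rec <- pairs$receptor[grid$i]
  testable <- frac[cbind(lig, grid$source)] >= min_frac &
    frac[cbind(rec, grid$target)] >= min_frac
  out <- data.frame(
    pair = pairs$pair[grid$i], ligand = lig, receptor = rec,
    source = grid$source, target = grid$target,
    mean = (mu[cbind(lig, grid$source)] + mu[cbind(rec, grid$target)]) / 2,
    stringsAsFactors = FALSE
  )[testable, , drop = FALSE]
  out <- out[order(out$pair, out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster-label permutation test for interaction strength
#'
#' Shuffles cluster labels `n_perm` times (one shared set of shuffles for
#' all triples) and estimates, per triple, the add-one p-value
#' `(1 + #\{permuted mean >= observed mean\}) / (1 + n_perm)` — a
#' permutation-valid estimator that never returns zero.
#'
#' @param expr raw counts, cells x genes.
#' @param labels cluster labels (as used to compute the observed means).
#' @param triples data.frame from [compute_interaction_means()].
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed.
#' @param log expression scale; must match the
#'   [compute_interaction_means()] call that produced `triples`.
#' @return the `triples` data.frame with a `p` column appended.
#' @export
permutation_test <- function(expr, labels, triples, n_perm = 1000, seed = 1L,
                             log = TRUE) {
  stopifnot(n_perm >= 100)
  labels <- as.character(labels)
  genes <- unique(c(triples$ligand, triples$receptor))
  # depth-normalize over the full gene universe first, then subset, so the
  # permuted means are on exactly the scale of the observed means
  norm <- t(as.matrix(normalize_counts(expr, log = log)[, genes, drop = FALSE]))
  clusters <- sort(unique(c(triples$source, triples$target)))
  li <- match(triples$ligand, genes)
  ri <- match(triples$receptor, genes)
  exceed <- integer(nrow(triples))
  obs <- triples$mean
  .with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample(labels)
      ind <- sparseMatrix(i = match(perm, clusters)[perm %in% clusters],
                          j = which(perm %in% clusters), x = 1,
                          dims = c(length(clusters), length(labels)))
      n_in <- Matrix::rowSums(ind)
      M <- as.matrix(norm %*% Matrix::t(ind)) /
        rep(pmax(n_in, 1), each = nrow(norm))
      pm <- (M[cbind(li, match(triples$source, clusters))] +
               M[cbind(ri, match(triples$target, clusters))]) / 2
      exceed <- exceed + (pm >= obs)
    }
  })
  triples$p <- (1 + exceed) / (1 + n_perm)
  triples
}

#' Select significant ligand-receptor interactions
#'
#' Flags triples with `p < p_cut` and `mean >= mean_cut` and tallies the
#' number of significant triples for every (source, target) cluster pair.
#'
#' @param results data.frame from [permutation_test()].
#' @param p_cut,mean_cut significance gates (defaults 0.05 and 1).
#' @return list: `significant` (flagged subset), `results` (all triples with
#'   a `significant` column), `counts` (source x target matrix).
#' @export
select_significant <- function(results, p_cut = 0.05, mean_cut = 1) {
  results$significant <- results$p < p_cut & results$mean >= mean_cut
  clusters <- sort(unique(c(results$source, results$target)))
  counts <- matrix(0L, length(clusters), length(clusters),
                   dimnames = list(clusters, clusters))
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) > 0) {
    tab <- table(factor(sig$source, clusters), factor(sig$target, clusters))
    counts[] <- as.integer(tab)
  }
  list(significant = sig, results = results, counts = counts)
}
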