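#' @importFrom Matrix rowSums colSums t Diagonal readMM writeMM sparseMatrix
#' @importFrom methods as is new
#' @importFrom stats rnbinom rbeta rnorm runif rexp median mad sd cor var
#'   p.adjust pt pnorm wilcox.test hclust cutree cophenetic as.dist dist
#'   quantile setNames aggregate rlnorm
#' @importFrom utils write.table read.table head tail
NULL

# Internal: coerce to dgCMatrix, keep dimnames
.as_sparse <- function(x) {
  if (is(x, "dgCMatrix")) return(x)
  as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Seeded evaluation that restores the caller's RNG state on exit.
.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Depth-normalize a cell-by-feature count matrix
#'
#' Counts are scaled to a fixed total per cell (counts per `scale_factor`)
#' and log1p-transformed, the convention used throughout the pipeline before
#' any statistical testing or averaging.
#'
#' @param counts sparse or dense matrix, cells in rows, features in columns.
#' @param scale_factor target per-cell total (default 1e4).
#' @param log whether to apply log1p after rescaling.
#' @return matrix of the same shape and dimnames.
#' @export
normalize_counts <- function(counts, scale_factor = 1e4, log = TRUE) {
  counts <- .as_sparse(counts)
  tot <- Matrix::rowSums(counts)
  tot[tot == 0] <- 1
  out <- Matrix::Diagonal(x = scale_factor / tot) %*% counts
  if (log) out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  out
}

#' Per-group feature means
#'
#' @param mat matrix, cells in rows, features in columns.
#' @param labels character/factor of length `nrow(mat)`.
#' @return dense matrix, groups x features.
#' @export
group_means <- function(mat, labels) {
  stopifnot(length(labels) == nrow(mat))
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  ind <- sparseMatrix(
    i = match(labels, groups), j = seq_along(labels), x = 1,
    dims = c(length(groups), length(labels))
  )
  n <- table(factor(labels, levels = groups))
  m <- as.matrix(ind %*% mat) / as.numeric(n)
  rownames(m) <- groups
  colnames(m) <- colnames(mat)
  m
}

#' Log-normalized per-cell-type means
#'
#' Convenience wrapper: depth-normalizes (`counts per 10k`, log1p) and then
#' averages within each label. Used for the cross-cell-type expression /
#' accessibility correlations of the cCRE linkage step.
#'
#' @inheritParams group_means
#' @param counts raw counts, cells x features.
#' @param log whether means are taken on log1p-normalized values (default)
#'   or on the un-logged normalized scale.
#' @export
type_means <- function(counts, labels, log = TRUE) {
  group_means(normalize_counts(counts, log = log), labels)
}

# Vectorized two-sided Wilcoxon rank-sum, one feature vector against a
# two-group split, normal approximation with tie and continuity correction.
# Matches stats::wilcox.test(x, y, exact = FALSE, correct = TRUE).
# x: numeric matrix cells x features; in_group: logical of length nrow(x).
.ranksum_p <- function(x, in_group) {
  n1 <- sum(in_group)
  n2 <- sum(!in_group)
  n <- n1 + n2
  p <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    r <- rank(v)
    W <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    nties <- table(v)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- W - n1 * n2 / 2
    z <- z - sign(z) * 0.5
    2 * pnorm(-abs(z) / sqrt(sigma2))
  }, numeric(1))
  pmin(p, 1)
}
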