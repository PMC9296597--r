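#' @import GenomicRanges
#' @importFrom IRanges IRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

# Peak midpoints as width-1 GRanges. Coordinates are 0-based half-open
# throughout the package; GRanges positions are 1-based closed, so a 0-based
# position p maps to p + 1.
.peak_midpoints <- function(peaks) {
  mid <- floor((peaks$start + peaks$end) / 2)
  GRanges(peaks$chrom, IRanges(mid + 1L, width = 1L))
}

# Half-open [a, b) interval (0-based) as GRanges
.granges_halfopen <- function(chrom, a, b) {
  GRanges(chrom, IRanges(pmin(a, b - 1) + 1L, pmax(b, a + 1)))
}

#' Gene-activity scores from peak accessibility
#'
#' The activity of a gene in a cell is the sum of ATAC counts over peaks
#' whose midpoint falls in the gene body extended 2 kb upstream of the
#' transcriptional start site (strand-aware).
#'
#' @param atac sparse counts, cells x peaks.
#' @param peaks data.frame with `peak`, `chrom`, `start`, `end` (0-based
#'   half-open), aligned with `colnames(atac)`.
#' @param genes data.frame gene models: `gene`, `chrom`, `strand`, `tss`,
#'   `start`, `end`.
#' @param upstream bp added upstream of the TSS (default 2000).
#' @return sparse matrix, cells x genes.
#' @export
gene_activity_scores <- function(atac, peaks, genes, upstream = 2000) {
  stopifnot(identical(colnames(atac), peaks$peak))
  if (!all(genes$strand %in% c("+", "-")))
    .stopf("unknown strand symbol: %s",
           paste(setdiff(unique(genes$strand), c("+", "-")), collapse = ", "))
  a <- ifelse(genes$strand == "+", genes$start - upstream, genes$start)
  b <- ifelse(genes$strand == "+", genes$end, genes$end + upstream)
  regions <- .granges_halfopen(genes$chrom, a, b)
  ov <- findOverlaps(.peak_midpoints(peaks), regions)
  assign_mat <- sparseMatrix(
    i = queryHits(ov), j = subjectHits(ov), x = 1,
    dims = c(nrow(peaks), nrow(genes)),
    dimnames = list(peaks$peak, genes$gene)
  )
  .as_sparse(atac %*% assign_mat)
}

#' Annotate peaks by genomic context
#'
#' A peak is `promoter` if its midpoint lies within 1 kb of any TSS
#' (promoter takes precedence), else `gene_body` if the midpoint lies inside
#' any gene body, else `distal`.
#'
#' @inheritParams gene_activity_scores
#' @param promoter_dist promoter half-window around the TSS in bp.
#' @return character vector of categories, one per peak.
#' @export
annotate_peaks <- function(peaks, genes, promoter_dist = 1000) {
  mids <- .peak_midpoints(peaks)
  prom <- GRanges(genes$chrom,
                  IRanges(genes$tss - promoter_dist + 1L, genes$tss + promoter_dist + 1L))
  body <- .granges_halfopen(genes$chrom, genes$start, genes$end)
  out <- rep("distal", nrow(peaks))
  out[unique(queryHits(findOverlaps(mids, body)))] <- "gene_body"
  out[unique(queryHits(findOverlaps(mids, prom)))] <- "promoter"
  out
}

# Per-peak gene sets by context: genes whose promoter window contains the
# peak midpoint, and genes whose body contains it.
.peak_gene_context <- function(peaks, genes, promoter_dist = 1000) {
  mids <- .peak_midpoints(peaks)
  prom <- GRanges(genes$chrom,
                  IRanges(genes$tss - promoter_dist + 1L, genes$tss + promoter_dist + 1L))
  body <- .granges_halfopen(genes$chrom, genes$start, genes$end)
  ovp <- findOverlaps(mids, prom)
  ovb <- findOverlaps(mids, body)
  list(
    promoter = split(genes$gene[subjectHits(ovp)], peaks$peak[queryHits(ovp)]),
    body = split(genes$gene[subjectHits(ovb)], peaks$peak[queryHits(ovb)])
  )
}

#' One-vs-rest differential features (DEGs / DARs)
#'
#' For every group with at least `min_cells` cells, tests each feature with a
#' two-sided Wilcoxon rank-sum on depth-normalized values (counts per 10k;
#' the log1p transform used elsewhere is rank-preserving). The fold change is
#' `log2((m_in + 1) / (m_out + 1))` with `m` the group mean of normalized
#' counts. P values are Bonferroni-corrected over all features x groups
#' tested; rows are returned iff `p_adj < alpha` and `log2fc > min_log2fc`.
#'
#' @param counts sparse counts, cells x features.
#' @param labels cell group labels, length `nrow(counts)`.
#' @param min_log2fc fold-change gate (default 0.25).
#' @param alpha adjusted-significance gate (default 0.05).
#' @param min_cells smallest group size tested (smaller groups are skipped
#'   with a warning).
#' @return data.frame: `feature`, `group`, `log2fc`, `p`, `p_adj`,
#'   `direction`.
#' @export
find_differential_features <- function(counts, labels, min_log2fc = 0.25,
                                       alpha = 0.05, min_cells = 3) {
  stopifnot(length(labels) == nrow(counts))
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2) .stopf("need at least two groups")
  small <- groups[table(factor(labels, levels = groups)) < min_cells]
  if (length(small) > 0) {
    warning("skipping groups with fewer than ", min_cells, " cells: ",
            paste(small, collapse = ", "))
    groups <- setdiff(groups, small)
  }
  norm <- as.matrix(normalize_counts(counts, log = FALSE))
  res <- do.call(rbind, lapply(groups, function(g) {
    ing <- labels == g
    m_in <- colMeans(norm[ing, , drop = FALSE])
    m_out <- colMeans(norm[!ing, , drop = FALSE])
    data.frame(feature = colnames(counts), group = g,
               log2fc = log2((m_in + 1) / (m_out + 1)),
               p = .ranksum_p(norm, ing),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  res$p_adj <- pmin(res$p * nrow(res), 1)
  res$direction <- ifelse(res$log2fc >= 0, "up", "down")
  res <- res[res$p_adj < alpha & res$log2fc > min_log2fc, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Proportion of DARs associated with a same-group DEG
#'
#' A differentially accessible region counts as associated when its peak lies
#' in the promoter or gene body of a gene that is differentially expressed in
#' the same group, or when it is linked to such a gene by a candidate
#' cis-regulatory element.
#'
#' @param dars,degs outputs of [find_differential_features()] on the ATAC
#'   peaks and RNA genes respectively, computed on the same group labels.
#' @param peaks,genes annotations as elsewhere.
#' @param ccre_links data.frame with columns `peak`, `gene` (may be empty or
#'   `NULL`).
#' @return list: `per_group` named proportions, `mean`, `sd` (sample SD
#'   across groups).
#' @export
dar_deg_association <- function(dars, degs, peaks, genes, ccre_links = NULL) {
  ctx <- .peak_gene_context(peaks, genes)
  link_map <- if (!is.null(ccre_links) && nrow(ccre_links) > 0)
    split(ccre_links$gene, ccre_links$peak) else list()
  groups <- sort(unique(dars$group))
  per_group <- vapply(groups, function(g) {
    pk <- dars$feature[dars$group == g]
    if (length(pk) == 0) return(0)
    deg_g <- degs$feature[degs$group == g]
    hit <- vapply(pk, function(p) {
      genes_near <- c(ctx$promoter[[p]], ctx$body[[p]], link_map[[p]])
      length(intersect(genes_near, deg_g)) > 0
    }, logical(1))
    mean(hit)
  }, numeric(1))
  names(per_group) <- groups
  list(per_group = per_group, mean = mean(per_group),
       sd = if (length(per_group) > 1) sd(per_group) else NA_real_)
}
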