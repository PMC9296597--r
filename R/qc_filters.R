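#' Per-cell RNA quality-control gate
#'
#' Keeps cells with a detected gene number between 200 and 6000 (inclusive),
#' more than 1000 UMIs, and a mitochondrial read fraction of at most 10%.
#' High-mitochondrial cells are excluded: retaining them would contradict the
#' purpose of removing low-quality cells (see the methods vignette for the
#' reading of the mitochondrial criterion).
#'
#' @param metrics data.frame with columns `cell`, `n_genes`, `n_umi`,
#'   `mito_fraction`.
#' @param min_genes,max_genes,min_umi,max_mito gate values.
#' @param audit if `TRUE`, return a data.frame with one row per cell and a
#'   logical column per gate plus the overall `keep` flag, instead of ids.
#' @return character vector of kept cell ids (input order preserved), or the
#'   audit data.frame.
#' @export
filter_rna_cells <- function(metrics, min_genes = 200, max_genes = 6000,
                             min_umi = 1000, max_mito = 0.10, audit = FALSE) {
  stopifnot(nrow(metrics) > 0,
            all(c("cell", "n_genes", "n_umi", "mito_fraction") %in% names(metrics)))
  gates <- data.frame(
    cell = metrics$cell,
    pass_gene_lower = metrics$n_genes >= min_genes,
    pass_gene_upper = metrics$n_genes <= max_genes,
    pass_umi = metrics$n_umi > min_umi,
    pass_mito = metrics$mito_fraction <= max_mito,
    stringsAsFactors = FALSE
  )
  gates$keep <- gates$pass_gene_lower & gates$pass_gene_upper &
    gates$pass_umi & gates$pass_mito
  if (audit) return(gates)
  metrics$cell[gates$keep]
}

#' Per-cell ATAC quality-control gate
#'
#' Keeps cells with peak-region fragments strictly between 1000 and 20000,
#' fraction of reads in peaks above 0.15, blacklist ratio below 0.05,
#' nucleosome signal below 4 and TSS enrichment above 3. Inequalities are
#' strict, matching the printed thresholds.
#'
#' @param metrics data.frame with columns `cell`, `peak_region_fragments`,
#'   `frip`, `blacklist_ratio`, `nucleosome_signal`, `tss_enrichment`.
#' @param min_frag,max_frag,min_frip,max_blacklist,max_nucleosome,min_tss
#'   gate values.
#' @param audit as in [filter_rna_cells()].
#' @return character vector of kept cell ids, or the audit data.frame.
#' @export
filter_atac_cells <- function(metrics, min_frag = 1000, max_frag = 20000,
                              min_frip = 0.15, max_blacklist = 0.05,
                              max_nucleosome = 4, min_tss = 3, audit = FALSE) {
  stopifnot(nrow(metrics) > 0,
            all(c("cell", "peak_region_fragments", "frip", "blacklist_ratio",
                  "nucleosome_signal", "tss_enrichment") %in% names(metrics)))
  gates <- data.frame(
    cell = metrics$cell,
    pass_frag_lower = metrics$peak_region_fragments > min_frag,
    pass_frag_upper = metrics$peak_region_fragments < max_frag,
    pass_frip = metrics$frip > min_frip,
    pass_blacklist = metrics$blacklist_ratio < max_blacklist,
    pass_nucleosome = metrics$nucleosome_signal < max_nucleosome,
    pass_tss = metrics$tss_enrichment > min_tss,
    stringsAsFactors = FALSE
  )
  gates$keep <- Reduce(`&`, gates[, -1])
  if (audit) return(gates)
  metrics$cell[gates$keep]
}

#' Jaccard consistency index between two cell labelings
#'
#' For every pair of labels (x from labeling A, y from labeling B) computes
#' `|cells(A=x) and cells(B=y)| / |cells(A=x) or cells(B=y)|`, the overlap
#' statistic used to compare predicted and curated cell-type annotations.
#'
#' @param labels_a,labels_b named character vectors (names are cell ids) over
#'   the same cell universe.
#' @return numeric matrix, labels of A in rows, labels of B in columns.
#' @export
jaccard_index <- function(labels_a, labels_b) {
  if (is.null(names(labels_a)) || is.null(names(labels_b)))
    .stopf("labelings must be named by cell id")
  common <- intersect(names(labels_a), names(labels_b))
  if (length(common) == 0)
    .stopf("cell universes of the two labelings are disjoint")
  if (!setequal(names(labels_a), names(labels_b)))
    .stopf("labelings must cover the same cell universe")
  a <- labels_a[common]
  b <- labels_b[common]
  la <- sort(unique(a))
  lb <- sort(unique(b))
  out <- matrix(0, length(la), length(lb), dimnames = list(la, lb))
  for (x in la) {
    sa <- common[a == x]
    for (y in lb) {
      sb <- common[b == y]
      out[x, y] <- length(intersect(sa, sb)) / length(union(sa, sb))
    }
  }
  out
}
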