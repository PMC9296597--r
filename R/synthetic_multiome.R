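#' Configuration for the synthetic paired multiome generator
#'
#' Returns a validated configuration list for [generate_multiome()]. The
#' defaults describe the study conditions the package is validated under:
#' three tumor samples, four annotated cell types (one of them malignant),
#' 100 cells per type per sample, a compact two-chromosome genome with 200
#' genes and 200 accessible peaks, 20 scanned motifs of which 3 are planted
#' tumor-specific regulators with a 3x accessibility gain, 20 planted distal
#' peak-gene cCREs, and two intratumoral expression programs shared across
#' samples plus one private program per sample.
#'
#' @param n_samples number of tumor samples.
#' @param n_cell_types number of annotated cell types; the first is "tumor".
#' @param cells_per_type_per_sample cells simulated per type per sample.
#' @param n_genes,n_peaks,n_motifs dimensions of the annotation universe.
#' @param n_tumor_specific_motifs motifs planted with tumor-restricted
#'   accessibility gain.
#' @param tumor_motif_effect accessibility multiplier (>= 1) applied to the
#'   planted tumor-motif peaks in tumor cells.
#' @param tumor_peaks_per_motif peaks carrying each tumor motif, drawn from
#'   the shared tumor-restricted pool.
#' @param tumor_peak_pool size of the shared pool of tumor-restricted peaks;
#'   planted tumor motifs overlap within it, emulating the family-level
#'   binding redundancy of tumor-specific regulators.
#' @param n_planted_ccres planted distal-peak/gene cis-regulatory links.
#' @param ccre_effect co-regulation strength in \[0, 1\] between a planted
#'   distal peak and its gene (1 = identical programmed cell-type profile;
#'   count-level noise still applies).
#' @param n_programs intratumoral expression programs shared by all samples.
#' @param n_private_programs additional sample-private programs.
#' @param program_size genes per program (>= 30).
#' @param program_cell_fraction fraction of each sample's tumor cells
#'   assigned to each program (programs are disjoint within a sample).
#' @param program_effect expression multiplier on a program's genes in its
#'   cells.
#' @param nb_dispersion negative-binomial dispersion of RNA counts
#'   (var = mu + a mu^2); captures transcriptional bursting.
#' @param atac_dispersion negative-binomial dispersion of ATAC counts;
#'   accessibility counts carry much less biological overdispersion than
#'   transcript counts, so the default is lower.
#' @param depth_lognormal_params c(meanlog, sdlog) of per-cell depth factors.
#' @param n_lr_pairs planted ligand-receptor cluster pairs.
#' @param seed integer seed; all outputs are deterministic given the config.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 3,
                             n_cell_types = 4,
                             cells_per_type_per_sample = 100,
                             n_genes = 200,
                             n_peaks = 200,
                             n_motifs = 20,
                             n_tumor_specific_motifs = 3,
                             tumor_motif_effect = 3,
                             tumor_peaks_per_motif = 20,
                             tumor_peak_pool = 30,
                             n_planted_ccres = 20,
                             ccre_effect = 1.0,
                             n_programs = 2,
                             n_private_programs = 1,
                             program_size = 30,
                             program_cell_fraction = 0.33,
                             program_effect = 4,
                             nb_dispersion = 0.5,
                             atac_dispersion = 0.2,
                             depth_lognormal_params = c(0, 0.4),
                             n_lr_pairs = 3,
                             seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

#' @rdname synthetic_config
#' @param config a `synthetic_config` list.
#' @export
validate_synthetic_config <- function(config) {
  with(config, {
    if (n_samples < 1 || n_cell_types < 2 || cells_per_type_per_sample < 1)
      .stopf("need >= 1 sample, >= 2 cell types and >= 1 cell per type")
    if (tumor_motif_effect < 1)
      .stopf("tumor_motif_effect must be >= 1 (got %g)", tumor_motif_effect)
    if (program_size < 30)
      .stopf("program_size must be >= 30 (got %d)", program_size)
    if (ccre_effect < 0 || ccre_effect > 1)
      .stopf("ccre_effect must lie in [0, 1]")
    if (nb_dispersion <= 0) .stopf("nb_dispersion must be > 0")
    if (atac_dispersion <= 0) .stopf("atac_dispersion must be > 0")
    if (program_cell_fraction < 0 || program_cell_fraction > 1)
      .stopf("program_cell_fraction must lie in [0, 1]")
    n_prog_total <- n_programs + n_private_programs
    if (n_prog_total * program_cell_fraction > 1)
      .stopf("programs per sample (%d) x program_cell_fraction (%g) exceeds 1",
             n_prog_total, program_cell_fraction)
    n_markers <- 5L * n_cell_types
    need_genes <- (n_programs + n_samples * n_private_programs) * program_size +
      n_planted_ccres + n_markers
    if (need_genes > n_genes)
      .stopf(paste0("infeasible config: program, cCRE and marker genes need ",
                    "%d genes but n_genes = %d"), need_genes, n_genes)
    n_promoter <- floor(n_peaks / 2)
    n_distal <- n_peaks - n_promoter
    if (n_planted_ccres > n_distal)
      .stopf("infeasible config: n_planted_ccres (%d) exceeds available distal peaks (%d)",
             n_planted_ccres, n_distal)
    if (n_planted_ccres > n_promoter)
      .stopf("infeasible config: n_planted_ccres (%d) exceeds available promoter peaks (%d)",
             n_planted_ccres, n_promoter)
    if (tumor_peaks_per_motif > tumor_peak_pool)
      .stopf("tumor_peaks_per_motif (%d) exceeds tumor_peak_pool (%d)",
             tumor_peaks_per_motif, tumor_peak_pool)
    if (tumor_peak_pool > n_distal - n_planted_ccres)
      .stopf(paste0("infeasible config: tumor peak pool (%d) exceeds distal ",
                    "peaks left after cCREs (%d)"),
             tumor_peak_pool, n_distal - n_planted_ccres)
    if (n_tumor_specific_motifs > n_motifs)
      .stopf("n_tumor_specific_motifs exceeds n_motifs")
    if (n_lr_pairs > n_cell_types * (n_cell_types - 1))
      .stopf("n_lr_pairs exceeds the number of ordered type pairs")
  })
  invisible(config)
}

#' Generate a paired synthetic multiome with planted ground truth
#'
#' Simulates paired RNA and ATAC count matrices over discrete cell types with
#' negative-binomial (gamma-Poisson) noise and lognormal per-cell depths,
#' together with all annotations the downstream stages consume, and a ground
#' truth record of everything that was planted:
#' * per-type marker genes and, for tumor cells, elevated accessibility at
#'   the peaks carrying the planted tumor-specific motifs;
#' * planted cCREs: a distal peak and a gene (with a promoter peak whose
#'   midpoint lies within 1 kb of the TSS) sharing a cell-type activity
#'   profile with correlation strength `ccre_effect`;
#' * intratumoral expression programs (shared across samples and private),
#'   each over-expressed by `program_cell_fraction` of the sample's tumor
#'   cells;
#' * ligand-receptor pairs between annotated source/target types;
#' * per-peak GC fractions drawn from a Beta(2, 2) distribution.
#'
#' Coordinates are 0-based half-open over two synthetic chromosomes.
#'
#' @param config a [synthetic_config()] list.
#' @return list with elements `rna` and `atac` (sparse cells x features
#'   counts), `peaks` (data.frame: peak, chrom, start, end, gc, category),
#'   `motifs` (sparse binary peaks x motifs), `genes` (data.frame gene
#'   model), `cells` (cell annotation + QC metrics), `truth` (planted ground
#'   truth), `lr_table` (planted + decoy ligand-receptor pairs).
#' @export
generate_multiome <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  .with_seed(config$seed, .generate_multiome_impl(config))
}

.generate_multiome_impl <- function(cfg) {
  n_types <- cfg$n_cell_types
  types <- c("tumor", paste0("type", seq_len(n_types - 1)))
  samples <- paste0("S", seq_len(cfg$n_samples))

  ## ---- gene models on two chromosomes -------------------------------------
  spacing <- 40000L
  per_chrom <- ceiling(cfg$n_genes / 2)
  chrom <- rep(c("chr1", "chr2"), times = c(per_chrom, cfg$n_genes - per_chrom))
  idx_within <- unlist(lapply(table(chrom)[unique(chrom)], seq_len), use.names = FALSE)
  tss <- 50000L + (idx_within - 1L) * spacing +
    as.integer(floor(runif(cfg$n_genes, 0, 2000)))
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  blen <- as.integer(floor(runif(cfg$n_genes, 2000, 8000)))
  gstart <- ifelse(strand == "+", tss, tss - blen)
  gend <- ifelse(strand == "+", tss + blen, tss)
  gene_ids <- sprintf("gene%03d", seq_len(cfg$n_genes))
  genes <- data.frame(gene = gene_ids, chrom = chrom, strand = strand,
                      tss = tss, start = gstart, end = gend,
                      stringsAsFactors = FALSE)

  ## ---- reserve gene roles -------------------------------------------------
  pool <- sample(gene_ids)
  take <- function(n) {
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  shared_prog <- lapply(seq_len(cfg$n_programs), function(i) sort(take(cfg$program_size)))
  names(shared_prog) <- paste0("MP", seq_len(cfg$n_programs))
  private_prog <- list()
  for (s in samples) {
    private_prog[[s]] <- lapply(seq_len(cfg$n_private_programs),
                                function(i) sort(take(cfg$program_size)))
    if (cfg$n_private_programs > 0)
      names(private_prog[[s]]) <- paste0(s, "_private", seq_len(cfg$n_private_programs))
  }
  ccre_genes <- take(cfg$n_planted_ccres)
  markers <- lapply(seq_len(n_types), function(i) take(5L))
  names(markers) <- types

  ## ---- peaks --------------------------------------------------------------
  n_promoter <- floor(cfg$n_peaks / 2)
  n_distal <- cfg$n_peaks - n_promoter
  prom_genes <- c(ccre_genes,
                  sample(setdiff(gene_ids, ccre_genes), n_promoter - cfg$n_planted_ccres))
  gi <- match(prom_genes, gene_ids)
  prom_mid <- genes$tss[gi] + as.integer(floor(runif(n_promoter, -300, 300)))
  # planted cCRE distal partners sit 9-15 kb downstream of their gene's TSS,
  # always intergenic at the 40 kb gene spacing used here
  ccre_gi <- match(ccre_genes, gene_ids)
  ccre_mid <- genes$tss[ccre_gi] + as.integer(floor(runif(cfg$n_planted_ccres, 9000, 15000)))
  other_distal_genes <- sample(gene_ids, n_distal - cfg$n_planted_ccres, replace = FALSE)
  od_gi <- match(other_distal_genes, gene_ids)
  od_mid <- genes$tss[od_gi] + as.integer(floor(runif(length(od_gi), 16000, 20000)))
  mids <- c(prom_mid, ccre_mid, od_mid)
  pk_chrom <- c(genes$chrom[gi], genes$chrom[ccre_gi], genes$chrom[od_gi])
  half <- 200L
  peak_ids <- sprintf("peak%03d", seq_len(cfg$n_peaks))
  peaks <- data.frame(peak = peak_ids, chrom = pk_chrom,
                      start = mids - half, end = mids + half,
                      gc = rbeta(cfg$n_peaks, 2, 2),
                      stringsAsFactors = FALSE)
  prom_peak_ids <- peak_ids[seq_len(n_promoter)]
  ccre_peak_ids <- peak_ids[n_promoter + seq_len(cfg$n_planted_ccres)]
  free_distal <- peak_ids[(n_promoter + cfg$n_planted_ccres + 1):cfg$n_peaks]
  promoter_of <- setNames(prom_peak_ids, prom_genes)

  ## ---- motifs -------------------------------------------------------------
  motif_ids <- sprintf("M%02d", seq_len(cfg$n_motifs))
  tumor_motifs <- sort(sample(motif_ids, cfg$n_tumor_specific_motifs))
  # planted motifs share one pool of tumor-restricted peaks (family-level
  # binding redundancy); each motif hits a subset of the pool
  pool_peaks <- sample(free_distal, cfg$tumor_peak_pool)
  tumor_peaks <- lapply(seq_len(cfg$n_tumor_specific_motifs), function(i)
    sort(sample(pool_peaks, cfg$tumor_peaks_per_motif)))
  names(tumor_peaks) <- tumor_motifs
  # null motifs draw their hits from peaks that carry no planted signal, so
  # the only motifs with planted cell-type behavior are the recorded truth
  null_pool <- setdiff(peak_ids, c(pool_peaks, ccre_peak_ids,
                                   unname(promoter_of[ccre_genes])))
  hits <- matrix(0L, cfg$n_peaks, cfg$n_motifs, dimnames = list(peak_ids, motif_ids))
  for (m in motif_ids) {
    if (m %in% tumor_motifs) {
      hits[tumor_peaks[[m]], m] <- 1L
    } else {
      repeat {
        h <- null_pool[runif(length(null_pool)) < 0.1]
        if (length(h) > 0) break
      }
      hits[h, m] <- 1L
    }
  }
  motifs <- .as_sparse(hits)
  tf_genes <- setNames(paste0("TF_", motif_ids), motif_ids)

  ## ---- cells --------------------------------------------------------------
  cells <- expand.grid(cell_type = types, sample = samples,
                       idx = seq_len(cfg$cells_per_type_per_sample),
                       stringsAsFactors = FALSE)
  cells <- cells[order(cells$sample, cells$cell_type, cells$idx), ]
  cells$cell <- sprintf("%s_%s_%03d", cells$sample, cells$cell_type, cells$idx)
  rownames(cells) <- NULL
  n_cells <- nrow(cells)
  tix <- match(cells$cell_type, types)

  ## ---- planted cell-type activity profiles --------------------------------
  gene_mult <- matrix(exp(rnorm(n_types * cfg$n_genes, 0, 0.2)),
                      n_types, cfg$n_genes, dimnames = list(types, gene_ids))
  peak_mult <- matrix(exp(rnorm(n_types * cfg$n_peaks, 0, 0.15)),
                      n_types, cfg$n_peaks, dimnames = list(types, peak_ids))
  for (t in types) gene_mult[t, markers[[t]]] <- gene_mult[t, markers[[t]]] * 8
  rho <- cfg$ccre_effect
  for (i in seq_len(cfg$n_planted_ccres)) {
    # planted regulatory activity spans an active-to-silent gradient across
    # cell types (permuted ladder) so every planted link varies enough to be
    # detectable; ccre_effect < 1 mixes in independent peak-side noise
    z <- sample(seq(-1.5, 1.5, length.out = n_types))
    w <- rho * z + sqrt(1 - rho^2) * rnorm(n_types, 0, 1)
    g <- ccre_genes[i]
    gene_mult[, g] <- exp(z)
    peak_mult[, ccre_peak_ids[i]] <- exp(w)
    peak_mult[, promoter_of[[g]]] <- exp(z)
  }
  # tumor-specific peaks gain tumor_motif_effect in tumor cells, then every
  # planted peak is rescaled so its POOLED mean matches the background peak
  # distribution: a cell-type-specific peak is closed elsewhere rather than
  # globally brighter, and the planted signal must live in the cell-type
  # contrast, not in the pooled mean the background matching conditions on
  pooled_gain <- (cfg$tumor_motif_effect + (n_types - 1)) / n_types
  peak_mult["tumor", pool_peaks] <-
    peak_mult["tumor", pool_peaks] * cfg$tumor_motif_effect
  peak_mult[, pool_peaks] <- peak_mult[, pool_peaks] / pooled_gain

  ## ---- intratumoral programs ----------------------------------------------
  prog_boost <- matrix(1, n_cells, cfg$n_genes, dimnames = list(cells$cell, gene_ids))
  program_genes <- list()
  program_cells <- list()
  for (s in samples) {
    tcells <- cells$cell[cells$sample == s & cells$cell_type == "tumor"]
    tcells <- sample(tcells)
    per_prog <- floor(length(tcells) * cfg$program_cell_fraction)
    progs <- c(shared_prog, private_prog[[s]])
    program_genes[[s]] <- progs
    program_cells[[s]] <- list()
    off <- 0L
    for (p in names(progs)) {
      idx <- tcells[seq_len(per_prog) + off]
      off <- off + per_prog
      prog_boost[idx, progs[[p]]] <- cfg$program_effect
      program_cells[[s]][[p]] <- idx
    }
  }

  ## ---- ligand-receptor planting -------------------------------------------
  type_pairs <- expand.grid(source = types, target = types, stringsAsFactors = FALSE)
  type_pairs <- type_pairs[type_pairs$source != type_pairs$target, ]
  type_pairs <- type_pairs[sample(nrow(type_pairs), cfg$n_lr_pairs), ]
  lr_truth <- data.frame(
    ligand = vapply(type_pairs$source, function(t) markers[[t]][1], character(1)),
    receptor = vapply(type_pairs$target, function(t) markers[[t]][2], character(1)),
    source = type_pairs$source, target = type_pairs$target,
    stringsAsFactors = FALSE, row.names = NULL
  )

  ## ---- counts -------------------------------------------------------------
  depth_rna <- rlnorm(n_cells, cfg$depth_lognormal_params[1], cfg$depth_lognormal_params[2])
  depth_atac <- rlnorm(n_cells, cfg$depth_lognormal_params[1], cfg$depth_lognormal_params[2])
  # per-feature base rates calibrated so per-cell totals sit inside the QC
  # bands the filters expect (roughly 2000 UMIs and 1400 ATAC fragments)
  lambda_g <- rlnorm(cfg$n_genes, log(6), 1)
  beta_p <- c(rlnorm(n_promoter, log(8), 0.5), rlnorm(n_distal, log(5), 0.5))
  mu_rna <- (depth_rna * gene_mult[tix, , drop = FALSE]) *
    rep(lambda_g, each = n_cells) * prog_boost
  rna <- matrix(rnbinom(length(mu_rna), mu = mu_rna, size = 1 / cfg$nb_dispersion),
                n_cells, cfg$n_genes, dimnames = list(cells$cell, gene_ids))
  mu_atac <- (depth_atac * peak_mult[tix, , drop = FALSE]) * rep(beta_p, each = n_cells)
  atac <- matrix(rnbinom(length(mu_atac), mu = mu_atac, size = 1 / cfg$atac_dispersion),
                 n_cells, cfg$n_peaks, dimnames = list(cells$cell, peak_ids))

  ## ---- QC metrics (simulated at realistic sequencing scale) ---------------
  qc_ngenes <- pmax(50L, as.integer(round(rlnorm(n_cells, log(2000), 0.4))))
  cells$n_genes <- pmin(qc_ngenes, 8000L)
  cells$n_umi <- as.integer(round(cells$n_genes * runif(n_cells, 2, 6)))
  cells$mito_fraction <- rbeta(n_cells, 2, 38)
  cells$peak_region_fragments <- as.integer(round(rlnorm(n_cells, log(5000), 0.6)))
  cells$frip <- rbeta(n_cells, 40, 60)
  cells$blacklist_ratio <- rbeta(n_cells, 1, 99)
  cells$nucleosome_signal <- rlnorm(n_cells, log(2), 0.3)
  cells$tss_enrichment <- rlnorm(n_cells, log(5), 0.3)
  cells$idx <- NULL
  cells <- cells[, c("cell", "sample", "cell_type", "n_genes", "n_umi",
                     "mito_fraction", "peak_region_fragments", "frip",
                     "blacklist_ratio", "nucleosome_signal", "tss_enrichment")]

  ## ---- decoy LR pairs -----------------------------------------------------
  decoy_pool <- setdiff(gene_ids, c(lr_truth$ligand, lr_truth$receptor))
  n_decoy <- 30L
  decoys <- data.frame(ligand = sample(decoy_pool, n_decoy),
                       receptor = sample(decoy_pool, n_decoy),
                       stringsAsFactors = FALSE)
  decoys <- decoys[decoys$ligand != decoys$receptor, ]
  lr_table <- unique(rbind(lr_truth[, c("ligand", "receptor")], decoys))
  lr_table$pair <- paste(lr_table$ligand, lr_table$receptor, sep = "_")
  rownames(lr_table) <- NULL

  truth <- list(
    tumor_specific_motifs = tumor_motifs,
    tumor_motif_peaks = tumor_peaks,
    ccre_links = data.frame(peak = ccre_peak_ids, gene = ccre_genes,
                            promoter_peak = unname(promoter_of[ccre_genes]),
                            stringsAsFactors = FALSE),
    program_genes = program_genes,
    program_cells = program_cells,
    meta_program_genes = shared_prog,
    marker_genes = markers,
    lr_pairs = lr_truth,
    tf_genes = tf_genes
  )
  peaks$category <- annotate_peaks(peaks, genes)

  list(rna = .as_sparse(rna), atac = .as_sparse(atac), peaks = peaks,
       motifs = motifs, genes = genes, cells = cells, truth = truth,
       lr_table = lr_table)
}

#' Simulate a drug-perturbation Z-score screen
#'
#' Builds a drugs x genes matrix of differential-expression Z-scores with a
#' standard-normal background, plants effective drugs that strongly
#' down-regulate (Z < -2) the TF gene of each planted tumor-specific motif,
#' and returns an approved-drug list containing at least one effective drug
#' per planted TF.
#'
#' @param truth ground truth from [generate_multiome()].
#' @param n_drugs,n_genes matrix dimensions; gene columns include every
#'   motif's TF gene plus filler genes.
#' @param n_effective_per_tf effective drugs planted per tumor motif.
#' @param seed integer seed.
#' @return list with `z` (drugs x genes matrix), `approved` (character),
#'   `effective_drugs` (named list: tumor motif -> drug ids).
#' @export
generate_drug_zscores <- function(truth, n_drugs = 50, n_genes = 100,
                                  n_effective_per_tf = 2, seed = 1L) {
  tf_all <- unname(truth$tf_genes)
  need <- length(truth$tumor_specific_motifs) * n_effective_per_tf
  if (n_drugs < need)
    .stopf("n_drugs (%d) is smaller than the %d planted effective drugs",
           n_drugs, need)
  if (n_genes < length(tf_all))
    .stopf("n_genes must cover the %d TF genes", length(tf_all))
  .with_seed(seed, {
    drug_ids <- sprintf("drug%03d", seq_len(n_drugs))
    gene_cols <- c(tf_all, sprintf("DG%03d", seq_len(n_genes - length(tf_all))))
    z <- matrix(rnorm(n_drugs * n_genes), n_drugs, n_genes,
                dimnames = list(drug_ids, gene_cols))
    eff_pool <- sample(drug_ids, need)
    effective <- split(eff_pool,
                       rep(truth$tumor_specific_motifs, each = n_effective_per_tf))
    for (m in names(effective))
      z[effective[[m]], truth$tf_genes[[m]]] <- runif(n_effective_per_tf, -6, -2.5)
    guaranteed <- vapply(effective, `[`, character(1), 1)
    others <- setdiff(drug_ids, unlist(effective))
    approved <- sort(unique(c(unlist(effective),
                              sample(others, floor(length(others) / 2)))))
    list(z = z, approved = approved, effective_drugs = effective,
         guaranteed_approved = guaranteed)
  })
}

#' Write a synthetic multiome to disk in standard text formats
#'
#' Matrices go out as Matrix Market `.mtx` with `features.tsv` /
#' `barcodes.tsv` sidecars, peaks as 6-column BED plus a `gc.tsv` sidecar,
#' gene models and cell annotations as TSV, and the ground truth as JSON.
#'
#' @param sim output of [generate_multiome()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_multiome <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_mm <- function(mat, stem) {
    Matrix::writeMM(mat, p(paste0(stem, ".mtx")))
    writeLines(colnames(mat), p(paste0(stem, "_features.tsv")))
    writeLines(rownames(mat), p(paste0(stem, "_barcodes.tsv")))
  }
  write_mm(sim$rna, "rna")
  write_mm(sim$atac, "atac")
  write_mm(sim$motifs, "motifs")
  bed <- data.frame(sim$peaks$chrom, sim$peaks$start, sim$peaks$end,
                    sim$peaks$peak, 0L, ".")
  write.table(bed, p("peaks.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(sim$peaks[, c("peak", "gc")], p("peaks_gc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$genes, p("genes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$cells, p("cells.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$lr_table, p("lr_pairs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list.files(dir, full.names = TRUE))
}
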