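#' Pipeline configuration
#'
#' Bundles the synthetic-generator configuration, every stage's parameters
#' (mirroring the stage function defaults), the output directory and the
#' global seed. Per-stage seeds are derived deterministically as
#' `seed + stage index` so that stages never share a random stream.
#'
#' @param outdir output directory.
#' @param seed global seed.
#' @param synthetic a [synthetic_config()]; its own seed is set from the
#'   global seed unless supplied explicitly.
#' @param qc,deviations,tumor_tf,ccre,nmf,lr,drugs named lists of stage
#'   parameter overrides.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, synthetic = NULL,
                            qc = list(), deviations = list(),
                            tumor_tf = list(), ccre = list(), nmf = list(),
                            lr = list(), drugs = list()) {
  if (is.null(synthetic)) synthetic <- synthetic_config(seed = seed + 1L)
  defaults <- list(
    qc = list(),
    deviations = list(n_iter = 50L, k = 50L, scale = "z"),
    tumor_tf = list(fc_in = 4, fc_out_max = 1, alpha = 1e-4, mad_multiplier = 4),
    ccre = list(group_size = 10L, window = 500000, coaccess_cutoff = 0.2,
                lambda = 0.2, q_cut = 0.05, min_detect_frac = 0.05),
    nmf = list(k_min = 2L, k_max = 6L, nrun = 30L, top_n = 30L,
               min_coverage_fraction = 0.5),
    lr = list(min_frac = 0.1, n_perm = 1000L, p_cut = 0.05, mean_cut = 1),
    drugs = list(n_drugs = 50L, n_genes = 100L, z_cut = -2)
  )
  user <- list(qc = qc, deviations = deviations, tumor_tf = tumor_tf,
               ccre = ccre, nmf = nmf, lr = lr, drugs = drugs)
  stages <- lapply(names(defaults), function(s) {
    utils::modifyList(defaults[[s]], user[[s]])
  })
  names(stages) <- names(defaults)
  if (!stages$deviations$scale %in% c("z", "deviation"))
    .stopf("deviations$scale must be 'z' or 'deviation'")
  cfg <- list(outdir = outdir, seed = as.integer(seed), synthetic = synthetic,
              stages = stages)
  class(cfg) <- "pipeline_config"
  cfg
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-multiome analysis pipeline
#'
#' Executes all stages in dependency order — simulation, QC, ATAC features
#' (gene activity, peak annotation, DARs/DEGs, DAR-DEG association), motif
#' deviations, tumor-specific TF selection, cCRE linkage and regulatory
#' networks, intratumoral NMF meta-programs, ligand-receptor testing, and
#' the drug screen — writing each stage's outputs under `outdir/<stage>/`
#' and a run manifest (`manifest.json`) recording the package version,
#' seeds, parameters and an MD5 hash of every output file. Outputs are
#' write-once; a stage failure aborts with the stage named, retaining the
#' outputs of completed stages.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "multiomeReg",
    version = as.character(utils::packageVersion("multiomeReg")),
    seed = config$seed,
    parameters = config$stages,
    synthetic = unclass(config$synthetic),
    stages = list()
  )
  written <- character(0)
  stage <- function(name, idx, fn) {
    res <- tryCatch(fn(config$seed + idx), error = function(e)
      .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    manifest$stages[[name]] <<- list(
      seed = config$seed + idx,
      outputs = lapply(res$files, function(f)
        list(path = sub(paste0("^", outdir, "/?"), "", f),
             md5 = unname(tools::md5sum(f))))
    )
    written <<- c(written, res$files)
    res$value
  }
  sdir <- function(name) {
    d <- file.path(outdir, name)
    dir.create(d, showWarnings = FALSE)
    d
  }

  ## stage 0: simulate ------------------------------------------------------
  sim <- stage("simulate", 0L, function(seed) {
    sim <- generate_multiome(config$synthetic)
    d <- sdir("simulate")
    files <- write_multiome(sim, d)
    list(value = sim, files = files)
  })

  ## stage 1: qc -------------------------------------------------------------
  kept <- stage("qc", 1L, function(seed) {
    d <- sdir("qc")
    rna_keep <- filter_rna_cells(sim$cells)
    atac_keep <- filter_atac_cells(sim$cells)
    keep <- intersect(rna_keep, atac_keep)
    f1 <- file.path(d, "kept_cells.txt")
    writeLines(keep, f1)
    jac <- jaccard_index(
      setNames(sim$cells$cell_type, sim$cells$cell),
      setNames(sim$cells$cell_type, sim$cells$cell)
    )
    f2 <- .write_tsv(data.frame(label = rownames(jac), jac, check.names = FALSE),
                     file.path(d, "jaccard_self.tsv"))
    list(value = keep, files = c(f1, f2))
  })
  cells <- sim$cells[sim$cells$cell %in% kept, ]
  rna <- sim$rna[cells$cell, , drop = FALSE]
  atac <- sim$atac[cells$cell, , drop = FALSE]
  labels <- setNames(cells$cell_type, cells$cell)

  ## stage 2: atac features ---------------------------------------------------
  feats <- stage("features", 2L, function(seed) {
    d <- sdir("features")
    activity <- gene_activity_scores(atac, sim$peaks, sim$genes)
    degs <- find_differential_features(rna, labels)
    dars <- find_differential_features(atac, labels)
    f_act <- file.path(d, "gene_activity.mtx")
    Matrix::writeMM(activity, f_act)
    files <- c(
      f_act,
      .write_tsv(data.frame(peak = sim$peaks$peak, category = sim$peaks$category),
                 file.path(d, "peak_annotation.tsv")),
      .write_tsv(degs, file.path(d, "degs.tsv")),
      .write_tsv(dars, file.path(d, "dars.tsv"))
    )
    list(value = list(activity = activity, degs = degs, dars = dars),
         files = files)
  })

  ## stage 3: motif deviations -----------------------------------------------
  devres <- stage("deviations", 3L, function(seed) {
    d <- sdir("deviations")
    par <- config$stages$deviations
    bg <- sample_background_peaks(sim$peaks, atac, n_iter = par$n_iter,
                                  k = min(par$k, nrow(sim$peaks) - 1L),
                                  seed = seed)
    dev <- compute_deviations(atac, sim$motifs, bg)
    diff <- differential_tf_activity(dev, labels, scale = par$scale)
    files <- c(
      .write_tsv(data.frame(cell = rownames(dev$deviations),
                            round(dev$deviations, 6), check.names = FALSE),
                 file.path(d, "deviations.tsv")),
      .write_tsv(data.frame(cell = rownames(dev$z), round(dev$z, 6),
                            check.names = FALSE),
                 file.path(d, "deviation_z.tsv")),
      .write_tsv(diff, file.path(d, "differential_activity.tsv"))
    )
    list(value = list(dev = dev, diff = diff), files = files)
  })

  ## stage 4: tumor-specific TFs ----------------------------------------------
  tumor_tf <- stage("tumor_tf", 4L, function(seed) {
    d <- sdir("tumor_tf")
    par <- config$stages$tumor_tf
    variab <- tf_variability(devres$dev, labels)
    sel <- select_specific_tfs(devres$diff, variab, "tumor",
                               fc_in = par$fc_in, fc_out_max = par$fc_out_max,
                               alpha = par$alpha,
                               mad_multiplier = par$mad_multiplier)
    files <- c(
      .write_tsv(attr(sel, "table"), file.path(d, "candidate_table.tsv")),
      { f <- file.path(d, "selected_tfs.txt"); writeLines(as.character(sel), f); f }
    )
    list(value = sel, files = files)
  })

  ## stage 5: cCREs and regulatory network -------------------------------------
  crenet <- stage("ccre_network", 5L, function(seed) {
    d <- sdir("ccre_network")
    par <- config$stages$ccre
    mc <- aggregate_to_metacells(atac, labels, group_size = par$group_size,
                                 seed = seed)
    pairs <- compute_coaccessibility(mc, sim$peaks, window = par$window,
                                     coaccess_cutoff = par$coaccess_cutoff,
                                     lambda = par$lambda)
    links <- link_ccres(pairs, sim$peaks, sim$genes,
                        type_means(atac, labels), type_means(rna, labels),
                        q_cut = par$q_cut)
    deg_tumor <- feats$degs$feature[feats$degs$group == "tumor"]
    targets <- do.call(rbind, lapply(as.character(tumor_tf), function(m)
      identify_tf_targets(m, sim$motifs, links, sim$peaks, sim$genes, atac,
                          labels, "tumor",
                          min_detect_frac = par$min_detect_frac)))
    net <- build_network(targets, deg_tumor)
    f_net <- file.path(d, "network.graphml")
    igraph::write_graph(net, f_net, format = "graphml")
    assoc <- dar_deg_association(feats$dars, feats$degs, sim$peaks, sim$genes,
                                 links)
    files <- c(
      .write_tsv(pairs, file.path(d, "coaccessibility.tsv")),
      .write_tsv(links, file.path(d, "ccre_links.tsv")),
      .write_tsv(data.frame(group = names(assoc$per_group),
                            proportion = unname(assoc$per_group),
                            mean = assoc$mean, sd = assoc$sd),
                 file.path(d, "dar_deg_association.tsv")),
      .write_tsv(if (is.null(targets)) data.frame(tf = character(0),
                                                  gene = character(0),
                                                  evidence = character(0),
                                                  peak = character(0))
                 else targets,
                 file.path(d, "tf_targets.tsv")),
      f_net
    )
    list(value = list(pairs = pairs, links = links, targets = targets,
                      network = net, dar_deg = assoc), files = files)
  })

  ## stage 6: NMF meta-programs -------------------------------------------------
  nmfres <- stage("nmf", 6L, function(seed) {
    d <- sdir("nmf")
    par <- config$stages$nmf
    samples <- sort(unique(cells$sample))
    programs <- list()
    expr_by_sample <- list()
    coph_all <- list()
    for (s in samples) {
      tcells <- cells$cell[cells$sample == s & cells$cell_type == "tumor"]
      expr <- rna[tcells, , drop = FALSE]
      expr_by_sample[[s]] <- expr
      rel <- prepare_relative_expression(expr)
      nr <- run_nmf_range(rel, k_min = par$k_min, k_max = par$k_max,
                          nrun = par$nrun, seed = seed + match(s, samples))
      k_star <- select_k_by_cophenetic_drop(nr$cophenetic)
      coph_all[[s]] <- nr$cophenetic
      programs <- c(programs,
                    extract_programs(nr$fits[[as.character(k_star)]], s,
                                     top_n = par$top_n))
    }
    metas <- derive_meta_programs(programs, expr_by_sample,
                                  min_coverage_fraction = par$min_coverage_fraction,
                                  sig_size = par$top_n, seed = seed)
    f1 <- file.path(d, "programs.json")
    jsonlite::write_json(lapply(programs, function(p)
      p[c("sample", "k", "program", "top_genes", "degenerate")]),
      f1, auto_unbox = TRUE, digits = NA)
    f2 <- file.path(d, "meta_programs.json")
    jsonlite::write_json(lapply(metas, function(m)
      list(samples_covered = m$samples_covered, signature = m$signature,
           members = m$members)),
      f2, auto_unbox = TRUE, digits = NA)
    f3 <- .write_tsv(data.frame(sample = rep(names(coph_all),
                                             lengths(coph_all)),
                                k = unlist(lapply(coph_all, names)),
                                cophenetic = unlist(coph_all)),
                     file.path(d, "cophenetic.tsv"))
    list(value = list(programs = programs, metas = metas), files = c(f1, f2, f3))
  })

  ## stage 7: ligand-receptor interactions ---------------------------------------
  lrres <- stage("lr", 7L, function(seed) {
    d <- sdir("lr")
    par <- config$stages$lr
    triples <- compute_interaction_means(rna, labels, sim$lr_table,
                                         min_frac = par$min_frac)
    triples <- permutation_test(rna, labels, triples, n_perm = par$n_perm,
                                seed = seed)
    sel <- select_significant(triples, p_cut = par$p_cut,
                              mean_cut = par$mean_cut)
    files <- c(
      .write_tsv(sel$results, file.path(d, "interactions.tsv")),
      .write_tsv(data.frame(source = rownames(sel$counts), sel$counts,
                            check.names = FALSE),
                 file.path(d, "interaction_counts.tsv"))
    )
    list(value = sel, files = files)
  })

  ## stage 8: drug screen ---------------------------------------------------------
  stage("drugs", 8L, function(seed) {
    d <- sdir("drugs")
    par <- config$stages$drugs
    dz <- generate_drug_zscores(sim$truth, n_drugs = par$n_drugs,
                                n_genes = par$n_genes, seed = seed)
    hits <- do.call(rbind, lapply(sim$truth$tumor_specific_motifs, function(m) {
      h <- screen_drugs(dz$z, sim$truth$tf_genes[[m]], dz$approved,
                        z_cut = par$z_cut)
      if (nrow(h) == 0) return(NULL)
      data.frame(motif = m, tf_gene = sim$truth$tf_genes[[m]], h,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(hits))
      hits <- data.frame(motif = character(0), tf_gene = character(0),
                         drug = character(0), z = numeric(0))
    files <- .write_tsv(hits, file.path(d, "drug_screen.tsv"))
    list(value = hits, files = files)
  })

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
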