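test_that("generation is bit-identical under a fixed seed", {
  a <- generate_multiome(synthetic_config(seed = 7))
  b <- generate_multiome(synthetic_config(seed = 7))
  expect_identical(a, b)
  c <- generate_multiome(synthetic_config(seed = 8))
  expect_false(identical(a$rna, c$rna))
})

test_that("dimensions, labels and count domains are consistent", {
  sim <- cached_sim()
  expect_equal(nrow(sim$cells), 3 * 4 * 100)
  expect_equal(unname(table(sim$cells$sample)), rep(400L, 3), ignore_attr = TRUE)
  expect_identical(rownames(sim$rna), sim$cells$cell)
  expect_identical(rownames(sim$atac), sim$cells$cell)
  expect_identical(colnames(sim$atac), sim$peaks$peak)
  expect_identical(rownames(sim$motifs), sim$peaks$peak)
  expect_true(all(sim$rna@x >= 0), all(sim$rna@x == round(sim$rna@x)))
  expect_true(all(sim$atac@x >= 0), all(sim$atac@x == round(sim$atac@x)))
  expect_true(all(sim$peaks$gc >= 0 & sim$peaks$gc <= 1))
  expect_true(all(Matrix::colSums(sim$motifs) >= 1))
  # every referenced truth id exists in the annotations
  expect_true(all(sim$truth$ccre_links$peak %in% sim$peaks$peak))
  expect_true(all(sim$truth$ccre_links$gene %in% sim$genes$gene))
  expect_true(all(unlist(sim$truth$program_genes) %in% sim$genes$gene))
  expect_true(all(sim$truth$tumor_specific_motifs %in% colnames(sim$motifs)))
})

test_that("planted cCRE geometry satisfies the promoter rule", {
  sim <- cached_sim()
  mid <- floor((sim$peaks$start + sim$peaks$end) / 2)
  names(mid) <- sim$peaks$peak
  tss <- setNames(sim$genes$tss, sim$genes$gene)
  d <- abs(mid[sim$truth$ccre_links$promoter_peak] - tss[sim$truth$ccre_links$gene])
  expect_true(all(d <= 1000))
  expect_true(all(sim$peaks$category[match(sim$truth$ccre_links$peak,
                                           sim$peaks$peak)] == "distal"))
})

test_that("a unit tumor-motif effect leaves planted peaks at background accessibility", {
  sim <- generate_multiome(synthetic_config(seed = 21, tumor_motif_effect = 1))
  tumor <- sim$cells$cell_type == "tumor"
  planted <- unique(unlist(sim$truth$tumor_motif_peaks))
  # compare against distal peaks that carry no planted profile of any kind
  other <- setdiff(sim$peaks$peak[sim$peaks$category == "distal"],
                   c(planted, sim$truth$ccre_links$peak))
  norm <- as.matrix(normalize_counts(sim$atac, log = FALSE))
  ratio <- function(p) colMeans(norm[tumor, p]) / colMeans(norm[!tumor, p])
  expect_lt(abs(median(ratio(planted)) - median(ratio(other))), 0.2)
  # whereas a 3x effect separates them cleanly
  sim3 <- cached_sim()
  tumor3 <- sim3$cells$cell_type == "tumor"
  norm3 <- as.matrix(normalize_counts(sim3$atac, log = FALSE))
  planted3 <- unique(unlist(sim3$truth$tumor_motif_peaks))
  r3 <- colMeans(norm3[tumor3, planted3]) / colMeans(norm3[!tumor3, planted3])
  expect_gt(median(r3), 2)
})

test_that("infeasible configurations fail with the violated constraint named", {
  expect_error(synthetic_config(n_planted_ccres = 200), "cCRE")
  expect_error(synthetic_config(n_genes = 50), "genes")
  expect_error(synthetic_config(tumor_motif_effect = 0.5), "tumor_motif_effect")
  expect_error(synthetic_config(program_size = 10), "program_size")
  expect_error(synthetic_config(tumor_peak_pool = 200), "pool")
})

test_that("stronger planted effects never shrink the tumor deviation gap", {
  gaps <- vapply(1:5, function(s) {
    vapply(c(2, 4), function(eff) {
      sim <- generate_multiome(synthetic_config(seed = 30 + s,
                                                tumor_motif_effect = eff))
      bg <- sample_background_peaks(sim$peaks, sim$atac, n_iter = 20, seed = s)
      dev <- compute_deviations(sim$atac, sim$motifs, bg)
      tumor <- sim$cells$cell_type == "tumor"
      mean(vapply(sim$truth$tumor_specific_motifs, function(m)
        mean(dev$deviations[tumor, m]) - mean(dev$deviations[!tumor, m]),
        numeric(1)))
    }, numeric(1))
  }, numeric(2))
  expect_true(all(gaps[2, ] >= gaps[1, ]))
})

test_that("drug Z-screen plants strong knockdowns on an N(0,1) background", {
  sim <- cached_sim()
  dz <- generate_drug_zscores(sim$truth, n_drugs = 60, n_genes = 120, seed = 3)
  expect_identical(dz, generate_drug_zscores(sim$truth, n_drugs = 60,
                                             n_genes = 120, seed = 3))
  for (m in names(dz$effective_drugs)) {
    tf <- sim$truth$tf_genes[[m]]
    expect_true(all(dz$z[dz$effective_drugs[[m]], tf] < -2))
    expect_true(any(dz$effective_drugs[[m]] %in% dz$approved))
  }
  # non-planted entries follow the standard normal lower tail
  planted_idx <- cbind(match(unlist(dz$effective_drugs), rownames(dz$z)),
                       match(sim$truth$tf_genes[names(dz$effective_drugs)][
                         rep(names(dz$effective_drugs),
                             lengths(dz$effective_drugs))], colnames(dz$z)))
  bgv <- dz$z
  bgv[planted_idx] <- NA
  frac <- mean(bgv < -2, na.rm = TRUE)
  n_bg <- sum(!is.na(bgv))
  p0 <- pnorm(-2)
  expect_lt(abs(frac - p0), 4 * sqrt(p0 * (1 - p0) / n_bg))
  expect_error(generate_drug_zscores(sim$truth, n_drugs = 2, n_genes = 120),
               "effective")
})

test_that("written multiome round-trips through standard text formats", {
  sim <- cached_sim()
  d <- withr::local_tempdir()
  write_multiome(sim, d)
  m <- Matrix::readMM(file.path(d, "rna.mtx"))
  expect_equal(dim(m), dim(sim$rna))
  expect_equal(sum(m), sum(sim$rna))
  expect_identical(readLines(file.path(d, "rna_features.tsv")), colnames(sim$rna))
  bed <- read.table(file.path(d, "peaks.bed"), sep = "\t")
  expect_equal(nrow(bed), nrow(sim$peaks))
  expect_true(all(bed$V3 > bed$V2))
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_setequal(unlist(truth$tumor_specific_motifs),
                  sim$truth$tumor_specific_motifs)
})
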