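test_that("metacell pooling conserves counts and respects cell types", {
  sim <- cached_sim()
  labels <- setNames(sim$cells$cell_type, sim$cells$cell)
  mc <- aggregate_to_metacells(sim$atac, labels, group_size = 10, seed = 2)
  expect_equal(Matrix::colSums(mc$counts), Matrix::colSums(sim$atac))
  expect_equal(nrow(mc$counts), length(mc$cell_type))
  expect_equal(unname(table(mc$cell_type)), rep(30L, 4), ignore_attr = TRUE)
  expect_identical(mc$counts,
                   aggregate_to_metacells(sim$atac, labels, 10, seed = 2)$counts)
  # 10 cells with group size 5 give exactly 2 pools
  small <- aggregate_to_metacells(sim$atac[1:10, ], rep("t", 10), 5, seed = 1)
  expect_equal(nrow(small$counts), 2)
  # group size beyond the type size collapses the type to one pool
  one <- aggregate_to_metacells(sim$atac[1:7, ], rep("t", 7), 50, seed = 1)
  expect_equal(nrow(one$counts), 1)
  expect_equal(Matrix::colSums(one$counts), Matrix::colSums(sim$atac[1:7, ]))
})

test_that("co-accessibility finds identical peaks and never crosses chromosomes", {
  set.seed(3)
  n_mc <- 40
  base <- matrix(rpois(n_mc * 6, 30), n_mc, 6)
  base[, 2] <- base[, 1]          # peak b duplicates peak a
  peaks <- data.frame(peak = paste0("p", 1:6),
                      chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2"),
                      start = c(1000, 21000, 61000, 101000, 1000, 41000),
                      end = c(1400, 21400, 61400, 101400, 1400, 41400))
  colnames(base) <- peaks$peak
  pairs <- compute_coaccessibility(base, peaks, window = 500000)
  dup <- pairs[pairs$peak_a == "p1" & pairs$peak_b == "p2", ]
  expect_equal(nrow(dup), 1)
  expect_gt(dup$score, 0.5)
  expect_false(any(substr(pairs$peak_a, 1, 2) != substr(pairs$peak_b, 1, 2) &
                     pairs$peak_a %in% c("p5", "p6")))
  chr_of <- setNames(peaks$chrom, peaks$peak)
  expect_true(all(chr_of[pairs$peak_a] == chr_of[pairs$peak_b]))
  expect_error(compute_coaccessibility(base[1:3, ], peaks), "metacells")
})

test_that("independent peaks rarely reach the co-accessibility cutoff", {
  set.seed(8)
  n_mc <- 100
  mat <- matrix(rpois(n_mc * 30, 25), n_mc, 30)
  peaks <- data.frame(peak = sprintf("p%02d", 1:30), chrom = "chr1",
                      start = seq(0, by = 15000, length.out = 30),
                      end = seq(400, by = 15000, length.out = 30))
  colnames(mat) <- peaks$peak
  pairs <- compute_coaccessibility(mat, peaks, coaccess_cutoff = -Inf)
  expect_gt(nrow(pairs), 100)
  expect_gte(mean(abs(pairs$score) < 0.2), 0.95)
})

test_that("cCRE linkage requires exactly one promoter peak and gates on BH q", {
  genes <- data.frame(gene = "g1", chrom = "chr1", strand = "+",
                      tss = 21200L, start = 21200L, end = 25000L)
  peaks <- data.frame(peak = paste0("p", 1:3), chrom = "chr1",
                      start = c(1000, 21000, 61000), end = c(1400, 21400, 61400))
  am <- matrix(c(1, 2, 3, 4,   2, 3, 4, 5,   1, 2, 4, 8), 4, 3,
               dimnames = list(paste0("t", 1:4), peaks$peak))
  rm_ <- matrix(c(2, 4, 6, 8), 4, 1, dimnames = list(paste0("t", 1:4), "g1"))
  pairs <- data.frame(peak_a = c("p1", "p1"), peak_b = c("p2", "p3"),
                      score = c(0.5, 0.4), distance = c(20000, 60000))
  links <- link_ccres(pairs, peaks, genes, am, rm_)
  # only (p1, p2) has exactly one promoter side; p1-p3 has none
  expect_equal(nrow(links), 1)
  expect_identical(links$peak, "p1")
  expect_identical(links$promoter_peak, "p2")
  # p1 accessibility is proportional to g1 expression: r = 1
  expect_equal(links$r, 1, tolerance = 1e-12)
  expect_true(all(links$q >= links$p))
  expect_error(link_ccres(pairs, peaks, genes, am[1:2, ], rm_[1:2, , drop = FALSE]),
               "3 cell types")
})

test_that("planted cCREs are recovered from the full chain", {
  sim <- cached_sim()
  labels <- setNames(sim$cells$cell_type, sim$cells$cell)
  mc <- aggregate_to_metacells(sim$atac, labels, group_size = 10, seed = 5)
  pairs <- compute_coaccessibility(mc, sim$peaks)
  links <- link_ccres(pairs, sim$peaks, sim$genes,
                      type_means(sim$atac, labels), type_means(sim$rna, labels))
  expect_true(all(abs(links$r) <= 1))
  truth <- paste(sim$truth$ccre_links$peak, sim$truth$ccre_links$gene)
  found <- paste(links$peak, links$gene)
  expect_gte(length(intersect(found, truth)) / max(length(found), 1), 0.8)
  expect_gte(length(intersect(found, truth)) / length(truth), 0.7)
})

test_that("TF target identification follows the two evidence rules", {
  genes <- data.frame(gene = c("g1", "g2"), chrom = "chr1", strand = "+",
                      tss = c(5000L, 50000L), start = c(5000L, 50000L),
                      end = c(9000L, 54000L))
  peaks <- data.frame(peak = c("prom1", "prom2", "dist1"), chrom = "chr1",
                      start = c(4800, 49800, 20000), end = c(5200, 50200, 20400))
  hits <- Matrix::Matrix(cbind(tf = c(1, 0, 1)), sparse = TRUE)
  rownames(hits) <- peaks$peak
  # 40 tumor cells: prom1 accessible in all, dist1 in all, prom2 in 1 cell (2.5%)
  atac <- Matrix::Matrix(cbind(prom1 = rep(1, 40), prom2 = c(1, rep(0, 39)),
                               dist1 = rep(1, 40)), sparse = TRUE)
  rownames(atac) <- paste0("c", 1:40)
  labels <- rep("tumor", 40)
  links <- data.frame(peak = "dist1", gene = "g2", promoter_peak = "prom2",
                      coaccess = 0.5, r = 0.99, p = 0.001, q = 0.01)
  tg <- identify_tf_targets("tf", hits, links, peaks, genes, atac, labels, "tumor")
  expect_identical(tg$gene, c("g1", "g2"))
  expect_identical(tg$evidence[tg$gene == "g1"], "promoter_motif")
  expect_identical(tg$evidence[tg$gene == "g2"], "linked_ccre")
  # below the 5% accessibility gate nothing is reported
  atac2 <- atac
  atac2[, "dist1"] <- c(1, rep(0, 39))
  tg2 <- identify_tf_targets("tf", hits, links, peaks, genes, atac2, labels, "tumor")
  expect_false("g2" %in% tg2$gene)
  expect_error(identify_tf_targets("nope", hits, links, peaks, genes, atac,
                                   labels, "tumor"), "nope")
  # brute-force agreement on the full synthetic instance
  sim <- cached_sim()
  lab <- setNames(sim$cells$cell_type, sim$cells$cell)
  m <- sim$truth$tumor_specific_motifs[1]
  got <- identify_tf_targets(m, sim$motifs, NULL, sim$peaks, sim$genes,
                             sim$atac, lab, "tumor")
  det <- Matrix::colSums(sim$atac[lab == "tumor", ] > 0) / sum(lab == "tumor")
  mid <- floor((sim$peaks$start + sim$peaks$end) / 2)
  expect_genes <- sort(unique(unlist(lapply(which(as.matrix(sim$motifs)[, m] > 0 &
                                                    det >= 0.05), function(i)
    sim$genes$gene[sim$genes$chrom == sim$peaks$chrom[i] &
                     abs(sim$genes$tss - mid[i]) <= 1000]))))
  expect_identical(sort(unique(got$gene[got$evidence == "promoter_motif"])),
                   expect_genes)
})

test_that("networks deduplicate edges and keep every evidence record", {
  expect_equal(igraph::vcount(build_network(NULL)), 0)
  tt <- data.frame(tf = c("tfA", "tfA", "tfA", "tfB"),
                   gene = c("g1", "g1", "g2", "g2"),
                   evidence = c("promoter_motif", "linked_ccre",
                                "promoter_motif", "promoter_motif"))
  g <- build_network(tt, deg_genes = "g2")
  expect_equal(igraph::ecount(g), 3)
  expect_equal(igraph::vcount(g), 4)
  e <- igraph::E(g)[.from(igraph::V(g)["tfA"]) & .to(igraph::V(g)["g1"])]
  expect_identical(e$evidence, "linked_ccre,promoter_motif")
  expect_identical(igraph::V(g)$is_deg[match("g2", igraph::V(g)$name)], TRUE)
  expect_identical(sort(igraph::V(g)$name[igraph::V(g)$role == "tf"]),
                   c("tfA", "tfB"))
})

test_that("module scores are centered null and seeded", {
  sim <- cached_sim()
  expr <- sim$rna[sim$cells$cell_type == "tumor", ]
  s1 <- score_gene_module(expr, colnames(expr)[1:25], seed = 3)
  expect_identical(s1, score_gene_module(expr, colnames(expr)[1:25], seed = 3))
  set.seed(21)
  null_means <- vapply(1:100, function(i) {
    gs <- sample(colnames(expr), 20)
    mean(score_gene_module(expr, gs, seed = i))
  }, numeric(1))
  expect_lt(abs(mean(null_means)), 3 * sd(null_means) / sqrt(100))
  expect_error(score_gene_module(expr, character(0)), "empty")
  expect_error(score_gene_module(expr, "not_a_gene"), "absent")
})
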