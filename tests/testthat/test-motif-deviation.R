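test_that("the deviation closed form matches hand computation", {
  # 2 cells, 3 peaks, motif on peaks {1,2}; c1 = (6,0,2), c2 = (0,0,4)
  counts <- Matrix::Matrix(rbind(c(6, 0, 2), c(0, 0, 4)), sparse = TRUE)
  dimnames(counts) <- list(c("c1", "c2"), c("p1", "p2", "p3"))
  hits <- Matrix::Matrix(cbind(m1 = c(1, 1, 0)), sparse = TRUE)
  rownames(hits) <- colnames(counts)
  bg <- matrix(c(3L, 3L, 3L), 3, 1)  # single background iteration on peak 3
  dev <- compute_deviations(counts, hits, bg)
  # f = 6/12, E = (4, 2), raw = ((6-4)/4, (0-2)/2)
  expect_equal(unname(dev$raw[, "m1"]), c(0.5, -1.0))
})

test_that("proportional cells have zero raw deviation", {
  counts <- Matrix::Matrix(rbind(c(2, 4, 6), c(1, 2, 3)), sparse = TRUE)
  dimnames(counts) <- list(c("a", "b"), c("p1", "p2", "p3"))
  hits <- Matrix::Matrix(cbind(m1 = c(1, 0, 1), m2 = c(0, 1, 0)), sparse = TRUE)
  rownames(hits) <- colnames(counts)
  bg <- matrix(rep(c(2L, 1L, 2L), 2), 3, 2)
  dev <- compute_deviations(counts, hits, bg)
  expect_equal(max(abs(dev$raw)), 0)
})

test_that("backgrounds equal to the motif's own peaks zero the corrected deviation", {
  sim <- cached_sim()
  counts <- sim$atac[1:50, 1:10]
  hits <- Matrix::Matrix(cbind(m = c(1, 1, 1, rep(0, 7))), sparse = TRUE)
  rownames(hits) <- colnames(counts)
  bg <- matrix(rep(1:10, 3), 10, 3)
  bg[1:3, ] <- 1:3  # backgrounds of hit peaks are the hit peaks themselves
  dev <- compute_deviations(counts, hits, bg)
  expect_equal(max(abs(dev$deviations[, "m"])), 0)
})

test_that("deviations match the brute-force oracle to 1e-12", {
  set.seed(5)
  counts <- Matrix::Matrix(matrix(rpois(12, 4), 3, 4), sparse = TRUE)
  dimnames(counts) <- list(paste0("c", 1:3), paste0("p", 1:4))
  hits <- Matrix::Matrix(cbind(m1 = c(1, 1, 0, 0), m2 = c(0, 1, 0, 1)),
                         sparse = TRUE)
  rownames(hits) <- colnames(counts)
  bg <- matrix(sample(1:4, 4 * 6, replace = TRUE), 4, 6)
  fast <- compute_deviations(counts, hits, bg)
  slow <- brute_force_deviations(counts, hits, bg)
  expect_equal(unname(as.matrix(fast$raw)), slow$raw, tolerance = 1e-12)
  expect_equal(unname(as.matrix(fast$deviations)), slow$deviations,
               tolerance = 1e-12)
  expect_equal(unname(as.matrix(fast$z)), slow$z, tolerance = 1e-12)
})

test_that("raw deviations carry depth normalization in the expectation", {
  sim <- cached_sim()
  counts <- sim$atac[1:100, ]
  hits <- sim$motifs
  bg <- sample_background_peaks(sim$peaks, counts, n_iter = 5, seed = 1)
  dev1 <- compute_deviations(counts, hits, bg)
  # uniform rescaling of every cell leaves the statistic exactly unchanged
  dev_u <- compute_deviations(counts * 3, hits, bg)
  expect_equal(dev_u$raw, dev1$raw, tolerance = 1e-12)
  # rescaling a single cell barely perturbs it (only through the global f)
  counts2 <- counts
  counts2[7, ] <- counts2[7, ] * 2
  dev2 <- compute_deviations(counts2, hits, bg)
  expect_equal(unname(dev2$raw[7, ]), unname(dev1$raw[7, ]), tolerance = 0.05)
})

test_that("background peaks are matched on GC and accessibility", {
  sim <- cached_sim()
  bg <- sample_background_peaks(sim$peaks, sim$atac, n_iter = 50, seed = 2)
  expect_identical(bg, sample_background_peaks(sim$peaks, sim$atac,
                                               n_iter = 50, seed = 2))
  # a peak never selects itself
  expect_true(all(bg != matrix(seq_len(nrow(bg)), nrow(bg), ncol(bg))))
  gc_bg <- rowMeans(matrix(sim$peaks$gc[bg], nrow(bg)))
  expect_gt(cor(sim$peaks$gc, gc_bg), 0.9)
  expect_error(sample_background_peaks(sim$peaks[1:20, ], sim$atac[, 1:20],
                                       k = 50), "peaks")
})

test_that("uniform random motifs center near zero after bias correction", {
  sim <- cached_sim()
  bg <- sample_background_peaks(sim$peaks, sim$atac, n_iter = 30, seed = 4)
  set.seed(11)
  means <- vapply(1:8, function(i) {
    hits <- Matrix::Matrix(cbind(m = as.numeric(runif(nrow(sim$peaks)) < 0.15)),
                           sparse = TRUE)
    rownames(hits) <- sim$peaks$peak
    dev <- compute_deviations(sim$atac, hits, bg)
    mean(dev$deviations[, "m"])
  }, numeric(1))
  expect_lt(abs(mean(means)), 3 * sd(means) / sqrt(length(means)) + 0.02)
})

test_that("differential activity is antisymmetric and gated", {
  sim <- cached_sim()
  labels <- setNames(sim$cells$cell_type, sim$cells$cell)
  bg <- sample_background_peaks(sim$peaks, sim$atac, n_iter = 20, seed = 3)
  dev <- compute_deviations(sim$atac, sim$motifs, bg)
  diff <- differential_tf_activity(dev, labels)
  expect_identical(attr(diff, "scale"), "z")
  # two-group antisymmetry
  two <- ifelse(labels == "tumor", "tumor", "rest")
  d2 <- differential_tf_activity(dev, two)
  dt <- d2[d2$group == "tumor", ]
  dr <- d2[d2$group == "rest", ]
  expect_equal(dt$activity_delta, -dr$activity_delta[match(dt$motif, dr$motif)])
  # planted motifs are significant in the tumor group
  planted <- diff[diff$group == "tumor" &
                    diff$motif %in% sim$truth$tumor_specific_motifs, ]
  expect_true(all(planted$significant))
  # identically distributed groups are not flagged
  set.seed(1)
  shuffled <- sample(labels)
  d0 <- differential_tf_activity(dev, shuffled)
  expect_true(all(abs(d0$activity_delta) < 1))
  # the deviation scale is exposed as a switch
  dd <- differential_tf_activity(dev, labels, scale = "deviation")
  expect_identical(attr(dd, "scale"), "deviation")
  expect_false(isTRUE(all.equal(dd$activity_delta, diff$activity_delta)))
})
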