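test_that("QC filters remove cells violating each rule and keep the rest", {
  # 3 cells: ok / too few genes / top-gene share too high
  counts <- matrix(0, 300, 3, dimnames = list(sprintf("g%03d", 1:300),
                                              paste0("c", 1:3)))
  counts[, 1] <- 2                       # 300 genes, 600 UMIs, even
  counts[1:200, 2] <- 3                  # 200 genes < 250 -> fails
  counts[, 3] <- 2
  counts[1, 3] <- 200                    # 200/798 = 25% in one gene
  meta <- data.frame(cell_id = paste0("c", 1:3), sample_id = "s1",
                     age = "P65", sex = "M", genotype = "control")
  mx <- MaturationExperiment(counts, meta)
  res <- applyQCFilters(mx, qcThresholds())
  expect_equal(colnames(res$experiment), "c1")
  expect_equal(res$report$firstFail, c(NA, "min_genes", "top_gene"))

  # a matrix in which every cell passes is returned unchanged, and
  # filtering is idempotent
  mx2 <- res$experiment
  res2 <- applyQCFilters(mx2, qcThresholds())
  expect_identical(dim(res2$experiment), dim(mx2))
  expect_true(all(res2$report$pass))
})

test_that("QC flags category-fraction violations", {
  counts <- matrix(2, 100, 2, dimnames = list(sprintf("g%03d", 1:100),
                                              c("c1", "c2")))
  counts[1:30, 1] <- 0    # c1 expresses no mito genes at all
  counts[1:30, 2] <- 10   # c2: mito genes hold 300/440 > 10%
  meta <- data.frame(cell_id = c("c1", "c2"), sample_id = "s1",
                     age = "P65", sex = "M", genotype = "control")
  gm <- data.frame(gene_id = rownames(counts), mito = seq_len(100) <= 30)
  mx <- MaturationExperiment(counts, meta, gm)
  th <- qcThresholds(minUMIs = 10, minGenes = 10)
  res <- applyQCFilters(mx, th)
  expect_equal(res$report$firstFail, c(NA, "mito"))

  rowData(mx)$mito <- NULL
  expect_error(applyQCFilters(mx, th), "mito")
})

test_that("log-normalization has its closed forms and scale invariance", {
  counts <- matrix(c(0, 1, 9999,   0, 2, 19998), 3, 2,
                   dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  meta <- data.frame(cell_id = c("c1", "c2"), sample_id = "s1",
                     age = "P65", sex = "M", genotype = "control")
  mx <- logNormalize(MaturationExperiment(counts, meta),
                     scaleFactor = 1e4)
  ln <- as.matrix(assay(mx, "logcounts"))
  expect_equal(ln["g1", "c1"], 0)            # zero stays zero
  expect_equal(ln["g2", "c1"], log(2))       # total = scale factor, count 1
  # c2 doubles every count of c1 -> identical normalized profile
  expect_equal(ln[, "c2"], ln[, "c1"])

  counts[, 1] <- 0
  mx0 <- MaturationExperiment(counts, meta)
  expect_error(logNormalize(mx0), "c1")
})

test_that("HVG selection ranks a high-variance gene first and handles n
           larger than the gene count", {
  withr::with_seed(1, {
    counts <- matrix(rpois(200 * 80, 5), 200, 80,
                     dimnames = list(sprintf("g%03d", 1:200),
                                     sprintf("c%02d", 1:80)))
    counts[7, ] <- rpois(80, 5) * sample(c(0L, 8L), 80, replace = TRUE)
  })
  meta <- data.frame(cell_id = colnames(counts), sample_id = "s1",
                     age = "P65", sex = "M", genotype = "control")
  mx <- MaturationExperiment(counts, meta)
  hv <- selectHVGs(mx, n = 20)
  expect_equal(hv[1], "g007")
  expect_warning(all <- selectHVGs(mx, n = 10000), "expressed")
  expect_lte(length(all), 200)
  # determinism under fixed input
  expect_identical(selectHVGs(mx, n = 20), hv)
})

test_that("PCA variance fractions match a dense eigendecomposition oracle", {
  withr::with_seed(2, {
    counts <- matrix(rpois(150 * 120, 4), 150, 120,
                     dimnames = list(sprintf("g%03d", 1:150),
                                     sprintf("c%03d", 1:120)))
  })
  meta <- data.frame(cell_id = colnames(counts), sample_id = "s1",
                     age = "P65", sex = "M", genotype = "control")
  mx <- logNormalize(MaturationExperiment(counts, meta))
  genes <- rownames(mx)
  space <- runPCA(mx, genes = genes, K = 30)

  # independent oracle: centered+scaled dense matrix, full eigen spectrum
  X <- scale(t(as.matrix(assay(mx, "logcounts"))))
  ev <- eigen(cov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(space@varianceFraction, (ev / sum(ev))[1:30],
               tolerance = 1e-8)
  # scores reproduce X %*% rotation
  expect_equal(unname(space@scores),
               unname(X %*% space@rotation), tolerance = 1e-8)

  # wide case (more genes than cells) agrees with prcomp
  mxw <- mx[, 1:40]
  spw <- runPCA(mxw, genes = genes, K = 10)
  pr <- prcomp(scale(t(as.matrix(assay(mxw, "logcounts")))))
  expect_equal(abs(unname(spw@scores)), abs(unname(pr$x[, 1:10])),
               tolerance = 1e-6)
})

test_that("the 20% variance rule counts components and respects the cap", {
  mk <- function(vf) new("PCASpace", rotation = matrix(0, 1, length(vf)),
                         scores = matrix(0, 1, length(vf)),
                         varianceFraction = vf, center = 0, scaleVec = 1,
                         hvgs = "g")
  expect_equal(pcCountForVariance(mk(c(0.25, 0.10, 0.05))), 1)
  expect_equal(pcCountForVariance(mk(c(0.08, 0.07, 0.06, 0.05))), 3)
  expect_equal(pcCountForVariance(mk(rep(0.001, 150)), cap = 100), 100)
  expect_error(pcCountForVariance(mk(c(0.5)), target = 1.2), "target")
})

test_that("module scores are seeded, centered under exchangeability and
           recover a planted uplift", {
  nG <- 240; nC <- 150
  withr::with_seed(3, {
    counts <- matrix(rpois(nG * nC, 6), nG, nC,
                     dimnames = list(sprintf("g%03d", 1:nG),
                                     sprintf("c%03d", 1:nC)))
    # uplift a gene set by a common factor
    set <- sprintf("g%03d", 1:12)
    counts[set, ] <- matrix(rpois(12 * nC, 12), 12, nC)
  })
  meta <- data.frame(cell_id = colnames(counts), sample_id = "s1",
                     age = "P65", sex = "M", genotype = "control")
  mx <- MaturationExperiment(counts, meta)

  s1 <- moduleScore(mx, set, seed = 7)
  expect_identical(s1, moduleScore(mx, set, seed = 7))

  # a random set drawn from one expression bin scores ~0 on average
  ln <- assay(logNormalize(mx), "logcounts")
  nullSets <- replicate(60, {
    g <- sample(sprintf("g%03d", 41:240), 10)
    mean(moduleScore(mx, g, seed = sample.int(1e6, 1)))
  })
  expect_lt(abs(mean(nullSets)), 0.05)

  # the uplifted set scores clearly above the null sets
  expect_gt(mean(s1), mean(nullSets) + 3 * sd(nullSets))

  # invariant to padding the matrix with silent genes
  pad <- matrix(0L, 30, nC,
                dimnames = list(sprintf("silent%02d", 1:30),
                                colnames(counts)))
  mxp <- MaturationExperiment(rbind(counts, pad), meta)
  expect_equal(moduleScore(mxp, set, seed = 7), s1)

  expect_error(moduleScore(mx, c("nope1", "nope2")), "nope")
})

test_that("z-scoring across ages matches the closed form and handles the
           degenerate constant case", {
  scores <- c(rep(1, 4), rep(2, 4), rep(3, 4))
  ages <- rep(c("E16", "P10", "P65"), each = 4)
  z <- zscoreAcrossAge(scores, ages)
  expect_equal(unname(z), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  z0 <- zscoreAcrossAge(rep(5, 12), ages)
  expect_equal(unname(z0), c(0, 0, 0))
  expect_error(zscoreAcrossAge(1:4, rep("P65", 4)), "2 ages")
})

test_that("cell-type correlations hit the exact limits and match a
           brute-force oracle", {
  mx <- gaussianClusters(nPerGroup = 12, groups = c("A", "B", "C", "D", "E"),
                         seed = 4)
  labels <- colData(mx)$cell_type
  cc <- cellTypeCorrelationMatrix(mx, labels)
  expect_equal(unname(diag(cc)), rep(1, 5))
  expect_true(isSymmetric(cc))

  # brute-force two-pass oracle
  ln <- as.matrix(assay(logNormalize(mx), "logcounts"))
  Z <- t(scale(t(ln)))
  Z[is.na(Z)] <- 0
  prof <- sapply(sort(unique(labels)),
                 function(ct) rowMeans(Z[, labels == ct, drop = FALSE]))
  oracle <- matrix(NA_real_, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    oracle[i, j] <- cor(prof[, i], prof[, j])
  }
  diag(oracle) <- 1
  dimnames(oracle) <- dimnames(cc)
  expect_equal(cc, oracle, tolerance = 1e-12)

  # duplicated cell type correlates at exactly 1
  mx2 <- duplicateCells(mx, which(labels == "A"))
  lab2 <- c(labels, rep("Adup", sum(labels == "A")))
  cc2 <- cellTypeCorrelationMatrix(mx2, lab2)
  expect_equal(cc2["A", "Adup"], 1, tolerance = 1e-12)
})
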