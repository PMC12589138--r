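test_that("monotonization applies the clamp rule and is idempotent", {
  expect_equal(monotonize(c(5, 3, 4, 2, 0)), c(5, 3, 3, 2, 0))
  expect_equal(monotonize(c(1, 2, 3)), c(1, 1, 1))
  # already non-increasing input is unchanged
  x <- c(9, 7, 7, 2, 0)
  expect_equal(monotonize(x), x)
  # idempotence and elementwise domination on random series
  withr::with_seed(10, {
    for (i in 1:25) {
      y <- abs(rnorm(sample(2:12, 1), sd = 3))
      m <- monotonize(y)
      expect_true(all(diff(m) <= 0))
      expect_true(all(m <= y))
      expect_equal(monotonize(m), m)
    }
  })
})

test_that("trajectory classification follows the largest-first 90% rule", {
  # one step carrying 95% of the decrease -> stepwise
  expect_equal(classifyTrajectory(c(100, 98, 3, 0)), 3L)
  # seven equal steps -> 90% needs 7 of them -> gradual
  expect_equal(classifyTrajectory(seq(7, 0)), 1L)
  # top-3 steps carrying 0.40 + 0.30 + 0.25 = 0.95 -> intermediate
  expect_equal(classifyTrajectory(c(1, 0.60, 0.30, 0.05, 0.025, 0)), 2L)
  # no net decrease -> NA
  expect_true(is.na(classifyTrajectory(c(2, 2, 2))))
  expect_true(is.na(classifyTrajectory(c(0, 0))))
  # every positive-decrease trajectory receives exactly one class
  withr::with_seed(11, {
    for (i in 1:50) {
      m <- monotonize(c(abs(rnorm(7, sd = 2)) + 0.5, 0))
      cls <- classifyTrajectory(m)
      if (m[1] > 0) expect_true(cls %in% 1:3) else expect_true(is.na(cls))
    }
  })
})

test_that("noiseless planted schedules classify as planted once the adult
           self-distance step is accounted for", {
  # a measured trajectory is signal x (1 - schedule) plus a centroid
  # sampling floor at every pre-adult age, and exactly 0 at the adult age
  for (signalToFloor in c(2, 4, 8)) {
    for (cl in 1:3) {
      sched <- maturationSchedule(cl, 8)
      measured <- c(signalToFloor * (1 - sched[-8]) + 1, 0)
      expect_equal(classifyTrajectory(monotonize(measured)), cl,
                   info = paste("class", cl, "S/F", signalToFloor))
      expect_true(all(diff(sched) >= 0))
      expect_equal(sched[1], 0)
      expect_equal(sched[8], 1)
      # final step carries no progress (delayed clock converges at adult)
      expect_equal(sched[7], 1)
    }
  }
})

test_that("distance trajectories are zero at the adult age and match a
           brute-force centroid oracle", {
  d <- .smallData()
  mx <- d$experiment
  tr <- distanceTrajectory(mx, cellType = "CT01", minCells = 5)
  expect_s4_class(tr, "DistanceTrajectory")
  expect_equal(unname(rawDistance(tr)[["P65"]]), 0)
  expect_true(all(diff(monoDistance(tr)) <= 1e-12))
  expect_equal(sum(tr@stepDecrease), unname(monoDistance(tr)[1]))

  # brute-force oracle: replicate the reduced space, then compute per-age
  # centroids and L1 distances with explicit loops
  sub <- mx[, !is.na(colData(mx)$cell_type) &
              colData(mx)$cell_type == "CT01"]
  sub <- logNormalize(sub)
  hv <- selectHVGs(sub, 2000)
  sp <- runPCA(sub, hv, K = 100)
  m <- pcCountForVariance(sp, 0.20, 100)
  expect_equal(m, tr@nPcs)
  sc <- sp@scores[, seq_len(m), drop = FALSE]
  ages <- as.character(colData(sub)$age)
  oracle <- sapply(tr@ages, function(a) {
    ca <- colMeans(sc[ages == a, , drop = FALSE])
    cj <- colMeans(sc[ages == "P65", , drop = FALSE])
    s <- 0
    for (k in seq_along(ca)) s <- s + abs(ca[k] - cj[k])
    s
  })
  expect_equal(unname(rawDistance(tr)), unname(oracle), tolerance = 1e-9)
})

test_that("distance trajectories separate planted shifts from a
           homogeneous control and drop thin ages", {
  d <- .smallData()
  mx <- d$experiment
  # planted-trend cell type shows much larger early distance than the
  # distance among ages drawn from its own plateau (positive control
  # versus noise floor)
  tr <- distanceTrajectory(mx, cellType = "CT02", minCells = 5)
  md <- monoDistance(tr)
  expect_gt(md[["E16"]], 2 * md[["P28"]])

  # age dropped when below minCells
  sub <- mx[, !is.na(colData(mx)$cell_type) &
              colData(mx)$cell_type == "CT01"]
  few <- which(as.character(colData(sub)$age) == "E18")
  sub2 <- sub[, -few[-(1:3)]]
  expect_warning(tr3 <- distanceTrajectory(sub2, minCells = 5), "E18")
  expect_false("E18" %in% tr3@ages)
})

test_that("duplicating every cell leaves the distance trajectory unchanged", {
  d <- .smallData()
  mx <- d$experiment
  sub <- mx[, !is.na(colData(mx)$cell_type) &
              colData(mx)$cell_type == "CT03"]
  dup <- duplicateCells(sub)
  tr1 <- distanceTrajectory(sub, minCells = 5)
  tr2 <- distanceTrajectory(dup, minCells = 5)
  # centroids are exactly invariant; the sample-variance scaling carries a
  # Bessel n/(n-1) correction, so tolerate its O(1/n) drift
  expect_equal(rawDistance(tr2), rawDistance(tr1), tolerance = 2e-3)
})

test_that("nearest-neighbour maturity matches an exhaustive pairwise
           oracle and behaves at the degenerate k", {
  d <- .smallData()
  mx <- d$experiment
  sub <- mx[, !is.na(colData(mx)$cell_type) &
              colData(mx)$cell_type == "CT01"]
  sub <- sub[, round(seq(1, ncol(sub), length.out = 200))]  # span all ages
  k <- 15
  nm <- nnMaturity(sub, k = k)

  # exhaustive oracle in the same reduced space
  subN <- logNormalize(sub)
  sp <- runPCA(subN, selectHVGs(subN, 2000), K = 100)
  m <- pcCountForVariance(sp)
  sc <- sp@scores[, seq_len(m), drop = FALSE]
  ages <- as.character(colData(sub)$age)
  n <- nrow(sc)
  adultHits <- numeric(n)
  for (i in seq_len(n)) {
    dd <- sqrt(rowSums((sc - matrix(sc[i, ], n, ncol(sc),
                                    byrow = TRUE))^2))
    dd[i] <- Inf
    nn <- order(dd)[1:k]
    adultHits[i] <- sum(ages[nn] == "P65")
  }
  for (a in names(nm$fraction)) {
    expect_equal(nm$fraction[[a]],
                 sum(adultHits[ages == a]) / (k * sum(ages == a)),
                 tolerance = 1e-12, info = a)
  }

  # k = n - 1: every age's fraction equals the adult share among the others
  nmAll <- nnMaturity(sub, k = ncol(sub) - 1)
  nAdult <- sum(ages == "P65")
  expect_equal(nmAll$fraction[["P65"]],
               (nAdult - 1) / (ncol(sub) - 1), tolerance = 1e-12)
  expect_equal(nmAll$fraction[["E16"]], nAdult / (ncol(sub) - 1),
               tolerance = 1e-12)

  expect_error(nnMaturity(sub[, 1:10], k = 50), "smaller k")
})

test_that("well-separated age clusters give adult fraction near 1 for
           adult cells and near 0 for the youngest", {
  # three tight clusters along disjoint genes, ages E16/P10/P65
  nPer <- 40
  withr::with_seed(12, {
    counts <- NULL
    for (g in 1:3) {
      lam <- rep(1, 90); lam[((g - 1) * 30 + 1):(g * 30)] <- 40
      counts <- cbind(counts, matrix(rpois(90 * nPer, lam), 90, nPer))
    }
  })
  meta <- data.frame(cell_id = paste0("c", seq_len(3 * nPer)),
                     sample_id = rep(c("s1", "s2", "s3"), each = nPer),
                     age = rep(c("E16", "P10", "P65"), each = nPer),
                     sex = "M", genotype = "control", cell_type = "T")
  rownames(meta) <- meta$cell_id
  colnames(counts) <- meta$cell_id
  rownames(counts) <- paste0("g", 1:90)
  mx <- MaturationExperiment(counts, meta,
                             ageLevels = c("E16", "P10", "P65"))
  nm <- nnMaturity(mx, k = 20)
  expect_gt(nm$fraction[["P65"]], 0.95)
  expect_lt(nm$fraction[["E16"]], 0.05)
})

test_that("group comparison of trajectories detects an offset and demands
           replication", {
  mkTraj <- function(scale, ct) {
    raw <- c(pmax(seq(6, 1) + rnorm(6, sd = 0.15), 0.1), 0) * scale
    mono <- monotonize(raw)
    new("DistanceTrajectory", cellType = ct,
        ages = c("E16", "E18", "P0", "P4", "P10", "P18", "P65"),
        nPcs = 5L, rawDistance = raw, monoDistance = mono,
        stepDecrease = -diff(mono),
        trajClass = 1L, nCells = rep(30L, 7))
  }
  withr::with_seed(13, {
    trajA <- lapply(1:10, function(i) mkTraj(1, paste0("A", i)))
    trajB <- lapply(1:10, function(i) mkTraj(2, paste0("B", i)))
  })
  res <- compareTrajectoryGroups(c(trajA, trajB), rep(c("a", "b"), each = 10))
  expect_lt(res$pValue, 0.001)
  expect_error(compareTrajectoryGroups(c(trajA[1], trajB[1]), c("a", "b")),
               "2 cell types")
  expect_error(compareTrajectoryGroups(trajA, rep("a", 10)), "2 groups")
})
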