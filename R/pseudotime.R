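## project points (rows of X) onto the polyline with vertices V and
## cumulative arc length cumLen; returns arc-length positions and distances
.projectToPolyline <- function(X, V, cumLen) {
  nSeg <- nrow(V) - 1
  n <- nrow(X)
  best <- rep(Inf, n)
  lambda <- numeric(n)
  for (s in seq_len(nSeg)) {
    a <- V[s, ]; b <- V[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    diff <- sweep(X, 2, a)
    t <- if (len2 == 0) rep(0, n) else pmin(pmax(drop(diff %*% ab) / len2, 0), 1)
    proj <- outer(t, ab)
    d2 <- rowSums((diff - proj)^2)
    upd <- d2 < best
    best[upd] <- d2[upd]
    lambda[upd] <- cumLen[s] + t[upd] * sqrt(len2)
  }
  list(lambda = lambda, dist2 = best)
}

.curveFromLambda <- function(scores, lambda, nGrid = 100, df = NULL) {
  # smooth.spline collapses near-ties; when cells pile up on a few
  # positions (e.g. snapped to a curve endpoint) spread them
  # deterministically so the smoother stays defined
  if (length(unique(signif(lambda, 6))) < 8) {
    lambda <- lambda +
      seq_along(lambda) * (diff(range(lambda)) + 1) * 1e-5
  }
  grid <- seq(min(lambda), max(lambda), length.out = nGrid)
  V <- vapply(seq_len(ncol(scores)), function(d) {
    fit <- tryCatch(
      if (is.null(df)) smooth.spline(lambda, scores[, d])
      else smooth.spline(lambda, scores[, d], df = df),
      error = function(e) lm(y ~ x, data.frame(x = lambda,
                                               y = scores[, d])))
    if (inherits(fit, "lm")) predict(fit, data.frame(x = grid))
    else predict(fit, grid)$y
  }, numeric(nGrid))
  cumLen <- c(0, cumsum(sqrt(rowSums(diff(V)^2))))
  list(V = V, cumLen = cumLen)
}

#' Fit a principal-curve maturation pseudotime
#'
#' Fits a one-dimensional principal curve through one cell type's cells in
#' a reduced space (2,000 HVGs, top `nPCs` = 20 components) by iterating
#' project-then-smooth: pseudotime is initialized on the first component,
#' each coordinate is smoothed against pseudotime (cubic smoothing spline,
#' 5 effective degrees of freedom; straight lines lie in the penalty null
#' space and are reproduced exactly), cells are re-projected onto the
#' resulting polyline, and the loop
#' stops when the mean projection displacement falls below `tol` of the
#' data scale (or after `maxIter` iterations, returning the last iterate
#' with a warning). Pseudotime is the normalized arc length, oriented so
#' adult cells score high.
#'
#' @param mx control cells of one cell type across ages (use `cellType` to
#'   subset).
#' @param cellType optional cell-type label to subset on.
#' @param nHVG,nPCs reduced-space parameters (defaults 2,000 and 20).
#' @param nGrid polyline vertices along the curve (default 100).
#' @param maxIter,tol iteration controls (defaults 50 and 1e-4).
#' @return a [PseudotimeCurve-class].
#' @export
fitPseudotimeCurve <- function(mx, cellType = NULL, nHVG = 2000, nPCs = 20,
                               nGrid = 100, maxIter = 50, tol = 1e-4) {
  if (!is.null(cellType)) {
    mx <- mx[, !is.na(colData(mx)$cell_type) &
               colData(mx)$cell_type == cellType]
  }
  ageVec <- as.character(colData(mx)$age)
  if (length(unique(ageVec)) < 3) stop("need cells from >= 3 ages")
  if (ncol(mx) < 50) stop("need >= 50 cells; have ", ncol(mx))
  mx <- logNormalize(mx)
  hvgs <- selectHVGs(mx, n = nHVG)
  space <- runPCA(mx, genes = hvgs, K = nPCs)
  X <- space@scores
  pc <- .principalCurve(X, nGrid = nGrid, maxIter = maxIter, tol = tol)
  lambda <- pc$lambda
  curve <- pc
  if (!pc$converged) {
    warning("principal curve did not converge in ", maxIter, " iterations")
  }
  rng <- range(lambda)
  if (diff(rng) == 0) rng <- c(rng[1], rng[1] + 1)
  pt <- (lambda - rng[1]) / diff(rng)
  agesPresent <- intersect(ageLevels(mx), unique(ageVec))
  adult <- agesPresent[length(agesPresent)]
  youngest <- agesPresent[1]
  flipped <- mean(pt[ageVec == adult]) < mean(pt[ageVec == youngest])
  if (flipped) pt <- 1 - pt
  ct <- if (is.null(cellType)) {
    u <- unique(stats::na.omit(as.character(colData(mx)$cell_type)))
    if (length(u) == 1) u else "(pooled)"
  } else cellType
  new("PseudotimeCurve", cellType = ct, hvgs = space@hvgs,
      center = space@center, scaleVec = space@scaleVec,
      rotation = space@rotation, curvePoints = curve$V,
      arcLength = curve$cumLen, lambdaRange = rng, flipped = flipped,
      pseudotime = setNames(pt, colnames(mx)), converged = pc$converged)
}

## iterative project-then-smooth principal curve on a score matrix;
## pseudotime initialized on the first column (first component). The
## smoother uses a fixed effective df (the usual principal-curve choice);
## lambda is renormalized each iteration so arc length cannot run away.
.principalCurve <- function(X, nGrid = 100, maxIter = 50, tol = 1e-4,
                            df = 5) {
  dataScale <- sqrt(mean(rowSums(sweep(X, 2, colMeans(X))^2)))
  lambda <- X[, 1]
  converged <- FALSE
  curve <- NULL
  df <- min(df, max(length(unique(lambda)) - 1, 2))
  for (it in seq_len(maxIter)) {
    rl <- range(lambda)
    if (diff(rl) > 0) lambda <- (lambda - rl[1]) / diff(rl)
    curve <- .curveFromLambda(X, lambda, nGrid = nGrid, df = df)
    pr <- .projectToPolyline(X, curve$V, curve$cumLen)
    disp <- mean(abs(pr$lambda - .rescaleLike(lambda, pr$lambda)))
    lambda <- pr$lambda
    if (disp < tol * dataScale) {
      converged <- TRUE
      break
    }
  }
  list(lambda = lambda, V = curve$V, cumLen = curve$cumLen,
       converged = converged)
}

## map an old lambda onto the scale of a new one for displacement tracking
.rescaleLike <- function(old, new) {
  ro <- range(old); rn <- range(new)
  if (diff(ro) == 0) return(rep(mean(rn), length(old)))
  (old - ro[1]) / diff(ro) * diff(rn) + rn[1]
}

#' Project cells onto a fitted pseudotime curve
#'
#' Standardizes query cells with the curve's stored centering and scaling,
#' rotates them into its component space, projects each onto the nearest
#' point of the curve polyline, and returns the normalized, orientation-
#' corrected pseudotime in [0, 1]. Re-projecting the training cells
#' reproduces their stored pseudotime.
#'
#' @param curve a [PseudotimeCurve-class].
#' @param mx query [MaturationExperiment-class].
#' @return named numeric pseudotime per query cell.
#' @export
projectCells <- function(curve, mx) {
  mx <- logNormalize(mx)
  q <- .projectIntoSpace(assay(mx, "logcounts"), curve@hvgs, curve@center,
                         curve@scaleVec, curve@rotation)
  pr <- .projectToPolyline(q, curve@curvePoints, curve@arcLength)
  pt <- (pr$lambda - curve@lambdaRange[1]) / diff(curve@lambdaRange)
  pt <- pmin(pmax(pt, 0), 1)
  if (curve@flipped) pt <- 1 - pt
  setNames(pt, colnames(mx))
}

#' Per-age developmental-delay test
#'
#' Averages pseudotime within each (cell type, sample), then across
#' samples, to one value per cell type per genotype, and runs a two-sided
#' t-test of mutant versus control cell-type means at each age. Ages with
#' fewer than `minCellTypes` cell types in either genotype are skipped
#' with a warning.
#'
#' @param pt data.frame with columns `cellType`, `genotype`, `age`,
#'   `sample`, `pseudotime` (one row per cell).
#' @param minCellTypes minimum cell types per genotype per age (default 5).
#' @return data.frame per age: mean pseudotime per genotype, difference
#'   (mutant - control), p-value, cell-type counts.
#' @export
delayTest <- function(pt, minCellTypes = 5) {
  stopifnot(all(c("cellType", "genotype", "age", "sample",
                  "pseudotime") %in% colnames(pt)))
  if (!all(c("control", "mutant") %in% pt$genotype)) {
    stop("need both control and mutant cells")
  }
  out <- list()
  for (a in unique(as.character(pt$age))) {
    sub <- pt[pt$age == a, ]
    bySample <- stats::aggregate(pseudotime ~ cellType + genotype + sample,
                                 sub, mean)
    byType <- stats::aggregate(pseudotime ~ cellType + genotype, bySample,
                               mean)
    ctl <- byType$pseudotime[byType$genotype == "control"]
    mut <- byType$pseudotime[byType$genotype == "mutant"]
    if (length(ctl) < minCellTypes || length(mut) < minCellTypes) {
      warning("age ", a, ": fewer than ", minCellTypes,
              " cell types per genotype; skipped")
      next
    }
    tt <- t.test(mut, ctl)
    out[[a]] <- data.frame(age = a, meanControl = mean(ctl),
                           meanMutant = mean(mut),
                           difference = mean(mut) - mean(ctl),
                           pValue = tt$p.value,
                           nControl = length(ctl), nMutant = length(mut))
  }
  if (!length(out)) stop("no age had enough cell types")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Estimate the developmental delay in age stages
#'
#' Finds the non-negative stage shift s minimizing the mean squared
#' discrepancy between the mutant per-age mean pseudotime and the control
#' mean pseudotime at ages shifted back by s (clamped at the first age) —
#' the shift that makes mutants "resemble" younger controls.
#'
#' @param pt data.frame as in [delayTest()].
#' @param ages ordered stage labels covering `pt$age`.
#' @param maxShift largest shift considered (default `length(ages) - 1`).
#' @return list with `delay` (estimated stages) and `discrepancy` per
#'   candidate shift.
#' @export
estimateDelay <- function(pt, ages, maxShift = length(ages) - 1) {
  byType <- stats::aggregate(pseudotime ~ cellType + genotype + age, pt, mean)
  meanAt <- function(gen) {
    v <- vapply(ages, function(a) {
      x <- byType$pseudotime[byType$genotype == gen & byType$age == a]
      if (length(x)) mean(x) else NA_real_
    }, numeric(1))
    v
  }
  ctl <- meanAt("control")
  mut <- meanAt("mutant")
  shifts <- 0:maxShift
  disc <- vapply(shifts, function(s) {
    ref <- ctl[pmax(seq_along(ages) - s, 1)]
    ok <- !is.na(mut) & !is.na(ref)
    mean((mut[ok] - ref[ok])^2)
  }, numeric(1))
  list(delay = shifts[which.min(disc)],
       discrepancy = setNames(disc, paste0("shift", shifts)))
}

#' Identify core maturation genes shared across cell types
#'
#' Draws a balanced, seeded subsample of `nPerType` cells per cell type at
#' the youngest stage(s) and at the adult stage, computes per-gene log2
#' fold changes (adult versus youngest) from mean log-normalized
#' expression, and keeps genes with log2FC > `lfcMin` that are expressed
#' in at least `pctMin` of the sampled adult cells. Cell types lacking
#' either stage are excluded with a warning.
#'
#' @param mx control [MaturationExperiment-class] with cell-type labels.
#' @param nPerType cells sampled per cell type per stage (default 10).
#' @param lfcMin log2 fold-change threshold (default 0.5, strict).
#' @param pctMin adult expressing-fraction threshold (default 0.3,
#'   inclusive).
#' @param youngAges stage labels pooled as "youngest" (default the first
#'   two, i.e. E16/E18 when present).
#' @param seed RNG seed of the subsample.
#' @return list with `genes`, and `table` holding per-gene log2FC and
#'   adult expressing fraction.
#' @export
identifyCoreMaturationGenes <- function(mx, nPerType = 10, lfcMin = 0.5,
                                        pctMin = 0.3, youngAges = NULL,
                                        seed = 0) {
  lv <- ageLevels(mx)
  if (is.null(youngAges)) youngAges <- lv[seq_len(min(2, length(lv) - 1))]
  adult <- adultAge(mx)
  ageVec <- as.character(colData(mx)$age)
  ctVec <- as.character(colData(mx)$cell_type)
  cts <- unique(stats::na.omit(ctVec))
  pick <- withr::with_seed(seed, {
    sel <- list()
    for (ct in cts) {
      yCells <- which(ctVec == ct & ageVec %in% youngAges)
      aCells <- which(ctVec == ct & ageVec == adult)
      if (length(yCells) < nPerType || length(aCells) < nPerType) {
        warning("cell type ", ct, " lacks ", nPerType,
                " cells at a stage; excluded")
        next
      }
      sel[[ct]] <- list(young = sample(yCells, nPerType),
                        adult = sample(aCells, nPerType))
    }
    sel
  })
  if (!length(pick)) stop("no cell type has both stages")
  young <- unlist(lapply(pick, `[[`, "young"))
  old <- unlist(lapply(pick, `[[`, "adult"))
  mx <- logNormalize(mx)
  ln <- assay(mx, "logcounts")
  muY <- Matrix::rowMeans(ln[, young, drop = FALSE])
  muA <- Matrix::rowMeans(ln[, old, drop = FALSE])
  lfc <- (muA - muY) / log(2)
  pct <- Matrix::rowMeans(assay(mx, "counts")[, old, drop = FALSE] > 0)
  keep <- lfc > lfcMin & pct >= pctMin
  tab <- data.frame(gene = rownames(mx), log2FC = as.numeric(lfc),
                    pctAdult = as.numeric(pct), selected = keep,
                    row.names = NULL)
  list(genes = rownames(mx)[keep], table = tab,
       parameters = list(nPerType = nPerType, lfcMin = lfcMin,
                         pctMin = pctMin, youngAges = youngAges,
                         seed = seed))
}

#' Compare maturation module scores between genotypes
#'
#' Scores every cell with [moduleScore()] on the core maturation gene set,
#' averages within (cell type, genotype), and t-tests mutant versus
#' control across cell types at one age.
#'
#' @param mx a [MaturationExperiment-class] containing both genotypes.
#' @param geneSet core maturation gene ids.
#' @param age stage to compare at (default all cells in `mx`).
#' @param seed module-score control-gene seed.
#' @return list with per-cell-type means, the mean difference
#'   (mutant - control) and the t-test p-value.
#' @export
maturationModuleComparison <- function(mx, geneSet, age = NULL, seed = 0) {
  if (!length(geneSet)) stop("empty gene set")
  if (!is.null(age)) mx <- mx[, as.character(colData(mx)$age) == age]
  sc <- moduleScore(mx, geneSet, seed = seed)
  df <- data.frame(cellType = as.character(colData(mx)$cell_type),
                   genotype = as.character(colData(mx)$genotype),
                   score = sc)
  df <- df[!is.na(df$cellType), ]
  byType <- stats::aggregate(score ~ cellType + genotype, df, mean)
  ctl <- byType$score[byType$genotype == "control"]
  mut <- byType$score[byType$genotype == "mutant"]
  if (!length(ctl) || !length(mut)) stop("need both genotypes")
  tt <- if (identical(ctl, mut)) list(p.value = 1) else t.test(mut, ctl)
  list(byCellType = byType, difference = mean(mut) - mean(ctl),
       pValue = tt$p.value)
}
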