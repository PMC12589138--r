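#' QC thresholds for nucleus filtering
#'
#' Retention rules: `minUMIs <= total UMIs <= maxUMIs`, at least `minGenes`
#' detected genes, top gene holding at most `maxTopGeneFraction` of the
#' cell's counts, and per-category UMI fractions (mitochondrial, ribosomal,
#' immediate-early, apoptotic, red-blood-cell) at most their caps. Cells
#' violating any rule are removed; comparisons on the fraction caps are
#' strict (a cell *exceeding* the cap fails).
#'
#' @param minUMIs,maxUMIs retained UMI range (default 400 to 100,000).
#' @param minGenes minimum detected genes (default 250).
#' @param maxTopGeneFraction cap on the largest single-gene share (0.20).
#' @param maxMitoFraction,maxRiboFraction caps on mitochondrial and
#'   ribosomal UMI fractions (0.10 each).
#' @param maxIegFraction,maxApoptoticFraction,maxRbcFraction caps on
#'   immediate-early, apoptotic and red-blood-cell fractions (0.01 each).
#' @return a `qcThresholds` list.
#' @export
qcThresholds <- function(minUMIs = 400, maxUMIs = 1e5, minGenes = 250,
                         maxTopGeneFraction = 0.20, maxMitoFraction = 0.10,
                         maxRiboFraction = 0.10, maxIegFraction = 0.01,
                         maxApoptoticFraction = 0.01, maxRbcFraction = 0.01) {
  th <- list(minUMIs = minUMIs, maxUMIs = maxUMIs, minGenes = minGenes,
             maxTopGeneFraction = maxTopGeneFraction,
             maxMitoFraction = maxMitoFraction,
             maxRiboFraction = maxRiboFraction,
             maxIegFraction = maxIegFraction,
             maxApoptoticFraction = maxApoptoticFraction,
             maxRbcFraction = maxRbcFraction)
  if (th$minUMIs >= th$maxUMIs) stop("minUMIs must be < maxUMIs")
  fr <- th[grep("Fraction$", names(th))]
  if (any(unlist(fr) <= 0 | unlist(fr) > 1)) {
    stop("all fraction thresholds must lie in (0, 1]")
  }
  structure(th, class = "qcThresholds")
}

#' Apply QC filters to a MaturationExperiment
#'
#' @param mx a [MaturationExperiment-class].
#' @param th thresholds from [qcThresholds()].
#' @return list with `experiment` (retained cells) and `report`, a
#'   data.frame of per-cell metrics with `pass` and the `firstFail`ing rule.
#' @export
applyQCFilters <- function(mx, th = qcThresholds()) {
  needed <- c("mito", "ribo", "ieg", "apoptotic", "rbc")
  missing <- setdiff(needed, colnames(rowData(mx)))
  if (length(missing)) {
    stop("rowData lacks gene category flag(s): ",
         paste(missing, collapse = ", "))
  }
  cts <- assay(mx, "counts")
  total <- Matrix::colSums(cts)
  nGenes <- Matrix::colSums(cts > 0)
  topGene <- apply(cts, 2, max)
  catFrac <- do.call(cbind, lapply(needed, function(cat) {
    idx <- which(rowData(mx)[[cat]])
    if (length(idx)) Matrix::colSums(cts[idx, , drop = FALSE]) / pmax(total, 1)
    else rep(0, ncol(cts))
  }))
  colnames(catFrac) <- needed
  report <- data.frame(cell_id = colnames(mx), total_umis = total,
                       n_genes = nGenes,
                       top_gene_fraction = topGene / pmax(total, 1),
                       mito_fraction = catFrac[, "mito"],
                       ribo_fraction = catFrac[, "ribo"],
                       ieg_fraction = catFrac[, "ieg"],
                       apoptotic_fraction = catFrac[, "apoptotic"],
                       rbc_fraction = catFrac[, "rbc"],
                       row.names = NULL)
  rules <- list(
    min_umis = report$total_umis < th$minUMIs,
    max_umis = report$total_umis > th$maxUMIs,
    min_genes = report$n_genes < th$minGenes,
    top_gene = report$top_gene_fraction > th$maxTopGeneFraction,
    mito = report$mito_fraction > th$maxMitoFraction,
    ribo = report$ribo_fraction > th$maxRiboFraction,
    ieg = report$ieg_fraction > th$maxIegFraction,
    apoptotic = report$apoptotic_fraction > th$maxApoptoticFraction,
    rbc = report$rbc_fraction > th$maxRbcFraction)
  fails <- do.call(cbind, rules)
  firstFail <- apply(fails, 1, function(f) {
    i <- which(f)[1]
    if (is.na(i)) NA_character_ else names(rules)[i]
  })
  report$pass <- !apply(fails, 1, any)
  report$firstFail <- firstFail
  list(experiment = mx[, report$pass], report = report)
}

#' Log-normalize counts
#'
#' Computes `ln(1 + count / cell_total * scaleFactor)` per cell and stores
#' it as the `logcounts` assay. Zeros stay zero and the transform is
#' monotone in the raw count within a cell, so doubling all counts of a
#' cell leaves its normalized profile unchanged.
#'
#' @param mx a [MaturationExperiment-class].
#' @param scaleFactor library-size target (default 10,000).
#' @return `mx` with a `logcounts` assay.
#' @export
logNormalize <- function(mx, scaleFactor = 1e4) {
  cts <- assay(mx, "counts")
  total <- Matrix::colSums(cts)
  if (any(total == 0)) {
    stop("cell(s) with zero total counts: ",
         paste(head(colnames(mx)[total == 0], 5), collapse = ", "))
  }
  if (inherits(cts, "CsparseMatrix")) {
    ln <- cts
    ln@x <- log1p(ln@x / rep.int(total, diff(ln@p)) * scaleFactor)
  } else {
    ln <- log1p(sweep(as.matrix(cts), 2, total, "/") * scaleFactor)
    ln <- Matrix(ln, sparse = TRUE)
  }
  assay(mx, "logcounts") <- ln
  mx
}

.logcounts <- function(mx) {
  if (!"logcounts" %in% assayNames(mx)) mx <- logNormalize(mx)
  assay(mx, "logcounts")
}

#' Select highly variable genes
#'
#' Ranks expressed genes by their dispersion (variance/mean of
#' log-normalized expression) standardized within equal-frequency bins of
#' mean expression, and returns the top `n`. Deterministic; ties broken by
#' gene id.
#'
#' @param mx a [MaturationExperiment-class] (log-normalized on the fly if
#'   needed).
#' @param n number of genes (default 2,000).
#' @param nBins mean-expression bins for standardization (default 20).
#' @return character vector of gene ids, ranked.
#' @export
selectHVGs <- function(mx, n = 2000, nBins = 20) {
  ln <- .logcounts(mx)
  expressed <- which(Matrix::rowSums(ln) > 0)
  if (length(expressed) < n) {
    warning("only ", length(expressed), " expressed genes; returning all")
  }
  ln <- ln[expressed, , drop = FALSE]
  mu <- Matrix::rowMeans(ln)
  v <- .rowVars(ln)
  disp <- v / pmax(mu, .Machine$double.eps)
  bins <- .equalFreqBins(mu, min(nBins, length(mu)))
  z <- disp
  for (b in unique(bins)) {
    i <- bins == b
    s <- sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  ord <- order(-z, rownames(ln))
  head(rownames(ln)[ord], n)
}

.equalFreqBins <- function(x, nBins) {
  if (nBins <= 1) return(rep(1L, length(x)))
  ceiling(rank(x, ties.method = "first") / (length(x) / nBins))
}

.rowVars <- function(m) {
  mu <- Matrix::rowMeans(m)
  Matrix::rowMeans(m^2) - mu^2 -> vv
  n <- ncol(m)
  pmax(vv * n / max(n - 1, 1), 0)
}

#' Principal component space over selected genes
#'
#' PCA of centered, unit-variance-scaled log-normalized expression.
#' Variance fractions are eigenvalues over the total variance of the
#' standardized matrix. Small problems (smaller dimension at most
#' `exactLimit`) are solved exactly through an eigendecomposition of the
#' smaller-side Gram matrix; larger problems use a seeded randomized
#' range-finder SVD with power iterations, which is deterministic given
#' `seed`.
#'
#' @slot rotation genes x K loadings.
#' @slot scores cells x K component scores.
#' @slot varianceFraction per-component fraction of total variance,
#'   non-increasing.
#' @slot center,scaleVec standardization vectors over `hvgs`.
#' @slot hvgs genes used.
#' @export
setClass("PCASpace",
  representation(rotation = "matrix", scores = "matrix",
                 varianceFraction = "numeric", center = "numeric",
                 scaleVec = "numeric", hvgs = "character"))

setValidity("PCASpace", function(object) {
  vf <- object@varianceFraction
  msg <- character()
  if (length(vf) && (any(vf < -1e-12 | vf > 1 + 1e-12) ||
                     any(diff(vf) > 1e-12))) {
    msg <- c(msg, "varianceFraction must be non-increasing and in [0,1]")
  }
  if (sum(vf) > 1 + 1e-8) msg <- c(msg, "varianceFraction must sum to <= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PCASpace", function(object) {
  cat("PCASpace:", nrow(object@scores), "cells x",
      ncol(object@scores), "components over", length(object@hvgs),
      "genes\n  top variance fractions:",
      paste(signif(head(object@varianceFraction, 5), 3), collapse = " "),
      "\n")
})

#' @rdname PCASpace-class
#' @param mx a [MaturationExperiment-class].
#' @param genes gene ids to use (e.g. from [selectHVGs()]).
#' @param K number of components to retain.
#' @param scale standardize genes to unit variance (default TRUE).
#' @param exactLimit exact solver used when `min(cells, genes)` is at most
#'   this (default 600).
#' @param seed seed of the randomized solver (default 0).
#' @return a `PCASpace`.
#' @export
runPCA <- function(mx, genes = selectHVGs(mx), K = 100, scale = TRUE,
                   exactLimit = 600, seed = 0) {
  stopifnot(K >= 1)
  ln <- .logcounts(mx)
  genes <- intersect(genes, rownames(ln))
  X <- as.matrix(Matrix::t(ln[genes, , drop = FALSE]))   # cells x genes
  ctr <- colMeans(X)
  scl <- if (scale) apply(X, 2, sd) else rep(1, ncol(X))
  scl[scl == 0] <- 1
  X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  n <- nrow(X); p <- ncol(X)
  K <- min(K, n - 1, p)
  totalVar <- sum(apply(X, 2, var))
  if (min(n, p) <= max(exactLimit, K + 10)) {
    if (p <= n) {
      C <- crossprod(X) / (n - 1)
      e <- eigen(C, symmetric = TRUE)
      lam <- pmax(e$values, 0)[seq_len(K)]
      rot <- e$vectors[, seq_len(K), drop = FALSE]
      sco <- X %*% rot
    } else {
      G <- tcrossprod(X) / (n - 1)
      e <- eigen(G, symmetric = TRUE)
      lam <- pmax(e$values, 0)
      U <- e$vectors[, seq_len(K), drop = FALSE]
      d <- sqrt(pmax(lam[seq_len(K)] * (n - 1), .Machine$double.eps))
      sco <- sweep(U, 2, d, "*")
      rot <- crossprod(X, U)
      rot <- sweep(rot, 2, d, "/")
      lam <- lam[seq_len(K)]
    }
  } else {
    rsvd <- .randomizedSVD(X, K, seed = seed)
    rot <- rsvd$v
    sco <- sweep(rsvd$u, 2, rsvd$d, "*")
    lam <- rsvd$d^2 / (n - 1)
  }
  rownames(rot) <- genes
  rownames(sco) <- rownames(X)
  colnames(rot) <- colnames(sco) <- paste0("PC", seq_len(K))
  new("PCASpace", rotation = rot, scores = sco,
      varianceFraction = lam / totalVar,
      center = setNames(ctr, genes), scaleVec = setNames(scl, genes),
      hvgs = genes)
}

## Halko-Martinsson-Tropp randomized range finder with power iterations
.randomizedSVD <- function(X, K, oversample = 10, power = 2, seed = 0) {
  n <- nrow(X); p <- ncol(X)
  L <- min(K + oversample, n, p)
  Omega <- withr::with_seed(seed, matrix(rnorm(p * L), p, L))
  Y <- X %*% Omega
  for (i in seq_len(power)) {
    Y <- qr.Q(qr(Y))
    Y <- X %*% crossprod(X, Y)
  }
  Q <- qr.Q(qr(Y))
  B <- crossprod(Q, X)                 # L x p
  sv <- svd(B, nu = K, nv = K)
  list(u = Q %*% sv$u, d = sv$d[seq_len(K)], v = sv$v)
}

#' Number of components explaining a variance target
#'
#' Smallest m whose cumulative variance fraction reaches `target`; capped
#' at `cap` components when the target is not reached earlier.
#'
#' @param space a [PCASpace-class].
#' @param target cumulative variance fraction in (0, 1) (default 0.20).
#' @param cap component cap (default 100).
#' @return integer component count.
#' @export
pcCountForVariance <- function(space, target = 0.20, cap = 100) {
  if (target <= 0 || target >= 1) stop("target must lie in (0, 1)")
  vf <- space@varianceFraction
  upTo <- min(cap, length(vf))
  cum <- cumsum(vf[seq_len(upTo)])
  m <- which(cum >= target)[1]
  if (is.na(m)) min(cap, length(vf)) else as.integer(m)
}

#' Gene-set module score with expression-matched controls
#'
#' Per-cell mean log-normalized expression of the set genes minus the mean
#' of control genes drawn (seeded) from the expression-mean bin of each set
#' gene. Never-expressed genes are excluded from the bin universe, so the
#' score is invariant to padding the matrix with silent genes.
#'
#' @param mx a [MaturationExperiment-class].
#' @param geneSet character vector of gene ids.
#' @param nBins equal-frequency expression bins (default 24).
#' @param nCtrl control genes drawn per set gene (default 100).
#' @param seed RNG seed for the control draw.
#' @return named numeric vector, one score per cell.
#' @export
moduleScore <- function(mx, geneSet, nBins = 24, nCtrl = 100, seed = 0) {
  ln <- .logcounts(mx)
  expressed <- rownames(ln)[Matrix::rowSums(ln) > 0]
  set <- intersect(geneSet, expressed)
  if (!length(set)) {
    stop("no gene of the set is expressed; missing: ",
         paste(head(setdiff(geneSet, expressed), 10), collapse = ", "))
  }
  mu <- Matrix::rowMeans(ln[expressed, , drop = FALSE])
  bins <- setNames(.equalFreqBins(mu, min(nBins, length(mu))), expressed)
  ctrl <- withr::with_seed(seed, {
    unlist(lapply(set, function(g) {
      pool <- expressed[bins == bins[[g]]]
      sample(pool, min(nCtrl, length(pool)))
    }))
  })
  setScore <- Matrix::colMeans(ln[set, , drop = FALSE])
  ctrlScore <- Matrix::colMeans(ln[ctrl, , drop = FALSE])
  setNames(as.numeric(setScore - ctrlScore), colnames(ln))
}

#' z-score per-cell values across age stages
#'
#' Averages per-cell values within each age and standardizes the age means
#' to zero mean and unit (population) SD across ages. When every age mean
#' is identical the z-scores are all zero by convention.
#'
#' @param scores named per-cell values.
#' @param ages per-cell age factor aligned with `scores`.
#' @return named numeric vector of per-age z-scores.
#' @export
zscoreAcrossAge <- function(scores, ages) {
  ages <- droplevels(as.factor(ages))
  if (nlevels(ages) < 2) stop("need cells from >= 2 ages")
  m <- tapply(scores, ages, mean)
  s <- sqrt(mean((m - mean(m))^2))
  if (s == 0) return(setNames(rep(0, length(m)), names(m)))
  setNames(as.numeric((m - mean(m)) / s), names(m))
}

#' Cell-type correlation matrix of mean scaled expression
#'
#' Genes are z-scored across cells, averaged within each cell type, and the
#' Pearson correlation between cell-type mean profiles is returned. Cell
#' types with fewer than two cells are excluded with a warning.
#'
#' @param mx a [MaturationExperiment-class].
#' @param labels per-cell labels (defaults to `colData(mx)$cell_type`).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
cellTypeCorrelationMatrix <- function(mx, labels = colData(mx)$cell_type) {
  labels <- as.character(labels)
  tab <- table(labels)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("excluding cell type(s) with < 2 cells: ",
            paste(small, collapse = ", "))
  }
  keep <- names(tab)[tab >= 2]
  if (length(keep) < 2) stop("need >= 2 cell types with >= 2 cells")
  ln <- as.matrix(.logcounts(mx))
  mu <- rowMeans(ln)
  s <- apply(ln, 1, sd)
  s[s == 0] <- 1
  Z <- (ln - mu) / s
  prof <- vapply(keep, function(ct) rowMeans(Z[, labels == ct, drop = FALSE]),
                 numeric(nrow(Z)))
  cc <- cor(prof)
  diag(cc) <- 1
  cc
}
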