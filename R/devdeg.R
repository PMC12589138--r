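#' Pseudobulk raw counts by sample
#'
#' Sums raw counts over all cells of each sample. Conserves totals: every
#' sample column sums to the total counts of its member cells.
#'
#' @param mx a [MaturationExperiment-class] (optionally subset by
#'   `cellType`).
#' @param cellType optional cell-type label to subset on.
#' @return list with `counts` (genes x samples integer matrix) and
#'   `samples` (data.frame: sample_id, age, sex, genotype, nCells).
#' @export
pseudobulkBySample <- function(mx, cellType = NULL) {
  if (!is.null(cellType)) {
    mx <- mx[, !is.na(colData(mx)$cell_type) &
               colData(mx)$cell_type == cellType]
  }
  smp <- as.character(colData(mx)$sample_id)
  ids <- unique(smp)
  cts <- assay(mx, "counts")
  agg <- vapply(ids, function(s) {
    cols <- which(smp == s)
    if (!length(cols)) {
      warning("sample ", s, " has no cells; zero row emitted")
      numeric(nrow(cts))
    } else {
      as.numeric(Matrix::rowSums(cts[, cols, drop = FALSE]))
    }
  }, numeric(nrow(cts)))
  rownames(agg) <- rownames(cts)
  cd <- as.data.frame(colData(mx))
  first <- cd[match(ids, cd$sample_id), c("sample_id", "age", "sex",
                                          "genotype")]
  first$age <- as.character(first$age)
  first$nCells <- as.integer(table(smp)[ids])
  rownames(first) <- NULL
  list(counts = agg, samples = first)
}

#' Developmental differential expression test (devDEGs)
#'
#' Per-gene moderated F-test of the age factor on sample-pseudobulk
#' log-CPM, with an intensity-trended empirical-Bayes variance
#' (limma-trend; expression filter [edgeR::filterByExpr()]), BH-adjusted.
#' Genes with FDR < 0.05 are the cell type's devDEGs. Ages represented by
#' a single sample are excluded with a warning.
#'
#' @param pb pseudobulk list from [pseudobulkBySample()].
#' @param minSamplesPerAge ages below this are dropped (default 2).
#' @return data.frame: gene, pValue, fdr, plus mean log-CPM per age.
#' @export
devdegTest <- function(pb, minSamplesPerAge = 2) {
  age <- pb$samples$age
  tab <- table(age)
  low <- names(tab)[tab < minSamplesPerAge]
  if (length(low)) {
    warning("excluding age(s) with < ", minSamplesPerAge, " samples: ",
            paste(low, collapse = ", "))
  }
  keepS <- !age %in% low
  if (length(unique(age[keepS])) < 2) {
    stop("need >= 2 ages with >= ", minSamplesPerAge, " samples")
  }
  counts <- pb$counts[, keepS, drop = FALSE]
  age <- factor(age[keepS])
  design <- stats::model.matrix(~age)
  dge <- edgeR::DGEList(counts = counts)
  keepG <- edgeR::filterByExpr(dge, design)
  dge <- edgeR::calcNormFactors(dge[keepG, , keep.lib.sizes = FALSE])
  logCPM <- edgeR::cpm(dge, log = TRUE, prior.count = 2)
  fit <- limma::eBayes(limma::lmFit(logCPM, design), trend = TRUE)
  tt <- limma::topTable(fit, coef = 2:ncol(design), number = Inf,
                        sort.by = "none")
  ageMeans <- vapply(levels(age), function(a) {
    rowMeans(logCPM[, age == a, drop = FALSE])
  }, numeric(nrow(logCPM)))
  if (is.null(dim(ageMeans))) ageMeans <- t(ageMeans)
  colnames(ageMeans) <- paste0("mean_", levels(age))
  data.frame(gene = rownames(tt), pValue = tt$P.Value,
             fdr = adjustBH(tt$P.Value), ageMeans, row.names = NULL)
}

#' Fit a smooth age trend to per-age means
#'
#' Penalized cubic regression spline on the age-rank axis (basis dimension
#' `min(6, n_ages - 1)`, smoothness by GCV), returning fitted values at
#' the observed ranks. Falls back to a linear fit (with a warning) below
#' four ages.
#'
#' @param y per-age means, ordered by age.
#' @param ranks age ranks (default `0:(length(y)-1)`).
#' @return fitted values at `ranks`.
#' @export
fitTrend <- function(y, ranks = seq_along(y) - 1) {
  stopifnot(length(y) == length(ranks))
  if (length(y) < 4) {
    warning("fewer than 4 ages; falling back to a linear fit")
    return(unname(stats::fitted(lm(y ~ ranks))))
  }
  k <- min(6, length(y) - 1)
  df <- data.frame(y = y, r = ranks)
  fit <- mgcv::gam(y ~ s(r, k = k, bs = "cr"), data = df, method = "GCV.Cp")
  unname(stats::fitted(fit))
}

#' Hierarchically cluster normalized expression trends
#'
#' Min-max normalizes each trend to [0, 1] (constant trends map to 0.5),
#' clusters with Ward linkage on Euclidean distance, and cuts the tree at
#' `nClusters`. Deterministic.
#'
#' @param trendMat instances x age-grid matrix of fitted trends.
#' @param nClusters number of clusters (>= 2).
#' @return list with `normalized`, `hclust`, `labels` and `clusterMeans`
#'   (cluster x age-grid mean trends).
#' @export
clusterTrends <- function(trendMat, nClusters) {
  if (nClusters < 2) stop("nClusters must be >= 2")
  if (nrow(trendMat) < nClusters) {
    stop("need at least nClusters = ", nClusters, " trend instances")
  }
  rng <- apply(trendMat, 1, function(x) diff(range(x)))
  lo <- apply(trendMat, 1, min)
  norm <- (trendMat - lo) / ifelse(rng == 0, 1, rng)
  norm[rng == 0, ] <- 0.5
  hc <- hclust(dist(norm), method = "ward.D2")
  labels <- cutree(hc, k = nClusters)
  means <- rowsum(norm, labels) / as.vector(table(labels))
  list(normalized = norm, hclust = hc, labels = labels,
       clusterMeans = means)
}

#' Classify devDEG sharing across cell types
#'
#' A gene detected as devDEG in more than 70% of cell types is `shared`,
#' in fewer than 20% `cell-type-specific`, otherwise `intermediate`
#' (strict inequalities at both boundaries).
#'
#' @param detection logical genes x cell types matrix (TRUE = devDEG).
#' @return named character vector of categories.
#' @export
classifySharing <- function(detection) {
  f <- rowMeans(detection)
  out <- ifelse(f > 0.7, "shared",
                ifelse(f < 0.2, "cell-type-specific", "intermediate"))
  setNames(out, rownames(detection))
}

#' Refinement score of a gene set between two ages
#'
#' Fraction of gene x cell-type combinations in the set that change
#' significantly (pseudobulk contrast, FDR < `fdr`) between `fromAge` and
#' `toAge`, among combinations with nonzero pseudobulk expression at one
#' or more ages.
#'
#' @param mx a [MaturationExperiment-class] with cell-type labels.
#' @param geneSet character vector of gene ids.
#' @param fromAge,toAge contrasted stages (defaults `"P10"`, `"P65"`).
#' @param fdr significance cutoff on the BH-adjusted p (default 0.05).
#' @param minCells cell types need this many cells at both stages.
#' @return list with `score`, `nSignificant`, `nExpressed` and the
#'   per-combination table.
#' @export
refinementScore <- function(mx, geneSet, fromAge = "P10", toAge = "P65",
                            fdr = 0.05, minCells = 10) {
  geneSet <- intersect(geneSet, rownames(mx))
  if (!length(geneSet)) stop("gene set does not intersect the matrix genes")
  cts <- unique(stats::na.omit(as.character(colData(mx)$cell_type)))
  rows <- list()
  for (ct in cts) {
    sub <- mx[, !is.na(colData(mx)$cell_type) &
                colData(mx)$cell_type == ct]
    ageVec <- as.character(colData(sub)$age)
    if (sum(ageVec == fromAge) < minCells ||
        sum(ageVec == toAge) < minCells) next
    pbAll <- pseudobulkBySample(sub)
    expressed <- rowSums(pbAll$counts[geneSet, , drop = FALSE]) > 0
    two <- sub[, ageVec %in% c(fromAge, toAge)]
    colData(two)$age <- droplevels(factor(as.character(colData(two)$age),
                                          levels = c(fromAge, toAge),
                                          ordered = TRUE))
    res <- tryCatch(devdegTest(pseudobulkBySample(two)),
                    error = function(e) NULL)
    if (is.null(res)) next
    sig <- setNames(res$fdr < fdr, res$gene)
    rows[[ct]] <- data.frame(cellType = ct, gene = geneSet,
                             expressed = unname(expressed),
                             significant = unname(sig[geneSet]) %in% TRUE)
  }
  tab <- do.call(rbind, rows)
  nExpressed <- sum(tab$expressed)
  if (!nExpressed) stop("no expressed gene x cell-type combinations")
  nSig <- sum(tab$significant & tab$expressed)
  list(score = nSig / nExpressed, nSignificant = nSig,
       nExpressed = nExpressed, table = tab)
}

#' Eigentrend of a gene set's fitted trends
#'
#' First principal component over ages of the row-centered trend matrix,
#' sign-oriented to correlate positively with the mean member trend.
#' Invariant to gene-wise constant offsets; flipping every input flips the
#' eigentrend.
#'
#' @param trendMat member genes x ages matrix of fitted trends.
#' @return numeric eigentrend over ages.
#' @export
eigentrend <- function(trendMat) {
  if (nrow(trendMat) < 2) {
    warning("fewer than 2 member trends; returning the centered trend")
    x <- trendMat[1, ] - mean(trendMat[1, ])
    return(setNames(as.numeric(x), colnames(trendMat)))
  }
  centered <- trendMat - rowMeans(trendMat)
  sv <- svd(centered)
  v1 <- sv$v[, 1] * sv$d[1] / sqrt(nrow(trendMat))
  meanTrend <- colMeans(centered)
  if (sum(v1 * meanTrend) < 0) v1 <- -v1
  setNames(v1, colnames(trendMat))
}

#' Filter gene sets by median devDEG overlap
#'
#' Keeps gene sets whose median number of overlapping devDEGs across cell
#' types is at least `minOverlap` (default 40), the inclusion rule used
#' upstream of eigentrend summaries.
#'
#' @param geneSets named list of gene-id vectors.
#' @param devdegLists named list (per cell type) of devDEG gene ids.
#' @param minOverlap minimum median overlap (default 40).
#' @return the retained subset of `geneSets`.
#' @export
filterGeneSetsByOverlap <- function(geneSets, devdegLists, minOverlap = 40) {
  keep <- vapply(geneSets, function(gs) {
    ov <- vapply(devdegLists, function(dd) length(intersect(gs, dd)),
                 numeric(1))
    stats::median(ov) >= minOverlap
  }, logical(1))
  geneSets[keep]
}
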