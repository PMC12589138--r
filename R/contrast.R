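#' Inter- versus intra-group centroid-distance contrast
#'
#' Tests whether two groups of samples (sexes or genotypes) occupy distinct
#' regions of the cell type's PCA space. All cells are jointly normalized
#' and embedded (2,000 HVGs, PCA, 20% variance rule, 100-component cap),
#' per-sample centroids are computed, and all pairwise Manhattan distances
#' between sample centroids are split into inter- and intra-group sets.
#' The effect size is mean(inter) / mean(intra); a two-sided t-test
#' compares the two distance sets. Distance pairs are treated as
#' independent observations, as in the source analyses; with few samples
#' the test is approximate and should be read alongside the permutation
#' calibration documented in the package vignette.
#'
#' @param mx a [MaturationExperiment-class] for one cell type (or use
#'   `cellType` to subset).
#' @param groupBy `colData` column defining the two groups
#'   (default `"sex"`).
#' @param cellType optional cell-type label to subset on.
#' @param minCells samples with fewer cells are dropped with a warning.
#' @param nHVG,maxPC,varTarget reduced-space parameters.
#' @return a [GroupContrast-class] (with `adjustedP = NA`; adjust across
#'   cell types with [adjustBH()]).
#' @export
groupDistanceContrast <- function(mx, groupBy = "sex", cellType = NULL,
                                  minCells = 10, nHVG = 2000, maxPC = 100,
                                  varTarget = 0.20) {
  if (!is.null(cellType)) {
    mx <- mx[, !is.na(colData(mx)$cell_type) &
               colData(mx)$cell_type == cellType]
  }
  grp <- as.character(colData(mx)[[groupBy]])
  smp <- as.character(colData(mx)$sample_id)
  sampleSize <- table(smp)
  low <- names(sampleSize)[sampleSize < minCells]
  if (length(low)) {
    warning("dropping sample(s) below ", minCells, " cells: ",
            paste(low, collapse = ", "))
    keep <- !smp %in% low
    mx <- mx[, keep]; grp <- grp[keep]; smp <- smp[keep]
  }
  sampleGroup <- tapply(grp, smp, function(g) g[1])
  gl <- sort(unique(sampleGroup))
  if (length(gl) != 2) stop("need exactly 2 groups; found ", length(gl))
  nPer <- table(factor(sampleGroup, levels = gl))
  if (any(nPer < 2)) {
    stop("group '", gl[which(nPer < 2)[1]],
         "' has fewer than 2 samples (no intra-group distances)")
  }
  rs <- .reducedSpace(mx, nHVG = nHVG, maxPC = maxPC, varTarget = varTarget)
  centroids <- rowsum(rs$scores, smp)
  centroids <- centroids / as.vector(table(smp)[rownames(centroids)])
  samples <- rownames(centroids)
  pairs <- utils::combn(samples, 2)
  d <- apply(pairs, 2, function(p) {
    sum(abs(centroids[p[1], ] - centroids[p[2], ]))
  })
  inter <- sampleGroup[pairs[1, ]] != sampleGroup[pairs[2, ]]
  tt <- t.test(d[inter], d[!inter])
  new("GroupContrast",
      cellType = if (is.null(cellType)) "(pooled)" else cellType,
      groupSizes = setNames(as.integer(nPer), gl),
      interDistances = d[inter], intraDistances = d[!inter],
      effectSize = mean(d[inter]) / mean(d[!inter]),
      pValue = tt$p.value, adjustedP = NA_real_,
      nPcs = as.integer(rs$m))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with cumulative-minimum
#' enforcement, capped at 1 (delegating to [stats::p.adjust()] after
#' validating the input).
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
adjustBH <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] and not be NA")
  }
  p.adjust(p, method = "BH")
}

#' Per-age sex difference in maturation distance
#'
#' Pairs male and female [DistanceTrajectory-class] objects by cell type
#' and, for every age shared by both sexes, reports the per-cell-type
#' (female - male) distance differences and a two-sided paired t-test of
#' male versus female distances across cell types.
#'
#' @param maleTrajectories,femaleTrajectories named lists of
#'   [DistanceTrajectory-class], names = cell types.
#' @param use `"mono"` (default) or `"raw"` distances.
#' @return data.frame with one row per age: mean and median difference,
#'   number of cell types, p-value.
#' @export
sexDistanceDifference <- function(maleTrajectories, femaleTrajectories,
                                  use = c("mono", "raw")) {
  use <- match.arg(use)
  shared <- intersect(names(maleTrajectories), names(femaleTrajectories))
  if (length(shared) < 2) {
    stop("need >= 2 shared cell types for the t-test; have ",
         length(shared))
  }
  pick <- function(tr) {
    d <- if (use == "mono") tr@monoDistance else tr@rawDistance
    setNames(d, tr@ages)
  }
  ages <- Reduce(intersect, c(lapply(maleTrajectories[shared],
                                     function(t) t@ages),
                              lapply(femaleTrajectories[shared],
                                     function(t) t@ages)))
  out <- lapply(ages, function(a) {
    m <- vapply(maleTrajectories[shared], function(t) pick(t)[[a]],
                numeric(1))
    f <- vapply(femaleTrajectories[shared], function(t) pick(t)[[a]],
                numeric(1))
    diffs <- f - m
    p <- if (all(diffs == 0)) 1 else t.test(f, m, paired = TRUE)$p.value
    data.frame(age = a, meanDifference = mean(diffs),
               medianDifference = stats::median(diffs),
               nCellTypes = length(shared), pValue = p)
  })
  do.call(rbind, out)
}

#' Pseudobulk two-group differential expression
#'
#' Sums raw counts per sample, removes genes flagged in the excluded
#' categories (mitochondrial, ribosomal, Y-chromosome and X-inactivation
#' by default), and tests each gene between the two conditions on log-CPM
#' with an intensity-trended empirical-Bayes moderated t-statistic
#' (limma-trend), followed by BH adjustment. Genes significant at adjusted
#' p < 0.05 are flagged.
#'
#' @param mx a [MaturationExperiment-class] for one cell type (or use
#'   `cellType` to subset).
#' @param groupBy `colData` column giving the two conditions
#'   (default `"sex"`).
#' @param cellType optional cell-type label to subset on.
#' @param excludeCategories rowData flag columns to drop before testing.
#' @return list with `table` (gene, log2FC — second condition level
#'   relative to the first —, pValue, adjustedP, significant),
#'   `excludedGenes` and `design`.
#' @export
pseudobulkDE <- function(mx, groupBy = "sex", cellType = NULL,
                         excludeCategories = c("mito", "ribo", "chrY", "xi")) {
  if (!is.null(cellType)) {
    mx <- mx[, !is.na(colData(mx)$cell_type) &
               colData(mx)$cell_type == cellType]
  }
  missing <- setdiff(excludeCategories, colnames(rowData(mx)))
  if (length(missing)) {
    stop("rowData lacks exclusion flag(s): ", paste(missing, collapse = ", "))
  }
  drop <- Reduce(`|`, lapply(excludeCategories,
                             function(cat) rowData(mx)[[cat]]))
  excluded <- rownames(mx)[drop]
  mx <- mx[!drop, ]
  pb <- pseudobulkBySample(mx)
  cond <- pb$samples[[groupBy]]
  if (length(unique(cond)) != 2) stop("need exactly 2 conditions")
  if (any(table(cond) < 2)) stop("need >= 2 samples per condition")
  design <- stats::model.matrix(~cond)
  dge <- edgeR::DGEList(counts = pb$counts)
  keep <- edgeR::filterByExpr(dge, design)
  dge <- edgeR::calcNormFactors(dge[keep, , keep.lib.sizes = FALSE])
  counts <- dge$counts
  logCPM <- edgeR::cpm(dge, log = TRUE, prior.count = 2)
  fit <- limma::lmFit(logCPM, design)
  fit <- limma::eBayes(fit, trend = TRUE)
  tab <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
  res <- data.frame(gene = rownames(tab), log2FC = tab$logFC,
                    pValue = tab$P.Value,
                    adjustedP = adjustBH(tab$P.Value), row.names = NULL)
  res$significant <- res$adjustedP < 0.05
  list(table = res, excludedGenes = excluded,
       design = data.frame(sample = colnames(counts), condition = cond))
}
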