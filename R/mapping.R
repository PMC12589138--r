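#' Train a k-nearest-neighbour label-transfer reference
#'
#' Builds the reference projection for prediction-score label transfer:
#' log-normalization, highly variable genes, PCA (up to `nPCs` components,
#' 150 by default) and the labeled reference cell scores used for
#' distance-weighted neighbour voting.
#'
#' @param mx reference [MaturationExperiment-class].
#' @param labels per-cell labels (defaults to `colData(mx)$cell_type`).
#' @param nHVG highly variable genes (default 2,000).
#' @param nPCs components of the reference projection (default 150).
#' @param k neighbours for soft voting (default 30).
#' @return a [ReferenceModel-class].
#' @export
trainReference <- function(mx, labels = colData(mx)$cell_type,
                           nHVG = 2000, nPCs = 150, k = 30) {
  labels <- as.character(labels)
  if (anyNA(labels)) stop("reference labels must not contain NA")
  tab <- table(labels)
  if (length(tab) < 2) stop("need >= 2 reference labels")
  if (any(tab < k)) {
    warning("label(s) with fewer than k = ", k, " cells: ",
            paste(names(tab)[tab < k], collapse = ", "))
  }
  mx <- logNormalize(mx)
  hvgs <- selectHVGs(mx, n = nHVG)
  space <- runPCA(mx, genes = hvgs, K = nPCs)
  new("ReferenceModel", hvgs = space@hvgs, center = space@center,
      scaleVec = space@scaleVec, rotation = space@rotation,
      scores = space@scores, labels = labels, k = as.integer(k))
}

## project query logcounts into a stored standardized-PCA space;
## genes absent from the query contribute their centered value 0
.projectIntoSpace <- function(ln, hvgs, center, scaleVec, rotation) {
  common <- intersect(hvgs, rownames(ln))
  if (!length(common)) stop("query shares no genes with the reference space")
  Q <- matrix(0, ncol(ln), length(hvgs),
              dimnames = list(colnames(ln), hvgs))
  Q[, common] <- sweep(sweep(as.matrix(Matrix::t(ln[common, , drop = FALSE])),
                             2, center[common]),
                       2, scaleVec[common], "/")
  Q %*% rotation
}

#' Prediction scores by distance-weighted neighbour voting
#'
#' Projects query cells into the reference PCA space and scores each
#' reference label as the inverse-distance-weighted fraction of that
#' label among the k nearest reference cells. Scores are non-negative and
#' sum to 1 per cell.
#'
#' @param model a [ReferenceModel-class].
#' @param mx query [MaturationExperiment-class].
#' @return matrix query cells x reference labels.
#' @export
predictionScores <- function(model, mx) {
  mx <- logNormalize(mx)
  q <- .projectIntoSpace(assay(mx, "logcounts"), model@hvgs, model@center,
                         model@scaleVec, model@rotation)
  ref <- model@scores
  labs <- sort(unique(model@labels))
  k <- min(model@k, nrow(ref))
  ## squared Euclidean distances query x reference via the expansion trick
  d2 <- outer(rowSums(q^2), rep(1, nrow(ref))) +
    outer(rep(1, nrow(q)), rowSums(ref^2)) - 2 * tcrossprod(q, ref)
  d2[d2 < 0] <- 0
  scores <- matrix(0, nrow(q), length(labs),
                   dimnames = list(rownames(q), labs))
  eps <- 1e-8
  for (i in seq_len(nrow(q))) {
    nn <- order(d2[i, ])[seq_len(k)]
    w <- 1 / (sqrt(d2[i, nn]) + eps)
    vote <- tapply(w, model@labels[nn], sum)
    scores[i, names(vote)] <- vote / sum(w)
  }
  scores
}

#' Assign labels from prediction scores
#'
#' A cell is assigned its top-scoring label when the top score exceeds
#' `hi`; otherwise it is still assigned when the top score exceeds `lo`
#' *and* is at least `ratio` times the second-best score; otherwise it is
#' unassigned (`NA`).
#'
#' @param scores matrix cells x labels of prediction scores.
#' @param hi high-confidence threshold (default 0.8, strict).
#' @param lo low threshold for the ratio clause (default 0.5, strict).
#' @param ratio top-to-second-best ratio (default 2, inclusive).
#' @return character vector of labels, `NA` = unassigned.
#' @export
assignLabels <- function(scores, hi = 0.8, lo = 0.5, ratio = 2.0) {
  labs <- colnames(scores)
  apply(scores, 1, function(s) {
    o <- order(s, decreasing = TRUE)
    top <- s[o[1]]
    second <- if (length(s) > 1) s[o[2]] else 0
    if (top > hi || (top > lo && top >= ratio * second)) labs[o[1]]
    else NA_character_
  })
}

#' Mean prediction-score matrix and identity ratio
#'
#' `predictionScoreMatrix()` averages per-cell scores within query cell
#' types. `identityRatio()` quantifies one-to-one mapping quality per row:
#' (best match - second-best match) / best match, which is 1 iff all
#' off-diagonal mass is zero and 0 when the runner-up ties the best.
#'
#' @param scores matrix cells x reference labels.
#' @param queryLabels per-cell query cell-type labels.
#' @return `predictionScoreMatrix()`: matrix query type x reference label.
#' @export
predictionScoreMatrix <- function(scores, queryLabels) {
  queryLabels <- as.character(queryLabels)
  keep <- !is.na(queryLabels)
  rowsum(scores[keep, , drop = FALSE], queryLabels[keep]) /
    as.vector(table(queryLabels[keep]))
}

#' @rdname predictionScoreMatrix
#' @param scoreMatrix query type x reference label mean-score matrix.
#' @return `identityRatio()`: named numeric vector per query type.
#' @export
identityRatio <- function(scoreMatrix) {
  vapply(rownames(scoreMatrix), function(ct) {
    if (!ct %in% colnames(scoreMatrix)) return(NA_real_)
    best <- scoreMatrix[ct, ct]
    others <- setdiff(colnames(scoreMatrix), ct)
    second <- if (length(others)) max(scoreMatrix[ct, others]) else 0
    (best - second) / best
  }, numeric(1))
}

#' Iterative age-wise label transfer
#'
#' Processes ages from oldest to youngest, the oldest (adult) age keeping
#' its given labels. Each younger age is scored against the union of all
#' older, already-labeled ages and assigned by [assignLabels()]. Mirrors
#' sequential mapping of developmental stages onto older stages.
#'
#' @param mx a [MaturationExperiment-class]; `colData(mx)$cell_type` must
#'   label the adult cells (labels at other ages are ignored).
#' @param hi,lo,ratio assignment thresholds, see [assignLabels()].
#' @param nHVG,nPCs,k reference-model parameters, see [trainReference()].
#' @return list with `labels` (per cell, `NA` = unassigned), `perAge`
#'   data.frame of assignment rates and `scoreMatrices` (per age, mean
#'   scores of assigned cells by assigned type).
#' @export
mapAgesIteratively <- function(mx, hi = 0.8, lo = 0.5, ratio = 2.0,
                               nHVG = 2000, nPCs = 150, k = 30) {
  agesPresent <- intersect(ageLevels(mx), unique(as.character(colData(mx)$age)))
  adult <- agesPresent[length(agesPresent)]
  labels <- setNames(rep(NA_character_, ncol(mx)), colnames(mx))
  isAdult <- colData(mx)$age == adult
  if (!any(isAdult) || all(is.na(colData(mx)$cell_type[isAdult]))) {
    stop("adult age must carry cell_type labels")
  }
  labels[isAdult] <- as.character(colData(mx)$cell_type[isAdult])
  perAge <- data.frame(age = character(), nCells = integer(),
                       assignedRate = numeric())
  scoreMatrices <- list()
  for (a in rev(agesPresent[-length(agesPresent)])) {
    refCells <- names(labels)[!is.na(labels)]
    ref <- mx[, refCells]
    colData(ref)$cell_type <- labels[refCells]
    model <- trainReference(ref, nHVG = nHVG, nPCs = nPCs, k = k)
    queryCells <- colnames(mx)[colData(mx)$age == a]
    sc <- predictionScores(model, mx[, queryCells])
    asg <- assignLabels(sc, hi = hi, lo = lo, ratio = ratio)
    if (!any(!is.na(asg))) {
      stop("age ", a, ": no cell passed the assignment thresholds")
    }
    labels[queryCells] <- asg
    perAge <- rbind(perAge,
                    data.frame(age = a, nCells = length(queryCells),
                               assignedRate = mean(!is.na(asg))))
    scoreMatrices[[a]] <- predictionScoreMatrix(sc, asg)
  }
  list(labels = labels, perAge = perAge, scoreMatrices = scoreMatrices)
}
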