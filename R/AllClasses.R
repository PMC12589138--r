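#' Gene category flags expected on a MaturationExperiment
#'
#' Logical columns of `rowData()` marking mitochondrial, ribosomal,
#' immediate-early, apoptotic, red-blood-cell, Y-chromosome and
#' X-inactivation genes. QC filtering and pseudobulk gene exclusion look
#' genes up by these names.
#' @keywords internal
.GENE_CATEGORIES <- c("mito", "ribo", "ieg", "apoptotic", "rbc", "chrY", "xi")

.CELL_META_COLUMNS <- c("sample_id", "age", "sex", "genotype")

#' MaturationExperiment: counts plus developmental metadata
#'
#' A thin extension of [SingleCellExperiment::SingleCellExperiment] that
#' guarantees the per-cell metadata the maturation analyses rely on:
#' `sample_id`, an ordered `age` factor (oldest stage last, treated as the
#' adult reference), `sex` (`"M"`/`"F"`), `genotype`
#' (`"control"`/`"mutant"`) and an optional `cell_type` label
#' (`NA` = unassigned). `rowData()` carries the logical gene category flags
#' (`mito`, `ribo`, `ieg`, `apoptotic`, `rbc`, `chrY`, `xi`).
#'
#' Rows are genes and columns are cells, following Bioconductor convention.
#' Each `sample_id` must map to a single (age, sex, genotype) combination.
#'
#' @export
setClass("MaturationExperiment", contains = "SingleCellExperiment")

setValidity("MaturationExperiment", function(object) {
  msg <- character()
  cd <- colData(object)
  missing_cols <- setdiff(.CELL_META_COLUMNS, colnames(cd))
  if (length(missing_cols)) {
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(missing_cols, collapse = ", ")))
  }
  if (!"counts" %in% assayNames(object)) {
    msg <- c(msg, "assay 'counts' is required")
  } else {
    cts <- assay(object, "counts")
    vals <- if (inherits(cts, "sparseMatrix")) cts@x else as.vector(cts)
    if (length(vals) && (any(vals < 0) || any(vals != round(vals)))) {
      msg <- c(msg, "counts must be non-negative integers")
    }
  }
  if ("age" %in% colnames(cd)) {
    # level order carries the stage ordering (oldest = adult last);
    # combination operations may drop the "ordered" attribute, which is
    # immaterial as long as the levels stay ordered
    if (!is.factor(cd$age)) {
      msg <- c(msg, "age must be a factor ordered oldest-last")
    }
  }
  if ("sex" %in% colnames(cd) && !all(cd$sex %in% c("M", "F"))) {
    msg <- c(msg, "sex must be 'M' or 'F'")
  }
  if ("genotype" %in% colnames(cd) &&
      !all(cd$genotype %in% c("control", "mutant"))) {
    msg <- c(msg, "genotype must be 'control' or 'mutant'")
  }
  if (all(c("sample_id", "age", "sex", "genotype") %in% colnames(cd)) &&
      nrow(cd) > 0) {
    key <- paste(cd$age, cd$sex, cd$genotype)
    if (any(tapply(key, cd$sample_id, function(k) length(unique(k))) > 1)) {
      msg <- c(msg, "each sample_id must map to one (age, sex, genotype)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MaturationExperiment
#'
#' @param counts genes x cells matrix of non-negative integer counts
#'   (dense or `Matrix` sparse).
#' @param cellMeta data.frame/DataFrame with one row per cell holding at
#'   least `sample_id`, `age`, `sex`, `genotype`; an optional `cell_type`
#'   column gives labels (`NA` = unassigned).
#' @param geneMeta data.frame/DataFrame with one row per gene; logical gene
#'   category columns (`mito`, `ribo`, ...) are added as `FALSE` when absent.
#' @param ageLevels character vector giving the ordered stage vocabulary;
#'   defaults to the order of first appearance in `cellMeta$age`.
#' @return A [MaturationExperiment-class] object.
#' @export
MaturationExperiment <- function(counts, cellMeta, geneMeta = NULL,
                                 ageLevels = NULL) {
  cellMeta <- as.data.frame(cellMeta)
  if (is.null(ageLevels)) {
    ageLevels <- if (is.factor(cellMeta$age)) levels(cellMeta$age)
                 else unique(as.character(cellMeta$age))
  }
  cellMeta$age <- factor(as.character(cellMeta$age), levels = ageLevels,
                         ordered = TRUE)
  if (anyNA(cellMeta$age)) {
    stop("cellMeta$age contains stages outside ageLevels")
  }
  if (!"cell_type" %in% colnames(cellMeta)) cellMeta$cell_type <- NA_character_
  if (is.null(geneMeta)) {
    geneMeta <- data.frame(gene_id = rownames(counts) %||%
                             paste0("gene", seq_len(nrow(counts))))
  }
  geneMeta <- as.data.frame(geneMeta)
  for (cat in .GENE_CATEGORIES) {
    if (!cat %in% colnames(geneMeta)) geneMeta[[cat]] <- FALSE
  }
  if (is.null(rownames(counts))) rownames(counts) <- geneMeta$gene_id
  if (is.null(colnames(counts))) {
    colnames(counts) <- cellMeta$cell_id %||% paste0("cell", seq_len(ncol(counts)))
  }
  sce <- SingleCellExperiment(assays = list(counts = counts),
                              colData = DataFrame(cellMeta, row.names = colnames(counts)),
                              rowData = DataFrame(geneMeta, row.names = rownames(counts)))
  new("MaturationExperiment", sce)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn MaturationExperiment ordered vector of age stage labels.
#' @param x a `MaturationExperiment`.
#' @export
ageLevels <- function(x) levels(colData(x)$age)

#' @describeIn MaturationExperiment the adult (last) stage label.
#' @export
adultAge <- function(x) {
  lv <- ageLevels(x)
  lv[length(lv)]
}

#' Per-cell-type maturation-distance trajectory
#'
#' Holds, for one cell type, the Manhattan (L1) distance between each age's
#' centroid and the adult centroid in the cell type's reduced PCA space,
#' together with the monotonized series, per-step decreases and the
#' gradual/stepwise trajectory class (1 = gradual, 2 = intermediate,
#' 3 = stepwise, `NA` when no net maturation).
#'
#' @slot cellType character scalar.
#' @slot ages stage labels retained (adult last).
#' @slot nPcs number of principal components used (20% variance rule).
#' @slot rawDistance per-age L1 distance to the adult centroid.
#' @slot monoDistance monotonized (non-increasing) distances.
#' @slot stepDecrease decrease across each consecutive age pair.
#' @slot trajClass integer 1/2/3 or NA.
#' @slot nCells cells per retained age.
#' @export
setClass("DistanceTrajectory",
  representation(cellType = "character", ages = "character",
                 nPcs = "integer", rawDistance = "numeric",
                 monoDistance = "numeric", stepDecrease = "numeric",
                 trajClass = "integer", nCells = "integer"))

setValidity("DistanceTrajectory", function(object) {
  msg <- character()
  n <- length(object@ages)
  if (length(object@rawDistance) != n || length(object@monoDistance) != n) {
    msg <- c(msg, "distance vectors must match ages")
  }
  if (n && any(diff(object@monoDistance) > 1e-12)) {
    msg <- c(msg, "monoDistance must be non-increasing")
  }
  if (n && abs(object@monoDistance[n]) > 1e-12) {
    msg <- c(msg, "adult monoDistance must be 0")
  }
  if (length(object@stepDecrease) &&
      any(object@stepDecrease < -1e-12)) {
    msg <- c(msg, "stepDecrease must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "DistanceTrajectory", function(object) {
  cat("DistanceTrajectory for", object@cellType, "\n")
  cat("  ages:", paste(object@ages, collapse = " "), "\n")
  cat("  nPcs:", object@nPcs, " class:",
      ifelse(is.na(object@trajClass), "NA", object@trajClass), "\n")
  cat("  mono distance:",
      paste(signif(object@monoDistance, 4), collapse = " "), "\n")
})

#' @describeIn DistanceTrajectory trajectory class (1/2/3 or NA).
#' @param x a `DistanceTrajectory`.
#' @export
trajectoryClass <- function(x) x@trajClass

#' @describeIn DistanceTrajectory monotonized distances, named by age.
#' @export
monoDistance <- function(x) setNames(x@monoDistance, x@ages)

#' @describeIn DistanceTrajectory raw distances, named by age.
#' @export
rawDistance <- function(x) setNames(x@rawDistance, x@ages)

#' Inter- versus intra-group centroid-distance contrast
#'
#' Result of [groupDistanceContrast()]: all pairwise Manhattan distances
#' between sample centroids in the joint PCA space, split into inter-group
#' and intra-group sets; the effect size mean(inter)/mean(intra); and the
#' two-sided t-test p-value of inter versus intra distances.
#'
#' @slot cellType character scalar.
#' @slot groupSizes named integer, samples per group.
#' @slot interDistances,intraDistances numeric distance sets.
#' @slot effectSize mean(inter)/mean(intra).
#' @slot pValue two-sided t-test p.
#' @slot adjustedP BH-adjusted p (NA until adjusted across cell types).
#' @slot nPcs number of components used.
#' @export
setClass("GroupContrast",
  representation(cellType = "character", groupSizes = "integer",
                 interDistances = "numeric", intraDistances = "numeric",
                 effectSize = "numeric", pValue = "numeric",
                 adjustedP = "numeric", nPcs = "integer"))

setValidity("GroupContrast", function(object) {
  msg <- character()
  n <- object@groupSizes
  if (length(n) == 2) {
    if (length(object@interDistances) != n[1] * n[2]) {
      msg <- c(msg, "expected n1*n2 inter-group distances")
    }
    if (length(object@intraDistances) != choose(n[1], 2) + choose(n[2], 2)) {
      msg <- c(msg, "expected C(n1,2)+C(n2,2) intra-group distances")
    }
  }
  if (length(object@effectSize) && !is.na(object@effectSize) &&
      object@effectSize <= 0) {
    msg <- c(msg, "effectSize must be positive")
  }
  if (length(object@pValue) && !is.na(object@pValue) &&
      (object@pValue < 0 || object@pValue > 1)) {
    msg <- c(msg, "pValue must lie in [0,1]")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroupContrast", function(object) {
  cat("GroupContrast for", object@cellType, "\n")
  cat("  groups:", paste(names(object@groupSizes), object@groupSizes,
                         sep = "=", collapse = ", "), "\n")
  cat("  effect size:", signif(object@effectSize, 4),
      " p:", signif(object@pValue, 4),
      " adjusted:", signif(object@adjustedP, 4), "\n")
})

#' @describeIn GroupContrast effect size mean(inter)/mean(intra).
#' @param x a `GroupContrast`.
#' @export
effectSize <- function(x) x@effectSize

#' Principal-curve pseudotime model for one cell type
#'
#' Stores the reduced space (HVGs, standardization vectors, rotation to the
#' top components), the fitted curve as an ordered polyline with arc-length
#' parameterization, the orientation (adult-high) and the pseudotime of the
#' training cells after normalization to [0, 1].
#'
#' @slot cellType character scalar.
#' @slot hvgs genes defining the reduced space.
#' @slot center,scaleVec standardization vectors over `hvgs`.
#' @slot rotation genes x K loading matrix.
#' @slot curvePoints grid x K polyline vertices along the curve.
#' @slot arcLength cumulative arc length at each vertex.
#' @slot lambdaRange raw arc-length range mapped to [0, 1].
#' @slot flipped TRUE when orientation required reversing the arc length.
#' @slot pseudotime per training cell, in [0, 1], adult-high.
#' @slot converged logical convergence flag of the iterative fit.
#' @export
setClass("PseudotimeCurve",
  representation(cellType = "character", hvgs = "character",
                 center = "numeric", scaleVec = "numeric",
                 rotation = "matrix", curvePoints = "matrix",
                 arcLength = "numeric", lambdaRange = "numeric",
                 flipped = "logical", pseudotime = "numeric",
                 converged = "logical"))

setMethod("show", "PseudotimeCurve", function(object) {
  cat("PseudotimeCurve for", object@cellType, "\n")
  cat("  reduced space:", length(object@hvgs), "genes x",
      ncol(object@rotation), "PCs;",
      nrow(object@curvePoints), "curve vertices\n")
  cat("  training cells:", length(object@pseudotime),
      " converged:", object@converged, "\n")
})

#' @describeIn PseudotimeCurve pseudotime of the training cells.
#' @param x a `PseudotimeCurve`.
#' @export
pseudotime <- function(x) x@pseudotime

#' k-nearest-neighbour label-transfer reference model
#'
#' Built by [trainReference()]: the reference PCA space (HVGs,
#' standardization, rotation), the reference cell scores and labels, and
#' the neighbourhood size used for soft voting.
#'
#' @slot hvgs,center,scaleVec,rotation reduced-space definition.
#' @slot scores reference cells x K component scores.
#' @slot labels reference cell labels.
#' @slot k neighbours used for voting.
#' @export
setClass("ReferenceModel",
  representation(hvgs = "character", center = "numeric",
                 scaleVec = "numeric", rotation = "matrix",
                 scores = "matrix", labels = "character", k = "integer"))

setMethod("show", "ReferenceModel", function(object) {
  cat("ReferenceModel:", length(object@labels), "cells,",
      length(unique(object@labels)), "labels,",
      ncol(object@scores), "PCs, k =", object@k, "\n")
})
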