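## shared reduced-space pipeline: log-normalize -> HVGs -> PCA (<= maxPC)
## -> keep the smallest m components explaining varTarget of variance
.reducedSpace <- function(mx, nHVG = 2000, maxPC = 100, varTarget = 0.20) {
  mx <- logNormalize(mx)
  hvgs <- selectHVGs(mx, n = nHVG)
  space <- runPCA(mx, genes = hvgs, K = maxPC)
  m <- pcCountForVariance(space, target = varTarget, cap = maxPC)
  list(scores = space@scores[, seq_len(m), drop = FALSE], m = m,
       space = space)
}

#' Monotonize a distance series
#'
#' Enforces the non-increasing maturation-distance convention: whenever the
#' distance rises at a later age it is clamped to the previous age's value,
#' i.e. `out[i] = min(out[i-1], in[i])` (the running minimum). Idempotent;
#' output never exceeds the input elementwise.
#'
#' @param x numeric distances ordered by age.
#' @return numeric vector, non-increasing.
#' @export
monotonize <- function(x) {
  stopifnot(length(x) >= 1)
  cummin(x)
}

#' Classify a maturation trajectory as gradual, intermediate or stepwise
#'
#' Counts the minimal number of consecutive-age steps, taken largest-first,
#' whose decreases sum to at least 90% of the total decrease. Class 3
#' (stepwise) when 1-2 steps suffice, class 2 (intermediate) at 3 steps,
#' class 1 (gradual) at 4 or more. `NA` when there is no net decrease.
#'
#' @param mono monotonized distance series ordered by age.
#' @return integer 1, 2, 3 or NA.
#' @export
classifyTrajectory <- function(mono) {
  total <- mono[1] - mono[length(mono)]
  if (length(mono) < 2 || total <= 0) return(NA_integer_)
  steps <- sort(-diff(mono), decreasing = TRUE)
  k <- which(cumsum(steps) >= 0.9 * total)[1]
  if (k <= 2) 3L else if (k == 3) 2L else 1L
}

#' Maturation-distance trajectory of one cell type
#'
#' For one cell type across ages: log-normalization, 2,000 HVGs, PCA, the
#' smallest m components explaining 20% of variance (capped at 100), the
#' per-age centroid over those components, and the Manhattan (L1) distance
#' between each age's centroid and the adult centroid. The series is then
#' monotonized and classified.
#'
#' @param mx a [MaturationExperiment-class], either already restricted to
#'   one cell type or with `cellType` naming the subset to take.
#' @param cellType optional cell-type label to subset on.
#' @param minCells ages with fewer cells are dropped with a warning
#'   (default 10).
#' @param nHVG,maxPC,varTarget reduced-space parameters.
#' @return a [DistanceTrajectory-class].
#' @export
distanceTrajectory <- function(mx, cellType = NULL, minCells = 10,
                               nHVG = 2000, maxPC = 100, varTarget = 0.20) {
  if (!is.null(cellType)) {
    mx <- mx[, !is.na(colData(mx)$cell_type) &
               colData(mx)$cell_type == cellType]
  } else {
    cellType <- unique(as.character(colData(mx)$cell_type))
    cellType <- cellType[!is.na(cellType)]
    if (length(cellType) != 1) cellType <- "(pooled)"
  }
  ageVec <- as.character(colData(mx)$age)
  tab <- table(factor(ageVec, levels = ageLevels(mx)))
  present <- names(tab)[tab > 0]
  low <- names(tab)[tab > 0 & tab < minCells]
  if (length(low)) {
    warning("dropping age(s) below ", minCells, " cells: ",
            paste(low, collapse = ", "))
  }
  keepAges <- setdiff(present, low)
  if (length(keepAges) < 2) stop("fewer than 2 ages with enough cells")
  mx <- mx[, ageVec %in% keepAges]
  ageVec <- as.character(colData(mx)$age)
  rs <- .reducedSpace(mx, nHVG = nHVG, maxPC = maxPC, varTarget = varTarget)
  centroids <- rowsum(rs$scores, ageVec)
  centroids <- centroids / as.vector(table(ageVec)[rownames(centroids)])
  centroids <- centroids[keepAges, , drop = FALSE]
  adult <- keepAges[length(keepAges)]
  rawD <- apply(centroids, 1, function(ce) sum(abs(ce - centroids[adult, ])))
  mono <- monotonize(rawD)
  new("DistanceTrajectory", cellType = cellType, ages = keepAges,
      nPcs = as.integer(rs$m), rawDistance = unname(rawD),
      monoDistance = unname(mono), stepDecrease = unname(-diff(mono)),
      trajClass = classifyTrajectory(mono),
      nCells = as.integer(tab[keepAges]))
}

#' Nearest-neighbour maturity per age
#'
#' In the same reduced space as [distanceTrajectory()], finds for every
#' cell its k nearest neighbours (Euclidean, self excluded) among all the
#' cell type's cells, and reports, per age, the fraction of those
#' neighbours that are adult cells.
#'
#' @param mx a [MaturationExperiment-class] for one cell type (or use
#'   `cellType` to subset).
#' @param cellType optional cell-type label to subset on.
#' @param k neighbours per cell (default 50).
#' @param nHVG,maxPC,varTarget reduced-space parameters.
#' @return list with `cellType`, `k` and `fraction` (named by age).
#' @export
nnMaturity <- function(mx, cellType = NULL, k = 50,
                       nHVG = 2000, maxPC = 100, varTarget = 0.20) {
  if (!is.null(cellType)) {
    mx <- mx[, !is.na(colData(mx)$cell_type) &
               colData(mx)$cell_type == cellType]
  }
  n <- ncol(mx)
  if (n <= k) stop("need more than k = ", k, " cells; have ", n,
                   " (use a smaller k)")
  rs <- .reducedSpace(mx, nHVG = nHVG, maxPC = maxPC, varTarget = varTarget)
  D <- as.matrix(dist(rs$scores))
  diag(D) <- Inf
  adult <- adultAge(mx)
  isAdult <- as.character(colData(mx)$age) == adult
  adultNN <- vapply(seq_len(n), function(i) {
    nn <- order(D[i, ])[seq_len(k)]
    sum(isAdult[nn])
  }, numeric(1))
  ageVec <- as.character(colData(mx)$age)
  agesPresent <- intersect(ageLevels(mx), unique(ageVec))
  frac <- vapply(agesPresent, function(a) {
    cells <- ageVec == a
    sum(adultNN[cells]) / (k * sum(cells))
  }, numeric(1))
  list(cellType = cellType %||% "(pooled)", k = k, fraction = frac)
}

#' Compare trajectory groups by two-way ANOVA
#'
#' Tests whether groups of cell types differ in their (monotonized)
#' maturation distance, with age and group as fixed factors and cell types
#' as replicates. Returns the group main-effect p-value.
#'
#' @param trajectories list of [DistanceTrajectory-class] objects.
#' @param groups group label per trajectory.
#' @return list with `pValue` (group main effect) and the `anova` table.
#' @export
compareTrajectoryGroups <- function(trajectories, groups) {
  groups <- as.character(groups)
  stopifnot(length(trajectories) == length(groups))
  if (length(unique(groups)) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("need >= 2 cell types per group")
  df <- do.call(rbind, Map(function(tr, g) {
    data.frame(cellType = tr@cellType, age = tr@ages,
               distance = tr@monoDistance, group = g)
  }, trajectories, groups))
  fit <- aov(distance ~ age + group, data = df)
  tab <- anova(fit)
  list(pValue = tab["group", "Pr(>F)"], anova = tab)
}
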