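#' Specification of a synthetic developmental snRNA-seq dataset
#'
#' Parameter object for [generateDataset()]. The generator emulates the
#' design of a developmental single-nucleus atlas: ordered age stages with a
#' fixed number of samples per sex per age, discrete cell types separated by
#' marker genes, negative-binomial counts with log-normal library sizes, and
#' planted per-gene age trends whose tempo follows a per-cell-type
#' maturation schedule (gradual, intermediate or stepwise). An optional
#' mutant genotype runs the same trends on a clock delayed by
#' `delayStages` age stages (clamped at the first stage).
#'
#' The negative-binomial parameterization is `variance = mu + mu^2/theta`;
#' `theta = Inf` (or very large) recovers Poisson. Trends act on the age
#' *rank* axis through the schedule, not on calendar days: each cell type's
#' schedule maps age rank to maturation progress in [0, 1], reaching 1 one
#' stage before the final one, so fully mature stages are indistinguishable.
#' Expected expression is composition-normalized: per condition the gene
#' means are scaled to proportions, and each cell's expected total equals
#' its drawn library size.
#'
#' @slot nCellTypes,nGenes positive counts.
#' @slot ages ordered stage labels; the last stage is the adult reference.
#' @slot samplesPerSexPerAge control samples per sex at each age.
#' @slot mutantSamplesPerSexPerAge mutant samples per sex at each age
#'   (0 disables the mutant genotype).
#' @slot cellsPerTypePerSample cells drawn per cell type per sample.
#' @slot depthLogMean,depthLogSd log-normal library-size parameters.
#' @slot nbDispersion inverse-overdispersion theta.
#' @slot markerGenesPerType,markerFoldChange cell-type markers and their
#'   baseline multiplier.
#' @slot identityLogSd per-cell-type identity program: log-normal SD of a
#'   gene-by-cell-type baseline multiplier applied to every gene, giving
#'   each type a stable genome-wide signature (real cell types differ
#'   across hundreds of genes, not only exclusive markers).
#' @slot trendGeneFraction fraction of genes carrying an age trend.
#' @slot trendTypeWeights sampling weights over trend shapes
#'   (`up`, `down`, `step`, `transient`).
#' @slot trendAmplitude maximum natural-log fold change over the age range.
#' @slot maturationClasses planted class (1/2/3) per cell type.
#' @slot sexEffect list of planted sex effects; each element a list with
#'   `cellType`, `genes` (gene ids), `lfc` (natural-log fold change added in
#'   females) and `ages` (stage labels affected).
#' @slot delayStages non-negative stage shift of the mutant clock.
#' @slot geneCategoryFractions named fractions of genes flagged per
#'   category (`mito`, `ribo`, `ieg`, `apoptotic`, `rbc`, `chrY`, `xi`).
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticSpec",
  representation(nCellTypes = "integer", nGenes = "integer",
                 ages = "character", samplesPerSexPerAge = "integer",
                 mutantSamplesPerSexPerAge = "integer",
                 cellsPerTypePerSample = "integer",
                 depthLogMean = "numeric", depthLogSd = "numeric",
                 nbDispersion = "numeric", markerGenesPerType = "integer",
                 markerFoldChange = "numeric", identityLogSd = "numeric",
                 trendGeneFraction = "numeric",
                 trendTypeWeights = "numeric", trendAmplitude = "numeric",
                 maturationClasses = "integer", sexEffect = "list",
                 delayStages = "integer",
                 geneCategoryFractions = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  chkPos <- function(v, nm) {
    if (length(v) != 1 || is.na(v) || v < 1)
      paste0("field '", nm, "' must be a positive count") else character()
  }
  msg <- c(msg,
           chkPos(object@nCellTypes, "nCellTypes"),
           chkPos(object@nGenes, "nGenes"),
           chkPos(object@samplesPerSexPerAge, "samplesPerSexPerAge"),
           chkPos(object@cellsPerTypePerSample, "cellsPerTypePerSample"))
  if (length(object@ages) < 2) msg <- c(msg, "field 'ages' needs >= 2 stages")
  if (anyDuplicated(object@ages)) msg <- c(msg, "field 'ages' has duplicates")
  if (object@mutantSamplesPerSexPerAge < 0) {
    msg <- c(msg, "field 'mutantSamplesPerSexPerAge' must be >= 0")
  }
  if (object@nbDispersion <= 0) {
    msg <- c(msg, "field 'nbDispersion' must be positive")
  }
  if (object@identityLogSd < 0) {
    msg <- c(msg, "field 'identityLogSd' must be >= 0")
  }
  if (object@trendGeneFraction < 0 || object@trendGeneFraction > 1) {
    msg <- c(msg, "field 'trendGeneFraction' must lie in [0,1]")
  }
  if (object@delayStages < 0 ||
      object@delayStages >= length(object@ages)) {
    msg <- c(msg, "field 'delayStages' must satisfy 0 <= delay < n ages")
  }
  gcf <- object@geneCategoryFractions
  if (any(gcf < 0 | gcf > 1) || sum(gcf) > 1) {
    msg <- c(msg,
             "field 'geneCategoryFractions' must lie in [0,1] and sum <= 1")
  }
  if (!all(object@maturationClasses %in% 1:3) ||
      length(object@maturationClasses) != object@nCellTypes) {
    msg <- c(msg,
             "field 'maturationClasses' must give a class in 1:3 per cell type")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SyntheticSpec-class
#' @param nCellTypes,nGenes,ages,samplesPerSexPerAge,mutantSamplesPerSexPerAge
#'   see slots.
#' @param cellsPerTypePerSample,depthLogMean,depthLogSd,nbDispersion see slots.
#' @param markerGenesPerType,markerFoldChange,identityLogSd see slots.
#' @param trendGeneFraction see slots.
#' @param trendTypeWeights,trendAmplitude,maturationClasses,sexEffect see slots.
#' @param delayStages,geneCategoryFractions,seed see slots.
#' @return A validated `SyntheticSpec`.
#' @export
syntheticSpec <- function(nCellTypes = 12, nGenes = 2000,
                          ages = c("E16", "E18", "P0", "P4", "P10", "P18",
                                   "P28", "P65"),
                          samplesPerSexPerAge = 2,
                          mutantSamplesPerSexPerAge = 0,
                          cellsPerTypePerSample = 60,
                          depthLogMean = log(5000), depthLogSd = 0.4,
                          nbDispersion = 10,
                          markerGenesPerType = 10, markerFoldChange = 8,
                          identityLogSd = 0.5,
                          trendGeneFraction = 0.25,
                          trendTypeWeights = c(up = 0.40, down = 0.40,
                                               step = 0.15, transient = 0.05),
                          trendAmplitude = log(4),
                          maturationClasses = NULL,
                          sexEffect = list(),
                          delayStages = 0,
                          geneCategoryFractions = c(mito = 0.01, ribo = 0.03,
                                                    ieg = 0.005,
                                                    apoptotic = 0.005,
                                                    rbc = 0.002, chrY = 0.002,
                                                    xi = 0.002),
                          seed = 1) {
  if (is.null(maturationClasses)) {
    maturationClasses <- rep_len(1:3, nCellTypes)
  }
  gcf <- setNames(rep(0, length(.GENE_CATEGORIES)), .GENE_CATEGORIES)
  gcf[names(geneCategoryFractions)] <- geneCategoryFractions
  new("SyntheticSpec",
      nCellTypes = as.integer(nCellTypes), nGenes = as.integer(nGenes),
      ages = as.character(ages),
      samplesPerSexPerAge = as.integer(samplesPerSexPerAge),
      mutantSamplesPerSexPerAge = as.integer(mutantSamplesPerSexPerAge),
      cellsPerTypePerSample = as.integer(cellsPerTypePerSample),
      depthLogMean = depthLogMean, depthLogSd = depthLogSd,
      nbDispersion = nbDispersion,
      markerGenesPerType = as.integer(markerGenesPerType),
      markerFoldChange = markerFoldChange, identityLogSd = identityLogSd,
      trendGeneFraction = trendGeneFraction,
      trendTypeWeights = trendTypeWeights,
      trendAmplitude = trendAmplitude,
      maturationClasses = as.integer(maturationClasses),
      sexEffect = sexEffect, delayStages = as.integer(delayStages),
      geneCategoryFractions = gcf, seed = as.integer(seed))
}

#' Maturation schedule for a planted trajectory class
#'
#' Cumulative maturation progress (0 at the first age, 1 from the
#' second-to-last age onward) across `nAges` ordered stages. Gradual
#' (class 1) spreads progress evenly; intermediate (class 2) concentrates
#' 94% in two dominant steps; stepwise (class 3) concentrates 92% in a
#' single dominant step. The measured distance trajectory always carries
#' one extra small step into the adult self-distance of exactly zero, so
#' the measured step counts land at >= 4 (gradual), 3 (intermediate) and
#' 1-2 (stepwise). The final step carries zero progress so that a clock
#' delayed by one stage coincides with the undelayed clock at the last
#' stage.
#'
#' @param class integer 1, 2 or 3.
#' @param nAges number of stages (>= 4 for classes 2 and 3).
#' @return numeric vector of length `nAges`, non-decreasing from 0 to 1.
#' @export
maturationSchedule <- function(class, nAges) {
  stopifnot(class %in% 1:3, nAges >= 2)
  nSteps <- nAges - 1
  inc <- numeric(nSteps)
  active <- seq_len(max(nSteps - 1, 1))   # last step stays at zero
  if (class == 1 || nAges < 5) {
    inc[active] <- 1 / length(active)
  } else if (class == 2) {
    big <- unique(c(max(max(active) - 2, 1), max(active)))
    inc[big] <- 0.94 / length(big)
    rest <- setdiff(active, big)
    if (length(rest)) inc[rest] <- 0.06 / length(rest) else
      inc[big] <- inc[big] + 0.06 / length(big)
  } else {
    big <- ceiling(max(active) / 2) + 1
    inc[big] <- 0.92
    rest <- setdiff(active, big)
    if (length(rest)) inc[rest] <- 0.08 / length(rest) else
      inc[big] <- 1
  }
  c(0, cumsum(inc))
}

## trend value in natural-log space at schedule position s in [0, 1]
.trendValue <- function(type, param, amplitude, s) {
  switch(type,
         flat = rep(0, length(s)),
         up = amplitude * s,
         down = -amplitude * s,
         step = amplitude * as.numeric(s >= param),
         transient = amplitude * exp(-(s - param)^2 / (2 * 0.15^2)),
         stop("unknown trend type: ", type))
}

#' Expected expression proportions for one condition
#'
#' Composition-normalized expected expression of every gene for cells of
#' one (cell type, age, sex, genotype) condition, as used by the generator:
#' a cell with library size `d` has expected counts `d * proportions`.
#'
#' @param gt ground truth returned by [generateDataset()].
#' @param cellType,age,sex,genotype condition selectors.
#' @return named numeric vector over genes summing to 1.
#' @export
expectedProportions <- function(gt, cellType, age, sex = "M",
                                genotype = "control") {
  spec <- gt$spec
  j <- match(age, spec@ages) - 1L
  if (is.na(j)) stop("unknown age: ", age)
  if (genotype == "mutant") j <- max(j - spec@delayStages, 0L)
  ct <- match(cellType, gt$cellTypes$cell_type)
  if (is.na(ct)) stop("unknown cell type: ", cellType)
  s <- gt$schedules[ct, j + 1L]
  g <- gt$genes
  logmu <- log(g$baseline)
  if (!is.null(gt$identity)) logmu <- logmu + gt$identity[, ct]
  mk <- which(!is.na(g$markerOf) & g$markerOf == cellType)
  logmu[mk] <- logmu[mk] + log(spec@markerFoldChange)
  A <- spec@trendAmplitude
  up <- g$trendType == "up"
  logmu[up] <- logmu[up] + A * s
  dn <- g$trendType == "down"
  logmu[dn] <- logmu[dn] - A * s
  st <- g$trendType == "step"
  logmu[st] <- logmu[st] + A * as.numeric(s >= g$trendParam[st])
  tc <- g$trendType == "transient"
  sgn <- if ("trendSign" %in% colnames(g)) g$trendSign[tc] else 1
  logmu[tc] <- logmu[tc] +
    sgn * A * exp(-(s - g$trendParam[tc])^2 / (2 * 0.15^2))
  if (nrow(gt$sexEffect) && sex == "F") {
    hit <- gt$sexEffect$cellType == cellType & gt$sexEffect$age == age
    if (any(hit)) {
      idx <- match(gt$sexEffect$gene[hit], g$gene_id)
      logmu[idx] <- logmu[idx] + gt$sexEffect$lfc[hit]
    }
  }
  p <- exp(logmu - max(logmu))
  setNames(p / sum(p), g$gene_id)
}

#' Generate a synthetic developmental count dataset
#'
#' Draws a genes x cells negative-binomial count matrix under the design in
#' a [SyntheticSpec-class], together with the ground truth of every planted
#' effect. Deterministic given `spec@seed`.
#'
#' @param spec a validated [SyntheticSpec-class].
#' @return list with `experiment` (a [MaturationExperiment-class]) and
#'   `groundTruth` (list: `genes` per-gene table with baseline, trend type
#'   and parameters; `cellTypes` with the planted class; `schedules`
#'   cell type x age maturation-progress matrix; `sexEffect` long table;
#'   `delayStages`; `spec`).
#' @export
generateDataset <- function(spec) {
  validObject(spec)
  withr::with_seed(spec@seed, .generateDataset(spec))
}

.generateDataset <- function(spec) {
  nG <- spec@nGenes
  nCT <- spec@nCellTypes
  ages <- spec@ages
  nA <- length(ages)
  geneIds <- sprintf("gene%04d", seq_len(nG))
  cellTypes <- sprintf("CT%02d", seq_len(nCT))

  ## gene category flags: disjoint blocks at the top of the gene list
  flags <- matrix(FALSE, nG, length(.GENE_CATEGORIES),
                  dimnames = list(geneIds, .GENE_CATEGORIES))
  at <- 0L
  for (cat in .GENE_CATEGORIES) {
    nCat <- round(spec@geneCategoryFractions[[cat]] * nG)
    if (nCat > 0) flags[at + seq_len(nCat), cat] <- TRUE
    at <- at + nCat
  }
  flagged <- at

  ## baseline relative abundances (log-normal across genes)
  baseline <- exp(rnorm(nG, 0, 1.4))

  ## per-cell-type identity program: stable genome-wide baseline signature
  identity <- matrix(rnorm(nG * nCT, 0, spec@identityLogSd), nG, nCT,
                     dimnames = list(geneIds, cellTypes))

  ## markers: unflagged genes, disjoint across cell types, no trend
  free <- setdiff(seq_len(nG), seq_len(flagged))
  markerOf <- rep(NA_character_, nG)
  need <- nCT * spec@markerGenesPerType
  if (need > length(free)) stop("not enough genes for the requested markers")
  mk <- sample(free, need)
  markerOf[mk] <- rep(cellTypes, each = spec@markerGenesPerType)

  ## trend genes among the remaining unflagged, non-marker genes, drawn
  ## from the better-expressed part of the pool: age-trending genes must be
  ## quantifiable, and at very low counts the log transform would flatten
  ## their planted dynamics
  pool <- setdiff(free, mk)
  nTrend <- min(round(spec@trendGeneFraction * nG), length(pool))
  hiPool <- pool[baseline[pool] >= quantile(baseline[pool], 0.4)]
  if (length(hiPool) < nTrend) hiPool <- pool
  trendIdx <- sample(hiPool, nTrend)
  trendType <- rep("flat", nG)
  w <- spec@trendTypeWeights[c("up", "down", "step", "transient")]
  w[is.na(w)] <- 0
  trendType[trendIdx] <- sample(names(w), nTrend, replace = TRUE,
                                prob = w)
  trendParam <- rep(NA_real_, nG)
  isStep <- trendType == "step"
  trendParam[isStep] <- runif(sum(isStep), 0.15, 0.85)
  isTrans <- trendType == "transient"
  trendParam[isTrans] <- runif(sum(isTrans), 0.3, 0.7)
  ## transient programs peak or trough with equal probability; mixed signs
  ## keep transient excursions from forming one coherent axis
  trendSign <- rep(1, nG)
  trendSign[isTrans] <- sample(c(-1, 1), sum(isTrans), replace = TRUE)

  schedules <- t(vapply(spec@maturationClasses, maturationSchedule,
                        numeric(nA), nAges = nA))
  rownames(schedules) <- cellTypes
  colnames(schedules) <- ages

  genes <- data.frame(gene_id = geneIds, baseline = baseline,
                      trendType = trendType, trendParam = trendParam,
                      trendSign = trendSign, markerOf = markerOf,
                      stringsAsFactors = FALSE)

  ## expand sex effects into a long table
  sexDf <- data.frame(cellType = character(), gene = character(),
                      lfc = numeric(), age = character())
  for (se in spec@sexEffect) {
    sexDf <- rbind(sexDf, expand.grid(cellType = se$cellType,
                                      gene = se$genes, lfc = se$lfc,
                                      age = se$ages,
                                      stringsAsFactors = FALSE))
  }

  gt <- list(genes = genes,
             cellTypes = data.frame(cell_type = cellTypes,
                                    class = spec@maturationClasses),
             schedules = schedules, identity = identity, sexEffect = sexDf,
             delayStages = spec@delayStages, spec = spec)

  ## sample layout: sample_id determines (age, sex, genotype)
  layout <- expand.grid(rep = seq_len(spec@samplesPerSexPerAge),
                        sex = c("M", "F"), age = ages,
                        genotype = "control", stringsAsFactors = FALSE)
  if (spec@mutantSamplesPerSexPerAge > 0) {
    layout <- rbind(layout,
                    expand.grid(rep = seq_len(spec@mutantSamplesPerSexPerAge),
                                sex = c("M", "F"), age = ages,
                                genotype = "mutant",
                                stringsAsFactors = FALSE))
  }
  layout$sample_id <- with(layout, paste(age, sex,
                                         ifelse(genotype == "mutant", "mut",
                                                "ctl"),
                                         rep, sep = "_"))

  theta <- spec@nbDispersion
  nCells <- spec@cellsPerTypePerSample
  nBlocks <- nrow(layout) * nCT
  ## assemble in chunks of blocks to bound peak memory: triplets for one
  ## chunk at a time, then one sparse cbind over the chunk matrices
  chunkSize <- max(1L, ceiling(2e6 / (nG * nCells)) * 8L)
  meta <- vector("list", nBlocks)
  chunks <- list()
  triplets <- list()
  b <- 0L
  colAt <- 0L
  chunkStart <- 0L
  piCache <- new.env(parent = emptyenv())
  flushChunk <- function() {
    trip <- do.call(rbind, triplets)
    chunks[[length(chunks) + 1L]] <<-
      sparseMatrix(i = trip[, 1], j = trip[, 2] - chunkStart, x = trip[, 3],
                   dims = c(nG, colAt - chunkStart))
    triplets <<- list()
    chunkStart <<- colAt
  }
  for (r in seq_len(nrow(layout))) {
    for (ct in cellTypes) {
      key <- paste(ct, layout$age[r], layout$sex[r], layout$genotype[r])
      p <- piCache[[key]]
      if (is.null(p)) {
        p <- expectedProportions(gt, ct, layout$age[r], layout$sex[r],
                                 layout$genotype[r])
        piCache[[key]] <- p
      }
      depth <- rlnorm(nCells, spec@depthLogMean, spec@depthLogSd)
      mu <- outer(unname(p), depth)              # genes x cells
      cts <- matrix(rnbinom(length(mu), mu = mu, size = theta), nG, nCells)
      b <- b + 1L
      nz <- which(cts != 0L)
      triplets[[length(triplets) + 1L]] <-
        cbind((nz - 1L) %% nG + 1L, colAt + (nz - 1L) %/% nG + 1L,
              cts[nz])
      colAt <- colAt + nCells
      meta[[b]] <- data.frame(sample_id = layout$sample_id[r],
                              age = layout$age[r], sex = layout$sex[r],
                              genotype = layout$genotype[r], cell_type = ct,
                              stringsAsFactors = FALSE)[rep(1, nCells), ]
      if (length(triplets) >= chunkSize) flushChunk()
    }
  }
  if (length(triplets)) flushChunk()
  counts <- if (length(chunks) == 1) chunks[[1]] else do.call(cbind, chunks)
  cellMeta <- do.call(rbind, meta)
  cellMeta$cell_id <- sprintf("cell%06d", seq_len(nrow(cellMeta)))
  rownames(cellMeta) <- cellMeta$cell_id
  colnames(counts) <- cellMeta$cell_id
  rownames(counts) <- geneIds

  geneMeta <- data.frame(gene_id = geneIds, as.data.frame(flags))
  mx <- MaturationExperiment(counts, cellMeta, geneMeta, ageLevels = ages)
  list(experiment = mx, groundTruth = gt)
}

#' Write / read a MaturationExperiment as a Matrix Market triple
#'
#' `writeCounts()` writes `matrix.mtx` (genes x cells), `features.tsv`
#' (gene metadata incl. category flags), `barcodes.tsv`, `cells.tsv`
#' (per-cell metadata) and `ages.tsv` (ordered stage vocabulary) into a
#' directory; `readCounts()` reconstructs the object, checking that sidecar
#' row counts match the matrix dimensions.
#'
#' @param mx a [MaturationExperiment-class].
#' @param path directory to write to / read from.
#' @return `writeCounts()` the path, invisibly; `readCounts()` a
#'   [MaturationExperiment-class].
#' @export
writeCounts <- function(mx, path) {
  if (ncol(mx) == 0) warning("writing an empty matrix (0 cells)")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cts <- assay(mx, "counts")
  if (!inherits(cts, "sparseMatrix")) cts <- Matrix(cts, sparse = TRUE)
  writeMM(cts, file.path(path, "matrix.mtx"))
  write.table(as.data.frame(rowData(mx)), file.path(path, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(colnames(mx), file.path(path, "barcodes.tsv"))
  cd <- as.data.frame(colData(mx))
  cd$age <- as.character(cd$age)
  write.table(cd, file.path(path, "cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(ageLevels(mx), file.path(path, "ages.tsv"))
  invisible(path)
}

#' @rdname writeCounts
#' @export
readCounts <- function(path) {
  mtx <- file.path(path, "matrix.mtx")
  cts <- tryCatch(readMM(mtx),
                  error = function(e) stop("malformed MTX file '", mtx,
                                           "': ", conditionMessage(e)))
  features <- read.delim(file.path(path, "features.tsv"),
                         stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(path, "barcodes.tsv"))
  cells <- read.delim(file.path(path, "cells.tsv"),
                      stringsAsFactors = FALSE,
                      colClasses = "character")
  ageLv <- readLines(file.path(path, "ages.tsv"))
  if (nrow(features) != nrow(cts)) {
    stop("features.tsv has ", nrow(features), " rows but matrix.mtx has ",
         nrow(cts), " rows")
  }
  if (length(barcodes) != ncol(cts) || nrow(cells) != ncol(cts)) {
    stop("barcodes.tsv/cells.tsv rows (", length(barcodes), "/",
         nrow(cells), ") do not match matrix.mtx columns (", ncol(cts), ")")
  }
  cts <- as(as(cts, "dMatrix"), "CsparseMatrix")  # pattern matrices (all
  rownames(cts) <- features$gene_id               # zero) become numeric
  colnames(cts) <- barcodes
  if (ncol(cts) == 0) warning("read an empty matrix (0 cells)")
  MaturationExperiment(cts, cells, features, ageLevels = ageLv)
}
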