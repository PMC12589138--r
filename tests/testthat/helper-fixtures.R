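# Small fixtures built in code; kept deliberately tiny so the whole suite
# runs quickly.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(Matrix)
})

# hand-built 4-gene x 3-cell experiment with known counts
toyExperiment <- function() {
  counts <- matrix(c(1, 0, 2,
                     3, 4, 0,
                     0, 5, 6,
                     7, 0, 8), nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
  cellMeta <- data.frame(cell_id = paste0("c", 1:3),
                         sample_id = c("s1", "s1", "s2"),
                         age = c("P10", "P10", "P65"),
                         sex = c("M", "M", "F"),
                         genotype = "control",
                         cell_type = c("A", "A", "B"))
  MaturationExperiment(counts, cellMeta, ageLevels = c("P10", "P65"))
}

# small synthetic dataset shared across test files (lazily cached)
.smallData <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- syntheticSpec(nCellTypes = 3, nGenes = 400,
                            cellsPerTypePerSample = 15,
                            markerGenesPerType = 8, seed = 42)
      cache <<- generateDataset(spec)
    }
    cache
  }
})

# deterministic Gaussian-cluster experiment: cell types separated along
# disjoint marker genes, ages shifted along one axis
gaussianClusters <- function(nPerGroup = 30, nGenes = 60, shift = 6,
                             groups = c("A", "B"), seed = 1) {
  withr::with_seed(seed, {
    counts <- NULL
    meta <- NULL
    for (gi in seq_along(groups)) {
      lam <- rep(2, nGenes)
      lam[((gi - 1) * 10 + 1):(gi * 10)] <- shift
      block <- matrix(rpois(nGenes * nPerGroup, lam), nGenes, nPerGroup)
      counts <- cbind(counts, block)
      meta <- rbind(meta, data.frame(sample_id = paste0("s", gi),
                                     age = "P65", sex = "M",
                                     genotype = "control",
                                     cell_type = groups[gi])[rep(1, nPerGroup), ])
    }
    meta$cell_id <- paste0("cell", seq_len(nrow(meta)))
    rownames(meta) <- meta$cell_id
    colnames(counts) <- meta$cell_id
    rownames(counts) <- paste0("g", seq_len(nGenes))
    MaturationExperiment(counts, meta, ageLevels = "P65")
  })
}

# explicit cell duplication (avoids relying on S4 dots-dispatch for cbind
# inside testthat's evaluation environment)
duplicateCells <- function(mx, idx = seq_len(ncol(mx)), suffix = "_dup") {
  cts <- assay(mx, "counts")
  cts2 <- cbind(as.matrix(cts), as.matrix(cts[, idx, drop = FALSE]))
  cd <- as.data.frame(colData(mx))
  cd2 <- cd[idx, , drop = FALSE]
  cd2$cell_id <- paste0(cd2$cell_id, suffix)
  allMeta <- rbind(cd, cd2)
  rownames(allMeta) <- allMeta$cell_id
  colnames(cts2) <- allMeta$cell_id
  MaturationExperiment(cts2, allMeta, as.data.frame(rowData(mx)),
                       ageLevels = ageLevels(mx))
}
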