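#' Read gene sets from GMT or two-column TSV
#'
#' GMT files are parsed with [fgsea::gmtPathways()]; a two-column TSV
#' (gene, set) is split into a named list. Used for signalling gene-set
#' scoring and refinement analysis.
#'
#' @param path file ending in `.gmt`, or a TSV with columns gene and set.
#' @return named list of gene-id vectors.
#' @export
readGeneSets <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expected a two-column TSV (gene, set)")
  split(tab[[1]], tab[[2]])
}

#' Packaged sex-linked gene lists
#'
#' Mouse X-inactivation(-escape) and Y-chromosome genes shipped as a
#' plain-text fixture, used to flag gene categories for the pseudobulk
#' sex-difference exclusions. Override by supplying your own table of the
#' same shape.
#'
#' @param path fixture path; defaults to the packaged list.
#' @return data.frame with columns `gene` and `category`
#'   (`xi` or `chrY`).
#' @export
sexLinkedGenes <- function(path = system.file("extdata",
                                              "xi_genes_mouse.tsv",
                                              package = "maturatlas")) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Flag gene categories on a MaturationExperiment
#'
#' Sets the logical rowData flags (`mito`, `ribo`, ..., `xi`) from named
#' gene lists, e.g. from [sexLinkedGenes()] or pattern matching on gene
#' symbols.
#'
#' @param mx a [MaturationExperiment-class].
#' @param lists named list: category -> gene ids.
#' @return `mx` with updated rowData flags.
#' @export
flagGeneCategories <- function(mx, lists) {
  bad <- setdiff(names(lists), .GENE_CATEGORIES)
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  for (cat in names(lists)) {
    rowData(mx)[[cat]] <- rownames(mx) %in% lists[[cat]]
  }
  mx
}
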