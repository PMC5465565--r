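#' Construct a GeneSetBundle
#'
#' @param disease known disease gene symbols (guilt-by-association seed).
#' @param candidates candidate gene symbols to prioritise.
#' @param negativeControls negative-control symbols for RUV cleaning.
#' @param userExcluded extra genes barred from serving as negative controls.
#' @return A \linkS4class{GeneSetBundle}; symbols are upper-cased,
#'   whitespace-stripped and de-duplicated.
#' @export
geneSetBundle <- function(disease, candidates, negativeControls = character(),
                          userExcluded = character()) {
  norm <- function(x) unique(normaliseGeneSymbols(x))
  new("GeneSetBundle", disease = norm(disease), candidates = norm(candidates),
      negativeControls = norm(negativeControls),
      userExcluded = norm(userExcluded))
}

#' @describeIn geneSetBundle known disease genes.
#' @param bundle a \linkS4class{GeneSetBundle}.
#' @export
diseaseGenes <- function(bundle) bundle@disease

#' @describeIn geneSetBundle candidate genes.
#' @export
candidateGenes <- function(bundle) bundle@candidates

#' @describeIn geneSetBundle negative-control genes.
#' @export
negativeControlGenes <- function(bundle) bundle@negativeControls

setMethod("show", "GeneSetBundle", function(object) {
  cat("GeneSetBundle: ", length(object@disease), " disease, ",
      length(object@candidates), " candidate, ",
      length(object@negativeControls), " negative-control, ",
      length(object@userExcluded), " user-excluded gene(s)\n", sep = "")
})

#' Read a plain-text gene list
#'
#' One symbol per line; blank lines and lines starting with \code{#} are
#' ignored, as is anything after a \code{#} on a line.
#'
#' @param path file path.
#' @return character vector of normalised gene symbols.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  x <- readLines(path, warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  unique(normaliseGeneSymbols(x[nzchar(x)]))
}

#' Default negative-control genes for RUV
#'
#' Starts from a housekeeping list (genes with stable expression, assumed to
#' be affected by unwanted technical variation but not by the biology of
#' interest), keeps those measured in the dataset, and removes known
#' disease genes, candidates and user-specified exclusions so that no signal
#' of interest can leak into the unwanted-variation estimate.
#'
#' @param allGenes gene symbols present in the dataset.
#' @param housekeeping housekeeping gene symbols; defaults to the packaged
#'   human list (see \code{system.file("extdata", "housekeeping_default.txt",
#'   package = "coexRank")}), fully replaceable.
#' @param bundle a \linkS4class{GeneSetBundle}.
#' @return character vector of control symbols.
#' @export
defaultNegativeControls <- function(allGenes,
                                    housekeeping = packagedHousekeeping(),
                                    bundle = geneSetBundle(character(),
                                                           character())) {
  if (!length(housekeeping)) stop("housekeeping list is empty")
  allGenes <- normaliseGeneSymbols(allGenes)
  housekeeping <- normaliseGeneSymbols(housekeeping)
  out <- setdiff(intersect(housekeeping, allGenes),
                 c(bundle@disease, bundle@candidates, bundle@userExcluded))
  if (!length(out))
    stop("no usable negative controls remain after filtering; ",
         "supply controls explicitly")
  out
}

#' @describeIn defaultNegativeControls the packaged housekeeping list.
#' @export
packagedHousekeeping <- function() {
  readGeneList(system.file("extdata", "housekeeping_default.txt",
                           package = "coexRank", mustWork = TRUE))
}
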