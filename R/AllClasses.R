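#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- colData
#'   colData<-
NULL

#' Expression dataset with donor and developmental-period metadata
#'
#' \code{CoexDataset} extends
#' \linkS4class{SummarizedExperiment} with the per-sample metadata the
#' prioritisation engine needs: a donor identifier (samples from the same
#' donor are statistically dependent and are down-weighted accordingly), an
#' age (value plus unit) and the developmental period derived from it.
#' The single assay \code{"exprs"} holds log-scale expression values,
#' genes in rows and samples in columns.
#'
#' Required \code{colData} columns:
#' \describe{
#'   \item{sample_id}{character, unique within the dataset.}
#'   \item{donor_id}{character; several samples may share a donor.}
#'   \item{age_value}{non-negative numeric.}
#'   \item{age_unit}{one of \code{"PCW"} (post-conception weeks), \code{"M"}
#'     (months), \code{"Y"} (years).}
#'   \item{period}{integer 1--15, normally filled in by
#'     \code{\link{assignPeriod}}.}
#' }
#'
#' @slot . see \linkS4class{SummarizedExperiment}; the dataset name is kept
#'   in \code{metadata(x)$name}.
#' @seealso \code{\link{loadExpression}}, \code{\link{donorWeights}},
#'   \code{\link{subsetByPeriods}}
#' @export
setClass("CoexDataset", contains = "SummarizedExperiment")

.AGE_UNITS <- c("PCW", "M", "Y")

setValidity("CoexDataset", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  g <- rownames(object)
  if (is.null(g) || anyDuplicated(g))
    msg <- c(msg, "gene symbols (rownames) must be present and unique")
  need <- c("sample_id", "donor_id", "age_value", "age_unit", "period")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  if (!length(msg)) {
    cd <- colData(object)
    if (anyDuplicated(cd$sample_id))
      msg <- c(msg, "sample_id values must be unique")
    if (!all(cd$age_unit %in% .AGE_UNITS))
      msg <- c(msg, "age_unit must be one of PCW, M, Y")
    if (any(cd$age_value < 0))
      msg <- c(msg, "age_value must be non-negative")
    if (anyNA(assay(object, "exprs")))
      msg <- c(msg, "expression matrix must not contain missing values")
    bad <- !is.na(cd$period) & (cd$period < 1L | cd$period > 15L)
    if (any(bad))
      msg <- c(msg, "period must be in 1..15")
    pcwpost <- cd$age_unit == "PCW" & !is.na(cd$period) & cd$period > 7L
    if (any(pcwpost))
      msg <- c(msg, "PCW-aged samples must be prenatal (period <= 7)")
  }
  if (length(msg)) msg else TRUE
})

#' Named gene sets used throughout a prioritisation run
#'
#' Bundles the four gene lists a run needs: the known \code{disease} genes
#' (the guilt-by-association seed), the \code{candidates} to be prioritised,
#' the \code{negativeControls} used by RUV cleaning, and genes the user wants
#' \code{userExcluded} from serving as negative controls. Symbols are
#' upper-cased and whitespace-stripped on construction; disease and candidate
#' sets must not overlap.
#'
#' @slot disease character vector of known disease gene symbols.
#' @slot candidates character vector of candidate gene symbols.
#' @slot negativeControls character vector of negative-control symbols.
#' @slot userExcluded character vector of additional exclusions.
#' @seealso \code{\link{geneSetBundle}}, \code{\link{defaultNegativeControls}}
#' @export
setClass("GeneSetBundle",
  representation(disease = "character", candidates = "character",
                 negativeControls = "character", userExcluded = "character"))

setValidity("GeneSetBundle", function(object) {
  msg <- character()
  both <- intersect(object@disease, object@candidates)
  if (length(both))
    msg <- c(msg, paste0("genes in both disease and candidate sets: ",
                         paste(both, collapse = ", ")))
  contam <- intersect(object@negativeControls,
                      c(object@disease, object@candidates, object@userExcluded))
  if (length(contam))
    msg <- c(msg, paste0("negative controls overlap excluded sets: ",
                         paste(contam, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Permutation null distribution of maximum absolute correlations
#'
#' Holds the pooled per-gene maximum absolute donor-weighted correlations
#' between randomly drawn gene sets and the known disease genes: \code{B}
#' random sets of \code{setSize} genes are drawn, and for each drawn gene the
#' maximum \code{|r|} over the disease genes is recorded. The empirical
#' quantiles of \code{values} calibrate the prioritisation cutoff
#' (\code{\link{thresholdFromNull}}).
#'
#' @slot values numeric in [0, 1]; \code{B * setSize} pooled maxima (minus
#'   any unsampleable genes, which are logged as a warning when dropped).
#' @slot B integer, number of random-set repeats.
#' @slot setSize integer, size of each random set.
#' @slot seed integer seed the draws were made with.
#' @slot dataset character, name of the source dataset.
#' @seealso \code{\link{sampleNull}}
#' @export
setClass("NullDistribution",
  representation(values = "numeric", B = "integer", setSize = "integer",
                 seed = "integer", dataset = "character"))

setValidity("NullDistribution", function(object) {
  msg <- character()
  if (any(object@values < 0 | object@values > 1 + 1e-12))
    msg <- c(msg, "null values must lie in [0, 1]")
  if (length(object@values) > object@B * object@setSize)
    msg <- c(msg, "more values than B * setSize")
  if (length(msg)) msg else TRUE
})

#' Donor-weighted gene-gene correlation matrix
#'
#' A symmetric correlation matrix with unit diagonal plus provenance: which
#' dataset it came from, which developmental periods were used and whether
#' donor weighting was applied. Genes whose expression is constant in the
#' (possibly subset) data have undefined correlations; they are recorded as 0
#' and flagged in \code{degenerate} rather than dropped, so matrix shapes
#' stay stable downstream.
#'
#' @slot values symmetric numeric matrix, entries in [-1, 1], diagonal 1 for
#'   non-degenerate genes; dimnames are gene symbols.
#' @slot degenerate named logical; TRUE for zero-variance genes.
#' @slot dataset character, source dataset name.
#' @slot periods integer vector of periods the samples were restricted to.
#' @slot weighted logical, TRUE when donor weights were used.
#' @seealso \code{\link{correlationMatrix}}, \code{\link{partialCorrelations}}
#' @export
setClass("CorrelationMatrix",
  representation(values = "matrix", degenerate = "logical",
                 dataset = "character", periods = "integer",
                 weighted = "logical"))

setValidity("CorrelationMatrix", function(object) {
  m <- object@values
  msg <- character()
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    msg <- c(msg, "matrix must be square with matching dimnames")
  if (length(object@degenerate) != nrow(m))
    msg <- c(msg, "degenerate flag length must equal gene count")
  if (any(abs(m) > 1 + 1e-8))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (max(abs(m - t(m))) > 1e-8)
    msg <- c(msg, "matrix must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Result of a multi-dataset prioritisation run
#'
#' \code{perDataset} holds one row per candidate per dataset (maximum
#' absolute weighted correlation with any disease gene, the sum of
#' above-threshold absolute correlations, the prioritised flag, and whether
#' the candidate was testable, i.e. present, in that dataset).
#' \code{consensus} holds one row per candidate with the consensus count
#' (number of datasets prioritising it), the number of testable datasets,
#' the aggregated above-threshold sum over prioritising datasets, and the
#' rank. A candidate is prioritised in a dataset iff its maximum absolute
#' correlation strictly exceeds that dataset's threshold.
#'
#' @slot perDataset data.frame with columns dataset, gene, max_abs_r,
#'   sum_above_threshold, prioritised, testable.
#' @slot consensus data.frame with columns gene, consensus_count,
#'   testable_datasets, total_sum_above_threshold, rank, tied.
#' @slot thresholds named numeric, per-dataset correlation cutoffs.
#' @slot proportion numeric, requested expected fraction of random genes
#'   prioritised.
#' @slot seed integer master seed of the run.
#' @seealso \code{\link{runPrioritisation}}, \code{\link{rankCandidates}},
#'   \code{\link{consensusFilter}}
#' @export
setClass("PrioritisationResult",
  representation(perDataset = "data.frame", consensus = "data.frame",
                 thresholds = "numeric", proportion = "numeric",
                 seed = "integer"))

setValidity("PrioritisationResult", function(object) {
  msg <- character()
  pd <- object@perDataset
  need <- c("dataset", "gene", "max_abs_r", "sum_above_threshold",
            "prioritised", "testable")
  if (!all(need %in% names(pd)))
    msg <- c(msg, "perDataset lacks required columns")
  cs <- object@consensus
  need2 <- c("gene", "consensus_count", "testable_datasets",
             "total_sum_above_threshold", "rank")
  if (!all(need2 %in% names(cs)))
    msg <- c(msg, "consensus lacks required columns")
  if (!length(msg) && nrow(cs) &&
      any(cs$consensus_count > cs$testable_datasets))
    msg <- c(msg, "consensus_count cannot exceed testable_datasets")
  if (length(msg)) msg else TRUE
})
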