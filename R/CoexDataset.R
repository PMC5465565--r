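#' Construct a CoexDataset
#'
#' @param exprs numeric matrix, genes x samples, log-scale expression;
#'   rownames are gene symbols, colnames are sample ids.
#' @param sampleData data.frame with columns \code{sample_id},
#'   \code{donor_id}, \code{age_value}, \code{age_unit}; rows are matched to
#'   the matrix columns by \code{sample_id}. A \code{period} column is added
#'   via \code{\link{assignPeriod}} when absent.
#' @param name character scalar naming the dataset.
#' @return A \linkS4class{CoexDataset}.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' meta <- data.frame(sample_id = c("s1", "s2"), donor_id = c("d1", "d1"),
#'                    age_value = c(25, 30), age_unit = "Y")
#' CoexDataset(m, meta, name = "toy")
#' @export
CoexDataset <- function(exprs, sampleData, name = "dataset") {
  exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  sampleData <- as.data.frame(sampleData)
  need <- c("sample_id", "donor_id", "age_value", "age_unit")
  miss <- setdiff(need, names(sampleData))
  if (length(miss))
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  sampleData$sample_id <- as.character(sampleData$sample_id)
  sampleData$donor_id <- as.character(sampleData$donor_id)
  sampleData$age_unit <- toupper(trimws(as.character(sampleData$age_unit)))
  sampleData$age_value <- as.numeric(sampleData$age_value)
  if (anyNA(sampleData$age_value))
    stop("unparseable age_value in sample metadata")

  cols <- colnames(exprs)
  if (is.null(cols)) stop("expression matrix must have sample ids as colnames")
  notInMeta <- setdiff(cols, sampleData$sample_id)
  notInMat <- setdiff(sampleData$sample_id, cols)
  if (length(notInMeta) || length(notInMat))
    stop("sample ids do not match between matrix and metadata; ",
         if (length(notInMeta))
           paste0("missing from metadata: ",
                  paste(notInMeta, collapse = ", "), ". "),
         if (length(notInMat))
           paste0("missing from matrix: ", paste(notInMat, collapse = ", ")))
  sampleData <- sampleData[match(cols, sampleData$sample_id), , drop = FALSE]

  if (is.null(sampleData$period))
    sampleData$period <- assignPeriod(sampleData$age_value,
                                      sampleData$age_unit)
  sampleData$period <- as.integer(sampleData$period)

  rownames(exprs) <- normaliseGeneSymbols(rownames(exprs))
  exprs <- collapseDuplicateGenes(exprs)
  exprs <- dropIncompleteRows(exprs)

  se <- SummarizedExperiment(
    assays = list(exprs = exprs),
    colData = DataFrame(sampleData, row.names = sampleData$sample_id))
  metadata(se)$name <- name
  new("CoexDataset", se)
}

# Uppercase + strip whitespace; gene matching everywhere is on this form.
normaliseGeneSymbols <- function(x) toupper(trimws(as.character(x)))

# Most-informative-probe rule: among duplicate symbols keep the row with the
# highest variance.
collapseDuplicateGenes <- function(m) {
  if (!anyDuplicated(rownames(m))) return(m)
  v <- apply(m, 1L, stats::var)
  ord <- order(rownames(m), -v)
  m <- m[ord, , drop = FALSE]
  keep <- !duplicated(rownames(m))
  dropped <- sum(!keep)
  warning(dropped, " duplicate gene row(s) collapsed to the highest-variance row")
  m[keep, , drop = FALSE]
}

dropIncompleteRows <- function(m) {
  bad <- rowSums(is.na(m)) > 0
  if (any(bad)) {
    warning(sum(bad), " gene row(s) with missing values dropped: ",
            paste(utils::head(rownames(m)[bad], 5L), collapse = ", "),
            if (sum(bad) > 5L) ", ...")
    m <- m[!bad, , drop = FALSE]
  }
  m
}

#' Load an expression dataset from TSV files
#'
#' The matrix file is tab-separated with a header row of sample ids and gene
#' symbols in the first column; cells are log2-scale expression values. The
#' metadata file is tab-separated with columns \code{sample_id},
#' \code{donor_id}, \code{age_value} and \code{age_unit} (values
#' \code{"PCW"}, \code{"M"} or \code{"Y"}). Samples are matched 1:1 between
#' matrix columns and metadata rows; a mismatch is fatal and names the
#' offending ids. Developmental periods are assigned from age, duplicate
#' gene symbols are collapsed to the highest-variance row, and rows with
#' missing values are dropped with a warning.
#'
#' @param matrixPath path to the expression TSV.
#' @param metaPath path to the sample-metadata TSV.
#' @param name dataset name; defaults to the matrix file name.
#' @return A \linkS4class{CoexDataset}.
#' @export
loadExpression <- function(matrixPath, metaPath,
                           name = sub("\\.[^.]*$", "", basename(matrixPath))) {
  if (!file.exists(matrixPath)) stop("expression file not found: ", matrixPath)
  if (!file.exists(metaPath)) stop("metadata file not found: ", metaPath)
  tab <- utils::read.delim(matrixPath, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression file needs a gene column and >= 1 sample")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1L]])
  meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE)
  CoexDataset(m, meta, name = name)
}

#' Write a dataset back to the TSV dialect used for input
#'
#' @param dataset a \linkS4class{CoexDataset}.
#' @param matrixPath,metaPath output file paths (either may be NULL to skip).
#' @return invisibly, the dataset.
#' @export
writeExpression <- function(dataset, matrixPath = NULL, metaPath = NULL) {
  if (!is.null(matrixPath)) {
    m <- exprs(dataset)
    out <- data.frame(gene = rownames(m), m, check.names = FALSE)
    utils::write.table(out, matrixPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(metaPath)) {
    utils::write.table(as.data.frame(colData(dataset)), metaPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dataset)
}

#' @describeIn CoexDataset-accessors expression matrix (genes x samples).
#' @export
exprs <- function(dataset) assay(dataset, "exprs")

#' Accessors for CoexDataset
#'
#' @param dataset a \linkS4class{CoexDataset}.
#' @name CoexDataset-accessors
NULL

#' @describeIn CoexDataset-accessors dataset name.
#' @export
datasetName <- function(dataset) metadata(dataset)$name

#' @describeIn CoexDataset-accessors per-sample donor ids.
#' @export
donorIds <- function(dataset) colData(dataset)$donor_id

#' @describeIn CoexDataset-accessors per-sample developmental periods.
#' @export
samplePeriods <- function(dataset) colData(dataset)$period

setMethod("show", "CoexDataset", function(object) {
  cat("CoexDataset '", datasetName(object), "': ", nrow(object), " genes x ",
      ncol(object), " samples, ",
      length(unique(donorIds(object))), " donors, periods ",
      paste(sort(unique(samplePeriods(object))), collapse = ","), "\n",
      sep = "")
})

#' Inverse donor-contribution sample weights
#'
#' Samples from the same donor are not independent; each sample receives
#' weight \code{1 / n_d}, where \code{n_d} is the number of samples its
#' donor contributes to the dataset. The weights sum to the number of
#' distinct donors, so each donor carries unit total weight in the weighted
#' correlation.
#'
#' @param dataset a \linkS4class{CoexDataset}.
#' @return named numeric vector of weights in (0, 1], one per sample.
#' @examples
#' d <- simulateNull(nGenes = 5, nSamples = 6, seed = 1)
#' sum(donorWeights(d)) == length(unique(donorIds(d)))
#' @export
donorWeights <- function(dataset) {
  d <- donorIds(dataset)
  if (anyNA(d) || any(d == "")) stop("every sample needs a donor_id")
  n <- table(d)
  w <- 1 / as.numeric(n[d])
  names(w) <- colData(dataset)$sample_id
  w
}

#' Restrict a dataset to chosen developmental periods
#'
#' Keeps exactly the samples whose period is in \code{periods}; the gene
#' list is unchanged. Donor weights are not carried over: recompute them on
#' the subset with \code{\link{donorWeights}}.
#'
#' @param dataset a \linkS4class{CoexDataset}.
#' @param periods integer vector, subset of 1..15.
#' @return A \linkS4class{CoexDataset} with the retained samples.
#' @export
subsetByPeriods <- function(dataset, periods) {
  periods <- as.integer(periods)
  if (!length(periods) || any(is.na(periods)) ||
      any(periods < 1L | periods > 15L))
    stop("periods must be a non-empty subset of 1..15")
  keep <- samplePeriods(dataset) %in% periods
  if (!any(keep))
    stop("no samples fall in periods {", paste(sort(periods), collapse = ","),
         "}; widen the period selection")
  dataset[, keep]
}
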