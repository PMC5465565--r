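#' Sample the permutation null of maximum absolute correlations
#'
#' Step 1 of the prioritisation. A random set of genes, the size of the
#' candidate set, is drawn from the eligible pool (all dataset genes minus
#' disease genes, candidates and any extra exclusions — candidates are
#' excluded so the null is not contaminated with signal). For each drawn
#' gene the maximum absolute donor-weighted correlation over the disease
#' genes is recorded, and the draw is repeated \code{B} times; all
#' \code{B * setSize} maxima are pooled.
#'
#' Because a gene's maximum absolute correlation with the disease set does
#' not depend on which repeat it is drawn in, the maxima are computed once
#' per pool gene and the repeats only resample gene indices; the result is
#' identical to the literal repeated computation.
#'
#' @param dataset a \linkS4class{CoexDataset}.
#' @param disease known disease gene symbols; absent ones are dropped with
#'   a warning.
#' @param setSize size of each random gene set (the candidate-set size).
#' @param B number of repeats (default 1000).
#' @param seed integer seed; fixing it makes the draw reproducible.
#' @param exclude additional gene symbols barred from the pool (typically
#'   the candidates).
#' @return A \linkS4class{NullDistribution}.
#' @export
sampleNull <- function(dataset, disease, setSize, B = 1000L, seed = 1L,
                       exclude = character()) {
  disease <- unique(normaliseGeneSymbols(disease))
  exclude <- unique(normaliseGeneSymbols(exclude))
  present <- intersect(disease, rownames(dataset))
  absent <- setdiff(disease, present)
  if (length(absent))
    warning("disease gene(s) absent from ", datasetName(dataset), ": ",
            paste(absent, collapse = ", "))
  if (!length(present)) stop("no disease genes present in the dataset")
  pool <- setdiff(rownames(dataset), c(disease, exclude))
  if (length(pool) < setSize)
    stop("eligible pool (", length(pool), " genes) smaller than setSize (",
         setSize, ")")
  w <- donorWeights(dataset)
  r <- .weightedCrossCor(exprs(dataset)[pool, , drop = FALSE],
                         exprs(dataset)[present, , drop = FALSE], w)
  geneMax <- apply(abs(r), 1L, max)
  set.seed(seed)
  draws <- unlist(lapply(seq_len(B), function(i)
    sample.int(length(pool), setSize)), use.names = FALSE)
  new("NullDistribution", values = unname(geneMax[draws]), B = as.integer(B),
      setSize = as.integer(setSize), seed = as.integer(seed),
      dataset = datasetName(dataset))
}

#' @describeIn sampleNull the pooled null values.
#' @param null a \linkS4class{NullDistribution}.
#' @export
nullValues <- function(null) null@values

setMethod("show", "NullDistribution", function(object) {
  cat("NullDistribution: ", length(object@values), " pooled maxima (B = ",
      object@B, ", set size = ", object@setSize, ") from '", object@dataset,
      "', median ", signif(stats::median(object@values), 3), "\n", sep = "")
})

#' Correlation threshold from the permutation null
#'
#' Step 2. The user chooses the proportion of random (non-disease) genes
#' allowed to be prioritised on average; the cutoff is the empirical
#' \code{1 - proportion} quantile of the pooled null maxima, using the
#' inverse-ECDF (type 1, lower) quantile definition. The threshold is
#' monotone non-increasing in \code{proportion}: \code{proportion = 0}
#' returns the null maximum (no random gene strictly exceeds it),
#' \code{proportion = 1} the minimum.
#'
#' @param null a \linkS4class{NullDistribution} (or bare numeric vector).
#' @param proportion target fraction of random genes prioritised, in [0, 1].
#' @return the correlation cutoff.
#' @export
thresholdFromNull <- function(null, proportion) {
  v <- if (is(null, "NullDistribution")) null@values else as.numeric(null)
  if (!length(v)) stop("null distribution is empty")
  if (proportion < 0 || proportion > 1) stop("proportion must be in [0, 1]")
  v <- sort(v)
  idx <- max(1L, ceiling((1 - proportion) * length(v)))
  v[idx]
}

#' Prioritise candidate genes against a correlation cutoff
#'
#' Step 3. For each candidate present in the dataset, the absolute
#' donor-weighted correlation with every disease gene is computed; a
#' candidate whose maximum absolute correlation with any disease gene is
#' strictly greater than the cutoff is prioritised. For later ranking, the
#' sum of all absolute correlations above the cutoff is also recorded.
#' Candidates absent from the dataset are marked untestable (not failed).
#'
#' @param dataset a \linkS4class{CoexDataset}.
#' @param disease known disease gene symbols.
#' @param candidates candidate gene symbols.
#' @param threshold correlation cutoff (>= 0), from
#'   \code{\link{thresholdFromNull}}.
#' @return data.frame with one row per candidate: gene, max_abs_r,
#'   sum_above_threshold, prioritised, testable.
#' @export
prioritise <- function(dataset, disease, candidates, threshold) {
  if (threshold < 0) stop("threshold must be non-negative")
  disease <- unique(normaliseGeneSymbols(disease))
  candidates <- unique(normaliseGeneSymbols(candidates))
  if (!length(candidates)) stop("candidate set is empty")
  present <- intersect(candidates, rownames(dataset))
  dis <- intersect(disease, rownames(dataset))
  if (!length(dis)) stop("no disease genes present in the dataset")
  out <- data.frame(gene = candidates, max_abs_r = NA_real_,
                    sum_above_threshold = NA_real_, prioritised = NA,
                    testable = candidates %in% present,
                    stringsAsFactors = FALSE)
  if (length(present)) {
    w <- donorWeights(dataset)
    r <- abs(.weightedCrossCor(exprs(dataset)[present, , drop = FALSE],
                               exprs(dataset)[dis, , drop = FALSE], w))
    i <- match(present, out$gene)
    out$max_abs_r[i] <- apply(r, 1L, max)
    out$sum_above_threshold[i] <- rowSums(r * (r > threshold))
    out$prioritised[i] <- out$max_abs_r[i] > threshold
  }
  out
}

#' Run the full multi-dataset prioritisation pipeline
#'
#' Per dataset: restrict to the requested developmental periods, sample the
#' permutation null (Step 1), derive the correlation cutoff at the
#' requested proportion (Step 2) and prioritise the candidates (Step 3).
#' Prioritisation is conducted on each dataset separately; the number of
#' datasets a candidate is prioritised in (its consensus count) indicates
#' how likely the association is to be real, and candidates are ranked by
#' consensus count and then by their summed above-cutoff correlations.
#' A dataset failing its preconditions (e.g. no samples in the chosen
#' periods) is skipped with a warning and excluded from the testable-dataset
#' denominators.
#'
#' @param datasets list of \linkS4class{CoexDataset} objects.
#' @param bundle a \linkS4class{GeneSetBundle} with disease genes and
#'   candidates.
#' @param proportion expected fraction of random genes prioritised
#'   (default 0.2).
#' @param periods developmental periods to use (default all, 1..15).
#' @param B null repeats (default 1000).
#' @param seed master seed; per-dataset streams are derived from it
#'   deterministically.
#' @return A \linkS4class{PrioritisationResult}.
#' @examples
#' sim <- simulateDatasets(simulationConfig(nDatasets = 2, nGenes = 60,
#'                         nSamples = 30, seed = 7))
#' bundle <- geneSetBundle(disease = sim$groundTruth$modules[[1]]$genes[1:3],
#'                         candidates = rownames(sim$datasets[[1]])[41:50])
#' res <- runPrioritisation(sim$datasets, bundle, B = 100, seed = 7)
#' head(consensusTable(res))
#' @export
runPrioritisation <- function(datasets, bundle, proportion = 0.2,
                              periods = 1:15, B = 1000L, seed = 1L) {
  if (!length(datasets)) stop("at least one dataset is required")
  if (proportion < 0 || proportion > 1) stop("proportion must be in [0, 1]")
  disease <- diseaseGenes(bundle)
  candidates <- candidateGenes(bundle)
  seed <- as.integer(seed)
  perDataset <- list()
  thresholds <- numeric()
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    name <- datasetName(ds)
    res <- tryCatch({
      sub <- subsetByPeriods(ds, periods)
      null <- sampleNull(sub, disease,
                         setSize = length(candidates), B = B,
                         seed = seed + i, exclude = candidates)
      thr <- thresholdFromNull(null, proportion)
      tab <- prioritise(sub, disease, candidates, thr)
      list(tab = tab, thr = thr)
    }, error = function(e) {
      warning("dataset '", name, "' skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    res$tab$dataset <- name
    perDataset[[name]] <- res$tab
    thresholds[name] <- res$thr
  }
  if (!length(perDataset)) stop("no dataset completed the prioritisation")
  pd <- do.call(rbind, perDataset)
  rownames(pd) <- NULL
  pd <- pd[, c("dataset", "gene", "max_abs_r", "sum_above_threshold",
               "prioritised", "testable")]
  consensus <- .consensusTable(pd, candidates)
  new("PrioritisationResult", perDataset = pd, consensus = consensus,
      thresholds = thresholds, proportion = proportion, seed = seed)
}

# Aggregate per-dataset records into the consensus/ranking table.
.consensusTable <- function(pd, candidates) {
  agg <- lapply(split(pd, pd$gene), function(g) {
    pri <- g$prioritised %in% TRUE
    data.frame(gene = g$gene[1L],
               consensus_count = sum(pri),
               testable_datasets = sum(g$testable),
               total_sum_above_threshold = sum(g$sum_above_threshold[pri]),
               stringsAsFactors = FALSE)
  })
  cs <- do.call(rbind, agg)
  cs <- cs[match(candidates, cs$gene), , drop = FALSE]
  cs <- cs[!is.na(cs$gene), , drop = FALSE]
  ord <- order(-cs$consensus_count, -cs$total_sum_above_threshold, cs$gene)
  cs <- cs[ord, , drop = FALSE]
  key <- paste(cs$consensus_count,
               signif(cs$total_sum_above_threshold, 12))
  cs$rank <- seq_len(nrow(cs))
  cs$tied <- duplicated(key) | duplicated(key, fromLast = TRUE)
  rownames(cs) <- NULL
  cs
}

#' @describeIn runPrioritisation the ranked consensus table.
#' @param result a \linkS4class{PrioritisationResult}.
#' @export
consensusTable <- function(result) result@consensus

#' @describeIn runPrioritisation the per-dataset records.
#' @export
perDatasetTable <- function(result) result@perDataset

#' @describeIn runPrioritisation the per-dataset correlation cutoffs.
#' @export
thresholds <- function(result) result@thresholds

setMethod("show", "PrioritisationResult", function(object) {
  cs <- object@consensus
  cat("PrioritisationResult: ", nrow(cs), " candidate(s) over ",
      length(object@thresholds), " dataset(s), proportion ",
      object@proportion, "\n", sep = "")
  cat("  prioritised in >= 1 dataset: ", sum(cs$consensus_count >= 1L),
      "; in >= 2: ", sum(cs$consensus_count >= 2L), "\n", sep = "")
  print(utils::head(cs, 5L))
})

#' Candidates prioritised in at least k datasets
#'
#' Requiring support from several datasets trades sensitivity for
#' specificity; the returned sets are nested in \code{k}.
#'
#' @param result a \linkS4class{PrioritisationResult}.
#' @param k minimum number of supporting datasets (default 2).
#' @return character vector of gene symbols, in rank order.
#' @export
consensusFilter <- function(result, k = 2L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  cs <- result@consensus
  cs$gene[cs$consensus_count >= k]
}

#' Ranked candidate list
#'
#' Candidates are ordered by consensus count (descending), then by the sum
#' of above-cutoff absolute correlations aggregated over the datasets that
#' prioritised them (descending), then alphabetically; exact ties on the
#' first two keys are marked in the consensus table's \code{tied} column.
#'
#' @param result a \linkS4class{PrioritisationResult}.
#' @return character vector of gene symbols in rank order.
#' @export
rankCandidates <- function(result) result@consensus$gene

#' Write the ranked prioritisation table as TSV
#'
#' One row per candidate: gene, consensus_count, testable_datasets,
#' total_sum_above_threshold, rank, plus per-dataset max_abs_r columns and a
#' header comment recording each dataset's threshold.
#'
#' @param result a \linkS4class{PrioritisationResult}.
#' @param path output path.
#' @return invisibly, the written data.frame.
#' @export
writePrioritisationTSV <- function(result, path) {
  cs <- result@consensus
  pd <- result@perDataset
  for (d in names(result@thresholds)) {
    col <- pd$max_abs_r[pd$dataset == d][match(cs$gene,
                                               pd$gene[pd$dataset == d])]
    cs[[paste0("max_abs_r.", d)]] <- col
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# proportion=", result@proportion, " seed=", result@seed),
             con)
  writeLines(paste0("# threshold.", names(result@thresholds), "=",
                    signif(result@thresholds, 6)), con)
  utils::write.table(cs, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cs)
}
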