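#' Leave-one-out cross-validation of the prioritisation
#'
#' For each gene in a known disease set, that gene is removed and termed
#' the defector; the remaining genes act as the disease set and the
#' defector is hidden among 99 decoy candidates drawn at random from genes
#' not in the known set (decoys are drawn once per defector trial, from
#' genes present in at least one dataset, so the trial is coherent across
#' datasets). The full pipeline is run and the number of datasets
#' supporting the defector and each decoy is recorded. The ability to
#' re-discover the defector measures sensitivity; the tendency to support
#' decoys measures (one minus) specificity.
#'
#' @param datasets list of \linkS4class{CoexDataset} objects.
#' @param knownSet known disease gene symbols (>= 2).
#' @param proportion expected random-gene prioritisation fraction.
#' @param B null repeats per dataset.
#' @param seed master seed; trial streams derive from it.
#' @param nDecoys decoys per trial (default 99; reduced with a warning when
#'   the eligible pool is exhausted).
#' @param periods developmental periods to use.
#' @return data.frame with one row per trial gene: gene_set trial columns
#'   \code{defector} (the left-out gene), \code{gene}, \code{type}
#'   (\code{"defector"} or \code{"decoy"}), \code{consensus_count},
#'   \code{testable_datasets}, \code{seed}.
#' @export
loocv <- function(datasets, knownSet, proportion = 0.2, B = 1000L, seed = 1L,
                  nDecoys = 99L, periods = 1:15) {
  knownSet <- unique(normaliseGeneSymbols(knownSet))
  if (length(knownSet) < 2L) stop("the known set needs at least 2 genes")
  allGenes <- unique(unlist(lapply(datasets, rownames)))
  pool <- setdiff(allGenes, knownSet)
  seed <- as.integer(seed)
  records <- list()
  for (t in seq_along(knownSet)) {
    defector <- knownSet[t]
    if (!defector %in% allGenes) {
      warning("known gene '", defector, "' absent from all datasets; ",
              "trial skipped")
      next
    }
    disease <- setdiff(knownSet, defector)
    trialSeed <- seed + 1000L * t
    nd <- nDecoys
    if (length(pool) < nd) {
      warning("decoy pool exhausted: using ", length(pool), " decoys")
      nd <- length(pool)
    }
    set.seed(trialSeed)
    decoys <- sample(pool, nd)
    bundle <- geneSetBundle(disease, c(defector, decoys))
    res <- suppressWarnings(
      runPrioritisation(datasets, bundle, proportion = proportion,
                        periods = periods, B = B, seed = trialSeed))
    cs <- consensusTable(res)
    cs$defector <- defector
    cs$type <- ifelse(cs$gene == defector, "defector", "decoy")
    cs$seed <- trialSeed
    records[[defector]] <- cs[, c("defector", "gene", "type",
                                  "consensus_count", "testable_datasets",
                                  "seed")]
  }
  if (!length(records)) stop("no LOOCV trial could be run")
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

#' Confusion matrix at a consensus requirement k
#'
#' A trial gene counts as prioritised when its consensus count is at least
#' \code{k}. Defectors supported at \code{k} are true positives, the rest
#' false negatives; supported decoys are false positives, the rest true
#' negatives. \code{TP + FN} equals the number of defector trials and
#' \code{FP + TN} the total number of decoy gene-trials, independent of k.
#'
#' @param records LOOCV records from \code{\link{loocv}}.
#' @param k minimum supporting datasets (>= 1).
#' @return one-row data.frame: k, TP, FP, TN, FN.
#' @export
confusionAtK <- function(records, k) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  def <- records$type == "defector"
  hit <- records$consensus_count >= k
  data.frame(k = k,
             TP = sum(def & hit), FN = sum(def & !hit),
             FP = sum(!def & hit), TN = sum(!def & !hit))
}

#' Accuracy metrics from a confusion matrix
#'
#' Sensitivity quantifies the ability to re-discover the defector gene;
#' specificity the tendency not to prioritise random decoys. A metric with
#' a zero denominator is returned as \code{NA} (undefined), not an error.
#'
#' @param confusion one-row data.frame with TP, FP, TN, FN (from
#'   \code{\link{confusionAtK}}).
#' @return named numeric: sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#'   precision TP/(TP+FP), npv TN/(TN+FN).
#' @export
benchmarkMetrics <- function(confusion) {
  rate <- function(a, b) if (a + b == 0) NA_real_ else a / (a + b)
  with(confusion,
       c(sensitivity = rate(TP, FN), specificity = rate(TN, FP),
         precision = rate(TP, FP), npv = rate(TN, FN)))
}

#' Benchmark a collection of gene sets across all consensus levels
#'
#' Runs \code{\link{loocv}} for every named gene set and tabulates the
#' confusion counts and the four accuracy metrics for each consensus
#' requirement \code{k = 1 .. n_datasets}, plus an unweighted across-set
#' mean row per k (gene_set \code{"mean"}).
#'
#' @param datasets list of \linkS4class{CoexDataset} objects.
#' @param geneSets named list of known-gene character vectors.
#' @param proportion,B,seed,nDecoys,periods passed to \code{\link{loocv}};
#'   each gene set gets a derived seed.
#' @return data.frame: gene_set, k, TP, FP, TN, FN, sensitivity,
#'   specificity, precision, npv.
#' @export
benchmarkSuite <- function(datasets, geneSets, proportion = 0.2, B = 1000L,
                           seed = 1L, nDecoys = 99L, periods = 1:15) {
  if (!length(geneSets)) stop("no gene sets supplied")
  if (is.null(names(geneSets)) || any(!nzchar(names(geneSets))))
    names(geneSets) <- paste0("set", seq_along(geneSets))
  ks <- seq_len(length(datasets))
  rows <- list()
  for (s in seq_along(geneSets)) {
    rec <- loocv(datasets, geneSets[[s]], proportion = proportion, B = B,
                 seed = as.integer(seed) + 100000L * s, nDecoys = nDecoys,
                 periods = periods)
    for (k in ks) {
      cf <- confusionAtK(rec, k)
      m <- benchmarkMetrics(cf)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(gene_set = names(geneSets)[s]), cf, t(m))
    }
  }
  tab <- do.call(rbind, rows)
  means <- do.call(rbind, lapply(ks, function(k) {
    sub <- tab[tab$k == k, , drop = FALSE]
    data.frame(gene_set = "mean", k = k,
               TP = mean(sub$TP), FP = mean(sub$FP), TN = mean(sub$TN),
               FN = mean(sub$FN),
               sensitivity = mean(sub$sensitivity, na.rm = TRUE),
               specificity = mean(sub$specificity, na.rm = TRUE),
               precision = mean(sub$precision, na.rm = TRUE),
               npv = mean(sub$npv, na.rm = TRUE))
  }))
  out <- rbind(tab, means)
  rownames(out) <- NULL
  out
}
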