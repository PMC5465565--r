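# Shared fixtures and independent oracles for the test suite.

# Quick in-memory dataset: matrix plus donor ids; ages default to adults so
# every sample lands in a postnatal period.
makeDataset <- function(m, donors = paste0("d", seq_len(ncol(m))),
                        ages = rep(25, ncol(m)),
                        units = rep("Y", ncol(m)), name = "test") {
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("G", seq_len(nrow(m)))
  meta <- data.frame(sample_id = colnames(m), donor_id = donors,
                     age_value = ages, age_unit = units,
                     stringsAsFactors = FALSE)
  CoexDataset(m, meta, name = name)
}

# Independent oracle for the weighted correlation: direct evaluation of the
# weighted-covariance formula, written without reusing package internals.
oracleWeightedPearson <- function(x, y, w) {
  mx <- sum(w * x) / sum(w)
  my <- sum(w * y) / sum(w)
  sum(w * (x - mx) * (y - my)) /
    sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
}

# Brute-force reimplementation of the three prioritisation steps with plain
# unweighted cor(); valid comparison when all donors are singletons.
oraclePrioritise <- function(dataset, disease, candidates, proportion, B,
                             seed) {
  x <- t(exprs(dataset))
  pool <- setdiff(rownames(dataset), c(disease, candidates))
  r <- abs(stats::cor(x[, pool, drop = FALSE], x[, disease, drop = FALSE]))
  geneMax <- apply(r, 1, max)
  set.seed(seed)
  draws <- unlist(lapply(seq_len(B), function(i)
    sample.int(length(pool), length(candidates))))
  vals <- sort(unname(geneMax[draws]))
  thr <- vals[max(1, ceiling((1 - proportion) * length(vals)))]
  rc <- abs(stats::cor(x[, candidates, drop = FALSE],
                       x[, disease, drop = FALSE]))
  list(threshold = thr,
       max_abs_r = apply(rc, 1, max),
       prioritised = apply(rc, 1, max) > thr,
       sum_above = rowSums(rc * (rc > thr)))
}

# Small multi-dataset simulation with one module, used by several files.
makeModuleSim <- function(nDatasets = 3, seed = 1, nGenes = 300,
                          nSamples = 80, loading = 2, moduleSize = 10,
                          nUnwanted = 0, unwantedSd = 1) {
  simulateDatasets(simulationConfig(
    nDatasets = nDatasets, nGenes = nGenes, nSamples = nSamples,
    modules = list(list(genes = seq_len(moduleSize), loading = loading)),
    nUnwantedFactors = nUnwanted, unwantedSd = unwantedSd, seed = seed))
}
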