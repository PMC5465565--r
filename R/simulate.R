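#' Configuration for the synthetic multi-dataset generator
#'
#' Describes a collection of expression datasets generated from a Gaussian
#' factor model with known ground truth: co-expression modules (latent
#' factors with per-gene loadings, optionally active only in chosen
#' developmental periods), donor structure (each donor contributes several
#' samples that share a random donor effect and the donor's age/period),
#' unwanted (batch-like) factors whose per-gene loadings are drawn once and
#' shared across datasets — technical artefacts tend to hit the same genes
#' on every platform — and independent Gaussian noise. A trailing fraction
#' of genes is reserved as housekeeping genes: they carry unwanted
#' variation and noise but never module signal, making them valid negative
#' controls.
#'
#' For genes with equal module loading \code{lambda} and no other shared
#' variance, the implied intra-module correlation is
#' \code{lambda^2 / (lambda^2 + donorSd^2 + noiseSd^2)}; the donor effect
#' is independent across genes (it adds to each gene's variance but not to
#' gene-gene covariance), while unwanted loadings add to both covariance
#' and variance. Both are accounted for in the ground-truth correlation
#' matrix.
#'
#' @param nDatasets number of datasets to generate.
#' @param nGenes genes per dataset (symbols G0001, G0002, ...).
#' @param nSamples samples per dataset.
#' @param samplesPerDonor integer vector; each donor's sample count is drawn
#'   uniformly from it (default 1:4, mixed donor sizes).
#' @param modules list of modules, each
#'   \code{list(genes = <indices>, loading = <numeric>, activePeriods =
#'   <1..15>)}; \code{loading} is recycled over the module's genes and
#'   \code{activePeriods} defaults to all periods.
#' @param nUnwantedFactors number of unwanted factors (default 0).
#' @param unwantedSd standard deviation of the per-gene unwanted loadings.
#' @param noiseSd independent noise standard deviation (default 1).
#' @param donorSd donor-effect standard deviation; default
#'   \code{sqrt(0.1) * noiseSd} (donor variance one tenth of the noise).
#' @param housekeepingFraction fraction of genes reserved as housekeeping
#'   controls (default 0.1); modules may not use them.
#' @param periodWeights length-15 non-negative weights for the donor period
#'   distribution (default uniform over periods 1..15).
#' @param baselineMean mean log-expression around which gene baselines are
#'   drawn.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a list of class \code{SimulationConfig}.
#' @seealso \code{\link{simulateDatasets}}, \code{\link{simulateNull}}
#' @export
simulationConfig <- function(nDatasets = 3L, nGenes = 1000L, nSamples = 100L,
                             samplesPerDonor = 1:4, modules = list(),
                             nUnwantedFactors = 0L, unwantedSd = 1,
                             noiseSd = 1, donorSd = sqrt(0.1) * noiseSd,
                             housekeepingFraction = 0.1,
                             periodWeights = rep(1, 15), baselineMean = 8,
                             seed = 1L) {
  nDatasets <- as.integer(nDatasets)
  nGenes <- as.integer(nGenes)
  nSamples <- as.integer(nSamples)
  stopifnot(nDatasets >= 1L, nGenes >= 2L, nSamples >= 3L,
            all(samplesPerDonor >= 1L), noiseSd > 0, donorSd >= 0,
            unwantedSd >= 0, nUnwantedFactors >= 0L,
            housekeepingFraction >= 0, housekeepingFraction < 1,
            length(periodWeights) == 15L, all(periodWeights >= 0),
            sum(periodWeights) > 0)
  nHk <- as.integer(floor(housekeepingFraction * nGenes))
  hkIdx <- if (nHk > 0L) (nGenes - nHk + 1L):nGenes else integer()
  for (i in seq_along(modules)) {
    m <- modules[[i]]
    if (is.null(m$genes)) stop("module ", i, " lacks gene indices")
    if (any(m$genes < 1L | m$genes > nGenes))
      stop("module ", i, " has gene indices outside 1..nGenes")
    if (length(intersect(m$genes, hkIdx)))
      stop("module ", i, " uses housekeeping (control) genes")
    if (is.null(m$loading)) stop("module ", i, " lacks a loading")
    modules[[i]]$loading <- rep_len(m$loading, length(m$genes))
    if (is.null(m$activePeriods)) modules[[i]]$activePeriods <- 1:15
  }
  structure(list(nDatasets = nDatasets, nGenes = nGenes, nSamples = nSamples,
                 samplesPerDonor = as.integer(samplesPerDonor),
                 modules = modules, nUnwantedFactors = as.integer(nUnwantedFactors),
                 unwantedSd = unwantedSd, noiseSd = noiseSd, donorSd = donorSd,
                 housekeepingIdx = hkIdx, periodWeights = periodWeights,
                 baselineMean = baselineMean, seed = as.integer(seed)),
            class = "SimulationConfig")
}

# Draw donors until nSamples is reached; donors share age (hence period).
.simulateSampleSheet <- function(config, prefix) {
  n <- config$nSamples
  donorSizes <- integer()
  while (sum(donorSizes) < n)
    donorSizes <- c(donorSizes, sample(config$samplesPerDonor, 1L))
  excess <- sum(donorSizes) - n
  if (excess > 0L)
    donorSizes[length(donorSizes)] <- donorSizes[length(donorSizes)] - excess
  donorSizes <- donorSizes[donorSizes > 0L]
  nd <- length(donorSizes)
  period <- sample.int(15L, nd, replace = TRUE,
                       prob = config$periodWeights / sum(config$periodWeights))
  tab <- developmentalPeriods()
  age <- numeric(nd)
  unit <- character(nd)
  for (i in seq_len(nd)) {
    p <- period[i]
    lo <- tab$lower[p]
    hi <- tab$upper[p]
    if (p <= 7L) {
      unit[i] <- "PCW"
      age[i] <- stats::runif(1L, lo, min(hi, 38))
    } else if (p <= 9L) {
      unit[i] <- "M"
      age[i] <- stats::runif(1L, lo * 12, hi * 12)
    } else {
      unit[i] <- "Y"
      age[i] <- stats::runif(1L, lo, min(hi, 90))
    }
  }
  donor <- rep(seq_len(nd), donorSizes)
  data.frame(
    sample_id = sprintf("%s_s%03d", prefix, seq_len(n)),
    donor_id = sprintf("%s_d%03d", prefix, donor),
    age_value = round(age[donor], 3),
    age_unit = unit[donor],
    stringsAsFactors = FALSE)
}

# Implied (population) correlation matrix over the given gene indices,
# assuming all modules active.
.impliedCorrelation <- function(config, beta, idx, symbols) {
  p <- length(idx)
  lam <- matrix(0, p, max(1L, length(config$modules)))
  for (m in seq_along(config$modules)) {
    mod <- config$modules[[m]]
    hit <- match(mod$genes, idx)
    lam[hit[!is.na(hit)], m] <- mod$loading[!is.na(hit)]
  }
  b <- beta[idx, , drop = FALSE]
  cov <- lam %*% t(lam) + b %*% t(b)
  v <- diag(cov) + config$donorSd^2 + config$noiseSd^2
  r <- cov / sqrt(tcrossprod(v))
  diag(r) <- 1
  dimnames(r) <- list(symbols[idx], symbols[idx])
  r
}

#' Generate synthetic expression datasets with known ground truth
#'
#' Draws \code{nDatasets} datasets from the factor model described in
#' \code{\link{simulationConfig}}. Module and unwanted factor scores, donor
#' effects and noise are redrawn per dataset; gene baselines and the
#' per-gene unwanted loadings are drawn once from the config seed and
#' shared across datasets. Module factors contribute only to samples whose
#' developmental period is among the module's active periods.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with elements \code{datasets} (list of
#'   \linkS4class{CoexDataset}) and \code{groundTruth}: module membership
#'   as gene symbols with loadings and active periods, the housekeeping
#'   (negative-control) symbols, the unwanted-loading matrix, and
#'   \code{impliedCorrelation}, the population correlation matrix over the
#'   module genes (all modules taken as active).
#' @examples
#' cfg <- simulationConfig(nDatasets = 1, nGenes = 50, nSamples = 40,
#'                         modules = list(list(genes = 1:5, loading = 2)),
#'                         seed = 3)
#' sim <- simulateDatasets(cfg)
#' sim$groundTruth$modules[[1]]$genes
#' @export
simulateDatasets <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  symbols <- sprintf("G%04d", seq_len(config$nGenes))
  set.seed(config$seed)
  mu <- stats::rnorm(config$nGenes, config$baselineMean, 1)
  beta <- matrix(0, config$nGenes, max(0L, config$nUnwantedFactors))
  if (config$nUnwantedFactors > 0L)
    beta[] <- stats::rnorm(length(beta), 0, config$unwantedSd)

  datasets <- vector("list", config$nDatasets)
  for (d in seq_len(config$nDatasets)) {
    set.seed(config$seed + 104729L * d)
    prefix <- sprintf("sim%d", d)
    sheet <- .simulateSampleSheet(config, prefix)
    n <- nrow(sheet)
    period <- assignPeriod(sheet$age_value, sheet$age_unit)

    x <- matrix(stats::rnorm(config$nGenes * n, 0, config$noiseSd),
                config$nGenes, n)
    x <- x + mu
    donors <- unique(sheet$donor_id)
    # per-donor, per-gene random effect: all samples of a donor share it,
    # so same-donor samples correlate across genes while gene-gene
    # correlations are untouched (the effect is independent across genes)
    delta <- matrix(stats::rnorm(config$nGenes * length(donors), 0,
                                 config$donorSd),
                    config$nGenes, length(donors),
                    dimnames = list(NULL, donors))
    x <- x + delta[, sheet$donor_id]
    for (mod in config$modules) {
      f <- stats::rnorm(n)
      active <- as.numeric(period %in% mod$activePeriods)
      x[mod$genes, ] <- x[mod$genes, ] +
        outer(mod$loading, f * active)
    }
    if (config$nUnwantedFactors > 0L) {
      u <- matrix(stats::rnorm(n * config$nUnwantedFactors), n)
      x <- x + beta %*% t(u)
    }
    dimnames(x) <- list(symbols, sheet$sample_id)
    datasets[[d]] <- CoexDataset(x, sheet, name = prefix)
  }

  moduleIdx <- sort(unique(unlist(lapply(config$modules, `[[`, "genes"))))
  gt <- list(
    modules = lapply(config$modules, function(m)
      list(genes = symbols[m$genes], loading = m$loading,
           activePeriods = m$activePeriods)),
    housekeeping = symbols[config$housekeepingIdx],
    unwantedLoadings = `rownames<-`(beta, symbols),
    impliedCorrelation = if (length(moduleIdx))
      .impliedCorrelation(config, beta, moduleIdx, symbols) else NULL,
    seed = config$seed, config = config)
  list(datasets = datasets, groundTruth = gt)
}

#' Generate a pure-noise dataset for calibration tests
#'
#' A single dataset with no co-expression modules and no unwanted factors;
#' donor structure (shared donor effects, mixed donor sizes) is retained so
#' the donor-weighting machinery is exercised. Used to check the
#' permutation-threshold contract: at proportion p, about a fraction p of
#' random candidate genes should be prioritised.
#'
#' @param nGenes,nSamples dimensions.
#' @param samplesPerDonor donor-size pool (default 1:4).
#' @param donorSd donor-effect standard deviation.
#' @param seed integer seed.
#' @return A \linkS4class{CoexDataset}.
#' @export
simulateNull <- function(nGenes = 1000L, nSamples = 120L,
                         samplesPerDonor = 1:4, donorSd = sqrt(0.1),
                         seed = 1L) {
  cfg <- simulationConfig(nDatasets = 1L, nGenes = nGenes,
                          nSamples = nSamples,
                          samplesPerDonor = samplesPerDonor,
                          donorSd = donorSd, housekeepingFraction = 0,
                          seed = seed)
  simulateDatasets(cfg)$datasets[[1L]]
}
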