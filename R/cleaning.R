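#' Configuration for RUV cleaning
#'
#' @param nFactors number of unwanted-variation dimensions to estimate from
#'   the negative-control genes (default 10; must be below the sample count).
#' @param ridge non-negative ridge regularisation strength, or \code{"auto"}
#'   (default). Each unwanted factor is removed with shrinkage
#'   \code{1/(1 + ridge)}: 0 removes the factors completely, large values
#'   leave the data untouched. \code{"auto"} picks, per dataset, the grid
#'   value for which the cleaned negative-control correlations best match
#'   what independent genes would show.
#' @param controlGenes negative-control gene symbols (see
#'   \code{\link{defaultNegativeControls}}); required when
#'   \code{nFactors > 0}.
#' @return a list of class \code{RuvConfig}.
#' @export
ruvConfig <- function(nFactors = 10L, ridge = "auto",
                      controlGenes = character()) {
  nFactors <- as.integer(nFactors)
  if (is.na(nFactors) || nFactors < 0L) stop("nFactors must be >= 0")
  if (!identical(ridge, "auto")) {
    ridge <- as.numeric(ridge)
    if (is.na(ridge) || ridge < 0) stop("ridge must be non-negative or 'auto'")
  }
  if (nFactors > 0L && !length(controlGenes))
    stop("control genes are required when nFactors > 0")
  structure(list(nFactors = nFactors, ridge = ridge,
                 controlGenes = unique(normaliseGeneSymbols(controlGenes))),
            class = "RuvConfig")
}

.RIDGE_GRID <- c(0, 0.1, 0.5, 1, 5, 10, 50)

#' Background correction with quantile normalisation
#'
#' The conventional cleaning strategy. Because inputs are already
#' summarised log-scale matrices (probe-level background models need raw
#' files), background correction is a per-sample positivity shift: when a
#' sample's low quantile (\code{bgQuantile}) is negative, that offset is
#' subtracted and values are floored at a small constant. Columns are then
#' quantile-normalised to a common empirical distribution (the mean of the
#' per-rank order statistics); ties within a column receive the mean of the
#' normalised values of the tied ranks. The operation is idempotent.
#'
#' @param dataset a \linkS4class{CoexDataset} with a complete matrix.
#' @param bgQuantile quantile used as the per-sample background level.
#' @return the dataset with a cleaned \code{exprs} assay; metadata and
#'   sample annotation are untouched.
#' @export
backgroundQuantile <- function(dataset, bgQuantile = 0.02) {
  m <- exprs(dataset)
  q <- apply(m, 2L, stats::quantile, probs = bgQuantile, names = FALSE)
  offset <- pmin(q, 0)
  m <- sweep(m, 2L, offset, "-")
  m <- pmax(m, 1e-8)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  assay(dataset, "exprs") <- out
  metadata(dataset)$cleaning <- list(strategy = "quantile",
                                     bgQuantile = bgQuantile)
  dataset
}

#' Remove unwanted variation using negative-control genes
#'
#' Estimates unwanted (technical/batch) variation from negative-control
#' genes — genes affected by unwanted variation but not by the biology of
#' interest — and regresses it out of every gene. All gene rows are centred;
#' the unwanted factors are the top \code{nFactors} right singular vectors
#' of the centred control-gene submatrix; each gene is then adjusted by
#' removing its ridge-regularised projection onto those factors (shrinkage
#' \code{1/(1 + ridge)} per factor). With \code{ridge = 0} the control rows
#' end exactly orthogonal to the estimated factors; as \code{ridge} grows
#' the output converges to the row-centred input. The ridge guards against
#' removing biology when unwanted and biological variation are correlated.
#'
#' @param dataset a \linkS4class{CoexDataset}.
#' @param config a \code{\link{ruvConfig}}.
#' @return the dataset with a cleaned, row-centred \code{exprs} assay;
#'   metadata records strategy, factor count, ridge and control count.
#' @export
ruvClean <- function(dataset, config) {
  stopifnot(inherits(config, "RuvConfig"))
  m <- exprs(dataset)
  k <- config$nFactors
  if (k >= ncol(m))
    stop("nFactors (", k, ") must be smaller than the sample count (",
         ncol(m), ")")
  centred <- m - rowMeans(m)
  if (k == 0L) {
    assay(dataset, "exprs") <- centred
    metadata(dataset)$cleaning <- list(strategy = "ruv", nFactors = 0L,
                                       ridge = 0, nControls = 0L)
    return(dataset)
  }
  ctrl <- intersect(config$controlGenes, rownames(m))
  missing <- setdiff(config$controlGenes, rownames(m))
  if (length(missing))
    stop("control gene(s) missing from dataset '", datasetName(dataset),
         "': ", paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ...")
  z <- centred[ctrl, , drop = FALSE]
  k <- min(k, length(ctrl), ncol(m) - 1L)
  sv <- svd(z, nu = 0L, nv = k)
  f <- sv$v[, seq_len(k), drop = FALSE]            # samples x k, orthonormal

  ridge <- config$ridge
  if (identical(ridge, "auto"))
    ridge <- .autoRidge(centred, ctrl, f, ncol(m))
  shrink <- 1 / (1 + ridge)
  cleaned <- centred - (centred %*% f) %*% t(f) * shrink
  dimnames(cleaned) <- dimnames(m)
  assay(dataset, "exprs") <- cleaned
  metadata(dataset)$cleaning <- list(strategy = "ruv", nFactors = k,
                                     ridge = ridge, nControls = length(ctrl))
  dataset
}

# Pick the grid ridge whose cleaned control-gene correlations look most like
# independent genes: mean |r| among controls compared with the expectation
# sqrt(2/(pi * (n - 1))) for independent Gaussian vectors of length n.
.autoRidge <- function(centred, ctrl, f, n) {
  target <- sqrt(2 / (pi * (n - 1)))
  z <- centred[ctrl, , drop = FALSE]
  score <- vapply(.RIDGE_GRID, function(lam) {
    zc <- z - (z %*% f) %*% t(f) / (1 + lam)
    r <- suppressWarnings(stats::cor(t(zc)))
    r[!is.finite(r)] <- 0
    abs(mean(abs(r[upper.tri(r)])) - target)
  }, numeric(1))
  .RIDGE_GRID[which.min(score)]
}

#' Apply a named cleaning strategy
#'
#' Dispatch helper used by the pipeline and CLI: \code{"quantile"} runs
#' \code{\link{backgroundQuantile}}, \code{"ruv"} runs
#' \code{\link{ruvClean}}, \code{"none"} returns the dataset unchanged.
#'
#' @param dataset a \linkS4class{CoexDataset}.
#' @param strategy one of \code{"none"}, \code{"quantile"}, \code{"ruv"}.
#' @param config a \code{\link{ruvConfig}} (required for \code{"ruv"}).
#' @return the cleaned dataset.
#' @export
cleanDataset <- function(dataset, strategy = c("none", "quantile", "ruv"),
                         config = NULL) {
  strategy <- match.arg(strategy)
  switch(strategy,
         none = dataset,
         quantile = backgroundQuantile(dataset),
         ruv = {
           if (is.null(config)) stop("ruv cleaning needs a ruvConfig")
           ruvClean(dataset, config)
         })
}
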