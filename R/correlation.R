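#' Donor-weighted Pearson correlation
#'
#' Pearson correlation with per-sample weights, intended to be the inverse
#' donor-contribution weights of \code{\link{donorWeights}} so that every
#' donor carries unit total weight regardless of how many samples it
#' contributed:
#' \deqn{r = \frac{\sum_i w_i (x_i - \bar x_w)(y_i - \bar y_w)}
#'   {\sqrt{\sum_i w_i (x_i-\bar x_w)^2 \; \sum_i w_i (y_i-\bar y_w)^2}}}
#' with \eqn{\bar x_w, \bar y_w} the weighted means. The value is invariant
#' to positive affine transforms of \code{x} or \code{y} and to global
#' rescaling of \code{w}; with equal weights it reduces to the ordinary
#' Pearson correlation.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param w positive weights, same length; defaults to equal weights.
#' @return correlation in [-1, 1], or \code{NA} if either input has zero
#'   weighted variance.
#' @examples
#' weightedPearson(1:4, c(2, 1, 4, 3), w = c(0.5, 0.5, 1, 1))
#' @export
weightedPearson <- function(x, y, w = rep(1, length(x))) {
  n <- length(x)
  if (length(y) != n || length(w) != n)
    stop("x, y and w must have equal length")
  if (n < 3L) stop("at least 3 observations are required")
  if (any(w <= 0)) stop("weights must be positive")
  w <- w / sum(w)
  xc <- x - sum(w * x)
  yc <- y - sum(w * y)
  vx <- sum(w * xc^2)
  vy <- sum(w * yc^2)
  if (vx <= .Machine$double.eps * max(abs(x))^2 + 1e-300 ||
      vy <= .Machine$double.eps * max(abs(y))^2 + 1e-300) return(NA_real_)
  r <- sum(w * xc * yc) / sqrt(vx * vy)
  max(-1, min(1, r))
}

# Weighted row standardisation: returns list(z, degenerate) where
# z %*% t(z) weighted by w gives the correlation matrix. Rows are centred by
# the weighted mean and scaled by the weighted sd; degenerate rows are zeroed.
.weightedStandardise <- function(m, w) {
  w <- w / sum(w)
  mu <- as.vector(m %*% w)
  mc <- m - mu
  v <- as.vector((mc * mc) %*% w)
  degenerate <- v <= 1e-24
  s <- sqrt(pmax(v, 1e-300))
  z <- sweep(mc, 2L, sqrt(w), "*") / s
  z[degenerate, ] <- 0
  list(z = z, degenerate = degenerate)
}

# Weighted correlation between the rows of two matrices sharing samples.
# Degenerate (zero-variance) rows yield 0.
.weightedCrossCor <- function(a, b, w) {
  sa <- .weightedStandardise(a, w)
  sb <- .weightedStandardise(b, w)
  r <- tcrossprod(sa$z, sb$z)
  pmin(pmax(r, -1), 1)
}

#' Donor-weighted correlation matrix for a set of genes
#'
#' Computes all pairwise donor-weighted Pearson correlations among the
#' requested genes, using weights recomputed from the dataset's donor
#' structure (\code{\link{donorWeights}}). Genes absent from the dataset are
#' dropped with a warning. Zero-variance genes are flagged as degenerate and
#' given correlation 0 (and diagonal 0) rather than dropped, so matrix
#' shapes stay stable for downstream ranking.
#'
#' @param dataset a \linkS4class{CoexDataset}, possibly period-subset.
#' @param genes gene symbols to correlate; default all genes.
#' @param weighted use donor weights (TRUE) or equal weights (FALSE).
#' @return A \linkS4class{CorrelationMatrix}.
#' @export
correlationMatrix <- function(dataset, genes = rownames(dataset),
                              weighted = TRUE) {
  genes <- unique(normaliseGeneSymbols(genes))
  absent <- setdiff(genes, rownames(dataset))
  if (length(absent)) {
    warning("gene(s) absent from ", datasetName(dataset), " dropped: ",
            paste(utils::head(absent, 10L), collapse = ", "),
            if (length(absent) > 10L) ", ...")
    genes <- setdiff(genes, absent)
  }
  if (length(genes) < 2L) stop("need at least 2 genes present in the dataset")
  if (ncol(dataset) < 3L) stop("need at least 3 samples to correlate")
  if (ncol(dataset) < 10L)
    warning("fewer than 10 samples; correlations will be noisy")
  w <- if (weighted) donorWeights(dataset) else rep(1, ncol(dataset))
  s <- .weightedStandardise(exprs(dataset)[genes, , drop = FALSE], w)
  r <- tcrossprod(s$z)
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- ifelse(s$degenerate, 0, 1)
  dimnames(r) <- list(genes, genes)
  new("CorrelationMatrix", values = r,
      degenerate = stats::setNames(s$degenerate, genes),
      dataset = datasetName(dataset),
      periods = sort(unique(samplePeriods(dataset))),
      weighted = weighted)
}

#' @describeIn correlationMatrix the numeric matrix of correlations.
#' @param cor a \linkS4class{CorrelationMatrix}.
#' @export
corValues <- function(cor) cor@values

setMethod("show", "CorrelationMatrix", function(object) {
  cat("CorrelationMatrix: ", nrow(object@values), " genes, dataset '",
      object@dataset, "', periods ",
      paste(object@periods, collapse = ","),
      if (object@weighted) ", donor-weighted" else ", unweighted",
      if (any(object@degenerate))
        paste0(", ", sum(object@degenerate), " degenerate gene(s)"),
      "\n", sep = "")
})

#' Partial correlations controlling for indirect interactions
#'
#' Converts a marginal correlation matrix into partial correlations, which
#' measure the association of each gene pair after removing the linear
#' influence of all other genes in the set — indirect interactions through
#' shared neighbours are thereby controlled for. The matrix is first shrunk
#' linearly toward the identity, \eqn{C^* = (1-s) C + s I}, which
#' guarantees invertibility when the gene count approaches or exceeds the
#' sample count; partials are then
#' \eqn{p_{jk} = -q_{jk} / \sqrt{q_{jj} q_{kk}}} with \eqn{Q = (C^*)^{-1}}.
#'
#' @param cor a \linkS4class{CorrelationMatrix}.
#' @param shrinkage shrinkage intensity in [0, 1); default 0.1.
#' @return A \linkS4class{CorrelationMatrix} of partial correlations.
#' @export
partialCorrelations <- function(cor, shrinkage = 0.1) {
  if (shrinkage < 0 || shrinkage >= 1) stop("shrinkage must be in [0, 1)")
  m <- cor@values
  shrunk <- (1 - shrinkage) * m + shrinkage * diag(nrow(m))
  q <- tryCatch(solve(shrunk), error = function(e)
    stop("correlation matrix is singular; use shrinkage > 0", call. = FALSE))
  d <- sqrt(diag(q))
  p <- -q / tcrossprod(d)
  diag(p) <- 1
  p <- pmin(pmax(p, -1), 1)
  dimnames(p) <- dimnames(m)
  methods::initialize(cor, values = p)
}

#' Per-period correlation matrices
#'
#' Estimates the gene-gene correlation matrix independently for each set of
#' developmental periods, with donor weights recomputed on each subset, so
#' that changes in gene regulation across brain development can be compared.
#' Period sets yielding fewer than \code{minSamples} samples are omitted
#' with a warning.
#'
#' @param dataset a \linkS4class{CoexDataset}.
#' @param genes gene symbols to correlate.
#' @param periodSets list of integer vectors (subsets of 1..15).
#' @param minSamples minimum samples required per period set (floor 3).
#' @return named list of \linkS4class{CorrelationMatrix} objects, one per
#'   retained period set.
#' @export
periodCorrelations <- function(dataset, genes = rownames(dataset), periodSets,
                               minSamples = 3L) {
  minSamples <- max(3L, as.integer(minSamples))
  if (!is.list(periodSets)) periodSets <- list(periodSets)
  out <- list()
  for (i in seq_along(periodSets)) {
    ps <- sort(unique(as.integer(periodSets[[i]])))
    label <- paste(ps, collapse = ",")
    n <- sum(samplePeriods(dataset) %in% ps)
    if (n < minSamples) {
      warning("period set {", label, "} has ", n,
              " sample(s) (< ", minSamples, "); omitted")
      next
    }
    out[[label]] <- correlationMatrix(subsetByPeriods(dataset, ps), genes)
  }
  out
}

#' Difference between two correlation matrices
#'
#' Elementwise \code{a - b} over the shared gene labels (the labels must be
#' identical); entries lie in [-2, 2]. Used to contrast gene regulation
#' between sets of developmental periods.
#'
#' @param a,b \linkS4class{CorrelationMatrix} objects on the same genes.
#' @return numeric matrix of correlation differences.
#' @export
differentialCorrelation <- function(a, b) {
  if (!identical(rownames(a@values), rownames(b@values)))
    stop("correlation matrices have different gene labels")
  a@values - b@values
}

#' Combine per-dataset correlation matrices
#'
#' Averages correlation matrices over their shared genes, weighting each
#' dataset by its number of distinct donors. Cross-platform merging of raw
#' expression values is unsound, so combination happens at the correlation
#' level.
#'
#' @param cors list of \linkS4class{CorrelationMatrix} objects.
#' @param donorCounts numeric weights per matrix (e.g. donors per dataset);
#'   defaults to equal weights.
#' @return A \linkS4class{CorrelationMatrix} on the shared genes.
#' @export
combineCorrelations <- function(cors, donorCounts = rep(1, length(cors))) {
  if (!length(cors)) stop("no correlation matrices supplied")
  if (length(donorCounts) != length(cors))
    stop("donorCounts must match the number of matrices")
  shared <- Reduce(intersect, lapply(cors, function(x) rownames(x@values)))
  if (length(shared) < 2L) stop("fewer than 2 genes shared across matrices")
  wts <- donorCounts / sum(donorCounts)
  acc <- matrix(0, length(shared), length(shared),
                dimnames = list(shared, shared))
  degen <- rep(FALSE, length(shared))
  for (i in seq_along(cors)) {
    acc <- acc + wts[i] * cors[[i]]@values[shared, shared]
    degen <- degen | cors[[i]]@degenerate[shared]
  }
  diag(acc) <- ifelse(degen, 0, 1)
  new("CorrelationMatrix", values = acc,
      degenerate = stats::setNames(degen, shared),
      dataset = paste0("combined(",
                       paste(vapply(cors, function(x) x@dataset, ""),
                             collapse = "+"), ")"),
      periods = sort(unique(unlist(lapply(cors, function(x) x@periods)))),
      weighted = all(vapply(cors, function(x) x@weighted, TRUE)))
}

#' Export a correlation matrix
#'
#' \code{writeCorrelationTSV} writes the genes x genes matrix as TSV.
#' \code{edgeList} flattens it to (gene_a, gene_b, r) rows, optionally
#' keeping only edges with \code{|r| >= cutoff}; \code{writeGraphML} writes
#' that edge list in GraphML for network viewers.
#'
#' @param cor a \linkS4class{CorrelationMatrix}.
#' @param path output file path.
#' @param cutoff minimum \code{|r|} for an edge (default 0, all pairs).
#' @return \code{edgeList}: data.frame gene_a, gene_b, r. The writers return
#'   their path invisibly.
#' @export
writeCorrelationTSV <- function(cor, path) {
  m <- cor@values
  out <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCorrelationTSV
#' @export
edgeList <- function(cor, cutoff = 0) {
  m <- cor@values
  idx <- which(upper.tri(m) & abs(m) >= cutoff, arr.ind = TRUE)
  data.frame(gene_a = rownames(m)[idx[, 1L]], gene_b = colnames(m)[idx[, 2L]],
             r = m[idx], stringsAsFactors = FALSE)
}

#' @rdname writeCorrelationTSV
#' @export
writeGraphML <- function(cor, path, cutoff = 0) {
  el <- edgeList(cor, cutoff = cutoff)
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = rownames(cor@values))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
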