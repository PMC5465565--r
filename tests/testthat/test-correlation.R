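test_that("weightedPearson handles the canonical cases", {
  expect_equal(weightedPearson(1:5, 1:5, rep(1, 5)), 1)
  expect_equal(weightedPearson(c(1, 2, 3), c(3, 2, 1), c(1, 1, 1)), -1)
  expect_equal(weightedPearson(1:4, c(2, 1, 4, 3)),
               cor(1:4, c(2, 1, 4, 3)))
  expect_error(weightedPearson(1:3, 1:4, rep(1, 3)), "length")
  expect_error(weightedPearson(1:2, 1:2, 1:2), "3 observations")
  expect_error(weightedPearson(1:3, 1:3, c(1, -1, 1)), "positive")
  expect_true(is.na(weightedPearson(c(1, 1, 1), 1:3, rep(1, 3))))
})

test_that("weightedPearson matches direct evaluation with repeated donors", {
  # donors (A,A,B,C) -> weights (0.5, 0.5, 1, 1)
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3); w <- c(0.5, 0.5, 1, 1)
  expect_equal(weightedPearson(x, y, w), oracleWeightedPearson(x, y, w),
               tolerance = 1e-14)
  expect_equal(weightedPearson(x, y, w),
               cov.wt(cbind(x, y), wt = w / sum(w), cor = TRUE)$cor[1, 2],
               tolerance = 1e-12)

  set.seed(10)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- rnorm(n); w <- runif(n, 0.1, 1)
    expect_equal(weightedPearson(x, y, w), oracleWeightedPearson(x, y, w),
                 tolerance = 1e-12)
  }
})

test_that("singleton donors reduce to the unweighted Pearson correlation", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(weightedPearson(x, y, rep(1, n)), cor(x, y),
                 tolerance = 1e-12)
  }
})

test_that("weightedPearson is invariant to affine maps and weight rescaling", {
  set.seed(12)
  x <- rnorm(20); y <- rnorm(20); w <- runif(20, 0.2, 1)
  r <- weightedPearson(x, y, w)
  expect_equal(weightedPearson(3 * x + 7, y, w), r, tolerance = 1e-12)
  expect_equal(weightedPearson(x, 0.1 * y - 2, w), r, tolerance = 1e-12)
  expect_equal(weightedPearson(x, y, 1000 * w), r, tolerance = 1e-12)
  expect_equal(weightedPearson(-x, y, w), -r, tolerance = 1e-12)
})

test_that("correlationMatrix computes pairwise donor-weighted correlations", {
  set.seed(13)
  m <- matrix(rnorm(5 * 20), 5, 20)
  m[2, ] <- m[1, ]                       # one gene duplicated as two labels
  donors <- rep(paste0("d", 1:8), length.out = 20)
  ds <- makeDataset(m, donors = donors)
  cm <- correlationMatrix(ds)
  v <- corValues(cm)
  expect_equal(v["G1", "G2"], 1)
  expect_equal(v, t(v))
  expect_true(all(diag(v) == 1))
  # agrees with elementwise weightedPearson
  w <- donorWeights(ds)
  expect_equal(v["G3", "G4"],
               weightedPearson(m[3, ], m[4, ], w), tolerance = 1e-12)
  # requesting an absent gene drops it with a warning
  expect_warning(cm2 <- correlationMatrix(ds, c("G1", "G3", "NOPE")),
                 "NOPE")
  expect_equal(rownames(corValues(cm2)), c("G1", "G3"))
})

test_that("independent genes show only sampling-level correlation", {
  ds <- simulateNull(nGenes = 15, nSamples = 500, donorSd = 0, seed = 14)
  v <- corValues(correlationMatrix(ds))
  expect_lt(max(abs(v[upper.tri(v)])), 0.15)
})

test_that("degenerate genes are flagged, not dropped", {
  m <- matrix(rnorm(30), 3, 10)
  m[2, ] <- 5
  ds <- makeDataset(m)
  cm <- correlationMatrix(ds)
  expect_true(cm@degenerate["G2"])
  expect_equal(unname(corValues(cm)["G2", "G1"]), 0)
  expect_equal(dim(corValues(cm)), c(3L, 3L))
  expect_error(correlationMatrix(makeDataset(m[, 1:2])), "3 samples")
})

test_that("partial correlations control for indirect interactions", {
  # closed-form Gaussian chain X -> Y -> Z: cor(X,Z) = r1 * r2 but
  # partial(X,Z | Y) = 0
  r1 <- 0.7; r2 <- 0.6
  cm <- new("CorrelationMatrix",
            values = matrix(c(1, r1, r1 * r2, r1, 1, r2, r1 * r2, r2, 1), 3,
                            dimnames = list(c("X", "Y", "Z"),
                                            c("X", "Y", "Z"))),
            degenerate = c(X = FALSE, Y = FALSE, Z = FALSE),
            dataset = "chain", periods = 1L, weighted = FALSE)
  p <- corValues(partialCorrelations(cm, shrinkage = 0))
  expect_equal(p["X", "Z"], 0, tolerance = 1e-12)
  # textbook first-order partial formula for the other pairs
  firstOrder <- function(rab, rac, rbc)
    (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
  expect_equal(p["X", "Y"], firstOrder(r1, r1 * r2, r2), tolerance = 1e-12)
  expect_equal(p["Y", "Z"], firstOrder(r2, r1 * r2, r1), tolerance = 1e-12)
})

test_that("partial correlation degenerate cases behave", {
  # 2 genes: nothing to condition on, partial equals marginal
  cm2 <- new("CorrelationMatrix",
             values = matrix(c(1, 0.4, 0.4, 1), 2,
                             dimnames = list(c("A", "B"), c("A", "B"))),
             degenerate = c(A = FALSE, B = FALSE),
             dataset = "t", periods = 1L, weighted = FALSE)
  expect_equal(corValues(partialCorrelations(cm2, 0))["A", "B"], 0.4,
               tolerance = 1e-12)
  # identity in, zeros out
  id <- new("CorrelationMatrix",
            values = diag(3) + 0,
            degenerate = rep(FALSE, 3), dataset = "t", periods = 1L,
            weighted = FALSE)
  dimnames(id@values) <- list(letters[1:3], letters[1:3])
  expect_equal(max(abs(corValues(partialCorrelations(id, 0)) - diag(3))), 0)
  # singular matrix needs shrinkage
  sing <- new("CorrelationMatrix",
              values = matrix(1, 2, 2, dimnames = list(c("A", "B"),
                                                       c("A", "B"))),
              degenerate = c(A = FALSE, B = FALSE), dataset = "t",
              periods = 1L, weighted = FALSE)
  expect_error(partialCorrelations(sing, 0), "shrinkage")
  expect_silent(partialCorrelations(sing, 0.1))
})

test_that("per-period correlations isolate period-restricted modules", {
  cfg <- simulationConfig(
    nDatasets = 1, nGenes = 40, nSamples = 160,
    modules = list(list(genes = 1:4, loading = 2, activePeriods = 1:7)),
    donorSd = 0, seed = 15)
  ds <- simulateDatasets(cfg)$datasets[[1]]
  mats <- periodCorrelations(ds, paste0("G000", 1:6),
                             list(prenatal = 1:7, postnatal = 8:15))
  expect_length(mats, 2)
  pre <- corValues(mats[["1,2,3,4,5,6,7"]])
  post <- corValues(mats[["8,9,10,11,12,13,14,15"]])
  expect_gt(mean(pre[1:4, 1:4][upper.tri(diag(4))]), 0.6)
  expect_lt(mean(abs(post[1:4, 1:4][upper.tri(diag(4))])), 0.3)

  # differential correlation highlights the prenatal-only module
  d <- differentialCorrelation(mats[[1]], mats[[2]])
  expect_gt(mean(d[1:4, 1:4][upper.tri(diag(4))]), 0.4)
  expect_equal(differentialCorrelation(mats[[1]], mats[[1]]),
               matrix(0, 6, 6, dimnames = dimnames(pre)))
  expect_equal(d, -differentialCorrelation(mats[[2]], mats[[1]]))

  # a single full-range period set equals the plain correlation matrix
  full <- periodCorrelations(ds, paste0("G000", 1:6), list(1:15))
  expect_equal(corValues(full[[1]]),
               corValues(correlationMatrix(ds, paste0("G000", 1:6))))
})

test_that("undersized period sets are omitted with a warning", {
  m <- matrix(rnorm(40), 4, 10)
  ds <- makeDataset(m, ages = c(rep(25, 8), 50, 50),
                    units = rep("Y", 10))
  warns <- capture_warnings(
    mats <- periodCorrelations(ds, rownames(ds), list(1:13, 14)))
  expect_true(any(grepl("omitted", warns)))
  expect_length(mats, 1)
  expect_error(differentialCorrelation(
    correlationMatrix(ds, c("g1", "g2")),
    correlationMatrix(ds, c("g1", "g3"))), "labels")
})

test_that("combined correlation matrices average over shared genes", {
  sim <- makeModuleSim(nDatasets = 2, seed = 16, nGenes = 30, nSamples = 50)
  cors <- lapply(sim$datasets, correlationMatrix, genes = sprintf("G%04d", 1:8))
  comb <- combineCorrelations(cors, c(3, 1))
  expect_equal(corValues(comb),
               0.75 * corValues(cors[[1]]) + 0.25 * corValues(cors[[2]]),
               ignore_attr = FALSE,
               tolerance = 1e-12)
  expect_equal(unname(diag(corValues(comb))), rep(1, 8))
})

test_that("correlation exports round-trip", {
  sim <- makeModuleSim(nDatasets = 1, seed = 17, nGenes = 20, nSamples = 40)
  cm <- correlationMatrix(sim$datasets[[1]], sprintf("G%04d", 1:6))
  tsv <- tempfile(fileext = ".tsv")
  writeCorrelationTSV(cm, tsv)
  back <- read.delim(tsv, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), corValues(cm), ignore_attr = TRUE,
               tolerance = 1e-6)

  el <- edgeList(cm, cutoff = 0.5)
  expect_true(all(abs(el$r) >= 0.5))
  expect_equal(nrow(edgeList(cm)), choose(6, 2))

  gml <- tempfile(fileext = ".graphml")
  writeGraphML(cm, gml, cutoff = 0.5)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 6)
  expect_equal(igraph::gsize(g), nrow(el))
})
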