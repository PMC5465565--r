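test_that("thresholdFromNull implements the inverse-ECDF quantile", {
  vals <- seq(0.1, 1.0, by = 0.1)
  null <- new("NullDistribution", values = vals, B = 1L, setSize = 10L,
              seed = 1L, dataset = "t")
  # hand computation over the sorted list: index ceiling(0.8 * 10) = 8
  expect_equal(thresholdFromNull(null, 0.2), 0.8)
  expect_equal(thresholdFromNull(null, 0), 1.0)   # maximum: none exceed
  expect_equal(thresholdFromNull(null, 1), 0.1)   # minimum: all exceed or tie
  expect_error(thresholdFromNull(null, 1.2), "proportion")

  # monotone non-increasing in the proportion
  set.seed(20)
  v <- runif(500)
  th <- vapply(seq(0, 1, by = 0.05), function(p) thresholdFromNull(v, p), 0)
  expect_true(all(diff(th) <= 0))
})

test_that("sampleNull pools B draws of per-gene maxima, reproducibly", {
  sim <- makeModuleSim(nDatasets = 1, seed = 21, nGenes = 60, nSamples = 40)
  ds <- sim$datasets[[1]]
  disease <- sprintf("G%04d", 1:5)
  n1 <- sampleNull(ds, disease, setSize = 10, B = 50, seed = 99)
  n2 <- sampleNull(ds, disease, setSize = 10, B = 50, seed = 99)
  expect_identical(nullValues(n1), nullValues(n2))
  expect_length(nullValues(n1), 50 * 10)
  expect_true(all(nullValues(n1) >= 0 & nullValues(n1) <= 1))
  n3 <- sampleNull(ds, disease, setSize = 10, B = 50, seed = 100)
  expect_false(identical(nullValues(n1), nullValues(n3)))

  expect_error(sampleNull(ds, disease, setSize = 60, B = 10, seed = 1),
               "pool")
  expect_warning(sampleNull(ds, c(disease, "NOPE"), setSize = 5, B = 5,
                            seed = 1), "NOPE")
})

test_that("sampleNull hits 1 for a pool gene duplicating a disease gene", {
  m <- matrix(rnorm(8 * 20), 8, 20)
  m[5, ] <- m[1, ]                      # pool gene identical to disease gene
  ds <- makeDataset(m)
  null <- sampleNull(ds, disease = c("G1", "G2"), setSize = 6, B = 3,
                     seed = 1)          # set size = whole pool: always drawn
  expect_equal(sort(unique(round(nullValues(null), 10)))[
    length(unique(round(nullValues(null), 10)))], 1)
  expect_equal(max(nullValues(null)), 1)
})

test_that("sampleNull draws match the independence null analytically", {
  # one disease gene, independent data: the pooled values are |r| of
  # independent Gaussian pairs, with E|r| = sqrt(2 / (pi * (n - 1)))
  ds <- simulateNull(nGenes = 400, nSamples = 120, donorSd = 0, seed = 22)
  null <- sampleNull(ds, disease = "G0001", setSize = 50, B = 100, seed = 2)
  expect_equal(mean(nullValues(null)), sqrt(2 / (pi * 119)),
               tolerance = 0.15)
})

test_that("prioritise matches brute-force evaluation on a worked fixture", {
  # 4 genes (2 disease, 2 candidates), 6 samples, repeated donors
  set.seed(23)
  m <- matrix(rnorm(24), 4, 6,
              dimnames = list(c("D1", "D2", "C1", "C2"), paste0("s", 1:6)))
  m["C1", ] <- m["D1", ] + rnorm(6, sd = 0.3)
  donors <- c("a", "a", "b", "b", "b", "c")
  ds <- makeDataset(m, donors = donors)
  w <- 1 / c(2, 2, 3, 3, 3, 1)
  rByHand <- sapply(c("D1", "D2"), function(d)
    sapply(c("C1", "C2"), function(cand)
      abs(oracleWeightedPearson(m[cand, ], m[d, ], w))))
  thr <- 0.3
  tab <- prioritise(ds, c("D1", "D2"), c("C1", "C2"), thr)
  expect_equal(tab$max_abs_r, unname(apply(rByHand, 1, max)),
               tolerance = 1e-12)
  expect_equal(tab$sum_above_threshold,
               unname(rowSums(rByHand * (rByHand > thr))),
               tolerance = 1e-12)
  expect_equal(tab$prioritised, unname(apply(rByHand, 1, max)) > thr)
})

test_that("prioritise flags perfect correlation and untestable candidates", {
  m <- matrix(rnorm(5 * 12), 5, 12)
  m[4, ] <- 2 * m[1, ] + 3              # affine copy of a disease gene
  ds <- makeDataset(m)
  tab <- prioritise(ds, disease = c("G1", "G2"),
                    candidates = c("G4", "G5", "MISSING"), threshold = 0.99)
  expect_equal(tab$max_abs_r[tab$gene == "G4"], 1, tolerance = 1e-12)
  expect_true(tab$prioritised[tab$gene == "G4"])
  expect_false(tab$testable[tab$gene == "MISSING"])
  expect_true(is.na(tab$max_abs_r[tab$gene == "MISSING"]))
  # strict inequality at the threshold
  expect_false(prioritise(ds, "G1", "G4", threshold = 1)$prioritised)
})

test_that("runPrioritisation composes the three steps deterministically", {
  sim <- makeModuleSim(nDatasets = 1, seed = 24, nGenes = 120, nSamples = 50)
  ds <- sim$datasets[[1]]
  bundle <- geneSetBundle(disease = sprintf("G%04d", 1:5),
                          candidates = sprintf("G%04d", 6:25))
  res <- runPrioritisation(list(ds), bundle, proportion = 0.2, B = 200,
                           seed = 31)
  # manual composition with the same derived seed (dataset index 1)
  null <- sampleNull(ds, diseaseGenes(bundle),
                     setSize = length(candidateGenes(bundle)), B = 200,
                     seed = 32, exclude = candidateGenes(bundle))
  thr <- thresholdFromNull(null, 0.2)
  tab <- prioritise(ds, diseaseGenes(bundle), candidateGenes(bundle), thr)
  expect_equal(unname(thresholds(res)), thr)
  pd <- perDatasetTable(res)
  expect_equal(pd$max_abs_r, tab$max_abs_r)
  expect_equal(pd$prioritised, tab$prioritised)

  res2 <- runPrioritisation(list(ds), bundle, proportion = 0.2, B = 200,
                            seed = 31)
  expect_identical(consensusTable(res), consensusTable(res2))
})

test_that("a module candidate reaches full consensus across datasets", {
  sim <- makeModuleSim(nDatasets = 3, seed = 25, nGenes = 200, nSamples = 80)
  mod <- sim$groundTruth$modules[[1]]$genes
  bundle <- geneSetBundle(disease = mod[1:5],
                          candidates = c(mod[6], sprintf("G%04d", 101:120)))
  res <- runPrioritisation(sim$datasets, bundle, B = 300, seed = 7)
  cs <- consensusTable(res)
  expect_equal(cs$consensus_count[cs$gene == mod[6]], 3L)
  expect_equal(cs$gene[1], mod[6])
})

test_that("datasets failing preconditions are skipped with a warning", {
  sim <- makeModuleSim(nDatasets = 1, seed = 26, nGenes = 50, nSamples = 30)
  tiny <- makeDataset(matrix(rnorm(9), 3, 3), name = "tiny")  # pool too small
  bundle <- geneSetBundle(disease = sprintf("G%04d", 1:3),
                          candidates = sprintf("G%04d", 11:20))
  warns <- capture_warnings(
    res <- runPrioritisation(list(sim$datasets[[1]], tiny), bundle, B = 50,
                             seed = 1))
  expect_true(any(grepl("skipped", warns)))
  expect_length(thresholds(res), 1)
  expect_true(all(consensusTable(res)$testable_datasets <= 1))
})

test_that("consensus filtering is nested and ranking keys are ordered", {
  pd <- data.frame(
    dataset = rep(c("d1", "d2", "d3"), each = 4),
    gene = rep(c("A", "B", "C", "D"), 3),
    max_abs_r = 0.5,
    sum_above_threshold = rep(c(0.8, 1.1, 0.8, 0), 3),
    prioritised = c(TRUE, TRUE, TRUE, FALSE,
                    TRUE, TRUE, TRUE, FALSE,
                    TRUE, FALSE, TRUE, FALSE),
    testable = TRUE)
  cs <- coexRank:::.consensusTable(pd, c("A", "B", "C", "D"))
  res <- new("PrioritisationResult", perDataset = pd, consensus = cs,
             thresholds = c(d1 = 0.3, d2 = 0.3, d3 = 0.3),
             proportion = 0.2, seed = 1L)
  # counts: A = 3, B = 2, C = 3, D = 0; sums: A = 2.4, C = 2.4 (tie -> abc)
  expect_equal(rankCandidates(res), c("A", "C", "B", "D"))
  expect_true(all(cs$tied[cs$gene %in% c("A", "C")]))
  expect_equal(consensusFilter(res, 1), c("A", "C", "B"))
  expect_equal(consensusFilter(res, 2), c("A", "C", "B"))
  expect_equal(consensusFilter(res, 3), c("A", "C"))
  expect_equal(consensusFilter(res, 4), character(0))
  for (k in 1:3)
    expect_true(all(consensusFilter(res, k + 1) %in% consensusFilter(res, k)))
})

test_that("the pipeline equals an unweighted oracle with singleton donors", {
  set.seed(27)
  m <- matrix(rnorm(18 * 40), 18, 40)
  ds <- makeDataset(m)                      # every donor contributes once
  disease <- c("G1", "G2", "G3")
  candidates <- c("G4", "G5", "G6", "G7")
  res <- runPrioritisation(list(ds), geneSetBundle(disease, candidates),
                           proportion = 0.25, B = 100, seed = 41)
  oracle <- oraclePrioritise(ds, disease, candidates, 0.25, B = 100,
                             seed = 42)     # seed + dataset index
  expect_equal(unname(thresholds(res)), oracle$threshold, tolerance = 1e-12)
  pd <- perDatasetTable(res)
  expect_equal(pd$max_abs_r[match(candidates, pd$gene)],
               unname(oracle$max_abs_r), tolerance = 1e-12)
  expect_equal(pd$prioritised[match(candidates, pd$gene)],
               unname(oracle$prioritised))
  expect_equal(pd$sum_above_threshold[match(candidates, pd$gene)],
               unname(oracle$sum_above), tolerance = 1e-12)
})

test_that("the ranked table export carries thresholds and ranks", {
  sim <- makeModuleSim(nDatasets = 2, seed = 28, nGenes = 80, nSamples = 40)
  bundle <- geneSetBundle(disease = sprintf("G%04d", 1:5),
                          candidates = sprintf("G%04d", 6:15))
  res <- runPrioritisation(sim$datasets, bundle, B = 100, seed = 3)
  path <- tempfile(fileext = ".tsv")
  writePrioritisationTSV(res, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# threshold.sim1=", lines)))
  tab <- read.delim(path, comment.char = "#")
  expect_equal(nrow(tab), 10)
  expect_equal(tab$rank, 1:10)
})
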