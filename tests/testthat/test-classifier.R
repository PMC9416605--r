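test_that("stratified split hits the rounded partition sizes exactly", {
  labels <- rep(names(movementClasses()), each = 90)
  cfg <- netConfig(seed = 4)
  parts <- splitDataset(labels, cfg)
  expect_identical(lengths(parts),
                   c(train = 378L, validation = 81L, test = 81L))
  ## disjoint and exhaustive
  all_idx <- sort(unlist(parts, use.names = FALSE))
  expect_identical(all_idx, seq_along(labels))
  ## stratification: every class appears in every partition
  for (p in parts) expect_true(all(table(labels[p]) >= 13))
  ## seed repeat -> identical partitions
  expect_identical(splitDataset(labels, cfg), parts)
  ## too-small class
  expect_error(splitDataset(c("M1", "M1", "M2"), cfg), "too few")
})

test_that("softmax probabilities sum to one and confusion math is exact", {
  gd <- classifierDataset("average")
  cfg <- netConfig(hiddenSize = 10, maxEpochs = 30, seed = 2)
  parts <- splitDataset(gd, cfg)
  net <- trainGestureNet(gd, cfg, parts)
  P <- predictGestureNet(net, gd, type = "prob")
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))

  ## closed-form confusion arithmetic: constant predictor (always M2) on a
  ## balanced truth set
  lv <- names(movementClasses())
  truth <- rep(lv, each = 15)
  cm <- confusionCounts(truth, rep("M2", 90), lv)
  rep0 <- semgflex:::reportFromConfusion(list(test = cm))
  expect_equal(unname(rep0@accuracy["test"]), 1 / 6)
  expect_equal(unname(rep0@sensitivity[, "test"]), c(0, 1, 0, 0, 0, 0))
  expect_equal(unname(rep0@precision["M2", "test"]), 1 / 6)
  ## empty predicted columns give precision 0, not NaN
  expect_identical(unname(rep0@precision["M1", "test"]), 0)

  ## hand-computed 3-class example
  truth3 <- c("a", "a", "a", "b", "b", "b", "c", "c", "c")
  pred3 <- c("a", "b", "a", "b", "b", "c", "c", "c", "a")
  cm3 <- confusionCounts(truth3, pred3, c("a", "b", "c"))
  expect_identical(unname(cm3),
                   matrix(c(2L, 0L, 1L, 1L, 2L, 0L, 0L, 1L, 2L), 3))
  rep3 <- semgflex:::reportFromConfusion(list(test = cm3))
  expect_equal(unname(rep3@accuracy["test"]), 6 / 9)
  expect_equal(unname(rep3@sensitivity[, "test"]), rep(2 / 3, 3))
})

test_that("training is deterministic, separates easy data and stops early", {
  ## linearly separable 2-class toy problem reaches 100% training accuracy
  set.seed(9)
  X <- rbind(matrix(rnorm(10 * 4, mean = 2), 10),
             matrix(rnorm(10 * 4, mean = -2), 10))
  segsY <- rep(c("M1", "M2"), each = 10)
  toy <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(X)),
    colData = S4Vectors::DataFrame(subjectId = "S01", arm = "left",
                                   cycle = 1L, movement = segsY),
    metadata = list(mode = "average", labelLevels = c("M1", "M2")))
  toy <- new("GestureDataset", toy)
  cfg <- netConfig(hiddenSize = 4, maxEpochs = 200, patience = Inf,
                   splitFractions = c(0.8, 0.1, 0.1), seed = 1)
  parts <- list(train = seq_len(20L), validation = integer(0),
                test = integer(0))
  expect_error(trainGestureNet(toy, netConfig(splitFractions = c(1, 0, 0)),
                               parts), "validation")
  net <- trainGestureNet(toy, cfg, parts)
  expect_identical(predictGestureNet(net, X), segsY)

  ## determinism: identical config -> identical weights and report
  gd <- classifierDataset("average")
  cfg2 <- netConfig(hiddenSize = 15, maxEpochs = 120, seed = 6)
  p2 <- splitDataset(gd, cfg2)
  n1 <- trainGestureNet(gd, cfg2, p2)
  n2 <- trainGestureNet(gd, cfg2, p2)
  expect_identical(n1@W1, n2@W1)
  expect_identical(n1@W2, n2@W2)
  r1 <- evaluateGestureNet(n1, gd, p2)
  r2 <- evaluateGestureNet(n2, gd, p2)
  expect_identical(r1@confusion, r2@confusion)
  expect_lte(n1@history$epochs, 120L)

  ## the net beats the nearest-centroid floor on the separable cohort
  cfg3 <- netConfig(hiddenSize = 49, seed = 3)
  p3 <- splitDataset(gd, cfg3)
  net3 <- trainGestureNet(gd, cfg3, p3)
  rep3 <- evaluateGestureNet(net3, gd, p3)
  nc <- baselineNearestCentroid(gd, p3)
  expect_gte(nc, 0.85)
  expect_gte(accuracy(rep3, "test"), 0.90)
  ## evaluation partitions account for every instance
  expect_identical(sum(confusion(rep3, "overall")), ncol(gd))
})

test_that("shuffled labels destroy accuracy to chance", {
  gd <- classifierDataset("average")
  accs <- vapply(1:4, function(r) {
    gds <- shuffleLabels(gd, 500 + r)
    cfg <- netConfig(hiddenSize = 15, maxEpochs = 80, patience = Inf,
                     seed = r)
    ps <- splitDataset(gds, cfg)
    net <- trainGestureNet(gds, cfg, ps)
    accuracy(evaluateGestureNet(net, gds, ps), "test")
  }, 0)
  expect_lt(mean(accs), 0.45)
  ## and far below the accuracy on true labels
  expect_gt(0.90, mean(accs))
})

test_that("networks round-trip through the portable JSON format", {
  d <- withr::local_tempdir()
  gd <- classifierDataset("average")
  cfg <- netConfig(hiddenSize = 8, maxEpochs = 40, seed = 11)
  parts <- splitDataset(gd, cfg)
  net <- trainGestureNet(gd, cfg, parts)
  p <- file.path(d, "net.json")
  writeGestureNet(net, p)
  back <- readGestureNet(p)
  expect_equal(back@W1, net@W1, tolerance = 1e-12)
  expect_identical(back@classLevels, net@classLevels)
  expect_identical(predictGestureNet(back, gd), predictGestureNet(net, gd))
  ## dimension mismatch is caught
  expect_error(predictGestureNet(net, matrix(0, 2, 7)), "mismatch")
})

test_that("the experiment grid reports one populated row per cell", {
  gd <- classifierDataset("average")
  grid <- runExperimentGrid(list(average = gd), hidden = c(10, 20),
                            config = netConfig(maxEpochs = 40, seed = 2))
  expect_identical(nrow(grid), 2L)
  expect_identical(grid$hidden, c(10L, 20L))
  expect_true(all(is.finite(unlist(grid[, c("train", "validation", "test",
                                            "overall", "epochs",
                                            "seconds")]))))
  ## repeat with the same seed: identical accuracy cells
  grid2 <- runExperimentGrid(list(average = gd), hidden = c(10, 20),
                             config = netConfig(maxEpochs = 40, seed = 2))
  expect_identical(grid[, 1:6], grid2[, 1:6])
})
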