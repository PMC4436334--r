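# Tree-ensemble density regression.

# A one-feature training set, for contract tests that need full control.
toyTrainingSet <- function(x, y) {
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "f1"))
  new("TrainingSet", X = X, y = y,
      provenance = data.frame(imageId = "toy", nPixels = length(y)),
      featureNames = "f1")
}

# Expected prediction of the one-feature extremely-randomized-tree model,
# by enumeration: thresholds are uniform on the node's observed feature
# range, recursion stops on pure or singleton nodes, and the query point
# follows the side its value falls on. Independent of the fitting code.
enumExpectedPred <- function(xs, ys, q) {
  if (length(xs) == 1 || length(unique(ys)) == 1) return(mean(ys))
  span <- max(xs) - min(xs)
  e <- 0
  for (i in seq_len(length(xs) - 1)) {
    p <- (xs[i + 1] - xs[i]) / span
    if (q <= xs[i])
      e <- e + p * enumExpectedPred(xs[seq_len(i)], ys[seq_len(i)], q)
    else
      e <- e + p * enumExpectedPred(xs[-seq_len(i)], ys[-seq_len(i)], q)
  }
  e
}

test_that("training sets crop full-image density maps into ROIs", {
  scene <- tinyDataset()
  img <- scene$images[[1]]
  ann <- scene$annotations[[1]]
  ts <- buildTrainingSet(list(a = img), list(a = ann),
                         rois = list(a = list(ROI(c(10, 10), 50, 50))),
                         featureCfg = smallFeatureConfig())
  expect_equal(nrow(ts@X), 2500L)   # one 50x50 ROI
  expect_true(all(ts@y >= 0))

  # an ROI containing no dot but 2 px from a labelled egg still sees the
  # Gaussian tails crossing its border
  annNear <- DotAnnotation("a", cbind(50L, 50L), c(96L, 96L))
  roiNear <- ROI(c(52, 45), 10, 10)
  expect_equal(nDots(dotsInRoi(annNear, roiNear)), 0L)
  tsN <- buildTrainingSet(list(a = img), list(a = annNear),
                          rois = list(a = list(roiNear)),
                          featureCfg = smallFeatureConfig())
  expect_gt(sum(tsN@y), 0)

  # two disjoint ROIs concatenate deterministically
  rois2 <- list(a = list(ROI(c(0, 0), 20, 30), ROI(c(40, 40), 10, 10)))
  ts2 <- buildTrainingSet(list(a = img), list(a = ann), rois = rois2,
                          featureCfg = smallFeatureConfig())
  expect_equal(nrow(ts2@X), 20L * 30L + 10L * 10L)
  expect_equal(ts2@provenance$nPixels, c(600L, 100L))
  expect_error(buildTrainingSet(list(a = img), list(a = ann),
                                rois = list(a = list())), "ROI")
})

test_that("fitting honours the averaging bounds and determinism contract", {
  set.seed(42)
  probe <- matrix(runif(200), ncol = 1, dimnames = list(NULL, "f1"))

  # all-zero targets: every prediction is exactly zero
  ts0 <- toyTrainingSet(runif(50), rep(0, 50))
  m0 <- fitModel(ts0, nTrees = 10, seed = 1)
  expect_identical(unique(eggCounter:::predictRows(m0, probe)), 0)

  # identical training set + seed: identical predictions
  tsS <- toyTrainingSet(runif(100), runif(100))
  p1 <- eggCounter:::predictRows(fitModel(tsS, nTrees = 15, seed = 7), probe)
  p2 <- eggCounter:::predictRows(fitModel(tsS, nTrees = 15, seed = 7), probe)
  expect_identical(p1, p2)

  # predictions are leaf averages: never outside the target range
  expect_true(all(p1 >= min(tsS@y) & p1 <= max(tsS@y)))

  # two-plateau toy: ends of the range are recovered
  tsT <- toyTrainingSet(0:9, c(rep(0, 5), rep(1, 5)))
  mT <- fitModel(tsT, nTrees = 30, seed = 3)
  ends <- eggCounter:::predictRows(
    mT, matrix(c(0, 9), ncol = 1, dimnames = list(NULL, "f1")))
  expect_lt(abs(ends[1] - 0), 0.05)
  expect_lt(abs(ends[2] - 1), 0.05)

  expect_error(fitModel(tsT, nTrees = 0), ">= 1")
})

test_that("the ensemble converges to the enumerated random-split model", {
  xs <- 0:9
  ys <- c(rep(0, 5), rep(1, 5))
  m <- fitModel(toyTrainingSet(xs, ys), nTrees = 200, seed = 11)
  got <- eggCounter:::predictRows(
    m, matrix(xs, ncol = 1, dimnames = list(NULL, "f1")))
  want <- vapply(xs, function(q) enumExpectedPred(xs, ys, q), numeric(1))
  expect_true(all(abs(got - want) < 0.05))
})

test_that("compiled forest traversal equals the ensemble's own predictions", {
  fx <- midScene()
  m <- fitModel(fx$ts, nTrees = 30, seed = 5, maxPixels = 8000)
  X <- matrix(values(fx$stack), 300 * 300, 60)
  colnames(X) <- featureNames(fx$stack)
  idx <- seq(1, nrow(X), by = 97)
  fast <- eggCounter:::predictRows(m, X[idx, , drop = FALSE])
  slow <- predict(m@ensemble, data = X[idx, , drop = FALSE],
                  num.threads = 1)$predictions
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("self-evaluation recovers the training image's count", {
  fx <- midScene()
  m <- fitModel(fx$ts, nTrees = 30, seed = 5, maxPixels = 8000)
  dm <- predictDensity(m, fx$stack)
  n <- nDots(fx$scene$annotation)
  expect_true(all(values(dm) >= 0))
  expect_lt(abs(countFromDensity(dm) - n) / n, 0.15)
  # max prediction never exceeds the largest training density
  expect_lte(max(values(dm)), max(fx$ts@y))

  # an egg-free vial scores a small non-negative count
  blank <- generateVialImage(sceneParams(imageShape = c(128L, 128L),
                                         nEggs = 0L, seed = 99L))
  pcBlank <- predictCount(m, blank$image)
  expect_gte(pcBlank, 0)
  expect_lt(pcBlank, n)
})

test_that("feature mismatches are refused with the differing planes named", {
  fx <- midScene()
  m <- fitModel(fx$ts, nTrees = 5, seed = 5, maxPixels = 2000)
  stackSmall <- computeFeatureStack(fx$scene$image[1:32, 1:32, ],
                                    smallFeatureConfig())
  expect_error(predictDensity(m, stackSmall), "R_s3.2")
})

test_that("model archives round-trip bit-identically and verify integrity", {
  fx <- midScene()
  m <- fitModel(fx$ts, nTrees = 10, seed = 21, maxPixels = 4000)
  probe <- computeFeatureStack(fx$scene$image[1:64, 1:64, ])
  before <- values(predictDensity(m, probe))

  f <- withr::local_tempfile(fileext = ".qfm")
  saveModel(m, f)
  m2 <- loadModel(f)
  expect_identical(values(predictDensity(m2, probe)), before)

  # corrupting the stored feature configuration is detected
  raw <- readRDS(f)
  raw$model@featureConfig <- smallFeatureConfig()
  f2 <- withr::local_tempfile(fileext = ".qfm")
  saveRDS(raw, f2)
  expect_error(loadModel(f2), "digest")

  # different seeds give different archives; both load
  f3 <- withr::local_tempfile(fileext = ".qfm")
  saveModel(fitModel(fx$ts, nTrees = 10, seed = 22, maxPixels = 4000), f3)
  expect_false(identical(readBin(f, "raw", file.size(f)),
                         readBin(f3, "raw", file.size(f3))))
  expect_s4_class(loadModel(f3), "EggModel")
  expect_error(suppressWarnings(
    loadModel(withr::local_tempfile(fileext = ".qfm"))), "archive")
})
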