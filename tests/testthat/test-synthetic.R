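# Synthetic vial-image generator.

test_that("scenes carry exact dot ground truth inside the dish", {
  p0 <- sceneParams(imageShape = c(128L, 128L), nEggs = 0L, seed = 3L)
  s0 <- generateVialImage(p0)
  expect_equal(nDots(s0$annotation), 0L)
  expect_equal(dim(s0$image), c(128L, 128L, 3L))
  expect_true(all(s0$image >= 0 & s0$image <= 1))

  p <- sceneParams(imageShape = c(200L, 200L), nEggs = 100L, seed = 5L)
  s <- generateVialImage(p)
  expect_equal(nDots(s$annotation), 100L)
  ctr <- (200 + 1) / 2
  d <- dots(s$annotation) + 1   # 1-based pixel centres
  expect_true(all(sqrt((d[, 1] - ctr)^2 + (d[, 2] - ctr)^2) <=
                  0.45 * 200 + 1))
})

test_that("generation is seed-deterministic and seed-sensitive", {
  p <- sceneParams(imageShape = c(150L, 150L), nEggs = 40L, seed = 9L)
  s1 <- generateVialImage(p)
  s2 <- generateVialImage(p)
  expect_identical(s1$image, s2$image)
  expect_identical(dots(s1$annotation), dots(s2$annotation))

  p2 <- sceneParams(imageShape = c(150L, 150L), nEggs = 40L, seed = 10L)
  s3 <- generateVialImage(p2)
  expect_gt(mean(s1$image != s3$image), 0.01)   # > 1% of pixels differ
})

test_that("impossible egg loads are refused", {
  expect_error(generateVialImage(sceneParams(imageShape = c(64L, 64L),
                                             nEggs = 2000L)),
               "half")
})

test_that("datasets span the requested count range with a valid manifest", {
  ds <- generateDataset(nImages = 8, countRange = c(15, 410),
                        params = sceneParams(imageShape = c(360L, 360L)),
                        masterSeed = 12)
  expect_equal(nrow(ds$manifest), 8L)
  expect_true(any(ds$manifest$count < 50))
  expect_true(any(ds$manifest$count > 300))
  expect_true(all(ds$manifest$count >= 15 & ds$manifest$count <= 410))
  # manifest counts equal the annotations
  for (i in 1:8)
    expect_equal(nDots(ds$annotations[[ds$manifest$image[i]]]),
                 ds$manifest$count[i])
  # any image can be regenerated from its manifest seed alone
  i <- 5
  p <- sceneParams(imageShape = c(360L, 360L))
  p@nEggs <- ds$manifest$count[i]
  p@seed <- ds$manifest$seed[i]
  again <- generateVialImage(p)
  expect_identical(again$image, ds$images[[ds$manifest$image[i]]])
})

test_that("datasets written to disk round-trip through the file dialects", {
  dir <- withr::local_tempdir()
  ds <- generateDataset(nImages = 2, countRange = c(8, 20),
                        params = sceneParams(imageShape = c(96L, 96L)),
                        masterSeed = 33, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  img <- readImageRGB(file.path(dir, "vial_01.png"))
  expect_equal(dim(img), c(96L, 96L, 3L))
  # PNG quantizes to 8 bits; content matches to within half a level
  expect_lt(max(abs(img - ds$images[["vial_01"]])), 0.5 / 255 + 1e-9)
  ann <- readDotsCsv(file.path(dir, "vial_01_dots.csv"),
                     imageDim = c(96L, 96L))
  expect_identical(dots(ann), dots(ds$annotations[["vial_01"]]))
})

test_that("a model trained on five vials generalizes to held-out vials", {
  # learnability gate for all recovery tests: the generator must not be
  # adversarially hard
  ds <- generateDataset(nImages = 8, countRange = c(30, 150),
                        params = sceneParams(imageShape = c(300L, 300L)),
                        masterSeed = 71)
  trainIds <- ds$manifest$image[1:5]
  testIds <- ds$manifest$image[6:8]
  ts <- buildTrainingSet(ds$images[trainIds], ds$annotations[trainIds])
  m <- fitModel(ts, nTrees = 30, seed = 4, maxPixels = 20000)
  pc <- vapply(testIds, function(id) predictCount(m, ds$images[[id]]),
               numeric(1))
  gt <- ds$manifest$count[match(testIds, ds$manifest$image)]
  expect_gte(accuracyPercent(pc, gt), 80)
})

test_that("opaque medium is at least as hard as translucent medium", {
  # the transparent-vs-opaque difficulty ordering, on matched seeds,
  # averaged over five replicate LOOCV runs per medium
  acc <- vapply(c("translucent", "opaque"), function(med) {
    ds <- generateDataset(nImages = 6, countRange = c(20, 120),
                          params = sceneParams(imageShape = c(256L, 256L),
                                               medium = med),
                          masterSeed = 81)
    cfg <- loocvConfig(nReplicates = 5, masterSeed = 82,
                       biasCorrection = FALSE, nTrees = 15,
                       maxTrainingPixels = 8000)
    runLoocv(ds$images, ds$annotations, cfg)$summary$meanAccuracyRaw
  }, numeric(1))
  expect_lte(acc[["opaque"]], acc[["translucent"]])
})
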