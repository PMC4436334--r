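# Shared fixtures, built lazily once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Small scale set used where the full five-scale bank is not the point.
smallFeatureConfig <- function() featureConfig(scales = c(0.8, 1.6))

# A mid-sized translucent scene with its feature stack and training set,
# reused by regressor tests.
midScene <- function() fixture("midScene", function() {
  scene <- generateVialImage(sceneParams(imageShape = c(300L, 300L),
                                         nEggs = 120L, seed = 77L))
  stack <- computeFeatureStack(scene$image)
  ts <- buildTrainingSet(list(img = scene$image),
                         list(img = scene$annotation),
                         stacks = list(img = stack))
  list(scene = scene, stack = stack, ts = ts)
})

# Smooth random test image (band-limited, so rotation comparisons are not
# dominated by pixel noise).
smoothRandomImage <- function(H, W, seed) {
  set.seed(seed)
  base <- matrix(runif(H * W), H, W)
  g <- eggCounter:::gaussKernel1d(2, 0L)
  sm <- eggCounter:::convSep(base, g, g)
  (sm - min(sm)) / (max(sm) - min(sm))
}

# One tiny annotated multi-image dataset for protocol tests.
tinyDataset <- function() fixture("tinyDataset", function() {
  generateDataset(nImages = 3L, countRange = c(10, 40),
                  params = sceneParams(imageShape = c(96L, 96L),
                                       nBubbles = 1L, nStreaks = 1L,
                                       nBaseMarks = 0L),
                  masterSeed = 55L)
})

# Independent density oracle: direct double-loop summation of the discrete
# normalized Gaussian over the truncation window, clipped to the image.
oracleDensitySum <- function(dotsRC, H, W, sigma = 1, truncation = 4) {
  r <- ceiling(truncation * sigma)
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g); k <- k / sum(k)
  total <- 0
  for (i in seq_len(nrow(dotsRC))) {
    for (dr in x) for (dc in x) {
      rr <- dotsRC[i, 1] + dr; cc <- dotsRC[i, 2] + dc
      if (rr >= 0 && rr < H && cc >= 0 && cc < W)
        total <- total + k[dr + r + 1, dc + r + 1]
    }
  }
  total
}
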