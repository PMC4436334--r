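# Extremely-randomized-trees density regression.
#
# Per-pixel feature vectors are regressed onto density values with an
# ensemble of extremely randomized trees: at every node a random subset of
# features is drawn, each with a uniformly random threshold between its
# observed minimum and maximum, and the candidate with the largest
# reduction of label variance is kept; recursion stops at pure or minimal
# nodes. The ensemble prediction is the per-pixel average over trees, so
# predictions are leaf averages of non-negative training densities and are
# non-negative by construction (no clamping stage exists). The forest is
# fitted by ranger (splitrule "extratrees", one random threshold per
# candidate, no bootstrap), which satisfies this contract.

# Deterministic row order for the pixels of one ROI: row-major within the
# rectangle. Returns linear (column-major) indices into an H x W matrix.
#' @noRd
roiLinearIndex <- function(roi, H, W) {
  if (roi@origin[1] + roi@height > H || roi@origin[2] + roi@width > W)
    stop("ROI extends beyond the image")
  rows <- (roi@origin[1] + 1L):(roi@origin[1] + roi@height)
  cols <- (roi@origin[2] + 1L):(roi@origin[2] + roi@width)
  as.vector(t(outer(rows, (cols - 1L) * H, "+")))  # row-major order
}

#' Assemble the pixel-level training set
#'
#' Every ROI must be completely labelled. Feature vectors are taken from
#' each ROI's pixels; density targets come from the density map of the
#' FULL image cropped to the ROI, so Gaussian mass of eggs lying just
#' outside an ROI still contributes to the target values inside it.
#'
#' Row order is deterministic: image order, then ROI order, then row-major
#' within the ROI (no downstream computation depends on it).
#'
#' @param images named list of H x W x 3 arrays (or H x W matrices).
#' @param annotations named list of [DotAnnotation-class], same names.
#' @param rois named list (same names) of lists of [ROI-class]; NULL means
#'   one whole-image region per image.
#' @param featureCfg a [FeatureConfig-class].
#' @param densityCfg a [DensityConfig-class].
#' @param stacks optional named list of precomputed [FeatureStack-class]
#'   objects (they must match `featureCfg`).
#' @return A [TrainingSet-class].
#' @export
buildTrainingSet <- function(images, annotations, rois = NULL,
                             featureCfg = featureConfig(),
                             densityCfg = densityConfig(),
                             stacks = NULL) {
  ids <- names(images)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("'images' must be a named list")
  if (!all(ids %in% names(annotations)))
    stop("every image needs a matching annotation")
  if (!is.null(rois) && length(rois) == 0)
    stop("empty ROI list")
  Xs <- list(); ys <- list(); prov <- list()
  for (id in ids) {
    img <- images[[id]]
    H <- dim(img)[1]; W <- dim(img)[2]
    st <- if (!is.null(stacks) && !is.null(stacks[[id]])) stacks[[id]]
          else computeFeatureStack(img, featureCfg)
    stMat <- matrix(st@values, H * W, dim(st@values)[3])
    dmap <- makeDensityMap(annotations[[id]], c(H, W), densityCfg)
    imgRois <- if (is.null(rois)) list(ROI(c(0L, 0L), H, W))
               else rois[[id]]
    if (is.null(imgRois) || length(imgRois) == 0)
      stop(sprintf("no ROI given for image '%s'", id))
    for (j in seq_along(imgRois)) {
      idx <- roiLinearIndex(imgRois[[j]], H, W)
      Xs[[length(Xs) + 1L]] <- stMat[idx, , drop = FALSE]
      ys[[length(ys) + 1L]] <- dmap@values[idx]
      prov[[length(prov) + 1L]] <- data.frame(
        imageId = id, roi = j,
        originRow = imgRois[[j]]@origin[1], originCol = imgRois[[j]]@origin[2],
        height = imgRois[[j]]@height, width = imgRois[[j]]@width,
        nPixels = length(idx),
        ac = nDots(dotsInRoi(annotations[[id]], imgRois[[j]])),
        stringsAsFactors = FALSE)
    }
  }
  X <- do.call(rbind, Xs)
  colnames(X) <- featurePlaneNames(featureCfg)
  new("TrainingSet", X = X, y = unlist(ys, use.names = FALSE),
      provenance = do.call(rbind, prov),
      featureNames = featurePlaneNames(featureCfg))
}

#' Fit the tree ensemble
#'
#' @param ts a [TrainingSet-class] with at least 2 rows.
#' @param nTrees number of trees (default 30).
#' @param seed master seed; all per-tree randomness and the optional pixel
#'   subsample derive from it. NULL draws (and records) an entropy seed,
#'   so even unseeded runs are reproducible after the fact.
#' @param maxPixels cap on training pixels: when the set is larger, a
#'   seeded uniform subsample of this size is used (0 = use all pixels,
#'   the default). Uniform sampling keeps the density distribution, and
#'   hence count-by-summation, unbiased.
#' @param minNodeSize minimal terminal node size (default 1: fully grown
#'   trees).
#' @param mtry random feature candidates per split; default
#'   `ceiling(sqrt(F))`.
#' @param featureCfg,densityCfg configurations recorded in the model
#'   (defaults match the package defaults the training set was built
#'   with).
#' @return An [EggModel-class]. Fits are deterministic given
#'   (`ts`, `nTrees`, `seed`).
#' @export
fitModel <- function(ts, nTrees = 30L, seed = NULL, maxPixels = 0L,
                     minNodeSize = 1L, mtry = NULL,
                     featureCfg = featureConfig(),
                     densityCfg = densityConfig()) {
  stopifnot(is(ts, "TrainingSet"))
  if (nTrees < 1L) stop("'nTrees' must be >= 1")
  if (nrow(ts@X) < 2L) stop("need at least 2 training pixels")
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
    logMsg("no seed given; using entropy seed ", seed)
  }
  seed <- as.integer(seed)
  X <- ts@X; y <- ts@y
  if (maxPixels > 0L && nrow(X) > maxPixels) {
    idx <- withSeed(deriveSeed(seed, "subsample"),
                    sample.int(nrow(X), maxPixels))
    X <- X[idx, , drop = FALSE]; y <- y[idx]
  }
  if (is.null(mtry)) mtry <- ceiling(sqrt(ncol(X)))
  ens <- ranger::ranger(
    x = X, y = y,
    num.trees = as.integer(nTrees),
    splitrule = "extratrees", num.random.splits = 1L,
    mtry = as.integer(mtry), min.node.size = as.integer(minNodeSize),
    replace = FALSE, sample.fraction = 1,
    seed = deriveSeed(seed, "forest"),
    num.threads = 1L, verbose = FALSE, oob.error = FALSE)
  digest <- contentDigest(list(featurePlaneNames(featureCfg),
                               densityCfg@sigma, densityCfg@truncationRadius,
                               ts@provenance$imageId, ts@provenance$nPixels))
  new("EggModel", ensemble = ens, nTrees = as.integer(nTrees),
      featureConfig = featureCfg, densityConfig = densityCfg,
      seed = seed, trainingDigest = digest, bias = NULL,
      yRange = range(y))
}

#' Predict a density map for a feature stack
#'
#' Per-pixel average of the tree responses; non-negative because leaves
#' average non-negative training densities.
#'
#' @param model an [EggModel-class].
#' @param stack a [FeatureStack-class] whose plane names match the model's
#'   feature configuration.
#' @return A [DensityMap-class].
#' @export
predictDensity <- function(model, stack) {
  stopifnot(is(model, "EggModel"), is(stack, "FeatureStack"))
  want <- featurePlaneNames(model@featureConfig)
  if (!identical(stack@featureNames, want)) {
    diff <- union(setdiff(stack@featureNames, want),
                  setdiff(want, stack@featureNames))
    stop("feature stack does not match the model's feature configuration; ",
         "differing planes: ", paste(diff, collapse = ", "))
  }
  d <- dim(stack@values)
  X <- matrix(stack@values, d[1] * d[2], d[3])
  colnames(X) <- stack@featureNames
  p <- predictRows(model, X)
  new("DensityMap", values = matrix(p, d[1], d[2]),
      sigma = model@densityConfig@sigma)
}

# Fast path shared by predictDensity and the evaluation module: direct
# traversal of the stored forest (compiled); bit-identical to the
# ensemble's own predict method (asserted in the test suite). Columns of X
# must be in training order, which featurePlaneNames() guarantees.
#' @noRd
predictRows <- function(model, X) {
  f <- model@ensemble$forest
  stopifnot(identical(colnames(X), f$independent.variable.names))
  .predictForestMean(
    lapply(f$child.nodeIDs, function(ch) as.integer(ch[[1]])),
    lapply(f$child.nodeIDs, function(ch) as.integer(ch[[2]])),
    lapply(f$split.varIDs, as.integer),
    lapply(f$split.values, as.numeric),
    X)
}

#' Predict the raw count PC of an image
#'
#' Composition of [computeFeatureStack()], [predictDensity()] and
#' [countFromDensity()]: the predicted per-pixel densities are summed over
#' the whole image (or an ROI).
#'
#' @param model an [EggModel-class].
#' @param image H x W x 3 array, H x W matrix, or an image file path.
#' @param roi optional [ROI-class] to restrict the count.
#' @return non-negative numeric raw count.
#' @export
predictCount <- function(model, image, roi = NULL) {
  if (is.character(image)) image <- readImageRGB(image)
  st <- computeFeatureStack(image, model@featureConfig)
  countFromDensity(predictDensity(model, st), roi)
}

.MODEL_FORMAT <- "eggCounter-model"
.MODEL_FORMAT_VERSION <- 1L

#' Save a trained model archive
#'
#' The archive is self-describing: a plain-text JSON header (configs, seed,
#' format version, training digest, package version) plus the serialized
#' ensemble and bias model. Loading reproduces predictions bit-identically.
#'
#' @param model an [EggModel-class].
#' @param path output file (conventionally `.qfm`).
#' @return `path`, invisibly.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "EggModel"))
  header <- list(
    format = .MODEL_FORMAT,
    formatVersion = .MODEL_FORMAT_VERSION,
    package = as.character(utils::packageVersion("eggCounter")),
    nTrees = model@nTrees,
    seed = model@seed,
    scales = model@featureConfig@scales,
    channels = model@featureConfig@channels,
    densitySigma = model@densityConfig@sigma,
    truncationRadius = model@densityConfig@truncationRadius,
    featureDigest = contentDigest(featurePlaneNames(model@featureConfig)),
    trainingDigest = model@trainingDigest,
    hasBias = !is.null(model@bias))
  saveRDS(list(headerJson = jsonlite::toJSON(header, auto_unbox = TRUE),
               model = model),
          path, version = 2)
  invisible(path)
}

#' Load a trained model archive
#'
#' Refuses archives with an unknown format, a different format version, or
#' a feature-configuration digest that does not match its header (never a
#' silent misprediction).
#'
#' @param path archive written by [saveModel()].
#' @return An [EggModel-class].
#' @export
loadModel <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop(sprintf(
                    "'%s' is not a readable model archive: %s",
                    path, conditionMessage(e))))
  if (!is.list(obj) || is.null(obj$headerJson))
    stop(sprintf("'%s' is not an eggCounter model archive", path))
  header <- jsonlite::fromJSON(obj$headerJson)
  if (!identical(header$format, .MODEL_FORMAT))
    stop(sprintf("'%s': unknown archive format '%s'", path, header$format))
  if (!identical(as.integer(header$formatVersion), .MODEL_FORMAT_VERSION))
    stop(sprintf("'%s': archive format version %s, this package reads %d",
                 path, header$formatVersion, .MODEL_FORMAT_VERSION))
  model <- obj$model
  if (!identical(header$featureDigest,
                 contentDigest(featurePlaneNames(model@featureConfig))))
    stop(sprintf(
      "'%s': feature configuration digest mismatch (archive corrupted?)",
      path))
  model
}

#' Model version string recorded in archives
#' @return character package version.
#' @export
modelFormatVersion <- function() {
  sprintf("%s (archive format %d)",
          as.character(utils::packageVersion("eggCounter")),
          .MODEL_FORMAT_VERSION)
}
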