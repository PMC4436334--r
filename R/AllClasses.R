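# S4 classes for the egg-counting pipeline.
#
# Coordinate convention used throughout the package: pixels are addressed as
# 0-based (row, col) pairs, row-major, matching the raster convention of the
# annotation files the package reads and writes. ROIs are half-open
# rectangles [row, row+height) x [col, col+width). Conversion to R's 1-based
# matrix indexing happens only at indexing sites, never in stored objects.

#' DotAnnotation: per-image egg-centre labels
#'
#' Holds the sparse supervision signal for counting-by-density: one
#' (row, col) pixel coordinate per labelled egg centre, 0-based, together
#' with the dimensions of the image the dots refer to.
#'
#' @slot imageId character identifier of the annotated image.
#' @slot dots integer matrix with columns `row`, `col` (0-based pixel
#'   coordinates), one row per labelled egg. Duplicates are permitted
#'   (two eggs may share a pixel in the CSV dialect).
#' @slot imageDim integer height and width of the associated image.
#' @export
setClass("DotAnnotation",
  representation(imageId = "character", dots = "matrix", imageDim = "integer"),
  validity = function(object) {
    d <- object@dots
    if (!is.numeric(d) || ncol(d) != 2L)
      return("'dots' must be a numeric matrix with columns row, col")
    if (length(object@imageDim) != 2L || any(object@imageDim < 1L))
      return("'imageDim' must be two positive integers (height, width)")
    if (nrow(d) > 0) {
      if (any(d != floor(d))) return("dot coordinates must be integers")
      bad <- d[, 1] < 0 | d[, 1] >= object@imageDim[1] |
             d[, 2] < 0 | d[, 2] >= object@imageDim[2]
      if (any(bad))
        return(sprintf("dot %d at (%d, %d) lies outside the %d x %d image",
                       which(bad)[1], d[which(bad)[1], 1], d[which(bad)[1], 2],
                       object@imageDim[1], object@imageDim[2]))
    }
    TRUE
  })

#' Construct a DotAnnotation
#'
#' @param imageId image identifier (opaque string).
#' @param dots two-column matrix (or data.frame) of 0-based (row, col)
#'   pixel coordinates; may have zero rows.
#' @param imageDim integer (height, width) of the associated image.
#' @return A [DotAnnotation-class] object.
#' @examples
#' DotAnnotation("vial_01", cbind(row = c(2L, 4L), col = c(3L, 0L)), c(5L, 5L))
#' @export
DotAnnotation <- function(imageId, dots, imageDim) {
  if (is.data.frame(dots)) dots <- as.matrix(dots)
  if (is.null(dots) || length(dots) == 0)
    dots <- matrix(integer(0), 0, 2)
  storage.mode(dots) <- "integer"
  dimnames(dots) <- list(NULL, c("row", "col"))
  new("DotAnnotation", imageId = as.character(imageId), dots = dots,
      imageDim = as.integer(imageDim))
}

#' ROI: rectangular region of interest
#'
#' Half-open rectangle [row, row+height) x [col, col+width), 0-based.
#'
#' @slot origin integer (row, col) of the top-left pixel, 0-based.
#' @slot height,width positive integer extents in pixels.
#' @export
setClass("ROI",
  representation(origin = "integer", height = "integer", width = "integer"),
  validity = function(object) {
    if (length(object@origin) != 2L || any(object@origin < 0L))
      return("'origin' must be a non-negative (row, col) pair")
    if (object@height < 1L || object@width < 1L)
      return("ROI must cover at least one pixel")
    TRUE
  })

#' Construct an ROI
#' @param origin 0-based (row, col) of the top-left corner.
#' @param height,width positive pixel extents.
#' @return An [ROI-class] object.
#' @examples
#' ROI(c(0, 0), 3, 5)
#' @export
ROI <- function(origin, height, width) {
  new("ROI", origin = as.integer(origin), height = as.integer(height),
      width = as.integer(width))
}

#' DensityConfig: parameters of the density ground-truth kernel
#'
#' @slot sigma Gaussian kernel width in pixels (default 1.0). Chosen so the
#'   kernel is smaller than the object; rescale together with image
#'   resolution.
#' @slot truncationRadius kernel support radius as a multiple of sigma
#'   (default 4.0; must be >= 3 so per-dot mass loss before discrete
#'   normalization is below 1e-3).
#' @export
setClass("DensityConfig",
  representation(sigma = "numeric", truncationRadius = "numeric"),
  validity = function(object) {
    if (object@sigma <= 0) return("'sigma' must be positive")
    if (object@truncationRadius < 3)
      return("'truncationRadius' must be >= 3 (keeps truncated mass < 1e-3)")
    TRUE
  })

#' @rdname DensityConfig-class
#' @param sigma,truncationRadius see slot documentation.
#' @return A `DensityConfig` object.
#' @export
densityConfig <- function(sigma = 1.0, truncationRadius = 4.0) {
  new("DensityConfig", sigma = as.numeric(sigma),
      truncationRadius = as.numeric(truncationRadius))
}

#' DensityMap: per-pixel object density
#'
#' Real-valued image in units of objects per pixel; the sum over any region
#' estimates the object count in that region.
#'
#' @slot values numeric matrix, same height/width as the source image.
#' @slot sigma the kernel width the map was built or predicted under.
#' @export
setClass("DensityMap",
  representation(values = "matrix", sigma = "numeric"),
  validity = function(object) {
    if (!is.numeric(object@values)) return("'values' must be numeric")
    if (any(!is.finite(object@values))) return("density values must be finite")
    if (any(object@values < 0)) return("density values must be non-negative")
    TRUE
  })

#' FeatureConfig: multiscale filter-bank configuration
#'
#' Four rotation-invariant filter responses (Gaussian gradient magnitude,
#' Laplacian of Gaussian, min and max structure-tensor eigenvalues) at each
#' scale on each colour channel: F = channels x scales x 4 feature planes.
#'
#' @slot scales strictly increasing Gaussian scales in pixels
#'   (default 0.8, 1.6, 3.2, 6.4, 12.8).
#' @slot channels colour channels to process, subset of R, G, B.
#' @export
setClass("FeatureConfig",
  representation(scales = "numeric", channels = "character"),
  validity = function(object) {
    if (length(object@scales) < 1 || any(object@scales <= 0))
      return("'scales' must be positive")
    if (is.unsorted(object@scales, strictly = TRUE))
      return("'scales' must be strictly increasing")
    if (length(object@channels) < 1 ||
        !all(object@channels %in% c("R", "G", "B")))
      return("'channels' must be a non-empty subset of R, G, B")
    TRUE
  })

#' @rdname FeatureConfig-class
#' @param scales,channels see slot documentation.
#' @return A `FeatureConfig` object.
#' @export
featureConfig <- function(scales = c(0.8, 1.6, 3.2, 6.4, 12.8),
                          channels = c("R", "G", "B")) {
  new("FeatureConfig", scales = as.numeric(scales),
      channels = as.character(channels))
}

# Filter short-names, in plane order within each (channel, scale) block.
.FILTER_NAMES <- c("ggm", "log", "stmin", "stmax")

#' Feature plane names implied by a FeatureConfig
#'
#' Deterministic order: channel (outer), scale, filter (inner);
#' e.g. `R_s0.8_ggm`, `R_s0.8_log`, ...
#' @param cfg a `FeatureConfig`.
#' @return character vector of length channels x scales x 4.
#' @export
featurePlaneNames <- function(cfg) {
  as.vector(vapply(cfg@channels, function(ch)
    vapply(cfg@scales, function(s)
      paste0(ch, "_s", format(s, trim = TRUE), "_", .FILTER_NAMES),
      character(4)),
    character(4 * length(cfg@scales))))
}

#' FeatureStack: per-pixel multiscale filter responses
#'
#' @slot values numeric array H x W x F of filter responses.
#' @slot featureNames character vector of length F naming each plane
#'   (channel, scale, filter), in a deterministic stable order.
#' @export
setClass("FeatureStack",
  representation(values = "array", featureNames = "character"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3L) return("'values' must be an H x W x F array")
    if (d[3] != length(object@featureNames))
      return("featureNames length must match the third array dimension")
    TRUE
  })

#' TrainingSet: pixel-level regression design
#'
#' @slot X numeric N x F matrix of per-pixel feature vectors.
#' @slot y numeric N-vector of density targets (objects/pixel), >= 0.
#' @slot provenance data.frame recording which (image, ROI) each block of
#'   rows came from.
#' @slot featureNames the F feature plane names of the columns of X.
#' @export
setClass("TrainingSet",
  representation(X = "matrix", y = "numeric", provenance = "data.frame",
                 featureNames = "character"),
  validity = function(object) {
    if (nrow(object@X) != length(object@y))
      return("X and y must have matching length")
    if (nrow(object@X) < 1) return("training set must be non-empty")
    if (any(object@y < 0)) return("density targets must be non-negative")
    if (ncol(object@X) != length(object@featureNames))
      return("featureNames must match ncol(X)")
    TRUE
  })

#' BiasModel: linear count-correction line
#'
#' The affine correction CC = beta * PC + c fitted by ordinary least squares
#' of actual on predicted region counts, together with the residual
#' statistics needed for prediction intervals on corrected counts.
#'
#' @slot beta slope of the correction line.
#' @slot offset intercept c of the correction line.
#' @slot pairs data.frame of the (pc, ac) region pairs used in the fit.
#' @slot n number of pairs; @slot meanPc mean predicted count;
#' @slot sxx centred sum of squares of pc; @slot s2 residual variance
#'   (RSS / (n - 2)); @slot df residual degrees of freedom.
#' @export
setClass("BiasModel",
  representation(beta = "numeric", offset = "numeric", pairs = "data.frame",
                 n = "integer", meanPc = "numeric", sxx = "numeric",
                 s2 = "numeric", df = "integer"),
  validity = function(object) {
    if (!is.finite(object@beta)) return("'beta' must be finite")
    if (object@n < 3L) return("a bias model needs at least 3 region pairs")
    TRUE
  })

#' EggModel: trained density-regression counter
#'
#' Fitted extremely-randomized-trees ensemble together with the feature and
#' density configuration it was trained under, the master seed, a digest of
#' the training provenance, and (optionally) a fitted [BiasModel-class].
#'
#' @slot ensemble the fitted ranger forest.
#' @slot nTrees number of trees (default 30).
#' @slot featureConfig,densityConfig configurations active at training.
#' @slot seed master seed of the fit.
#' @slot trainingDigest short provenance summary for reproducibility checks.
#' @slot bias a `BiasModel`, or NULL when fewer than 3 training regions
#'   were available.
#' @slot yRange range of training targets (predictions, being leaf
#'   averages, always lie inside it).
#' @export
setClass("EggModel",
  representation(ensemble = "ANY", nTrees = "integer",
                 featureConfig = "FeatureConfig",
                 densityConfig = "DensityConfig",
                 seed = "integer", trainingDigest = "character",
                 bias = "ANY", yRange = "numeric"))

#' SceneParams: synthetic vial-image generator settings
#'
#' Defaults emulate the study conditions: a 600 x 600 photograph of a vial
#' food surface, bright ellipsoidal eggs of roughly uniform size (major axis
#' 8-14 px, minor 3-5 px), partial clustering, one of two background media
#' (translucent defined medium vs opaque textured sugar/yeast medium), and
#' the usual photographic artefacts (bubbles, specular streaks, vial-base
#' marks) plus additive Gaussian noise.
#'
#' @slot imageShape integer (height, width), default 600 x 600.
#' @slot nEggs number of eggs to place.
#' @slot majorRange,minorRange egg axis length ranges in pixels.
#' @slot clusterFraction share of eggs placed within one egg-length of an
#'   already-placed egg (default 0.3); overlap permitted.
#' @slot medium "translucent" or "opaque".
#' @slot nBubbles,nStreaks,nBaseMarks artefact counts.
#' @slot noiseSigma additive Gaussian noise s.d. on [0,1] intensities.
#' @slot seed RNG seed; the image is fully determined by it.
#' @export
setClass("SceneParams",
  representation(imageShape = "integer", nEggs = "integer",
                 majorRange = "numeric", minorRange = "numeric",
                 clusterFraction = "numeric", medium = "character",
                 nBubbles = "integer", nStreaks = "integer",
                 nBaseMarks = "integer", noiseSigma = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (any(object@imageShape < 32L))
      return("'imageShape' must be at least 32 x 32")
    if (object@nEggs < 0L) return("'nEggs' must be >= 0")
    if (any(object@majorRange <= 0) || any(object@minorRange <= 0))
      return("egg axes must be positive")
    if (min(object@majorRange) < max(object@minorRange))
      return("major axis range must dominate the minor axis range")
    if (object@clusterFraction < 0 || object@clusterFraction > 1)
      return("'clusterFraction' must lie in [0, 1]")
    if (!object@medium %in% c("translucent", "opaque"))
      return("'medium' must be 'translucent' or 'opaque'")
    TRUE
  })

#' @rdname SceneParams-class
#' @param imageShape,nEggs,majorRange,minorRange,clusterFraction,medium
#'   see slot documentation.
#' @param nBubbles,nStreaks,nBaseMarks,noiseSigma,seed see slot
#'   documentation.
#' @return A `SceneParams` object.
#' @export
sceneParams <- function(imageShape = c(600L, 600L), nEggs = 100L,
                        majorRange = c(8, 14), minorRange = c(3, 5),
                        clusterFraction = 0.3,
                        medium = c("translucent", "opaque"),
                        nBubbles = 3L, nStreaks = 2L, nBaseMarks = 2L,
                        noiseSigma = 0.01, seed = 1L) {
  medium <- match.arg(medium)
  new("SceneParams", imageShape = as.integer(imageShape),
      nEggs = as.integer(nEggs), majorRange = as.numeric(majorRange),
      minorRange = as.numeric(minorRange),
      clusterFraction = as.numeric(clusterFraction), medium = medium,
      nBubbles = as.integer(nBubbles), nStreaks = as.integer(nStreaks),
      nBaseMarks = as.integer(nBaseMarks),
      noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed))
}

#' LoocvConfig: leave-one-out evaluation settings
#'
#' @slot nReplicates statistical replicates (default 5); the summary is
#'   reported as mean +/- SE over replicates.
#' @slot nTrainingImages images used per fold (default 0 = all others,
#'   the hold-one-out protocol).
#' @slot masterSeed seed from which all per-replicate, per-fold randomness
#'   is derived.
#' @slot biasCorrection fit and apply the linear correction per fold
#'   (requires >= 3 training regions).
#' @slot nTrees,maxTrainingPixels,minNodeSize regressor settings;
#'   `maxTrainingPixels` caps the seeded uniform subsample of training
#'   pixels per fit (0 = use all ROI pixels).
#' @slot featureConfig,densityConfig pipeline configurations.
#' @export
setClass("LoocvConfig",
  representation(nReplicates = "integer", nTrainingImages = "integer",
                 masterSeed = "integer", biasCorrection = "logical",
                 nTrees = "integer", maxTrainingPixels = "integer",
                 minNodeSize = "integer",
                 featureConfig = "FeatureConfig",
                 densityConfig = "DensityConfig"),
  validity = function(object) {
    if (object@nReplicates < 1L) return("'nReplicates' must be >= 1")
    if (object@nTrees < 1L) return("'nTrees' must be >= 1")
    TRUE
  })

#' @rdname LoocvConfig-class
#' @param nReplicates,nTrainingImages,masterSeed,biasCorrection see slots.
#' @param nTrees,maxTrainingPixels,minNodeSize,featureConfig,densityConfig
#'   see slot documentation.
#' @return A `LoocvConfig` object.
#' @export
loocvConfig <- function(nReplicates = 5L, nTrainingImages = 0L,
                        masterSeed = 1L, biasCorrection = TRUE,
                        nTrees = 30L, maxTrainingPixels = 20000L,
                        minNodeSize = 1L,
                        featureConfig = NULL, densityConfig = NULL) {
  if (is.null(featureConfig))
    featureConfig <- new("FeatureConfig",
                         scales = c(0.8, 1.6, 3.2, 6.4, 12.8),
                         channels = c("R", "G", "B"))
  if (is.null(densityConfig))
    densityConfig <- new("DensityConfig", sigma = 1.0, truncationRadius = 4.0)
  new("LoocvConfig", nReplicates = as.integer(nReplicates),
      nTrainingImages = as.integer(nTrainingImages),
      masterSeed = as.integer(masterSeed),
      biasCorrection = isTRUE(biasCorrection), nTrees = as.integer(nTrees),
      maxTrainingPixels = as.integer(maxTrainingPixels),
      minNodeSize = as.integer(minNodeSize),
      featureConfig = featureConfig, densityConfig = densityConfig)
}
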