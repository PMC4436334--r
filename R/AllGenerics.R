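# Generics and accessors.

#' Dot coordinates of an annotation
#' @param x a [DotAnnotation-class].
#' @return integer matrix of 0-based (row, col) coordinates.
#' @export
setGeneric("dots", function(x) standardGeneric("dots"))

#' @rdname dots
#' @export
setMethod("dots", "DotAnnotation", function(x) x@dots)

#' Number of labelled dots
#' @param x a [DotAnnotation-class].
#' @return integer count.
#' @export
setGeneric("nDots", function(x) standardGeneric("nDots"))

#' @rdname nDots
#' @export
setMethod("nDots", "DotAnnotation", function(x) nrow(x@dots))

#' Image identifier of an annotation
#' @param x a [DotAnnotation-class].
#' @return character id.
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))

#' @rdname imageId
#' @export
setMethod("imageId", "DotAnnotation", function(x) x@imageId)

#' Density values as a plain matrix
#' @param x a [DensityMap-class] or [FeatureStack-class].
#' @return numeric matrix or array.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname values
#' @export
setMethod("values", "DensityMap", function(x) x@values)

#' @rdname values
#' @export
setMethod("values", "FeatureStack", function(x) x@values)

#' Feature plane names of a stack
#' @param x a [FeatureStack-class].
#' @return character vector.
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname featureNames
#' @export
setMethod("featureNames", "FeatureStack", function(x) x@featureNames)

#' Bias model attached to a trained counter
#' @param x an [EggModel-class].
#' @return a [BiasModel-class] or NULL.
#' @export
setGeneric("biasModel", function(x) standardGeneric("biasModel"))

#' @rdname biasModel
#' @export
setMethod("biasModel", "EggModel", function(x) x@bias)

setMethod("show", "DotAnnotation", function(object) {
  cat(sprintf("DotAnnotation '%s': %d dot(s) on a %d x %d image\n",
              object@imageId, nrow(object@dots),
              object@imageDim[1], object@imageDim[2]))
})

setMethod("show", "ROI", function(object) {
  cat(sprintf("ROI [%d, %d) x [%d, %d) (%d x %d px)\n",
              object@origin[1], object@origin[1] + object@height,
              object@origin[2], object@origin[2] + object@width,
              object@height, object@width))
})

setMethod("show", "DensityMap", function(object) {
  cat(sprintf("DensityMap %d x %d (sigma = %g): total count %.3f\n",
              nrow(object@values), ncol(object@values), object@sigma,
              sum(object@values)))
})

setMethod("show", "FeatureStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("FeatureStack %d x %d with %d plane(s): %s ...\n",
              d[1], d[2], d[3],
              paste(utils::head(object@featureNames, 4), collapse = ", ")))
})

setMethod("show", "TrainingSet", function(object) {
  cat(sprintf("TrainingSet: %d pixel(s) x %d feature(s) from %d region(s)\n",
              nrow(object@X), ncol(object@X), nrow(object@provenance)))
})

setMethod("show", "BiasModel", function(object) {
  cat(sprintf("BiasModel: CC = %.4f * PC + %.4f (n = %d region pairs)\n",
              object@beta, object@offset, object@n))
})

setMethod("show", "EggModel", function(object) {
  cat(sprintf(paste0("EggModel: %d extremely randomized trees, %d feature(s),",
                     " density sigma = %g, seed = %d\n"),
              object@nTrees, length(featurePlaneNames(object@featureConfig)),
              object@densityConfig@sigma, object@seed))
  if (!is.null(object@bias)) {
    cat("  bias correction: ")
    show(object@bias)
  } else {
    cat("  bias correction: none\n")
  }
})

setMethod("show", "SceneParams", function(object) {
  cat(sprintf("SceneParams: %d x %d %s vial, %d egg(s), cluster fraction %g\n",
              object@imageShape[1], object@imageShape[2], object@medium,
              object@nEggs, object@clusterFraction))
})
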