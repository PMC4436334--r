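# Density ground-truth construction: sparse dots -> dense regression target.
#
# Each labelled egg contributes one discrete 2-D Gaussian of exactly unit
# mass: the kernel is evaluated at pixel centres over a truncation window of
# radius truncationRadius * sigma and divided by its window sum. The pixel
# sum of the map over any region therefore estimates the egg count there,
# exactly for interior dots; mass falling outside the image is lost, not
# renormalized (eggs rarely touch the borders of vial photographs).

# Discrete unit-mass Gaussian kernel on a (2r+1)^2 window.
#' @noRd
densityKernel <- function(cfg) {
  r <- ceiling(cfg@truncationRadius * cfg@sigma)
  x <- (-r):r
  g <- exp(-x^2 / (2 * cfg@sigma^2))
  k <- outer(g, g)
  list(k = k / sum(k), r = r)
}

#' Build the density ground-truth map from a dot annotation
#'
#' @param ann a [DotAnnotation-class]; every dot must lie inside
#'   `imageShape`.
#' @param imageShape integer (height, width) of the target map; defaults to
#'   the annotation's image dimensions.
#' @param cfg a [DensityConfig-class] (default sigma = 1.0 px).
#' @return A [DensityMap-class] whose sum approximates the number of dots
#'   (exact for dots at least `truncationRadius * sigma` from every
#'   border).
#' @examples
#' ann <- DotAnnotation("x", cbind(10L, 10L), c(21L, 21L))
#' sum(values(makeDensityMap(ann)))   # 1 (interior dot, unit mass)
#' @export
makeDensityMap <- function(ann, imageShape = ann@imageDim,
                           cfg = densityConfig()) {
  H <- as.integer(imageShape[1]); W <- as.integer(imageShape[2])
  d <- ann@dots
  if (nrow(d) > 0) {
    bad <- d[, 1] < 0 | d[, 1] >= H | d[, 2] < 0 | d[, 2] >= W
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("dot %d at (%d, %d) is outside the %d x %d image",
                   i, d[i, 1], d[i, 2], H, W))
    }
  }
  kern <- densityKernel(cfg)
  r <- kern$r
  m <- matrix(0, H, W)
  for (i in seq_len(nrow(d))) {
    pr <- d[i, 1] + 1L; pc <- d[i, 2] + 1L   # 1-based centre
    rows <- max(1L, pr - r):min(H, pr + r)
    cols <- max(1L, pc - r):min(W, pc + r)
    m[rows, cols] <- m[rows, cols] +
      kern$k[rows - pr + r + 1L, cols - pc + r + 1L, drop = FALSE]
  }
  new("DensityMap", values = m, sigma = cfg@sigma)
}

#' Count objects by summing density over a region
#'
#' Summation of the per-pixel densities over the whole image (or an ROI)
#' yields the estimated object count for that region; on a predicted map
#' this is the raw predicted count PC.
#'
#' @param d a [DensityMap-class].
#' @param roi optional [ROI-class]; default is the whole map.
#' @return numeric count estimate.
#' @export
countFromDensity <- function(d, roi = NULL) {
  stopifnot(is(d, "DensityMap"))
  v <- d@values
  if (is.null(roi)) return(sum(v))
  stopifnot(is(roi, "ROI"))
  if (roi@origin[1] + roi@height > nrow(v) ||
      roi@origin[2] + roi@width > ncol(v))
    stop("ROI extends beyond the density map")
  sum(v[(roi@origin[1] + 1L):(roi@origin[1] + roi@height),
        (roi@origin[2] + 1L):(roi@origin[2] + roi@width)])
}
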