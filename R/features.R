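# Per-pixel multiscale filter features.
#
# Each (channel, scale) pair yields four rotation-invariant responses:
#   ggm    Gaussian gradient magnitude at scale sigma
#   log    Laplacian of Gaussian at scale sigma
#   stmin  smaller eigenvalue of the 2x2 structure tensor
#   stmax  larger eigenvalue of the 2x2 structure tensor
# The structure tensor uses inner (gradient) scale sigma/2 and outer
# (integration) scale sigma. Boundaries are handled by half-sample
# reflection, so every pixel, including ROI edges, has a feature value.
# All filters are derivative-based: a constant image has identically zero
# response in every plane.

# 1-D sampled Gaussian (order 0, 1, 2). Order-0 kernels sum to exactly 1,
# order-1 kernels are odd (zero response to constants), order-2 kernels
# have their mean removed so the constant response is exactly zero.
#' @noRd
gaussKernel1d <- function(sigma, order = 0L, truncate = 3) {
  r <- max(1L, ceiling(truncate * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- switch(as.character(order),
    "0" = g,
    "1" = -x / sigma^2 * g,
    "2" = (x^2 / sigma^4 - 1 / sigma^2) * g,
    stop("order must be 0, 1 or 2"))
  if (order == 2L) k <- k - mean(k)
  k
}

# Smallest 2,3,5-smooth integer >= n: FFT sizes with large prime factors
# are pathologically slow in R's mixed-radix transform.
#' @noRd
goodFFTSize <- function(n) {
  while (TRUE) {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# Separable 2-D convolution with reflect boundary. kRow acts along rows
# (first index), kCol along columns. Uses FFT convolution on a
# reflect-padded copy (padded up to an FFT-friendly size); the circular
# wrap-around of the FFT stays inside the padding and is cropped away.
#' @noRd
convSep <- function(img, kRow, kCol) {
  H <- nrow(img); W <- ncol(img)
  pr <- (length(kRow) - 1L) %/% 2L
  pc <- (length(kCol) - 1L) %/% 2L
  er <- goodFFTSize(H + 2L * pr) - H - pr   # high-side padding
  ec <- goodFFTSize(W + 2L * pc) - W - pc
  rows <- reflectIndex((1L - pr):(H + er), H)
  cols <- reflectIndex((1L - pc):(W + ec), W)
  padded <- img[rows, cols, drop = FALSE]
  out <- EBImage::filter2(padded, outer(kRow, kCol), boundary = "circular")
  out[(pr + 1L):(pr + H), (pc + 1L):(pc + W), drop = FALSE]
}

# The four filter responses of one channel at one scale, as an H x W x 4
# array in plane order ggm, log, stmin, stmax.
#' @noRd
filterResponses <- function(ch, sigma) {
  g0 <- gaussKernel1d(sigma, 0L)
  g1 <- gaussKernel1d(sigma, 1L)
  g2 <- gaussKernel1d(sigma, 2L)
  gr <- convSep(ch, g1, g0)                 # d/drow
  gc <- convSep(ch, g0, g1)                 # d/dcol
  ggm <- sqrt(gr^2 + gc^2)
  logr <- convSep(ch, g2, g0) + convSep(ch, g0, g2)
  # structure tensor: gradients at inner scale sigma/2, smoothed at sigma
  h0 <- gaussKernel1d(sigma / 2, 0L)
  h1 <- gaussKernel1d(sigma / 2, 1L)
  ir <- convSep(ch, h1, h0)
  ic <- convSep(ch, h0, h1)
  j11 <- convSep(ir * ir, g0, g0)
  j22 <- convSep(ic * ic, g0, g0)
  j12 <- convSep(ir * ic, g0, g0)
  mid <- (j11 + j22) / 2
  disc <- sqrt(((j11 - j22) / 2)^2 + j12^2)
  stmax <- mid + disc
  stmin <- pmax(mid - disc, 0)   # analytically >= 0; clamp rounding noise
  array(c(ggm, logr, stmin, stmax), c(nrow(ch), ncol(ch), 4L))
}

#' Compute the multiscale per-pixel feature stack
#'
#' Decomposes the scene with basic image filters so that every pixel is
#' described by a feature vector: four filter responses per scale per
#' colour channel (60 planes under the default five scales and R, G, B).
#'
#' @param image H x W matrix (grayscale) or H x W x 3 array (RGB) with
#'   finite intensities; integer-coded 8/16-bit data are rescaled to
#'   [0, 1] before filtering. Grayscale input is replicated across the
#'   configured channels.
#' @param cfg a [FeatureConfig-class].
#' @return A [FeatureStack-class] with F = channels x scales x 4 planes,
#'   named deterministically (channel, scale, filter).
#' @examples
#' img <- array(runif(32 * 32 * 3), c(32, 32, 3))
#' st <- computeFeatureStack(img, featureConfig(scales = c(0.8, 1.6)))
#' featureNames(st)[1:4]
#' @export
computeFeatureStack <- function(image, cfg = featureConfig()) {
  if (any(!is.finite(image)))
    stop("image contains non-finite pixel values")
  image <- normalizeIntensity(image)
  if (is.matrix(image)) {
    chans <- setNames(rep(list(image), length(cfg@channels)), cfg@channels)
  } else if (length(dim(image)) == 3L && dim(image)[3] == 3L) {
    chanIdx <- c(R = 1L, G = 2L, B = 3L)
    chans <- lapply(setNames(nm = cfg@channels),
                    function(ch) image[, , chanIdx[[ch]]])
  } else {
    stop(sprintf("unsupported channel count: image must be H x W or H x W x 3"))
  }
  H <- nrow(chans[[1]]); W <- ncol(chans[[1]])
  nF <- length(chans) * length(cfg@scales) * 4L
  vals <- array(0, c(H, W, nF))
  i <- 0L
  for (ch in chans) {
    for (s in cfg@scales) {
      vals[, , i + 1:4] <- filterResponses(ch, s)
      i <- i + 4L
    }
  }
  new("FeatureStack", values = vals, featureNames = featurePlaneNames(cfg))
}

#' Export one named feature plane as 32-bit float TIFF
#'
#' Debug aid for inspecting individual filter responses.
#' @param stack a [FeatureStack-class].
#' @param plane a name from `featureNames(stack)`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFeaturePlaneTiff <- function(stack, plane, path) {
  i <- match(plane, stack@featureNames)
  if (is.na(i))
    stop(sprintf("unknown feature plane '%s'", plane))
  tiff::writeTIFF(stack@values[, , i], path, bits.per.sample = 32L)
  invisible(path)
}
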