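# Seeded synthetic vial-image generator.
#
# Emulates the visual challenges of photographed vial food surfaces: a
# circular food disc under radial illumination, bright ellipsoidal eggs of
# roughly uniform size and variable orientation with partial clustering and
# overlap, two background classes (pale low-texture translucent defined
# medium vs darker yellow-brown opaque medium with multiplicative speckle),
# and photographic artefacts (bubbles in the medium, specular streaks near
# the vial wall, marks on the vial base) plus additive Gaussian sensor
# noise. Every image is fully determined by its seed and carries an exact
# dot ground truth (the rounded ellipse centres).

# Smooth multiplicative texture field with mean ~1.
#' @noRd
speckleField <- function(H, W, smoothSigma, amplitude) {
  raw <- matrix(stats::runif(H * W, -1, 1), H, W)
  g <- gaussKernel1d(smoothSigma, 0L)
  sm <- convSep(raw, g, g)
  sm <- sm / max(stats::sd(sm), 1e-12)
  1 + amplitude * sm
}

# Alpha-composite a shaded ellipse into img (H x W x 3), centre (cr, cc)
# 1-based continuous, semi-axes (a, b), orientation theta, peak colour col
# (length 3), edge softness in pixels, global alpha.
#' @noRd
drawEllipse <- function(img, cr, cc, a, b, theta, col, soft = 1.2,
                        alpha = 1, shading = 0.22) {
  H <- dim(img)[1]; W <- dim(img)[2]
  s <- ceiling(max(a, b) + soft + 1)
  rows <- max(1, floor(cr - s)):min(H, ceiling(cr + s))
  cols <- max(1, floor(cc - s)):min(W, ceiling(cc + s))
  if (!length(rows) || !length(cols)) return(img)
  dr <- outer(rows - cr, rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - cc)
  u <- cos(theta) * dr + sin(theta) * dc
  v <- -sin(theta) * dr + cos(theta) * dc
  rho <- sqrt((u / a)^2 + (v / b)^2)
  # anti-aliased coverage: 1 inside, smooth roll-off of width ~soft/b px
  cov <- pmin(1, pmax(0, (1 + soft / (2 * b) - rho) / (soft / b)))
  if (all(cov == 0)) return(img)
  cov <- cov * alpha
  shade <- 1 - shading * pmin(rho, 1)^2
  for (k in 1:3) {
    patch <- img[rows, cols, k]
    img[rows, cols, k] <- patch * (1 - cov) + col[k] * shade * cov
  }
  img
}

#' Generate one synthetic vial image with exact ground truth
#'
#' @param p a [SceneParams-class].
#' @return list with elements `image` (H x W x 3 array in [0, 1]) and
#'   `annotation` (a [DotAnnotation-class] with one dot per egg, the
#'   rounded ellipse centres). Identical parameters (including seed)
#'   reproduce the image bit-identically.
#' @examples
#' scene <- generateVialImage(sceneParams(imageShape = c(128, 128),
#'                                        nEggs = 12, seed = 7))
#' nDots(scene$annotation)   # 12
#' @export
generateVialImage <- function(p) {
  stopifnot(is(p, "SceneParams"))
  withSeed(p@seed, {
    H <- p@imageShape[1]; W <- p@imageShape[2]
    chR <- (H + 1) / 2; chC <- (W + 1) / 2
    R <- 0.45 * min(H, W)

    meanEggArea <- pi * mean(p@majorRange) / 2 * mean(p@minorRange) / 2
    if (p@nEggs * meanEggArea > 0.5 * pi * R^2)
      stop(sprintf(
        "cannot place %d eggs: they would cover more than half the dish",
        p@nEggs))

    dist <- sqrt(outer((seq_len(H) - chR)^2, (seq_len(W) - chC)^2, "+"))
    disc <- dist <= R
    radial <- 1 - 0.30 * pmin(dist / R, 1)^2

    # translucent defined medium photographs as a darker, smooth surface
    # (bright eggs stand out); opaque sugar/yeast food is pale, textured
    # and close to egg brightness, which is what makes it the harder class
    img <- array(0.10, c(H, W, 3))
    if (p@medium == "translucent") {
      base <- c(0.52, 0.54, 0.55)
      tex <- speckleField(H, W, 2.0, 0.01)
    } else {
      base <- c(0.80, 0.70, 0.46)
      tex <- speckleField(H, W, 1.0, 0.18)
    }
    for (k in 1:3) {
      plane <- img[, , k]
      plane[disc] <- (base[k] * radial * tex)[disc]
      img[, , k] <- plane
    }

    # egg placement: free eggs by rejection inside 0.92 R, clustered eggs
    # seeded within one egg-length of an already-placed egg
    nClust <- if (p@nEggs > 1) round(p@clusterFraction * p@nEggs) else 0L
    centres <- matrix(0, 0, 2)
    placeFree <- function() {
      repeat {
        cand <- c(stats::runif(1, chR - R, chR + R),
                  stats::runif(1, chC - R, chC + R))
        if (sqrt((cand[1] - chR)^2 + (cand[2] - chC)^2) <= 0.92 * R)
          return(cand)
      }
    }
    eggLen <- max(p@majorRange)
    for (i in seq_len(p@nEggs)) {
      if (i > p@nEggs - nClust && nrow(centres) > 0) {
        for (attempt in 1:100) {
          anchor <- centres[sample.int(nrow(centres), 1), ]
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- stats::runif(1, 0.25 * eggLen, eggLen)
          cand <- anchor + rad * c(cos(ang), sin(ang))
          if (sqrt((cand[1] - chR)^2 + (cand[2] - chC)^2) <= 0.92 * R)
            break
          if (attempt == 100) cand <- placeFree()
        }
      } else {
        cand <- placeFree()
      }
      centres <- rbind(centres, cand)
    }

    # render eggs: bright, slightly warm-white shaded ellipses
    for (i in seq_len(p@nEggs)) {
      a <- stats::runif(1, p@majorRange[1], p@majorRange[2]) / 2
      b <- stats::runif(1, p@minorRange[1], p@minorRange[2]) / 2
      theta <- stats::runif(1, 0, pi)
      inten <- stats::runif(1, 0.82, 0.98)
      img <- drawEllipse(img, centres[i, 1], centres[i, 2], a, b, theta,
                         col = c(inten, inten, 0.93 * inten))
    }

    # artefacts ------------------------------------------------------
    for (i in seq_len(p@nBubbles)) {
      br <- stats::runif(1, 4, 10)
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0, 0.8 * R)
      cb <- c(chR + rad * cos(ang), chC + rad * sin(ang))
      # dark rim
      img <- drawEllipse(img, cb[1], cb[2], br, br, 0,
                         col = c(0.25, 0.22, 0.18), soft = 1.5,
                         alpha = 0.45, shading = -0.6)
      # interior sheen + specular glint
      img <- drawEllipse(img, cb[1], cb[2], 0.7 * br, 0.7 * br, 0,
                         col = base * 1.1, soft = 1.5, alpha = 0.8,
                         shading = 0.1)
      img <- drawEllipse(img, cb[1] - 0.4 * br, cb[2] - 0.4 * br,
                         0.18 * br, 0.18 * br, 0,
                         col = c(0.98, 0.98, 0.96), soft = 1, alpha = 0.9,
                         shading = 0)
    }
    for (i in seq_len(p@nStreaks)) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0.78, 0.95) * R
      cs <- c(chR + rad * cos(ang), chC + rad * sin(ang))
      img <- drawEllipse(img, cs[1], cs[2],
                         stats::runif(1, 15, 40), stats::runif(1, 1.2, 2.2),
                         ang + pi / 2 + stats::runif(1, -0.15, 0.15),
                         col = c(0.96, 0.96, 0.95), soft = 2.5,
                         alpha = 0.5, shading = 0.05)
    }
    for (i in seq_len(p@nBaseMarks)) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0.88, 0.99) * R
      cm <- c(chR + rad * cos(ang), chC + rad * sin(ang))
      img <- drawEllipse(img, cm[1], cm[2],
                         stats::runif(1, 6, 18), stats::runif(1, 1, 2),
                         ang + pi / 2,
                         col = c(0.18, 0.16, 0.14), soft = 2, alpha = 0.55,
                         shading = 0)
    }

    if (p@noiseSigma > 0)
      img <- img + array(stats::rnorm(length(img), 0, p@noiseSigma),
                         dim(img))
    img <- pmin(pmax(img, 0), 1)

    d <- if (p@nEggs > 0)
      cbind(row = pmin(pmax(round(centres[, 1]) - 1L, 0L), H - 1L),
            col = pmin(pmax(round(centres[, 2]) - 1L, 0L), W - 1L))
    else NULL
    list(image = img,
         annotation = DotAnnotation(paste0("synthetic_seed", p@seed), d,
                                    c(H, W)))
  })
}

#' Generate a seeded multi-vial dataset
#'
#' Egg counts are spread across `countRange` (default 15-410, a broad span
#' of vial densities) with seeded jitter; each image gets its own seed
#' derived from the master seed, so any image can be regenerated from the
#' manifest alone.
#'
#' @param nImages number of vials (default 8).
#' @param countRange numeric (min, max) egg counts.
#' @param params a [SceneParams-class] template (its `nEggs` and `seed`
#'   are overridden per image).
#' @param masterSeed master seed for the dataset.
#' @param dir optional output directory; when given, writes
#'   `vial_XX.png`, `vial_XX_dots.csv` and `manifest.csv`.
#' @return list with `images` (named list of arrays), `annotations`
#'   (named list of [DotAnnotation-class]) and `manifest` (data.frame:
#'   image, count, seed, medium).
#' @export
generateDataset <- function(nImages = 8L, countRange = c(15, 410),
                            params = sceneParams(), masterSeed = 1L,
                            dir = NULL) {
  nImages <- as.integer(nImages)
  counts <- withSeed(deriveSeed(masterSeed, "counts"), {
    base <- seq(countRange[1], countRange[2], length.out = nImages)
    jit <- stats::runif(nImages, -0.04, 0.04) * diff(range(countRange))
    pmax(1L, as.integer(round(pmin(pmax(base + jit, countRange[1]),
                                   countRange[2]))))
  })
  ids <- sprintf("vial_%02d", seq_len(nImages))
  seeds <- vapply(seq_len(nImages),
                  function(i) deriveSeed(masterSeed, "image", i), integer(1))
  images <- list(); annotations <- list()
  for (i in seq_len(nImages)) {
    pi_ <- params
    pi_@nEggs <- counts[i]
    pi_@seed <- seeds[i]
    scene <- generateVialImage(pi_)
    scene$annotation@imageId <- ids[i]
    images[[ids[i]]] <- scene$image
    annotations[[ids[i]]] <- scene$annotation
  }
  manifest <- data.frame(image = ids, count = counts, seed = seeds,
                         medium = params@medium, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (id in ids) {
      writeImagePNG(images[[id]], file.path(dir, paste0(id, ".png")))
      writeDotsCsv(annotations[[id]],
                   file.path(dir, paste0(id, "_dots.csv")))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(images = images, annotations = annotations, manifest = manifest)
}
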