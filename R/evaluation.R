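# Accuracy metric, leave-one-out cross-validation, batch evaluation.

#' Percent accuracy of predicted counts
#'
#' 100 minus the mean absolute relative count error in percent:
#' `100 - (1/n) * sum(|PC_i - GT_i| / GT_i) * 100`. Perfect predictions
#' score 100; the value can go negative when the mean relative error
#' exceeds 100%. Invariant to pair order and to duplicating the pair list.
#'
#' @param predicted numeric predicted counts (raw or corrected).
#' @param groundTruth positive ground-truth counts.
#' @param imageIds optional labels used in error messages.
#' @return percent accuracy (scalar). The mean relative error itself is
#'   available as `100 - accuracyPercent(...)`.
#' @examples
#' accuracyPercent(90, 100)                     # 90
#' accuracyPercent(c(110, 50), c(100, 100))     # 70
#' @export
accuracyPercent <- function(predicted, groundTruth, imageIds = NULL) {
  n <- length(predicted)
  if (n < 1L || n != length(groundTruth))
    stop("'predicted' and 'groundTruth' must be non-empty and equal length")
  if (any(groundTruth <= 0)) {
    i <- which(groundTruth <= 0)[1]
    lab <- if (!is.null(imageIds)) imageIds[i] else as.character(i)
    stop(sprintf(
      "ground-truth count for image '%s' is %s; the metric divides by GT",
      lab, groundTruth[i]))
  }
  100 - mean(abs(predicted - groundTruth) / groundTruth) * 100
}

#' Leave-one-out cross-validation of the counting pipeline
#'
#' The hold-one-out protocol: each image is predicted by a model trained on
#' (a subset of) the remaining images, using whole images as training
#' regions. When bias correction is enabled and at least 3 training regions
#' are available, the correction line is refitted inside each fold from the
#' trained model's predictions on its own training images (no information
#' from the held-out image leaks into the fold). The whole procedure is
#' repeated for `nReplicates` statistical replicates with derived seeds and
#' summarized as mean +/- SE over replicates.
#'
#' @param images named list of H x W x 3 arrays.
#' @param annotations named list of [DotAnnotation-class] (same names);
#'   every image must be annotated.
#' @param cfg a [LoocvConfig-class].
#' @param countFun optional testing hook: a `function(imageId)` returning a
#'   count, used in place of training and prediction (e.g. a perfect
#'   predictor to validate the protocol's bookkeeping).
#' @return list with elements
#'   `perImage` (data.frame: replicate, image, gt, pcRaw, cc, ciLo, ciHi,
#'   beta, offset), `perReplicate` (data.frame: replicate, accuracyRaw,
#'   accuracyCorrected, meanRelErrRaw, meanRelErrCorrected) and `summary`
#'   (named list of means and standard errors over replicates,
#'   SE = sd / sqrt(nReplicates)).
#' @export
runLoocv <- function(images, annotations, cfg = loocvConfig(),
                     countFun = NULL) {
  ids <- names(images)
  if (length(ids) < 2L) stop("LOOCV needs at least 2 images")
  missing <- setdiff(ids, names(annotations))
  if (length(missing))
    stop("unannotated image(s): ", paste(missing, collapse = ", "))
  fNames <- featurePlaneNames(cfg@featureConfig)

  # Per-image caches shared across folds and replicates: flattened feature
  # matrix, density target vector and ground-truth count.
  cache <- lapply(ids, function(id) {
    img <- images[[id]]
    H <- dim(img)[1]; W <- dim(img)[2]
    if (is.null(countFun)) {
      st <- computeFeatureStack(img, cfg@featureConfig)
      X <- matrix(st@values, H * W, length(fNames))
      colnames(X) <- fNames
      y <- as.vector(makeDensityMap(annotations[[id]], c(H, W),
                                    cfg@densityConfig)@values)
    } else {
      X <- NULL; y <- NULL
    }
    list(X = X, y = y, gt = nDots(annotations[[id]]), H = H, W = W)
  })
  names(cache) <- ids

  perImage <- list()
  for (rep in seq_len(cfg@nReplicates)) {
    for (i in seq_along(ids)) {
      testId <- ids[i]
      trainIds <- setdiff(ids, testId)
      if (cfg@nTrainingImages > 0L &&
          cfg@nTrainingImages < length(trainIds)) {
        trainIds <- withSeed(
          deriveSeed(cfg@masterSeed, "subset", rep, testId),
          sample(trainIds, cfg@nTrainingImages))
      }
      acTrain <- vapply(trainIds, function(id) cache[[id]]$gt, numeric(1))
      if (!is.null(countFun)) {
        pcTest <- countFun(testId)
        pcTrain <- vapply(trainIds, countFun, numeric(1))
        model <- NULL
      } else {
        sizes <- vapply(trainIds, function(id) nrow(cache[[id]]$X),
                        numeric(1))
        total <- sum(sizes)
        take <- if (cfg@maxTrainingPixels > 0L &&
                    cfg@maxTrainingPixels < total)
          sort(withSeed(deriveSeed(cfg@masterSeed, "pixels", rep, testId),
                        sample.int(total, cfg@maxTrainingPixels)))
        else seq_len(total)
        offsets <- c(0, cumsum(sizes))
        X <- matrix(0, length(take), length(fNames),
                    dimnames = list(NULL, fNames))
        y <- numeric(length(take))
        for (j in seq_along(trainIds)) {
          sel <- take[take > offsets[j] & take <= offsets[j + 1]]
          if (!length(sel)) next
          local <- sel - offsets[j]
          pos <- which(take > offsets[j] & take <= offsets[j + 1])
          X[pos, ] <- cache[[trainIds[j]]]$X[local, , drop = FALSE]
          y[pos] <- cache[[trainIds[j]]]$y[local]
        }
        ts <- new("TrainingSet", X = X, y = y,
                  provenance = data.frame(imageId = trainIds,
                                          nPixels = NA_integer_),
                  featureNames = fNames)
        model <- fitModel(ts, nTrees = cfg@nTrees,
                          seed = deriveSeed(cfg@masterSeed, "fit", rep,
                                            testId),
                          minNodeSize = cfg@minNodeSize,
                          featureCfg = cfg@featureConfig,
                          densityCfg = cfg@densityConfig)
        pcTest <- sum(predictRows(model, cache[[testId]]$X))
        pcTrain <- if (cfg@biasCorrection && length(trainIds) >= 3L)
          vapply(trainIds,
                 function(id) sum(predictRows(model, cache[[id]]$X)),
                 numeric(1))
        else NULL
      }
      cc <- ciLo <- ciHi <- beta <- offset <- NA_real_
      if (cfg@biasCorrection && length(trainIds) >= 3L &&
          !is.null(pcTrain) && length(unique(pcTrain)) >= 2L) {
        b <- fitBias(pcTrain, acTrain, regionIds = trainIds)
        ci <- suppressWarnings(correctedCountInterval(b, pcTest))
        cc <- ci$cc; ciLo <- ci$lo; ciHi <- ci$hi
        beta <- b@beta; offset <- b@offset
      }
      perImage[[length(perImage) + 1L]] <- data.frame(
        replicate = rep, image = testId, gt = cache[[testId]]$gt,
        pcRaw = pcTest, cc = cc, ciLo = ciLo, ciHi = ciHi,
        beta = beta, offset = offset, stringsAsFactors = FALSE)
    }
  }
  perImage <- do.call(rbind, perImage)

  perReplicate <- do.call(rbind, lapply(seq_len(cfg@nReplicates),
    function(rep) {
      rows <- perImage[perImage$replicate == rep, ]
      accRaw <- accuracyPercent(rows$pcRaw, rows$gt, rows$image)
      accCor <- if (all(is.finite(rows$cc)))
        accuracyPercent(rows$cc, rows$gt, rows$image) else NA_real_
      data.frame(replicate = rep, accuracyRaw = accRaw,
                 accuracyCorrected = accCor,
                 meanRelErrRaw = 100 - accRaw,
                 meanRelErrCorrected = 100 - accCor)
    }))

  se <- function(x) stats::sd(x) / sqrt(length(x))
  summary <- list(
    nImages = length(ids),
    nReplicates = cfg@nReplicates,
    meanAccuracyRaw = mean(perReplicate$accuracyRaw),
    seAccuracyRaw = se(perReplicate$accuracyRaw),
    meanAccuracyCorrected = mean(perReplicate$accuracyCorrected),
    seAccuracyCorrected = se(perReplicate$accuracyCorrected),
    biasCorrection = cfg@biasCorrection,
    masterSeed = cfg@masterSeed)
  list(perImage = perImage, perReplicate = perReplicate, summary = summary)
}

#' Write a LOOCV report to disk
#'
#' Writes the per-image per-replicate rows as CSV plus a JSON summary.
#'
#' @param report result of [runLoocv()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeLoocvReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$perImage, file.path(dir, "loocv_per_image.csv"),
                   row.names = FALSE)
  utils::write.csv(report$perReplicate,
                   file.path(dir, "loocv_per_replicate.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$summary, file.path(dir, "loocv_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Batch-evaluate a directory or list of images
#'
#' One row per image, in input order: raw count, corrected count and 95%
#' prediction interval (when the model carries a bias correction), plus a
#' status column. A failing image is recorded in its row and does not
#' abort the batch.
#'
#' @param model an [EggModel-class] (optionally with a bias model).
#' @param imagePaths character vector of image files.
#' @param outCsv optional CSV output path (header:
#'   `image,raw_count,corrected_count,ci_low,ci_high,status`).
#' @return data.frame with the same columns.
#' @export
batchEvaluate <- function(model, imagePaths, outCsv = NULL) {
  stopifnot(is(model, "EggModel"))
  rows <- lapply(imagePaths, function(p) {
    res <- tryCatch({
      pc <- predictCount(model, p)
      if (!is.null(model@bias)) {
        ci <- suppressWarnings(correctedCountInterval(model@bias, pc))
        data.frame(image = basename(p), raw_count = pc,
                   corrected_count = ci$cc, ci_low = ci$lo, ci_high = ci$hi,
                   status = "ok", stringsAsFactors = FALSE)
      } else {
        data.frame(image = basename(p), raw_count = pc,
                   corrected_count = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, status = "ok",
                   stringsAsFactors = FALSE)
      }
    }, error = function(e) {
      data.frame(image = basename(p), raw_count = NA_real_,
                 corrected_count = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_,
                 status = paste0("error: ", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  if (!is.null(outCsv))
    utils::write.csv(out, outCsv, row.names = FALSE)
  out
}
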