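# Reading and writing dot annotations and ROIs.
#
# Two annotation dialects are supported: binary mask images (the point-tool
# export convention: every nonzero pixel marks one egg centre) and CSV
# coordinate lists with a `row,col` header (0-based). Masks cannot express
# two eggs on the same pixel; the CSV dialect can.

#' Read a dot annotation from a binary mask
#'
#' Every strictly positive pixel of the mask is one egg centre. Masks are
#' scanned in row-major order so the resulting dot order is deterministic;
#' no downstream computation depends on the order.
#'
#' @param mask single-channel matrix, or path to a single-channel PNG/TIFF
#'   (8- or 16-bit; any nonzero value, e.g. 255, marks a dot).
#' @param imageId identifier for the annotated image; defaults to the file
#'   basename (without extension) or "mask".
#' @return A [DotAnnotation-class].
#' @examples
#' m <- matrix(0L, 5, 5); m[3, 4] <- 1L; m[5, 1] <- 255L
#' dots(readDotMask(m))   # (2,3) and (4,0), 0-based
#' @export
readDotMask <- function(mask, imageId = NULL) {
  if (is.character(mask)) {
    if (is.null(imageId))
      imageId <- tools::file_path_sans_ext(basename(mask))
    mask <- readImageGray(mask)
  }
  if (is.null(imageId)) imageId <- "mask"
  if (length(dim(mask)) == 3L && dim(mask)[3] == 1L)
    mask <- mask[, , 1]
  if (!is.matrix(mask))
    stop("mask must be a 2-D single-channel image")
  nz <- which(mask > 0)
  if (length(nz) == 0)
    return(DotAnnotation(imageId, NULL, dim(mask)))
  r <- (nz - 1L) %% nrow(mask)          # 0-based row
  c <- (nz - 1L) %/% nrow(mask)         # 0-based col
  ord <- order(r, c)                    # row-major scan order
  DotAnnotation(imageId, cbind(row = r[ord], col = c[ord]), dim(mask))
}

#' Rasterize a dot annotation into a binary mask
#'
#' Inverse of [readDotMask()] for annotations with at most one dot per
#' pixel (the mask dialect cannot express duplicates).
#'
#' @param ann a [DotAnnotation-class].
#' @return integer matrix with 1 at every dot, 0 elsewhere.
#' @export
rasterizeDots <- function(ann) {
  m <- matrix(0L, ann@imageDim[1], ann@imageDim[2])
  if (nrow(ann@dots) > 0)
    m[cbind(ann@dots[, 1] + 1L, ann@dots[, 2] + 1L)] <- 1L
  m
}

#' Read a dot annotation from CSV
#'
#' Expects a header line `row,col` and one 0-based integer coordinate pair
#' per line. Dots keep file order. A header-only file yields an empty
#' annotation.
#'
#' @param path CSV file path.
#' @param imageDim integer (height, width) of the associated image; when
#'   omitted, bounds are taken as just enclosing the dots.
#' @param imageId image identifier; defaults to the file basename with a
#'   trailing `_dots` stripped.
#' @return A [DotAnnotation-class].
#' @export
readDotsCsv <- function(path, imageDim = NULL, imageId = NULL) {
  if (is.null(imageId))
    imageId <- sub("_dots$", "", tools::file_path_sans_ext(basename(path)))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0 || tolower(trimws(lines[1])) != "row,col")
    stop(sprintf("'%s': expected header 'row,col' on line 1", path))
  body <- lines[-1]
  parse1 <- function(i) {
    parts <- strsplit(trimws(body[i]), ",", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 2 || any(is.na(vals)) || any(vals != floor(vals)))
      stop(sprintf("'%s': malformed row on line %d: '%s'",
                   path, i + 1L, body[i]))
    as.integer(vals)
  }
  dts <- if (length(body)) t(vapply(seq_along(body), parse1, integer(2)))
         else matrix(integer(0), 0, 2)
  if (is.null(imageDim)) {
    imageDim <- if (nrow(dts)) c(max(dts[, 1]) + 1L, max(dts[, 2]) + 1L)
                else c(1L, 1L)
  }
  DotAnnotation(imageId, dts, imageDim)
}

#' Write a dot annotation to CSV
#'
#' Writes `row,col` (0-based) with LF line endings; [readDotsCsv()] of the
#' result reproduces the annotation exactly.
#'
#' @param ann a [DotAnnotation-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDotsCsv <- function(ann, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("row,col",
               if (nrow(ann@dots))
                 paste(ann@dots[, 1], ann@dots[, 2], sep = ",")),
             con, sep = "\n")
  invisible(path)
}

#' Restrict an annotation to an ROI
#'
#' Keeps the dots with row in [r0, r0+h) and col in [c0, c0+w) (half-open,
#' 0-based); the count of the result is the actual count AC of that region.
#'
#' @param ann a [DotAnnotation-class].
#' @param roi an [ROI-class], fully contained in the annotated image.
#' @return A [DotAnnotation-class] with the selected dots (original order).
#' @export
dotsInRoi <- function(ann, roi) {
  stopifnot(is(ann, "DotAnnotation"), is(roi, "ROI"))
  if (roi@origin[1] + roi@height > ann@imageDim[1] ||
      roi@origin[2] + roi@width > ann@imageDim[2])
    stop("ROI extends beyond the annotated image")
  d <- ann@dots
  keep <- d[, 1] >= roi@origin[1] & d[, 1] < roi@origin[1] + roi@height &
          d[, 2] >= roi@origin[2] & d[, 2] < roi@origin[2] + roi@width
  DotAnnotation(ann@imageId, d[keep, , drop = FALSE], ann@imageDim)
}

#' Locate the companion annotation file of an image
#'
#' Annotation files share the image's basename with a suffix, default
#' `<name>_dots.csv` or `<name>_dots.png`.
#'
#' @param imagePath path of the image.
#' @param dir directory holding annotations (default: the image's).
#' @param suffix basename suffix (default "_dots").
#' @return the first existing candidate path, or NA.
#' @export
findAnnotationFile <- function(imagePath, dir = dirname(imagePath),
                               suffix = "_dots") {
  base <- tools::file_path_sans_ext(basename(imagePath))
  cand <- file.path(dir, paste0(base, suffix, c(".csv", ".png", ".tif",
                                                ".tiff")))
  hit <- cand[file.exists(cand)]
  if (length(hit)) hit[1] else NA_character_
}
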