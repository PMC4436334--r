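# Linear bias correction of raw density counts.
#
# Raw summed-density counts systematically over-estimate sparse regions and
# under-estimate dense ones (regression toward the training mean). The
# correction is the affine map CC = beta * PC + c, with beta and c chosen
# by least squares over the training regions' (predicted, actual) count
# pairs:
#     (beta, c) = argmin sum_ij (beta * PC_ij + c - AC_ij)^2
# Implemented in closed form via the normal equations. Corrected counts
# carry an OLS prediction interval (new-observation interval, t
# distribution with n - 2 degrees of freedom): the feedback concerns a
# single new vial's count, not the mean of the line.

#' Fit the count-correction line
#'
#' @param pc numeric vector of predicted region counts PC_ij, or a
#'   data.frame with columns `pc` and `ac`.
#' @param ac integer vector of actual labelled counts AC_ij (ignored when
#'   `pc` is a data.frame).
#' @param regionIds optional labels for the regions (stored with the
#'   pairs).
#' @return A [BiasModel-class].
#' @examples
#' fitBias(c(1, 2, 3), c(3, 5, 7))   # beta = 2, c = 1
#' @export
fitBias <- function(pc, ac = NULL, regionIds = NULL) {
  if (is.data.frame(pc)) {
    ac <- pc$ac
    if (is.null(regionIds)) regionIds <- pc$regionId
    pc <- pc$pc
  }
  n <- length(pc)
  if (n != length(ac)) stop("'pc' and 'ac' must have the same length")
  if (n < 3L)
    stop("bias correction needs at least 3 labelled regions (got ", n,
         "); label more ROIs before fitting")
  if (any(!is.finite(pc)) || any(!is.finite(ac)))
    stop("'pc' and 'ac' must be finite")
  if (any(ac < 0)) stop("actual counts must be non-negative")
  sxx <- sum((pc - mean(pc))^2)
  if (sxx == 0)
    stop("all predicted counts are identical; the correction slope is ",
         "undefined")
  beta <- sum((pc - mean(pc)) * (ac - mean(ac))) / sxx
  offset <- mean(ac) - beta * mean(pc)
  resid <- ac - (beta * pc + offset)
  df <- n - 2L
  s2 <- sum(resid^2) / df
  pairs <- data.frame(pc = pc, ac = ac,
                      regionId = if (is.null(regionIds))
                        as.character(seq_len(n)) else as.character(regionIds),
                      stringsAsFactors = FALSE)
  new("BiasModel", beta = beta, offset = offset, pairs = pairs,
      n = as.integer(n), meanPc = mean(pc), sxx = sxx, s2 = s2,
      df = as.integer(df))
}

#' Apply the bias correction to a raw count
#'
#' Returns CC = beta * PC + c. Pathological extrapolation can produce a
#' negative corrected count; it is reported as-is with a warning, never
#' silently clamped.
#'
#' @param b a [BiasModel-class].
#' @param pc finite numeric raw count(s).
#' @return corrected count(s) CC.
#' @export
applyBias <- function(b, pc) {
  stopifnot(is(b, "BiasModel"))
  if (any(!is.finite(pc))) stop("'pc' must be finite")
  cc <- b@beta * pc + b@offset
  if (any(cc < 0))
    warning("bias correction produced a negative corrected count ",
            "(extrapolation far outside the training range)")
  cc
}

#' 95% prediction interval for a corrected count
#'
#' Standard OLS new-observation interval at `pc`: CC +/- t_{df, (1+level)/2}
#' * sqrt(s2 * (1 + 1/n + (pc - mean(pc))^2 / Sxx)). The interval widens as
#' `pc` moves away from the mean of the training predictions. With exactly
#' collinear pairs the residual variance is zero and a degenerate
#' zero-width interval is returned, flagged by the `degenerate` attribute.
#'
#' @param b a [BiasModel-class].
#' @param pc finite numeric raw count(s).
#' @param level coverage level (default 0.95).
#' @return data.frame with columns `cc`, `lo`, `hi` (attribute
#'   `degenerate` = TRUE when the fit had zero residual variance).
#' @export
correctedCountInterval <- function(b, pc, level = 0.95) {
  stopifnot(is(b, "BiasModel"))
  if (any(!is.finite(pc))) stop("'pc' must be finite")
  cc <- b@beta * pc + b@offset
  sePred <- sqrt(b@s2 * (1 + 1 / b@n + (pc - b@meanPc)^2 / b@sxx))
  tq <- stats::qt((1 + level) / 2, df = b@df)
  out <- data.frame(cc = cc, lo = cc - tq * sePred, hi = cc + tq * sePred)
  degenerate <- b@s2 == 0
  if (degenerate)
    warning("zero residual variance (collinear training pairs): ",
            "prediction interval is degenerate (zero width)")
  attr(out, "degenerate") <- degenerate
  out
}

#' Export bias parameters as JSON
#'
#' @param b a [BiasModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBiasJson <- function(b, path) {
  stopifnot(is(b, "BiasModel"))
  jsonlite::write_json(list(beta = b@beta, c = b@offset, n_pairs = b@n),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
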