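# Internal helpers: seeded evaluation, seed derivation, intensity scaling.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `expr`, and restores the caller's RNG state,
#' so library internals never perturb user-level random streams.
#' @noRd
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a child seed from a master seed and a stream label
#'
#' Deterministic 31-bit hash so every component (per-image substreams,
#' per-tree seeds, subsampling) draws from its own named stream of one
#' master seed. Exact in double precision (values stay < 2^53).
#' @noRd
deriveSeed <- function(master, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  p <- 2147483629  # prime < 2^31
  h <- as.numeric(master) %% p
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% p
  as.integer(h %% (p - 1) + 1)
}

#' Scale integer-coded images onto [0, 1]
#'
#' 8-bit data are divided by 255, 16-bit by 65535; float data already in
#' [0, 1] pass through unchanged.
#' @noRd
normalizeIntensity <- function(x) {
  mx <- max(x)
  if (mx <= 1) return(x)
  if (mx <= 255) return(x / 255)
  if (mx <= 65535) return(x / 65535)
  stop("image intensities exceed 16-bit range; supply data scaled to [0, 1]")
}

#' Rotate a matrix 90 degrees counter-clockwise
#' @noRd
rot90ccw <- function(m) {
  t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
}

#' Reflect (half-sample symmetric) index mapping onto 1..n
#' @noRd
reflectIndex <- function(i, n) {
  m <- (i - 1) %% (2 * n)
  ifelse(m < n, m + 1, 2 * n - m)
}

#' Short content hash used to guard model archives
#' @noRd
contentDigest <- function(x) {
  s <- paste(deparse(x), collapse = "")
  p <- 2147483629
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% p
  sprintf("%08x", as.integer(h))
}

#' Timestamped log line
#' @noRd
logMsg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}
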