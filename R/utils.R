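## Internal helpers: geometry, RNG, filtering.

normalizeVec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero vector cannot be normalized")
  v / n
}

#' Quasi-uniform points on the unit sphere (Fibonacci lattice)
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacciSphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  m <- cbind(r * cos(phi), r * sin(phi), z)
  dimnames(m) <- NULL
  m
}

## Spherical linear interpolation between unit vectors.
slerp <- function(a, b, t) {
  a <- normalizeVec(a); b <- normalizeVec(b)
  w <- acos(max(-1, min(1, sum(a * b))))
  if (w < 1e-12) return(matrix(rep(a, length(t)), ncol = 3, byrow = TRUE))
  s <- sin(w)
  out <- outer(sin((1 - t) * w) / s, a) + outer(sin(t * w) / s, b)
  out
}

## Evaluate with a local, restorable RNG seeded deterministically.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

#' Zero-phase Butterworth high-pass filter
#'
#' 4th-order Butterworth applied forward-backward (zero phase).
#'
#' @param x numeric signal.
#' @param cutoffHz corner frequency, Hz.
#' @param rate sampling rate, Hz.
#' @param order filter order.
#' @return filtered signal.
#' @export
highpassFilter <- function(x, cutoffHz, rate, order = 4L) {
  wn <- cutoffHz / (rate / 2)
  if (wn <= 0 || wn >= 1) stop("high-pass cutoff must lie below the Nyquist frequency")
  bf <- signal::butter(order, wn, type = "high")
  signal::filtfilt(bf, x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' @inheritParams highpassFilter
#' @param lowHz,highHz band corners, Hz (the upper corner is clipped just
#'   below Nyquist).
#' @return filtered signal.
#' @export
bandpassFilter <- function(x, lowHz, highHz, rate, order = 4L) {
  ny <- rate / 2
  wn <- c(lowHz, min(highHz, 0.999 * ny)) / ny
  if (wn[1] <= 0 || wn[1] >= wn[2]) stop("invalid band limits")
  bf <- signal::butter(order, wn, type = "pass")
  signal::filtfilt(bf, x)
}

#' Amplitude statistic of a sample window
#'
#' The 10th-to-90th percentile difference (linear interpolation between order
#' statistics) or peak-to-peak range.
#'
#' @param x numeric samples.
#' @param statistic "p90_minus_p10" or "peak_to_peak".
#' @return nonnegative amplitude.
#' @export
amplitudeStat <- function(x, statistic = c("p90_minus_p10", "peak_to_peak")) {
  statistic <- match.arg(statistic)
  if (statistic == "p90_minus_p10") {
    q <- quantile(x, c(0.1, 0.9), names = FALSE, type = 7)
    q[2] - q[1]
  } else {
    max(x) - min(x)
  }
}

## Voxel-center coordinate vectors of a LabeledVolume along each axis.
voxelAxes <- function(volume) {
  d <- dim(volume@labels)
  lapply(1:3, function(a) volume@origin[a] + (seq_len(d[a]) - 1) * volume@spacing)
}

stopifnotScalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("%s must be a finite numeric scalar", name))
}
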