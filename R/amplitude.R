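#' Amplitude-statistic parameters
#'
#' Defaults follow the study's chewing-related (ChR) amplitude definition:
#' 100-Hz high-passed data, difference between the 10th and 90th percentile in
#' a 100-ms window around the event center. Variants: 55-Hz high-pass,
#' peak-to-peak statistic, window lengths 50-300 ms.
#'
#' @param highPass high-pass cutoff, Hz (default 100; variant 55).
#' @param window_ms window length, ms (default 100; variants 50-300).
#' @param statistic "p90_minus_p10" or "peak_to_peak".
#' @return Parameter list for [chrAmplitude()].
#' @export
amplitudeParams <- function(highPass = 100, window_ms = 100,
                            statistic = c("p90_minus_p10", "peak_to_peak")) {
  stopifnot(highPass > 0, window_ms > 0)
  list(highPass = highPass, window_ms = window_ms,
       statistic = match.arg(statistic))
}

#' Chewing-related amplitude per trial and channel
#'
#' High-pass filters every channel (zero-phase 4th-order Butterworth), then for
#' each chewing event computes the amplitude statistic in a window around the
#' event center. The statistic is nonnegative, invariant to DC offsets, and
#' the percentile difference never exceeds peak-to-peak on the same samples.
#'
#' @param recording a [Recording-class].
#' @param trials a [TrialSet-class].
#' @param params see [amplitudeParams()].
#' @param channels optional channel-label subset.
#' @return list: \code{amplitudes} (matrix trial x channel, uV),
#'   \code{perTrialMedian}, \code{perTrialMax} (channel reductions per trial),
#'   \code{perChannelMedian} (trial reduction per channel), \code{params}.
#' @export
chrAmplitude <- function(recording, trials, params = amplitudeParams(),
                         channels = NULL) {
  rate <- recording@rate
  if (params$highPass >= rate / 2) stop("high-pass cutoff must be below Nyquist")
  sel <- if (is.null(channels)) seq_along(recording@channels)
         else match(channels, recording@channels)
  if (anyNA(sel)) stop("unknown channel requested")
  x <- recording@samples[, sel, drop = FALSE]
  for (c in seq_len(ncol(x))) x[, c] <- highpassFilter(x[, c], params$highPass, rate)

  nw <- round(params$window_ms / 1000 * rate)
  if (nw < 2) stop("window too short for the sampling rate")
  if (nw > nrow(x)) stop("window longer than the recording")
  ev <- trials@events
  amp <- matrix(NA_real_, nrow(ev), ncol(x),
                dimnames = list(NULL, recording@channels[sel]))
  half <- nw %/% 2
  for (i in seq_len(nrow(ev))) {
    c0 <- round(ev$center[i] * rate) + 1L
    idx <- (c0 - half):(c0 - half + nw - 1L)
    if (idx[1] < 1L || idx[length(idx)] > nrow(x))
      stop("amplitude window extends beyond the recording")
    for (c in seq_len(ncol(x)))
      amp[i, c] <- amplitudeStat(x[idx, c], params$statistic)
  }
  list(amplitudes = amp,
       perTrialMedian = apply(amp, 1, median),
       perTrialMax = apply(amp, 1, max),
       perChannelMedian = apply(amp, 2, median),
       params = params)
}

#' Summarize paired scalp/intracranial median amplitudes
#'
#' Given per-patient median chewing amplitudes on the scalp (EEG) and
#' intracranially (ECoG), computes the arithmetic means and the per-patient
#' EEG-to-ECoG attenuation factors (scalp / intracranial).
#'
#' @param scalpMedians per-patient scalp median amplitudes, uV.
#' @param intracranialMedians per-patient intracranial median amplitudes, uV.
#' @return list: \code{meanScalp}, \code{meanIntracranial} (uV),
#'   \code{attenuation} per patient, \code{meanAttenuation}.
#' @export
#' @examples
#' s <- summarizeAmplitudes(c(24.9, 25.1, 33.7, 38.8, 29.4),
#'                          c(5.0, 5.4, 6.4, 4.3, 7.6))
#' round(s$attenuation, 1)
summarizeAmplitudes <- function(scalpMedians, intracranialMedians) {
  stopifnot(length(scalpMedians) == length(intracranialMedians))
  if (any(intracranialMedians <= 0)) stop("intracranial medians must be > 0")
  if (any(scalpMedians <= 0)) stop("scalp medians must be > 0")
  att <- scalpMedians / intracranialMedians
  list(meanScalp = mean(scalpMedians),
       meanIntracranial = mean(intracranialMedians),
       attenuation = att,
       meanAttenuation = mean(att))
}
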