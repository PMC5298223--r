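#' Re-reference a recording
#'
#' Common average reference (CAR) subtracts the instantaneous mean across
#' channels from every channel; a single reference subtracts one channel.
#' Intracranial data are conventionally CAR-referenced; scalp data referenced
#' to a single electrode (e.g. Cz) when a clean CAR is not available.
#'
#' @param recording a [Recording-class].
#' @param scheme "CAR" or "single:<label>".
#' @param channels optional subset of channel labels to re-reference among
#'   (e.g. only the subdural contacts); others pass through unchanged.
#' @return A [Recording-class].
#' @export
rereference <- function(recording, scheme = "CAR", channels = NULL) {
  x <- recording@samples
  sel <- if (is.null(channels)) seq_len(ncol(x))
         else match(channels, recording@channels)
  if (anyNA(sel)) stop("unknown channel in 'channels'")
  if (identical(scheme, "CAR")) {
    x[, sel] <- x[, sel, drop = FALSE] - rowMeans(x[, sel, drop = FALSE])
  } else if (startsWith(scheme, "single:")) {
    ref <- sub("^single:", "", scheme)
    ri <- match(ref, recording@channels)
    if (is.na(ri)) stop(sprintf("missing reference channel '%s'", ref))
    x[, sel] <- x[, sel, drop = FALSE] - x[, ri]
  } else stop("scheme must be 'CAR' or 'single:<label>'")
  methods::initialize(recording, samples = x)
}

#' Excerpt center-aligned trials from a recording
#'
#' Cuts fixed-length excerpts around each event center (default -2..+2 s, the
#' trial span of the event-related analysis) or around each baseline window
#' center. Trials clipped by the recording edge are dropped with a warning.
#'
#' @param recording a [Recording-class].
#' @param trials a [TrialSet-class].
#' @param span numeric length-2, seconds relative to the alignment point.
#' @param align "center" (event 0-s point) or "baseline" (baseline window
#'   center).
#' @return numeric array time x channel x trial with attributes \code{time}
#'   (s, relative), \code{rate} and \code{channels}; the \code{trial} dimnames
#'   hold the retained event indices.
#' @export
excerptTrials <- function(recording, trials, span = c(-2, 2),
                          align = c("center", "baseline")) {
  align <- match.arg(align)
  rate <- recording@rate
  ev <- trials@events
  at <- switch(align, center = ev$center,
               baseline = ev$baseline_start + trials@baselineDur / 2)
  nwin <- round((span[2] - span[1]) * rate)
  i0 <- round((at + span[1]) * rate) + 1L
  ok <- i0 >= 1L & (i0 + nwin - 1L) <= nrow(recording@samples)
  if (any(!ok))
    warning(sprintf("%d trial(s) clipped by the recording edge were dropped", sum(!ok)))
  i0 <- i0[ok]
  out <- array(0, dim = c(nwin, ncol(recording@samples), length(i0)),
               dimnames = list(NULL, recording@channels, which(ok)))
  for (t in seq_along(i0))
    out[, , t] <- recording@samples[i0[t]:(i0[t] + nwin - 1L), ]
  attr(out, "time") <- span[1] + (seq_len(nwin) - 1) / rate
  attr(out, "rate") <- rate
  attr(out, "channels") <- recording@channels
  out
}

#' Spectral analysis parameters
#'
#' Defaults follow the study analysis: 250-ms window (256 samples at 1024 Hz),
#' 24.41-ms step (25 samples), -2..+2 s trial span, 200-ms baseline.
#'
#' @param windowSamples FFT window length in samples.
#' @param stepSamples hop between consecutive windows in samples.
#' @param logTransform return log10 relative power (default TRUE).
#' @param baselineOrder "median_then_mean" (median across baseline time bins
#'   within trial, then mean across trials; the default reading) or
#'   "mean_then_median".
#' @return Parameter list for [relativeSpectra()].
#' @export
spectralParams <- function(windowSamples = 256L, stepSamples = 25L,
                           logTransform = TRUE,
                           baselineOrder = c("median_then_mean", "mean_then_median")) {
  stopifnot(windowSamples > 0, stepSamples > 0)
  list(windowSamples = as.integer(windowSamples),
       stepSamples = as.integer(stepSamples),
       logTransform = logTransform,
       baselineOrder = match.arg(baselineOrder))
}

## Sliding-window FFT power of one trial matrix (time x channel):
## returns array channel x timebin x freqbin.
slidingPower <- function(x, wlen, step) {
  n <- nrow(x)
  starts <- seq(1L, n - wlen + 1L, by = step)
  nf <- wlen %/% 2 + 1L
  out <- array(0, dim = c(ncol(x), length(starts), nf))
  for (s in seq_along(starts)) {
    seg <- x[starts[s]:(starts[s] + wlen - 1L), , drop = FALSE]
    sp <- stats::mvfft(seg)
    out[, s, ] <- t(Mod(sp[seq_len(nf), , drop = FALSE])^2)
  }
  attr(out, "starts") <- starts
  out
}

#' Event-related relative time-frequency spectra
#'
#' Sliding-window FFT power of each trial, divided by the trial-averaged
#' median baseline power and log-scaled: per channel and frequency, the
#' baseline value is the median power across baseline time bins within each
#' trial, averaged across trials (order configurable, see [spectralParams()]).
#'
#' @param trials trial tensor from [excerptTrials()] (time x channel x trial).
#' @param baselines baseline tensor (time x channel x trial), e.g.
#'   \code{excerptTrials(rec, ts, span = c(-0.25, 0.25), align = "baseline")}.
#' @param params see [spectralParams()].
#' @return list of class \code{"RelativeSpectra"}: \code{logPower} array
#'   channel x trial x timebin x freqbin, \code{time} (s, window centers),
#'   \code{freq} (Hz), \code{baseline} (channel x freq), \code{params}.
#' @export
relativeSpectra <- function(trials, baselines, params = spectralParams()) {
  stopifnot(dim(trials)[3] >= 1, dim(baselines)[3] >= 1)
  rate <- attr(trials, "rate")
  wlen <- params$windowSamples; step <- params$stepSamples
  if (wlen > dim(trials)[1]) stop("FFT window exceeds the trial span")
  nC <- dim(trials)[2]; nT <- dim(trials)[3]
  nf <- wlen %/% 2 + 1L

  slice <- function(tens, t) array(tens[, , t], dim = dim(tens)[1:2])

  ## baseline power: per trial, median across its time bins, then across trials
  nB <- dim(baselines)[3]
  base <- array(0, dim = c(nC, nB, nf))
  for (t in seq_len(nB)) {
    pw <- slidingPower(slice(baselines, t), wlen, step)
    base[, t, ] <- apply(pw, c(1, 3), median)
  }
  baseline <- switch(params$baselineOrder,
    median_then_mean = apply(base, c(1, 3), mean),
    mean_then_median = apply(base, c(1, 3), median))
  if (any(baseline <= 0)) stop("degenerate input: zero baseline power")

  first <- slidingPower(slice(trials, 1), wlen, step)
  nW <- dim(first)[2]
  logPower <- array(0, dim = c(nC, nT, nW, nf))
  for (t in seq_len(nT)) {
    pw <- if (t == 1) first else slidingPower(slice(trials, t), wlen, step)
    rel <- sweep(pw, c(1, 3), baseline, `/`)
    logPower[, t, , ] <- if (params$logTransform) log10(rel) else rel
  }
  starts <- attr(first, "starts")
  tax <- attr(trials, "time")
  structure(list(
    logPower = logPower,
    time = tax[starts] + (wlen / 2) / rate,
    freq = (seq_len(nf) - 1) * rate / wlen,
    channels = attr(trials, "channels"),
    baseline = baseline, params = params), class = "RelativeSpectra")
}

#' Statistical-test parameters
#'
#' @param q FDR q-level (default 0.001).
#' @param fdrMethod "BY" (Benjamini-Yekutieli, valid under arbitrary
#'   dependence, appropriate for correlated neighboring time-frequency bins)
#'   or "BH".
#' @return Parameter list for [signTestMap()].
#' @export
statParams <- function(q = 0.001, fdrMethod = c("BY", "BH")) {
  stopifnot(q > 0, q < 1)
  list(q = q, fdrMethod = match.arg(fdrMethod))
}

#' Exact two-tailed sign test p-values
#'
#' For each value of \code{k} successes out of \code{n} nonzero observations,
#' the exact two-tailed binomial sign test of H0: median = 0, doubling the
#' smaller tail and capping at 1. All-zero bins give p = 1.
#'
#' @param k number of positive observations per bin.
#' @param n number of nonzero observations per bin.
#' @return p-values.
#' @export
signTestP <- function(k, n) {
  p <- rep(1, length(k))
  nz <- n > 0
  kk <- pmin(k[nz], n[nz] - k[nz])
  p[nz] <- pmin(1, 2 * pbinom(kk, n[nz], 0.5))
  p
}

#' Sign-test significance map of relative spectra
#'
#' Per channel x time x frequency bin, tests across trials whether the log
#' relative power has median zero (exact two-tailed sign test, zeros dropped),
#' then controls the false discovery rate across all bins of the map at level
#' q with the Benjamini-Yekutieli step-up procedure.
#'
#' @param spectra a \code{"RelativeSpectra"} object.
#' @param params see [statParams()].
#' @return list: \code{p} (array channel x time x freq), \code{mask} (logical,
#'   FDR-corrected rejections), \code{q}.
#' @export
signTestMap <- function(spectra, params = statParams()) {
  lp <- spectra$logPower
  nT <- dim(lp)[2]
  if (nT < 6) stop("at least 6 trials are required for the sign test")
  pos <- apply(lp > 0, c(1, 3, 4), sum)
  nnz <- apply(lp != 0, c(1, 3, 4), sum)
  p <- array(signTestP(as.vector(pos), as.vector(nnz)), dim = dim(pos))
  padj <- array(p.adjust(as.vector(p), method = params$fdrMethod), dim = dim(p))
  list(p = p, mask = padj <= params$q, q = params$q)
}

#' Percentage of contacts with significant chewing-related effects
#'
#' @param nSignificant number of contacts with at least one significant bin.
#' @param nContacts number of analyzed contacts.
#' @return Percentage, rounded to the nearest integer.
#' @export
significantContactPercent <- function(nSignificant, nContacts) {
  stopifnot(nContacts > 0, nSignificant >= 0, nSignificant <= nContacts)
  round(100 * nSignificant / nContacts)
}

#' Band-averaged topography of relative power
#'
#' Mean log relative power over a frequency band (default the gamma range
#' 32-400 Hz used for the chewing-effect topography), a peri-event time window
#' and all trials, per channel.
#'
#' @param spectra a \code{"RelativeSpectra"} object.
#' @param band frequency band, Hz.
#' @param window time window relative to the event center, s.
#' @return named per-channel scalar vector.
#' @export
bandTopography <- function(spectra, band = c(32, 400), window = c(-0.25, 0.25)) {
  fsel <- spectra$freq >= band[1] & spectra$freq <= band[2]
  if (!any(fsel)) stop("empty frequency band")
  tsel <- spectra$time >= window[1] & spectra$time <= window[2]
  if (!any(tsel)) stop("empty time window")
  vals <- apply(spectra$logPower[, , tsel, fsel, drop = FALSE], 1, mean)
  names(vals) <- spectra$channels
  vals
}
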