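#' Generate a synthetic chewing recording with ground-truth annotations
#'
#' Synthesizes a multichannel recording at the study's acquisition parameters
#' (1024 Hz, 1-344 Hz acquisition band) containing a train of broadband chewing
#' EMG bursts: band-limited (30-500 Hz) Gaussian noise under a sharp-onset
#' envelope (10 ms rise, exponential decay), repeated at the chewing rate.
#' Scalp channels carry the burst at the configured scalp amplitude with
#' distance-weighted mixing from the muscle compartment; intracranial channels
#' carry it attenuated by \code{attenuation}. Every channel receives
#' independent 1/f background noise. Burst waveforms are normalized so that a
#' channel of gain g uV yields a chewing-related amplitude statistic
#' (100-Hz high-passed 10th-to-90th percentile difference in a 100-ms window)
#' of g uV; per-trial chewing strength varies lognormally.
#'
#' @param electrodes an [ElectrodeSet-class].
#' @param params list overriding any of: duration (s), repRate (Hz, in
#'   \code{[0.8, 1.8]} for realistic chewing), burstDuration (s), emgBand (Hz),
#'   scalpAmplitude (uV), attenuation (EEG-to-ECoG factor, default 5.5),
#'   background (uV, 1/f level in amplitude-statistic units), amplitudeSdlog
#'   (per-trial lognormal spread), sourcePos (mm, muscle reference point for
#'   distance weighting), rate (Hz).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param channelGains optional named numeric vector of per-channel burst gains
#'   (uV) that overrides the distance-weighted mixing (used to couple the
#'   generator to a computed forward solution).
#' @param trialStrengths optional vector of per-trial strength factors
#'   (overrides the lognormal draw; recycled/truncated to the event count).
#' @param scalpTrialStrengths optional per-trial strength factors applied to
#'   scalp channels only (default: same as \code{trialStrengths}; both muscle
#'   projections then share one drive). Letting them differ emulates
#'   independent variability of the scalp and intracranial projections.
#' @return list(recording = [Recording-class], trials = [TrialSet-class],
#'   truth = data.frame of per-trial designed strengths).
#' @export
generateRecording <- function(electrodes, params = list(), seed = 1,
                              channelGains = NULL, trialStrengths = NULL,
                              scalpTrialStrengths = NULL) {
  p <- modifyList(list(
    duration = 60, repRate = 1.25, burstDuration = 0.3,
    emgBand = c(30, 500), scalpAmplitude = 30, attenuation = 5.5,
    background = 1, amplitudeSdlog = 0.35, sourcePos = NULL,
    rate = 1024, band = c(1, 344)), params)
  if (p$repRate <= 0 || p$repRate >= p$rate / 2)
    stop("repetition rate must be positive and Nyquist-compatible")
  if (p$duration < 2 / p$repRate + 3)
    stop("duration must accommodate at least two chewing events")
  rate <- p$rate
  nS <- round(p$duration * rate)
  nC <- length(electrodes@labels)

  withSeed(seed, {
    ## event centers
    iv <- 1 / p$repRate
    centers <- numeric(0)
    t0 <- 1.5 + iv / 2
    while (t0 < p$duration - 1.5) {
      centers <- c(centers, t0)
      t0 <- t0 + iv * exp(rnorm(1, 0, 0.06))
    }
    nT <- length(centers)
    if (nT < 2) stop("duration must accommodate at least two chewing events")
    strengths <- if (!is.null(trialStrengths)) rep_len(trialStrengths, nT)
                 else rlnorm(nT, 0, p$amplitudeSdlog)
    scalpStrengths <- if (!is.null(scalpTrialStrengths))
      rep_len(scalpTrialStrengths, nT) else strengths
    isScalp <- electrodes@kind == "scalp"

    ## channel gains
    if (is.null(channelGains)) {
      src <- if (is.null(p$sourcePos)) {
        sc <- electrodes@positions[electrodes@kind == "scalp", , drop = FALSE]
        if (nrow(sc)) 0.95 * sc[which.max(sc[, 1]), ] else c(1, 0, 0) * 44
      } else p$sourcePos
      d <- sqrt(rowSums(sweep(electrodes@positions, 2, src)^2))
      gains <- numeric(nC)
      for (kd in c("scalp", "subdural")) {
        sel <- electrodes@kind == kd
        if (!any(sel)) next
        w <- 1 / pmax(d[sel], 5)^2
        if (kd == "subdural" && sum(sel) > 1) {
          ## intracranial analysis is CAR-referenced: design the sub-grid
          ## topography as a zero-mean pattern of unit median magnitude so
          ## the configured amplitude survives the common average reference
          w <- w - mean(w)
          w <- w / median(abs(w))
        } else {
          w <- w / median(w)
        }
        gains[sel] <- w * if (kd == "scalp") p$scalpAmplitude
                          else p$scalpAmplitude / p$attenuation
      }
    } else {
      gains <- channelGains[electrodes@labels]
      if (anyNA(gains)) stop("channelGains must cover every electrode label")
    }

    ## burst template bank (one fresh carrier per event)
    nb <- round(p$burstDuration * rate)
    tb <- (seq_len(nb) - 1) / rate
    env <- pmin(tb / 0.010, 1) * exp(-pmax(tb - 0.010, 0) / (p$burstDuration / 3))
    samples <- matrix(0, nS, nC)
    winHalf <- round(0.05 * rate)
    for (i in seq_len(nT)) {
      carrier <- bandpassFilter(rnorm(nb), p$emgBand[1], p$emgBand[2], rate)
      w <- carrier * env
      ## normalize to unit amplitude statistic under the default analysis params
      pad <- c(numeric(nb), w, numeric(nb))
      hp <- highpassFilter(pad, 100, rate)
      ctr <- nb + round(nb / 2)
      stat <- amplitudeStat(hp[(ctr - winHalf):(ctr + winHalf)])
      w <- w / stat
      i0 <- round((centers[i] - p$burstDuration / 2) * rate) + 1L
      idx <- i0:(i0 + nb - 1L)
      keep <- idx >= 1L & idx <= nS
      strc <- ifelse(isScalp, scalpStrengths[i], strengths[i])
      samples[idx[keep], ] <- samples[idx[keep], ] +
        outer(w[keep], gains * strc)
    }

    ## independent 1/f background per channel, scaled in statistic units;
    ## background may be a scalar or named per-kind c(scalp=, subdural=)
    bg <- p$background
    bgOf <- function(kind) if (length(bg) > 1) bg[[kind]] else bg
    if (any(bg > 0)) {
      for (c in seq_len(nC)) {
        lev <- bgOf(electrodes@kind[c])
        if (lev <= 0) next
        noise <- pinkNoise(nS)
        noise <- noise / noiseStatUnit(noise, rate)
        samples[, c] <- samples[, c] + lev * noise
      }
    }

    rec <- new("Recording", samples = samples, rate = rate,
               channels = electrodes@labels, band = p$band)
    onset <- centers - p$burstDuration / 2
    endt <- centers + p$burstDuration / 2
    mids <- (centers[-1] + head(centers, -1)) / 2
    bstart <- c(centers[1] - median(diff(centers)) / 2, mids) - 0.1
    trials <- new("TrialSet",
                  events = data.frame(onset = onset, end = endt, center = centers,
                                      baseline_start = bstart),
                  baselineDur = 0.2)
    list(recording = rec, trials = trials,
         truth = data.frame(trial = seq_len(nT), strength = strengths,
                            center = centers))
  })
}

## 1/f-amplitude noise via spectral shaping, unit variance.
pinkNoise <- function(n) {
  nf <- n %/% 2
  f <- seq_len(nf)
  amp <- 1 / sqrt(f)
  phase <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- c(0, spec, if (n %% 2 == 0) Conj(rev(spec[-nf])) else Conj(rev(spec)))
  x <- Re(fft(full, inverse = TRUE))
  x <- x[seq_len(n)]
  x / sd(x)
}

## Median amplitude statistic of 100-Hz high-passed noise over 100-ms windows.
noiseStatUnit <- function(x, rate) {
  hp <- highpassFilter(x, 100, rate)
  nw <- round(0.1 * rate)
  starts <- seq(1, length(hp) - nw, by = nw)
  stats <- vapply(starts, function(s) amplitudeStat(hp[s:(s + nw - 1)]), 0)
  median(stats)
}

#' Detect chewing events from a recording channel
#'
#' Recovers burst annotations from the data alone: band-pass (30-500 Hz),
#' rectify, smooth (15 ms moving average), segment at a fraction of each
#' burst's envelope peak.
#'
#' @param recording a [Recording-class].
#' @param channel channel label (default: channel with the largest variance).
#' @param frac envelope fraction defining onset/end (default 0.05 of burst peak).
#' @return data.frame with onset, end, center (s).
#' @export
detectChewingEvents <- function(recording, channel = NULL, frac = 0.05) {
  x <- recording@samples
  rate <- recording@rate
  if (is.null(channel)) channel <- recording@channels[which.max(apply(x, 2, var))]
  v <- x[, match(channel, recording@channels)]
  env <- abs(bandpassFilter(v, 30, 500, rate))
  k <- round(0.015 * rate)
  env <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
  env[is.na(env)] <- 0
  thrHi <- max(6 * median(env), 0.08 * quantile(env, 0.999))
  above <- env > thrHi
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1); ends <- which(d == -1) - 1L
  ## merge segments separated by < 100 ms
  if (length(starts) > 1) {
    keep <- c(TRUE, (starts[-1] - ends[-length(ends)]) > 0.1 * rate)
    gid <- cumsum(keep)
    starts <- tapply(starts, gid, min); ends <- tapply(ends, gid, max)
  }
  out <- lapply(seq_along(starts), function(i) {
    seg <- env[starts[i]:ends[i]]
    ipk <- starts[i] + which.max(seg) - 1L
    pk <- env[ipk]
    thr <- frac * pk
    ## the rise is sharp: a higher walk-back threshold stays noise-immune and
    ## costs at most ~2 ms of the 10-ms ramp
    thrOn <- max(thr, 0.15 * pk)
    s <- starts[i]; while (s > 1 && env[s - 1] > thrOn) s <- s - 1
    ## the decay tail is noise-limited at the threshold level: fit the
    ## log-envelope over its high-SNR part (60%..15% of peak) and
    ## extrapolate the exponential to the threshold crossing
    e <- ipk
    while (e < length(env) && env[e + 1] > 0.15 * pk &&
           (i == length(starts) || e < starts[i + 1])) e <- e + 1
    fitIdx <- ipk:e
    fitIdx <- fitIdx[env[fitIdx] <= 0.6 * pk & env[fitIdx] > 0]
    refined <- FALSE
    if (length(fitIdx) >= 8) {
      co <- stats::coef(stats::lm(log(env[fitIdx]) ~ fitIdx))
      ## smoothing biases the apparent peak; the decay fit extrapolated back
      ## to the end of the rise gives an unbiased peak for the threshold
      riseEnd <- s + round(0.010 * rate)
      pkHat <- exp(co[1] + co[2] * riseEnd)
      eHat <- (log(frac * pkHat) - co[1]) / co[2]
      if (is.finite(co[2]) && co[2] < -1 / rate &&
          eHat > ipk && eHat < ipk + rate) {
        e <- round(eHat); refined <- TRUE
      }
    }
    if (!refined) while (e < length(env) && env[e + 1] > thr) e <- e + 1
    c(s, max(e, ipk))
  })
  out <- do.call(rbind, out)
  data.frame(onset = (out[, 1] - 1) / rate, end = (out[, 2] - 1) / rate,
             center = (out[, 1] + out[, 2] - 2) / 2 / rate)
}
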