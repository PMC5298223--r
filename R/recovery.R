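#' Parameter-recovery simulation of the calibration pipeline
#'
#' End-to-end closed loop: draws per-trial ground-truth dipole strengths,
#' synthesizes the intracranial recording through the implanted head model's
#' (HM1) forward solution for the source model - each sub-grid channel
#' carries the burst scaled by the reversal factor times its unit contact
#' potential times the trial strength - plus background noise at the
#' configured signal-to-noise ratio, runs the full calibration pipeline, and
#' compares recovered strengths and exceedance fractions with the designed
#' truth.
#'
#' @param unit a [UnitForward-class] for the source model under test.
#' @param electrodes the phantom [ElectrodeSet-class] (subdural + scalp).
#' @param nTrials number of chewing events to simulate.
#' @param seed integer seed.
#' @param snr intracranial amplitude signal-to-noise ratio (burst amplitude
#'   over background amplitude at the median trial strength; default 10).
#' @param scalpAmplitude_uV designed scalp channel amplitude M0 (constant
#'   across trials so that the scaled-field distribution reflects the
#'   strength distribution; default 30).
#' @param strengthSdlog lognormal spread of the true dipole strengths.
#' @param targetMedianScaledEF_Vpm design target: the median gum-condition
#'   scaled field, placing the distribution astride the 0.2 V/m threshold.
#' @param scaling a [ScalingTable-class].
#' @param params see [calibrationParams()].
#' @return list: \code{result} ([EFResult-class]), \code{trueStrengths},
#'   \code{recoveredStrengths}, \code{medianRelError},
#'   \code{trueExceedance} and \code{recoveredExceedance} (per condition, %),
#'   \code{nTrials}.
#' @export
recoverySimulation <- function(unit, electrodes, nTrials = 500, seed = 1,
                               snr = 10, scalpAmplitude_uV = 30,
                               strengthSdlog = 0.4,
                               targetMedianScaledEF_Vpm = 0.15,
                               scaling = defaultScalingTable(),
                               params = calibrationParams()) {
  K <- unit@peakEF_Vpm
  Sgum <- scaling@amplitudes[["gum"]]
  q0 <- targetMedianScaledEF_Vpm * scalpAmplitude_uV / (Sgum * K)
  q <- withSeed(seed + 77L, rlnorm(nTrials, log(q0), strengthSdlog))

  ## per-channel burst gains: subdural from the HM1 forward solution (with
  ## the reversal factor), scalp constant at M0
  uc <- unit@contactPotentials_uV
  gains <- numeric(length(electrodes@labels))
  names(gains) <- electrodes@labels
  gains[names(uc)] <- params$reversalFactor * uc * q0
  gains[electrodes@kind == "scalp"] <- scalpAmplitude_uV
  medSub <- median(abs(uc)) * params$reversalFactor * q0

  repRate <- 1.25
  duration <- ceiling((nTrials + 1) / repRate + 4)
  gen <- generateRecording(
    electrodes,
    params = list(duration = duration, repRate = repRate,
                  background = c(subdural = medSub / snr,
                                 scalp = scalpAmplitude_uV / snr)),
    seed = seed, channelGains = gains,
    trialStrengths = q / q0, scalpTrialStrengths = rep(1, nTrials))
  nGen <- nrow(gen$truth)
  q <- q[seq_len(min(nTrials, nGen))]

  res <- calibrationPipeline(gen$recording, gen$trials, electrodes, unit,
                             scaling, params)
  qhat <- unique(res@trials[, c("trial", "strength_Am")])$strength_Am
  qhat <- qhat[seq_along(q)]
  relErr <- abs(qhat - q) / q

  trueScaled <- outer(q * K / scalpAmplitude_uV, scaling@amplitudes)
  trueExc <- exceedance(trueScaled, params$threshold_Vpm)
  recExc <- structure(res@exceedance$exceedance_pct,
                      names = res@exceedance$condition)
  list(result = res, trueStrengths = q, recoveredStrengths = qhat,
       medianRelError = median(relErr),
       trueExceedance = trueExc, recoveredExceedance = recExc[names(trueExc)],
       nTrials = length(q))
}
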