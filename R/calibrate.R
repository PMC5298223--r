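#' Calibration parameters
#'
#' @param reversalFactor simulated sub-grid potentials are multiplied by this
#'   factor before matching measured amplitudes, modeling the potential
#'   reversal contained in a peak-to-peak style amplitude (default 2).
#' @param reduction how per-channel amplitudes are reduced to one value per
#'   trial for matching: "channel_median" (default) or "channel_max".
#' @param threshold_Vpm electric-field threshold, V/m (default 0.2, the
#'   literature threshold for neuromodulatory effects).
#' @param amplitude see [amplitudeParams()].
#' @return Parameter list.
#' @export
calibrationParams <- function(reversalFactor = 2,
                              reduction = c("channel_median", "channel_max"),
                              threshold_Vpm = 0.2,
                              amplitude = amplitudeParams()) {
  stopifnot(reversalFactor > 0, threshold_Vpm > 0)
  list(reversalFactor = reversalFactor, reduction = match.arg(reduction),
       threshold_Vpm = threshold_Vpm, amplitude = amplitude)
}

#' Forward constants per unit dipole moment
#'
#' Step 1 and 2 infrastructure of the calibration pipeline: solves the
#' implanted head model (HM1) for the source model and reduces the simulated
#' sub-grid contact potentials (common-average referenced) to an amplitude
#' measure per unit moment; solves the intact model (HM3) for the peak
#' gray-matter electric field per unit moment. Both are linear in the shared
#' dipole moment, so one solve per variant suffices.
#'
#' @param context a \code{"FEMContext"} containing HM1 and HM3 (see
#'   [femContext()]).
#' @param source a [SourceModel-class] (unit moments recommended).
#' @param params see [calibrationParams()].
#' @param tol solver tolerance.
#' @return A [UnitForward-class].
#' @export
unitForward <- function(context, source, params = calibrationParams(), tol = 1e-9) {
  if (!all(c("HM1", "HM3") %in% names(context$variants)))
    stop("context must contain HM1 and HM3")
  moment <- source@dipoles[[1]]@moment
  grid <- subsetElectrodes(context$electrodes, "subdural")
  ctx1 <- context$variants[["HM1"]]
  sol1 <- solveForward(ctx1$system, sourceLoad(source, ctx1$mesh), ctx1$mesh,
                       electrodes = grid, tol = tol)
  contact <- sol1@electrodePotentials * 1e6 / moment   # uV per unit moment
  measure <- switch(params$reduction,
                    channel_median = median(abs(contact)),
                    channel_max = max(abs(contact)))
  if (measure <= 0) stop("degenerate sub-grid measure (zero potentials)")
  ctx3 <- context$variants[["HM3"]]
  sol3 <- solveForward(ctx3$system, sourceLoad(source, ctx3$mesh), ctx3$mesh,
                       tol = tol)
  peak <- which.max(sol3@efMag)
  new("UnitForward", sourceModel = source@name,
      gridMeasure_uV = measure,
      peakEF_Vpm = max(sol3@efMag) / moment,
      contactPotentials_uV = contact,
      peakLocation = elementCentroids(ctx3$mesh, sol3@grayElems[peak])[1, ])
}

#' Calibrate per-trial dipole strengths (step 1)
#'
#' The dipole strength that reproduces each measured intracranial trial
#' amplitude: \code{strength_i = A_i / (reversalFactor * gridMeasure)}. The
#' reversal factor is applied exactly once, to the simulated measure.
#'
#' @param amplitudes_uV per-trial intracranial amplitudes (uV), reduced
#'   across channels (see [calibrationParams()] reduction).
#' @param unit a [UnitForward-class].
#' @param params see [calibrationParams()].
#' @return per-trial dipole strengths, A*m.
#' @export
calibrateTrials <- function(amplitudes_uV, unit, params = calibrationParams()) {
  stopifnot(all(amplitudes_uV >= 0))
  amplitudes_uV / (params$reversalFactor * unit@gridMeasure_uV)
}

#' Peak cortical field expected in the intact head (step 2)
#'
#' @param strengths_Am per-trial dipole strengths from [calibrateTrials()].
#' @param unit a [UnitForward-class].
#' @return per-trial peak gray-matter electric field, V/m; attribute
#'   \code{peakLocation} gives the mm position of the peak-field element.
#' @export
healthyEF <- function(strengths_Am, unit) {
  structure(strengths_Am * unit@peakEF_Vpm, peakLocation = unit@peakLocation)
}

#' Scale fields to chewing conditions (step 3)
#'
#' Scales each trial's field by the ratio of the condition's noninvasive
#' scaling amplitude to the trial's median scalp amplitude:
#' \code{EF_i,cond = EF_i * S_cond / M_i}. Trials with non-positive scalp
#' amplitude are excluded with a warning.
#'
#' @param ef_Vpm per-trial peak fields from [healthyEF()].
#' @param scalpMedian_uV per-trial scalp channel-median amplitudes, uV.
#' @param scaling a [ScalingTable-class].
#' @return matrix trials x conditions of scaled fields, V/m (excluded trials NA).
#' @export
scaleByCondition <- function(ef_Vpm, scalpMedian_uV, scaling = defaultScalingTable()) {
  stopifnot(length(ef_Vpm) == length(scalpMedian_uV))
  bad <- scalpMedian_uV <= 0
  if (any(bad)) {
    warning(sprintf("%d trial(s) with non-positive scalp amplitude excluded", sum(bad)))
    scalpMedian_uV[bad] <- NA_real_
  }
  out <- outer(ef_Vpm / scalpMedian_uV, scaling@amplitudes)
  dimnames(out) <- list(NULL, names(scaling@amplitudes))
  out
}

#' Exceedance fractions (step 4)
#'
#' Percentage of trials whose scaled peak cortical field strictly exceeds the
#' threshold, per condition.
#'
#' @param scaledEF matrix trials x conditions from [scaleByCondition()] (or a
#'   vector for a single condition).
#' @param threshold_Vpm V/m threshold (default 0.2).
#' @return named percentages in \code{[0, 100]}.
#' @export
exceedance <- function(scaledEF, threshold_Vpm = 0.2) {
  scaledEF <- cbind(scaledEF)
  if (nrow(scaledEF) == 0) stop("empty field distribution")
  100 * colMeans(scaledEF > threshold_Vpm, na.rm = TRUE)
}

#' Run the four-step calibration pipeline on a recording
#'
#' Computes intracranial (sub-grid, CAR-referenced) and scalp chewing
#' amplitudes per trial, calibrates per-trial dipole strengths against the
#' implanted head model, predicts per-trial peak cortical fields in the intact
#' model, scales them to the conditions of the scaling table, and summarizes
#' exceedance fractions.
#'
#' @param recording a [Recording-class] containing both subdural and scalp
#'   channels of \code{electrodes}.
#' @param trials a [TrialSet-class].
#' @param electrodes the matching [ElectrodeSet-class].
#' @param unit a [UnitForward-class] for the source model to use.
#' @param scaling a [ScalingTable-class].
#' @param params see [calibrationParams()].
#' @return An [EFResult-class].
#' @export
calibrationPipeline <- function(recording, trials, electrodes, unit,
                                scaling = defaultScalingTable(),
                                params = calibrationParams()) {
  sub <- electrodes@labels[electrodes@kind == "subdural"]
  sca <- electrodes@labels[electrodes@kind == "scalp"]
  if (!length(sub) || !length(sca)) stop("need both subdural and scalp channels")
  rec <- rereference(recording, "CAR", channels = sub)
  ampI <- chrAmplitude(rec, trials, params$amplitude, channels = sub)
  Ai <- switch(params$reduction,
               channel_median = ampI$perTrialMedian,
               channel_max = ampI$perTrialMax)
  ampS <- chrAmplitude(recording, trials, params$amplitude, channels = sca)
  Mi <- ampS$perTrialMedian
  strengths <- calibrateTrials(Ai, unit, params)
  ef <- healthyEF(strengths, unit)
  scaled <- scaleByCondition(as.numeric(ef), Mi, scaling)
  exc <- exceedance(scaled, params$threshold_Vpm)
  nT <- length(strengths)
  conds <- colnames(scaled)
  tab <- data.frame(
    trial = rep(seq_len(nT), times = length(conds)),
    source_model = unit@sourceModel,
    condition = rep(conds, each = nT),
    high_pass = params$amplitude$highPass,
    window_ms = params$amplitude$window_ms,
    statistic = params$amplitude$statistic,
    amplitude_uV = rep(Ai, times = length(conds)),
    scalp_uV = rep(Mi, times = length(conds)),
    strength_Am = rep(strengths, times = length(conds)),
    peak_EF_Vpm = rep(as.numeric(ef), times = length(conds)),
    scaled_EF_Vpm = as.vector(scaled))
  excTab <- data.frame(source_model = unit@sourceModel, condition = names(exc),
                       high_pass = params$amplitude$highPass,
                       window_ms = params$amplitude$window_ms,
                       statistic = params$amplitude$statistic,
                       exceedance_pct = as.numeric(exc))
  new("EFResult", trials = tab, exceedance = excTab,
      threshold = params$threshold_Vpm)
}

#' Parameter sweep of the calibration pipeline
#'
#' Recomputes the exceedance fractions over the analysis-parameter grid:
#' high-pass cutoffs, amplitude window lengths, amplitude statistics and
#' source models.
#'
#' @param recording,trials,electrodes as in [calibrationPipeline()].
#' @param units named list of [UnitForward-class] objects (per source model).
#' @param scaling a [ScalingTable-class].
#' @param highPass high-pass cutoffs, Hz.
#' @param windows_ms amplitude window lengths, ms.
#' @param statistics amplitude statistics.
#' @param threshold_Vpm V/m threshold.
#' @return data.frame of exceedance percentages per sweep cell x condition.
#' @export
sweepCalibration <- function(recording, trials, electrodes, units,
                             scaling = defaultScalingTable(),
                             highPass = c(55, 100),
                             windows_ms = c(50, 100, 150, 200, 250, 300),
                             statistics = c("p90_minus_p10", "peak_to_peak"),
                             threshold_Vpm = 0.2) {
  out <- NULL
  for (hp in highPass) for (w in windows_ms) for (st in statistics) {
    prm <- calibrationParams(threshold_Vpm = threshold_Vpm,
                             amplitude = amplitudeParams(hp, w, st))
    for (u in units) {
      res <- calibrationPipeline(recording, trials, electrodes, u,
                                 scaling, prm)
      out <- rbind(out, res@exceedance)
    }
  }
  out
}
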