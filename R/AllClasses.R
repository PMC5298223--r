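#' @import methods
#' @importFrom stats median quantile fft pbinom p.adjust rnorm runif rlnorm cmdscale dist sd var
#' @importFrom utils head tail read.table write.table modifyList
NULL

#' Tissue label codes
#'
#' The closed enumeration of tissue compartments used by [LabeledVolume-class]
#' volumes. Code 0 is reserved for background (outside the head; never meshed).
#'
#' @return Named integer vector mapping tissue names to label codes.
#' @export
#' @examples
#' tissueCodes()["gray"]
tissueCodes <- function() {
  c(background = 0L, soft_tissue = 1L, skull = 2L, CSF = 3L, gray = 4L,
    white = 5L, muscle = 6L, internal_air = 7L, blood = 8L,
    foramen_fill = 9L, grid_insulator = 10L, defect_fill = 11L)
}

#' LabeledVolume: integer tissue labels on a regular voxel grid
#'
#' The geometric substrate of every head model: a 3-D array of integer tissue
#' codes (see [tissueCodes()]) on an isotropic voxel lattice. Voxel \code{(i,j,k)}
#' has its center at \code{origin + (c(i,j,k) - 1) * spacing} (mm).
#'
#' @slot labels integer 3-D array of tissue codes.
#' @slot spacing isotropic voxel edge length in mm (> 0).
#' @slot origin mm coordinates of the center of voxel (1,1,1).
#' @export
setClass("LabeledVolume",
  representation(labels = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@labels)) != 3L) msg <- c(msg, "labels must be a 3-D array")
    if (length(object@spacing) != 1L || object@spacing <= 0) msg <- c(msg, "spacing must be a positive scalar")
    if (length(object@origin) != 3L) msg <- c(msg, "origin must have length 3")
    if (!all(object@labels %in% tissueCodes())) msg <- c(msg, "labels outside the closed tissue enumeration")
    if (length(msg)) msg else TRUE
  }
)

#' PhantomSpec: parametric layered head phantom
#'
#' Concentric-sphere head (white < gray < CSF < skull < scalp radii) with an
#' extracranial masticatory-muscle compartment (a spherical-shell sector about
#' \code{muscleAxis}), optional craniotomy defects (burr-hole cylinders and a
#' saw-line slot, CSF-filled), a skull-base foramen channel, and an insulating
#' subdural grid patch draped over the gray-matter surface on the +x side.
#'
#' @slot radii named increasing numeric, mm: white, gray, csf, skull, scalp.
#' @slot spacing voxel edge length mm (default 2).
#' @slot muscleAxis unit direction of the muscle sector center.
#' @slot muscleAngleDeg angular radius (degrees) of the muscle sector.
#' @slot burrHoles matrix with columns dx,dy,dz,diameter_mm (one row per hole);
#'   directions are unit vectors from the head center.
#' @slot sawLines list of lists with fields \code{from}, \code{to} (unit
#'   directions) and \code{width_mm}; the slot follows the great-circle arc.
#' @slot foramen list with \code{dir} (unit direction) and \code{diameter_mm}
#'   in \code{[1, 7]}; \code{NULL} for no channel.
#' @slot grid list: rows, cols, pitch_mm, contactDiameter_mm, thicknessVox,
#'   capRadius_mm (lateral footprint radius of the insulator patch);
#'   \code{NULL} for no grid.
#' @slot nScalp number of quasi-uniform scalp electrodes.
#' @export
setClass("PhantomSpec",
  representation(radii = "numeric", spacing = "numeric",
                 muscleAxis = "numeric", muscleAngleDeg = "numeric",
                 burrHoles = "matrix", sawLines = "list",
                 foramen = "ANY", grid = "ANY", nScalp = "numeric"),
  validity = function(object) {
    msg <- character()
    r <- object@radii
    need <- c("white", "gray", "csf", "skull", "scalp")
    if (!all(need %in% names(r))) msg <- c(msg, "radii must name white, gray, csf, skull, scalp")
    else if (any(diff(r[need]) <= 0)) msg <- c(msg, "radii must be strictly increasing")
    if (object@spacing <= 0) msg <- c(msg, "spacing must be > 0")
    if (!is.null(object@foramen)) {
      d <- object@foramen$diameter_mm
      if (is.null(d) || d < 1 || d > 7) msg <- c(msg, "foramen diameter must lie in [1, 7] mm")
    }
    if (!is.null(object@grid)) {
      g <- object@grid
      if (g$rows < 2 || g$cols < 2) msg <- c(msg, "grid needs rows, cols >= 2")
    }
    if (length(msg)) msg else TRUE
  }
)

#' ElectrodeSet: labeled contact positions
#'
#' @slot labels character channel labels (unique).
#' @slot positions numeric matrix (n x 3), mm.
#' @slot kind character, one of "scalp" or "subdural" per electrode.
#' @slot reference reference scheme: "CAR" or "single:<label>".
#' @export
setClass("ElectrodeSet",
  representation(labels = "character", positions = "matrix",
                 kind = "character", reference = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@labels)
    if (anyDuplicated(object@labels)) msg <- c(msg, "labels must be unique")
    if (nrow(object@positions) != n || ncol(object@positions) != 3L)
      msg <- c(msg, "positions must be an n x 3 matrix")
    if (length(object@kind) != n || !all(object@kind %in% c("scalp", "subdural")))
      msg <- c(msg, "kind must be scalp/subdural per electrode")
    if (!(object@reference == "CAR" || startsWith(object@reference, "single:")))
      msg <- c(msg, "reference must be 'CAR' or 'single:<label>'")
    if (length(msg)) msg else TRUE
  }
)

#' Recording: multichannel time series
#'
#' @slot samples numeric matrix, time x channel, in microvolts.
#' @slot rate sampling rate Hz (default 1024).
#' @slot channels character channel labels matching an [ElectrodeSet-class].
#' @slot band numeric length-2: high-pass and low-pass corner frequencies (Hz)
#'   of the acquisition chain (default c(1, 344)).
#' @export
setClass("Recording",
  representation(samples = "matrix", rate = "numeric",
                 channels = "character", band = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(is.finite(object@samples))) msg <- c(msg, "samples must be finite")
    if (ncol(object@samples) != length(object@channels))
      msg <- c(msg, "one label per channel column required")
    if (object@rate <= 0) msg <- c(msg, "rate must be > 0")
    if (length(object@band) == 2L && object@rate < 2 * object@band[2])
      msg <- c(msg, "rate must exceed twice the low-pass limit")
    if (length(msg)) msg else TRUE
  }
)

#' TrialSet: chewing-event annotations
#'
#' One row per chewing event: EMG onset and end (s), the event center (their
#' arithmetic mean, the 0-s point of the trial), and the start of a baseline
#' window (default 200 ms) centered between consecutive events.
#'
#' @slot events data.frame with columns onset, end, center, baseline_start (s).
#' @slot baselineDur baseline window duration, s (default 0.2).
#' @export
setClass("TrialSet",
  representation(events = "data.frame", baselineDur = "numeric"),
  validity = function(object) {
    ev <- object@events
    msg <- character()
    need <- c("onset", "end", "center", "baseline_start")
    if (!all(need %in% names(ev))) msg <- c(msg, "events needs onset, end, center, baseline_start")
    else if (nrow(ev)) {
      if (any(ev$onset >= ev$end)) msg <- c(msg, "onset must precede end")
      if (is.unsorted(ev$center, strictly = TRUE)) msg <- c(msg, "centers must be strictly increasing")
      if (max(abs(ev$center - (ev$onset + ev$end) / 2)) > 1e-9)
        msg <- c(msg, "center must be the arithmetic mean of onset and end")
      bs <- ev$baseline_start; be <- bs + object@baselineDur
      ov <- outer(bs, ev$end, `<`) & outer(be, ev$onset, `>`)
      if (any(ov)) msg <- c(msg, "baseline windows must not overlap event windows")
    }
    if (object@baselineDur <= 0) msg <- c(msg, "baselineDur must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' ScalingTable: per-condition scalp chewing amplitudes
#'
#' Named numeric vector of mean chewing-related scalp EMG amplitudes (uV) per
#' food condition; see [defaultScalingTable()].
#'
#' @slot amplitudes named positive numeric, uV.
#' @export
setClass("ScalingTable",
  representation(amplitudes = "numeric"),
  validity = function(object) {
    if (any(object@amplitudes <= 0)) "amplitudes must be > 0"
    else if (is.null(names(object@amplitudes))) "amplitudes must be named by condition"
    else TRUE
  }
)

#' ConductivityTable: tissue conductivities in S/m
#'
#' @slot sigma named numeric, S/m per tissue label name.
#' @export
setClass("ConductivityTable",
  representation(sigma = "numeric"),
  validity = function(object) {
    if (any(object@sigma < 0)) "conductivities must be >= 0" else TRUE
  }
)

#' HexMesh: regular hexahedral mesh from a labeled volume
#'
#' @slot nodes numeric matrix (nNodes x 3), mm.
#' @slot elems integer matrix (nElems x 8), node indices in VTK hexahedron order.
#' @slot labels integer per-element tissue code.
#' @slot spacing element edge length, mm.
#' @slot voxelIndex integer matrix (nElems x 3), source voxel of each element.
#' @slot dims integer voxel-grid dimensions of the source volume.
#' @slot elemOfVoxel integer array mapping voxel (i,j,k) to element id (0 = none).
#' @export
setClass("HexMesh",
  representation(nodes = "matrix", elems = "matrix", labels = "integer",
                 spacing = "numeric", voxelIndex = "matrix",
                 dims = "integer", elemOfVoxel = "array"))

#' DipoleSource: a point current dipole
#'
#' @slot position mm.
#' @slot orientation unit vector.
#' @slot moment dipole moment magnitude, A*m.
#' @export
setClass("DipoleSource",
  representation(position = "numeric", orientation = "numeric", moment = "numeric"),
  validity = function(object) {
    msg <- character()
    if (abs(sqrt(sum(object@orientation^2)) - 1) > 1e-6)
      msg <- c(msg, "orientation must be a unit vector")
    if (object@moment < 0) msg <- c(msg, "moment must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' SourceModel: named set of muscle dipoles
#'
#' SM1: one dipole in the belly of the temporal muscle. SM2: seven dipoles in
#' the belly plus one in the superior part. SM3: one dipole in the medial
#' pterygoid, adjacent to the foramen channel.
#'
#' @slot name "SM1", "SM2" or "SM3".
#' @slot dipoles list of [DipoleSource-class].
#' @export
setClass("SourceModel",
  representation(name = "character", dipoles = "list"),
  validity = function(object) {
    n <- length(object@dipoles)
    want <- c(SM1 = 1L, SM2 = 8L, SM3 = 1L)
    if (!object@name %in% names(want)) return("name must be SM1, SM2 or SM3")
    if (n != want[[object@name]])
      return(sprintf("%s requires %d dipole(s), got %d", object@name, want[[object@name]], n))
    TRUE
  }
)

#' ForwardSolution: potentials and cortical electric field
#'
#' @slot potentials node potentials, V (zero mean over nodes).
#' @slot electrodePotentials named electrode potentials, V, after re-referencing.
#' @slot efVectors gray-matter element electric-field vectors, V/m (nGray x 3).
#' @slot efMag gray-matter element field magnitudes, V/m.
#' @slot grayElems element ids of the gray-matter rows.
#' @slot residual relative solver residual.
#' @slot iterations solver iterations used.
#' @export
setClass("ForwardSolution",
  representation(potentials = "numeric", electrodePotentials = "numeric",
                 efVectors = "matrix", efMag = "numeric", grayElems = "integer",
                 residual = "numeric", iterations = "numeric"))

#' TriSurface: triangulated surface
#'
#' @slot vertices numeric matrix (n x 3), mm.
#' @slot triangles integer matrix (m x 3) of vertex indices.
#' @export
setClass("TriSurface",
  representation(vertices = "matrix", triangles = "matrix"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
    if (ncol(object@triangles) != 3L) msg <- c(msg, "triangles must be m x 3")
    tr <- object@triangles
    if (nrow(tr) && (min(tr) < 1 || max(tr) > nrow(object@vertices)))
      msg <- c(msg, "triangle indices out of range")
    key <- apply(object@triangles, 1L, function(t) paste(sort(t), collapse = "-"))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate triangles")
    if (length(msg)) msg else TRUE
  }
)

#' UnitForward: linear forward constants per unit dipole moment
#'
#' The calibration cache: the simulated sub-grid amplitude measure per unit
#' moment in the implanted head model (HM1, common-average referenced, reduced
#' across contacts), and the peak gray-matter electric field per unit moment in
#' the intact model (HM3).
#'
#' @slot sourceModel "SM1", "SM2" or "SM3".
#' @slot gridMeasure_uV uV of sub-grid amplitude per A*m (HM1; before the
#'   reversal factor).
#' @slot peakEF_Vpm V/m of peak gray-matter field per A*m (HM3).
#' @slot contactPotentials_uV named per-contact HM1 potentials, uV per A*m (CAR).
#' @slot peakLocation mm position of the HM3 peak-field element centroid.
#' @export
setClass("UnitForward",
  representation(sourceModel = "character", gridMeasure_uV = "numeric",
                 peakEF_Vpm = "numeric", contactPotentials_uV = "numeric",
                 peakLocation = "numeric"),
  validity = function(object) {
    if (object@gridMeasure_uV <= 0 || object@peakEF_Vpm <= 0)
      "unit forward constants must be > 0" else TRUE
  }
)

#' EFResult: calibrated per-trial electric-field predictions
#'
#' @slot trials data.frame with one row per trial x condition (columns: trial,
#'   source_model, condition, high_pass, window_ms, statistic, amplitude_uV,
#'   strength_Am, peak_EF_Vpm, scaled_EF_Vpm).
#' @slot exceedance data.frame of per-condition (x sweep cell) percentages of
#'   trials with scaled peak EF above the threshold.
#' @slot threshold V/m threshold (default 0.2).
#' @export
setClass("EFResult",
  representation(trials = "data.frame", exceedance = "data.frame",
                 threshold = "numeric"))

## ---- show methods -----------------------------------------------------------

setMethod("show", "LabeledVolume", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabeledVolume %dx%dx%d @ %.3g mm\n", d[1], d[2], d[3], object@spacing))
  tb <- table(factor(object@labels, levels = tissueCodes(),
                     labels = names(tissueCodes())))
  tb <- tb[tb > 0]
  cat(paste(sprintf("  %s: %d", names(tb), as.integer(tb)), collapse = "\n"), "\n")
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channels x %.1f s @ %g Hz (band %g-%g Hz)\n",
              ncol(object@samples), nrow(object@samples) / object@rate,
              object@rate, object@band[1], object@band[2]))
})

setMethod("show", "TrialSet", function(object) {
  cat(sprintf("TrialSet: %d chewing events, baseline %g ms\n",
              nrow(object@events), 1000 * object@baselineDur))
})

setMethod("show", "ElectrodeSet", function(object) {
  cat(sprintf("ElectrodeSet: %d contacts (%d scalp, %d subdural), reference %s\n",
              length(object@labels), sum(object@kind == "scalp"),
              sum(object@kind == "subdural"), object@reference))
})

setMethod("show", "HexMesh", function(object) {
  cat(sprintf("HexMesh: %d elements, %d nodes, h = %.3g mm\n",
              nrow(object@elems), nrow(object@nodes), object@spacing))
})

setMethod("show", "ForwardSolution", function(object) {
  cat(sprintf("ForwardSolution: %d node potentials, %d electrodes, peak gray EF %.4g V/m (residual %.2g)\n",
              length(object@potentials), length(object@electrodePotentials),
              if (length(object@efMag)) max(object@efMag) else NA_real_,
              object@residual))
})

setMethod("show", "UnitForward", function(object) {
  cat(sprintf("UnitForward[%s]: grid measure %.4g uV/(A*m), peak EF %.4g (V/m)/(A*m)\n",
              object@sourceModel, object@gridMeasure_uV, object@peakEF_Vpm))
})

setMethod("show", "EFResult", function(object) {
  cat(sprintf("EFResult: %d trial rows, %d exceedance cells, threshold %g V/m\n",
              nrow(object@trials), nrow(object@exceedance), object@threshold))
})

## ---- accessors --------------------------------------------------------------

#' @describeIn LabeledVolume-class voxel label array.
#' @param volume a LabeledVolume.
#' @export
labelArray <- function(volume) volume@labels

#' @describeIn LabeledVolume-class voxel spacing (mm).
#' @export
voxelSpacing <- function(volume) volume@spacing

#' @describeIn Recording-class sample matrix (time x channel, uV).
#' @param recording a Recording.
#' @export
sampleMatrix <- function(recording) recording@samples

#' @describeIn Recording-class sampling rate (Hz).
#' @export
samplingRate <- function(recording) recording@rate

#' @describeIn Recording-class channel labels.
#' @export
channelLabels <- function(recording) recording@channels

#' @describeIn TrialSet-class event table (one row per chewing event).
#' @param trials a TrialSet.
#' @export
eventTable <- function(trials) trials@events

#' @describeIn ElectrodeSet-class electrode positions (n x 3 mm).
#' @param electrodes an ElectrodeSet.
#' @export
electrodePositions <- function(electrodes) electrodes@positions

#' @describeIn ElectrodeSet-class electrode kinds.
#' @export
electrodeKinds <- function(electrodes) electrodes@kind

#' @describeIn ElectrodeSet-class electrode labels.
#' @export
electrodeLabels <- function(electrodes) electrodes@labels

#' @describeIn ScalingTable-class named condition amplitudes (uV).
#' @param table a ScalingTable.
#' @export
conditionAmplitudes <- function(table) table@amplitudes

#' @describeIn ConductivityTable-class named conductivities (S/m).
#' @export
conductivities <- function(table) table@sigma

#' @describeIn EFResult-class per-condition exceedance table.
#' @param result an EFResult.
#' @export
exceedanceTable <- function(result) result@exceedance

#' @describeIn EFResult-class per-trial calibrated table.
#' @export
trialTable <- function(result) result@trials
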