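#' Construct a parametric head-phantom specification
#'
#' The phantom is a concentric-sphere head (white/gray/CSF/skull/scalp) with an
#' extracranial masticatory-muscle compartment, craniotomy defects (burr holes
#' and a saw line, CSF-filled), a skull-base foramen channel and an insulating
#' subdural grid patch. It preserves the mechanisms that shape extra- to
#' intracranial EMG propagation - skull barrier, defect shunts, high-conductance
#' foramen tunnel, insulating grid shield - at desk scale.
#'
#' @param radii named increasing radii in mm (white, gray, csf, skull, scalp).
#' @param spacing isotropic voxel edge length, mm.
#' @param muscleAxis direction of the muscle sector (need not be unit length).
#' @param muscleAngleDeg angular radius of the muscle sector in degrees.
#' @param burrHoles matrix/data.frame with columns dx, dy, dz, diameter_mm
#'   (diameters 12 or 16 mm in the study); NULL or zero rows for none.
#' @param sawLines list of lists(from, to, width_mm) of great-circle slots.
#' @param foramen list(dir, diameter_mm) skull-base channel, or NULL.
#' @param grid list(rows, cols, pitch_mm, contactDiameter_mm, thicknessVox,
#'   capRadius_mm), or NULL.
#' @param nScalp number of scalp electrodes.
#' @return A [PhantomSpec-class] object.
#' @export
#' @examples
#' spec <- phantomSpec()
#' vol <- buildPhantom(spec, "HM3")
phantomSpec <- function(radii = c(white = 26, gray = 32, csf = 36, skull = 42, scalp = 48),
                        spacing = 2,
                        muscleAxis = c(1, 0, 0),
                        muscleAngleDeg = 45,
                        burrHoles = rbind(
                          c(cos(40 * pi / 180), 0, sin(40 * pi / 180), 12),
                          c(cos(40 * pi / 180), sin(40 * pi / 180), 0, 16)),
                        sawLines = list(list(
                          from = c(cos(40 * pi / 180), 0.15, sin(40 * pi / 180)),
                          to = c(cos(40 * pi / 180), sin(40 * pi / 180), 0.15),
                          width_mm = 4)),
                        foramen = list(dir = c(cos(35 * pi / 180), 0, -sin(35 * pi / 180)),
                                       diameter_mm = 5),
                        grid = list(rows = 4, cols = 4, pitch_mm = 10,
                                    contactDiameter_mm = 4, thicknessVox = 3,
                                    capRadius_mm = 26),
                        nScalp = 19) {
  if (is.null(burrHoles)) burrHoles <- matrix(numeric(0), ncol = 4)
  burrHoles <- as.matrix(burrHoles)
  if (ncol(burrHoles) != 4) stop("burrHoles must have 4 columns (dx, dy, dz, diameter_mm)")
  dimnames(burrHoles) <- list(NULL, c("dx", "dy", "dz", "diameter_mm"))
  new("PhantomSpec", radii = radii, spacing = spacing,
      muscleAxis = normalizeVec(muscleAxis), muscleAngleDeg = muscleAngleDeg,
      burrHoles = burrHoles, sawLines = if (is.null(sawLines)) list() else sawLines,
      foramen = foramen, grid = grid, nScalp = nScalp)
}

## Voxel-center coordinate grid for a spec: returns list(x, y, z, dims, origin).
phantomGrid <- function(spec) {
  R <- spec@radii[["scalp"]]
  h <- spec@spacing
  n <- 2L * ceiling(R / h) + 1L
  ax <- (seq_len(n) - (n + 1) / 2) * h
  list(ax = ax, dims = c(n, n, n), origin = rep(ax[1], 3))
}

#' Build a labeled head-phantom volume
#'
#' Rasterizes a [PhantomSpec-class] into a [LabeledVolume-class] for one of the
#' three head-model variants: \code{"HM1"} (craniotomy defects + insulating
#' grid), \code{"HM2"} (grid only, defects closed with skull) and \code{"HM3"}
#' (neither; the intact, "healthy" head). The foramen channel and muscle
#' compartment are anatomy and present in every variant. Voxels outside the
#' scalp sphere carry the background code 0 and are never meshed.
#'
#' @param spec a [PhantomSpec-class].
#' @param variant "HM1", "HM2" or "HM3".
#' @return A [LabeledVolume-class].
#' @export
buildPhantom <- function(spec, variant = c("HM1", "HM2", "HM3")) {
  variant <- match.arg(variant)
  validObject(spec)
  tc <- tissueCodes()
  g <- phantomGrid(spec)
  ax <- g$ax; n <- g$dims[1]
  h <- spec@spacing
  r <- spec@radii

  X <- array(ax, dim = g$dims)
  Y <- aperm(array(ax, dim = g$dims), c(2, 1, 3))
  Z <- aperm(array(ax, dim = g$dims), c(3, 2, 1))
  RR <- sqrt(X^2 + Y^2 + Z^2)

  lab <- array(tc[["background"]], dim = g$dims)
  lab[RR <= r[["scalp"]]] <- tc[["soft_tissue"]]
  lab[RR <= r[["skull"]]] <- tc[["skull"]]
  lab[RR <= r[["csf"]]]   <- tc[["CSF"]]
  lab[RR <= r[["gray"]]]  <- tc[["gray"]]
  lab[RR <= r[["white"]]] <- tc[["white"]]

  ## muscle: soft-tissue shell sector about muscleAxis
  ca <- cos(spec@muscleAngleDeg * pi / 180)
  dotA <- (X * spec@muscleAxis[1] + Y * spec@muscleAxis[2] + Z * spec@muscleAxis[3])
  musc <- lab == tc[["soft_tissue"]] & RR > 0 & (dotA / pmax(RR, 1e-9)) >= ca
  lab[musc] <- tc[["muscle"]]

  ## foramen channel: radial cylinder through the skull shell
  if (!is.null(spec@foramen)) {
    u <- normalizeVec(spec@foramen$dir)
    rad <- spec@foramen$diameter_mm / 2
    proj <- X * u[1] + Y * u[2] + Z * u[3]
    d2 <- pmax(0, X^2 + Y^2 + Z^2 - proj^2)
    inCyl <- lab == tc[["skull"]] & proj > 0 & d2 <= rad^2
    lab[inCyl] <- tc[["foramen_fill"]]
  }

  ## grid insulator: draped sheet over the +x gray surface (computed on the
  ## defect-free geometry so the voxel set is identical across variants)
  gridVox <- NULL
  if (!is.null(spec@grid)) {
    gridVox <- gridInsulatorVoxels(spec, lab, ax)
    if (variant %in% c("HM1", "HM2")) lab[gridVox] <- tc[["grid_insulator"]]
  }

  ## craniotomy defects (HM1 only): relabel skull voxels to defect_fill
  if (variant == "HM1") {
    skullMid <- (r[["csf"]] + r[["skull"]]) / 2
    if (nrow(spec@burrHoles)) {
      for (b in seq_len(nrow(spec@burrHoles))) {
        u <- normalizeVec(spec@burrHoles[b, 1:3])
        rad <- spec@burrHoles[b, 4] / 2
        proj <- X * u[1] + Y * u[2] + Z * u[3]
        d2 <- pmax(0, X^2 + Y^2 + Z^2 - proj^2)
        hit <- lab == tc[["skull"]] & proj > 0 & d2 <= rad^2
        if (!any(hit)) stop("burr-hole cylinder misses the skull shell")
        lab[hit] <- tc[["defect_fill"]]
      }
    }
    for (sl in spec@sawLines) {
      pts <- slerp(sl$from, sl$to, seq(0, 1, length.out = 200)) * skullMid
      w <- sl$width_mm / 2 + h / 2
      hit <- array(FALSE, dim = g$dims)
      ii <- which(lab == tc[["skull"]])
      P <- cbind(X[ii], Y[ii], Z[ii])
      ## radial slot: skull voxels whose direction passes near the polyline
      Pn <- P / sqrt(rowSums(P^2))
      near <- rep(FALSE, nrow(P))
      for (q in seq_len(nrow(pts))) {
        qn <- pts[q, ] / skullMid
        ## lateral distance of the voxel direction to the path point at skull-mid radius
        dlat <- sqrt(pmax(0, 2 - 2 * (Pn %*% qn)[, 1])) * skullMid
        near <- near | dlat <= w
      }
      if (!any(near)) stop("saw-line slot misses the skull shell")
      hit[ii[near]] <- TRUE
      lab[hit] <- tc[["defect_fill"]]
    }
  }

  vol <- new("LabeledVolume", labels = lab, spacing = h, origin = g$origin)
  if (!is.null(gridVox) && variant %in% c("HM1", "HM2")) {
    sc <- sealCheck(gridVox)
    if (!sc$pass) stop("grid insulator patch is not face-sealed")
  }
  vol
}

## Insulator voxel mask: for each (y,z) column inside the cap footprint, the
## thicknessVox voxels immediately above the outermost +x gray voxel.
gridInsulatorVoxels <- function(spec, lab, ax) {
  tc <- tissueCodes()
  n <- length(ax)
  mask <- array(FALSE, dim = dim(lab))
  cap <- spec@grid$capRadius_mm
  thick <- spec@grid$thicknessVox
  jIdx <- which(abs(ax) <= cap)
  for (j in jIdx) for (k in jIdx) {
    if (ax[j]^2 + ax[k]^2 > cap^2) next
    col <- lab[, j, k]
    ig <- which(col == tc[["gray"]] & ax > 0)
    if (!length(ig)) next
    top <- max(ig)
    up <- seq.int(top + 1L, min(top + thick, n))
    ## the sheet may displace CSF or skull, never muscle, soft tissue or the
    ## foramen channel
    up <- up[col[up] %in% tc[c("CSF", "skull")]]
    mask[up, j, k] <- TRUE
  }
  sealVoxelSet(mask, allowed = array(lab %in% tc[c("CSF", "skull")], dim = dim(lab)))
}

## Add face connectors until the voxel set has no edge/corner-only contacts.
sealVoxelSet <- function(mask, allowed, maxIter = 25L) {
  d <- dim(mask)
  ei <- function(a) { v <- c(0L, 0L, 0L); v[a] <- 1L; v }
  for (iter in seq_len(maxIter)) {
    added <- FALSE
    ## edge-only contacts in each axis pair
    for (pa in list(c(1, 2), c(1, 3), c(2, 3))) {
      a <- pa[1]; b <- pa[2]
      sft <- function(da, db) {
        idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
        idx[[a]] <- seq_len(d[a] - 1L) + da
        idx[[b]] <- seq_len(d[b] - 1L) + db
        do.call(`[`, c(list(mask), idx, list(drop = FALSE)))
      }
      m00 <- sft(0L, 0L); m11 <- sft(1L, 1L); m10 <- sft(1L, 0L); m01 <- sft(0L, 1L)
      for (diag in 1:2) {
        bad <- if (diag == 1) m00 & m11 & !m10 & !m01 else !m00 & !m11 & m10 & m01
        if (!any(bad)) next
        w <- which(bad, arr.ind = TRUE)
        for (q in seq_len(nrow(w))) {
          base <- as.integer(w[q, ])
          cand1 <- base + if (diag == 1) ei(a) else c(0L, 0L, 0L)
          cand2 <- base + if (diag == 1) ei(b) else ei(a) + ei(b)
          for (cc in list(cand1, cand2)) {
            if (allowed[cc[1], cc[2], cc[3]] && !mask[cc[1], cc[2], cc[3]]) {
              mask[cc[1], cc[2], cc[3]] <- TRUE; added <- TRUE; break
            }
          }
        }
      }
    }
    ## corner-only contacts in 2x2x2 blocks
    sc <- sealCheck(mask)
    if (sc$pass && !added) return(mask)
    if (!sc$pass && !added) {
      ## remaining leaks are corner contacts; connect along a face path
      w <- sc$leaks
      for (q in seq_len(nrow(w))) {
        base <- as.integer(w[q, 1:3])
        blk <- expand.grid(0:1, 0:1, 0:1)
        on <- which(apply(blk, 1, function(o) mask[base[1] + o[1], base[2] + o[2], base[3] + o[3]]))
        if (length(on) < 2) next
        c1 <- base + as.integer(blk[on[1], ]); c2 <- base + as.integer(blk[on[2], ])
        v1 <- c(c2[1], c1[2], c1[3]); v2 <- c(c2[1], c2[2], c1[3])
        for (cc in list(v1, v2)) {
          if (allowed[cc[1], cc[2], cc[3]]) mask[cc[1], cc[2], cc[3]] <- TRUE
        }
        added <- TRUE
      }
    }
  }
  mask
}

#' Check that a voxel set is sealed by face-to-face contacts
#'
#' In FEM rasterizations an insulating sheet leaks current wherever two of its
#' voxels touch only along an edge or at a corner. This scans all 2x2 squares
#' (three orientations) and 2x2x2 blocks of the mask for diagonal-only contact
#' patterns and reports their locations.
#'
#' @param mask logical 3-D array marking the grid (insulator) voxels.
#' @return list(pass = logical, leaks = integer matrix of voxel indices
#'   involved in edge/corner-only contacts).
#' @export
sealCheck <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  leaks <- NULL
  addLeak <- function(idx) leaks <<- rbind(leaks, idx)
  ## edge contacts: in each axis pair, 2x2 squares with only a diagonal present
  pairAxes <- list(c(1, 2), c(1, 3), c(2, 3))
  for (pa in pairAxes) {
    a <- pa[1]; b <- pa[2]
    sft <- function(da, db) {
      idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      idx[[a]] <- seq_len(d[a] - 1L) + da
      idx[[b]] <- seq_len(d[b] - 1L) + db
      do.call(`[`, c(list(mask), idx, list(drop = FALSE)))
    }
    m00 <- sft(0L, 0L); m11 <- sft(1L, 1L); m10 <- sft(1L, 0L); m01 <- sft(0L, 1L)
    bad <- (m00 & m11 & !m10 & !m01) | (!m00 & !m11 & m10 & m01)
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)
      addLeak(w)
    }
  }
  ## corner contacts: 2x2x2 blocks where two antipodal corners are the only voxels
  s <- function(dx, dy, dz)
    mask[seq_len(d[1] - 1L) + dx, seq_len(d[2] - 1L) + dy, seq_len(d[3] - 1L) + dz, drop = FALSE]
  corners <- list(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1), c(1,1,0), c(1,0,1), c(0,1,1), c(1,1,1))
  blocks <- lapply(corners, function(cc) s(cc[1], cc[2], cc[3]))
  tot <- Reduce(`+`, blocks)
  antip <- list(c(1, 8), c(2, 7), c(3, 6), c(4, 5))
  for (apr in antip) {
    bad <- tot == 2L & blocks[[apr[1]]] & blocks[[apr[2]]]
    if (any(bad)) addLeak(which(bad, arr.ind = TRUE))
  }
  list(pass = is.null(leaks), leaks = leaks)
}

#' Place scalp and subdural electrodes on a phantom
#'
#' Subdural contacts form the rows x cols lattice of the grid at its nominal
#' pitch, draped on the gray-matter surface beneath the insulator patch; scalp
#' contacts are distributed quasi-uniformly (Fibonacci lattice) on the outer
#' scalp sphere.
#'
#' @param spec a [PhantomSpec-class].
#' @param volume the matching [LabeledVolume-class] (used for surface checks).
#' @param nScalp number of scalp contacts; defaults to \code{spec@nScalp}.
#'   Use 0 for a subdural-only set.
#' @param reference reference scheme, default "CAR".
#' @param depthOffset_mm subdural contacts are placed this far below the
#'   gray/CSF interface (default half a voxel) so that they sample cortical
#'   tissue facing the contact rather than the insulator sheet above it.
#' @return An [ElectrodeSet-class].
#' @export
placeElectrodes <- function(spec, volume, nScalp = spec@nScalp, reference = "CAR",
                            depthOffset_mm = spec@spacing / 2) {
  labels <- character(0); kinds <- character(0)
  pos <- matrix(numeric(0), ncol = 3)
  if (!is.null(spec@grid)) {
    gR <- spec@radii[["gray"]] - depthOffset_mm
    gdef <- spec@grid
    yy <- (seq_len(gdef$cols) - (gdef$cols + 1) / 2) * gdef$pitch_mm
    zz <- (seq_len(gdef$rows) - (gdef$rows + 1) / 2) * gdef$pitch_mm
    ext <- sqrt(max(yy^2) + max(zz^2))
    if (ext >= gR) stop("grid patch is too small for the requested lattice")
    if (!is.null(gdef$capRadius_mm) && ext > gdef$capRadius_mm)
      stop("electrode lattice exceeds the insulator footprint")
    for (iz in seq_along(zz)) for (iy in seq_along(yy)) {
      x <- sqrt(gR^2 - yy[iy]^2 - zz[iz]^2)
      pos <- rbind(pos, c(x, yy[iy], zz[iz]))
      labels <- c(labels, sprintf("G%02d", (iz - 1L) * gdef$cols + iy))
      kinds <- c(kinds, "subdural")
    }
  }
  if (nScalp > 0) {
    sph <- fibonacciSphere(nScalp) * spec@radii[["scalp"]]
    pos <- rbind(pos, sph)
    labels <- c(labels, sprintf("S%02d", seq_len(nScalp)))
    kinds <- c(kinds, rep("scalp", nScalp))
  }
  new("ElectrodeSet", labels = labels, positions = pos, kind = kinds,
      reference = reference)
}

#' Per-condition scalp chewing amplitudes (noninvasive scaling table)
#'
#' Mean chewing-related scalp EMG amplitudes across healthy participants for
#' six food conditions of increasing hardness, in uV. These are the scaling
#' amplitudes used to map calibrated per-trial electric fields onto chewing of
#' different intensity.
#'
#' @return A [ScalingTable-class] with conditions yoghurt, banana, carrot,
#'   gum, candy, licorice.
#' @export
#' @examples
#' conditionAmplitudes(defaultScalingTable())[["gum"]]
defaultScalingTable <- function() {
  new("ScalingTable", amplitudes = c(
    yoghurt = 46.6, banana = 45.7, carrot = 116.4,
    gum = 107.3, candy = 139.9, licorice = 155.2))
}

#' Per-patient chewing-trial counts of the intracranial study
#'
#' Bookkeeping metadata of the clinical recordings: number of annotated
#' chewing events per implanted patient.
#'
#' @return Named integer vector (S1..S5).
#' @export
patientTrialCounts <- function() {
  c(S1 = 551L, S2 = 438L, S3 = 252L, S4 = 264L, S5 = 147L)
}
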