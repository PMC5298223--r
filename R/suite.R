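#' Construct a muscle source model for a phantom
#'
#' SM1: a single dipole central in the belly of the temporal-muscle analogue
#' (the +x muscle sector). SM2: seven dipoles spread through the belly plus
#' one in the superior part (toward the burr holes). SM3: a single dipole in
#' the medial-pterygoid position, directly outside the skull-base foramen
#' channel. Belly/superior dipoles are oriented along the muscle long axis
#' (phantom z); the pterygoid dipole along the foramen axis.
#'
#' @param name "SM1", "SM2" or "SM3".
#' @param spec the [PhantomSpec-class] the model refers to.
#' @param moment per-dipole moment magnitude, A*m (shared by all dipoles).
#' @return A [SourceModel-class].
#' @export
makeSourceModel <- function(name = c("SM1", "SM2", "SM3"), spec = phantomSpec(),
                            moment = 1) {
  name <- match.arg(name)
  rMid <- (spec@radii[["skull"]] + spec@radii[["scalp"]]) / 2
  dip <- function(pos, ori) new("DipoleSource", position = pos,
                                orientation = normalizeVec(ori), moment = moment)
  dipoles <- switch(name,
    SM1 = list(dip(c(rMid, 0, 0), c(0, 0, 1))),
    SM2 = {
      offs <- rbind(c(0, 0), c(8, 0), c(-8, 0), c(0, 8), c(0, -8), c(8, 8), c(-8, -8))
      belly <- lapply(seq_len(nrow(offs)), function(i)
        dip(c(sqrt(rMid^2 - sum(offs[i, ]^2)), offs[i, 1], offs[i, 2]), c(0, 0, 1)))
      sup <- dip(rMid * c(cos(33 * pi / 180), 0, sin(33 * pi / 180)), c(0, 0, 1))
      c(belly, list(sup))
    },
    SM3 = {
      if (is.null(spec@foramen)) stop("SM3 requires a foramen channel in the phantom")
      u <- normalizeVec(spec@foramen$dir)
      list(dip(rMid * u, u))
    })
  new("SourceModel", name = name, dipoles = dipoles)
}

#' Precompute meshes and stiffness systems for head-model variants
#'
#' Builds the phantom, mesh and assembled FEM system for each requested
#' variant once so that several source models can be solved against the same
#' geometry (the stiffness assembly dominates the cost).
#'
#' @param spec a [PhantomSpec-class].
#' @param table a [ConductivityTable-class].
#' @param variants subset of c("HM1", "HM2", "HM3").
#' @return list of class \code{"FEMContext"}: per-variant list(volume, mesh,
#'   system), plus \code{electrodes} (full set) and \code{spec}.
#' @export
femContext <- function(spec, table = defaultConductivityTable(),
                       variants = c("HM1", "HM2", "HM3")) {
  out <- list()
  for (v in variants) {
    vol <- buildPhantom(spec, v)
    mesh <- meshFromVolume(vol)
    out[[v]] <- list(volume = vol, mesh = mesh,
                     system = assembleSystem(mesh, table))
  }
  structure(list(variants = out,
                 electrodes = placeElectrodes(spec, out[[1]]$volume),
                 spec = spec, table = table), class = "FEMContext")
}

#' Summed St. Venant load of a source model
#'
#' @param source a [SourceModel-class].
#' @param mesh a [HexMesh-class].
#' @return node load vector (superposition of all dipole loads).
#' @export
sourceLoad <- function(source, mesh) {
  load <- numeric(nrow(mesh@nodes))
  for (d in source@dipoles) load <- load + stVenantLoad(d, mesh)
  load
}

## Subset an ElectrodeSet by kind.
subsetElectrodes <- function(electrodes, kind) {
  sel <- electrodes@kind == kind
  new("ElectrodeSet", labels = electrodes@labels[sel],
      positions = electrodes@positions[sel, , drop = FALSE],
      kind = electrodes@kind[sel], reference = electrodes@reference)
}

#' Run a source model through all head-model variants
#'
#' Solves the forward problem for the source model in each variant and
#' summarizes the shielding behavior: the peak potential power across the
#' sub-grid contact positions (identical positions in every variant) and the
#' peak gray-matter electric field. Opening craniotomy defects increases the
#' EMG signal below the grid (HM1 > HM2); removing the insulating grid
#' outweighs closing the defects (HM3 > HM1).
#'
#' @param context a \code{"FEMContext"} from [femContext()] (or a
#'   [PhantomSpec-class], in which case the context is built internally).
#' @param source a [SourceModel-class].
#' @param tol solver tolerance.
#' @return list: \code{solutions} per variant, \code{summary} data.frame with
#'   variant, peakSubgridPower_uV2, peakGrayEF_Vpm.
#' @export
runHeadModelSuite <- function(context, source, tol = 1e-9) {
  if (is(context, "PhantomSpec")) context <- femContext(context)
  grid <- subsetElectrodes(context$electrodes, "subdural")
  if (!length(grid@labels)) stop("phantom has no subdural contacts")
  sols <- list(); rows <- NULL
  for (v in names(context$variants)) {
    ctx <- context$variants[[v]]
    load <- sourceLoad(source, ctx$mesh)
    sol <- solveForward(ctx$system, load, ctx$mesh, electrodes = grid, tol = tol)
    sols[[v]] <- sol
    pw <- max((sol@electrodePotentials * 1e6)^2)
    rows <- rbind(rows, data.frame(variant = v,
                                   peakSubgridPower_uV2 = pw,
                                   peakGrayEF_Vpm = max(sol@efMag)))
  }
  list(solutions = sols, summary = rows)
}
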