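#' Read and write package data files
#'
#' Plain-format interchange: labeled volumes as NIfTI (int16 labels, affine
#' from spacing/origin); electrode sets as tab-delimited label/x/y/z/kind
#' tables; trial annotations and scaling tables as CSV; recordings as a CSV
#' sample matrix with a JSON metadata sidecar; phantom specifications as JSON;
#' meshes and surfaces as legacy ASCII VTK.
#'
#' @param volume,electrodes,trials,table,recording,result object to write.
#' @param path file path (for recordings, the metadata sidecar is
#'   \code{paste0(path, ".json")}).
#' @return The read functions return the corresponding object; write
#'   functions return \code{path} invisibly.
#' @name chewEF-io
NULL

#' @rdname chewEF-io
#' @export
writeVolume <- function(volume, path) {
  img <- RNifti::asNifti(array(as.integer(volume@labels), dim = dim(volume@labels)))
  RNifti::pixdim(img) <- rep(volume@spacing, 3)
  af <- diag(c(rep(volume@spacing, 3), 1))
  af[1:3, 4] <- volume@origin
  img <- RNifti::`qform<-`(img, structure(af, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname chewEF-io
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  af <- RNifti::xform(img)
  sp <- RNifti::pixdim(img)[1]
  new("LabeledVolume", labels = array(as.integer(img), dim = dim(img)),
      spacing = sp, origin = as.numeric(af[1:3, 4]))
}

#' @rdname chewEF-io
#' @export
writeElectrodes <- function(electrodes, path) {
  df <- data.frame(label = electrodes@labels,
                   x = electrodes@positions[, 1],
                   y = electrodes@positions[, 2],
                   z = electrodes@positions[, 3],
                   kind = electrodes@kind)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname chewEF-io
#' @param reference reference scheme recorded with the electrode set.
#' @export
readElectrodes <- function(path, reference = "CAR") {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  pos <- as.matrix(df[, c("x", "y", "z")])
  dimnames(pos) <- NULL
  new("ElectrodeSet", labels = as.character(df$label),
      positions = pos, kind = df$kind, reference = reference)
}

#' @rdname chewEF-io
#' @export
writeTrials <- function(trials, path) {
  write.table(trials@events, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname chewEF-io
#' @param baselineDur baseline duration (s) for trial sets read from CSV.
#' @export
readTrials <- function(path, baselineDur = 0.2) {
  ev <- read.table(path, sep = ",", header = TRUE)
  new("TrialSet", events = ev, baselineDur = baselineDur)
}

#' @rdname chewEF-io
#' @export
writeScalingTable <- function(table, path) {
  df <- data.frame(condition = names(table@amplitudes),
                   amplitude_uV = as.numeric(table@amplitudes))
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname chewEF-io
#' @export
readScalingTable <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE)
  new("ScalingTable",
      amplitudes = structure(df$amplitude_uV, names = df$condition))
}

#' @rdname chewEF-io
#' @export
writeRecording <- function(recording, path) {
  write.table(recording@samples, path, sep = ",", quote = FALSE,
              row.names = FALSE, col.names = recording@channels)
  meta <- list(rate = recording@rate, channels = recording@channels,
               band = recording@band)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname chewEF-io
#' @export
readRecording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  x <- as.matrix(read.table(path, sep = ",", header = TRUE))
  dimnames(x) <- NULL
  new("Recording", samples = x, rate = meta$rate,
      channels = meta$channels, band = meta$band)
}

#' @rdname chewEF-io
#' @param spec a [PhantomSpec-class] to serialize.
#' @export
writePhantomSpec <- function(spec, path) {
  obj <- list(radii = as.list(spec@radii), spacing = spec@spacing,
              muscleAxis = spec@muscleAxis, muscleAngleDeg = spec@muscleAngleDeg,
              burrHoles = if (nrow(spec@burrHoles)) as.data.frame(spec@burrHoles) else NULL,
              sawLines = spec@sawLines, foramen = spec@foramen,
              grid = spec@grid, nScalp = spec@nScalp)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname chewEF-io
#' @export
readPhantomSpec <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  phantomSpec(radii = unlist(o$radii), spacing = o$spacing,
              muscleAxis = o$muscleAxis, muscleAngleDeg = o$muscleAngleDeg,
              burrHoles = if (is.null(o$burrHoles)) NULL else as.matrix(o$burrHoles),
              sawLines = if (length(o$sawLines)) lapply(seq_len(nrow(o$sawLines)),
                function(i) list(from = unlist(o$sawLines[i, "from"]),
                                 to = unlist(o$sawLines[i, "to"]),
                                 width_mm = o$sawLines[i, "width_mm"][[1]])) else NULL,
              foramen = o$foramen, grid = o$grid, nScalp = o$nScalp)
}

#' @rdname chewEF-io
#' @param mesh a [HexMesh-class].
#' @export
writeMeshVTK <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "hexahedral mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", nrow(mesh@nodes))), con)
  write.table(mesh@nodes, con, row.names = FALSE, col.names = FALSE)
  m <- nrow(mesh@elems)
  writeLines(sprintf("CELLS %d %d", m, 9 * m), con)
  write.table(cbind(8L, mesh@elems - 1L), con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(12L, m)), con)
  writeLines(c(sprintf("CELL_DATA %d", m), "SCALARS tissue int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh@labels), con)
  invisible(path)
}

#' @rdname chewEF-io
#' @param surface a [TriSurface-class].
#' @export
writeSurfaceVTK <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "triangulated surface", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(surface@vertices))), con)
  write.table(surface@vertices, con, row.names = FALSE, col.names = FALSE)
  m <- nrow(surface@triangles)
  writeLines(sprintf("POLYGONS %d %d", m, 4 * m), con)
  write.table(cbind(3L, surface@triangles - 1L), con, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname chewEF-io
#' @param dir output directory for the per-trial CSV and exceedance JSON.
#' @export
writeEFResult <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(result@trials, file.path(dir, "trials.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  exc <- result@exceedance
  jsonlite::write_json(
    list(threshold_Vpm = result@threshold, exceedance = exc),
    file.path(dir, "exceedance.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
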