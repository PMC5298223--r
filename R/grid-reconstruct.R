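#' Electrode-grid geometry
#'
#' @param rows,cols lattice dimensions (>= 2).
#' @param pitch_mm center-to-center contact distance (default 10 mm).
#' @param contactDiameter_mm contact disc diameter (default 4 mm).
#' @return Layout list.
#' @export
gridLayout <- function(rows = 4L, cols = 4L, pitch_mm = 10, contactDiameter_mm = 4) {
  stopifnot(rows >= 2, cols >= 2, pitch_mm > 0)
  list(rows = as.integer(rows), cols = as.integer(cols),
       pitch_mm = pitch_mm, contactDiameter_mm = contactDiameter_mm)
}

#' Shrinkwrap hull around a closed surface
#'
#' Fits a smooth enclosing hull that follows the outer envelope of the input
#' (the brain surface) without descending into its concavities (the sulci):
#' a subdivided icosphere is shrunk radially from the bounding sphere toward
#' the directional maxima of the input, with Laplacian smoothing of the radial
#' field at every step, and finally clamped to enclose the input. Assumes the
#' input is star-shaped about its centroid (true for brain-hull geometry).
#'
#' @param surface a closed [TriSurface-class].
#' @param iterations shrink/smooth iterations.
#' @param smoothWeight Laplacian smoothing weight in \code{[0, 1)}; larger
#'   values give a smoother hull that bridges concavities more aggressively.
#' @param subdivisions icosphere resolution of the hull.
#' @return A [TriSurface-class] hull enclosing the input.
#' @export
shrinkwrap <- function(surface, iterations = 60L, smoothWeight = 0.6,
                       subdivisions = 3L) {
  if (!isClosedSurface(surface)) stop("shrinkwrap requires a closed input surface")
  ctr <- colMeans(surface@vertices)
  tv <- sweep(surface@vertices, 2, ctr)
  tr <- sqrt(rowSums(tv^2))
  tn <- tv / tr
  hull <- icosphere(subdivisions, radius = 1)
  hv <- hull@vertices
  ## directional neighborhoods: target vertices within an angular radius that
  ## guarantees full coverage of the hull directions
  cosTh <- cos(2.5 * sqrt(4 * pi / nrow(hv)))
  rReq <- vapply(seq_len(nrow(hv)), function(i) {
    sel <- (tn %*% hv[i, ])[, 1] >= cosTh
    if (!any(sel)) max(tr) else max(tr[sel])
  }, 0)
  ## hull vertex adjacency for smoothing
  e <- surfaceEdges(hull)
  nb <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  nb <- nb[order(as.integer(names(nb)))]
  r <- rReq
  for (it in seq_len(iterations)) {
    rs <- vapply(seq_along(nb), function(i) mean(r[nb[[i]]]), 0)
    r <- pmax(rReq, (1 - smoothWeight) * r + smoothWeight * rs)
  }
  r <- pmax(r, rReq)
  triSurface(sweep(hv * r, 2, ctr, `+`), hull@triangles)
}

## Snap points to nearest surface vertices; returns vertex indices.
nearestVertices <- function(surface, points) {
  apply(rbind(points), 1, function(p)
    which.min(rowSums(sweep(surface@vertices, 2, p)^2)))
}

#' Extract a geodesically bounded quadrilateral patch from a hull
#'
#' The patch boundary follows the shortest (Dijkstra) paths between
#' consecutive corners on the hull edge graph; the interior is the
#' flood-filled region containing the centroid direction of the corners.
#'
#' @param hull a [TriSurface-class].
#' @param corners 4 x 3 matrix of corner positions (snapped to hull vertices).
#' @return A [TriSurface-class] patch (vertex subset of the hull, with
#'   attributes \code{hullVertices} (original indices) and \code{corners}
#'   (patch-vertex indices of the four corners)).
#' @export
extractPatch <- function(hull, corners) {
  corners <- rbind(corners)
  if (nrow(corners) != 4) stop("exactly four corners are required")
  ci <- nearestVertices(hull, corners)
  g <- surfaceGraph(hull)
  boundary <- integer(0)
  for (k in 1:4) {
    a <- ci[k]; b <- ci[k %% 4 + 1]
    sp <- igraph::shortest_paths(g, from = a, to = b, output = "vpath")$vpath[[1]]
    if (!length(sp)) stop("corners cannot be connected on the hull")
    boundary <- c(boundary, as.integer(sp))
  }
  boundary <- unique(boundary)
  ## interior seed: hull vertex nearest the mean corner direction
  ctr <- colMeans(hull@vertices)
  seedDir <- normalizeVec(colMeans(hull@vertices[ci, , drop = FALSE]) - ctr)
  cand <- setdiff(seq_len(nrow(hull@vertices)), boundary)
  dirs <- sweep(hull@vertices[cand, , drop = FALSE], 2, ctr)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  seed <- cand[which.max(dirs %*% seedDir)]
  ## vertex ids shift after deletion; map via names
  g2 <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(igraph::vcount(g))))
  gi <- igraph::delete_vertices(g2, as.character(boundary))
  comp <- igraph::components(gi)
  seedComp <- comp$membership[[as.character(seed)]]
  inner <- as.integer(igraph::V(gi)$name[comp$membership == seedComp])
  keep <- sort(unique(c(inner, boundary)))
  sel <- matrix(hull@triangles %in% keep, ncol = 3)
  tri <- hull@triangles[rowSums(sel) == 3L, , drop = FALSE]
  remap <- integer(nrow(hull@vertices)); remap[keep] <- seq_along(keep)
  patch <- triSurface(hull@vertices[keep, , drop = FALSE],
                      matrix(remap[tri], ncol = 3))
  attr(patch, "hullVertices") <- keep
  attr(patch, "corners") <- remap[ci]
  patch
}

#' Geodesic-preserving planar embedding of a surface patch
#'
#' Classical multidimensional scaling of the graph-geodesic (Dijkstra)
#' distance matrix of the patch - the isomap construction restricted to the
#' patch graph. For developable patches (planes, cylinders) the embedding
#' preserves geodesic distances up to graph-discretization error; the result
#' is defined up to rigid motion and reflection.
#'
#' @param patch a connected [TriSurface-class].
#' @param augmentRadius_mm augment the edge graph with chords between all
#'   vertex pairs within this Euclidean radius. A fixed physical radius
#'   suppresses the direction quantization of lattice-like triangulations,
#'   and refining the mesh within the radius monotonically improves the
#'   geodesic estimates. The default matches the electrode-pitch scale;
#'   0 disables augmentation.
#' @return n x 2 matrix of planar coordinates (attribute \code{eig} holds the
#'   MDS eigenvalues).
#' @export
embedPatch2D <- function(patch, augmentRadius_mm = 10) {
  e <- surfaceEdges(patch)
  V <- patch@vertices
  ## exactly planar patches are isometric to their orthogonal projection;
  ## use it directly instead of the (quantized) graph geodesics
  ctr <- colMeans(V)
  sv <- svd(sweep(V, 2, ctr))
  if (sv$d[3] < 1e-9 * sv$d[1]) {
    out <- sweep(V, 2, ctr) %*% sv$v[, 1:2]
    return(structure(out, eig = c(sv$d[1:2]^2, rep(0, nrow(V) - 2))))
  }
  if (augmentRadius_mm > 0) {
    D3 <- as.matrix(dist(V))
    close <- which(D3 > 0 & D3 <= augmentRadius_mm, arr.ind = TRUE)
    close <- close[close[, 1] < close[, 2], , drop = FALSE]
    if (nrow(close)) e <- unique(rbind(e, close))
  }
  w <- sqrt(rowSums((V[e[, 1], , drop = FALSE] - V[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = w)
  if (igraph::components(g)$no != 1L) stop("patch must be connected")
  D <- igraph::distances(g)
  mds <- cmdscale(D, k = 2, eig = TRUE)
  structure(mds$points, eig = mds$eig)
}

#' Place electrode lattice in the embedding and back-project to 3-D
#'
#' Places the rows x cols contact lattice at fixed pitch in the plane (a rigid
#' lattice anchored at the first corner, advancing toward the second), links
#' each center to its three nearest embedded patch vertices (ties broken by
#' vertex index), and back-projects through the barycentric coordinates of
#' that vertex triple to the original 3-D patch.
#'
#' @param patch a [TriSurface-class] from [extractPatch()] (or any patch).
#' @param embedding n x 2 planar coordinates from [embedPatch2D()].
#' @param layout see [gridLayout()].
#' @param corners optional patch-vertex indices of the four grid corners
#'   (defaults to \code{attr(patch, "corners")}); used to anchor and orient
#'   the lattice and to resolve the embedding's reflection ambiguity by
#'   matching the corner winding to the 3-D patch.
#' @return list: \code{centers2d}, \code{centers3d}, \code{triangles}
#'   (contacts x 3 patch-vertex indices), \code{bary} (barycentric weights).
#' @export
placeAndTriangulate <- function(patch, embedding, layout = gridLayout(),
                                corners = attr(patch, "corners")) {
  emb <- embedding
  if (is.null(corners)) stop("corner indices are required to anchor the lattice")
  c2 <- emb[corners, , drop = FALSE]
  ## resolve reflection: 2-D corner winding must match the 3-D winding sense
  n3 <- crossProduct(patch@vertices[corners[2], ] - patch@vertices[corners[1], ],
                     patch@vertices[corners[4], ] - patch@vertices[corners[1], ])
  ctr <- colMeans(patch@vertices)
  outward <- sum(n3 * (patch@vertices[corners[1], ] - ctr)) >= 0
  a2 <- c2[2, ] - c2[1, ]; b2 <- c2[4, ] - c2[1, ]
  if ((a2[1] * b2[2] - a2[2] * b2[1] < 0) == outward) {
    emb[, 2] <- -emb[, 2]
    c2 <- emb[corners, , drop = FALSE]
  }
  ex <- normalizeVec(c(c2[2, ] - c2[1, ], 0))[1:2]
  ey <- c(-ex[2], ex[1])
  if (sum((c2[4, ] - c2[1, ]) * ey) < 0) ey <- -ey
  centers <- NULL
  for (r in seq_len(layout$rows)) for (cc in seq_len(layout$cols)) {
    centers <- rbind(centers, c2[1, ] + (cc - 1) * layout$pitch_mm * ex +
                                  (r - 1) * layout$pitch_mm * ey)
  }
  ## contract: every center must fall inside the embedded patch
  maxEdge <- max(sqrt(rowSums((patch@vertices[surfaceEdges(patch)[, 1], , drop = FALSE] -
                               patch@vertices[surfaceEdges(patch)[, 2], , drop = FALSE])^2)))
  tri <- matrix(0L, nrow(centers), 3)
  bary <- matrix(0, nrow(centers), 3)
  c3 <- matrix(0, nrow(centers), 3)
  for (i in seq_len(nrow(centers))) {
    d2 <- rowSums(sweep(emb, 2, centers[i, ])^2)
    if (min(d2) > (2 * maxEdge)^2)
      stop("layout exceeds the patch extent")
    nn <- order(d2, seq_along(d2))[1:3]   # ties broken by vertex index
    A <- cbind(emb[nn, ], 1)
    det3 <- det(A)
    if (abs(det3) < 1e-9 * maxEdge^2) {
      ## nearly collinear neighbors: inverse-distance weights
      w <- 1 / pmax(sqrt(d2[nn]), 1e-9); w <- w / sum(w)
    } else {
      w <- solve(t(A), c(centers[i, ], 1))
    }
    tri[i, ] <- nn
    bary[i, ] <- w
    c3[i, ] <- colSums(patch@vertices[nn, , drop = FALSE] * w)
  }
  list(centers2d = centers, centers3d = c3, triangles = tri, bary = bary)
}
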