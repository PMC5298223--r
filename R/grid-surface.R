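#' Create a TriSurface
#'
#' @param vertices numeric n x 3 matrix, mm.
#' @param triangles integer m x 3 matrix of vertex indices.
#' @return A [TriSurface-class].
#' @export
triSurface <- function(vertices, triangles) {
  new("TriSurface", vertices = as.matrix(vertices),
      triangles = matrix(as.integer(triangles), ncol = 3))
}

#' Triangulated sphere (subdivided icosahedron)
#'
#' @param subdivisions subdivision level (0 = icosahedron; each level
#'   quadruples the triangle count).
#' @param radius sphere radius, mm.
#' @param bumpAmplitude optional amplitude of a sinusoidal radial perturbation
#'   (an idealized gyral pattern) applied as
#'   \code{r = radius + bumpAmplitude * sin(f*theta) * sin(f*phi)}.
#' @param bumpFrequency angular frequency of the perturbation.
#' @return A [TriSurface-class].
#' @export
icosphere <- function(subdivisions = 3L, radius = 1,
                      bumpAmplitude = 0, bumpFrequency = 6) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1,12,6), c(1,6,2), c(1,2,8), c(1,8,11), c(1,11,12),
             c(2,6,10), c(6,12,5), c(12,11,3), c(11,8,7), c(8,2,9),
             c(4,10,5), c(4,5,3), c(4,3,7), c(4,7,9), c(4,9,10),
             c(5,10,6), c(3,5,12), c(7,3,11), c(9,7,8), c(10,9,2))
  for (s in seq_len(subdivisions)) {
    mid <- new.env()
    key <- function(a, b) paste(min(a, b), max(a, b))
    getMid <- function(a, b) {
      k <- key(a, b)
      if (!is.null(mid[[k]])) return(mid[[k]])
      m <- normalizeVec(v[a, ] + v[b, ])
      v <<- rbind(v, m)
      mid[[k]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- getMid(a, b); bc <- getMid(b, c); ca <- getMid(c, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  r <- radius
  if (bumpAmplitude != 0) {
    th <- acos(pmin(1, pmax(-1, v[, 3])))
    ph <- atan2(v[, 2], v[, 1])
    r <- radius + bumpAmplitude * sin(bumpFrequency * th) * sin(bumpFrequency * ph)
  }
  triSurface(v * r, f)
}

## Edge list (unique, sorted pairs) of a TriSurface.
surfaceEdges <- function(surface) {
  tr <- surface@triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  unique(e)
}

## TRUE when every edge borders exactly two triangles.
isClosedSurface <- function(surface) {
  tr <- surface@triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

## Vertex adjacency as an igraph with Euclidean edge weights.
surfaceGraph <- function(surface) {
  e <- surfaceEdges(surface)
  w <- sqrt(rowSums((surface@vertices[e[, 1], , drop = FALSE] -
                     surface@vertices[e[, 2], , drop = FALSE])^2))
  igraph::graph_from_edgelist(e, directed = FALSE) |>
    igraph::set_edge_attr("weight", value = w)
}

#' Rasterize a triangulated sheet into a sealed voxel mask
#'
#' Samples each triangle densely, marks the voxels hit within the volume, and
#' seals the resulting voxel set by face connectors (see [sealCheck()]). Used
#' to insert a reconstructed electrode-grid sheet into a labeled volume as
#' insulator.
#'
#' @param surface a [TriSurface-class] (the grid sheet).
#' @param volume a [LabeledVolume-class] defining the voxel lattice.
#' @param thickness_mm sheet thickness along the triangle normals.
#' @param orientAwayFrom optional mm point; triangle normals are flipped to
#'   point away from it, so the sheet thickens outward (e.g. away from the
#'   head center, into CSF rather than into cortex).
#' @return logical voxel mask.
#' @export
rasterizeSurface <- function(surface, volume, thickness_mm = volume@spacing,
                             orientAwayFrom = NULL) {
  d <- dim(volume@labels)
  h <- volume@spacing
  mask <- array(FALSE, dim = d)
  V <- surface@vertices
  tc <- tissueCodes()
  markPoint <- function(p) {
    idx <- round((p - volume@origin) / h) + 1L
    if (all(idx >= 1L) && all(idx <= d)) mask[idx[1], idx[2], idx[3]] <<- TRUE
  }
  step <- h / 2
  for (t in seq_len(nrow(surface@triangles))) {
    tri <- V[surface@triangles[t, ], ]
    n <- crossProduct(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    nn <- sqrt(sum(n^2)); if (nn == 0) next
    n <- n / nn
    if (!is.null(orientAwayFrom) &&
        sum(n * (colMeans(tri) - orientAwayFrom)) < 0) n <- -n
    maxEdge <- max(sqrt(rowSums((tri[c(2, 3, 1), ] - tri)^2)))
    k <- max(2L, ceiling(maxEdge / step))
    for (a in 0:k) for (b in 0:(k - a)) {
      l <- c(a, b, k - a - b) / k
      p <- l[1] * tri[1, ] + l[2] * tri[2, ] + l[3] * tri[3, ]
      for (off in seq(0, thickness_mm, by = step))
        markPoint(p + n * off)
    }
  }
  sealVoxelSet(mask, allowed = array(TRUE, dim = d))
}

crossProduct <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
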