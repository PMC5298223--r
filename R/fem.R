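#' Default tissue conductivities
#'
#' Isotropic conductivities in S/m: white matter 0.14, gray matter 0.33,
#' CSF 1.54, blood 0.63, skull 0.0063, muscle 0.11, soft tissue 0.17,
#' internal air 0.002. Foramina (blood + nerve fill) 0.38 S/m, the average of
#' blood and white matter; craniotomy defects are CSF-filled. The insulating
#' silicone grid is modeled at 1e-12 S/m - numerically indistinguishable from
#' a perfect insulator at the solver tolerance while keeping the stiffness
#' matrix well conditioned.
#'
#' @param gridSigma conductivity of the grid insulator, S/m.
#' @return A [ConductivityTable-class].
#' @export
defaultConductivityTable <- function(gridSigma = 1e-12) {
  new("ConductivityTable", sigma = c(
    white = 0.14, gray = 0.33, CSF = 1.54, blood = 0.63, skull = 0.0063,
    muscle = 0.11, soft_tissue = 0.17, internal_air = 0.002,
    foramen_fill = 0.38, defect_fill = 1.54, grid_insulator = gridSigma))
}

#' Hexahedral mesh from a labeled volume
#'
#' One trilinear 8-node hexahedral element per non-background voxel, nodes on
#' the voxel-corner lattice (regular, axis-aligned cubes of edge = spacing).
#'
#' @param volume a [LabeledVolume-class].
#' @return A [HexMesh-class].
#' @export
meshFromVolume <- function(volume) {
  lab <- volume@labels
  d <- dim(lab)
  vox <- which(lab != tissueCodes()[["background"]], arr.ind = TRUE)
  if (nrow(vox) == 0L) stop("volume contains no tissue voxels")
  h <- volume@spacing
  nx1 <- d[1] + 1L; ny1 <- d[2] + 1L
  nodeId <- function(i, j, k) i + (j - 1L) * nx1 + (k - 1L) * (nx1 * ny1)
  i <- vox[, 1]; j <- vox[, 2]; k <- vox[, 3]
  ## VTK hexahedron corner order
  conn <- cbind(nodeId(i,      j,      k),
                nodeId(i + 1L, j,      k),
                nodeId(i + 1L, j + 1L, k),
                nodeId(i,      j + 1L, k),
                nodeId(i,      j,      k + 1L),
                nodeId(i + 1L, j,      k + 1L),
                nodeId(i + 1L, j + 1L, k + 1L),
                nodeId(i,      j + 1L, k + 1L))
  used <- sort(unique(as.vector(conn)))
  remap <- integer(nx1 * ny1 * (d[3] + 1L))
  remap[used] <- seq_along(used)
  elems <- matrix(remap[conn], ncol = 8L)
  storage.mode(elems) <- "integer"
  u <- used - 1L
  ui <- u %% nx1
  uj <- (u %/% nx1) %% ny1
  uk <- u %/% (nx1 * ny1)
  nodes <- cbind(volume@origin[1] + (ui - 0.5) * h,
                 volume@origin[2] + (uj - 0.5) * h,
                 volume@origin[3] + (uk - 0.5) * h)
  eov <- array(0L, dim = d)
  eov[vox] <- seq_len(nrow(vox))
  new("HexMesh", nodes = nodes, elems = elems,
      labels = as.integer(lab[vox]), spacing = h,
      voxelIndex = vox, dims = as.integer(d), elemOfVoxel = eov)
}

#' Reference stiffness matrix of the unit-cube trilinear element
#'
#' Exact 8x8 stiffness for sigma = 1 and edge 1 (2-point Gauss per axis is
#' exact for the quadratic integrand). Element matrices are sigma * h * Kref.
#'
#' @return 8 x 8 symmetric matrix (VTK hexahedron corner order).
#' @export
hexRefStiffness <- function() {
  offs <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
                c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
  gp <- c(0.5 - 0.5 / sqrt(3), 0.5 + 0.5 / sqrt(3))
  K <- matrix(0, 8, 8)
  for (gx in gp) for (gy in gp) for (gz in gp) {
    G <- matrix(0, 8, 3)
    for (a in 1:8) {
      o <- offs[a, ]
      f <- c(if (o[1] == 1) gx else 1 - gx,
             if (o[2] == 1) gy else 1 - gy,
             if (o[3] == 1) gz else 1 - gz)
      s <- ifelse(o == 1, 1, -1)
      G[a, ] <- c(s[1] * f[2] * f[3], s[2] * f[1] * f[3], s[3] * f[1] * f[2])
    }
    K <- K + (G %*% t(G)) / 8
  }
  K
}

#' Assemble the FEM stiffness system
#'
#' Galerkin assembly of the quasi-static volume-conduction operator
#' div(sigma grad V) on the regular hexahedral mesh with trilinear shape
#' functions. For cube elements of edge h the element matrix is
#' sigma * h * Kref with Kref the unit-cube reference stiffness, so assembly
#' reduces to a sparse triplet accumulation. The assembled matrix is symmetric
#' positive-semidefinite with the constant vector in its null space; the
#' zero-mean reference constraint is applied at solve time.
#'
#' @param mesh a [HexMesh-class].
#' @param table a [ConductivityTable-class].
#' @return list of class \code{"FEMSystem"}: \code{K} (dgCMatrix, in S, with
#'   node coordinates taken in meters), \code{sigma} per element.
#' @export
assembleSystem <- function(mesh, table) {
  tc <- tissueCodes()
  name <- names(tc)[match(mesh@labels, tc)]
  sig <- table@sigma[name]
  if (anyNA(sig)) stop(sprintf("no conductivity for label(s): %s",
                               paste(unique(name[is.na(sig)]), collapse = ", ")))
  hm <- mesh@spacing / 1000   # mm -> m
  Kref <- hexRefStiffness()
  E <- mesh@elems
  a <- rep(1:8, each = 8); b <- rep(1:8, times = 8)
  ii <- E[, a]; jj <- E[, b]
  vals <- outer(as.numeric(sig) * hm, as.vector(t(Kref)))  # [elem, (a,b)] col idx (a-1)*8+b
  K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                            x = as.vector(vals),
                            dims = c(nrow(mesh@nodes), nrow(mesh@nodes)))
  structure(list(K = K, sigma = as.numeric(sig)), class = "FEMSystem")
}

#' Locate the mesh element containing a point
#'
#' @param mesh a [HexMesh-class].
#' @param p mm position.
#' @return element id, or 0 when the point lies outside the mesh.
#' @export
locateElement <- function(mesh, p) {
  v1 <- mesh@voxelIndex[1, ]
  c1 <- (mesh@nodes[mesh@elems[1, 1], ] + mesh@spacing / 2)
  orig <- c1 - (v1 - 1) * mesh@spacing
  idx <- round((p - orig) / mesh@spacing) + 1L
  d <- mesh@dims
  if (any(idx < 1L) || any(idx > d)) return(0L)
  mesh@elemOfVoxel[idx[1], idx[2], idx[3]]
}

## Nearest mesh element to a point, searching a (2r+1)^3 voxel neighborhood.
locateNearestElement <- function(mesh, p, radius = 3L) {
  el <- locateElement(mesh, p)
  if (el > 0L) return(el)
  v1 <- mesh@voxelIndex[1, ]
  c1 <- (mesh@nodes[mesh@elems[1, 1], ] + mesh@spacing / 2)
  orig <- c1 - (v1 - 1) * mesh@spacing
  idx <- round((p - orig) / mesh@spacing) + 1L
  d <- mesh@dims
  best <- 0L; bestd <- Inf
  for (di in -radius:radius) for (dj in -radius:radius) for (dk in -radius:radius) {
    q <- idx + c(di, dj, dk)
    if (any(q < 1L) || any(q > d)) next
    e <- mesh@elemOfVoxel[q[1], q[2], q[3]]
    if (e > 0L) {
      ctr <- orig + (q - 1) * mesh@spacing
      dd <- sum((ctr - p)^2)
      if (dd < bestd) { bestd <- dd; best <- e }
    }
  }
  best
}

#' St. Venant dipole load vector
#'
#' Distributes a point current dipole onto monopole loads at the nodes of the
#' element containing the dipole and its vertex-neighbor elements: the
#' minimum-norm load set whose zeroth moment vanishes (charge conservation)
#' and whose first moment about the dipole position equals the dipole moment
#' exactly (relative error < 1e-8 by construction).
#'
#' @param dipole a [DipoleSource-class].
#' @param mesh a [HexMesh-class].
#' @return numeric load vector (A) over mesh nodes, zero outside the
#'   neighborhood; attribute \code{nodes} lists the loaded node ids.
#' @export
stVenantLoad <- function(dipole, mesh) {
  el <- locateElement(mesh, dipole@position)
  if (el == 0L) stop("dipole lies outside the mesh")
  vi <- mesh@voxelIndex[el, ]
  d <- mesh@dims
  nbr <- integer(0)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    q <- vi + c(di, dj, dk)
    if (any(q < 1L) || any(q > d)) next
    e <- mesh@elemOfVoxel[q[1], q[2], q[3]]
    if (e > 0L) nbr <- c(nbr, e)
  }
  nodes <- sort(unique(as.vector(mesh@elems[nbr, ])))
  R <- (mesh@nodes[nodes, , drop = FALSE] - matrix(dipole@position, length(nodes), 3,
                                                   byrow = TRUE)) / 1000  # m
  X <- rbind(1, t(R))                       # 4 x K constraints
  tgt <- c(0, dipole@orientation * dipole@moment)
  q <- t(X) %*% solve(X %*% t(X), tgt)      # minimum-norm exact-constraint fit
  load <- numeric(nrow(mesh@nodes))
  load[nodes] <- as.numeric(q)
  attr(load, "nodes") <- nodes
  load
}

## Jacobi-preconditioned conjugate gradients for the singular consistent
## system K x = b (constant null space); returns zero-mean solution.
pcgSolve <- function(K, b, tol = 1e-9, maxit = 30000L) {
  b <- b - mean(b)
  M <- Matrix::diag(K)
  if (any(M <= 0)) stop("non-positive diagonal in stiffness matrix")
  x <- numeric(length(b))
  r <- b
  z <- r / M
  p <- z
  rz <- sum(r * z)
  nb <- sqrt(sum(b * b))
  if (nb == 0) return(list(x = x, residual = 0, iterations = 0L))
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(K %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rn <- sqrt(sum(r * r))
    if (rn / nb <= tol) {
      x <- x - mean(x)
      return(list(x = x, residual = rn / nb, iterations = it))
    }
    z <- r / M
    rz2 <- sum(r * z)
    beta <- rz2 / rz
    rz <- rz2
    p <- z + beta * p
  }
  stop(sprintf("conjugate gradients did not converge in %d iterations (residual %.3g)",
               maxit, rn / nb))
}

#' Trilinear interpolation of nodal values
#'
#' Interpolates node values at arbitrary points; points falling in background
#' voxels (the staircase surface) clamp to the nearest mesh element.
#'
#' @param mesh a [HexMesh-class].
#' @param values per-node values.
#' @param points n x 3 mm positions.
#' @return interpolated values.
#' @export
interpolateAt <- function(mesh, values, points) {
  points <- rbind(points)
  out <- numeric(nrow(points))
  h <- mesh@spacing
  for (q in seq_len(nrow(points))) {
    el <- locateNearestElement(mesh, points[q, ])
    if (el == 0L) stop("point too far outside the mesh to interpolate")
    nd <- mesh@elems[el, ]
    p0 <- mesh@nodes[nd[1], ]
    t3 <- pmin(1, pmax(0, (points[q, ] - p0) / h))
    w <- c((1 - t3[1]) * (1 - t3[2]) * (1 - t3[3]),
           t3[1] * (1 - t3[2]) * (1 - t3[3]),
           t3[1] * t3[2] * (1 - t3[3]),
           (1 - t3[1]) * t3[2] * (1 - t3[3]),
           (1 - t3[1]) * (1 - t3[2]) * t3[3],
           t3[1] * (1 - t3[2]) * t3[3],
           t3[1] * t3[2] * t3[3],
           (1 - t3[1]) * t3[2] * t3[3])
    out[q] <- sum(w * values[nd])
  }
  out
}

#' Solve the forward problem
#'
#' Solves the assembled system for a load vector with Jacobi-preconditioned
#' conjugate gradients (relative residual <= tol), interpolates electrode
#' potentials at the contact positions and re-references them, and extracts
#' the electric field E = -grad V from trilinear gradients at the centroids of
#' the elements of the requested tissue region (default gray matter).
#'
#' @param system a \code{"FEMSystem"} from [assembleSystem()].
#' @param load node load vector from [stVenantLoad()] (superpose loads for
#'   multi-dipole source models).
#' @param mesh the [HexMesh-class] the system was assembled from.
#' @param electrodes optional [ElectrodeSet-class]; potentials are
#'   interpolated at contact centers and re-referenced per its scheme.
#' @param region tissue name for field extraction (default "gray").
#' @param tol relative residual tolerance.
#' @param maxit iteration cap.
#' @return A [ForwardSolution-class].
#' @export
solveForward <- function(system, load, mesh, electrodes = NULL,
                         region = "gray", tol = 1e-9, maxit = 30000L) {
  sol <- pcgSolve(system$K, as.numeric(load), tol = tol, maxit = maxit)
  V <- sol$x
  ep <- numeric(0)
  if (!is.null(electrodes)) {
    ep <- interpolateAt(mesh, V, electrodes@positions)
    names(ep) <- electrodes@labels
    if (electrodes@reference == "CAR") ep <- ep - mean(ep)
    else {
      ref <- sub("^single:", "", electrodes@reference)
      ep <- ep - ep[[ref]]
    }
  }
  gsel <- which(mesh@labels == tissueCodes()[[region]])
  hm <- mesh@spacing / 1000
  E <- matrix(0, length(gsel), 3)
  if (length(gsel)) {
    Vm <- matrix(V[mesh@elems[gsel, ]], length(gsel), 8)
    E[, 1] <- -(Vm[, 2] - Vm[, 1] + Vm[, 3] - Vm[, 4] + Vm[, 6] - Vm[, 5] + Vm[, 7] - Vm[, 8]) / (4 * hm)
    E[, 2] <- -(Vm[, 4] - Vm[, 1] + Vm[, 3] - Vm[, 2] + Vm[, 8] - Vm[, 5] + Vm[, 7] - Vm[, 6]) / (4 * hm)
    E[, 3] <- -(Vm[, 5] - Vm[, 1] + Vm[, 6] - Vm[, 2] + Vm[, 7] - Vm[, 3] + Vm[, 8] - Vm[, 4]) / (4 * hm)
  }
  new("ForwardSolution", potentials = V, electrodePotentials = ep,
      efVectors = E, efMag = sqrt(rowSums(E^2)), grayElems = as.integer(gsel),
      residual = sol$residual, iterations = sol$iterations)
}

#' Topography and magnitude error metrics
#'
#' RDM (relative difference measure) compares the shapes of two potential
#' vectors after norm scaling, lnMAG their magnitudes:
#' RDM = || a/||a|| - b/||b|| || in \code{[0, 2]}; lnMAG = ln(||a||/||b||).
#'
#' @param a,b numeric potential vectors of equal length.
#' @return list(RDM, lnMAG).
#' @export
errorMetrics <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-norm input")
  list(RDM = sqrt(sum((a / na - b / nb)^2)), lnMAG = log(na / nb))
}

#' Element centroids
#'
#' @param mesh a [HexMesh-class].
#' @param elems element ids (default all).
#' @return n x 3 mm centroid positions.
#' @export
elementCentroids <- function(mesh, elems = seq_len(nrow(mesh@elems))) {
  p <- mesh@nodes[mesh@elems[elems, 1], , drop = FALSE]
  p + mesh@spacing / 2
}
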