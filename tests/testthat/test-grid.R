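## Lattice-triangulated test surfaces.
latticeSurface <- function(X, Y, Z, n) {
  idx <- function(i, j) (i - 1L) * n + j
  tri <- NULL
  for (i in seq_len(n - 1)) for (j in seq_len(n - 1)) {
    tri <- rbind(tri, c(idx(i, j), idx(i, j + 1), idx(i + 1, j)),
                      c(idx(i + 1, j), idx(i, j + 1), idx(i + 1, j + 1)))
  }
  triSurface(cbind(as.vector(X), as.vector(Y), as.vector(Z)), tri)
}

quarterCylinder <- function(r = 40, len = 60, n = 25) {
  th <- seq(0, pi / 2, length.out = n)
  zz <- seq(0, len, length.out = n)
  V <- NULL
  for (z in zz) V <- rbind(V, cbind(r * cos(th), r * sin(th), z))
  idx <- function(i, j) (i - 1L) * n + j
  tri <- NULL
  for (i in seq_len(n - 1)) for (j in seq_len(n - 1)) {
    tri <- rbind(tri, c(idx(i, j), idx(i, j + 1), idx(i + 1, j)),
                      c(idx(i + 1, j), idx(i, j + 1), idx(i + 1, j + 1)))
  }
  list(surface = triSurface(V, tri), th = th, zz = zz, r = r, n = n,
       idx = idx)
}

test_that("shrinkwrap reproduces spheres and bridges gyral ripples", {
  s <- icosphere(3, radius = 40)
  h <- shrinkwrap(s)
  hr <- sqrt(rowSums(h@vertices^2))
  expect_true(all(abs(hr - 40) / 40 < 0.02))

  a <- 3
  sb <- icosphere(4, radius = 40, bumpAmplitude = a)
  hb <- shrinkwrap(sb)
  hbr <- sqrt(rowSums(hb@vertices^2))
  expect_lt((max(hbr) - min(hbr)) / 2, a / 3)

  ## enclosure: along every input direction the hull is at least as far out
  tn <- sb@vertices / sqrt(rowSums(sb@vertices^2))
  hn <- hb@vertices / sqrt(rowSums(hb@vertices^2))
  hullR <- apply(tn, 1, function(u) sqrt(sum(hb@vertices[which.max(hn %*% u), ]^2)))
  expect_gt(min(hullR - sqrt(rowSums(sb@vertices^2))), -0.3)

  open <- triSurface(s@vertices, s@triangles[-1, ])
  expect_error(shrinkwrap(open), "closed")
})

test_that("patch extraction returns a bounded region containing the corners", {
  h <- shrinkwrap(icosphere(3, radius = 40))
  corners <- rbind(c(40, 12, 12), c(40, -12, 12), c(40, -12, -12), c(40, 12, -12))
  patch <- extractPatch(h, corners)
  expect_s4_class(patch, "TriSurface")
  expect_true(all(attr(patch, "hullVertices") %in% seq_len(nrow(h@vertices))))
  ## patch vertices are a subset of hull vertices
  expect_true(all(patch@vertices[, 1] > 0))
  ## boundary passes near every corner
  ci <- attr(patch, "corners")
  for (k in 1:4) {
    d <- sqrt(sum((patch@vertices[ci[k], ] -
                   corners[k, ] / sqrt(sum(corners[k, ]^2)) * 40)^2))
    expect_lt(d, 10)
  }
  ## much smaller than the full hull
  expect_lt(nrow(patch@vertices), nrow(h@vertices) / 2)
})

test_that("planar patches embed isometrically", {
  n <- 15
  g <- seq(0, 28, length.out = n)
  G <- expand.grid(x = g, y = g)
  flat <- latticeSurface(matrix(G$x, n), matrix(G$y, n), matrix(0, n, n), n)
  emb <- embedPatch2D(flat)
  d3 <- dist(flat@vertices)
  d2 <- dist(emb)
  expect_lt(max(abs(d2 - d3)) / max(d3), 1e-6)
  ## output is intrinsically 2-D
  sv <- svd(scale(emb, scale = FALSE))$d
  expect_lt(length(sv), 3.5)  # 2 columns by construction
})

test_that("developable patches embed with small geodesic distortion", {
  qc <- quarterCylinder()
  emb <- embedPatch2D(qc$surface)
  set.seed(1)
  pr <- cbind(sample(qc$n^2, 400, TRUE), sample(qc$n^2, 400, TRUE))
  pr <- pr[pr[, 1] != pr[, 2], ]
  i1 <- pr[, 1]; i2 <- pr[, 2]
  t1 <- qc$th[(i1 - 1) %% qc$n + 1]; t2 <- qc$th[(i2 - 1) %% qc$n + 1]
  z1 <- qc$zz[(i1 - 1) %/% qc$n + 1]; z2 <- qc$zz[(i2 - 1) %/% qc$n + 1]
  true <- sqrt((qc$r * (t1 - t2))^2 + (z1 - z2)^2)
  est <- sqrt(rowSums((emb[i1, ] - emb[i2, ])^2))
  expect_lt(median(abs(est - true) / true), 0.02)
  ## third dimension is negligible: residual MDS eigenvalues are small
  eig <- attr(emb, "eig")
  expect_lt(abs(eig[3]) / eig[1], 0.02)
})

test_that("embedding stress decreases with patch refinement on a developable surface", {
  stress <- sapply(c(13, 25), function(n) {
    qc <- quarterCylinder(n = n)
    emb <- embedPatch2D(qc$surface)
    i <- seq_len(n^2)
    t0 <- qc$th[(i - 1) %% n + 1]; z0 <- qc$zz[(i - 1) %/% n + 1]
    true <- dist(cbind(qc$r * t0, z0))
    est <- dist(emb)
    sqrt(sum((est - true)^2) / sum(true^2))
  })
  expect_lt(stress[2], stress[1])
})

test_that("lattice placement gives a 10-mm grid with surface back-projection", {
  n <- 15
  g <- seq(0, 42, length.out = n)
  G <- expand.grid(x = g, y = g)
  flat <- latticeSurface(matrix(G$x, n), matrix(G$y, n), matrix(0, n, n), n)
  emb <- embedPatch2D(flat)
  idx <- function(i, j) (j - 1L) * n + i
  corners <- c(idx(2, 2), idx(14, 2), idx(14, 14), idx(2, 14))
  pl <- placeAndTriangulate(flat, emb, gridLayout(2, 2), corners = corners)
  d <- as.matrix(dist(pl$centers2d))
  expect_equal(sort(d[upper.tri(d)]), c(10, 10, 10, 10, sqrt(200), sqrt(200)),
               tolerance = 1e-6)
  expect_equal(max(abs(pl$centers3d[, 3])), 0, tolerance = 1e-9)

  qc <- quarterCylinder()
  embc <- embedPatch2D(qc$surface)
  cc <- c(qc$idx(3, 3), qc$idx(3, 23), qc$idx(23, 23), qc$idx(23, 3))
  plc <- placeAndTriangulate(qc$surface, embc, gridLayout(4, 4), corners = cc)
  p3 <- plc$centers3d
  ## back-projected centers lie on the cylinder within one edge length
  expect_lt(max(abs(sqrt(p3[, 1]^2 + p3[, 2]^2) - qc$r)), 3)
  ## geodesic spacing between lattice neighbors is the pitch
  thp <- atan2(p3[, 2], p3[, 1]); zp <- p3[, 3]
  sp <- c()
  for (r in 0:3) for (c in 0:2) {
    i <- r * 4 + c + 1
    sp <- c(sp, sqrt((qc$r * (thp[i] - thp[i + 1]))^2 + (zp[i] - zp[i + 1])^2))
  }
  for (r in 0:2) for (c in 0:3) {
    i <- r * 4 + c + 1
    sp <- c(sp, sqrt((qc$r * (thp[i] - thp[i + 4]))^2 + (zp[i] - zp[i + 4])^2))
  }
  expect_true(all(abs(sp - 10) <= 0.5))

  expect_error(placeAndTriangulate(flat, emb, gridLayout(9, 9), corners = corners),
               "exceeds")
})
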