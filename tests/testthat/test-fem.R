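## Simple Gauss-Legendre nodes/weights on [0, 1] via the Golub-Welsch
## eigenvalue construction (test-local oracle helper).
statmodLikeGauss <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- (e$values + 1) / 2
  w <- (e$vectors[1, ]^2) / 2 * 2
  ord <- order(x)
  list(x = x[ord], w = w[ord] / sum(w))
}

test_that("meshing a uniform block gives the full node lattice", {
  lab <- array(tissueCodes()[["gray"]], dim = c(4, 4, 4))
  vol <- new("LabeledVolume", labels = lab, spacing = 1, origin = c(0, 0, 0))
  mesh <- meshFromVolume(vol)
  expect_identical(nrow(mesh@elems), 64L)
  expect_identical(nrow(mesh@nodes), 125L)
  expect_true(all(mesh@labels == tissueCodes()[["gray"]]))
  ## adjacent voxels share exactly 4 nodes
  e1 <- mesh@elems[mesh@elemOfVoxel[1, 1, 1], ]
  e2 <- mesh@elems[mesh@elemOfVoxel[2, 1, 1], ]
  expect_identical(length(intersect(e1, e2)), 4L)
})

test_that("reference stiffness matches an independent dense quadrature", {
  K <- hexRefStiffness()
  expect_equal(K, t(K))
  expect_equal(max(abs(rowSums(K))), 0, tolerance = 1e-14)
  ## oracle: 5-point Gauss-Legendre per axis, independent implementation
  offs <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
                c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
  gl <- statmodLikeGauss(5)
  Ko <- matrix(0, 8, 8)
  for (ix in 1:5) for (iy in 1:5) for (iz in 1:5) {
    p <- c(gl$x[ix], gl$x[iy], gl$x[iz])
    w <- gl$w[ix] * gl$w[iy] * gl$w[iz]
    G <- t(vapply(1:8, function(a) {
      o <- offs[a, ]
      f <- ifelse(o == 1, p, 1 - p)
      s <- ifelse(o == 1, 1, -1)
      c(s[1] * f[2] * f[3], s[2] * f[1] * f[3], s[3] * f[1] * f[2])
    }, numeric(3)))
    Ko <- Ko + w * (G %*% t(G))
  }
  expect_equal(K, Ko, tolerance = 1e-12)
})

test_that("assembly is linear in conductivity and has the constant null space", {
  vol <- sphereVolume(16, 8)
  mesh <- meshFromVolume(vol)
  t1 <- sphereConductivities(1, 0.33)
  t2 <- sphereConductivities(1, 0.66)
  K1 <- assembleSystem(mesh, t1)$K
  K2 <- assembleSystem(mesh, t2)$K
  expect_equal(max(abs(K2 - 2 * K1)), 0, tolerance = 1e-18)
  ones <- rep(1, nrow(mesh@nodes))
  expect_lt(max(abs(K1 %*% ones)), 1e-12)
  expect_equal(K1, Matrix::t(K1))
  bad <- new("ConductivityTable", sigma = c(white = 0.14))
  expect_error(assembleSystem(mesh, bad), "no conductivity")
})

test_that("St. Venant loads conserve charge and reproduce the dipole moment", {
  vol <- sphereVolume(20, 4)
  mesh <- meshFromVolume(vol)
  for (ori in list(c(0, 0, 1), c(1, 0, 0), c(1, 1, 1) / sqrt(3))) {
    dip <- new("DipoleSource", position = c(3, -2, 5), orientation = ori,
               moment = 2.5e-8)
    load <- stVenantLoad(dip, mesh)
    expect_equal(sum(load), 0, tolerance = 1e-20)
    nodes <- attr(load, "nodes")
    R <- (mesh@nodes[nodes, ] - matrix(dip@position, length(nodes), 3,
                                       byrow = TRUE)) / 1000
    m <- as.numeric(t(R) %*% load[nodes])
    expect_lt(max(abs(m - ori * 2.5e-8)) / 2.5e-8, 1e-8)
  }
  dip1 <- new("DipoleSource", position = c(0, 0, 0), orientation = c(0, 0, 1),
              moment = 1e-8)
  dip2 <- new("DipoleSource", position = c(0, 0, 0), orientation = c(0, 0, 1),
              moment = 2e-8)
  expect_equal(stVenantLoad(dip2, mesh), 2 * stVenantLoad(dip1, mesh),
               ignore_attr = TRUE)
  out <- new("DipoleSource", position = c(500, 0, 0), orientation = c(0, 0, 1),
             moment = 1e-8)
  expect_error(stVenantLoad(out, mesh), "outside")
})

test_that("forward solutions superpose and scale with the moment", {
  vol <- sphereVolume(20, 4)
  mesh <- meshFromVolume(vol)
  sys <- assembleSystem(mesh, sphereConductivities(1, 0.33))
  d1 <- new("DipoleSource", position = c(4, 0, 0), orientation = c(0, 0, 1),
            moment = 1e-8)
  d2 <- new("DipoleSource", position = c(-4, 0, 2), orientation = c(1, 0, 0),
            moment = 1e-8)
  l1 <- stVenantLoad(d1, mesh); l2 <- stVenantLoad(d2, mesh)
  s1 <- solveForward(sys, l1, mesh)
  s2 <- solveForward(sys, l2, mesh)
  s12 <- solveForward(sys, l1 + l2, mesh)
  expect_equal(s12@potentials, s1@potentials + s2@potentials,
               tolerance = 1e-6)
  s10 <- solveForward(sys, 10 * l1, mesh)
  expect_equal(s10@potentials, 10 * s1@potentials, tolerance = 1e-7)
  expect_equal(s10@efMag, 10 * s1@efMag, tolerance = 1e-6)
  expect_lt(s1@residual, 1e-9)
  expect_equal(mean(s1@potentials), 0, tolerance = 1e-12)
})

test_that("central dipole matches the closed-form pole potential", {
  sig <- 0.33; R <- 100; p <- 1e-8
  dip <- new("DipoleSource", position = c(0, 0, 0), orientation = c(0, 0, 1),
             moment = p)
  v <- validateSphere(R, sig, dip, spacing = 4, nPoints = 200)
  expect_lt(v$RDM, 0.05)
  closed <- 3 * p / (4 * pi * sig * (R / 1000)^2)
  expect_equal(closed, 0.723e-6, tolerance = 1e-3)
  pole <- analyticSphere(R, sig, dip, rbind(c(0, 0, R)))
  expect_equal(pole, closed, tolerance = 1e-9)
})

test_that("RDM and lnMAG behave as topography and magnitude metrics", {
  a <- c(1, -2, 3, 0.5)
  m <- errorMetrics(a, a)
  expect_equal(m$RDM, 0); expect_equal(m$lnMAG, 0)
  m2 <- errorMetrics(2 * a, a)
  expect_equal(m2$RDM, 0); expect_equal(m2$lnMAG, log(2))
  m3 <- errorMetrics(-a, a)
  expect_equal(m3$RDM, 2); expect_equal(m3$lnMAG, 0)
  expect_error(errorMetrics(c(0, 0), c(1, 1)), "zero-norm")
})

test_that("refining the mesh reduces the oracle mismatch", {
  dip <- new("DipoleSource", position = c(0, 0, 30), orientation = c(1, 0, 0),
             moment = 1e-8)
  coarse <- validateSphere(60, 0.33, dip, spacing = 8, nPoints = 120)
  fine <- validateSphere(60, 0.33, dip, spacing = 4, nPoints = 120)
  expect_lt(fine$RDM, coarse$RDM)
})

test_that("CAR electrode potentials are reference-invariant", {
  vol <- sphereVolume(20, 4)
  mesh <- meshFromVolume(vol)
  pts <- fibonacciSphere(12) * 16
  el <- new("ElectrodeSet", labels = sprintf("e%02d", 1:12), positions = pts,
            kind = rep("scalp", 12), reference = "CAR")
  sys <- assembleSystem(mesh, sphereConductivities(1, 0.33))
  d <- new("DipoleSource", position = c(4, 0, 0), orientation = c(0, 0, 1),
           moment = 1e-8)
  sol <- solveForward(sys, stVenantLoad(d, mesh), mesh, electrodes = el)
  shifted <- interpolateAt(mesh, sol@potentials + 0.123, pts)
  expect_equal(unname(sol@electrodePotentials), shifted - mean(shifted),
               tolerance = 1e-9)
})

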