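test_that("source models carry the required dipole counts inside muscle", {
  spec <- defaultSpecFixture()
  vol <- buildPhantom(spec, "HM3")
  mesh <- meshFromVolume(vol)
  counts <- c(SM1 = 1L, SM2 = 8L, SM3 = 1L)
  for (nm in names(counts)) {
    sm <- makeSourceModel(nm, spec)
    expect_identical(length(sm@dipoles), counts[[nm]])
    for (d in sm@dipoles) {
      el <- locateElement(mesh, d@position)
      expect_identical(mesh@labels[el], tissueCodes()[["muscle"]])
    }
  }
})

test_that("insulating grid shields the sub-grid contacts (variant ordering)", {
  ctx <- contextFixture()
  out <- runHeadModelSuite(ctx, makeSourceModel("SM1", defaultSpecFixture()))
  s <- out$summary
  p <- structure(s$peakSubgridPower_uV2, names = s$variant)
  ## closing craniotomy defects reduces intracranial EMG power
  expect_lt(p[["HM2"]], p[["HM1"]])
  ## removing the insulating grid outweighs closing the defects
  expect_gt(p[["HM3"]], p[["HM1"]])
})

test_that("the field runs parallel to the insulator faces", {
  ctx <- contextFixture()
  spec <- defaultSpecFixture()
  sol <- runHeadModelSuite(ctx, makeSourceModel("SM1", spec))$solutions[["HM1"]]
  mesh <- ctx$variants[["HM1"]]$mesh
  tc <- tissueCodes()
  ## gray elements directly beneath the central region of the insulator patch:
  ## field normal component (x, the drape axis) must be a small fraction of
  ## the magnitude
  cents <- elementCentroids(mesh, sol@grayElems)
  lat <- sqrt(cents[, 2]^2 + cents[, 3]^2)
  gR <- spec@radii[["gray"]]
  sel <- lat < 10 & cents[, 1] > gR - 4 & cents[, 1] > 0
  expect_gt(sum(sel), 3)
  frac <- abs(sol@efVectors[sel, 1]) / sol@efMag[sel]
  expect_lt(median(frac), 0.10)
})

test_that("reconstructed and rasterized grids shield like the built-in patch", {
  ## end-to-end: shrinkwrap a hull over the cortex sphere, extract the +x
  ## patch, embed, place a 4x4 grid, rasterize it as insulator into the
  ## intact phantom, and check both the seal and the shielding direction
  spec <- defaultSpecFixture()
  noGrid <- phantomSpec(grid = NULL)
  vol <- buildPhantom(noGrid, "HM3")
  hull <- shrinkwrap(icosphere(3, radius = spec@radii[["gray"]] + 1))
  ## the sheet must extend a few mm beyond the contact lattice (as the real
  ## silicone does): a rim-adjacent contact sees wrap-around fields instead
  ## of shielding
  corners <- rbind(c(40, 22, 22), c(40, -22, 22), c(40, -22, -22), c(40, 22, -22))
  patch <- extractPatch(hull, corners)
  emb <- embedPatch2D(patch)
  pl <- placeAndTriangulate(patch, emb, gridLayout(4, 4))
  sheet <- triSurface(patch@vertices, patch@triangles)
  mask <- rasterizeSurface(sheet, vol, thickness_mm = 4,
                           orientAwayFrom = c(0, 0, 0))
  expect_true(sealCheck(mask)$pass)

  lab <- labelArray(vol)
  tc <- tissueCodes()
  editable <- lab %in% tc[c("CSF", "skull")]
  lab2 <- lab
  lab2[mask & array(editable, dim = dim(lab))] <- tc[["grid_insulator"]]
  volG <- new("LabeledVolume", labels = lab2, spacing = vol@spacing,
              origin = vol@origin)

  ## contacts at the back-projected lattice, nudged under the sheet
  pos <- pl$centers3d * (1 - 2 / spec@radii[["gray"]])
  el <- new("ElectrodeSet", labels = sprintf("G%02d", 1:16), positions = pos,
            kind = rep("subdural", 16), reference = "CAR")
  tab <- defaultConductivityTable()
  sm <- makeSourceModel("SM1", spec)
  power <- sapply(list(vol, volG), function(v) {
    mesh <- meshFromVolume(v)
    sys <- assembleSystem(mesh, tab)
    sol <- solveForward(sys, sourceLoad(sm, mesh), mesh, electrodes = el)
    max(sol@electrodePotentials^2)
  })
  expect_lt(power[2], power[1])
})

test_that("unit forward constants are positive, linear, and foramen-sensitive", {
  u1 <- unitForwardFixture("SM1")
  expect_gt(u1@gridMeasure_uV, 0)
  expect_gt(u1@peakEF_Vpm, 0)

  ## linearity: doubling all dipole moments doubles the raw solves, so the
  ## per-unit-moment constants are invariant to the probe moment
  ctx <- contextFixture()
  spec <- defaultSpecFixture()
  u2 <- unitForward(ctx, makeSourceModel("SM1", spec, moment = 2))
  expect_equal(u2@gridMeasure_uV, u1@gridMeasure_uV, tolerance = 1e-6)
  expect_equal(u2@peakEF_Vpm, u1@peakEF_Vpm, tolerance = 1e-6)

  ## the pterygoid source in front of the foramen channel delivers more
  ## cortical field per recorded sub-grid microvolt than the belly source
  u3 <- unitForwardFixture("SM3")
  expect_gt(u3@peakEF_Vpm / u3@gridMeasure_uV,
            u1@peakEF_Vpm / u1@gridMeasure_uV)
})
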