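test_that("head-model variants differ only at defect and grid voxels", {
  spec <- defaultSpecFixture()
  v1 <- labelArray(buildPhantom(spec, "HM1"))
  v2 <- labelArray(buildPhantom(spec, "HM2"))
  v3 <- labelArray(buildPhantom(spec, "HM3"))
  tc <- tissueCodes()

  d12 <- which(v1 != v2)
  expect_true(all(v1[d12] == tc[["defect_fill"]]))
  expect_true(all(v2[d12] == tc[["skull"]]))

  d23 <- which(v2 != v3)
  expect_true(all(v2[d23] == tc[["grid_insulator"]]))

  ## everything outside defect + grid voxels is identical across variants
  touched <- union(d12, d23)
  expect_identical(v1[-touched], v3[-touched])
  ## foramen is anatomy: present in all variants
  expect_identical(sum(v1 == tc[["foramen_fill"]]), sum(v3 == tc[["foramen_fill"]]))
})

test_that("defect-free spec gives concentric shells with white at the center", {
  spec <- phantomSpec(burrHoles = NULL, sawLines = NULL, foramen = NULL,
                      grid = NULL)
  vol <- buildPhantom(spec, "HM3")
  lab <- labelArray(vol)
  ctr <- (dim(lab) + 1) / 2
  expect_identical(lab[ctr[1], ctr[2], ctr[3]], tissueCodes()[["white"]])
  expect_setequal(unique(as.vector(lab)),
                  tissueCodes()[c("background", "soft_tissue", "skull", "CSF",
                                  "gray", "white", "muscle")])
})

test_that("burr-hole voxel count matches the analytic cylinder volume", {
  spec <- defaultSpecFixture()
  base <- phantomSpec(burrHoles = NULL, sawLines = NULL,
                      foramen = spec@foramen, grid = spec@grid)
  one <- phantomSpec(burrHoles = rbind(c(spec@burrHoles[1, 1:3], 12)),
                     sawLines = NULL, foramen = spec@foramen, grid = spec@grid)
  nDefect <- sum(labelArray(buildPhantom(one, "HM1")) ==
                 tissueCodes()[["defect_fill"]])
  ## cylinder through the skull shell: radius 6 mm, length = shell thickness
  shell <- spec@radii[["skull"]] - spec@radii[["csf"]]
  expected <- pi * 6^2 * shell / one@spacing^3
  expect_gt(nDefect, 0.8 * expected)
  expect_lt(nDefect, 1.2 * expected)
})

test_that("defect cylinders that miss the skull are rejected", {
  ## a cylinder too thin to catch any skull voxel at this resolution (its
  ## axis runs between voxel centers)
  bad2 <- phantomSpec(burrHoles = rbind(c(1, 0.41, 0.33, 0.01)), sawLines = NULL)
  expect_error(buildPhantom(bad2, "HM1"), "misses the skull")
})

test_that("grid insulator voxels form a face-sealed set on the gray surface", {
  spec <- defaultSpecFixture()
  vol <- buildPhantom(spec, "HM2")
  tc <- tissueCodes()
  mask <- labelArray(vol) == tc[["grid_insulator"]]
  expect_true(sealCheck(mask)$pass)
  ## insulator sits just above gray matter: every patch column has gray below
  w <- which(mask, arr.ind = TRUE)
  lab <- labelArray(vol)
  below <- lab[cbind(pmax(w[, 1] - 3L, 1L), w[, 2], w[, 3])]
  expect_gt(mean(below %in% tc[c("gray", "grid_insulator")]), 0.9)
})

test_that("seal check accepts slabs and rejects edge and corner contacts", {
  slab <- array(FALSE, dim = c(6, 6, 6)); slab[2:5, 2:5, 3:4] <- TRUE
  expect_true(sealCheck(slab)$pass)

  edge <- array(FALSE, dim = c(6, 6, 6))
  edge[2:3, 2:3, 2] <- TRUE; edge[4:5, 4:5, 2] <- TRUE
  edge[3, 4, 2] <- FALSE; edge[4, 3, 2] <- FALSE
  sc <- sealCheck(edge)
  expect_false(sc$pass)
  expect_gt(nrow(sc$leaks), 0)

  checker <- array(FALSE, dim = c(6, 6, 2))
  idx <- which(array(TRUE, dim = c(6, 6, 1)), arr.ind = TRUE)
  checker[cbind(idx[, 1], idx[, 2], 1L)] <- (idx[, 1] + idx[, 2]) %% 2 == 0
  expect_false(sealCheck(checker)$pass)

  corner <- array(FALSE, dim = c(4, 4, 4))
  corner[2, 2, 2] <- TRUE; corner[3, 3, 3] <- TRUE
  expect_false(sealCheck(corner)$pass)
})

test_that("electrode placement follows the grid lattice and phantom surfaces", {
  spec <- defaultSpecFixture()
  vol <- buildPhantom(spec, "HM3")
  el <- placeElectrodes(spec, vol)
  sub <- electrodeKinds(el) == "subdural"
  expect_identical(sum(sub), 16L)
  p <- electrodePositions(el)[sub, ]
  nn <- as.matrix(dist(p)); diag(nn) <- Inf
  expect_true(all(abs(apply(nn, 1, min) - 10) <= 1))
  ## contacts lie within half a voxel of their nominal (offset) surface
  rNominal <- spec@radii[["gray"]] - spec@spacing / 2
  expect_true(all(abs(sqrt(rowSums(p^2)) - rNominal) <= spec@spacing / 2))
  sc <- electrodePositions(el)[!sub, ]
  expect_true(all(abs(sqrt(rowSums(sc^2)) - spec@radii[["scalp"]]) < 1e-6))

  only <- placeElectrodes(spec, vol, nScalp = 0)
  expect_true(all(electrodeKinds(only) == "subdural"))

  big <- phantomSpec(grid = list(rows = 9, cols = 9, pitch_mm = 10,
                                 contactDiameter_mm = 4, thicknessVox = 3,
                                 capRadius_mm = 26))
  expect_error(placeElectrodes(big, vol), "too small|exceeds")
})

test_that("the scaling table holds the six condition amplitudes", {
  tab <- conditionAmplitudes(defaultScalingTable())
  expect_identical(tab[["gum"]], 107.3)
  expect_identical(tab[["licorice"]], 155.2)
  expect_identical(unname(tab), c(46.6, 45.7, 116.4, 107.3, 139.9, 155.2))
  expect_true(all(tab > 0))
})
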