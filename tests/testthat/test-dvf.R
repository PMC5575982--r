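test_that("field inversion matches closed forms", {
  g <- voxelGrid(c(32, 32, 32), 2)
  # zero field
  z <- invertDvf(displacementField(0, g, "forward"))
  expect_equal(max(abs(volumeValues(z))), 0)
  # uniform translation inverts exactly
  v <- array(0, dim = c(32, 32, 32, 3)); v[, , , 3] <- 7.3; v[, , , 2] <- -2.1
  b <- invertDvf(displacementField(v, g, "forward"))
  expect_lt(max(abs(volumeValues(b)[, , , 3] + 7.3)), 1e-6)
  expect_lt(max(abs(volumeValues(b)[, , , 2] - 2.1)), 1e-6)
  # 1-D linear field u = alpha z zhat  ->  u_b = -alpha z / (1 + alpha)
  alpha <- 0.4
  ax <- worldAxes(g)
  v2 <- array(0, dim = c(32, 32, 32, 3))
  v2[, , , 3] <- rep(alpha * ax$z, each = 32 * 32)
  b2 <- invertDvf(displacementField(v2, g, "forward"))
  got <- volumeValues(b2)[16, 16, , 3]
  want <- -alpha * ax$z / (1 + alpha)
  expect_lt(max(abs(got[4:28] - want[4:28])), 0.02)
})

test_that("repair restores isolated outliers and nothing else", {
  g <- voxelGrid(c(24, 24, 24), 2)
  ax <- worldAxes(g)
  v <- array(0, dim = c(24, 24, 24, 3))
  v[, , , 3] <- rep(0.05 * ax$z, each = 24 * 24)   # smooth ramp
  clean <- displacementField(v, g, "forward")
  expect_equal(volumeValues(repairDvf(clean)), volumeValues(clean))

  # single injected 10 mm outlier is replaced by the local median
  v1 <- v; v1[12, 12, 12, 3] <- v1[12, 12, 12, 3] + 10
  rep1 <- repairDvf(displacementField(v1, g, "forward"))
  expect_lt(abs(volumeValues(rep1)[12, 12, 12, 3] - v[12, 12, 12, 3]), 0.2)
  untouched <- volumeValues(rep1)[-12, , , 3]
  expect_equal(untouched, v[-12, , , 3])
  # idempotence
  rep2 <- repairDvf(rep1)
  expect_equal(volumeValues(rep2), volumeValues(rep1))

  # a coherent 4^3 cluster is not "isolated" and survives
  v3 <- v; v3[10:13, 10:13, 10:13, 3] <- v3[10:13, 10:13, 10:13, 3] + 10
  rep3 <- repairDvf(displacementField(v3, g, "forward"))
  expect_equal(volumeValues(rep3)[11:12, 11:12, 11:12, 3],
               v3[11:12, 11:12, 11:12, 3])
})

test_that("warping is exact for identity, integer shifts and linear ramps", {
  g <- voxelGrid(c(24, 24, 24), 2)
  set.seed(9)
  vol <- imageVolume(array(runif(24^3, 0, 100), dim = gridDims(g)), g)
  idf <- displacementField(0, g, "backward")
  expect_identical(volumeValues(warpVolume(vol, idf)), volumeValues(vol))

  # integer-voxel translation: exact shifted copy in the interior
  v <- array(0, dim = c(24, 24, 24, 3)); v[, , , 3] <- 2 * 2  # +2 voxels in z
  sh <- warpVolume(vol, displacementField(v, g, "backward"))
  expect_equal(volumeValues(sh)[, , 1:20], volumeValues(vol)[, , 3:22])

  # half-voxel shift of a linear ramp: cubic interpolation is exact
  ax <- worldAxes(g)
  ramp <- imageVolume(array(rep(3 + 2 * ax$z, each = 24 * 24),
                            dim = gridDims(g)), g)
  vh <- array(0, dim = c(24, 24, 24, 3)); vh[, , , 3] <- 1  # +0.5 voxel
  rw <- warpVolume(ramp, displacementField(vh, g, "backward"))
  want <- array(rep(3 + 2 * (ax$z + 1), each = 24 * 24), dim = gridDims(g))
  expect_lt(max(abs(volumeValues(rw)[, , 2:22] - want[, , 2:22])), 1e-9)

  # mean preservation: warping a uniform volume returns the constant
  uni <- imageVolume(array(42, dim = gridDims(g)), g)
  set.seed(1)
  vr <- array(rnorm(24^3 * 3, 0, 3), dim = c(24, 24, 24, 3))
  wu <- warpVolume(uni, displacementField(vr, g, "backward"), fill = 42)
  expect_lt(max(abs(volumeValues(wu) - 42)), 1e-9)
})

test_that("label warping is nearest-neighbour and label-closed", {
  g <- voxelGrid(c(16, 16, 16), 2)
  lab <- array(1L, dim = gridDims(g)); lab[5:8, 5:8, 5:8] <- 7L
  lv <- labelVolume(lab, g)
  idf <- displacementField(0, g, "backward")
  expect_identical(volumeValues(warpLabels(lv, idf)), lab)
  v <- array(0, dim = c(16, 16, 16, 3)); v[, , , 1] <- 2  # +1 voxel in x
  shifted <- warpLabels(lv, v |> displacementField(g, "backward"), fill = 1L)
  expect_identical(volumeValues(shifted)[4:7, , ], lab[5:8, , ])
  expect_true(all(volumeValues(shifted) %in% lab))
})

test_that("forward fields honour the motion model anchors", {
  ha <- halfAnatomy()
  an <- ha$anatomy; cache <- ha$cache
  tb <- defaultStructureTable()
  g <- an$labels@grid
  pr <- motionPreset("normal")

  # t = 0: zero field for any preset
  f0 <- buildForwardDvf(an$labels, pr, 0, tb, cache)
  expect_equal(max(abs(volumeValues(f0))), 0)

  # EOI: exact rigid vector in the eroded liver core (tumor centre)
  f2 <- buildForwardDvf(an$labels, pr, 2, tb, cache)
  ci <- round((an$tumor$center_mm - gridOrigin(g)) / gridSpacing(g)) + 1
  u <- volumeValues(f2)[ci[1], ci[2], ci[3], ]
  expect_equal(u, c(0, 11.0, -19.2), tolerance = 1e-8)

  # deep spine-complex voxel: immobile (the spine label itself is an
  # annulus around the static marrow and cord)
  spine <- structureMask(an$labels, tb, c("spine", "static_marrow", "cord"))
  core <- erodeMask(spine, gridSpacing(g), 7)
  si <- which(core, arr.ind = TRUE)[1, ]
  expect_lt(max(abs(volumeValues(f2)[si[1], si[2], si[3], ])), 1e-9)

  # periodicity: t and t + 5 s identical
  f7 <- buildForwardDvf(an$labels, pr, 7, tb, cache)
  expect_equal(volumeValues(f7), volumeValues(f2))

  # unknown labels rejected
  bad <- volumeValues(an$labels); bad[1] <- 99L
  expect_error(buildForwardDvf(labelVolume(bad, g), pr, 2, tb),
               class = "phantom4D_invalid_input")
})

test_that("volume is preserved inside the rigid core under warping", {
  ha <- halfAnatomy()
  an <- ha$anatomy
  tb <- defaultStructureTable()
  g <- an$labels@grid
  fwd <- buildForwardDvf(an$labels, motionPreset("normal"), 2, tb, ha$cache)
  back <- invertDvf(fwd)
  # the tumor mask lies fully inside the eroded liver core: a pure
  # translation there, so its pulled-back volume changes by < 1%
  tl <- array(0L, dim = gridDims(g)); tl[an$tumor$mask] <- 1L
  wl <- warpLabels(labelVolume(tl, g), back)
  n0 <- sum(tl); n1 <- sum(volumeValues(wl) == 1L)
  expect_lt(abs(n1 - n0) / n0, 0.01)
  # and its centroid moves by exactly the rigid EOI displacement
  com0 <- centerOfMass(tl == 1L, g)
  com1 <- centerOfMass(volumeValues(wl) == 1L, g)
  # nearest-neighbour pullback of a uniform sub-voxel translation snaps
  # to the nearest lattice vector: COM accurate to half a voxel
  expect_lt(max(abs(as.numeric(com1 - com0) - c(0, 11.0, -19.2))),
            0.55 * gridSpacing(g))
})
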