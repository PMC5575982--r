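test_that("segmentation recovers the analytic half-depth surface", {
  fx <- syntheticTumorVolume()
  tm <- segmentTumor(fx$volume, fx$center)
  # half-depth iso-surface: rho = 15 sqrt(1 - 1/sqrt(2)) = 8.106 mm,
  # volume 4/3 pi rho^3 = 2.231 cm^3
  expect_lt(abs(attr(tm, "volume_cm3") - 2.231), 0.12)
  expect_lt(max(abs(attr(tm, "com_mm") - fx$center)), 0.2)
  # equivalent radius of the segmented volume
  r_eq <- (3 * attr(tm, "volume_cm3") * 1000 / (4 * pi))^(1 / 3)
  expect_lt(abs(r_eq - 8.106), 0.15)
})

test_that("segmentation fails cleanly without a tumor", {
  g <- voxelGrid(c(32, 32, 32), 2)
  flat <- imageVolume(array(255, dim = gridDims(g)), g)
  expect_error(segmentTumor(flat, c(31, 31, 31)),
               class = "phantom4D_segmentation_failure")
  expect_error(segmentTumor(flat, c(1e4, 1e4, 1e4)),
               class = "phantom4D_segmentation_failure")
})

test_that("centre of mass and volume metrics behave geometrically", {
  g <- voxelGrid(c(32, 32, 32), 1.6719)
  ctr <- c(25.3, 26.1, 24.8)
  sph <- rasterizeShape(superellipsoid(ctr, 12), g)
  expect_lt(max(abs(centerOfMass(sph, g) - ctr)), 0.1)

  one <- array(FALSE, gridDims(g)); one[5, 9, 13] <- TRUE
  expect_equal(as.numeric(centerOfMass(one, g)),
               c(4, 8, 12) * 1.6719)
  expect_equal(measureVolume(one, g), 1.6719^3 / 1000)
  expect_equal(measureVolume(one & FALSE, g), 0)
  expect_error(centerOfMass(one & FALSE, g),
               class = "phantom4D_invalid_input")

  # additivity over disjoint masks
  two <- array(FALSE, gridDims(g)); two[20:22, 5, 5] <- TRUE
  expect_equal(measureVolume(one | two, g),
               measureVolume(one, g) + measureVolume(two, g))

  # COM of a translated copy moves by the translation
  sph2 <- rasterizeShape(superellipsoid(ctr + c(5, -3, 7), 12), g)
  expect_lt(max(abs((centerOfMass(sph2, g) - centerOfMass(sph, g)) -
                    c(5, -3, 7))), 1.7)
})

test_that("segmented COM tracks a rigid translation of the tumor", {
  fx <- syntheticTumorVolume()
  g <- fx$grid
  shift <- c(0, 4.7, -8.3)
  arr <- array(255, dim = gridDims(g))
  arr <- insertTumor(arr, list(center_mm = fx$center + shift,
                               radius_mm = 15, depth = 100), g)
  tm0 <- segmentTumor(fx$volume, fx$center)
  tm1 <- segmentTumor(imageVolume(arr, g), fx$center + shift)
  d <- attr(tm1, "com_mm") - attr(tm0, "com_mm")
  expect_lt(max(abs(d - shift)), 0.3)
  expect_lt(abs(attr(tm1, "volume_cm3") - attr(tm0, "volume_cm3")), 0.05)
})
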