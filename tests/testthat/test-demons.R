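test_that("identical masks register to a near-identity field", {
  g <- voxelGrid(c(48, 48, 48), 2)
  m <- rasterizeShape(superellipsoid(c(47, 47, 47), 28), g)
  f <- demonsRegister(m, m, g)
  expect_equal(attr(f, "dice"), 1)
  expect_lt(max(abs(volumeValues(f))), 1)
})

test_that("zero-iteration registration returns the zero field", {
  g <- voxelGrid(c(32, 32, 32), 2)
  a <- rasterizeShape(superellipsoid(c(31, 31, 31), 16), g)
  b <- rasterizeShape(superellipsoid(c(35, 31, 31), 16), g)
  p <- demonsParams(levels = 1, iterations = 0)
  f <- suppressWarnings(demonsRegister(a, b, g, p))
  expect_equal(max(abs(volumeValues(f))), 0)
})

test_that("sphere-to-ellipsoid and translated-sphere pairs reach Dice 0.98", {
  g <- voxelGrid(c(64, 64, 64), 2)
  ctr <- c(63.2, 62.7, 63.5)
  # equal-volume sphere vs ellipsoid: r^3 = a b c
  sph <- rasterizeShape(superellipsoid(ctr, 24), g)
  ell <- rasterizeShape(superellipsoid(ctr, c(28, 24, 24^3 / (28 * 24))), g)
  f1 <- demonsRegister(sph, ell, g)
  expect_gte(attr(f1, "dice"), 0.98)
  # 10 mm translated sphere
  sph2 <- rasterizeShape(superellipsoid(ctr + c(10, 0, 0), 24), g)
  f2 <- demonsRegister(sph, sph2, g)
  expect_gte(attr(f2, "dice"), 0.98)
  # Dice is monotone non-decreasing across pyramid levels (tol 0.005)
  dl <- attr(f1, "dice_levels")
  expect_true(all(diff(dl) > -0.005))
})

test_that("field application to textures preserves constants and identity", {
  g <- voxelGrid(c(24, 24, 24), 2)
  tex <- imageVolume(array(runif(24^3, 50, 150), dim = gridDims(g)), g)
  z <- displacementField(0, g, "backward")
  expect_identical(volumeValues(applyFieldToTexture(tex, z)),
                   volumeValues(tex))
  uni <- imageVolume(array(7, dim = gridDims(g)), g)
  set.seed(2)
  v <- array(rnorm(24^3 * 3, 0, 1.2), dim = c(24, 24, 24, 3))
  w <- applyFieldToTexture(uni, displacementField(v, g, "backward"))
  expect_lt(max(abs(volumeValues(w)[6:19, 6:19, 6:19] - 7)), 1e-9)
})

test_that("volume difference is the percent mismatch against the reference", {
  g <- voxelGrid(c(16, 16, 16), 2)
  a <- array(FALSE, gridDims(g)); a[2:9, 2:9, 2:9] <- TRUE
  expect_equal(volumeDifference(a, a), 0)
  expect_error(volumeDifference(a, a & FALSE),
               class = "phantom4D_invalid_input")
  # the printed reference volumes: 100 |1975.90 - 2200| / 2200 = 10.19%
  expect_equal(round(100 * abs(1975.90 - 2200) / 2200, 2), 10.19)
})
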