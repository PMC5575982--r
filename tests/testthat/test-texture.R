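test_that("rescaleMean applies a pure multiplicative factor", {
  v <- array(200, dim = c(6, 6, 6))
  m <- array(TRUE, dim = dim(v))
  out <- rescaleMean(v, m, 160)
  expect_equal(mean(out[m]), 160)
  expect_equal(out[1], 200 * 0.8)
  # identity when already at target
  expect_equal(rescaleMean(out, m, 160), out)
  # mask-locality: voxels outside the mask untouched
  m2 <- m; m2[1:3, , ] <- FALSE
  out2 <- rescaleMean(v, m2, 100)
  expect_equal(out2[1, 1, 1], 200)
  expect_equal(mean(out2[m2]), 100)
  expect_error(rescaleMean(v * 0, m, 160), class = "phantom4D_rescale_error")
  expect_error(rescaleMean(v, m & FALSE, 160),
               class = "phantom4D_rescale_error")
})

test_that("A + B compositing yields organ mean A + B", {
  n <- c(8, 8, 8)
  vol <- array(0, dim = n)
  m <- array(FALSE, dim = n); m[3:6, 3:6, 3:6] <- TRUE
  detail <- array(rnorm(prod(n), 160, 10), dim = n)
  detail <- rescaleMean(detail, m, 160)
  out <- composeAB(vol, 95, detail, m)
  expect_equal(mean(out[m]), 255)           # liver: A = 95, B = 160
  expect_true(all(out[!m] == 0))            # untouched outside
  out2 <- composeAB(vol, 25, rescaleMean(detail, m, 170), m)
  expect_equal(mean(out2[m]), 195)          # spleen: A = 25, B = 170
  out3 <- composeAB(vol, 40, array(0, n), m)
  expect_true(all(out3[m] == 40))           # zero detail: uniform A
})

test_that("pattern generation assigns every SOI voxel exactly once", {
  set.seed(42)
  dn <- c(16, 16, 16)
  donor <- array(runif(prod(dn), 80, 120), dim = dn)
  roi <- array(FALSE, dim = dn); roi[2:15, 2:15, 2:15] <- TRUE

  # SOI of exactly 5^3: a single 5-patch covers it
  soi5 <- array(FALSE, dim = dn); soi5[4:8, 4:8, 4:8] <- TRUE
  r5 <- generatePattern(soi5, donor, roi, seed = 1, details = TRUE)
  expect_equal(r5$n_assigned, sum(soi5))
  expect_equal(r5$placements$w, 5)

  # SOI of 6^3: full coverage with at least one 5-patch and some fill
  soi6 <- array(FALSE, dim = dn); soi6[4:9, 4:9, 4:9] <- TRUE
  r6 <- generatePattern(soi6, donor, roi, seed = 1, details = TRUE)
  expect_equal(r6$n_assigned, sum(soi6))
  expect_true(any(r6$placements$w == 5))
  expect_true(any(r6$placements$w %in% c(3, 1)))
  # bijection: placement volumes sum to the SOI voxel count
  expect_equal(sum(r6$placements$w^3), sum(soi6))

  # each transplanted patch appears verbatim in the donor ROI
  pdim <- dim(donor)
  for (i in seq_len(nrow(r6$placements))) {
    w <- r6$placements$w[i]
    s0 <- arrayInd(r6$placements$site[i], dn)
    d0 <- arrayInd(r6$placements$donor[i], pdim)
    got <- r6$prefilter[s0[1]:(s0[1] + w - 1), s0[2]:(s0[2] + w - 1),
                        s0[3]:(s0[3] + w - 1)]
    want <- donor[d0[1]:(d0[1] + w - 1), d0[2]:(d0[2] + w - 1),
                  d0[3]:(d0[3] + w - 1)]
    expect_equal(got, want)
    expect_true(all(roi[d0[1]:(d0[1] + w - 1), d0[2]:(d0[2] + w - 1),
                        d0[3]:(d0[3] + w - 1)]))
  }

  # deterministic under a fixed seed
  r6b <- generatePattern(soi6, donor, roi, seed = 1, details = TRUE)
  expect_identical(r6$values, r6b$values)

  expect_error(generatePattern(soi6 & FALSE, donor, roi),
               class = "phantom4D_invalid_argument")
  expect_error(generatePattern(soi6, donor, roi & FALSE),
               class = "phantom4D_invalid_argument")
})

test_that("Rayleigh noise has the requested mean and variance", {
  n <- c(64, 64, 32)
  v <- array(0, dim = n)
  m <- array(TRUE, dim = n)       # 131072 voxels
  out <- addRayleighNoise(v, m, 5, seed = 3)
  expect_lt(abs(mean(out[m]) - 5), 0.1)
  sigma <- 5 * sqrt(2 / pi)
  expect_lt(abs(var(out[m]) - (2 - pi / 2) * sigma^2), 0.2)
  expect_true(all(out[m] >= 0))
  # zero level leaves the volume unchanged
  expect_identical(addRayleighNoise(v, m, 0), v)
  expect_error(addRayleighNoise(v, m, -1),
               class = "phantom4D_invalid_argument")
})

test_that("tumor depression follows the quartic radial profile", {
  sp <- 1.6719
  g <- voxelGrid(c(32, 32, 32), sp)
  ctr <- c(15, 15, 15) * sp
  bg <- 255
  arr <- array(bg, dim = gridDims(g))
  r <- 6 * sp * sqrt(2)   # a voxel 6 steps along x sits at rho = r/sqrt(2)
  out <- insertTumor(arr, list(center_mm = ctr, radius_mm = r, depth = 100), g)
  expect_equal(out[16, 16, 16], bg - 100)            # centre: full depth
  expect_equal(out[16 + 6, 16, 16], bg - 25)         # rho = r/sqrt(2): 25
  rim <- ctr + c(r + sp, 0, 0)
  expect_equal(out[16 + 10, 16, 16], bg)             # outside: untouched
  # monotone, smooth rim (value within 2 of background just inside rim)
  rho_in <- floor(r / sp)
  expect_lt(bg - out[16 + rho_in, 16, 16], 6)
})

test_that("donor texture is reproducible with calibrated statistics", {
  g <- demoGrid()
  d1 <- makeDonorTexture(g, seed = 5)
  d2 <- makeDonorTexture(g, seed = 5)
  expect_identical(volumeValues(d1$volume), volumeValues(d2$volume))
  roi_vals <- volumeValues(d1$volume)[d1$muscle_roi]
  expect_gt(mean(roi_vals), 95); expect_lt(mean(roi_vals), 105)
  expect_gt(sd(roi_vals), 10); expect_lt(sd(roi_vals), 20)
  d0 <- makeDonorTexture(g, seed = 5, sd_intensity = 0)
  vals <- volumeValues(d0$volume)
  expect_true(all(vals[d0$muscle_roi] == 100))
  # donor organ masks carry the precedence carving (kidneys bite liver)
  expect_false(any(d1$masks$liver & d1$masks$kidneys))
})

test_that("reference volume hits the category means", {
  ref <- demoReference()
  tb <- defaultStructureTable()
  v <- volumeValues(ref$volume)
  lab <- volumeValues(ref$labels)
  liver <- lab == structureId(tb, "liver")
  ball <- rasterizeShape(superellipsoid(ref$anatomy$tumor$center_mm, 31),
                         ref$labels@grid)
  expect_lt(abs(mean(v[liver & !ball]) / 255 - 1), 0.02)
  lungs <- lab == structureId(tb, "lungs")
  expect_lt(abs(mean(v[lungs]) - 23), 0.2)
  expect_true(all(v >= 0))
  # category IV placeholders resolve to muscle or body
  expect_true(all(ref$placeholders %in% c("muscle", "body")))
})

test_that("full reference build is bit-reproducible", {
  a <- buildReference(demoGrid(), seed = 23)
  b <- buildReference(demoGrid(), seed = 23)
  expect_identical(volumeValues(a$volume), volumeValues(b$volume))
  expect_identical(volumeValues(a$labels), volumeValues(b$labels))
})
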