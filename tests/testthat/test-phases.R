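test_that("the reference phase equals the post-processed reference volume", {
  ref <- demoReference()
  tb <- defaultStructureTable()
  ph1 <- assemblePhase(ref$volume, ref$labels, motionPreset("normal"), 0, tb)
  # rebuild the same post-processing directly on the reference
  pc <- phantom4D:::makePhasePostCache(ref$labels, tb)
  arr <- volumeValues(ref$volume)
  lab <- volumeValues(ref$labels)
  for (i in seq_along(pc$cat4)) arr[lab == pc$cat4_ids[i]] <- pc$cat4_A[i]
  arr[pc$marrow_idx] <- volumeValues(ref$volume)[pc$marrow_idx]
  f3 <- phantom4D:::cpp_boxfilter_plain(as.numeric(arr), dim(arr), 3L)
  dim(f3) <- dim(arr)
  arr[pc$band] <- f3[pc$band]
  f5 <- phantom4D:::cpp_conv_sep_norm(as.numeric(arr), dim(arr),
                                      phantom4D:::weightedKernel5())
  dim(f5) <- dim(arr)
  arr[!pc$band] <- f5[!pc$band]
  expect_equal(volumeValues(ph1$volume), arr)
})

test_that("bony structures carry their uniform intensities before filtering", {
  ref <- demoReference()
  tb <- defaultStructureTable()
  ph <- assemblePhase(ref$volume, ref$labels, motionPreset("normal"), 1.5,
                      tb, filters = FALSE)
  v <- volumeValues(ph$volume)
  wl <- volumeValues(ph$labels)
  expect_true(all(v[wl == structureId(tb, "spine")] == 38))
  expect_true(all(v[wl == structureId(tb, "cord")] == 195))
  expect_true(all(v[wl == structureId(tb, "rib")] == 32))
})

test_that("series generation is deterministic and preset-aware", {
  s1 <- build4DSeries("normal", demoGrid(), seed = 19, phases = c(1, 5))
  s2 <- build4DSeries("normal", demoGrid(), seed = 19, phases = c(1, 5))
  expect_identical(volumeValues(s1@volumes[[2]]), volumeValues(s2@volumes[[2]]))
  md <- seriesMetadata(s1)
  expect_equal(md$A_d_cm, 2.0)
  expect_equal(md$A_ap_cm, 1.2)
  expect_error(build4DSeries("bogus", demoGrid()),
               class = "phantom4D_invalid_config")
})

test_that("phase 5 is the maximum-displacement phase of the cycle", {
  s <- halfSeries()
  k <- measureTumorKinematics(s)
  dz <- abs(k$per_phase$com_z - k$per_phase$com_z[1])
  expect_equal(which.max(dz), 5)
  expect_equal(k$eoi_phase, 5)
})

test_that("the limited preset scales the AP excursion accordingly", {
  ha <- halfAnatomy()
  an <- ha$anatomy
  tb <- defaultStructureTable()
  g <- an$labels@grid
  fwd <- buildForwardDvf(an$labels, motionPreset("limited"), 2, tb, ha$cache)
  ci <- round((an$tumor$center_mm - gridOrigin(g)) / gridSpacing(g)) + 1
  u <- volumeValues(fwd)[ci[1], ci[2], ci[3], ]
  # kappa_ap 11/12 of the 5 mm chest amplitude; SI unchanged vs normal
  expect_equal(u[2], 11 / 12 * 5, tolerance = 1e-8)
  expect_equal(u[3], -19.2, tolerance = 1e-8)
})

test_that("tumor kinematics report serializes to JSON", {
  s <- halfSeries()
  k <- measureTumorKinematics(s)
  f <- tempfile(fileext = ".json")
  writeMetricsJson(k, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$si_shift_cm, k$si_shift_cm)
  expect_equal(length(back$per_phase$volume_cm3), 10)
})
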