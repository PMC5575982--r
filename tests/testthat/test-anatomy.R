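test_that("reference labels cover every structure and partition the grid", {
  ref <- demoReference()
  tb <- defaultStructureTable()
  lab <- volumeValues(ref$labels)
  ids <- sort(unique(as.vector(lab)))
  expect_setequal(ids, structureRecords(tb)$id)
  # partition: per-structure masks are disjoint and exhaustive
  counts <- vapply(structureRecords(tb)$name, function(nm)
    sum(structureMask(ref$labels, tb, nm)), numeric(1))
  expect_equal(sum(counts), length(lab))
})

test_that("key organs rasterize as connected masks", {
  an <- halfAnatomy()$anatomy
  tb <- defaultStructureTable()
  for (nm in c("liver", "stomach", "spleen", "pancreas", "gallbladder",
               "heart_blood", "cord")) {
    m <- structureMask(an$labels, tb, nm)
    cc <- phantom4D:::largestComponent(m)
    expect_equal(sum(cc), sum(m), info = nm)
  }
  # kidneys are two components sharing one record
  kid <- structureMask(an$labels, tb, "kidneys")
  expect_lt(sum(phantom4D:::largestComponent(kid)), sum(kid))
})

test_that("liver is calibrated to the reference volume on the native grid", {
  g <- defaultGrid()
  an <- buildReferenceLabels(grid = g)
  tb <- defaultStructureTable()
  v <- sum(structureMask(an$labels, tb, "liver")) * voxelVolumeMl(g)
  expect_lt(abs(v - 1975.90), 0.05)
})

test_that("volume calibration hits targets, is idempotent, and fails cleanly", {
  g <- voxelGrid(c(48, 48, 48), 1.6719)
  ctr <- c(39.1, 40.2, 39.7)
  # sphere calibrated to the analytic 15 mm-radius volume
  cal <- calibrateVolume(superellipsoid(ctr, 12), 14.137, g)
  expect_lt(abs(cal$shape$semi[1] - 15), 0.1)
  expect_lt(abs(cal$volume_ml - 14.137), max(0.05, 1.5 * voxelVolumeMl(g)))
  # template already at target: scale stays ~1
  cal2 <- calibrateVolume(cal$shape, cal$volume_ml, g)
  expect_lt(abs(cal2$scale - 1), 0.01)
  # mask-template recalibration changes volume by at most the tolerance
  cal3 <- calibrateVolume(cal$mask, cal$volume_ml, g)
  expect_lt(abs(cal3$volume_ml - cal$volume_ml),
            max(0.05, 1.5 * voxelVolumeMl(g)))
  # unreachable target inside the grid
  expect_error(calibrateVolume(superellipsoid(ctr, 12), 1e6, g),
               class = "phantom4D_calibration_failure")
  expect_error(calibrateVolume(superellipsoid(ctr, 12), -1, g),
               class = "phantom4D_invalid_argument")
})

test_that("tumor placement counts voxel centres and enforces the margin", {
  sp <- 1.6719
  g <- voxelGrid(c(40, 40, 40), sp)
  ctr <- c(19.38, 19.87, 19.34) * sp  # generic (non-lattice) centre
  liver <- rasterizeShape(superellipsoid(ctr, 31), g)  # 31 mm clearance
  mask <- placeTumor(liver, list(center_mm = ctr, radius_mm = 15,
                                 margin_mm = 12), g)
  # brute-force lattice count oracle
  ax <- worldAxes(g)
  d2 <- outer(outer((ax$x - ctr[1])^2, (ax$y - ctr[2])^2, "+"),
              (ax$z - ctr[3])^2, "+")
  expect_equal(sum(mask), sum(d2 <= 15^2))
  # nominal continuous volume is 14.137 cm^3 = 3025.1 voxels; the
  # rasterized count can deviate by at most a sub-voxel surface shell
  expect_lt(abs(sum(mask) - 3025), 64)

  expect_error(placeTumor(liver, list(center_mm = ctr, radius_mm = 0), g),
               class = "phantom4D_placement_error")
  # centre on the liver boundary violates the margin
  edge <- ctr + c(30, 0, 0)
  expect_error(placeTumor(liver, list(center_mm = edge, radius_mm = 15,
                                      margin_mm = 12), g),
               class = "phantom4D_placement_error")
})

test_that("default tumor centre keeps the full interior clearance", {
  ref <- demoReference()
  tb <- defaultStructureTable()
  liver <- structureMask(ref$labels, tb, "liver")
  g <- ref$labels@grid
  d <- distanceTransform(liver, gridSpacing(g))
  ci <- round((ref$anatomy$tumor$center_mm - gridOrigin(g)) /
                gridSpacing(g)) + 1
  expect_gte(d[ci[1], ci[2], ci[3]], 15 + 12)
})

test_that("configs missing required structures are rejected", {
  cfg <- defaultAnatomy()
  cfg$paint <- Filter(function(p) p$name != "lungs", cfg$paint)
  expect_error(buildReferenceLabels(cfg, demoGrid()),
               class = "phantom4D_invalid_config")
})
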