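test_that("motion curve matches its closed form and anchor points", {
  expect_equal(evalMotionCurve(c(0, 1, 2, 3.5, 5)), c(0, 0.5, 1, 0.5, 0))
  # continuity at the inhale/exhale junction and the period boundary
  expect_lt(abs(evalMotionCurve(2 - 1e-9) - evalMotionCurve(2 + 1e-9)), 1e-6)
  expect_lt(abs(evalMotionCurve(5 - 1e-9) - evalMotionCurve(5 + 1e-9)), 1e-6)
  # maximum over a fine sampling is 1, attained only at EOI
  ts <- seq(0, 5, by = 0.01)
  m <- evalMotionCurve(ts)
  expect_equal(max(m), 1)
  expect_equal(ts[m > 1 - 1e-12], 2)
  expect_true(all(m >= 0 & m <= 1))
  # periodicity
  expect_equal(evalMotionCurve(1.3), evalMotionCurve(6.3))
})

test_that("phase times are uniform and validated", {
  expect_equal(phaseTimes(), seq(0, 4.5, by = 0.5))
  expect_equal(phaseTimes(1, 5), 0)
  expect_equal(phaseTimes(4, 2), c(0, 0.5, 1, 1.5))
  expect_error(phaseTimes(0), class = "phantom4D_invalid_argument")
  expect_error(phaseTimes(10, -1), class = "phantom4D_invalid_argument")
})

test_that("breathing presets carry the three amplitude pairs", {
  p <- motionPresets()
  expect_equal(p$A_d_cm[match(c("large", "normal", "limited"), p$name)],
               c(3.0, 2.0, 2.0))
  expect_equal(p$A_ap_cm[match(c("large", "normal", "limited"), p$name)],
               c(2.0, 1.2, 0.5))
  expect_equal(motionPreset("normal")$A_ap_cm, 1.2)
  expect_error(motionPreset("bogus"), class = "phantom4D_invalid_config")
})

test_that("structure table reproduces the reference intensity constants", {
  tb <- defaultStructureTable()
  r <- structureRecords(tb)
  want <- list(
    liver = c("I", 95, 160), gallbladder = c("I", 82, 160),
    pancreas = c("I", 100, 112), spleen = c("I", 25, 170),
    stomach = c("I", 85, 140), kidneys = c("I", 90, 105),
    heart = c("I", 45, 150), myocardium = c("I", 65, 150),
    heart_blood = c("I", 110, 150),
    muscle = c("II", 40, 140), body = c("II", 30, 80),
    static_marrow = c("II", 30, 80), intestine_wall = c("II", 30, 85),
    lungs = c("III", 18, NA), airway_tree = c("III", 235, NA),
    intestine_air = c("III", 40, NA), esophagus_wall = c("III", 136, NA),
    air = c("III", 40, NA),
    rib = c("IV", 32, NA), spine = c("IV", 38, NA), cord = c("IV", 195, NA),
    cortical_bone = c("IV", 28, NA), cartilage = c("IV", 140, NA),
    mobile_marrow = c("IV", 135, NA))
  expect_setequal(r$name, names(want))
  for (nm in names(want)) {
    i <- match(nm, r$name)
    expect_equal(r$category[i], want[[nm]][1], info = nm)
    expect_equal(r$A[i], as.numeric(want[[nm]][2]), info = nm)
    expect_equal(r$B[i], suppressWarnings(as.numeric(want[[nm]][3])),
                 info = nm)
  }
  # liver motion fractions calibrate the reported tumor excursion
  k <- motionFractions(tb, "liver")
  expect_equal(as.numeric(k[1, ]), c(0.96, 1.10 / 1.2))
  # bones and cord are immobile
  expect_true(all(motionFractions(tb, structuresInCategory(tb, "IV")) == 0))
})

test_that("structure ids round-trip and the shipped YAML matches", {
  tb <- defaultStructureTable()
  nm <- structureRecords(tb)$name
  expect_equal(structureName(tb, structureId(tb, nm)), nm)
  expect_error(structureId(tb, "femur"), class = "phantom4D_invalid_input")

  shipped <- system.file("extdata", "structures.yaml", package = "phantom4D")
  expect_true(nzchar(shipped))
  expect_equal(structureRecords(readStructureTable(shipped)),
               structureRecords(tb))

  tmp <- tempfile(fileext = ".yaml")
  writeStructureTable(tb, tmp)
  expect_equal(structureRecords(readStructureTable(tmp)),
               structureRecords(tb))
})
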