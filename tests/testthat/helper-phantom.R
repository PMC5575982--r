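# Shared fixtures, built lazily and cached for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# coarse demonstration reference (64 x 64 x 48 @ 6.6876 mm)
demoReference <- function() {
  fixture("demo_ref", function() buildReference(demoGrid(), seed = 11))
}

# half-resolution anatomy + motion cache (128 x 128 x 75 @ 3.3438 mm)
halfAnatomy <- function() {
  fixture("half_anatomy", function() {
    an <- buildReferenceLabels(grid = halfResGrid())
    list(anatomy = an,
         cache = makeMotionCache(an$labels, defaultStructureTable()))
  })
}

# half-resolution 10-phase normal-preset series (shared by the
# kinematics and stability acceptance checks)
halfSeries <- function() {
  fixture("half_series", function() build4DSeries("normal", halfResGrid(),
                                                  seed = 7))
}

# uniform-liver test volume with the analytic tumor profile inserted
syntheticTumorVolume <- function(background = 255, radius = 15,
                                 spacing = 1.6719) {
  n <- ceiling(2 * (radius + 25) / spacing)
  g <- voxelGrid(rep(n, 3), spacing)
  ctr <- (n - 1) / 2 * spacing + rep(0, 3)
  arr <- array(background, dim = gridDims(g))
  arr <- insertTumor(arr, list(center_mm = ctr, radius_mm = radius,
                               depth = 100), g)
  list(volume = imageVolume(arr, g), center = ctr, grid = g)
}
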