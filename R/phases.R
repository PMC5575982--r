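# Phase assembly and 4-D series generation.

# static post-processing cache: category IV uniform assignment table,
# static-marrow reference indices and the spine/marrow fusion shell
makePhasePostCache <- function(labels, table) {
  g <- labels@grid
  lab <- labels@labels
  cat4 <- structuresInCategory(table, "IV")
  cat4 <- cat4[vapply(cat4, function(nm)
    any(lab == structureId(table, nm)), logical(1))]
  marrow <- lab == structureId(table, "static_marrow")
  S <- marrow | lab == structureId(table, "spine")
  r1 <- 1.01 * g@spacing
  band <- dilateMask(S, g@spacing, r1) & !erodeMask(S, g@spacing, r1)
  list(cat4 = cat4,
       cat4_ids = structureId(table, cat4),
       cat4_A = intensityA(table, cat4),
       marrow_idx = which(marrow),
       band = band)
}

# truncated 5-tap Gaussian kernel (sigma 1.25 voxels) of the weighted
# 5x5x5 smoothing pass
weightedKernel5 <- function(sigma_vox = 1.25) {
  k <- exp(-0.5 * (-2:2)^2 / sigma_vox^2)
  k / sum(k)
}

#' Assemble one respiratory phase
#'
#' Pipeline: synthesize the forward field at time t, repair it, invert it
#' to the backward field, warp the reference volume (tricubic) and labels
#' (nearest neighbour), overwrite category IV voxels with their uniform
#' intensities per the phase labels, re-insert the reference-phase static
#' marrow texture unchanged, fuse the spine/marrow interface shell with a
#' 3x3x3 moving average, and apply the weighted 5x5x5 kernel everywhere
#' else.
#'
#' @param ref_volume reference \linkS4class{ImageVolume} (EOE).
#' @param labels reference \linkS4class{LabelVolume}.
#' @param preset a preset from \code{\link{motionPreset}}.
#' @param t phase time (s).
#' @param table a \linkS4class{StructureTable}.
#' @param motion_cache,post_cache optional precomputed caches.
#' @param filters apply the fusion/smoothing filters (TRUE for output
#'   phases; FALSE exposes the raw assembled volume).
#' @param keep_fields also return the forward/backward fields.
#' @return list with \code{volume}, \code{labels} (phase labels),
#'   \code{time}, and optionally \code{forward}/\code{backward}.
#' @export
assemblePhase <- function(ref_volume, labels, preset, t,
                          table = defaultStructureTable(),
                          motion_cache = NULL, post_cache = NULL,
                          filters = TRUE, keep_fields = FALSE) {
  g <- labels@grid
  if (is.null(motion_cache)) motion_cache <- makeMotionCache(labels, table)
  if (is.null(post_cache)) post_cache <- makePhasePostCache(labels, table)
  air_id <- structureId(table, "air")
  air_A <- intensityA(table, "air")

  fwd <- buildForwardDvf(labels, preset, t, table, motion_cache)
  fwd <- repairDvf(fwd)
  if (max(abs(fwd@vectors)) == 0) {
    back <- displacementField(0, g, "backward")
  } else {
    back <- invertDvf(fwd, strict = FALSE)
  }
  vol <- warpVolume(ref_volume, back, "cubic", fill = air_A)
  lab_w <- warpLabels(labels, back, fill = air_id)

  arr <- vol@values
  # per-phase uniform category IV assignment
  wl <- lab_w@labels
  for (i in seq_along(post_cache$cat4))
    arr[wl == post_cache$cat4_ids[i]] <- post_cache$cat4_A[i]
  # static marrow: reference texture re-inserted unchanged
  arr[post_cache$marrow_idx] <- ref_volume@values[post_cache$marrow_idx]

  if (filters) {
    band <- post_cache$band
    f3 <- cpp_boxfilter_plain(as.numeric(arr), g@dims, 3L)
    dim(f3) <- g@dims
    arr[band] <- f3[band]
    f5 <- cpp_conv_sep_norm(as.numeric(arr), g@dims, weightedKernel5())
    dim(f5) <- g@dims
    arr[!band] <- f5[!band]
  }
  out <- list(volume = imageVolume(arr, g), labels = lab_w, time = t)
  if (keep_fields) { out$forward <- fwd; out$backward <- back }
  out
}

#' Build the full reference phantom (labels, donor, textured volume)
#'
#' Convenience wrapper running the anatomy builder, the donor texture
#' generator and the reference-volume synthesis on one grid.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param seed integer seed governing all stochastic steps (the donor
#'   uses \code{seed + 1}).
#' @param table a \linkS4class{StructureTable}.
#' @param config anatomy configuration.
#' @param keep_donor keep the donor texture in the result (large).
#' @return list with \code{anatomy}, \code{volume}, \code{labels},
#'   \code{mapping}, \code{table} and \code{seed}.
#' @export
buildReference <- function(grid = defaultGrid(), seed = 7,
                           table = defaultStructureTable(),
                           config = defaultAnatomy(), keep_donor = FALSE) {
  g <- gridOf(grid)
  anatomy <- buildReferenceLabels(config, g, table)
  donor <- makeDonorTexture(g, seed + 1, config)
  ref <- buildReferenceVolume(anatomy, donor, table, seed)
  out <- list(anatomy = anatomy, volume = ref$volume, labels = anatomy$labels,
              mapping = ref$mapping, placeholders = ref$placeholders,
              table = table, seed = seed)
  if (keep_donor) out$donor <- donor
  out
}

#' Build a 10-phase 4-D series
#'
#' Generates the reference phantom and warps it to every phase of the
#' respiratory cycle for a breathing preset.
#'
#' @param preset preset name: "large", "normal" or "limited".
#' @param grid a \linkS4class{VoxelGrid}.
#' @param seed integer seed.
#' @param n_phases number of phases (default 10 over the 5 s cycle).
#' @param phases optional integer subset of phases to generate (e.g.
#'   \code{c(1, 5)}); others are omitted from the series.
#' @param table a \linkS4class{StructureTable}.
#' @param config anatomy configuration.
#' @param reference optional prebuilt output of \code{\link{buildReference}}
#'   (to reuse one reference across presets).
#' @param filters apply the per-phase fusion/smoothing filters.
#' @return a \linkS4class{PhaseSeries}; metadata records the preset,
#'   seeds, grid, tumor geometry, liver calibration and the category I
#'   mapping report.
#' @export
build4DSeries <- function(preset = "normal", grid = defaultGrid(), seed = 7,
                          n_phases = 10, phases = NULL,
                          table = defaultStructureTable(),
                          config = defaultAnatomy(), reference = NULL,
                          filters = TRUE) {
  pr <- motionPreset(preset)
  g <- gridOf(grid)
  if (is.null(reference))
    reference <- buildReference(g, seed, table, config)
  labels <- reference$labels
  times <- phaseTimes(n_phases, 5)
  if (is.null(phases)) phases <- seq_along(times)
  mc <- makeMotionCache(labels, table)
  pc <- makePhasePostCache(labels, table)
  vols <- vector("list", length(phases))
  for (i in seq_along(phases)) {
    ph <- assemblePhase(reference$volume, labels, pr, times[phases[i]],
                        table, mc, pc, filters = filters)
    vols[[i]] <- ph$volume
  }
  kl <- motionFractions(table, "liver")
  meta <- list(preset = pr$name, A_d_cm = pr$A_d_cm, A_ap_cm = pr$A_ap_cm,
               seed = seed, donor_seed = seed + 1,
               grid_dims = g@dims, grid_spacing = g@spacing,
               n_phases = n_phases, phases = phases,
               tumor_center_mm = reference$anatomy$tumor$center_mm,
               tumor_radius_mm = reference$anatomy$tumor$radius_mm,
               tumor_depth = reference$anatomy$tumor$depth,
               kappa_si = kl[1, "kappa_si"], kappa_ap = kl[1, "kappa_ap"],
               liver_volume_ml = sum(structureMask(labels, table, "liver")) *
                 voxelVolumeMl(g),
               mapping = reference$mapping,
               version = as.character(utils::packageVersion("phantom4D")))
  new("PhaseSeries", volumes = vols, times = times[phases], metadata = meta)
}
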