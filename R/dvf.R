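# Forward DVF synthesis from per-structure motion fractions, fixed-point
# inversion to backward fields, morphological repair, and warping.

#' Precompute motion-model weights for a label volume
#'
#' Caches the distance-transform-derived blending weights used by
#' \code{\link{buildForwardDvf}}: the anterior chest-wall weight field,
#' the rigid-core re-imposition ramps of the category I organs (exact
#' rigid displacement inside the mask eroded by 6 mm, linear ramp across
#' the annulus, relaxed near differently-moving organ contacts) and the
#' zero ramps of the deep immobile bone units (spine complex with cord
#' and static marrow, cortical bone).
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param table a \linkS4class{StructureTable}.
#' @param core_mm rigid-core erosion depth (mm).
#' @return an opaque cache list for \code{\link{buildForwardDvf}}.
#' @export
makeMotionCache <- function(labels, table, core_mm = 6) {
  g <- labels@grid
  lab <- labels@labels
  ids <- table@records$id
  kmap_si <- kmap_ap <- numeric(max(ids))
  kmap_si[ids] <- table@records$kappa_si
  kmap_ap[ids] <- table@records$kappa_ap

  # anterior chest-wall weight: 1 on the anterior 10 mm body band,
  # tapering over 25 mm into the air in front of the chest and fading in
  # over 40 mm from the mid-coronal plane so the lateral skin carries no
  # abrupt AP cutoff
  torso <- lab != structureId(table, "air")
  d_in <- distanceTransform(torso, g@spacing)
  d_out <- distanceTransform(!torso, g@spacing)
  yc <- mean(maskWorldCoords(torso, g)[, 2])
  ax <- worldAxes(g)
  fy <- pmin(pmax((ax$y - yc) / 40, 0), 1)
  fy_arr <- array(rep(fy, each = g@dims[1]), dim = g@dims)
  w_ant <- array(0, dim = g@dims)
  band <- torso & d_in <= 10
  w_ant[band] <- 1
  taper <- !torso & d_out <= 25
  w_ant[taper] <- 1 - d_out[taper] / 25
  w_ant <- w_ant * fy_arr

  rampFor <- function(mask) {
    d <- distanceTransform(mask, g@spacing)
    idx <- which(mask)
    list(idx = idx, w = pmin(1, d[idx] / core_mm))
  }
  # category I organ velocities are painted onto masks dilated by the
  # core depth, so the velocity transition to the surroundings lives in
  # the visceral cushion and the in-organ rigid ramp has almost nothing
  # left to correct after blending. Where two category I organs with
  # different motion fractions are in direct contact (kidney against the
  # liver's renal impression, heart on the dome) the rigid pinning is
  # relaxed over 12 mm so the Gaussian blend carries that transition;
  # the tumor, placed >= 27 mm inside the liver, is unaffected.
  cat1 <- structuresInCategory(table, "I")
  kap <- motionFractions(table, cat1)
  rigid <- list()
  for (i in seq_along(cat1)) {
    nm <- cat1[i]
    m <- lab == structureId(table, nm)
    if (!any(m)) next
    rg <- rampFor(m)
    rg$dilated_idx <- which(dilateMask(m, g@spacing, core_mm))
    differing <- cat1[abs(kap[, 1] - kap[i, 1]) + abs(kap[, 2] - kap[i, 2]) > 0.02]
    other <- array(lab %in% structureId(table, differing), dim = g@dims)
    if (any(other)) {
      d_other <- distanceTransform(!other, g@spacing)
      rg$w <- rg$w * pmin(1, d_other[rg$idx] / 12)
    }
    rigid[[nm]] <- rg
  }
  # immobile bone re-imposition: only units deep enough to carry the full
  # 6 mm ramp to exact zero without a cliff (the spine complex and the
  # cortical bone); thin shell bones (ribs, cartilage, mobile marrow)
  # keep the small bled motion of their surroundings -- their appearance
  # is re-assigned per phase anyway, mirroring how bony structures are
  # handled in the per-phase pipeline
  zero <- list()
  zero_units <- list(
    spine_complex = c("spine", "cord", "static_marrow"),
    cortical_bone = "cortical_bone")
  for (un in names(zero_units)) {
    m <- array(lab %in% structureId(table, zero_units[[un]]), dim = g@dims)
    if (!any(m)) next
    zero[[un]] <- rampFor(m)
  }
  list(grid = g, kmap_si = kmap_si, kmap_ap = kmap_ap, w_ant = w_ant,
       rigid = rigid, zero = zero, core_mm = core_mm)
}

#' Synthesize the forward displacement field at time t
#'
#' Piecewise-rigid per-structure velocities
#' \eqn{v_s = (0, \kappa_{ap,s} A_{ap} m(t), -\kappa_{si,s} A_d m(t))}
#' (inhalation moves the diaphragm inferiorly and the chest anteriorly),
#' with the anterior body wall carried at the full AP amplitude, blended
#' by Gaussian smoothing (sigma 5 mm) of each component; the exact rigid
#' velocity is then re-imposed inside each category I organ eroded by
#' 6 mm (ramped across the annulus) and the bony structures are ramped
#' back to zero.
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param preset a preset from \code{\link{motionPreset}}.
#' @param t time (s).
#' @param table a \linkS4class{StructureTable}.
#' @param cache from \code{\link{makeMotionCache}} (built on the fly when
#'   NULL).
#' @param sigma_mm Gaussian blending scale (mm).
#' @return a forward \linkS4class{DisplacementField}.
#' @export
buildForwardDvf <- function(labels, preset, t, table = defaultStructureTable(),
                            cache = NULL, sigma_mm = 5) {
  g <- labels@grid
  lab <- labels@labels
  bad <- setdiff(unique(as.vector(lab)), table@records$id)
  if (length(bad))
    phantomStop("invalid_input", "labels contain unknown ids: %s",
                paste(bad, collapse = ", "))
  if (is.null(cache)) cache <- makeMotionCache(labels, table)
  m <- evalMotionCurve(t)
  vec <- array(0, dim = c(g@dims, 3L))
  if (m == 0) return(displacementField(vec, g, "forward"))

  ap_mm <- preset$A_ap_cm * 10 * m
  si_mm <- preset$A_d_cm * 10 * m
  uy <- array(cache$kmap_ap[lab] * ap_mm, dim = g@dims)
  uz <- array(-cache$kmap_si[lab] * si_mm, dim = g@dims)
  # organ velocities extended over the dilated masks (paint order)
  for (nm in names(cache$rigid)) {
    di <- cache$rigid[[nm]]$dilated_idx
    uy[di] <- cache$kmap_ap[structureId(table, nm)] * ap_mm
    uz[di] <- -cache$kmap_si[structureId(table, nm)] * si_mm
  }
  # anterior chest wall at full AP amplitude
  w <- cache$w_ant
  uy <- uy * (1 - w) + w * ap_mm

  uy <- smoothArray(uy, g@spacing, sigma_mm)
  uz <- smoothArray(uz, g@spacing, sigma_mm)

  for (nm in names(cache$rigid)) {
    rg <- cache$rigid[[nm]]
    vy <- cache$kmap_ap[structureId(table, nm)] * ap_mm
    vz <- -cache$kmap_si[structureId(table, nm)] * si_mm
    uy[rg$idx] <- (1 - rg$w) * uy[rg$idx] + rg$w * vy
    uz[rg$idx] <- (1 - rg$w) * uz[rg$idx] + rg$w * vz
  }
  for (nm in names(cache$zero)) {
    rg <- cache$zero[[nm]]
    uy[rg$idx] <- (1 - rg$w) * uy[rg$idx]
    uz[rg$idx] <- (1 - rg$w) * uz[rg$idx]
  }
  vec[, , , 2] <- uy
  vec[, , , 3] <- uz
  displacementField(vec, g, "forward")
}

#' Invert a forward displacement field
#'
#' Fixed-point iteration \eqn{u_b(x) \leftarrow -u_f(x + u_b(x))}, at most
#' \code{max_iter} iterations, stopping when the largest update falls
#' below \code{tol_mm} (0.01 voxel on the native grid). The composition
#' residual \eqn{\|u_f(x + u_b(x)) + u_b(x)\|_\infty} is checked over
#' voxels whose pullback stays in-grid.
#'
#' @param forward a forward \linkS4class{DisplacementField}.
#' @param max_iter iteration cap.
#' @param tol_mm convergence tolerance on the update (mm); defaults to
#'   0.01 voxel (0.017 mm on the native grid).
#' @param residual_tol_mm acceptance bound on the composition residual
#'   (mm); defaults to 0.05 voxel (0.084 mm on the native grid).
#' @param omega under-relaxation factor of the fixed-point update (1 =
#'   the plain iteration); 0.6 keeps the iteration contractive where the
#'   displacement Jacobian's spectral radius approaches 1.
#' @param strict when TRUE (default) non-convergence raises an
#'   inversion-failure error; when FALSE it signals a classed warning and
#'   the best-effort field is returned (used for the large-amplitude
#'   preset, which locally exceeds the invertibility limit of the
#'   blended field).
#' @return a backward \linkS4class{DisplacementField} with attributes
#'   \code{residual_mm} and \code{iterations}.
#' @export
invertDvf <- function(forward, max_iter = 50, tol_mm = NULL,
                      residual_tol_mm = NULL, omega = 0.6, strict = TRUE) {
  g <- forward@grid
  # 0.01 / 0.05 voxel on the field's own grid (0.017 mm and 0.084 mm on
  # the native 1.6719 mm raster)
  if (is.null(tol_mm)) tol_mm <- 0.01 * g@spacing
  if (is.null(residual_tol_mm)) residual_tol_mm <- 0.05 * g@spacing
  # coarse-level initial guess: invert a half-resolution copy of the
  # field first, so the fine fixed point starts close to the solution
  # and converges well inside the iteration cap
  u0 <- numeric(0)
  if (all(g@dims >= 16L)) {
    nc <- as.integer((g@dims - 1L) %/% 2L + 1L)
    fc <- vapply(1:3, function(c3)
      cpp_resample_linear(forward@vectors[, , , c3], g@dims, nc),
      numeric(prod(nc)))
    rc <- cpp_invert_dvf(as.numeric(fc), nc, g@spacing * 2, 200L, tol_mm,
                         numeric(0), omega)
    u0 <- as.numeric(vapply(1:3, function(c3) {
      uc <- rc$field[((c3 - 1) * prod(nc) + 1):(c3 * prod(nc))]
      dim(uc) <- nc
      cpp_resample_linear(uc, nc, g@dims)
    }, numeric(prod(g@dims))))
  }
  res <- cpp_invert_dvf(as.numeric(forward@vectors), g@dims, g@spacing,
                        as.integer(max_iter), tol_mm, u0, omega)
  # the composition residual is the contract; the update tolerance is
  # only the stop rule, so hitting the iteration cap with an acceptable
  # residual still counts as converged
  ok <- res$residual <= residual_tol_mm
  if (!ok) {
    msg <- sprintf(
      "field inversion did not converge (%d iterations, max update %.4f mm, residual %.4f mm)",
      res$iterations, res$max_update, res$residual)
    if (strict) phantomStop("inversion_failure", msg)
    warning(structure(class = c("phantom4D_inversion_failure", "warning",
                                "condition"),
                      list(message = msg, call = sys.call())))
  }
  v <- res$field
  dim(v) <- c(g@dims, 3L)
  out <- displacementField(v, g, "backward")
  attr(out, "residual_mm") <- res$residual
  attr(out, "iterations") <- res$iterations
  attr(out, "converged") <- ok
  out
}

#' Morphological DVF repair
#'
#' Flags voxels whose component deviates from the 3x3x3 neighbourhood
#' median by more than \code{dev_mm} while at least \code{min_agree} of
#' the 26 neighbours agree with that median within \code{agree_mm}
#' (isolated "holes" and "spurs"), replaces them by the neighbourhood
#' median, and sweeps at most twice. Idempotent on repaired fields.
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param dev_mm outlier deviation threshold (mm).
#' @param agree_mm neighbour agreement tolerance (mm).
#' @param min_agree minimum agreeing neighbours (of 26).
#' @param max_sweeps sweep cap.
#' @return the repaired field, with attribute \code{n_repaired}.
#' @export
repairDvf <- function(field, dev_mm = 2, agree_mm = 0.5, min_agree = 20,
                      max_sweeps = 2) {
  g <- field@grid
  res <- cpp_repair_dvf(as.numeric(field@vectors), g@dims, dev_mm, agree_mm,
                        as.integer(min_agree), as.integer(max_sweeps))
  v <- res$field
  dim(v) <- c(g@dims, 3L)
  out <- displacementField(v, g, field@direction)
  attr(out, "n_repaired") <- res$n_repaired
  out
}

#' Warp an image volume through a backward field
#'
#' \code{out(x) = reference(x + u_b(x))} with tricubic (Catmull-Rom,
#' exact at grid nodes) or trilinear interpolation; out-of-grid pullbacks
#' are filled with the air intensity (40).
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param backward a backward \linkS4class{DisplacementField}.
#' @param interpolation "cubic" or "linear".
#' @param fill out-of-grid fill intensity.
#' @export
warpVolume <- function(volume, backward, interpolation = c("cubic", "linear"),
                       fill = 40) {
  interpolation <- match.arg(interpolation)
  g <- volume@grid
  if (!identical(g@dims, backward@grid@dims))
    phantomStop("invalid_input", "volume and field must share one grid")
  fn <- if (interpolation == "cubic") cpp_warp_tricubic else cpp_warp_trilinear
  out <- fn(as.numeric(volume@values), g@dims, as.numeric(backward@vectors),
            g@spacing, fill)
  dim(out) <- g@dims
  imageVolume(out, g)
}

#' Warp a label volume (nearest neighbour)
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param backward a backward \linkS4class{DisplacementField}.
#' @param fill label for out-of-grid pullbacks.
#' @export
warpLabels <- function(labels, backward, fill = 0L) {
  g <- labels@grid
  if (!identical(g@dims, backward@grid@dims))
    phantomStop("invalid_input", "labels and field must share one grid")
  out <- cpp_warp_nn(as.integer(labels@labels), g@dims,
                     as.numeric(backward@vectors), g@spacing, as.integer(fill))
  dim(out) <- g@dims
  labelVolume(out, g)
}
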