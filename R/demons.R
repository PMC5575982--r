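# Mask-driven Demons deformable registration. Binary masks are converted
# to Gaussian-smoothed indicator images so the intensity-gradient force
# has a nonzero capture band, then registered coarse-to-fine with the
# classic Demons update, fluid smoothing of each update and diffusion
# smoothing of the accumulated field.

#' Demons registration parameters
#'
#' @param levels multiresolution downsampling factors, coarse to fine.
#' @param iterations Demons iterations per level.
#' @param sigma_fluid fluid (update) smoothing, voxels.
#' @param sigma_diff diffusion (field) smoothing, voxels.
#' @param sigma_mask Gaussian pre-smoothing of the binary masks, voxels.
#' @param epsilon force-normalisation floor.
#' @param force \code{"symmetric"} averages the fixed and warped-moving
#'   gradients (keeps the force alive as the interfaces overlap);
#'   \code{"classic"} uses the warped-moving gradient only.
#' @param gain multiplier on the Demons update before capping.
#' @param image registered representation of the masks:
#'   \code{"distance"} (clamped signed-distance maps, default) or
#'   \code{"indicator"} (Gaussian-smoothed indicators).
#' @param distance_cap_mm clamp of the signed-distance image (mm).
#' @export
demonsParams <- function(levels = c(4, 2, 1), iterations = c(100, 50, 25),
                         sigma_fluid = 2, sigma_diff = 1, sigma_mask = 2,
                         epsilon = 1e-6, force = c("symmetric", "classic"),
                         gain = 1, image = c("distance", "indicator"),
                         distance_cap_mm = 12) {
  force <- match.arg(force)
  image <- match.arg(image)
  stopifnot(length(levels) == length(iterations),
            sigma_fluid > 0, sigma_diff > 0, sigma_mask > 0,
            all(iterations >= 0), gain > 0, distance_cap_mm > 0)
  list(levels = levels, iterations = iterations, sigma_fluid = sigma_fluid,
       sigma_diff = sigma_diff, sigma_mask = sigma_mask, epsilon = epsilon,
       force = force, gain = gain, image = image,
       distance_cap_mm = distance_cap_mm)
}

# clamped signed-distance image of a mask (negative inside, in [-1, 1]):
# unlike a smoothed indicator it has a nonzero gradient over a wide band
# and graded interior values, so the Demons force vanishes exactly at
# alignment instead of leaving the interior free to drift
signedDistanceImage <- function(mask, spacing, cap_mm) {
  d_in <- distanceTransform(mask, spacing)
  d_out <- distanceTransform(!mask, spacing)
  sd <- ifelse(mask, -d_in, d_out)
  pmax(pmin(sd, cap_mm), -cap_mm) / cap_mm
}

#' Register a moving mask onto a fixed mask with Demons
#'
#' Returns the backward field (fixed to moving): sampling the moving
#' image at \code{x + u(x)} renders it in the fixed frame. Registration
#' runs on a padded bounding box around both masks and the field is
#' embedded (zero outside) into the full grid.
#'
#' @param moving_mask,fixed_mask logical arrays on the same grid.
#' @param grid a \linkS4class{VoxelGrid}.
#' @param params see \code{\link{demonsParams}}.
#' @param margin_mm bounding-box padding (mm).
#' @return a backward \linkS4class{DisplacementField} with attributes
#'   \code{dice} (final), \code{dice_levels} (after each level) and
#'   \code{support_volume_ml} (volume of the warped moving mask). A
#'   \code{phantom4D_registration_failure} warning is signalled when the
#'   final Dice is below 0.90.
#' @export
demonsRegister <- function(moving_mask, fixed_mask, grid,
                           params = demonsParams(), margin_mm = 25) {
  g <- gridOf(grid)
  if (!sum(moving_mask) || !sum(fixed_mask))
    phantomStop("invalid_input", "both masks must be nonempty")
  if (!identical(dim(moving_mask), dim(fixed_mask)))
    phantomStop("invalid_input", "masks must share one grid")

  # padded crop around both masks, outer dims chosen so that every level
  # divides the voxel lattice exactly (n - 1 multiple of the coarsest factor)
  both <- moving_mask | fixed_mask
  idx <- which(both, arr.ind = TRUE)
  mar <- ceiling(margin_mm / g@spacing)
  f0 <- max(params$levels)
  lo <- pmax(apply(idx, 2, min) - mar, 1L)
  hi <- pmin(apply(idx, 2, max) + mar, g@dims)
  n <- hi - lo + 1L
  n_pad <- (ceiling((n - 1L) / f0) * f0) + 1L
  hi <- pmin(lo + n_pad - 1L, g@dims)
  lo <- pmax(hi - n_pad + 1L, 1L)
  n <- hi - lo + 1L
  crop <- function(a) a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]

  if (identical(params$image, "distance")) {
    Fi <- signedDistanceImage(crop(fixed_mask), g@spacing, params$distance_cap_mm)
    Mi <- signedDistanceImage(crop(moving_mask), g@spacing, params$distance_cap_mm)
  } else {
    Fi <- smoothArray(crop(fixed_mask) * 1.0, 1, params$sigma_mask)
    Mi <- smoothArray(crop(moving_mask) * 1.0, 1, params$sigma_mask)
  }

  # skip pyramid levels at which the structure would shrink below ~6
  # voxels across (small organs vanish from the smoothed indicators at
  # coarse scale and the force field drags them away)
  ext_vox <- min(apply(idx, 2, max) - apply(idx, 2, min) + 1L)
  keep <- params$levels == 1 | ext_vox / params$levels >= 6
  levels <- params$levels[keep]
  iters <- params$iterations[keep]
  # skipped coarse levels donate their iterations to the finest level so
  # small structures receive the same total effort
  iters[length(iters)] <- iters[length(iters)] + sum(params$iterations[!keep])

  u <- NULL
  dice_levels <- numeric(0)
  for (li in seq_along(levels)) {
    f <- levels[li]
    nl <- as.integer((n - 1L) %/% f + 1L)
    sp_l <- g@spacing * f
    Fl <- if (f == 1) Fi else downsampleArray(Fi, nl, f)
    Ml <- if (f == 1) Mi else downsampleArray(Mi, nl, f)
    u0 <- if (is.null(u)) numeric(0) else {
      up <- vapply(1:3, function(c3)
        cpp_resample_linear(u[, , , c3], dim(u)[1:3], nl), numeric(prod(nl)))
      as.numeric(up)
    }
    u <- cpp_demons_level(as.numeric(Fl), as.numeric(Ml), nl, sp_l,
                          iters[li], params$sigma_fluid,
                          params$sigma_diff, params$epsilon, u0,
                          as.integer(identical(params$force, "symmetric")),
                          params$gain)
    dim(u) <- c(nl, 3L)
    # overlap of the warped binary mask (partial-volume threshold 0.5),
    # not of the smoothed indicators, whose 0.5 level set shrinks for
    # small structures
    Mb <- if (f == 1) crop(moving_mask) * 1.0 else
      cpp_resample_linear(crop(moving_mask) * 1.0, n, nl)
    Fb <- if (f == 1) crop(fixed_mask) * 1.0 else
      cpp_resample_linear(crop(fixed_mask) * 1.0, n, nl)
    Mw <- cpp_warp_trilinear(as.numeric(Mb), nl, as.numeric(u), sp_l, 0)
    dice_levels[li] <- diceArrays(Mw >= 0.5, Fb >= 0.5)
  }
  # embed into the full grid
  vec <- array(0, dim = c(g@dims, 3L))
  vec[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], ] <- u
  fld <- displacementField(vec, g, direction = "backward")

  Mw_full <- cpp_warp_trilinear(as.numeric(moving_mask * 1.0),
                                g@dims, as.numeric(vec), g@spacing, 0)
  support <- Mw_full >= 0.5
  dice <- diceArrays(support, fixed_mask)
  if (dice < 0.90)
    warning(structure(class = c("phantom4D_registration_failure", "warning",
                                "condition"),
                      list(message = sprintf(
                        "Demons registration did not converge (Dice %.3f < 0.90)",
                        dice), call = sys.call())))
  attr(fld, "dice") <- dice
  attr(fld, "dice_levels") <- dice_levels
  attr(fld, "support_volume_ml") <- sum(support) * voxelVolumeMl(g)
  attr(fld, "support_mask") <- support
  fld
}

# smooth-then-subsample downsampling by integer factor
downsampleArray <- function(a, new_dims, f) {
  s <- smoothArray(a, 1, f / 2)
  out <- cpp_resample_linear(as.numeric(s), dim(a), as.integer(new_dims))
  dim(out) <- new_dims
  out
}

diceArrays <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Dice overlap coefficient of two masks
#'
#' @param a,b logical arrays of equal dimension.
#' @export
diceCoefficient <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    phantomStop("invalid_input", "masks must share one grid")
  diceArrays(a != 0, b != 0)
}

#' Warp a texture volume through a displacement field
#'
#' Trilinear backward pullback of intensities; out-of-grid pullbacks are
#' filled with 0.
#'
#' @param texture an \linkS4class{ImageVolume} (or numeric array).
#' @param field a backward \linkS4class{DisplacementField}.
#' @return object of the same kind as \code{texture}.
#' @export
applyFieldToTexture <- function(texture, field) {
  arr <- if (is(texture, "ImageVolume")) texture@values else texture
  g <- field@grid
  if (!identical(dim(arr), as.integer(g@dims)))
    phantomStop("invalid_input", "texture and field must share one grid")
  out <- cpp_warp_trilinear(as.numeric(arr), g@dims, as.numeric(field@vectors),
                            g@spacing, 0)
  dim(out) <- g@dims
  if (is(texture, "ImageVolume")) imageVolume(out, g) else out
}

#' Percent volume difference between two masks
#'
#' \code{100 |V_A - V_B| / V_B}.
#'
#' @param mask_a,mask_b logical arrays on one grid.
#' @export
volumeDifference <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    phantomStop("invalid_input", "masks must share one grid")
  vb <- sum(mask_b)
  if (vb == 0) phantomStop("invalid_input", "reference mask is empty")
  100 * abs(sum(mask_a) - vb) / vb
}
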