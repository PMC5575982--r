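# Procedural donor texture: a synthetic stand-in for a patient T1 VIBE
# scan, consisting of a Gaussian-correlated random field with dark
# quasi-tubular vessel tracks inside the donor liver, plus donor organ
# masks (perturbed copies of the phantom organ shapes) and a muscle ROI
# for pattern generation.

donorOrganNames <- function() {
  c("liver", "gallbladder", "pancreas", "spleen", "stomach", "kidneys",
    "heart")
}

#' Generate the synthetic donor texture
#'
#' The texture is a Gaussian random field with ~4 mm correlation length,
#' mean 100 and standard deviation 15, clipped at 0, with darkened
#' vessel-like tubes inside the donor liver. Donor organ masks are the
#' phantom organ shapes perturbed by small anisotropic scalings and
#' translations, so the category I mapping exercises a genuine (but
#' modest) deformable registration problem. Deterministic given the seed.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param seed integer RNG seed.
#' @param config anatomy configuration supplying the organ shapes.
#' @param mean_intensity,sd_intensity,corr_mm random-field parameters.
#' @param roi_center_mm,roi_half_mm muscle ROI cube (centre and half-width,
#'   mm); the ROI must be at least 40 mm across.
#' @return list with \code{volume} (\linkS4class{ImageVolume}),
#'   \code{masks} (named list of donor organ masks), \code{muscle_roi}
#'   (logical array) and \code{seed}.
#' @export
makeDonorTexture <- function(grid = defaultGrid(), seed = 1,
                             config = defaultAnatomy(),
                             mean_intensity = 100, sd_intensity = 15,
                             corr_mm = 4,
                             roi_center_mm = c(100, 150, 200),
                             roi_half_mm = 24) {
  g <- gridOf(grid)
  set.seed(seed)
  white <- array(rnorm(prod(g@dims)), dim = g@dims)
  sm <- smoothArray(white, g@spacing, corr_mm)
  if (sd_intensity > 0) {
    sm <- (sm - mean(sm)) / stats::sd(sm) * sd_intensity + mean_intensity
  } else {
    sm[] <- mean_intensity
  }

  # donor organ masks: perturbed phantom shapes painted with the same
  # precedence as the anatomy builder, so later organs carve the earlier
  # ones (renal impression in the liver, gallbladder fossa, ...) exactly
  # as they do in the phantom masks
  heart_names <- c("heart", "myocardium", "heart_blood")
  paint_id <- array(0L, dim = g@dims)
  organ_order <- character(0)
  for (p in config$paint) {
    nm <- if (p$name %in% heart_names) "heart" else p$name
    if (!nm %in% donorOrganNames()) next
    if (nm != "heart" || p$name == "heart") {
      sh <- p$shape
      jig_s <- runif(3, 0.94, 1.06)
      jig_t <- runif(3, -4, 4)
      if (sh$type == "superellipsoid") {
        sh$semi <- sh$semi * jig_s
        sh$center <- sh$center + jig_t
      } else {
        sh$radius <- sh$radius * jig_s[1:2]
        sh$center <- sh$center + jig_t[1:2]
        sh$z0 <- sh$z0 + jig_t[3]; sh$z1 <- sh$z1 + jig_t[3]
      }
      if (!nm %in% organ_order) organ_order <- c(organ_order, nm)
      paint_id[rasterizeShape(sh, g)] <- match(nm, organ_order)
    }
  }
  masks <- lapply(seq_along(organ_order), function(i) paint_id == i)
  names(masks) <- organ_order

  # dark vessel tracks inside the donor liver
  if (!is.null(masks$liver) && sum(masks$liver) > 0) {
    core_idx <- which(erodeMask(masks$liver, g@spacing, 8))
    if (length(core_idx)) {
      seeds <- array(FALSE, g@dims)
      nseg <- 6L
      for (v in seq_len(nseg)) {
        start <- maskWorldCoords(arrayFromIndex(core_idx[
          sample.int(length(core_idx), 1)], g@dims), g)[1, ]
        dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
        len <- runif(1, 30, 70)
        pts <- t(sapply(seq(0, len, by = g@spacing / 2),
                        function(s) start + s * dirv))
        pi_ <- round(sweep(pts, 2, g@origin) / g@spacing) + 1
        keep <- pi_[, 1] >= 1 & pi_[, 1] <= g@dims[1] &
                pi_[, 2] >= 1 & pi_[, 2] <= g@dims[2] &
                pi_[, 3] >= 1 & pi_[, 3] <= g@dims[3]
        pi_ <- pi_[keep, , drop = FALSE]
        seeds[pi_] <- TRUE
      }
      tubes <- dilateMask(seeds, g@spacing, 2.5) & masks$liver
      sm[tubes] <- sm[tubes] * 0.45
    }
  }
  sm[sm < 0] <- 0

  roi <- rasterizeShape(superellipsoid(roi_center_mm, roi_half_mm,
                                       exponent = 40), g)
  if (2 * roi_half_mm < 40)
    phantomStop("invalid_argument", "muscle ROI must be at least 40 mm across")
  list(volume = imageVolume(sm, g), masks = masks, muscle_roi = roi,
       seed = seed)
}

# logical array with a single TRUE voxel at a linear index
arrayFromIndex <- function(idx, dims) {
  a <- array(FALSE, dims)
  a[idx] <- TRUE
  a
}
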