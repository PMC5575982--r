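# Internal raster helpers shared across modules.

gaussKernel1D <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-0.5 * ((-r):r)^2 / sigma_vox^2)
  k / sum(k)
}

# Gaussian smoothing of a 3-D array, sigma given in mm (edge-renormalised).
smoothArray <- function(arr, spacing, sigma_mm) {
  d <- dim(arr)
  out <- cpp_conv_sep_norm(as.numeric(arr), as.integer(d),
                           gaussKernel1D(sigma_mm / spacing))
  dim(out) <- d
  out
}

#' Euclidean distance transform of a binary mask
#'
#' Exact distance (mm) from each in-mask voxel to the nearest out-of-mask
#' voxel centre; 0 outside the mask.
#'
#' @param mask logical/integer 3-D array.
#' @param spacing isotropic voxel size in mm.
#' @export
distanceTransform <- function(mask, spacing) {
  d <- dim(mask)
  out <- cpp_edt(as.integer(mask != 0), as.integer(d), spacing)
  dim(out) <- d
  out
}

#' Binary erosion / dilation by a metric radius
#'
#' Euclidean (ball) erosion and dilation via the exact distance transform.
#'
#' @param mask logical 3-D array.
#' @param spacing voxel size in mm.
#' @param r_mm radius in mm.
#' @export
erodeMask <- function(mask, spacing, r_mm) {
  distanceTransform(mask, spacing) > r_mm
}

#' @rdname erodeMask
#' @export
dilateMask <- function(mask, spacing, r_mm) {
  mask | (distanceTransform(!mask, spacing) <= r_mm & !mask)
}

# largest 26-connected component of a logical array
largestComponent <- function(mask) {
  d <- dim(mask)
  out <- cpp_largest_cc(as.integer(mask != 0), as.integer(d)) != 0L
  dim(out) <- d
  out
}

# voxel-centre world coordinates for a logical mask (n x 3 matrix, mm)
maskWorldCoords <- function(mask, grid) {
  g <- gridOf(grid)
  idx <- which(mask) - 1L
  nx <- g@dims[1]; ny <- g@dims[2]
  i <- idx %% nx
  j <- (idx %/% nx) %% ny
  k <- idx %/% (nx * ny)
  cbind(x = g@origin[1] + i * g@spacing,
        y = g@origin[2] + j * g@spacing,
        z = g@origin[3] + k * g@spacing)
}

maskVolumeMl <- function(mask, grid) sum(mask) * voxelVolumeMl(grid)
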