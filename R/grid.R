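#' Construct a voxel grid
#'
#' @param dims integer triple of voxel counts; default is the phantom's
#'   native 256 x 256 x 150 raster.
#' @param spacing isotropic voxel size in mm (default 1.6719).
#' @param origin world position (mm) of the centre of voxel (0,0,0).
#' @return a \linkS4class{VoxelGrid}.
#' @examples
#' voxelGrid()                        # native phantom raster
#' voxelGrid(c(64, 64, 48), 6.6876)   # demo-scale raster, same FOV
#' @export
voxelGrid <- function(dims = c(256L, 256L, 150L), spacing = 1.6719,
                      origin = c(0, 0, 0)) {
  new("VoxelGrid", dims = as.integer(dims), spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @rdname voxelGrid
#' @export
defaultGrid <- function() voxelGrid()

#' Reduced-size grids covering the same physical field of view
#'
#' \code{halfResGrid} halves the raster (128 x 128 x 75 at 3.3438 mm);
#' \code{demoGrid} is the coarse 64 x 64 x 48 raster at 6.6876 mm used by
#' the quick demonstration pipeline. All physical lengths (organ sizes,
#' tumor radius, motion amplitudes) are unchanged, only the sampling is
#' coarser.
#' @export
halfResGrid <- function() voxelGrid(c(128L, 128L, 75L), 1.6719 * 2)

#' @rdname halfResGrid
#' @export
demoGrid <- function() voxelGrid(c(64L, 64L, 48L), 1.6719 * 4)

#' Grid accessors
#'
#' @param grid a \linkS4class{VoxelGrid} (or an object carrying one).
#' @return \code{gridDims}: integer triple; \code{gridSpacing}: mm;
#'   \code{gridOrigin}: mm triple; \code{voxelVolumeMl}: the volume of one
#'   voxel in mL; \code{nVoxels}: total voxel count.
#' @export
gridDims <- function(grid) gridOf(grid)@dims

#' @rdname gridDims
#' @export
gridSpacing <- function(grid) gridOf(grid)@spacing

#' @rdname gridDims
#' @export
gridOrigin <- function(grid) gridOf(grid)@origin

#' @rdname gridDims
#' @export
voxelVolumeMl <- function(grid) gridOf(grid)@spacing^3 / 1000

#' @rdname gridDims
#' @export
nVoxels <- function(grid) prod(gridOf(grid)@dims)

gridOf <- function(x) {
  if (is(x, "VoxelGrid")) return(x)
  if (isVirtualClass(class(x))) stop("no grid in object")
  if (.hasSlot(x, "grid")) return(x@grid)
  stop("object does not carry a VoxelGrid")
}

#' World coordinates of voxel centres along each axis
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @return list with numeric vectors \code{x}, \code{y}, \code{z} (mm).
#' @export
worldAxes <- function(grid) {
  g <- gridOf(grid)
  list(x = g@origin[1] + (seq_len(g@dims[1]) - 1) * g@spacing,
       y = g@origin[2] + (seq_len(g@dims[2]) - 1) * g@spacing,
       z = g@origin[3] + (seq_len(g@dims[3]) - 1) * g@spacing)
}

#' Wrap a numeric array as an ImageVolume
#'
#' @param values numeric 3-D array matching the grid dims (a scalar is
#'   recycled).
#' @param grid a \linkS4class{VoxelGrid}.
#' @export
imageVolume <- function(values, grid) {
  g <- gridOf(grid)
  if (length(values) == 1L) values <- array(values, dim = g@dims)
  if (is.null(dim(values))) dim(values) <- g@dims
  new("ImageVolume", grid = g, values = values)
}

#' Wrap an integer array as a LabelVolume
#'
#' @param labels integer 3-D array matching the grid dims.
#' @param grid a \linkS4class{VoxelGrid}.
#' @export
labelVolume <- function(labels, grid) {
  g <- gridOf(grid)
  storage.mode(labels) <- "integer"
  if (is.null(dim(labels))) dim(labels) <- g@dims
  new("LabelVolume", grid = g, labels = labels)
}

#' Extract raw array data
#'
#' @param x an \linkS4class{ImageVolume}, \linkS4class{LabelVolume} or
#'   \linkS4class{DisplacementField}.
#' @return the underlying numeric/integer array.
#' @export
volumeValues <- function(x) {
  if (is(x, "ImageVolume")) return(x@values)
  if (is(x, "LabelVolume")) return(x@labels)
  if (is(x, "DisplacementField")) return(x@vectors)
  stop("unsupported object")
}

#' Construct a displacement field
#'
#' @param vectors numeric (nx, ny, nz, 3) array of displacements in mm
#'   (world axes); a scalar 0 builds a zero field.
#' @param grid a \linkS4class{VoxelGrid}.
#' @param direction \code{"forward"} (reference to phase) or
#'   \code{"backward"} (phase to reference).
#' @export
displacementField <- function(vectors = 0, grid, direction = "forward") {
  g <- gridOf(grid)
  if (length(vectors) == 1L) vectors <- array(vectors, dim = c(g@dims, 3L))
  new("DisplacementField", grid = g, vectors = vectors, direction = direction)
}

#' Phase volumes and times of a PhaseSeries
#'
#' @param series a \linkS4class{PhaseSeries}.
#' @param p phase number (1-based).
#' @export
phaseVolume <- function(series, p) series@volumes[[p]]

#' @rdname phaseVolume
#' @export
seriesTimes <- function(series) series@times

#' @rdname phaseVolume
#' @export
seriesMetadata <- function(series) series@metadata
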