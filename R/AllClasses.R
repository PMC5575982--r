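#' @import methods
NULL

#' VoxelGrid: raster geometry with world-coordinate semantics
#'
#' An isotropic 3-D voxel lattice. The world coordinate of voxel
#' \code{(i,j,k)} (0-based) is \code{origin + (i,j,k) * spacing}, in
#' millimetres. Axis convention: +x left, +y anterior, +z superior, so
#' superior--inferior motion is along z and anterior--posterior motion
#' along y.
#'
#' @slot dims integer(3), voxel counts per axis; all >= 8.
#' @slot spacing numeric(1), isotropic voxel edge length in mm.
#' @slot origin numeric(3), world position (mm) of the centre of voxel
#'   (0,0,0).
#' @export
setClass("VoxelGrid",
  representation(dims = "integer", spacing = "numeric", origin = "numeric"),
  prototype(dims = c(256L, 256L, 150L), spacing = 1.6719, origin = c(0, 0, 0))
)

setValidity("VoxelGrid", function(object) {
  if (length(object@dims) != 3L) return("dims must have length 3")
  if (any(object@dims < 8L)) return("all dims must be >= 8")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    return("spacing must be a single positive number")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be a finite numeric triple")
  TRUE
})

#' ImageVolume: scalar intensity raster
#'
#' @slot grid a \linkS4class{VoxelGrid}.
#' @slot values numeric 3-D array of per-voxel intensities (arbitrary MR
#'   units), finite.
#' @export
setClass("ImageVolume", representation(grid = "VoxelGrid", values = "array"))

setValidity("ImageVolume", function(object) {
  if (!identical(dim(object@values), as.integer(object@grid@dims)))
    return("values dimensions do not match the grid")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    return("values must be finite")
  TRUE
})

#' LabelVolume: integer structure-ID raster
#'
#' One structure ID per voxel; 0 means outside the body/unlabelled. Labels
#' partition the volume by construction (no overlaps).
#'
#' @slot grid a \linkS4class{VoxelGrid}.
#' @slot labels integer 3-D array of structure IDs.
#' @export
setClass("LabelVolume", representation(grid = "VoxelGrid", labels = "array"))

setValidity("LabelVolume", function(object) {
  if (!identical(dim(object@labels), as.integer(object@grid@dims)))
    return("labels dimensions do not match the grid")
  if (!is.integer(object@labels)) return("labels must be integer")
  if (anyNA(object@labels) || any(object@labels < 0L))
    return("labels must be non-negative integers")
  TRUE
})

#' StructureTable: per-structure category, intensities and motion fractions
#'
#' Holds one record per modelled structure: its integer ID, category
#' (I--IV), base intensity A, detail intensity B (categories I and II
#' only), and the dimensionless superior--inferior / anterior--posterior
#' motion fractions kappa used by the motion engine.
#'
#' @slot records a data.frame with columns \code{name}, \code{id},
#'   \code{category}, \code{A}, \code{B}, \code{kappa_si}, \code{kappa_ap}.
#' @export
setClass("StructureTable", representation(records = "data.frame"))

setValidity("StructureTable", function(object) {
  r <- object@records
  need <- c("name", "id", "category", "A", "B", "kappa_si", "kappa_ap")
  if (!all(need %in% names(r))) return("records is missing required columns")
  if (anyDuplicated(r$name)) return("duplicate structure names")
  if (anyDuplicated(r$id)) return("duplicate structure ids")
  if (!all(r$category %in% c("I", "II", "III", "IV")))
    return("category must be one of I, II, III, IV")
  if (any(!is.na(r$B) & !r$category %in% c("I", "II")))
    return("B must be absent outside categories I and II")
  if (any(is.na(r$B) & r$category %in% c("I", "II")))
    return("B is required for categories I and II")
  if (any(r$kappa_si < 0 | r$kappa_si > 1 | r$kappa_ap < 0 | r$kappa_ap > 1))
    return("motion fractions must lie in [0, 1]")
  if (any(r$category == "IV" & (r$kappa_si != 0 | r$kappa_ap != 0)))
    return("category IV structures must have zero motion fractions")
  TRUE
})

#' DisplacementField: per-voxel 3-vector displacement raster
#'
#' Displacements are stored in millimetres along the world axes. A
#' \code{forward} field maps the reference anatomy to a phase; a
#' \code{backward} field is the pullback used when rendering a phase from
#' the reference.
#'
#' @slot grid a \linkS4class{VoxelGrid}.
#' @slot vectors numeric 4-D array (nx, ny, nz, 3) of displacements in mm.
#' @slot direction either \code{"forward"} or \code{"backward"}.
#' @export
setClass("DisplacementField",
  representation(grid = "VoxelGrid", vectors = "array", direction = "character"))

setValidity("DisplacementField", function(object) {
  d <- dim(object@vectors)
  if (length(d) != 4L || d[4] != 3L ||
      !identical(d[1:3], as.integer(object@grid@dims)))
    return("vectors must be an (nx, ny, nz, 3) array matching the grid")
  if (anyNA(object@vectors) || any(!is.finite(object@vectors)))
    return("vector components must be finite")
  if (!object@direction %in% c("forward", "backward"))
    return("direction must be 'forward' or 'backward'")
  TRUE
})

#' PhaseSeries: ordered 10-phase 4-D output
#'
#' @slot volumes list of \linkS4class{ImageVolume}, one per phase.
#' @slot times numeric vector of phase times (s); phase 1 is the EOE
#'   reference, the mid-cycle phase is EOI.
#' @slot metadata list recording preset, seed, grid and provenance.
#' @export
setClass("PhaseSeries",
  representation(volumes = "list", times = "numeric", metadata = "list"))

setValidity("PhaseSeries", function(object) {
  if (length(object@volumes) != length(object@times))
    return("one phase time per volume is required")
  if (length(object@volumes) < 1L) return("at least one phase is required")
  ok <- vapply(object@volumes, is, logical(1), class2 = "ImageVolume")
  if (!all(ok)) return("volumes must all be ImageVolume objects")
  TRUE
})

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid: %d x %d x %d voxels @ %.4f mm (origin %s mm)\n",
              object@dims[1], object@dims[2], object@dims[3], object@spacing,
              paste(format(object@origin), collapse = ", ")))
})

setMethod("show", "ImageVolume", function(object) {
  v <- object@values
  cat(sprintf("ImageVolume: %d x %d x %d @ %.4f mm, range [%.2f, %.2f]\n",
              dim(v)[1], dim(v)[2], dim(v)[3], object@grid@spacing,
              min(v), max(v)))
})

setMethod("show", "LabelVolume", function(object) {
  ids <- sort(unique(as.vector(object@labels)))
  cat(sprintf("LabelVolume: %d x %d x %d @ %.4f mm, %d distinct labels\n",
              dim(object@labels)[1], dim(object@labels)[2],
              dim(object@labels)[3], object@grid@spacing,
              length(setdiff(ids, 0L))))
})

setMethod("show", "DisplacementField", function(object) {
  mx <- max(abs(object@vectors))
  cat(sprintf("DisplacementField (%s): %d x %d x %d, max |u| = %.3f mm\n",
              object@direction, object@grid@dims[1], object@grid@dims[2],
              object@grid@dims[3], mx))
})

setMethod("show", "StructureTable", function(object) {
  r <- object@records
  cat(sprintf("StructureTable: %d structures (I: %d, II: %d, III: %d, IV: %d)\n",
              nrow(r), sum(r$category == "I"), sum(r$category == "II"),
              sum(r$category == "III"), sum(r$category == "IV")))
})

setMethod("show", "PhaseSeries", function(object) {
  cat(sprintf("PhaseSeries: %d phases, t = %s s (preset: %s)\n",
              length(object@volumes),
              paste(format(object@times), collapse = ", "),
              if (is.null(object@metadata$preset)) "?" else object@metadata$preset))
})
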