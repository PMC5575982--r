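# File formats: NIfTI-1 (via RNifti) and MetaImage (.mha, plain header +
# raw payload, written/read here since no installed package handles it).
# Grid spacing, origin and values round-trip losslessly; labels are
# stored as int32 and displacement fields as 4-D (nx,ny,nz,3) volumes
# with the direction tagged in the header.

volumeKind <- function(x) {
  if (is(x, "LabelVolume")) "labels"
  else if (is(x, "DisplacementField")) "field"
  else if (is(x, "ImageVolume")) "image"
  else phantomStop("io_error", "unsupported object of class %s", class(x)[1])
}

#' Write a volume, label volume or displacement field
#'
#' Format is inferred from the extension: \code{.nii}/\code{.nii.gz}
#' (NIfTI-1) or \code{.mha} (MetaImage). Spacing, origin and values
#' round-trip losslessly; labels are written as integers; fields as
#' 3-component vector volumes with their direction recorded in the header
#' (NIfTI \code{intent_name} / MetaImage \code{AnatomicalOrientation}
#' comment line).
#'
#' @param x an \linkS4class{ImageVolume}, \linkS4class{LabelVolume} or
#'   \linkS4class{DisplacementField}.
#' @param path output path.
#' @export
writeVolume <- function(x, path) {
  kind <- volumeKind(x)
  g <- gridOf(x)
  ext <- fileExt(path)
  if (ext %in% c("nii", "nii.gz")) {
    arr <- volumeValues(x)
    im <- RNifti::asNifti(arr * 1.0)
    nd <- length(dim(arr))
    RNifti::pixdim(im) <- c(rep(g@spacing, 3), rep(1, nd - 3))
    m <- diag(c(rep(g@spacing, 3), 1))
    m[1:3, 4] <- g@origin
    im <- RNifti::`sform<-`(im, structure(m, code = 2L))
    im <- RNifti::`qform<-`(im, structure(m, code = 2L))
    tag <- if (kind == "field") x@direction else kind
    im <- RNifti::asNifti(im, list(intent_name = substr(tag, 1, 15)))
    RNifti::writeNifti(im, path,
                       datatype = if (kind == "labels") "int32" else "auto")
  } else if (ext == "mha") {
    writeMha(x, path)
  } else {
    phantomStop("io_error", "unknown volume extension '%s'", ext)
  }
  invisible(path)
}

#' Read a volume, label volume or displacement field
#'
#' @param path input path (\code{.nii}, \code{.nii.gz} or \code{.mha}).
#' @param type \code{"auto"} infers from the file (integer payload =>
#'   labels, 3-channel 4-D => field); or force \code{"image"},
#'   \code{"labels"}, \code{"field"}.
#' @return an \linkS4class{ImageVolume}, \linkS4class{LabelVolume} or
#'   \linkS4class{DisplacementField}.
#' @export
readVolume <- function(path, type = c("auto", "image", "labels", "field")) {
  type <- match.arg(type)
  if (!file.exists(path)) phantomStop("io_error", "no such file: %s", path)
  ext <- fileExt(path)
  if (ext %in% c("nii", "nii.gz")) {
    im <- RNifti::readNifti(path)
    arr <- as.array(im)
    arr <- array(as.vector(arr), dim = dim(arr))  # strip the image class
    sp <- RNifti::pixdim(im)[1]
    xf <- RNifti::xform(im)
    origin <- xf[1:3, 4]
    h <- RNifti::niftiHeader(im)
    tag <- h$intent_name
  } else if (ext == "mha") {
    r <- readMha(path)
    arr <- r$array; sp <- r$spacing; origin <- r$origin; tag <- r$tag
  } else {
    phantomStop("io_error", "unknown volume extension '%s'", ext)
  }
  d <- dim(arr)
  g <- voxelGrid(d[1:3], sp, origin)
  if (type == "auto") {
    type <- if (length(d) == 4L && d[4] == 3L) "field"
            else if (is.integer(arr)) "labels" else "image"
  }
  switch(type,
    image = imageVolume(arr * 1.0, g),
    labels = labelVolume(arr, g),
    field = displacementField(arr * 1.0, g,
      direction = if (identical(tag, "forward")) "forward" else "backward"))
}

fileExt <- function(path) {
  if (grepl("\\.nii\\.gz$", path)) return("nii.gz")
  tolower(sub(".*\\.", "", basename(path)))
}

# --- MetaImage -------------------------------------------------------------

writeMha <- function(x, path) {
  arr <- volumeValues(x)
  g <- gridOf(x)
  kind <- volumeKind(x)
  d <- dim(arr)
  nchan <- if (length(d) == 4L) d[4] else 1L
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           sprintf("ElementSpacing = %.10g %.10g %.10g", g@spacing,
                   g@spacing, g@spacing),
           sprintf("Offset = %.10g %.10g %.10g", g@origin[1], g@origin[2],
                   g@origin[3]),
           sprintf("ElementNumberOfChannels = %d", nchan),
           sprintf("ElementType = %s",
                   if (kind == "labels") "MET_INT" else "MET_DOUBLE"),
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("Comment = kind:%s%s", kind,
                   if (kind == "field") paste0(";direction:", x@direction)
                   else ""),
           "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  # channels fastest-varying, per MetaImage convention
  payload <- if (nchan > 1L) aperm(arr, c(4, 1, 2, 3)) else arr
  if (kind == "labels")
    writeBin(as.integer(payload), con, size = 4L, endian = "little")
  else
    writeBin(as.numeric(payload), con, size = 8L, endian = "little")
  invisible(path)
}

readMha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readBinLine(con)
    if (is.null(line)) phantomStop("io_error", "malformed MetaImage header")
    kv <- strsplit(line, " = ", fixed = TRUE)[[1]]
    if (length(kv) != 2) phantomStop("io_error", "malformed MetaImage header")
    hdr[[kv[1]]] <- kv[2]
    if (kv[1] == "ElementDataFile") break
  }
  d <- as.integer(strsplit(hdr$DimSize, " ")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing, " ")[[1]])
  origin <- as.numeric(strsplit(hdr$Offset, " ")[[1]])
  nchan <- as.integer(hdr$ElementNumberOfChannels %||% "1")
  n <- prod(d) * nchan
  arr <- if (identical(hdr$ElementType, "MET_INT"))
    readBin(con, "integer", n, size = 4L, endian = "little")
  else
    readBin(con, "numeric", n, size = 8L, endian = "little")
  if (length(arr) != n) phantomStop("io_error", "truncated MetaImage payload")
  if (nchan > 1L) {
    dim(arr) <- c(nchan, d)
    arr <- aperm(arr, c(2, 3, 4, 1))
  } else {
    dim(arr) <- d
  }
  tag <- NULL
  if (!is.null(hdr$Comment) && grepl("direction:", hdr$Comment))
    tag <- sub(".*direction:", "", hdr$Comment)
  list(array = arr, spacing = sp[1], origin = origin, tag = tag)
}

readBinLine <- function(con) {
  out <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1L)
    if (!length(b)) return(if (length(out)) rawToChar(out) else NULL)
    if (b == as.raw(10L)) return(rawToChar(out))
    out <- c(out, b)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- phase series ----------------------------------------------------------

#' Write a phase series
#'
#' A path ending in \code{.nii}/\code{.nii.gz} writes one 4-D file;
#' otherwise \code{path} is treated as a directory receiving
#' \code{phase01.nii.gz} ... plus a \code{series.json} metadata file.
#'
#' @param series a \linkS4class{PhaseSeries}.
#' @param path output file or directory.
#' @export
writePhaseSeries <- function(series, path) {
  g <- series@volumes[[1]]@grid
  if (fileExt(path) %in% c("nii", "nii.gz")) {
    arr <- array(0, dim = c(g@dims, length(series@volumes)))
    for (i in seq_along(series@volumes))
      arr[, , , i] <- series@volumes[[i]]@values
    im <- RNifti::asNifti(arr)
    dt <- if (length(series@times) >= 2) diff(series@times[1:2]) else 0.5
    RNifti::pixdim(im) <- c(rep(g@spacing, 3), dt)
    m <- diag(c(rep(g@spacing, 3), 1)); m[1:3, 4] <- g@origin
    RNifti::`sform<-`(im, structure(m, code = 2L))
    RNifti::`qform<-`(im, structure(m, code = 2L))
    RNifti::writeNifti(im, path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(series@volumes))
      writeVolume(series@volumes[[i]],
                  file.path(path, sprintf("phase%02d.nii.gz", i)))
    jsonlite::write_json(c(series@metadata[!vapply(series@metadata, is.data.frame,
                                                   logical(1))],
                           list(times_s = series@times)),
                         file.path(path, "series.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a phase series from a 4-D NIfTI file
#'
#' Frames become phases with uniformly spaced times (0.5 s apart by
#' default, matching the 10-phase / 5 s cycle).
#'
#' @param path 4-D NIfTI file.
#' @param dt phase spacing in seconds.
#' @export
readPhaseSeries <- function(path, dt = 0.5) {
  im <- RNifti::readNifti(path)
  arr <- as.array(im)
  if (length(dim(arr)) != 4L)
    phantomStop("io_error", "expected a 4-D file, got %d-D", length(dim(arr)))
  sp <- RNifti::pixdim(im)[1]
  origin <- RNifti::xform(im)[1:3, 4]
  g <- voxelGrid(dim(arr)[1:3], sp, origin)
  n <- dim(arr)[4]
  vols <- lapply(seq_len(n), function(i) imageVolume(arr[, , , i], g))
  new("PhaseSeries", volumes = vols, times = (seq_len(n) - 1) * dt,
      metadata = list(source = path))
}

#' Write mid-slice preview PNGs
#'
#' Axial, coronal and sagittal mid-slices of a volume, intensity-scaled
#' to [0, 1].
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param prefix output path prefix; writes
#'   \code{<prefix>_axial.png} etc.
#' @export
previewSlices <- function(volume, prefix) {
  v <- volume@values
  d <- dim(v)
  rng <- range(v)
  norm <- function(s) {
    s <- (s - rng[1]) / max(rng[2] - rng[1], 1e-9)
    # image rows top-to-bottom: flip second axis for display
    t(s[, rev(seq_len(ncol(s)))])
  }
  png::writePNG(norm(v[, , ceiling(d[3] / 2)]),
                paste0(prefix, "_axial.png"))
  png::writePNG(norm(v[, ceiling(d[2] / 2), ]),
                paste0(prefix, "_coronal.png"))
  png::writePNG(norm(v[ceiling(d[1] / 2), , ]),
                paste0(prefix, "_sagittal.png"))
  invisible(prefix)
}
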