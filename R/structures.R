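#' Default structure table
#'
#' The per-structure category, modelled MR intensity constants A and B
#' (arbitrary units) and motion fractions. Categories: I key textured
#' organs (uniform base A plus mapped detail with mean B, so the organ
#' mean is A + B); II large soft-tissue volumes textured by iterative
#' pattern generation; III air-associated structures with uniform A (lungs
#' and intestinal air additionally receive Rayleigh noise); IV bony
#' structures assigned uniform A separately at every phase. Motion
#' fractions kappa scale the preset amplitudes per structure; bones, cord
#' and static marrow are immobile. The liver fractions (0.96 SI, 11/12 AP)
#' calibrate the end-exhale to end-inhale tumor excursion of the
#' normal-breath series to 1.92 cm SI / 1.10 cm AP.
#'
#' @return a \linkS4class{StructureTable}.
#' @export
defaultStructureTable <- function() {
  k_liver_ap <- 1.10 / 1.2
  r <- data.frame(
    name = c("liver", "gallbladder", "pancreas", "spleen", "stomach",
             "kidneys", "heart", "myocardium", "heart_blood",
             "muscle", "body", "static_marrow", "intestine_wall",
             "lungs", "airway_tree", "intestine_air", "esophagus_wall", "air",
             "rib", "spine", "cord", "cortical_bone", "cartilage",
             "mobile_marrow"),
    id = 1:24,
    category = c(rep("I", 9), rep("II", 4), rep("III", 5), rep("IV", 6)),
    A = c(95, 82, 100, 25, 85, 90, 45, 65, 110,
          40, 30, 30, 30,
          18, 235, 40, 136, 40,
          32, 38, 195, 28, 140, 135),
    B = c(160, 160, 112, 170, 140, 105, 150, 150, 150,
          140, 80, 80, 85,
          rep(NA_real_, 5), rep(NA_real_, 6)),
    kappa_si = c(0.96, 0.96, 0.70, 0.85, 0.80,
                 0.60, 0.55, 0.55, 0.55,
                 0.10, 0.10, 0.00, 0.55,
                 0.50, 0.30, 0.55, 0.30, 0.00,
                 rep(0, 6)),
    kappa_ap = c(k_liver_ap, k_liver_ap, 0.70, 0.85, 0.80,
                 0.60, 0.10, 0.10, 0.10,
                 0.10, 0.10, 0.00, 0.55,
                 0.50, 0.30, 0.55, 0.30, 0.00,
                 rep(0, 6)),
    stringsAsFactors = FALSE
  )
  new("StructureTable", records = r)
}

#' Structure table accessors
#'
#' @param table a \linkS4class{StructureTable}.
#' @param name structure name (or vector of names).
#' @return \code{structureRecords}: the full data.frame;
#'   \code{structureId}: integer ID(s); \code{structureName}: name(s) for
#'   ID(s); \code{structuresInCategory}: names in a category;
#'   \code{intensityA}/\code{intensityB}: intensity constants;
#'   \code{motionFractions}: two-column matrix of kappa values.
#' @export
structureRecords <- function(table) table@records

#' @rdname structureRecords
#' @export
structureId <- function(table, name) {
  i <- match(name, table@records$name)
  if (anyNA(i))
    phantomStop("invalid_input", "unknown structure(s): %s",
                paste(name[is.na(i)], collapse = ", "))
  table@records$id[i]
}

#' @rdname structureRecords
#' @param id integer structure ID(s).
#' @export
structureName <- function(table, id) {
  i <- match(id, table@records$id)
  if (anyNA(i))
    phantomStop("invalid_input", "unknown structure id(s): %s",
                paste(id[is.na(i)], collapse = ", "))
  table@records$name[i]
}

#' @rdname structureRecords
#' @param category one of "I", "II", "III", "IV".
#' @export
structuresInCategory <- function(table, category) {
  table@records$name[table@records$category %in% category]
}

#' @rdname structureRecords
#' @export
intensityA <- function(table, name) {
  table@records$A[match(name, table@records$name)]
}

#' @rdname structureRecords
#' @export
intensityB <- function(table, name) {
  table@records$B[match(name, table@records$name)]
}

#' @rdname structureRecords
#' @export
motionFractions <- function(table, name) {
  i <- match(name, table@records$name)
  cbind(kappa_si = table@records$kappa_si[i],
        kappa_ap = table@records$kappa_ap[i])
}

#' Read/write a structure table as YAML
#'
#' The shipped default file (\code{system.file("extdata",
#' "structures.yaml", package = "phantom4D")}) reproduces
#' \code{defaultStructureTable()} exactly.
#'
#' @param path YAML file path.
#' @export
readStructureTable <- function(path) {
  if (!file.exists(path))
    phantomStop("io_error", "no such file: %s", path)
  y <- yaml::read_yaml(path)
  r <- do.call(rbind, lapply(y$structures, function(s) {
    data.frame(name = s$name, id = as.integer(s$id), category = s$category,
               A = as.numeric(s$A),
               B = if (is.null(s$B)) NA_real_ else as.numeric(s$B),
               kappa_si = as.numeric(s$kappa_si),
               kappa_ap = as.numeric(s$kappa_ap),
               stringsAsFactors = FALSE)
  }))
  rownames(r) <- NULL
  new("StructureTable", records = r)
}

#' @rdname readStructureTable
#' @param table a \linkS4class{StructureTable}.
#' @export
writeStructureTable <- function(table, path) {
  recs <- lapply(seq_len(nrow(table@records)), function(i) {
    r <- as.list(table@records[i, ])
    if (is.na(r$B)) r$B <- NULL
    r
  })
  yaml::write_yaml(list(structures = recs), path, precision = 12L)
  invisible(path)
}
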