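# Parametric reference anatomy: a geometric stand-in for voxelized
# whole-body anatomy masks. Shapes are defined in millimetres in world
# coordinates, so the same anatomy rasterizes onto any grid covering the
# field of view.

#' Shape primitives for the anatomy builder
#'
#' \code{superellipsoid}: implicit body
#' \eqn{\sum_a |(x_a - c_a)/s_a|^{p_a} \le 1}; \code{ratio_inner} > 0 makes
#' it a shell (between the \code{ratio_inner}-scaled and full surface).
#' \code{cappedCylinder}: elliptical cylinder along z between \code{z0} and
#' \code{z1}; \code{ratio_inner} makes an annulus. \code{limits} clips by
#' world planes (named \code{xmin}, \code{xmax}, ..., \code{zmax}).
#'
#' @param center world centre (mm).
#' @param semi semi-axes (mm), length 1 or 3.
#' @param exponent superellipsoid exponents, length 1 or 3 (2 = ellipsoid).
#' @param ratio_inner inner/outer linear scale of a shell (0 = solid).
#' @param limits named list of world clipping planes (mm).
#' @return a shape spec (list) understood by \code{rasterizeShape}.
#' @export
superellipsoid <- function(center, semi, exponent = 2, ratio_inner = 0,
                           limits = list()) {
  list(type = "superellipsoid", center = as.numeric(center),
       semi = rep(as.numeric(semi), length.out = 3),
       exponent = rep(as.numeric(exponent), length.out = 3),
       ratio_inner = ratio_inner, limits = limits)
}

#' @rdname superellipsoid
#' @param radius cylinder radii (mm), length 1 or 2 (x, y).
#' @param z0,z1 axial extent (mm, world z).
#' @export
cappedCylinder <- function(center, radius, z0, z1, ratio_inner = 0,
                           limits = list()) {
  list(type = "cylinder", center = as.numeric(center[1:2]),
       radius = rep(as.numeric(radius), length.out = 2),
       z0 = z0, z1 = z1, ratio_inner = ratio_inner, limits = limits)
}

#' @rdname superellipsoid
#' @param organs structure names whose union is dilated.
#' @param r_mm dilation radius (mm).
#' @param clip optional shape the cushion is intersected with.
#' @export
organCushion <- function(organs, r_mm, clip = NULL) {
  list(type = "cushion", organs = organs, r_mm = r_mm, clip = clip)
}

# world-space bounding box of a shape at linear scale s
shapeBBox <- function(shape, scale = 1) {
  if (shape$type == "superellipsoid") {
    lo <- shape$center - shape$semi * scale
    hi <- shape$center + shape$semi * scale
  } else {
    zc <- (shape$z0 + shape$z1) / 2
    zh <- (shape$z1 - shape$z0) / 2 * scale
    lo <- c(shape$center - shape$radius * scale, zc - zh)
    hi <- c(shape$center + shape$radius * scale, zc + zh)
  }
  for (nm in names(shape$limits)) {
    v <- shape$limits[[nm]]
    a <- match(substr(nm, 1, 1), c("x", "y", "z"))
    if (grepl("min", nm)) lo[a] <- max(lo[a], v) else hi[a] <- min(hi[a], v)
  }
  list(lo = lo, hi = hi)
}

#' Rasterize a shape onto a grid
#'
#' @param shape a shape spec from \code{\link{superellipsoid}} or
#'   \code{\link{cappedCylinder}}.
#' @param grid a \linkS4class{VoxelGrid}.
#' @param scale isotropic linear scale about the shape centre.
#' @return logical 3-D array (TRUE inside).
#' @export
rasterizeShape <- function(shape, grid, scale = 1) {
  g <- gridOf(grid)
  ax <- worldAxes(g)
  out <- array(FALSE, dim = g@dims)
  bb <- shapeBBox(shape, scale)
  ir <- lapply(1:3, function(a) {
    which(ax[[a]] >= bb$lo[a] - g@spacing & ax[[a]] <= bb$hi[a] + g@spacing)
  })
  if (any(lengths(ir) == 0L)) return(out)
  xs <- ax$x[ir[[1]]]; ys <- ax$y[ir[[2]]]; zs <- ax$z[ir[[3]]]

  insideAt <- function(sc) {
    if (shape$type == "superellipsoid") {
      vx <- (abs(xs - shape$center[1]) / (shape$semi[1] * sc))^shape$exponent[1]
      vy <- (abs(ys - shape$center[2]) / (shape$semi[2] * sc))^shape$exponent[2]
      vz <- (abs(zs - shape$center[3]) / (shape$semi[3] * sc))^shape$exponent[3]
      outer(outer(vx, vy, "+"), vz, "+") <= 1
    } else {
      vx <- ((xs - shape$center[1]) / (shape$radius[1] * sc))^2
      vy <- ((ys - shape$center[2]) / (shape$radius[2] * sc))^2
      zc <- (shape$z0 + shape$z1) / 2
      zh <- (shape$z1 - shape$z0) / 2 * sc
      inz <- abs(zs - zc) <= zh
      r2 <- outer(vx, vy, "+") <= 1
      outer(r2, inz, "&")
    }
  }
  m <- insideAt(scale)
  if (shape$ratio_inner > 0) m <- m & !insideAt(scale * shape$ratio_inner)
  # world-plane clipping
  for (nm in names(shape$limits)) {
    v <- shape$limits[[nm]]
    a <- match(substr(nm, 1, 1), c("x", "y", "z"))
    co <- list(xs, ys, zs)[[a]]
    keep <- if (grepl("min", nm)) co >= v else co <= v
    perm <- c(a, setdiff(1:3, a))
    m <- aperm(aperm(m, perm) & keep, order(perm))
  }
  out[ir[[1]], ir[[2]], ir[[3]]] <- m
  out
}

#' Default anatomy configuration
#'
#' The parametric chest--abdomen layout: a torso with a muscle shell, a
#' visceral compartment (intestine), lungs and airway, a rib cage with
#' cartilage and mobile marrow, spine with cord and static marrow,
#' cortical bone, and the category I organs (liver, stomach, spleen,
#' kidneys, pancreas, three-part heart, gallbladder). Shapes are listed in
#' paint order; later entries take precedence (tumor > category I > bones
#' > category III > category II > body). The liver is volume-calibrated to
#' the reference 1975.90 mL. The structure adjacency graph is laid out so
#' that the motion-fraction differential between touching structures stays
#' below the invertibility limit of the blended deformation field (see the
#' methods vignette).
#'
#' @return a config list with elements \code{paint} (named shape list in
#'   paint order), \code{liver_target_ml} and \code{tumor}.
#' @export
defaultAnatomy <- function() {
  paint <- list(
    list(name = "body",
         shape = superellipsoid(c(213, 205, 120), c(160, 115, 118), c(2, 2, 8))),
    list(name = "muscle",
         shape = superellipsoid(c(213, 205, 120),
                                c(160, 115, 118) * 0.96, c(2, 2, 8),
                                ratio_inner = 0.86 / 0.96,
                                limits = list(zmin = 60, zmax = 238))),
    list(name = "intestine_wall",
         shape = superellipsoid(c(213, 205, 112), c(124.8, 89.7, 92),
                                c(2, 2, 6), limits = list(zmax = 190))),
    # adaptive visceral cushion: every fast abdominal organ is wrapped in
    # >= 14 mm of intestine so its motion steps down to the near-static
    # body in two decoupled increments (see the methods vignette)
    list(name = "intestine_wall",
         shape = organCushion(c("liver", "stomach", "spleen", "kidneys",
                                "pancreas", "gallbladder"), r_mm = 16,
                              clip = superellipsoid(c(213, 205, 120),
                                                    c(160, 115, 118) * 0.92,
                                                    c(2, 2, 8),
                                                    limits = list(zmax = 210)))),
    # slow "body" cushion around the spine complex so the immobile bone
    # is never in direct contact with fast-moving viscera
    list(name = "body",
         shape = cappedCylinder(c(213, 120), 24, 30, 222)),
    list(name = "intestine_air",
         shape = superellipsoid(c(180, 230, 60), c(30, 25, 20))),
    list(name = "intestine_air",
         shape = superellipsoid(c(250, 228, 55), c(28, 22, 18))),
    list(name = "intestine_air",
         shape = superellipsoid(c(213, 185, 45), c(35, 25, 15))),
    list(name = "lungs",
         shape = superellipsoid(c(155, 205, 196), c(47, 58, 36))),
    list(name = "lungs",
         shape = superellipsoid(c(271, 205, 196), c(47, 58, 36))),
    list(name = "airway_tree",
         shape = cappedCylinder(c(213, 205), 8, 168, 238)),
    list(name = "airway_tree",
         shape = superellipsoid(c(184, 205, 212), c(26, 7, 7))),
    list(name = "airway_tree",
         shape = superellipsoid(c(242, 205, 212), c(26, 7, 7))),
    list(name = "esophagus_wall",
         shape = cappedCylinder(c(213, 170), 5, 190, 230)),
    # bony thorax: open-bottomed shell, anterior portion is cartilage,
    # a thin mid-shell band is mobile marrow
    list(name = "rib",
         shape = superellipsoid(c(213, 205, 185), c(138, 97, 57), c(2, 2, 4),
                                ratio_inner = 0.95, limits = list(zmin = 170))),
    list(name = "cartilage",
         shape = superellipsoid(c(213, 205, 185), c(138, 97, 57), c(2, 2, 4),
                                ratio_inner = 0.95,
                                limits = list(zmin = 170, ymin = 262))),
    list(name = "mobile_marrow",
         shape = superellipsoid(c(213, 205, 185), c(138, 97, 57) * 0.9875,
                                c(2, 2, 4), ratio_inner = 0.9625 / 0.9875,
                                limits = list(zmin = 170))),
    list(name = "spine", shape = cappedCylinder(c(213, 120), 16, 36, 218)),
    list(name = "static_marrow",
         shape = cappedCylinder(c(213, 120), 10, 40, 214, ratio_inner = 0.55)),
    list(name = "cord", shape = cappedCylinder(c(213, 120), 5, 40, 216)),
    list(name = "cortical_bone",
         shape = cappedCylinder(c(105, 138), 12, 15, 55)),
    list(name = "cortical_bone",
         shape = cappedCylinder(c(321, 138), 12, 15, 55)),
    # category I organs
    list(name = "liver",
         shape = superellipsoid(c(163, 206, 120), c(76, 72, 80), 2.3,
                                limits = list(ymin = 150))),
    list(name = "stomach",
         shape = superellipsoid(c(262, 235, 130), c(35, 28, 30))),
    list(name = "spleen",
         shape = superellipsoid(c(285, 215, 125), c(24, 22, 22))),
    list(name = "kidneys",
         shape = superellipsoid(c(160, 180, 90), c(24, 18, 40))),
    list(name = "kidneys",
         shape = superellipsoid(c(266, 180, 90), c(24, 18, 40))),
    list(name = "pancreas",
         shape = superellipsoid(c(230, 200, 110), c(55, 15, 12))),
    list(name = "heart",
         shape = superellipsoid(c(240, 212, 190), c(42, 37, 33))),
    list(name = "myocardium",
         shape = superellipsoid(c(240, 212, 190), c(42, 37, 33) * 0.85)),
    list(name = "heart_blood",
         shape = superellipsoid(c(240, 212, 190), c(42, 37, 33) * 0.60)),
    list(name = "gallbladder",
         shape = superellipsoid(c(168, 232, 95), c(12, 12, 15)))
  )
  list(paint = paint,
       liver_target_ml = 1975.90,
       tumor = list(radius_mm = 15, depth = 100, margin_mm = 12,
                    center_mm = NULL))
}

#' Calibrate a mask or shape to a target volume
#'
#' Isotropically rescales the primitive (or a template mask) about its
#' centre by bisection until the rasterized volume matches the target
#' within \code{tol_ml}.
#'
#' @param template a shape spec (from \code{\link{superellipsoid}} /
#'   \code{\link{cappedCylinder}}) or a logical mask array.
#' @param target_ml target volume in mL (> 0).
#' @param grid a \linkS4class{VoxelGrid}.
#' @param tol_ml tolerance in mL; default \code{max(0.05, 1.5 voxel
#'   volumes)} (0.05 mL on the native 1.6719 mm grid).
#' @param carve optional logical array of voxels excluded from the mask
#'   (regions later overwritten by higher-precedence structures).
#' @return list with \code{mask}, \code{scale}, \code{volume_ml} and (for
#'   shape input) the scaled \code{shape}.
#' @export
calibrateVolume <- function(template, target_ml, grid, tol_ml = NULL,
                            carve = NULL) {
  g <- gridOf(grid)
  if (!is.finite(target_ml) || target_ml <= 0)
    phantomStop("invalid_argument", "target volume must be positive")
  vv <- voxelVolumeMl(g)
  if (is.null(tol_ml)) tol_ml <- max(0.05, 1.5 * vv)

  countAt <- if (is.list(template)) {
    function(s) {
      m <- rasterizeShape(template, g, scale = s)
      if (!is.null(carve)) m <- m & !carve
      m
    }
  } else {
    if (sum(template) == 0L)
      phantomStop("invalid_argument", "template mask is empty")
    com <- colMeans(maskWorldCoords(template, g))
    function(s) scaleMaskNN(template, g, com, s)
  }
  lo <- 0.2; hi <- 5
  best <- NULL; best_err <- Inf
  for (it in 1:60) {
    s <- (lo + hi) / 2
    m <- countAt(s)
    v <- sum(m) * vv
    err <- abs(v - target_ml)
    if (err < best_err) { best <- list(mask = m, scale = s, volume_ml = v); best_err <- err }
    if (err <= tol_ml / 2) break
    if (v < target_ml) lo <- s else hi <- s
  }
  if (best_err > tol_ml)
    phantomStop("calibration_failure",
                "could not reach %.2f mL within %.3f mL (best %.3f mL)",
                target_ml, tol_ml, best$volume_ml)
  if (is.list(template)) {
    sh <- template
    sh$semi <- if (!is.null(sh$semi)) sh$semi * best$scale else sh$semi
    if (sh$type == "cylinder") {
      sh$radius <- sh$radius * best$scale
      zc <- (sh$z0 + sh$z1) / 2
      sh$z0 <- zc - (zc - sh$z0) * best$scale
      sh$z1 <- zc + (sh$z1 - zc) * best$scale
    }
    best$shape <- sh
  }
  best
}

# nearest-neighbour rescale of a mask about a world point
scaleMaskNN <- function(mask, grid, center_mm, s) {
  g <- gridOf(grid)
  ax <- worldAxes(g)
  # target bbox: source bbox scaled by s about center
  src <- maskWorldCoords(mask, g)
  lo <- center_mm + (apply(src, 2, min) - center_mm) * s - g@spacing
  hi <- center_mm + (apply(src, 2, max) - center_mm) * s + g@spacing
  ir <- lapply(1:3, function(a) which(ax[[a]] >= lo[a] & ax[[a]] <= hi[a]))
  out <- array(FALSE, g@dims)
  if (any(lengths(ir) == 0L)) return(out)
  toSrcIdx <- function(a) {
    w <- center_mm[a] + (ax[[a]][ir[[a]]] - center_mm[a]) / s
    i <- round((w - g@origin[a]) / g@spacing) + 1
    i[i < 1 | i > g@dims[a]] <- NA
    i
  }
  si <- toSrcIdx(1); sj <- toSrcIdx(2); sk <- toSrcIdx(3)
  sub <- array(FALSE, lengths(ir))
  ok_i <- !is.na(si); ok_j <- !is.na(sj); ok_k <- !is.na(sk)
  sub[ok_i, ok_j, ok_k] <- mask[si[ok_i], sj[ok_j], sk[ok_k]]
  out[ir[[1]], ir[[2]], ir[[3]]] <- sub
  out
}

#' Place the spherical tumor inside the liver
#'
#' The tumor is a sphere of radius \code{radius_mm} whose surface must
#' stay at least \code{margin_mm} inside the liver boundary (checked with
#' the exact distance transform).
#'
#' @param liver_mask logical array, the liver mask.
#' @param spec list with \code{center_mm}, \code{radius_mm} (default 15)
#'   and \code{margin_mm} (default 12).
#' @param grid a \linkS4class{VoxelGrid}.
#' @return logical tumor mask (voxel centres within the radius).
#' @export
placeTumor <- function(liver_mask, spec, grid) {
  g <- gridOf(grid)
  r <- spec$radius_mm
  margin <- if (is.null(spec$margin_mm)) 12 else spec$margin_mm
  if (!is.finite(r) || r <= 0)
    phantomStop("placement_error", "tumor radius must be positive")
  ctr <- spec$center_mm
  if (is.null(ctr))
    phantomStop("placement_error", "tumor centre is not set")
  ci <- round((ctr - g@origin) / g@spacing) + 1
  if (any(ci < 1 | ci > g@dims))
    phantomStop("placement_error", "tumor centre outside the grid")
  d <- distanceTransform(liver_mask, g@spacing)
  if (d[ci[1], ci[2], ci[3]] < r + margin)
    phantomStop("placement_error",
                "tumor sphere does not fit %g mm inside the liver (clearance %.1f mm, need %.1f mm)",
                margin, d[ci[1], ci[2], ci[3]], r + margin)
  sph <- superellipsoid(ctr, r, 2)
  rasterizeShape(sph, g)
}

#' Build the reference-phase label volume
#'
#' Rasterizes the configured anatomy in paint order, calibrates the liver
#' to the target volume (accounting for organs painted over it), labels
#' all remaining voxels as air, and places the tumor in the upper liver:
#' the default centre is the most superior point on the liver's vertical
#' axis with enough interior clearance for the margin.
#'
#' @param config anatomy configuration (default \code{defaultAnatomy()}).
#' @param grid a \linkS4class{VoxelGrid}.
#' @param table a \linkS4class{StructureTable}.
#' @return list with \code{labels} (a \linkS4class{LabelVolume}),
#'   \code{tumor} (list: \code{mask}, \code{center_mm}, \code{radius_mm},
#'   \code{depth}), \code{liver_scale} and \code{config}.
#' @export
buildReferenceLabels <- function(config = defaultAnatomy(),
                                 grid = defaultGrid(),
                                 table = defaultStructureTable()) {
  g <- gridOf(grid)
  painted <- vapply(config$paint, function(p) p$name, character(1))
  required <- setdiff(table@records$name, "air")
  missing <- setdiff(required, painted)
  if (length(missing))
    phantomStop("invalid_config", "required structure(s) missing from config: %s",
                paste(missing, collapse = ", "))
  unknown <- setdiff(painted, table@records$name)
  if (length(unknown))
    phantomStop("invalid_config", "config paints unknown structure(s): %s",
                paste(unknown, collapse = ", "))

  labels <- array(structureId(table, "air"), dim = g@dims)
  liver_scale <- 1
  rasterizeEntry <- function(shape) {
    if (identical(shape$type, "cushion")) {
      u <- array(FALSE, g@dims)
      for (q in config$paint) {
        if (q$name %in% shape$organs && !identical(q$shape$type, "cushion"))
          u <- u | rasterizeShape(q$shape, g)
      }
      m <- dilateMask(u, g@spacing, shape$r_mm)
      if (!is.null(shape$clip)) m <- m & rasterizeShape(shape$clip, g)
      m
    } else {
      rasterizeShape(shape, g)
    }
  }
  for (i in seq_along(config$paint)) {
    p <- config$paint[[i]]
    if (p$name == "liver" && !is.null(config$liver_target_ml)) {
      # voxels later overwritten by higher-precedence organs must not
      # count toward the calibrated liver volume
      carve <- array(FALSE, g@dims)
      for (q in config$paint[seq_along(config$paint) > i])
        carve <- carve | rasterizeEntry(q$shape)
      cal <- calibrateVolume(p$shape, config$liver_target_ml, g, carve = carve)
      liver_scale <- cal$scale
      m <- rasterizeShape(p$shape, g, scale = cal$scale)
    } else {
      m <- rasterizeEntry(p$shape)
    }
    labels[m] <- structureId(table, p$name)
  }
  lv <- labelVolume(labels, g)

  liver_mask <- labels == structureId(table, "liver")
  tum <- config$tumor
  if (is.null(tum$center_mm)) {
    tum$center_mm <- defaultTumorCenter(liver_mask, g, tum$radius_mm,
                                        tum$margin_mm)
  }
  tmask <- placeTumor(liver_mask, tum, g)
  list(labels = lv,
       tumor = list(mask = tmask, center_mm = tum$center_mm,
                    radius_mm = tum$radius_mm, depth = tum$depth,
                    margin_mm = tum$margin_mm),
       liver_scale = liver_scale, config = config)
}

# most superior point on the liver's vertical (centroid) axis with
# clearance >= radius + margin + a small buffer
defaultTumorCenter <- function(liver_mask, grid, radius_mm, margin_mm) {
  g <- gridOf(grid)
  com <- colMeans(maskWorldCoords(liver_mask, g))
  ci <- round((com[1:2] - g@origin[1:2]) / g@spacing) + 1
  d <- distanceTransform(liver_mask, g@spacing)
  need <- radius_mm + margin_mm + max(1.5, g@spacing / 2)
  col <- d[ci[1], ci[2], ]
  ks <- which(col >= need)
  if (!length(ks))
    phantomStop("placement_error",
                "no point on the liver axis offers %.1f mm clearance", need)
  k <- max(ks)
  c(g@origin[1] + (ci[1] - 1) * g@spacing,
    g@origin[2] + (ci[2] - 1) * g@spacing,
    g@origin[3] + (k - 1) * g@spacing)
}

#' Extract a structure mask from a label volume
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param table a \linkS4class{StructureTable}.
#' @param name structure name(s); the union mask is returned.
#' @return logical array.
#' @export
structureMask <- function(labels, table, name) {
  array(labels@labels %in% structureId(table, name), dim = dim(labels@labels))
}

#' Motion-contrast diagnostic
#'
#' For every pair of structures in face contact, the differential rigid
#' displacement (mm) at end of inhalation for a preset. Pairs whose
#' differential approaches the Gaussian blending scale (sigma sqrt(2 pi)
#' ~ 12.5 mm for sigma = 5 mm) risk locally non-invertible forward fields.
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param table a \linkS4class{StructureTable}.
#' @param preset a preset from \code{\link{motionPreset}}.
#' @return data.frame of contact pairs with contact voxel counts and
#'   differential SI/AP displacements.
#' @export
motionContrast <- function(labels, table, preset) {
  lab <- labels@labels
  d <- dim(lab)
  pairs <- list()
  shift_pairs <- function(a, b) {
    key <- paste(pmin(a, b), pmax(a, b), sep = "-")
    keep <- a != b
    table(key[keep])
  }
  p1 <- shift_pairs(lab[-d[1], , ], lab[-1, , ])
  p2 <- shift_pairs(lab[, -d[2], ], lab[, -1, ])
  p3 <- shift_pairs(lab[, , -d[3]], lab[, , -1])
  tab <- tapply(c(p1, p2, p3), names(c(p1, p2, p3)), sum)
  ids <- do.call(rbind, strsplit(names(tab), "-"))
  a <- as.integer(ids[, 1]); b <- as.integer(ids[, 2])
  na <- structureName(table, a); nb <- structureName(table, b)
  ka <- motionFractions(table, na); kb <- motionFractions(table, nb)
  data.frame(a = na, b = nb, contacts = as.integer(tab),
             d_si_mm = abs(ka[, 1] - kb[, 1]) * preset$A_d_cm * 10,
             d_ap_mm = abs(ka[, 2] - kb[, 2]) * preset$A_ap_cm * 10,
             row.names = NULL)
}
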