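# Stylized hindpaw atlas: spheres and capsules in a paw-like layout.
#
# Only the topology of the real hindpaw is preserved: bone counts per
# compartment, medial-to-lateral digit ordering, an anterolateral tarsal
# cluster (cuboid / talus / NAVLATINT), and sporadic fusion of the
# intermediate cuneiform. Primitive sizes are NOT anatomical: every bone is
# sized so that, under the default rendering physics (blur sigma 20 um, bone
# 4000 HU, tissue 200 HU) and the >2500 HU mask, it retains >= ~91% of its
# voxels, which keeps per-bone Dice >= 0.95 achievable by construction.
# Coordinates are micrometres in a 200 x 150 x 110 voxel grid at 17.5 um;
# x runs proximal (tarsals) to distal (distal phalanges), y lateral (digit 5)
# to medial (digit 1), z plantar to dorsal.

# digit rays: y centre and z centre per digit; alternating z keeps adjacent
# rays > 1 voxel apart despite radii of 230 um.
.ray_y <- c(2220, 1770, 1320, 870, 420)   # digits 1..5 (medial -> lateral)
.ray_z <- c(1060, 790, 1060, 790, 1060)
.ses_z <- c(530, 260, 530, 260, 530)

sphere <- function(center, radius) list(type = "sphere",
                                        center = as.numeric(center),
                                        radius = as.numeric(radius))
capsule <- function(p1, p2, radius) list(type = "capsule",
                                         p1 = as.numeric(p1),
                                         p2 = as.numeric(p2),
                                         radius = as.numeric(radius))

hindpaw_geometry <- function(fusion_variant) {
  g <- list(
    Calc = list(capsule(c(310, 700, 960), c(510, 700, 960), 250)),
    Tal = list(capsule(c(330, 1350, 960), c(530, 1350, 960), 250)),
    Tib = list(sphere(c(300, 2050, 960), 270)),
    Cub = list(sphere(c(1070, 600, 960), 270)),
    Med = list(sphere(c(1100, 2000, 960), 260))
  )
  navlat <- capsule(c(1060, 1270, 960), c(1100, 1430, 960), 230)
  if (fusion_variant == "unfused") {
    g$NAVLAT <- list(navlat)
    g$IntCun <- list(capsule(c(900, 1560, 470), c(1000, 1560, 470), 230))
  } else {
    # bony fusion: the intermediate cuneiform primitive overlaps the
    # navicular/lateral-cuneiform capsule so the fused entity is one
    # connected component of the bone mask.
    g$NAVLATINT <- list(navlat,
                        capsule(c(1040, 1360, 870), c(1100, 1440, 870), 230))
  }
  for (d in 1:5) {
    y <- .ray_y[d]; z <- .ray_z[d]; zs <- .ses_z[d]
    g[[paste0("Met", d)]] <- list(capsule(c(1590, y, z), c(1870, y, z), 230))
    g[[paste0("PP", d)]] <- list(capsule(c(2400, y, z), c(2560, y, z), 230))
    if (d >= 2) {
      g[[paste0("DP", d)]] <- list(capsule(c(3090, y, z), c(3190, y, z), 240))
    }
    g[[paste0("S", 2 * d - 1)]] <-
      list(capsule(c(1470, y, zs), c(1570, y, zs), 240))
    g[[paste0("S", 2 * d)]] <-
      list(capsule(c(2090, y, zs), c(2180, y, zs), 240))
  }
  g
}

#' Build the synthetic hindpaw bone atlas
#'
#' Returns a stylized geometric atlas of the mouse hindpaw: 31 uniquely
#' labelled bones (unfused variant) or 30 (fused variant, in which the
#' intermediate cuneiform geometry is merged into the NAVLATINT entity).
#' Bones are spheres and capsules arranged in five compartments with digits
#' ordered medial to lateral; see [bone_catalog()] for labels.
#'
#' The same arguments always produce the identical atlas (no hidden
#' randomness).
#'
#' @param fusion_variant `"unfused"` (31 bones) or `"fused"` (30).
#' @param grid_shape voxel counts per axis, default `c(200, 150, 110)`.
#' @param spacing isotropic voxel spacing in micrometres, default 17.5.
#' @return list of class `phantom_atlas` with elements `bones` (list of
#'   `bone`, `label`, `primitives`), `fusion_variant`, `grid_shape`,
#'   `spacing`, `catalog`.
#' @export
build_bone_atlas <- function(fusion_variant = c("unfused", "fused"),
                             grid_shape = c(200L, 150L, 110L),
                             spacing = 17.5) {
  fusion_variant <- match.arg(fusion_variant)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(spacing) == 1L, spacing > 0)
  grid_shape <- as.integer(grid_shape)
  cat <- bone_catalog(fusion_variant)
  geom <- hindpaw_geometry(fusion_variant)
  if (!identical(sort(names(geom)), sort(cat$bone))) {
    stop("internal error: geometry/catalog mismatch")  # nocov
  }
  extent_um <- (grid_shape - 1L) * spacing
  bones <- lapply(seq_len(nrow(cat)), function(i) {
    bone <- cat$bone[i]
    prims <- geom[[bone]]
    for (p in prims) {
      pts <- if (p$type == "sphere") list(p$center) else list(p$p1, p$p2)
      for (pt in pts) {
        if (any(pt - p$radius < -spacing / 2) ||
            any(pt + p$radius > extent_um + spacing / 2)) {
          stop(sprintf(
            "grid %s too small at %g um spacing: bone '%s' does not fit",
            paste(grid_shape, collapse = "x"), spacing, bone))
        }
      }
    }
    list(bone = bone, label = cat$label[i], primitives = prims)
  })
  structure(list(bones = bones, fusion_variant = fusion_variant,
                 grid_shape = grid_shape, spacing = spacing, catalog = cat),
            class = "phantom_atlas")
}

#' @export
print.phantom_atlas <- function(x, ...) {
  cat(sprintf("<phantom_atlas> %d bones (%s), grid %s @ %g um\n",
              length(x$bones), x$fusion_variant,
              paste(x$grid_shape, collapse = "x"), x$spacing))
  invisible(x)
}

# voxel-centre coordinates along one axis, micrometres
axis_coords <- function(n, spacing) (seq_len(n) - 1) * spacing

#' Rasterize an atlas into a ground-truth label map
#'
#' A voxel belongs to a bone iff its centre lies inside (or on) one of the
#' bone's primitives. Distinct bones must not claim the same voxel (the
#' atlas layout guarantees separation); a bone that rasterizes to zero
#' voxels is an error.
#'
#' @param atlas a [build_bone_atlas()] result.
#' @return a [label_map()] using the atlas labels.
#' @export
rasterize_atlas <- function(atlas) {
  stopifnot(inherits(atlas, "phantom_atlas"))
  d <- atlas$grid_shape
  sp <- atlas$spacing
  lab <- array(0L, d)
  for (b in atlas$bones) {
    sel_total <- 0L
    for (p in b$primitives) {
      hit <- rasterize_primitive(p, d, sp)
      if (length(hit) == 0L) next
      prev <- lab[hit]
      clash <- prev != 0L & prev != b$label
      if (any(clash)) {
        stop(sprintf("bones '%s' and label %d overlap during rasterization",
                     b$bone, prev[clash][1]))
      }
      lab[hit] <- b$label
      sel_total <- sel_total + length(hit)
    }
    if (sel_total == 0L) {
      stop(sprintf("bone '%s' rasterizes to zero voxels", b$bone))
    }
  }
  label_map(lab, sp)
}

# linear indices of voxels inside a primitive, restricted to its bounding box
rasterize_primitive <- function(p, d, sp) {
  lo_pt <- if (p$type == "sphere") p$center else pmin(p$p1, p$p2)
  hi_pt <- if (p$type == "sphere") p$center else pmax(p$p1, p$p2)
  lo <- pmax(1L, floor((lo_pt - p$radius) / sp) + 1L)
  hi <- pmin(d, ceiling((hi_pt + p$radius) / sp) + 1L)
  if (any(lo > hi)) return(integer(0))
  xs <- (lo[1]:hi[1] - 1) * sp
  ys <- (lo[2]:hi[2] - 1) * sp
  zs <- (lo[3]:hi[3] - 1) * sp
  nxb <- length(xs); nyb <- length(ys); nzb <- length(zs)
  X <- rep(xs, times = nyb * nzb)
  Y <- rep(rep(ys, each = nxb), times = nzb)
  Z <- rep(zs, each = nxb * nyb)
  if (p$type == "sphere") {
    inside <- (X - p$center[1])^2 + (Y - p$center[2])^2 +
      (Z - p$center[3])^2 <= p$radius^2
  } else {
    ab <- p$p2 - p$p1
    len2 <- sum(ab^2)
    if (len2 == 0) {
      inside <- (X - p$p1[1])^2 + (Y - p$p1[2])^2 + (Z - p$p1[3])^2 <=
        p$radius^2
    } else {
      t <- ((X - p$p1[1]) * ab[1] + (Y - p$p1[2]) * ab[2] +
              (Z - p$p1[3]) * ab[3]) / len2
      t <- pmin(pmax(t, 0), 1)
      inside <- (X - (p$p1[1] + t * ab[1]))^2 +
        (Y - (p$p1[2] + t * ab[2]))^2 +
        (Z - (p$p1[3] + t * ab[3]))^2 <= p$radius^2
    }
  }
  if (!any(inside)) return(integer(0))
  # local box indices -> global linear indices
  ix <- rep(lo[1]:hi[1], times = nyb * nzb)[inside]
  iy <- rep(rep(lo[2]:hi[2], each = nxb), times = nzb)[inside]
  iz <- rep(lo[3]:hi[3], each = nxb * nyb)[inside]
  ix + d[1] * (iy - 1L) + d[1] * d[2] * (iz - 1L)
}

#' Apply an erosion trajectory to an atlas
#'
#' Shrinks (or grows) each bone to a target fraction of its baseline volume
#' by an isotropic similarity transform about the bone's centroid: all
#' primitive radii, endpoints, and centres are scaled by `fraction^(1/3)`,
#' which scales the continuum volume of the bone (including multi-primitive
#' unions) exactly by `fraction` while leaving its position unchanged.
#'
#' @param atlas a [build_bone_atlas()] result (baseline geometry).
#' @param trajectory an erosion-trajectory data.frame (see
#'   [erosion_trajectory()]) with columns `group`, `sex`, `bone`,
#'   `timepoint`, `fraction`.
#' @param group,sex,timepoint the condition to realize; the trajectory must
#'   define a fraction for every atlas bone at this condition.
#' @return a new `phantom_atlas` with scaled primitives.
#' @export
apply_erosion_trajectory <- function(atlas, trajectory, group, sex,
                                     timepoint) {
  stopifnot(inherits(atlas, "phantom_atlas"))
  tr <- trajectory[trajectory$group == group & trajectory$sex == sex &
                     trajectory$timepoint == timepoint, , drop = FALSE]
  out <- atlas
  for (i in seq_along(atlas$bones)) {
    b <- atlas$bones[[i]]
    f <- tr$fraction[tr$bone == b$bone]
    if (length(f) != 1L) {
      stop(sprintf(
        "trajectory does not define bone '%s' at (%s, %s, timepoint %s)",
        b$bone, group, sex, as.character(timepoint)))
    }
    if (!is.finite(f) || f <= 0) {
      stop(sprintf("volume fraction for bone '%s' must be > 0", b$bone))
    }
    out$bones[[i]] <- scale_bone(b, f)
  }
  out
}

scale_bone <- function(b, fraction) {
  if (fraction == 1) return(b)
  s <- fraction^(1 / 3)
  pts <- lapply(b$primitives, function(p) {
    if (p$type == "sphere") p$center else (p$p1 + p$p2) / 2
  })
  centroid <- Reduce(`+`, pts) / length(pts)
  b$primitives <- lapply(b$primitives, function(p) {
    p$radius <- p$radius * s
    if (p$type == "sphere") {
      p$center <- centroid + s * (p$center - centroid)
    } else {
      p$p1 <- centroid + s * (p$p1 - centroid)
      p$p2 <- centroid + s * (p$p2 - centroid)
    }
    p
  })
  b
}
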