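#' Segmentation parameters
#'
#' Bundles the tunable parameters of the hindpaw segmentation pipeline.
#'
#' @param hu_threshold bone mask threshold in Hounsfield units; voxels with
#'   value strictly greater than this enter the mask. Default 2500 HU.
#' @param median_radius radius (voxels) of the cubic median filter window,
#'   i.e. a \eqn{(2r+1)^3} neighbourhood. Default 1 (3x3x3).
#' @param seed_core_distance erosion depth in micrometres used to carve seed
#'   cores out of the mask's Euclidean distance transform. Default 70 um
#'   (4 voxels at 17.5 um).
#' @param landscape flooding landscape for the watershed: `"gradient"`
#'   (gradient magnitude of the median-filtered image; intensity-watershed
#'   semantics) or `"inverse-distance"` (negated distance transform of the
#'   mask; geometry-driven separation).
#' @return list of class `seg_params`.
#' @export
seg_params <- function(hu_threshold = 2500, median_radius = 1L,
                       seed_core_distance = 70,
                       landscape = c("gradient", "inverse-distance")) {
  landscape <- match.arg(landscape)
  stopifnot(is.finite(hu_threshold), median_radius >= 0,
            seed_core_distance >= 0)
  structure(list(hu_threshold = hu_threshold,
                 median_radius = as.integer(median_radius),
                 seed_core_distance = seed_core_distance,
                 landscape = landscape),
            class = "seg_params")
}

#' Median filter a volume
#'
#' Replaces each voxel by the median of its \eqn{(2r+1)^3} neighbourhood;
#' grid edges are handled by nearest-value (replicate) padding. `radius = 0`
#' returns the image unchanged.
#'
#' @param image a [voxel_image()].
#' @param median_radius window radius in voxels.
#' @return a [voxel_image()].
#' @export
median_filter <- function(image, median_radius = 1L) {
  stopifnot(inherits(image, "voxel_image"), median_radius >= 0)
  d <- grid_dim(image)
  out <- .cpp_median_filter3(as.numeric(image$values), as.integer(d),
                             as.integer(median_radius))
  voxel_image(array(out, d), image$spacing)
}

#' Fixed-threshold bone mask
#'
#' A voxel belongs to the mask iff its intensity is strictly greater than
#' `hu_threshold` (so a voxel at exactly the threshold is excluded).
#'
#' @param image a [voxel_image()].
#' @param hu_threshold threshold in Hounsfield units (default 2500).
#' @return a [binary_mask()].
#' @export
threshold_mask <- function(image, hu_threshold = 2500) {
  stopifnot(inherits(image, "voxel_image"), is.finite(hu_threshold))
  binary_mask(image$values > hu_threshold, image$spacing)
}

#' Generate watershed markers from distance-transform cores
#'
#' Computes the Euclidean distance transform of the mask (micrometres),
#' keeps voxels at depth `>= seed_core_distance` as cores, and labels the
#' 26-connected components of the cores 1..k in deterministic scan order
#' (lexicographic (z, y, x)). This reconstructs the "semi-automated"
#' marker-generation stage; user-supplied markers can be merged downstream
#' (see [segment_hindpaw()]).
#'
#' An empty mask yields an empty seed set (not an error); a core distance so
#' deep that no cores survive yields an empty seed set with a warning.
#'
#' @param mask a [binary_mask()].
#' @param seed_core_distance erosion depth in micrometres.
#' @param spacing voxel spacing in micrometres (defaults to the mask's).
#' @return list of class `seed_set`: `values` (integer marker array, 0 = no
#'   marker), `n` markers, and `provenance` (`"automatic"`).
#' @export
generate_seeds <- function(mask, seed_core_distance = 70,
                           spacing = mask$spacing) {
  stopifnot(inherits(mask, "binary_mask"), seed_core_distance >= 0)
  d <- grid_dim(mask)
  sp <- if (length(spacing) > 1L) mean(spacing) else spacing
  if (!is_isotropic(mask)) {
    warning("anisotropic spacing; seed core depth uses mean spacing")
  }
  if (!any(mask$values)) {
    return(new_seed_set(array(0L, d), mask$spacing, "automatic"))
  }
  dist_um <- sqrt(.cpp_edt_sq3(mask$values, as.integer(d))) * sp
  cores <- array(dist_um >= seed_core_distance & mask$values, d)
  if (!any(cores)) {
    warning("seed_core_distance eroded away all cores; empty seed set")
    return(new_seed_set(array(0L, d), mask$spacing, "automatic"))
  }
  lab <- .cpp_label_components3(cores, as.integer(d))
  new_seed_set(array(lab, d), mask$spacing, "automatic")
}

new_seed_set <- function(values, spacing, provenance) {
  structure(list(values = values, spacing = spacing,
                 n = length(unique(values[values > 0L])),
                 provenance = provenance),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> %d markers (%s)\n", x$n, x$provenance))
  invisible(x)
}

#' Build a seed set from explicit marker voxels
#'
#' @param coords data.frame with columns `x`, `y`, `z` (0-based voxel
#'   indices) and `label` (positive integer marker id).
#' @param dim grid dimensions `c(nx, ny, nz)`.
#' @param spacing voxel spacing in micrometres.
#' @return a `seed_set` with provenance `"user-supplied"`.
#' @export
seeds_from_coords <- function(coords, dim, spacing = 17.5) {
  stopifnot(all(c("x", "y", "z", "label") %in% names(coords)))
  if (any(coords$label < 1L)) stop("marker labels must be >= 1")
  v <- array(0L, dim)
  idx <- cbind(coords$x + 1L, coords$y + 1L, coords$z + 1L)
  if (any(idx < 1L) || any(t(t(idx) > dim))) stop("marker voxel outside grid")
  v[idx] <- as.integer(coords$label)
  sp <- if (length(spacing) == 1L) rep(spacing, 3L) else spacing
  new_seed_set(v, sp, "user-supplied")
}

# User markers override automatic markers voxel-wise; user labels are offset
# above the automatic range so the two never collide.
merge_seed_sets <- function(auto, user) {
  off <- max(0L, auto$values)
  merged <- auto$values
  sel <- user$values > 0L
  merged[sel] <- user$values[sel] + off
  new_seed_set(merged, auto$spacing, "mixed")
}

#' Marker-based watershed inside a mask
#'
#' Floods the chosen landscape from the marker voxels so that every mask
#' voxel receives exactly one marker label; voxels outside the mask stay 0.
#' Marker voxels pre-claim their own labels. The flood is a priority queue
#' of (landscape value at voxel, proposing label, voxel index) entries
#' popped lowest-priority-first; among equal priorities, entries pop in
#' insertion (FIFO) order, which grows equal-priority plateaus in balanced
#' breadth-first layers from all competing markers. Insertion order is
#' itself deterministic: seeds enter sorted by (label, scan order) and
#' neighbours are pushed in lexicographic (z, y, x) offset order, so the
#' output is a pure function of its inputs.
#'
#' @param image a [voxel_image()]; used when `landscape = "gradient"`
#'   (gradient magnitude of this image, which should already be filtered).
#' @param mask a [binary_mask()] delimiting the flood region.
#' @param seeds a `seed_set`; all marker voxels must lie inside the mask.
#' @param landscape `"gradient"` or `"inverse-distance"`.
#' @return a [label_map()] whose label set equals the seed label set.
#' @export
watershed_inside_mask <- function(image, mask, seeds,
                                  landscape = c("gradient",
                                                "inverse-distance")) {
  landscape <- match.arg(landscape)
  stopifnot(inherits(mask, "binary_mask"), inherits(seeds, "seed_set"))
  check_same_grid(mask, seeds)
  d <- grid_dim(mask)
  if (!any(seeds$values > 0L)) stop("no markers")
  outside <- seeds$values > 0L & !mask$values
  if (any(outside)) {
    bad <- sort(unique(seeds$values[outside]))
    stop(sprintf("marker(s) outside mask: %s",
                 paste(bad, collapse = ", ")))
  }
  if (landscape == "gradient") {
    stopifnot(inherits(image, "voxel_image"))
    check_same_grid(image, mask)
    prio <- .cpp_gradient_magnitude3(as.numeric(image$values), as.integer(d))
  } else {
    prio <- -sqrt(.cpp_edt_sq3(mask$values, as.integer(d)))
  }
  lab <- .cpp_watershed_flood3(prio, mask$values,
                               as.integer(seeds$values), as.integer(d))
  label_map(array(lab, d), mask$spacing)
}

#' Segment a hindpaw volume
#'
#' Full semi-automated pipeline: median filter, fixed-HU bone mask, seed
#' generation (optionally merged with user-supplied markers, which take
#' precedence voxel-wise), and marker-based watershed inside the mask.
#'
#' @param image a [voxel_image()] in calibrated Hounsfield units.
#' @param params a [seg_params()].
#' @param user_seeds optional `seed_set` of user markers.
#' @return list of class `segmentation_result` with elements `label_map`,
#'   `seeds`, `params`, and `mask_voxel_count`.
#' @examples
#' \donttest{
#' atl <- build_bone_atlas("unfused")
#' img <- render_image(atl, rng_seed = 1)
#' seg <- segment_hindpaw(img)
#' seg$label_map
#' }
#' @export
segment_hindpaw <- function(image, params = seg_params(), user_seeds = NULL) {
  stopifnot(inherits(image, "voxel_image"), inherits(params, "seg_params"))
  filt <- median_filter(image, params$median_radius)
  mask <- threshold_mask(filt, params$hu_threshold)
  seeds <- generate_seeds(mask, params$seed_core_distance)
  if (!is.null(user_seeds)) {
    stopifnot(inherits(user_seeds, "seed_set"))
    check_same_grid(mask, user_seeds)
    seeds <- merge_seed_sets(seeds, user_seeds)
  }
  lm <- watershed_inside_mask(filt, mask, seeds, params$landscape)
  structure(list(label_map = lm, seeds = seeds, params = params,
                 mask_voxel_count = sum(mask$values)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d labels over %d mask voxels (%s landscape)\n",
              length(label_counts(x$label_map)), x$mask_voxel_count,
              x$params$landscape))
  invisible(x)
}
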