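#' Render a micro-CT-like image from an atlas
#'
#' Rasterizes the atlas, paints bone voxels at `bone_hu` and background at
#' `tissue_hu`, applies a Gaussian partial-volume blur of standard deviation
#' `blur_sigma` (micrometres), then adds i.i.d. Gaussian noise of standard
#' deviation `noise_sd` (HU). The same `rng_seed` always yields a
#' bit-identical image; the caller's RNG state is left untouched.
#'
#' Defaults give plausible micro-CT contrast with the 2500 HU bone threshold
#' comfortably between the two classes.
#'
#' @param atlas a [build_bone_atlas()] result.
#' @param noise_sd additive noise standard deviation in HU (default 150).
#' @param blur_sigma partial-volume blur standard deviation in micrometres
#'   (default 20).
#' @param bone_hu,tissue_hu class intensities in HU (defaults 4000 / 200);
#'   `bone_hu` must exceed `tissue_hu`.
#' @param rng_seed integer seed for the noise stream.
#' @return a [voxel_image()].
#' @export
render_image <- function(atlas, noise_sd = 150, blur_sigma = 20,
                         bone_hu = 4000, tissue_hu = 200, rng_seed = 1L) {
  stopifnot(inherits(atlas, "phantom_atlas"), bone_hu > tissue_hu,
            noise_sd >= 0, blur_sigma >= 0)
  truth <- rasterize_atlas(atlas)
  render_from_truth(truth, noise_sd, blur_sigma, bone_hu, tissue_hu,
                    rng_seed)
}

render_from_truth <- function(truth, noise_sd, blur_sigma, bone_hu,
                              tissue_hu, rng_seed) {
  d <- grid_dim(truth)
  img <- ifelse(truth$values > 0L, bone_hu, tissue_hu)
  if (blur_sigma > 0) {
    sigma_vox <- blur_sigma / mean(truth$spacing)
    img <- .cpp_gaussian_blur3(as.numeric(img), as.integer(d), sigma_vox)
  }
  if (noise_sd > 0) {
    img <- as.numeric(img) +
      with_local_seed(rng_seed, rnorm(prod(d), sd = noise_sd))
  }
  voxel_image(array(as.numeric(img), d), truth$spacing)
}

# run expr under a private RNG seed, restoring the caller's state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Erosion trajectories
#'
#' An erosion trajectory is a tidy table giving, for each (group, sex, bone,
#' timepoint), the target bone volume as a fraction of the first-timepoint
#' baseline (1.0 = no change). `erosion_trajectory()` validates the table:
#' the baseline fraction must be exactly 1 for every bone, all fractions
#' must be positive, and any bone flagged `"U-shaped"` in the optional
#' `shape` column must have exactly one interior minimum
#' (`"monotone-decreasing"` must be non-increasing; `"free"` is unchecked).
#'
#' @param data data.frame with columns `group`, `sex`, `bone`, `timepoint`,
#'   `fraction` and optionally `shape`.
#' @return the validated data.frame, classed `erosion_trajectory`.
#' @export
erosion_trajectory <- function(data) {
  need <- c("group", "sex", "bone", "timepoint", "fraction")
  stopifnot(all(need %in% names(data)))
  if (any(!is.finite(data$fraction)) || any(data$fraction <= 0)) {
    stop("all trajectory fractions must be finite and > 0")
  }
  sel <- split(data, list(data$group, data$sex, data$bone), drop = TRUE)
  for (s in sel) {
    s <- s[order(s$timepoint), ]
    if (abs(s$fraction[1] - 1) > 0) {
      stop(sprintf("baseline fraction must be exactly 1 (bone '%s', %s %s)",
                   s$bone[1], s$group[1], s$sex[1]))
    }
    shape <- if ("shape" %in% names(s)) s$shape[1] else "free"
    if (identical(shape, "monotone-decreasing") &&
        any(diff(s$fraction) > 0)) {
      stop(sprintf("bone '%s' flagged monotone-decreasing but increases",
                   s$bone[1]))
    }
    if (identical(shape, "U-shaped")) {
      n <- length(s$fraction)
      interior_min <- which(diff(sign(diff(s$fraction))) > 0) + 1L
      if (n < 3L || length(interior_min) != 1L) {
        stop(sprintf("bone '%s' flagged U-shaped needs exactly one interior minimum",
                     s$bone[1]))
      }
    }
  }
  class(data) <- c("erosion_trajectory", class(data))
  data
}

#' Default longitudinal erosion trajectory
#'
#' Encodes the qualitative disease course of the TNF-transgenic arthritis
#' model as programmable volume fractions over ages 2-5 months: wild-type
#' bones are static; in TNF-Tg females the cuboid declines early (-24% by
#' 4 months) and the talus and NAVLATINT collapse between 4 and 5 months;
#' TNF-Tg males erode more slowly, the tibiale gains volume, and the
#' sesamoids follow a "U"-shaped course (erosion then remodelling). Where a
#' mean percent change is printed in the source domain (e.g. cuboid
#' -24.1% at 4 months, -44.9% at 5 months in females), the fraction is
#' 1 + pct/100; remaining values interpolate that course.
#'
#' @param timepoints ordered ages in months (default `c(2, 3, 4, 5)`); must
#'   be a subset of the encoded ages.
#' @return an [erosion_trajectory()] covering groups WT and TNF, sexes M
#'   and F, and every atlas bone code (both fusion variants).
#' @export
default_erosion_trajectory <- function(timepoints = c(2, 3, 4, 5)) {
  ages <- c(2, 3, 4, 5)
  if (!all(timepoints %in% ages)) {
    stop("default trajectory is defined for ages 2-5 months")
  }
  # per-bone fractions at ages 2,3,4,5; digit compartments share a course
  tnf_f <- list(
    Cub = c(1, 0.82, 0.759, 0.551), Tal = c(1, 0.97, 0.910, 0.592),
    NAV = c(1, 0.96, 0.914, 0.681), Calc = c(1, 0.97, 0.95, 0.892),
    Med = c(1, 0.93, 0.90, 0.835), Tib = c(1, 0.99, 0.98, 0.987),
    Met = c(1, 0.94, 0.90, 0.88), PP = c(1, 0.92, 0.88, 0.87),
    DP = c(1, 0.91, 0.88, 0.87), S = c(1, 0.93, 0.89, 0.88))
  tnf_m <- list(
    Cub = c(1, 0.93, 0.85, 0.769), Tal = c(1, 0.97, 0.94, 0.875),
    NAV = c(1, 0.98, 0.95, 0.899), Calc = c(1, 0.98, 0.95, 0.917),
    Med = c(1, 0.98, 0.96, 0.921), Tib = c(1, 1.02, 1.05, 1.083),
    Met = c(1, 0.97, 0.94, 0.92), PP = c(1, 0.96, 0.93, 0.91),
    DP = c(1, 0.96, 0.93, 0.92), S = c(1, 0.88, 0.82, 0.90))
  shapes <- c(Cub = "monotone-decreasing", Tal = "monotone-decreasing",
              NAV = "monotone-decreasing", Calc = "monotone-decreasing",
              Med = "monotone-decreasing", Tib = "free",
              Met = "monotone-decreasing", PP = "monotone-decreasing",
              DP = "monotone-decreasing", S = "monotone-decreasing")
  shapes_m <- shapes
  shapes_m["S"] <- "U-shaped"

  all_bones <- unique(c(bone_catalog("unfused")$bone,
                        bone_catalog("fused")$bone))
  key_of <- function(bone) {
    if (bone %in% c("NAVLAT", "IntCun", "NAVLATINT")) return("NAV")
    if (grepl("^Met", bone)) return("Met")
    if (grepl("^PP", bone)) return("PP")
    if (grepl("^DP", bone)) return("DP")
    if (grepl("^S[0-9]+$", bone)) return("S")
    bone
  }
  rows <- list()
  for (bone in all_bones) {
    k <- key_of(bone)
    for (cfg in list(list("WT", "M", rep(1, 4), "free"),
                     list("WT", "F", rep(1, 4), "free"),
                     list("TNF", "M", tnf_m[[k]], unname(shapes_m[k])),
                     list("TNF", "F", tnf_f[[k]], unname(shapes[k])))) {
      rows[[length(rows) + 1L]] <- data.frame(
        group = cfg[[1]], sex = cfg[[2]], bone = bone, timepoint = ages,
        fraction = cfg[[3]], shape = cfg[[4]], stringsAsFactors = FALSE)
    }
  }
  tr <- do.call(rbind, rows)
  tr <- tr[tr$timepoint %in% timepoints, , drop = FALSE]
  # subsetting timepoints can truncate a U-shaped course into a monotone
  # one; downgrade the shape flag so validation reflects the visible series
  if (length(timepoints) < length(ages)) {
    keys <- split(seq_len(nrow(tr)),
                  paste(tr$group, tr$sex, tr$bone, sep = "\r"))
    for (idx in keys) {
      s <- tr[idx, ]
      o <- order(s$timepoint)
      fr <- s$fraction[o]
      if (s$shape[1] == "U-shaped") {
        interior_min <- which(diff(sign(diff(fr))) > 0) + 1L
        if (length(fr) < 3L || length(interior_min) != 1L) {
          tr$shape[idx] <- if (all(diff(fr) <= 0)) "monotone-decreasing"
                           else "free"
        }
      }
    }
  }
  rownames(tr) <- NULL
  erosion_trajectory(tr)
}

#' Cohort specification
#'
#' Describes a synthetic longitudinal cohort: groups with limb counts,
#' scan timepoints, the erosion trajectory, rendering physics, the
#' probability that a limb carries the fused cuneiform variant, and the
#' master RNG seed. The entire generated cohort is a pure function of this
#' specification.
#'
#' Default group sizes mirror the source study design (limbs as the unit of
#' measure): 8 WT male, 8 WT female, 8 TNF-Tg male, and 14 TNF-Tg female
#' limbs, scanned at 2, 3, 4, and 5 months of age.
#'
#' @param groups data.frame with columns `name`, `sex`, `n_limbs`.
#' @param timepoints strictly increasing numeric vector.
#' @param trajectory an [erosion_trajectory()].
#' @param noise_sd,blur_sigma,bone_hu,tissue_hu rendering physics, see
#'   [render_image()]; `bone_hu > 2500 > tissue_hu` is required so the
#'   standard mask threshold separates the classes by construction.
#' @param fusion_probability per-limb probability of the fused variant
#'   (default 0.25, "sporadic").
#' @param grid_shape,spacing atlas grid, see [build_bone_atlas()].
#' @param rng_seed master seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = data.frame(
                          name = c("WT", "WT", "TNF", "TNF"),
                          sex = c("M", "F", "M", "F"),
                          n_limbs = c(8L, 8L, 8L, 14L),
                          stringsAsFactors = FALSE),
                        timepoints = c(2, 3, 4, 5),
                        trajectory = default_erosion_trajectory(timepoints),
                        noise_sd = 150, blur_sigma = 20,
                        bone_hu = 4000, tissue_hu = 200,
                        fusion_probability = 0.25,
                        grid_shape = c(200L, 150L, 110L), spacing = 17.5,
                        rng_seed = 1L) {
  stopifnot(is.data.frame(groups),
            all(c("name", "sex", "n_limbs") %in% names(groups)))
  if (nrow(groups) == 0L) stop("group list is empty")
  if (any(groups$n_limbs < 1L)) stop("each group needs n_limbs >= 1")
  if (length(timepoints) < 1L || is.unsorted(timepoints, strictly = TRUE)) {
    stop("timepoints must be strictly increasing")
  }
  if (!(bone_hu > 2500 && 2500 > tissue_hu)) {
    stop("bone_hu > 2500 > tissue_hu is required")
  }
  if (fusion_probability < 0 || fusion_probability > 1) {
    stop("fusion_probability must be in [0, 1]")
  }
  structure(list(groups = groups, timepoints = timepoints,
                 trajectory = trajectory, noise_sd = noise_sd,
                 blur_sigma = blur_sigma, bone_hu = bone_hu,
                 tissue_hu = tissue_hu,
                 fusion_probability = fusion_probability,
                 grid_shape = as.integer(grid_shape), spacing = spacing,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws a per-limb fusion variant, realizes the erosion trajectory at each
#' timepoint, and (optionally) renders noisy images next to ground-truth
#' label maps. With `output_dir` set, images and truth are written as
#' MetaImage volumes and dropped from memory; otherwise they are returned
#' in the `records` list (suitable for small cohorts).
#'
#' @param spec a [cohort_spec()].
#' @param output_dir optional directory for on-disk volumes.
#' @param render if `FALSE`, skip image rendering (truth only; fast path
#'   for statistics work).
#' @return list of class `cohort_dataset`: `design` (one row per generated
#'   volume: limb_id, group, sex, timepoint, fusion_variant),
#'   `truth_volumes` (truth VolumeTable rows from the rasterized label
#'   maps, report units), `records`, and `spec`.
#' @export
generate_cohort <- function(spec, output_dir = NULL, render = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(output_dir) &&
      !dir.exists(output_dir) && !dir.create(output_dir, recursive = TRUE)) {
    stop("cannot create output_dir")  # nocov
  }
  plan <- with_local_seed(spec$rng_seed, {
    rows <- list()
    for (g in seq_len(nrow(spec$groups))) {
      for (l in seq_len(spec$groups$n_limbs[g])) {
        limb_id <- sprintf("%s_%s_L%02d", spec$groups$name[g],
                           spec$groups$sex[g], l)
        fused <- stats::runif(1) < spec$fusion_probability
        for (tp in spec$timepoints) {
          rows[[length(rows) + 1L]] <- data.frame(
            limb_id = limb_id, group = spec$groups$name[g],
            sex = spec$groups$sex[g], timepoint = tp,
            fusion_variant = if (fused) "fused" else "unfused",
            render_seed = sample.int(.Machine$integer.max, 1L),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })

  base_atlas <- list(
    unfused = build_bone_atlas("unfused", spec$grid_shape, spec$spacing),
    fused = build_bone_atlas("fused", spec$grid_shape, spec$spacing))

  records <- vector("list", nrow(plan))
  vol_rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    atl <- apply_erosion_trajectory(base_atlas[[p$fusion_variant]],
                                    spec$trajectory, p$group, p$sex,
                                    p$timepoint)
    truth <- rasterize_atlas(atl)
    vt <- material_statistics(truth, catalog_assignment(atl))
    vt <- cbind(limb_id = p$limb_id, group = p$group, sex = p$sex,
                timepoint = p$timepoint, vt, stringsAsFactors = FALSE)
    vol_rows[[i]] <- vt
    img <- if (render) {
      render_from_truth(truth, spec$noise_sd, spec$blur_sigma, spec$bone_hu,
                        spec$tissue_hu, p$render_seed)
    } else {
      NULL
    }
    rec <- list(limb_id = p$limb_id, group = p$group, sex = p$sex,
                timepoint = p$timepoint, fusion_variant = p$fusion_variant)
    if (!is.null(output_dir)) {
      stem <- sprintf("%s_t%s", p$limb_id, gsub("[^0-9A-Za-z]", "p",
                                                as.character(p$timepoint)))
      rec$truth_path <- file.path(output_dir, paste0(stem, "_truth.mha"))
      write_volume(truth, rec$truth_path)
      if (!is.null(img)) {
        rec$image_path <- file.path(output_dir, paste0(stem, ".mha"))
        write_volume(img, rec$image_path)
      }
    } else {
      rec$truth <- truth
      rec$image <- img
    }
    records[[i]] <- rec
  }
  design <- plan[, c("limb_id", "group", "sex", "timepoint",
                     "fusion_variant")]
  rownames(design) <- NULL
  truth_volumes <- do.call(rbind, vol_rows)
  rownames(truth_volumes) <- NULL
  structure(list(design = design, truth_volumes = truth_volumes,
                 records = records, spec = spec),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d volumes (%d limbs x %d timepoints)\n",
              nrow(x$design), length(unique(x$design$limb_id)),
              length(unique(x$design$timepoint))))
  invisible(x)
}

#' Label-to-bone assignment implied by an atlas
#'
#' @param atlas a `phantom_atlas`.
#' @return data.frame with columns `label`, `bone` (the truth assignment).
#' @export
catalog_assignment <- function(atlas) {
  stopifnot(inherits(atlas, "phantom_atlas"))
  atlas$catalog[, c("label", "bone")]
}
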