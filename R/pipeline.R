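# End-to-end orchestration: configuration, the full phantom -> segmentation
# -> QC -> morphometry -> effect-size pipeline, and the artifact manifest.

#' Pipeline run configuration
#'
#' A serializable description of a full demonstration run on synthetic
#' data: cohort design, segmentation parameters, QC options, baseline
#' timepoint, statistics options, and the master seed. `write_run_config()`
#' / `read_run_config()` round-trip the configuration through JSON
#' (word-for-word: `read_run_config(write_run_config(cfg))` is identical
#' to `cfg`).
#'
#' @param groups,timepoints,fusion_probability,noise_sd,blur_sigma,bone_hu,tissue_hu,grid_shape,spacing cohort design, see [cohort_spec()].
#' @param hu_threshold,median_radius,seed_core_distance,landscape segmentation, see [seg_params()].
#' @param min_overlap_fraction QC split-detection threshold, see
#'   [classify_errors()].
#' @param baseline_timepoint baseline for percent change (required).
#' @param effect_response `"volume_mm3"` (default; raw volumes) or
#'   `"pct_change"` for effect-size computation.
#' @param large_effect_threshold default 0.138.
#' @param rng_seed master seed.
#' @param log_level `"info"` or `"quiet"`.
#' @return list of class `run_config`.
#' @export
run_config <- function(groups = data.frame(
                         name = c("WT", "TNF"), sex = c("F", "F"),
                         n_limbs = c(2L, 2L), stringsAsFactors = FALSE),
                       timepoints = c(2, 3, 4, 5),
                       fusion_probability = 0.25,
                       noise_sd = 150, blur_sigma = 20, bone_hu = 4000,
                       tissue_hu = 200,
                       grid_shape = c(200L, 150L, 110L), spacing = 17.5,
                       hu_threshold = 2500, median_radius = 1L,
                       seed_core_distance = 70, landscape = "gradient",
                       min_overlap_fraction = 0.05,
                       baseline_timepoint = 2,
                       effect_response = c("volume_mm3", "pct_change"),
                       large_effect_threshold = 0.138,
                       rng_seed = 1L, log_level = c("info", "quiet")) {
  effect_response <- match.arg(effect_response)
  log_level <- match.arg(log_level)
  if (is.null(baseline_timepoint) || length(baseline_timepoint) != 1L ||
      !is.finite(baseline_timepoint)) {
    stop(validation_error("baseline_timepoint is required"))
  }
  if (!baseline_timepoint %in% timepoints) {
    stop(validation_error("baseline_timepoint must be one of the timepoints"))
  }
  groups <- data.frame(name = as.character(groups$name),
                       sex = as.character(groups$sex),
                       n_limbs = as.integer(groups$n_limbs),
                       stringsAsFactors = FALSE)
  structure(list(groups = groups, timepoints = as.numeric(timepoints),
                 fusion_probability = as.numeric(fusion_probability),
                 noise_sd = as.numeric(noise_sd),
                 blur_sigma = as.numeric(blur_sigma),
                 bone_hu = as.numeric(bone_hu),
                 tissue_hu = as.numeric(tissue_hu),
                 grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing),
                 hu_threshold = as.numeric(hu_threshold),
                 median_radius = as.integer(median_radius),
                 seed_core_distance = as.numeric(seed_core_distance),
                 landscape = landscape,
                 min_overlap_fraction = as.numeric(min_overlap_fraction),
                 baseline_timepoint = as.numeric(baseline_timepoint),
                 effect_response = effect_response,
                 large_effect_threshold = as.numeric(large_effect_threshold),
                 rng_seed = as.integer(rng_seed), log_level = log_level),
            class = "run_config")
}

validation_error <- function(msg) {
  structure(class = c("validation_error", "error", "condition"),
            list(message = msg, call = NULL))
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$groups <- as.data.frame(raw$groups, stringsAsFactors = FALSE)
  do.call(run_config, raw)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes phantom generation, segmentation, QC against truth,
#' volume extraction, percent change, per-group heatmaps, and effect-size
#' ranking, writing stable CSV/JSON artifacts plus a checksum manifest to
#' `output_dir`. Rerunning with the same configuration reproduces
#' byte-identical tabular outputs.
#'
#' @param config a [run_config()].
#' @param output_dir output directory (created if needed).
#' @param keep_volumes write rendered images / truth / predicted label
#'   maps as MetaImage files (default TRUE).
#' @return invisibly, a list with `manifest` (data.frame file, md5_checksum),
#'   `volumes`, `pct_change`, `effects`, `qc`.
#' @export
run_pipeline <- function(config, output_dir, keep_volumes = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(output_dir) && !dir.create(output_dir, recursive = TRUE)) {
    stop(validation_error("cannot create output_dir"))  # nocov
  }
  say <- function(fmt, ...) {
    if (config$log_level != "quiet") message(sprintf(fmt, ...))
  }
  t0 <- proc.time()[["elapsed"]]
  write_run_config(config, file.path(output_dir, "run_config.json"))

  spec <- cohort_spec(groups = config$groups,
                      timepoints = config$timepoints,
                      trajectory = default_erosion_trajectory(config$timepoints),
                      noise_sd = config$noise_sd,
                      blur_sigma = config$blur_sigma,
                      bone_hu = config$bone_hu, tissue_hu = config$tissue_hu,
                      fusion_probability = config$fusion_probability,
                      grid_shape = config$grid_shape,
                      spacing = config$spacing, rng_seed = config$rng_seed)
  say("[phantom] generating %d volumes", sum(config$groups$n_limbs) *
        length(config$timepoints))
  cohort <- generate_cohort(spec)

  params <- seg_params(hu_threshold = config$hu_threshold,
                       median_radius = config$median_radius,
                       seed_core_distance = config$seed_core_distance,
                       landscape = config$landscape)
  vol_dir <- file.path(output_dir, "volumes")
  if (keep_volumes) dir.create(vol_dir, showWarnings = FALSE)

  vol_rows <- list()
  qc_list <- list()
  for (i in seq_along(cohort$records)) {
    rec <- cohort$records[[i]]
    stem <- sprintf("%s_t%s", rec$limb_id,
                    gsub("[^0-9A-Za-z]", "p", as.character(rec$timepoint)))
    seg <- segment_hindpaw(rec$image, params)
    catalog <- bone_catalog(rec$fusion_variant)
    corr <- match_labels(seg$label_map, rec$truth)
    report <- classify_errors(corr, config$min_overlap_fraction,
                              total_bones = nrow(catalog))
    assign <- assign_labels_to_catalog(seg$label_map, rec$truth,
                                       catalog[, c("label", "bone")])
    vt <- material_statistics(seg$label_map, assign)
    vol_rows[[i]] <- cbind(limb_id = rec$limb_id, group = rec$group,
                           sex = rec$sex, timepoint = rec$timepoint, vt,
                           stringsAsFactors = FALSE)
    qc_list[[stem]] <- list(
      limb_id = rec$limb_id, timepoint = rec$timepoint,
      fusion_variant = rec$fusion_variant,
      n_labels = length(label_counts(seg$label_map)),
      error_rate_percent = report$error_rate,
      accuracy_percent = report$accuracy,
      counts = as.list(report$counts))
    if (keep_volumes) {
      write_volume(rec$image, file.path(vol_dir, paste0(stem, ".mha")))
      write_volume(rec$truth, file.path(vol_dir, paste0(stem, "_truth.mha")))
      write_volume(seg$label_map,
                   file.path(vol_dir, paste0(stem, "_labels.mha")))
    }
    say("[segment] %s: %d labels, error rate %.1f%%", stem,
        qc_list[[stem]]$n_labels, report$error_rate)
  }
  volumes <- do.call(rbind, vol_rows)
  write.csv(volumes, file.path(output_dir, "volumes.csv"),
            row.names = FALSE)
  jsonlite::write_json(qc_list, file.path(output_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  pct <- percent_change(volumes, config$baseline_timepoint)
  pct_out <- pct
  names(pct_out)[names(pct_out) == "pct_change"] <- "pct_change_percent"
  write.csv(pct_out, file.path(output_dir, "pct_change.csv"),
            row.names = FALSE)

  comp <- aggregate_compartments(volumes)
  write.csv(comp, file.path(output_dir, "compartments.csv"),
            row.names = FALSE)

  for (g in seq_len(nrow(config$groups))) {
    nm <- config$groups$name[g]
    sx <- config$groups$sex[g]
    hm <- heatmap_matrix(pct, nm, sx)
    hm_df <- data.frame(bone = rownames(hm), hm, check.names = FALSE)
    names(hm_df)[-1] <- paste0("t", colnames(hm), "_pct")
    write.csv(hm_df,
              file.path(output_dir, sprintf("heatmap_%s_%s.csv", nm, sx)),
              row.names = FALSE)
  }

  effects <- NULL
  if (length(unique(volumes$group)) >= 2L) {
    say("[stats] effect sizes on %s", config$effect_response)
    stat_tab <- if (config$effect_response == "volume_mm3") {
      data.frame(bone = volumes$bone, group = volumes$group,
                 timepoint = volumes$timepoint,
                 response = volumes$volume_mm3, stringsAsFactors = FALSE)
    } else {
      data.frame(bone = pct$bone, group = pct$group,
                 timepoint = pct$timepoint, response = pct$pct_change,
                 stringsAsFactors = FALSE)
    }
    effects <- rank_biomarkers(
      stat_tab, large_effect_threshold = config$large_effect_threshold)
    effects$response_metric <- config$effect_response
    write.csv(effects, file.path(output_dir, "effects.csv"),
              row.names = FALSE)
  } else {
    say("[stats] single group: skipping effect sizes")
  }

  files <- sort(setdiff(list.files(output_dir, recursive = TRUE),
                        "manifest.csv"))
  manifest <- data.frame(
    file = files,
    md5_checksum = unname(tools::md5sum(file.path(output_dir, files))),
    stringsAsFactors = FALSE)
  write.csv(manifest, file.path(output_dir, "manifest.csv"),
            row.names = FALSE)
  say("[done] %d artifacts in %.1f s", nrow(manifest),
      proc.time()[["elapsed"]] - t0)
  invisible(list(manifest = manifest, volumes = volumes, pct_change = pct,
                 effects = effects, qc = qc_list))
}
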