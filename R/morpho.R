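# Per-bone volume extraction and longitudinal normalization.

# lookup over every bone code either variant can produce, plus the combined
# NAVLATINT reporting unit
full_catalog_lookup <- function() {
  u <- bone_catalog("unfused")
  f <- bone_catalog("fused")
  lk <- rbind(u[, c("bone", "report_unit", "compartment", "digit")],
              f[!f$bone %in% u$bone, c("bone", "report_unit", "compartment",
                                       "digit")])
  rownames(lk) <- NULL
  lk
}

#' Extract per-bone volumes from a label map
#'
#' The "material statistics" stage: volume(bone) = voxel count of its label
#' times the voxel volume \eqn{(spacing/1000)^3} in mm^3. Labels are mapped
#' to bones via `assignment`; the navicular / lateral cuneiform /
#' intermediate cuneiform components are always summed into the single
#' NAVLATINT reporting unit. Voxel counts are kept alongside volumes for
#' exact checks.
#'
#' @param label_map a [label_map()].
#' @param assignment data.frame with columns `label`, `bone` covering every
#'   positive label present in the map (an unassigned label is an error).
#' @return data.frame with columns `bone` (reporting unit), `voxels`,
#'   `volume_mm3`, ordered by catalog order; empty for an empty label map.
#' @examples
#' lm <- label_map(array(c(1L, rep(0L, 7)), c(2, 2, 2)), spacing = 17.5)
#' material_statistics(lm, data.frame(label = 1, bone = "Cub"))
#' # one voxel at 17.5 um = 0.0175^3 = 5.359375e-6 mm3
#' @export
material_statistics <- function(label_map, assignment) {
  stopifnot(inherits(label_map, "label_map"),
            all(c("label", "bone") %in% names(assignment)))
  counts <- label_counts(label_map)
  if (length(counts) == 0L) {
    return(data.frame(bone = character(0), voxels = integer(0),
                      volume_mm3 = numeric(0), stringsAsFactors = FALSE))
  }
  labs <- as.integer(names(counts))
  miss <- setdiff(labs, assignment$label)
  if (length(miss) > 0L) {
    stop(sprintf("unassigned label(s): %s", paste(miss, collapse = ", ")))
  }
  lk <- full_catalog_lookup()
  bone <- assignment$bone[match(labs, assignment$label)]
  unknown <- setdiff(bone, lk$bone)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown bone id(s): %s", paste(unknown, collapse = ", ")))
  }
  unit <- lk$report_unit[match(bone, lk$bone)]
  vox <- tapply(as.numeric(counts), unit, sum)
  voxel_mm3 <- prod(label_map$spacing / 1000)
  out <- data.frame(bone = names(vox), voxels = as.integer(vox),
                    volume_mm3 = as.numeric(vox) * voxel_mm3,
                    stringsAsFactors = FALSE)
  # catalog order (tarsals, then digit compartments medial->lateral)
  ord <- match(out$bone, unique(lk$report_unit))
  out <- out[order(ord), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map predicted labels to catalog bones by plurality overlap
#'
#' Each predicted label is assigned to the reference bone holding the
#' plurality of its voxels (phantom / reference-label mode). Labels whose
#' plurality is tied are an error demanding an explicit user mapping;
#' predicted labels sharing a bone are returned flagged (candidates for
#' [merge_labels()]).
#'
#' @param predicted a [label_map()] (e.g. `segmentation_result$label_map`).
#' @param reference truth [label_map()] whose labels follow `ref_assignment`.
#' @param ref_assignment data.frame `label`, `bone` for the reference map.
#' @return data.frame with columns `label` (predicted), `bone`, and
#'   `shared` (TRUE when >1 predicted label maps to the same bone).
#' @export
assign_labels_to_catalog <- function(predicted, reference, ref_assignment) {
  corr <- match_labels(predicted, reference)
  maj <- corr$majority
  ties <- corr$majority_tied
  if (any(ties)) {
    stop(sprintf(
      "plurality tie for predicted label(s) %s; supply a user mapping",
      paste(names(maj)[ties], collapse = ", ")))
  }
  bone <- ref_assignment$bone[match(maj, ref_assignment$label)]
  if (any(is.na(bone))) {
    stop("reference assignment does not cover all reference labels")
  }
  data.frame(label = as.integer(names(maj)), bone = bone,
             shared = duplicated(bone) | duplicated(bone, fromLast = TRUE),
             stringsAsFactors = FALSE)
}

#' Aggregate bone volumes into compartments and totals
#'
#' Sums a volume table into the five hindpaw compartments (tarsals,
#' metatarsals, proximal phalanges, distal phalanges, sesamoids) plus a
#' grand `total` per limb and timepoint; the total equals the sum of the
#' five compartments (all 30 reporting units) by construction.
#'
#' @param volume_table data.frame with at least `limb_id`, `timepoint`,
#'   `bone`, `volume_mm3` (and optionally `group`, `sex`, `voxels`).
#' @return data.frame with `limb_id`, (`group`, `sex`,) `timepoint`,
#'   `compartment` (five compartments plus `"total"`), `volume_mm3`.
#' @export
aggregate_compartments <- function(volume_table) {
  stopifnot(all(c("limb_id", "timepoint", "bone", "volume_mm3") %in%
                  names(volume_table)))
  lk <- full_catalog_lookup()
  comp <- lk$compartment[match(volume_table$bone, lk$bone)]
  if (any(is.na(comp))) {
    stop(sprintf("unknown bone id(s): %s",
                 paste(unique(volume_table$bone[is.na(comp)]),
                       collapse = ", ")))
  }
  keys <- intersect(c("limb_id", "group", "sex", "timepoint"),
                    names(volume_table))
  base <- volume_table[, keys, drop = FALSE]
  per_comp <- aggregate(list(volume_mm3 = volume_table$volume_mm3),
                        c(base, list(compartment = comp)), sum)
  total <- aggregate(list(volume_mm3 = volume_table$volume_mm3), base, sum)
  total$compartment <- "total"
  out <- rbind(per_comp, total[, names(per_comp)])
  out <- out[order(out$limb_id, out$timepoint,
                   match(out$compartment, c(compartment_names(), "total"))), ]
  rownames(out) <- NULL
  out
}

#' Percent change from a baseline timepoint
#'
#' Computes `100 * (V_t - V_baseline) / V_baseline` per limb and bone (or
#' compartment). The baseline defaults to the earliest timepoint present in
#' the table. Limbs lacking a baseline measurement are excluded with a
#' message (mirroring exclusion of limbs whose baseline scan failed);
#' baseline values of zero yield `NA` percent change with a flag.
#'
#' @param volume_table data.frame with `limb_id`, `timepoint`,
#'   `volume_mm3`, and a unit column `bone` or `compartment`.
#' @param baseline_timepoint baseline; default the minimum timepoint.
#' @return data.frame with the unit column, `limb_id`, (`group`, `sex`,)
#'   `timepoint`, `pct_change`, `baseline_undefined` flag; carries the
#'   baseline as attribute `"baseline_timepoint"`.
#' @export
percent_change <- function(volume_table, baseline_timepoint = NULL) {
  unit_col <- if ("bone" %in% names(volume_table)) {
    "bone"
  } else if ("compartment" %in% names(volume_table)) {
    "compartment"
  } else {
    stop("volume_table needs a 'bone' or 'compartment' column")
  }
  stopifnot(all(c("limb_id", "timepoint", "volume_mm3") %in%
                  names(volume_table)))
  if (is.null(baseline_timepoint)) {
    baseline_timepoint <- min(volume_table$timepoint)
  }
  base <- volume_table[volume_table$timepoint == baseline_timepoint, ]
  if (nrow(base) == 0L) stop("no rows at the baseline timepoint")
  key <- function(d) paste(d$limb_id, d[[unit_col]], sep = "\r")
  base_v <- setNames(base$volume_mm3, key(base))
  has_base <- key(volume_table) %in% names(base_v)
  dropped <- unique(volume_table$limb_id[!has_base])
  if (length(dropped) > 0L) {
    message(sprintf("excluding %d limb/unit series without baseline: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  out <- volume_table[has_base, , drop = FALSE]
  vb <- base_v[key(out)]
  out$pct_change <- ifelse(vb > 0, 100 * (out$volume_mm3 - vb) / vb, NA_real_)
  out$baseline_undefined <- vb <= 0
  keep <- intersect(c("limb_id", "group", "sex", "timepoint", unit_col,
                      "pct_change", "baseline_undefined"), names(out))
  out <- out[, keep]
  rownames(out) <- NULL
  attr(out, "baseline_timepoint") <- baseline_timepoint
  out
}

#' Group-mean percent-change heatmap matrix
#'
#' Bones (rows) by timepoints (columns), each cell the arithmetic mean of
#' the available limb percent-change values for one group and sex. Missing
#' cells stay `NA` (never imputed).
#'
#' @param pct_table output of [percent_change()] (bone-level rows).
#' @param group,sex group selection; must select at least one limb.
#' @return numeric matrix with bones as rownames, timepoints as colnames;
#'   attributes `group` and `sex`.
#' @export
heatmap_matrix <- function(pct_table, group, sex) {
  unit_col <- if ("bone" %in% names(pct_table)) "bone" else "compartment"
  sel <- pct_table[pct_table$group == group & pct_table$sex == sex, ]
  if (nrow(sel) == 0L) stop("empty selection: no limbs for that group/sex")
  bones <- unique(sel[[unit_col]])
  tps <- sort(unique(sel$timepoint))
  m <- matrix(NA_real_, nrow = length(bones), ncol = length(tps),
              dimnames = list(bones, as.character(tps)))
  agg <- aggregate(list(v = sel$pct_change),
                   list(bone = sel[[unit_col]], timepoint = sel$timepoint),
                   function(x) mean(x, na.rm = TRUE))
  m[cbind(match(agg$bone, bones), match(agg$timepoint, tps))] <- agg$v
  attr(m, "group") <- group
  attr(m, "sex") <- sex
  m
}
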