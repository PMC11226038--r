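# Segmentation quality control: overlap matching, the oversplit /
# overconnected / combination error taxonomy, and scripted corrections.

#' Voxel-overlap correspondence between two label maps
#'
#' Tallies exact voxel overlaps for every (reference bone, predicted label)
#' pair and derives both majority assignments: each predicted label maps to
#' the reference bone holding the plurality of its voxels, and each
#' reference bone records the predicted label covering the plurality of its
#' voxels. Plurality ties are broken toward the lower label and flagged.
#'
#' @param predicted,reference [label_map()]s on the same grid.
#' @return list of class `label_correspondence`: `overlap` (matrix,
#'   reference bones x predicted labels), `ref_counts`, `pred_counts`,
#'   `majority` (predicted -> reference), `majority_tied`,
#'   `ref_majority` (reference -> predicted), `ref_majority_tied`.
#' @export
match_labels <- function(predicted, reference) {
  stopifnot(inherits(predicted, "label_map"), inherits(reference, "label_map"))
  check_same_grid(predicted, reference)
  pv <- predicted$values
  rv <- reference$values
  ref_counts <- label_counts(reference)
  pred_counts <- label_counts(predicted)
  sel <- rv > 0L & pv > 0L
  if (any(sel)) {
    tab <- table(ref = rv[sel], pred = pv[sel])
    overlap <- matrix(as.integer(tab), nrow = nrow(tab),
                      dimnames = dimnames(tab))
  } else {
    overlap <- matrix(integer(0), nrow = length(ref_counts), ncol = 0,
                      dimnames = list(names(ref_counts), NULL))
  }
  # make sure every reference bone / predicted label appears even with no
  # overlap at all
  overlap <- pad_matrix(overlap, names(ref_counts), names(pred_counts))

  argmax_low <- function(v) {
    if (all(v == 0L)) return(c(idx = NA_integer_, tied = FALSE))
    m <- max(v)
    w <- unname(which(v == m))
    c(idx = w[1], tied = length(w) > 1L)
  }
  maj <- apply(overlap, 2, function(col) argmax_low(col))
  ref_maj <- apply(overlap, 1, function(row) argmax_low(row))
  majority <- setNames(
    as.integer(rownames(overlap))[maj["idx", ]], colnames(overlap))
  ref_majority <- setNames(
    as.integer(colnames(overlap))[ref_maj["idx", ]], rownames(overlap))
  structure(list(overlap = overlap, ref_counts = ref_counts,
                 pred_counts = pred_counts,
                 majority = majority,
                 majority_tied = setNames(maj["tied", ] > 0,
                                          colnames(overlap)),
                 ref_majority = ref_majority,
                 ref_majority_tied = setNames(ref_maj["tied", ] > 0,
                                              rownames(overlap))),
            class = "label_correspondence")
}

pad_matrix <- function(m, rows, cols) {
  out <- matrix(0L, nrow = length(rows), ncol = length(cols),
                dimnames = list(rows, cols))
  if (length(m) > 0L && nrow(m) > 0L && ncol(m) > 0L) {
    out[rownames(m), colnames(m)] <- m
  }
  out
}

#' Classify segmentation errors per bone
#'
#' Applies the whole-bone error taxonomy: a reference bone is **oversplit**
#' when at least two predicted labels each hold at least
#' `min_overlap_fraction` of its voxels (1 bone split into >1 material);
#' **overconnected** when its plurality predicted label is also the
#' plurality label of another bone (>1 bone combined into 1 material);
#' a **combination** when both hold; otherwise correct. The error rate is
#' the number of incorrectly segmented bones as a percentage of total
#' bones; a combination error counts as one incorrect bone with a type
#' attribute.
#'
#' @param correspondence a [match_labels()] result.
#' @param min_overlap_fraction smaller overlapping slivers are treated as
#'   boundary noise, not splits (default 0.05).
#' @param total_bones denominator for the error rate; defaults to the
#'   number of reference bones, but should be the expected catalog count
#'   (30 or 31) when evaluating against a catalog.
#' @return list of class `error_report`: `per_bone` (data.frame `bone`,
#'   `status`), `counts` (named: correct / oversplit / overconnected /
#'   combination), `error_rate` (percent), `accuracy` (percent),
#'   `total_bones`, `min_overlap_fraction`.
#' @export
classify_errors <- function(correspondence, min_overlap_fraction = 0.05,
                            total_bones = NULL) {
  stopifnot(inherits(correspondence, "label_correspondence"))
  ov <- correspondence$overlap
  rc <- correspondence$ref_counts
  bones <- rownames(ov)
  if (is.null(total_bones)) total_bones <- length(bones)
  split_flag <- vapply(bones, function(b) {
    sum(ov[b, ] / rc[[b]] >= min_overlap_fraction) >= 2L
  }, logical(1))
  rm_lab <- correspondence$ref_majority
  conn_flag <- vapply(bones, function(b) {
    lab <- rm_lab[[b]]
    !is.na(lab) && sum(rm_lab == lab, na.rm = TRUE) >= 2L
  }, logical(1))
  status <- ifelse(split_flag & conn_flag, "combination",
                   ifelse(split_flag, "oversplit",
                          ifelse(conn_flag, "overconnected", "correct")))
  counts <- c(correct = sum(status == "correct"),
              oversplit = sum(status == "oversplit"),
              overconnected = sum(status == "overconnected"),
              combination = sum(status == "combination"))
  incorrect <- sum(status != "correct")
  error_rate <- 100 * incorrect / total_bones
  structure(list(per_bone = data.frame(bone = bones, status = status,
                                       stringsAsFactors = FALSE,
                                       row.names = NULL),
                 counts = counts, error_rate = error_rate,
                 accuracy = 100 - error_rate, total_bones = total_bones,
                 min_overlap_fraction = min_overlap_fraction),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> error rate %.1f%% (accuracy %.1f%%) over %d bones\n",
              x$error_rate, x$accuracy, x$total_bones))
  print(x$counts)
  invisible(x)
}

#' Merge labels (oversplit correction)
#'
#' Rewrites all listed labels to `target_id`; every other voxel is
#' untouched, so the total labelled voxel count is conserved exactly.
#'
#' @param label_map a [label_map()].
#' @param label_ids labels to merge; all must be present.
#' @param target_id the surviving label id.
#' @return corrected [label_map()].
#' @export
merge_labels <- function(label_map, label_ids, target_id) {
  stopifnot(inherits(label_map, "label_map"), length(target_id) == 1L,
            target_id >= 1L)
  present <- as.integer(names(label_counts(label_map)))
  miss <- setdiff(as.integer(label_ids), present)
  if (length(miss) > 0L) {
    stop(sprintf("label id(s) not present: %s", paste(miss, collapse = ", ")))
  }
  v <- label_map$values
  v[v %in% as.integer(label_ids)] <- as.integer(target_id)
  label_map(v, label_map$spacing)
}

#' Re-split a label with extra markers (overconnected correction)
#'
#' Re-runs the marker-based watershed on the region of `target_id` only,
#' flooded from the supplied extra markers; all other labels are untouched
#' and the region's voxel count is conserved exactly. Child regions receive
#' fresh labels above the current maximum.
#'
#' @param label_map a [label_map()].
#' @param image the [voxel_image()] the map came from (used for the
#'   gradient landscape; should be the filtered image).
#' @param target_id label to re-split; must be present.
#' @param extra_seeds a `seed_set` (e.g. [seeds_from_coords()]); every
#'   marker voxel must lie inside the target region.
#' @param landscape `"gradient"` or `"inverse-distance"`.
#' @return corrected [label_map()]; attribute `"children"` maps the new
#'   labels to the original `target_id`.
#' @export
resplit_label <- function(label_map, image, target_id, extra_seeds,
                          landscape = c("gradient", "inverse-distance")) {
  landscape <- match.arg(landscape)
  stopifnot(inherits(label_map, "label_map"), inherits(extra_seeds, "seed_set"))
  check_same_grid(label_map, extra_seeds)
  present <- as.integer(names(label_counts(label_map)))
  if (!(target_id %in% present)) {
    stop(sprintf("label id not present: %d", target_id))
  }
  region <- binary_mask(label_map$values == as.integer(target_id),
                        label_map$spacing)
  outside <- extra_seeds$values > 0L & !region$values
  if (any(outside)) {
    stop(sprintf("seed marker(s) outside target region: %s",
                 paste(sort(unique(extra_seeds$values[outside])),
                       collapse = ", ")))
  }
  if (!any(extra_seeds$values > 0L)) stop("no markers")
  # the flood only reaches seed-connected voxels; demand a marker in every
  # connected component so the region's voxel count is conserved exactly
  comp <- .cpp_label_components3(region$values, grid_dim(region))
  seeded <- unique(comp[extra_seeds$values > 0L])
  unreached <- setdiff(unique(comp[comp > 0L]), seeded)
  if (length(unreached) > 0L) {
    stop(sprintf(
      "target region has %d connected component(s) without a marker",
      length(unreached)))
  }
  sub <- watershed_inside_mask(image, region, extra_seeds, landscape)
  child_src <- sort(unique(sub$values[sub$values > 0L]))
  new_ids <- max(present) + seq_along(child_src)
  v <- label_map$values
  for (i in seq_along(child_src)) {
    v[sub$values == child_src[i]] <- new_ids[i]
  }
  out <- label_map(v, label_map$spacing)
  attr(out, "children") <- setNames(rep(as.integer(target_id),
                                        length(new_ids)), new_ids)
  out
}

#' Per-bone Dice coefficients
#'
#' Dice = 2|A n B| / (|A| + |B|) per reference bone, where A is the union
#' of predicted labels majority-assigned to that bone and B the bone's
#' reference voxels. A bone claimed by no predicted label scores 0 and is
#' flagged `absent`.
#'
#' @param predicted,reference [label_map()]s on the same grid.
#' @return data.frame with columns `bone` (reference label), `dice`,
#'   `absent`.
#' @export
per_bone_dice <- function(predicted, reference) {
  corr <- match_labels(predicted, reference)
  ov <- corr$overlap
  bones <- rownames(ov)
  dice <- numeric(length(bones))
  absent <- logical(length(bones))
  for (i in seq_along(bones)) {
    b <- bones[i]
    preds <- colnames(ov)[!is.na(corr$majority) &
                            corr$majority == as.integer(b)]
    if (length(preds) == 0L) {
      dice[i] <- 0
      absent[i] <- TRUE
      next
    }
    inter <- sum(ov[b, preds])
    size_a <- sum(corr$pred_counts[preds])
    size_b <- corr$ref_counts[[b]]
    dice[i] <- 2 * inter / (size_a + size_b)
  }
  data.frame(bone = as.integer(bones), dice = dice, absent = absent,
             row.names = NULL)
}
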