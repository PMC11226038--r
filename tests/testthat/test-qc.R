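# QC: overlap matching, error taxonomy, merge/resplit corrections, Dice.

test_that("match_labels reproduces identity, permutation, and random tallies", {
  truth <- block_truth(6L)
  # identity
  corr <- match_labels(truth, truth)
  expect_true(all(corr$overlap[cbind(rownames(corr$overlap),
                                     rownames(corr$overlap))] ==
                    corr$ref_counts))
  expect_identical(unname(corr$majority[as.character(1:6)]), 1:6)
  # swap two labels -> permutation matrix
  sw <- truth
  sw$values[truth$values == 1L] <- 2L
  sw$values[truth$values == 2L] <- 1L
  cs <- match_labels(sw, truth)
  expect_equal(unname(cs$majority[c("1", "2")]), c(2L, 1L))
  # random pair equals a per-voxel tally
  set.seed(3)
  dm <- c(20L, 20L, 20L)
  a <- label_map(array(sample(0:3, prod(dm), TRUE), dm))
  b <- label_map(array(sample(0:4, prod(dm), TRUE), dm))
  cr <- match_labels(a, b)
  for (rb in rownames(cr$overlap)) {
    for (pa in colnames(cr$overlap)) {
      expect_identical(cr$overlap[rb, pa],
                       sum(b$values == as.integer(rb) &
                             a$values == as.integer(pa)))
    }
  }
  expect_error(match_labels(a, block_truth(6L)), "mismatch")
})

test_that("error taxonomy classifies canonical single faults", {
  truth <- block_truth(8L)
  # perfect segmentation: zero errors, 100% accuracy
  perfect <- classify_errors(match_labels(truth, truth))
  expect_equal(perfect$error_rate, 0)
  expect_equal(perfect$accuracy, 100)
  expect_true(all(perfect$per_bone$status == "correct"))

  # oversplit: bone 1 covered 60/40 by two predicted labels
  pred <- truth
  reg <- which(truth$values == 1L)
  pred$values[reg[seq_len(round(0.4 * length(reg)))]] <- 99L
  r <- classify_errors(match_labels(pred, truth))
  expect_identical(r$per_bone$status[r$per_bone$bone == "1"], "oversplit")
  expect_equal(unname(r$counts["oversplit"]), 1L)
  expect_equal(r$error_rate, 100 / 8)

  # overconnected: bones 3 and 4 share one predicted label
  pred2 <- truth
  pred2$values[truth$values == 4L] <- 3L
  r2 <- classify_errors(match_labels(pred2, truth))
  expect_identical(r2$per_bone$status[r2$per_bone$bone %in% c("3", "4")],
                   c("overconnected", "overconnected"))
  expect_equal(r2$error_rate, 2 / 8 * 100)

  # slivers below min_overlap_fraction are not splits
  pred3 <- truth
  pred3$values[reg[1]] <- 98L  # 1 voxel of 125
  r3 <- classify_errors(match_labels(pred3, truth))
  expect_identical(r3$per_bone$status[r3$per_bone$bone == "1"], "correct")
})

test_that("merge_labels conserves voxels and validates ids", {
  truth <- block_truth(6L)
  cnt <- label_counts(truth)
  m <- merge_labels(truth, c(5L, 6L), 5L)
  mc <- label_counts(m)
  expect_false("6" %in% names(mc))
  expect_identical(mc[["5"]], cnt[["5"]] + cnt[["6"]])
  expect_identical(sum(mc), sum(cnt))
  # identity merge
  expect_identical(merge_labels(truth, 3L, 3L)$values, truth$values)
  expect_error(merge_labels(truth, c(5L, 77L), 5L), "not present")
  # per-label volumes are sum-preserving under merge
  assign <- data.frame(label = 1:6,
                       bone = c("Calc", "Tal", "Tib", "Cub", "Med", "Tal"))
  v_before <- material_statistics(truth, assign)
  assign_m <- assign[assign$label != 6L, ]
  v_after <- material_statistics(m, assign_m)
  expect_equal(sum(v_after$volume_mm3), sum(v_before$volume_mm3))
})

test_that("resplit_label separates a merged two-sphere region", {
  dm <- c(40L, 20L, 20L)
  s1 <- sphere_mask(dm, rbind(c(12, 10, 10)), 6)
  s2 <- sphere_mask(dm, rbind(c(28, 10, 10)), 6)
  dumbbell <- s1 | s2
  dumbbell[12:28, 9:11, 9:11] <- TRUE  # neck joining the spheres
  lm <- label_map(array(dumbbell * 4L, dm))
  img <- mask_image(dumbbell)
  seeds <- point_seeds(dm, rbind(c(12, 10, 10), c(28, 10, 10)), 1:2)
  before <- label_counts(lm)[["4"]]
  out <- resplit_label(lm, img, 4L, seeds, "inverse-distance")
  kids <- attr(out, "children")
  expect_length(kids, 2L)
  cnt <- label_counts(out)
  # conservation: the children partition the old region exactly
  expect_identical(sum(cnt[names(kids)]), before)
  # each child covers >= 95% of its sphere
  for (s in list(s1, s2)) {
    ov <- max(sum(out$values[s] == as.integer(names(kids)[1])),
              sum(out$values[s] == as.integer(names(kids)[2])))
    expect_gte(ov / sum(s), 0.95)
  }
  # single seed: region relabelled wholesale
  lone <- resplit_label(lm, img, 4L, point_seeds(dm, rbind(c(12, 10, 10)), 1L))
  expect_identical(sum(label_counts(lone)[names(attr(lone, "children"))]),
                   before)
  expect_error(resplit_label(lm, img, 4L,
                             point_seeds(dm, rbind(c(1, 1, 1)), 1L)),
               "outside target region")
  expect_error(resplit_label(lm, img, 9L, seeds), "not present")
  # a disconnected region demands one marker per component
  twin <- label_map(array((s1 | s2) * 4L, dm))
  expect_error(resplit_label(twin, img, 4L,
                             point_seeds(dm, rbind(c(12, 10, 10)), 1L)),
               "without a marker")
})

test_that("per_bone_dice covers identity, disjoint, and half-overlap cases", {
  truth <- block_truth(4L)
  expect_true(all(per_bone_dice(truth, truth)$dice == 1))
  # disjoint: prediction misses bone 1 entirely
  pred <- truth
  pred$values[truth$values == 1L] <- 0L
  d <- per_bone_dice(pred, truth)
  expect_equal(d$dice[d$bone == 1], 0)
  expect_true(d$absent[d$bone == 1])
  # half-overlapping equal cubes -> Dice 0.5
  dm <- c(16L, 8L, 8L)
  a <- array(0L, dm); a[1:8, 1:4, 1:4] <- 1L
  b <- array(0L, dm); b[5:12, 1:4, 1:4] <- 1L
  dh <- per_bone_dice(label_map(a), label_map(b))
  expect_equal(dh$dice, 0.5)
})

test_that("correcting every reported error restores a clean report", {
  truth <- block_truth(8L)
  img <- mask_image(truth$values > 0)
  pred <- truth
  # inject one merge (bones 3+4) and one split (bone 1, axial halves)
  pred$values[truth$values == 4L] <- 3L
  reg <- which(truth$values == 1L, arr.ind = TRUE)
  cut <- reg[reg[, 1] > mean(range(reg[, 1])), ]
  pred$values[cut] <- 90L
  rep1 <- classify_errors(match_labels(pred, truth))
  expect_equal(unname(rep1$counts["oversplit"]), 1L)
  expect_equal(unname(rep1$counts["overconnected"]), 2L)
  # fix the split by merging, the merge by resplitting at the true centres
  fixed <- merge_labels(pred, c(1L, 90L), 1L)
  cent <- function(b) {
    ix <- which(truth$values == b, arr.ind = TRUE)
    round(colMeans(ix))
  }
  fixed <- resplit_label(fixed, img, 3L,
                         point_seeds(dim(fixed$values),
                                     rbind(cent(3L), cent(4L)), 1:2),
                         "inverse-distance")
  # map child labels back onto the truth ids they cover
  corr <- match_labels(fixed, truth)
  relabel <- fixed
  for (pl in names(corr$majority)) {
    relabel$values[fixed$values == as.integer(pl)] <- corr$majority[[pl]]
  }
  rep2 <- classify_errors(match_labels(relabel, truth))
  expect_equal(rep2$error_rate, 0)
})
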