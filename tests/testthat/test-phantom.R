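# Phantom generator: atlas, rasterization, erosion programming, rendering,
# cohorts.

test_that("atlas variants produce 31 / 30 uniquely labelled bones", {
  atl <- phantom_cache("atlas")
  expect_equal(length(atl$bones), 31L)
  labs <- vapply(atl$bones, `[[`, integer(1), "label")
  expect_identical(sort(labs), 1:31)
  atlf <- phantom_cache("atlas", "fused")
  expect_equal(length(atlf$bones), 30L)
  expect_false("IntCun" %in% vapply(atlf$bones, `[[`, character(1), "bone"))
  # deterministic: same arguments -> identical atlas
  expect_identical(build_bone_atlas("unfused"), build_bone_atlas("unfused"))
  # compartment counts: 7 tarsal entities (unfused), 5/5/4/10 digit bones
  expect_identical(as.integer(table(atl$catalog$compartment)[
    compartment_names()]), c(7L, 5L, 5L, 4L, 10L))
  # digit bones ordered medial -> lateral (digit 1 at larger y)
  met_y <- vapply(atl$bones[atl$catalog$bone %in% paste0("Met", 1:5)],
                  function(b) b$primitives[[1]]$p1[2], numeric(1))
  expect_true(all(diff(met_y) < 0))
  # too-small grids fail naming the bone
  expect_error(build_bone_atlas("unfused", grid_shape = c(40L, 40L, 40L)),
               "too small")
})

test_that("rasterized truth partitions the bone voxels", {
  truth <- phantom_cache("truth")
  cnt <- label_counts(truth)
  expect_equal(length(cnt), 31L)
  expect_true(all(cnt >= 1L))
  expect_identical(sum(cnt), sum(truth$values > 0L))
  # the fused NAVLATINT entity is one connected component, so the fused
  # phantom has 30 mask components and the unfused 31
  for (cfg in list(list("unfused", 31L), list("fused", 30L))) {
    t <- phantom_cache("truth", cfg[[1]])
    comp <- hindpawCT:::.cpp_label_components3(t$values > 0L,
                                               dim(t$values))
    expect_equal(length(unique(comp[comp > 0L])), cfg[[2]])
  }
})

test_that("erosion programming hits target fractions within 2%", {
  atl <- phantom_cache("atlas")
  base <- label_counts(phantom_cache("truth"))
  flat <- function(f_cub, f_all) {
    erosion_trajectory(do.call(rbind, lapply(
      unique(atl$catalog$bone), function(b)
        data.frame(group = "G", sex = "F", bone = b, timepoint = c(0, 1),
                   fraction = c(1, if (b == "Cub") f_cub else f_all)))))
  }
  # identity: fraction 1.0 -> voxel-identical atlas
  a1 <- apply_erosion_trajectory(atl, flat(1, 1), "G", "F", 1)
  expect_identical(rasterize_atlas(a1)$values, phantom_cache("truth")$values)
  # cuboid-only decline: cuboid scales, everything else untouched
  a2 <- apply_erosion_trajectory(atl, flat(0.75, 1), "G", "F", 1)
  cnt2 <- label_counts(rasterize_atlas(a2))
  cub <- as.character(atl$catalog$label[atl$catalog$bone == "Cub"])
  expect_lt(abs(cnt2[[cub]] / base[[cub]] - 0.75), 0.02)
  others <- setdiff(names(base), cub)
  expect_identical(cnt2[others], base[others])
  # global shrink across the stated fraction range
  for (f in c(0.3, 0.5, 0.8)) {
    af <- apply_erosion_trajectory(atl, flat(f, f), "G", "F", 1)
    cf <- label_counts(rasterize_atlas(af))
    ratio <- cf[names(base)] / base
    expect_true(all(abs(ratio - f) <= 0.02))
    expect_lt(abs(sum(cf) / sum(base) - f), 0.02)
  }
  # invalid fractions are rejected
  bad <- flat(1, 1)
  bad$fraction[bad$bone == "Tal" & bad$timepoint == 1] <- -0.1
  expect_error(erosion_trajectory(bad), "> 0")
  expect_error(apply_erosion_trajectory(atl, flat(1, 1)[-(1:2), ],
                                        "G", "F", 1), "does not define")
})

test_that("trajectory validation enforces baseline and shape flags", {
  tr <- default_erosion_trajectory()
  expect_s3_class(tr, "erosion_trajectory")
  expect_true(all(tr$fraction[tr$timepoint == 2] == 1))
  # the TNF male sesamoid course is U-shaped with one interior minimum
  s <- tr[tr$group == "TNF" & tr$sex == "M" & tr$bone == "S1", ]
  s <- s[order(s$timepoint), ]
  expect_identical(s$shape[1], "U-shaped")
  expect_equal(which.min(s$fraction), 3L)
  # a broken baseline is rejected
  bad <- tr
  bad$fraction[bad$timepoint == 2][1] <- 0.9
  expect_error(erosion_trajectory(bad), "baseline")
})

test_that("rendering is seed-deterministic with the stated contrast", {
  atl <- phantom_cache("atlas")
  # noiseless, unblurred render contains exactly the two class values and
  # thresholding recovers the truth mask exactly
  img0 <- render_image(atl, noise_sd = 0, blur_sigma = 0, rng_seed = 1)
  expect_setequal(unique(as.vector(img0$values)), c(200, 4000))
  expect_identical(threshold_mask(img0)$values,
                   phantom_cache("truth")$values > 0L)
  # same seed -> bit-identical; different seed -> different noise
  a <- render_image(atl, rng_seed = 42)
  b <- render_image(atl, rng_seed = 42)
  c <- render_image(atl, rng_seed = 43)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
  # default render: the mask recovers most truth bone voxels. NOTE: with the
  # stated physics (blur sigma 20 um, 4000/200 HU, threshold 2500) the
  # blurred boundary crosses 2500 HU about 5.4 um inside the true surface,
  # so ~8-9% of boundary voxels are necessarily lost; >= 0.90 is the
  # attainable bound (see methods vignette, "Partial-volume bias").
  truth_mask <- phantom_cache("truth")$values > 0L
  m <- threshold_mask(median_filter(a, 1))$values
  expect_gte(sum(m & truth_mask) / sum(truth_mask), 0.90)
  jac <- sum(m & truth_mask) / sum(m | truth_mask)
  expect_gte(jac, 0.90)
  expect_lte(sum(m & !truth_mask), 0.005 * sum(truth_mask))
})

test_that("generate_cohort is a pure function of its spec", {
  spec <- cohort_spec(groups = data.frame(name = c("WT", "TNF"),
                                          sex = c("F", "F"),
                                          n_limbs = c(2L, 1L)),
                      timepoints = c(2, 3, 4),
                      rng_seed = 99)
  coh <- generate_cohort(spec, render = FALSE)
  # 3 limbs x 3 timepoints -> 9 volumes, 9 design rows
  expect_equal(nrow(coh$design), 9L)
  expect_equal(length(coh$records), 9L)
  expect_equal(nrow(coh$truth_volumes), 9L * 30L)
  # reproducibility
  coh2 <- generate_cohort(spec, render = FALSE)
  expect_identical(coh$design, coh2$design)
  expect_identical(coh$truth_volumes, coh2$truth_volumes)
  # WT limbs stay constant across timepoints
  wt <- coh$truth_volumes[coh$truth_volumes$group == "WT", ]
  for (l in unique(wt$limb_id)) {
    sub <- wt[wt$limb_id == l, ]
    expect_true(all(tapply(sub$voxels, sub$bone,
                           function(v) length(unique(v))) == 1L))
  }
  # programmed TNF female cuboid decline shows up in truth volumes
  pct <- percent_change(coh$truth_volumes)
  cub4 <- pct$pct_change[pct$group == "TNF" & pct$bone == "Cub" &
                           pct$timepoint == 4]
  expect_true(all(abs(cub4 - (-24.1)) <= 2))
  # invalid specs are rejected
  expect_error(cohort_spec(groups = data.frame(name = character(0),
                                               sex = character(0),
                                               n_limbs = integer(0))),
               "empty")
  expect_error(cohort_spec(timepoints = c(3, 2)), "strictly increasing")
  expect_error(cohort_spec(tissue_hu = 3000), "2500")
})
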