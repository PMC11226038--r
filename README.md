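# hindpawCT

Seeded-watershed segmentation and longitudinal bone morphometry for murine
hindpaw micro-CT, with a synthetic phantom cohort for validation.

## The problem

In the TNF-transgenic mouse model of inflammatory-erosive arthritis, bone
erosion localizes to specific bones of the hindpaw — a complex of 30–31
bones (the intermediate cuneiform sporadically fuses with the navicular /
lateral cuneiform). Quantifying *per-bone* volume over time turns in-vivo
micro-CT into a biomarker instrument: the cuboid reports disease early in
females, the talus and calcaneus respond fastest to anti-TNF therapy, the
tibiale barely changes. This package re-implements that analysis chain as
tested, reusable code:

1. **Segmentation** — median filter → fixed bone threshold (> 2500 HU,
   strict) → distance-core marker generation → marker-based watershed
   flooded inside the mask (`segment_hindpaw()`), deterministic down to the
   documented tie-break.
2. **QC** — voxel-overlap matching against reference labels with an
   oversplit / overconnected / combination error taxonomy and per-dataset
   error rates (`classify_errors()`); scripted corrections
   (`merge_labels()`, `resplit_label()`) that conserve voxel counts
   exactly.
3. **Morphometry** — per-bone volumes in mm³ ("material statistics", with
   the navicular+cuneiform complex always reported combined as NAVLATINT,
   30 analysis units per limb), compartment aggregation, percent change
   from a 2-month baseline, group-mean heatmap matrices.
4. **Biomarker statistics** — treatment × time two-way ANOVA decompositions
   and the printed effect-size equations

   η² = SS_eff/SS_tot,  partial η² = SS_eff/(SS_tot+SS_err),
   ω² = (SS_eff − DF_eff·MS_err)/(SS_tot + MS_err)

   with a large-effect threshold of 0.138 (`rank_biomarkers()`), plus a
   median/MAD + FDR outlier detector standing in for ROUT (Q = 1%).
5. **Phantom** — a stylized 30/31-bone hindpaw with HU-realistic contrast,
   partial-volume blur, noise, sporadic fusion, and programmable per-bone
   erosion trajectories (`build_bone_atlas()`, `generate_cohort()`), the
   ground truth for every quantitative claim the tests make.

## Worked example

```r
library(hindpawCT)

atlas <- build_bone_atlas("unfused")        # 31 uniquely labelled bones
image <- render_image(atlas, rng_seed = 7)  # blur 20 um, noise 150 HU
seg   <- segment_hindpaw(image)             # default params, 2500 HU
seg
#> <segmentation_result> 31 labels over 432204 mask voxels (gradient landscape)

truth <- rasterize_atlas(atlas)
summary(per_bone_dice(seg$label_map, truth)$dice)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.9551  0.9557  0.9564  0.9571  0.9572  0.9617

vols <- material_statistics(seg$label_map,
                            assign_labels_to_catalog(
                              seg$label_map, truth,
                              catalog_assignment(atlas)))
head(vols, 3)
#>   bone voxels volume_mm3
#> 1 Calc  18100 0.09700469
#> 2  Tal  18136 0.09719763
#> 3  Tib  14120 0.07567438
```

31 labels is the full unfused bone count; every bone overlaps its ground
truth at Dice ≥ 0.95 (the ~0.96 ceiling is the partial-volume erosion of a
blurred boundary thresholded at 2500 HU — see the methods vignette);
volumes are voxel counts × (0.0175 mm)³. A longitudinal run over a cohort
(phantom generation → segmentation → QC → percent change → heatmaps →
effect sizes, with a checksum manifest) is one call:

```r
cfg <- run_config(groups = data.frame(name = c("WT", "TNF"),
                                      sex = c("F", "F"),
                                      n_limbs = c(2L, 2L)),
                  timepoints = c(2, 3, 4, 5), baseline_timepoint = 2)
res <- run_pipeline(cfg, "out/")
subset(res$pct_change, bone == "Cub" & group == "TNF" & timepoint == 4)
#>       limb_id group sex timepoint bone pct_change baseline_undefined
#> 304 TNF_F_L01   TNF   F         4  Cub  -25.18760              FALSE
#> 424 TNF_F_L02   TNF   F         4  Cub  -24.99823              FALSE
```

The programmed TNF-female cuboid decline at month 4 is −24.1%; the
end-to-end pipeline (rendering physics, segmentation, and volume
extraction included) recovers it within about one percentage point.

There is also a command-line front end
(`inst/cli/hindpawct.R`; subcommands `phantom-generate`, `segment`,
`qc-evaluate`, `qc-merge`, `qc-resplit`, `volumes`, `run`; exit codes
0/1/2 = ok/validation/runtime).

## Layout

- `R/` — atlas/phantom (`atlas.R`, `phantom.R`, `catalog.R`), segmentation
  (`imgseg.R`), QC (`qc.R`), morphometry (`morpho.R`), statistics
  (`stats.R`), I/O (`io.R`: native MetaImage + NIfTI-1), orchestration
  (`pipeline.R`).
- `src/` — Rcpp primitives: 3D median filter, separable Gaussian blur,
  gradient magnitude, exact Euclidean distance transform, 26-connected
  components, priority-flood watershed.
- `vignettes/hindpaw-methods.Rmd` — the model, its assumptions, parameter
  choices, phantom design (and what a green test does *not* establish),
  numerical conventions, known limitations.
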