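---
title: "Methods: phantom-validated hindpaw micro-CT morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-validated hindpaw micro-CT morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hindpawCT)
```

## The problem

Inflammatory-erosive arthritis in the TNF-transgenic (TNF-Tg) mouse destroys
bone in the hindpaw, a joint complex of 30–31 bones (the count varies because
the intermediate cuneiform sporadically fuses with the navicular / lateral
cuneiform, even differing between the two limbs of one animal). Tracking
*which* bone erodes, and when, turns per-limb micro-CT into a biomarker
instrument: some tarsals (cuboid, talus) report disease early or respond
fast to anti-TNF therapy, others (tibiale) barely change. This package
implements the full quantitative chain — segmentation, error accounting,
longitudinal volume morphometry, and effect-size-based biomarker ranking —
and validates it against a synthetic phantom cohort with known ground truth.

## Segmentation model

The pipeline mirrors a marker-based-watershed protocol for
Hounsfield-calibrated volumes at 17.5 µm isotropic spacing:

1. **Median filter** (radius 1, i.e. a 3×3×3 window; replicate padding).
2. **Bone mask** at a fixed threshold: voxel ∈ mask ⇔ value **> 2500 HU**
   (strictly; a voxel at exactly 2500 is excluded — a literal reading of the
   printed parenthesis).
3. **Marker generation**: the Euclidean distance transform of the mask is
   eroded at depth ≥ `seed_core_distance` (default 70 µm ≈ 4 voxels); the
   26-connected components of the surviving cores become markers, numbered
   in deterministic scan order. The reference protocol is "semi-automated"
   without printed operators, so this distance-core construction is our
   stand-in, and user-supplied markers are first class (they override
   automatic markers voxel-wise and are recorded in the provenance field).
4. **Marker-based watershed inside the mask**: a priority flood over a
   landscape, constrained to the mask, so that every mask voxel receives
   exactly one marker label.

**Flooding landscape.** The original software does not document its
landscape. Default is the gradient magnitude of the median-filtered image
(intensity-watershed semantics); `"inverse-distance"` (negated EDT of the
mask) is available for geometry-driven separation. Both are recorded in the
result's parameters.

**Determinism and plateau handling.** Marker voxels pre-claim their own
labels, so a marker can never be overrun by a competing flood. Queue
entries pop lowest-landscape-value first; among equal values they pop in
insertion (FIFO) order, which grows an equal-priority plateau in balanced
breadth-first layers from all competing markers — the standard watershed
plateau semantics, and the reason two touching equal spheres with
symmetric markers split evenly. (A strict value-label-index ordering was
considered and rejected: on quantized landscapes such as a mask's EDT, it
lets the lowest label sweep an entire connected plateau, splitting
touching equal spheres ~27/73.) Insertion order is itself deterministic —
seeds enter sorted by (label, scan order), neighbours are pushed in
lexicographic (z, y, x) offset order — so identical inputs give
bit-identical label maps, and the flood matches an independently coded
brute-force priority flood voxel-for-voxel (acceptance criterion 2).

## Error taxonomy and corrections

Against reference labels, each bone is **oversplit** (≥ 2 predicted labels
each hold ≥ 5% of its voxels), **overconnected** (its plurality label is
also another bone's plurality label), a **combination** (both), or correct.
The 5% sliver threshold is a design choice: the error rate counts
whole-bone faults, not boundary voxel disputes; it is configurable and
logged. The error rate divides incorrect bones by the catalog bone count
(30 or 31); a combination error counts one incorrect bone carrying a type
attribute (the source does not state whether it was counted once or twice —
we chose once, recorded here). Corrections are scripted operators:
`merge_labels()` (oversplit) and `resplit_label()` (overconnected; re-runs
the watershed inside the target region only, demanding one marker per
connected component so voxel counts are conserved exactly).

## Morphometry

Volume(bone) = voxel count × (spacing/1000)³ mm³. The navicular + lateral
cuneiform + intermediate cuneiform are always reported combined
("NAVLATINT"), so every limb yields 30 analysis units. Percent change is
100·(V_t − V_baseline)/V_baseline per limb, baseline defaulting to the
first available timepoint (2 months of age in the emulated design); limbs
without a baseline are excluded, never imputed, mirroring the source
study's exclusions for motion artifact. Compartment totals (tarsals,
metatarsals, proximal/distal phalanges, sesamoids) sum to the grand total
by construction; whether the original "total" included sesamoids is not
stated numerically, so here total = all 30 units, documented.

## Effect sizes

For bone-level biomarker ranking the response (default raw volume; percent
change selectable, and the choice is recorded in output metadata) is
decomposed by a cell-means two-way ANOVA in treatment × time, and the
"Effect" is the interaction. The three printed equations are applied
verbatim:

- η² = SS_effect / SS_total
- partial η² = SS_effect / (SS_total + SS_error)
- ω² = (SS_effect − DF_effect·MS_error) / (SS_total + MS_error)

**The partial η² denominator deserves a note.** The classical definition is
SS_effect/(SS_effect + SS_error) and satisfies partial η² ≥ η². The printed
equation instead uses SS_total + SS_error, and the published values confirm
it (talus partial η² = 0.20 < η² = 0.21; calcaneus 0.19 < 0.22), which is
impossible under the classical formula. We therefore follow the printed
equation — so here partial η² ≤ η² always — and expose the classical value
as `partial_eta2_classical`. ω² is reported raw and may be negative; an
effect is "large" above 0.138 (a configurable constant defaulting to the
published dashed line).

Unbalanced designs (deaths, exclusions) use the unweighted-means analysis
(harmonic-mean cell size) and are flagged; mixed-effects modelling and
Tukey post-hocs are deliberately out of scope. Outlier flagging is a
median/MAD robust z-score with Benjamini–Hochberg control at a Q-like 1%
target — a documented stand-in for the proprietary ROUT procedure, not
bit-compatible with it.

## The synthetic phantom

No imaging data are deposited with the source study, so validation runs on
a stylized phantom preserving only hindpaw *topology*: 30/31 bones in five
compartments (7/6 tarsal entities, 5 metatarsals, 5 proximal phalanges,
4 distal phalanges on digits 2–5, 10 sesamoids), digits ordered medial to
lateral, an anterolateral tarsal cluster, and sporadic cuneiform fusion
(per-limb Bernoulli draw, default probability 0.25 — "sporadic"). Bones are
spheres and capsules; rendering paints bone at 4000 HU on a 200 HU
background, applies Gaussian partial-volume blur (σ = 20 µm), and adds
i.i.d. Gaussian noise (σ = 150 HU). These defaults put the 2500 HU
threshold comfortably between the classes; the source gives no quantitative
noise/contrast characterization, so they are stated, not fitted.

**Partial-volume bias and bone sizing.** With a 3800 HU step blurred at
σ = 20 µm, the rendered intensity crosses 2500 HU at
qnorm((2500−200)/3800)·σ ≈ 5.4 µm *inside* the true surface (plus a
curvature-dependent term), so the recovered mask systematically loses
≈ 8–9% of boundary voxels. This is physics, not a bug: per-bone Dice
against voxel truth is bounded near 2v/(1+v) with v the retained fraction.
We therefore sized every primitive (numeric calibration on isolated
spheres/capsules, then frozen) so each bone retains ≥ 91% of its voxels,
keeping per-bone Dice ≥ 0.95 attainable. That calibration forced two
design deviations, both deliberate: (i) the default grid is 200×150×110
voxels rather than the smaller desk-scale suggestion, because 31
sufficiently thick bones with ≥ 2-voxel separations cannot pack into the
smaller grid; (ii) relative bone sizes are *not* anatomical (sesamoids are
nearly as thick as tarsals) — the analysis consumes volumes and labels, not
shapes. Consequently a green segmentation test establishes correct
topology, labelling, and volume recovery under the stated physics; it does
not establish performance on real anatomy, real noise spectra, motion
artifact, or beam hardening, none of which are simulated.

**Erosion programming.** A trajectory table assigns each (group, sex, bone,
timepoint) a target volume fraction of baseline. Bones are shrunk by an
isotropic similarity transform about their centroid (radii and endpoints
scaled by fraction^(1/3)), which scales even multi-primitive unions
exactly; rasterized volumes land within ±2% of target down to fraction
0.3. The default trajectory encodes the emulated disease course over
months 2–5: wild-type static; TNF-Tg females with early cuboid decline
(−24.1% by 4 months) and a talus/NAVLATINT collapse between 4 and 5
months; TNF-Tg males slower, with a growing tibiale and a "U"-shaped
sesamoid course. Printed group means, where available, enter as fractions
1 + pct/100; the remaining values interpolate those courses and were fixed
once, before any test was run.

**Cohort defaults** mirror the emulated design with limbs as the unit:
8/8/8/14 limbs (WT-M/WT-F/TNF-M/TNF-F) at months 2–5. Tests and the
acceptance suite run smaller cohorts (1–2 limbs) purely for time budget;
the per-limb recovery property they assert does not depend on cohort size.

## Numerical choices

- Arrays are `dim = c(nx, ny, nz)`; voxel (x, y, z) is 0-based in
  coordinates; physical position = index × spacing (µm). Linear index
  order realizes the lexicographic (z, y, x) tie-break.
- 26-connectivity everywhere (components, flooding), fixed and documented.
- Median filter and blur use replicate padding; the gradient uses central
  differences with one-sided edges.
- Volumes are reported in mm³ (double precision) with voxel counts kept
  alongside for exact checks.
- Images are stored as signed 16-bit HU, label maps as unsigned 16-bit;
  file spacing is millimetres (the MetaImage/NIfTI convention), in-memory
  spacing micrometres.
- Config serialization is JSON (no YAML reader is available in the
  offline dependency set); the schema is otherwise as designed.
- The biomarker-recovery simulation (criterion 8) uses 2 groups × 3
  timepoints × 6 limbs, time slope 0.02 mm³/unit, responder interaction
  0.10 mm³/unit, noise σ = 0.08 mm³ — calibrated once so the responder's
  expected η² ≈ 0.21, the magnitude reported for the talus, then frozen.

## Known limitations

- The phantom's noiseless configuration is segmented with median radius 0;
  with a radius-1 median filter a noiseless binary image still loses
  convex-corner voxels, so "Dice = 1.0" is a property of the noiseless
  *configuration*, not of the default filter chain.
- The seed-core marker generator assumes each bone keeps a core at the
  default 70 µm depth; bones thinner than ~140 µm after erosion would lose
  their marker and must be seeded manually (`seeds_from_coords()`).
- Real scanner effects (motion, beam hardening, calibration drift) are out
  of scope; inputs are assumed HU-calibrated.
- Statistical outputs stop at decompositions and effect sizes: no p-values,
  post-hoc letters, or mixed-effects fits.
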