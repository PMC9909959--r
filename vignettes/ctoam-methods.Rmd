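---
title: "CT osteoabsorptiometry of subchondral bone: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT osteoabsorptiometry of subchondral bone: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctoam)
```

## The measurement and its rationale

Subchondral bone remodels under habitual load (Wolff's law): regions of a
joint surface that carry more stress over years mineralize more densely.
Computed tomography osteoabsorptiometry (CTOAM) turns a calibrated CT scan
into a map of that load history. The analysis chain implemented here is:

1. **Density binning.** Bone voxels are assigned to twelve Hounsfield-unit
   intervals, `[100,200], [201,300], ..., [1101,1200], [1201,max]`, grouped
   into *low* (bins 1–4), *medium* (5–8) and *high* (9–12) density classes.
   Intervals are closed on integer HU and gapless; values below 100 HU are
   not bone tissue of interest. Float HU are rounded to the nearest integer
   first, which makes bin membership exact and label-faithful.
2. **Bone tissue of interest (BTOI).** The analyzed compartment is the
   subchondral bone between the articular surface and the epiphyseal line
   (the growth-plate remnant). We model the epiphyseal line as a flat plane
   at a configurable slice: `bone_mask()` thresholds at 100 HU,
   `region_grow()` isolates the bone as a 26-connected component, and
   `clip_to_epiphyseal()` keeps the articular side of the plane and re-grows
   the largest component. A best-effort plane detector
   (`detect_epiphyseal_plane()`, lowest in-mask mean slice HU) exists but an
   explicit plane always overrides it.
3. **%BTV.** For each interval *i*, `btv_profile()` reports the volume of
   bone in that interval and the percentage of the BTOI it represents,
   \(\%BTV_i = 100\, V_i / \sum_{j=1}^{12} V_j\). The twelve percentages sum
   to 100 by construction. Voxels below 100 HU are excluded from the
   denominator; this choice keeps the profile a true composition over the
   twelve printed intervals.
4. **Surface mapping.** `project_density()` computes a maximum-intensity
   projection along the inferior–superior axis over the ROI: densitograms
   conventionally visualize the *maximal* subchondral density, and maxima
   are what high-density-area detection should see. Mean projection and
   surface-normal projection are deliberately out of scope.
5. **Nine regions.** `nine_regions()` lays a 3×3 equal-thirds grid over the
   bounding box of the articular footprint. Rows run anterior→posterior,
   columns medial→lateral; region 5 is central, and the medial column flips
   sides between left and right knees so numbering is anatomical. This grid
   is an explicit convention of the package: the anatomical drawings that
   usually define such regions cannot be reduced to code without the
   original images, so only the count→percent arithmetic and
   self-consistency of the partition are ever asserted, never agreement
   with any particular atlas.
6. **High-density areas and patterns.** `detect_high_density()` thresholds
   the map at 901 HU — the start of the high-density class — and keeps
   8-connected components of at least 25 mm². Both values are configurable
   because published analyses typically do not print their cutoffs.
   `region_frequency()` counts, per region, the knees with at least one
   component touching it; percentages are integers with halves rounded away
   from zero (verified against every printed pair of the published cohort
   tables, e.g. 24/30→80%, 17/30→57%, 19/30→63%).
7. **Pattern taxonomy.** `classify_pattern()` assigns each knee one label:
   femur — Blank, Anterior-Lateral, Dual Center, Center Connections; tibia
   — Blank, Scatter, Multi-Center, Multi-Center Connections. The taxonomy
   names and their bone-applicability come from the literature; the decision
   geometry is ours, fixed and parameterized, because the named types were
   never given operational rules. Precedence (femur): Blank, then Center
   Connections (one component bridges regions 4 and 6), then
   Anterior-Lateral (all centroids in the anterior-lateral quadrant,
   defined anatomically so it mirrors with side), then Dual Center as the
   total-function fallback. Tibia: Blank; Multi-Center Connections (one
   component spans ≥2 columns); Multi-Center (≥2 components each ≥
   `big_area_mm2`, default 100 mm²); Scatter otherwise.
8. **Statistics.** `compare_groups()` follows a normality-gated design:
   each sample is tested with a one-sample Kolmogorov–Smirnov test against
   a normal law with the sample's own mean and SD at α = 0.05; if both pass,
   a pooled-variance Student t-test compares the groups, otherwise a
   two-sided Mann–Whitney U. Results are reported as mean ± SD with the
   per-interval p-value. No multiple-testing correction is applied by
   default — per-interval p-values mirror how such tables are printed — but
   `p_adjust` accepts any `stats::p.adjust` method. Estimating the KS
   parameters from the sample makes the gate conservative (the Lilliefors
   caveat); it is a routing device, not a calibrated test. Left–right
   contrasts are two-sample by default (`paired = TRUE` is available)
   because published reports rarely state pairing for within-group side
   comparisons.

## The synthetic phantom: what it emulates and what it does not

No public CT archive accompanies the cohort results this pipeline targets,
so validation rests on `make_phantom()` / `make_cohort()`: stylized knee
phantoms with voxel-exact ground truth.

**Geometry.** The distal femur is two overlapping condylar half-ellipsoids
below a flat epiphyseal plane, plus a metaphyseal stub above it (which ROI
extraction must remove); the tibial plateau is a domed slab with the plane
below the surface. Grids default to 48×48×36 voxels at isotropic 0.625 mm —
the slice thickness of thin-slice knee CT. The geometry is schematic on
purpose: it exercises ROI extraction, projection, the region grid and %BTV
exactly, at desk scale, and nothing in the package depends on anatomical
realism of the outline.

**Density field.** Inside the bone:

* a *deep trabecular field*: baseline 280 HU plus a deterministic
  voxel-scale texture, an integer-hash offset uniform in ±150 HU. Two
  design constraints force this form. First, real trabecular bone at
  sub-millimetre voxels has a broad continuous HU spectrum, not a single
  value. Second, %BTV recovery under additive noise is only well-posed if
  the HU distribution is smooth across interval edges: a field with an HU
  point mass at or near an edge migrates arbitrarily much mass across that
  edge under any noise. A flat (uniform) spectrum makes interior-bin noise
  migration balance exactly. The texture depends only on the voxel index,
  never on the RNG seed, so it is part of the specified field.
* a *laminar subchondral plate*: a depth-decaying elevation
  (amplitude 200 HU, e-folding 3 mm) that reaches zero *continuously* at
  the shell depth (5 mm) via a shifted exponential — a hard cutoff or an
  unshifted decay would leave a discontinuity or pile-up in the spectrum,
  with the same noise-migration pathology as above.
* **control-like** phantoms stop there: a laminar, low-density profile.
* **judo-like** phantoms add (a) a broad remodeling effect — the laminar
  amplitude gains a factor `remodel_gain = 1.5` and the densified plate
  deepens by `remodel_depth_gain = 3` — and (b) Gaussian high-density foci
  (450 HU amplitude, σ = 3 mm, decaying with depth like the plate) centred
  on regions 4, 5, 6 of the femur and 2, 4, 5, 7 of the tibia, i.e. the
  central/ligament-insertion zones. All three ingredients are needed, and
  the split between amplitude and depth is deliberate. %BTV is
  compositional, so foci alone *reduce* the medium-density share by pushing
  mass into the high bins; broad densification is what makes the
  medium-density classes larger in the loaded group, the qualitative
  direction reported for athletes. But a large *amplitude* gain saturates
  the maximum-intensity projection above the 901 HU detection class across
  the whole surface, collapsing the frequency tables; thickening the plate
  at *depth* adds medium-density volume that the column-maximum projection
  never sees, so detected high-density areas remain focal to the seeded
  regions. The published group contrasts are reproduced in *direction
  only*; no attempt is made to match their magnitudes, which would require
  the original scans.
* Gaussian noise (SD 30 HU) is added everywhere and truncated at −1024 HU;
  HU are stored as signed 16-bit integers.

**Cohorts and jitter.** `make_cohort()` derives one seed per subject from a
master seed and applies multiplicative log-normal jitter: sdlog 0.05 on the
baseline, 0.08 on the laminar amplitude, 0.25 on each focus amplitude.
The constants create overlap between groups (so the statistics stage has
something to do) and knee-to-knee variation in which foci clear the
high-density threshold (so frequency tables are non-trivial). Defaults:
15 subjects per group, matching the elite-athlete/control design the
pipeline targets; the pipeline generates both knees, giving 30 knees per
group in the cohort tables.

**What passing tests do and do not show.** Phantom-based tests demonstrate
that the *implementation* is exact (oracle equivalence, voxel-exact truth
recovery, normalization) and that the *procedure* behaves correctly on data
with known structure (calibration under the null, power in the direction of
the built-in contrast, mirror invariance). They cannot show that the
pipeline recovers biological truth from real knees: the phantoms have flat
epiphyseal planes, schematic outlines, no cortical shell, no beam-hardening
or partial-volume artefacts, and a texture model much simpler than real
trabecular architecture.

## Numerical choices

* **Binning** uses `findInterval` on the integer lower edges; ground truth
  in the phantom is computed by an independent `.bincode` scan, and tests
  compare both against a literal if-chain oracle.
* **Connectivity** is 26-connected in 3D and 8-connected in 2D throughout,
  implemented in compiled code with deterministic scan-order labels and
  checked against breadth-first R oracles.
* **Rounding of percentages**: nearest integer, halves away from zero —
  the only rule consistent with every printed count→percent pair we checked
  (n = 30 knees produces no exact halves, so the tie rule is untestable
  from those tables; we fix it anyway for determinism).
* **Equal-thirds bands** split a width *w* as
  `round(w/3), round(2w/3) − round(w/3), w − round(2w/3)`, which is
  symmetric under mirroring for every *w* — this is what makes the region
  grid mirror exactly between sides.
* **Degenerate comparisons** (both samples constant and equal) return
  p = 1 and are flagged rather than erroring: cohort tables must be total
  even when a density bin is structurally empty.
* **Statistical calibration** is asserted where it is meaningful: in
  control-like cohorts the upper bins contain either nothing (degenerate,
  p = 1 by convention) or a handful of noise-tail voxels (zero-inflated
  counts, routed to the Mann–Whitney branch, whose discreteness makes it
  conservative). The ±0.02 band around the nominal 0.05 level is asserted
  for bins with continuous %BTV (non-degenerate in ≥90% of replicates and
  t-routed in ≥50%); for sparse tail bins the suite asserts the rate never
  exceeds 0.07 — conservative is acceptable, anti-conservative is not.
* **Problem sizes.** Oracle-equivalence tests use 100 randomized grids per
  operation at up to ~12³ voxels; the calibration study uses 1000 replicate
  pairs of n = 15 cohorts on 24×24×20 grids; the power study uses 50
  cohort pairs; default pipeline runs use 48×48×36 grids. These sizes were
  chosen to make the full validation suite run in a few minutes on a
  single core while keeping every Monte-Carlo margin wide relative to its
  threshold.

## Design decisions that were genuinely open

* **DICOM input** is read by a minimal explicit-VR little-endian parser
  (uncompressed, single-frame, 16-bit) written for this package; slices
  are sorted by position, rescale slope/intercept map stored values to HU,
  and mixed series, missing spacing, or single-slice input are rejected by
  name. NIfTI I/O goes through RNifti, with reorientation to the canonical
  axis convention when the header carries a complete orientation.
* **The epiphyseal plane is flat.** The anatomical epiphyseal line is
  curved, but a plane keeps the ROI contract exact and testable; the plane
  index is configurable per knee, and partial-depth (fixed-mm shell)
  analyses are possible by supplying a custom mask.
* **Femur fallback label.** The femur precedence leaves a single component
  outside the anterior-lateral quadrant without a natural label; Dual
  Center is the documented fallback so classification is a total function.
* **"At least two" centers.** Dual Center and Multi-Center accept two *or
  more* centers; the minimum extent of a tibial "center" is the
  `big_area_mm2` knob (default 100 mm²). Both are conventions, not facts
  about the published taxonomy.
* **Frequency tables are per bone and group.** The combined published
  layout with "/" cells for inapplicable bone/label pairs is a rendering
  concern; the package emits tidy per-bone tables whose label sets are
  bone-exclusive by construction.

## Known limitations

Real scanner effects (beam hardening, partial volume, metal artefacts) are
not modelled; HU-to-mineral-density calibration is out of scope (no
calibration phantom data); projection is axis-aligned, not normal to the
articular surface; the nine-region grid is a bounding-box convention, not
an anatomical atlas; and the pattern rules, while deterministic and
mirror-invariant, are one reasonable operationalization of names that were
never formally defined.
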