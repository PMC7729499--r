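---
title: "Quantifying neuronal-like morphological conversion: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neuronal-like morphological conversion: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytomorph)
```

## The problem

When mesenchymal stem cells convert toward a neuronal-like phenotype on a
biomaterial surface, the change is first visible in their shape: the spread,
fibroblast-like cell body gives way to a polarized cell with a body
enlargement at one pole and a single long, narrow protrusion at the other,
while the nucleus elongates and drifts toward the neck of the body
enlargement. cytomorph packages the image-analysis side of that readout: it
quantifies per-cell morphology and per-cell marker fluorescence from
multi-channel fluorescence micrographs, and it runs the group statistics used
to compare substrates, timepoints and serum conditions.

Because raw micrographs for such studies are rarely deposited, the package
ships a first-class synthetic-scene generator with complete ground truth.
Every quantitative guarantee the package makes is demonstrated on generated
scenes whose true geometry and intensities are known exactly.

## The synthetic-scene generator

`render_scene()` draws each cell from one of two phenotype models:

* **mesenchymal** — a filled ellipse (full axes `body_major_px` x
  `body_minor_px`), optionally boundary-perturbed by a low-frequency radial
  ripple bounded by ten percent of the minor axis;
* **polarized** — the same elliptical body fused with a single straight
  protrusion emanating from one pole along the cell's orientation, its width
  tapering linearly from the stated neck width to a 2 px tip. The Euclidean
  distance from the protrusion tip to the far body pole is exactly
  `body_major_px + protrusion_length_px`, which is what makes analytic
  length oracles possible.

Nuclei are smaller ellipses, displaced toward the protrusion-side pole by
`nucleus_offset_frac` of the body semi-major axis, emulating the nuclear
repositioning that accompanies polarization. Cells are placed by rejection
sampling with a bounded retry count (default 100 per cell) and a 3 px
exclusion moat, so masks never touch; failure to place is an explicit error
rather than a silent overlap. Channel images follow a multiplicative
flat-field model:

```
channel = (signal + background_level) * shading + noise
```

with the shading field a mean-normalized two-dimensional Gaussian bump
(amplitude expressed as a fraction of the mean, default 0.2; scale 0.4 of
the frame diagonal), additive Gaussian pixel noise (default sd 4 a.u.) and
optional Poisson resampling. Outputs are written as 16-bit grayscale TIFFs
clipped to `[0, 65535]`.

Defaults mirror a 20x widefield acquisition: a 1388 x 1040 px frame at
0.32 um/px. Body major axes default to 60–100 px (about 19–32 um),
protrusions to 80–220 px (about 26–70 um at that calibration, and up to
~200 um at coarser calibrations), marker levels to 80–120 a.u. over a
background of 20 a.u. A fixed `scene_config()` (including its seed) renders
bit-identically; seeded generation never disturbs the caller's RNG stream.

What the generator does **not** emulate: textured cytoplasm (cells are flat
plateaus plus noise), out-of-focus light and point-spread blurring, touching
or overlapping cells, curved or branched protrusions, multi-nucleated cells
and uneven staining within a cell. Passing tests therefore demonstrate the
correctness of the measurement chain under the flat-field imaging model, not
segmentation robustness on difficult real micrographs.

## Preprocessing

**Flat-field correction.** `flatfield_correct()` estimates the shading field
by large-scale Gaussian smoothing of the image itself (default sigma 100 px,
which must sit well above the cell size and below the frame size), divides
by the mean-normalized estimate, and rescales so the global mean is exactly
preserved. Two design details matter in practice. First, the smoothing that
produces the estimate also flattens the shading bump slightly, so a single
pass leaves a residual of roughly `sigma_smooth^2 / sigma_shading^2`; the
correction therefore runs two estimate-and-divide passes by default, which
removes the residual quadratically (about 96% of the injected amplitude at
the default geometry, versus about 90% for one pass). Second, bright compact
cells inflate the local estimate; when a structuring-element diameter is
supplied (as the CTCF chain does), the estimate is computed from the
grayscale opening of the image so that features narrower than the disk do
not bias it. A constant image is returned unchanged; an all-zero image is
returned with a warning rather than an error, because pipelines over empty
fields must not crash. For speed, smoothing at sigma >= 32 px runs on a
4x block-mean downsampled image and is resized back bilinearly — for fields
this smooth the two estimates agree to a fraction of a percent.

**Opening background.** `opening_background()` performs grayscale opening
with a rasterized disk. A "disk of 20 pixel diameter" is read literally as a
radius-10 disk (sampled on a 21 x 21 grid). EBImage provides the erosion and
dilation; intensities are affinely mapped to `[0, 1]` and back because its
grayscale morphology expects that range (erosion and dilation commute with
increasing affine maps, so the result is exact). Border handling is
replicate padding — for a disk structuring element, clipping the
neighbourhood at the frame is mathematically identical to replicate padding,
which avoids dark rims that would bias background estimates. Anti-extensivity
and idempotence are enforced by property tests against a brute-force oracle.

**Thresholding and labeling.** Otsu's method is the default (the study
protocol names no algorithm; Otsu is standard and parameter-free), with a
manual override. Components are 8-connected — diagonal contact joins
regions — and labels are assigned in raster order of first occurrence so
runs are stable. A constant image is a named error, not an empty mask.

**Cytoskeleton elaboration.** The two-filter elaboration used for
visualizing coordinated cytoskeletal fibres is provided as `north_shadow()`
(3x3 unit-sum north-emboss kernel `[1,2,1; 0,1,0; -1,-2,-1]`, replicate
padding, so constants are fixed points), `convolve_colorize()` (true
convolution mapped into one RGB channel), and `merge_elaborated()` (screen
blend, commutative, clipped to range). The exact emboss kernel is a
convention choice — the filter is named in imaging software but its kernel is
not standardized — and it is therefore an argument, not a constant.

## Morphometry

`region_properties()` measures area (pixel count), perimeter, centroid,
moment-equivalent ellipse axes, maximum Feret diameter and angle, and the
bounding box.

* **Perimeter** uses a Moore chain-code trace with Vossepoel–Smeulders
  isotropic weights (0.980 per axial step, 1.406 per diagonal, −0.091 per
  corner) plus a half-pixel offset closure of `pi`: the chain code runs
  through pixel centres, half a pixel inside the true region boundary, and
  offsetting a convex contour outward by half a pixel lengthens it by
  `2*pi*(1/2)`. Raw edge counting would bias circularity low by 8–10% and
  break the circle oracle; the corrected estimator keeps digitized circles
  within ~1% of `2*pi*r` and axis-aligned squares within ~2.5% of `4s`.
* **Feret diameter** is the maximum caliper width, computed over the convex
  hull of boundary-pixel corners; on every tested mask it equals the
  brute-force maximum pairwise distance over all boundary corners exactly,
  because the hull preserves the diameter of the point set. The Feret
  *angle* is the orientation of the maximal chord in `[0, 180)` (the
  maximum-Feret convention; the minimal-width angle is a different, also
  defensible reading).
* **Moment axes** come from central second moments with the 1/12
  pixel-integration term; `AR = major/minor`.

The headline descriptors are `CSI = 4*pi*area/perimeter^2` (cell shape
index; 1 for a circle) and its nuclear counterpart NSI — the classical
circularity reading of a "shape index", adopted here as the formula and
exposed as such; `CL`, the total cell length, implemented as the calibrated
maximum Feret diameter because polarized cells are far from elliptical and
the moment major axis underestimates tip-to-tip extent (the moment axis is
still reported); the nuclear positioning ratio
`NP = feret_max / max(distance from nucleus centroid to the boundary)`,
measured over the same corner point set so that `NP` is guaranteed to lie in
`[1, 2]` (2 = centred nucleus, 1 = nucleus at a pole); and the protrusion
length.

**Protrusion length** is measured geometrically: the cell body is isolated
by a binary opening with a disk sized to half (configurable) of the cell's
maximal inscribed width, so everything locally narrower than that fraction
is protrusion territory; the protrusion length is the largest geodesic
distance from the body attained inside a narrow component, computed by
multi-source Dijkstra on the pixel grid with a 16-neighbourhood (axial,
diagonal and knight moves weighted 1, sqrt(2), sqrt(5)), which keeps the
metrication error of straight paths below ~2%. A narrow component only
counts as a protrusion if it outreaches the body's own width; a plain
ellipse therefore returns 0 with `detected = FALSE` rather than a spurious
few-pixel "protrusion" from its pole caps. Euclidean distance from the
nucleus centroid (used by NP) admits exact toy oracles; the geodesic is
reserved for the protrusion, where paths must stay inside the mask.

**Phenotype classification** calls a cell `elongated_polarized` when it has
exactly one protrusion, that protrusion is longer than one body minor-axis
length, and `AR >= 2.2`. The aspect-ratio threshold was calibrated on the
generator's default populations: mesenchymal cells (body aspect 1.2–2.0)
never exceed AR ~2.0, while about a fifth of genuine polarized cells —
those with round bodies and shorter protrusions — fall below the
conventional cutoff of 3 because the moment ellipse of body-plus-protrusion
is dominated by the body mass. At 2.2 the false-positive rate on
mesenchymal cells is zero by construction and the miss rate on polarized
cells is a few percent. The threshold (and the protrusion-length threshold)
are configuration, because studies reporting "percent elongated cells"
rarely state their criterion.

## CTCF quantification

The per-cell corrected total cell fluorescence follows the chain: flat-field
correction, opening background estimation and subtraction, per-cell
integrated density (`cFID`) and area (`Ac`) under the mask, background
estimation from five automatically sampled 30 x 30 px ROIs (seeded, pairwise
disjoint, foreground-free; `MFB` = mean of ROI means, `MAb` = mean ROI
area), and finally

```
standard:  CTCF = cFID - Ac * MFB
literal:   CTCF = cFID - Ac * MAb * MFB
```

The *literal* triple-product form reproduces, letter for letter, a published
variant of the formula in which the mean background-ROI area multiplies the
background term; read as an intensity correction it is dimensionally
inconsistent (it scales the background by an area a second time), so the
standard area-scaled correction is the default and the literal form is kept
behind `mode = "literal"` for fidelity. The mode is recorded in every
output record.

One modelling interaction deserves emphasis: opening with a disk only
estimates the background *under* features narrower than the disk. The
synthetic CTCF scenes therefore use cell bodies narrower than the default
20 px disk (or, equivalently, users should size the disk above their cell
width when cells are flat). On such scenes the chain is exact: CTCF equals
area x marker level to rounding, is linear in the level (R² ≈ 1), ignores
constant intensity offsets (absorbed by MFB), and is robust to 30%
multiplicative shading when flat-fielding is enabled (deviations of a few
tenths of a percent) while biased by up to the shading amplitude without it.

## Group statistics

The reporting layer mirrors a common wet-lab analysis stack: percent change
versus control (`reduction` = (ctrl − group)/ctrl x 100), one-way ANOVA by
the classical sum-of-squares decomposition, Dunn's rank-based multiple
comparison test and Pearson correlation. Dunn's test ranks all observations
jointly with mid-ranks for ties and compares mean ranks with the
tie-corrected standard error
`sqrt((N(N+1)/12 − T/(12(N−1))) (1/n_i + 1/n_j))`, `T = sum(t^3 − t)`;
it is implemented in the package (and verified against hand-rank oracles)
because no installed package provides it. The default adjustment is
Bonferroni with Holm available — the post-hoc test is usually named without
its adjustment, and Bonferroni is the conservative default. Boxplot
summaries use type-7 (linear interpolation) quantiles, whiskers at the most
extreme points within 1.5 x IQR, and list outliers explicitly; the quantile
convention is fixed so tests can be exact. Significance stars follow the
legend convention `* p<0.05, ** p<0.01, *** p<0.005, **** p<0.0001` and are
annotations only.

Null calibration is tested by simulation: over 2000 null data sets
(3 groups x 30), both the ANOVA and the Dunn family-wise rejection rates
stay within three binomial standard errors of the nominal 5%.

## Pipeline and reproducibility

`run_pipeline()` drives generation, segmentation, morphometry, CTCF and
summaries from a single validated `run_config()`; a manifest (config,
package version, seed) is written before any output and finalized with
per-file MD5 checksums. One global seed fans out to per-stage child seeds by
hashing the stage name (`child_seed()`), so identical configs give
byte-identical CSVs while stages never share a stream.
`simulate_experiment()` renders a full multi-condition design
(substrate x timepoint x serum, several fields per condition — the bundled
defaults mirror a protocol of 8 fields and ~100 cells per condition) and
returns matched wide and long descriptor tables for the statistics layer. A
thin command-line wrapper (`inst/cli/cytomorph.R`) exposes `generate`,
`preprocess`, `morphometry`, `ctcf`, `stats`, `run-all` and
`simulate-experiment` with exit codes 0/2/1 for success, validation error
and runtime error.

## Problem sizes used in the checks

The shipped tests and the acceptance script size their simulations to make
each property measurable while staying desk-scale: 400 noise-free cells
(80 fields of 5) for parameter and classification recovery, ~100 cells
through full segmentation at default noise, 100 random masks for the Feret
oracle, twenty 64 x 64 images across disk diameters 3–21 for the
morphology oracle, 20000 permutations for the ANOVA p oracle, 2000 null
simulations for type-I calibration, and a two-condition experiment of
25 fields x 4 cells per condition for the injected-effect recovery. Recovery
on noise-free scenes uses the ground-truth masks directly (the Otsu mask of a
noise-free scene is identical to the truth mask; this is verified separately
by an IoU test), while the noisy variant runs the full segmentation path.

## Known limitations

* Aspect-ratio ground truth is only defined for mesenchymal cells (the
  generator does not prescribe a closed-form moment ratio for
  body-plus-protrusion unions); AR recovery is therefore assessed on the
  mesenchymal subpopulation, CL on all cells, protrusion length on polarized
  cells.
* The protrusion measure assumes a single dominant protrusion wider than
  2 px and a body at least twice the protrusion width; heavily branched
  protrusions would be measured along their longest branch.
* The opening-based background model breaks down when cells are wider than
  the structuring element and flat; real textured cells degrade more
  gracefully than the synthetic plateaus.
* Feret angles of near-circular cells are dominated by rasterization and are
  only meaningful in aggregate (their uniformity under isotropic orientation
  is tested at the population level).

## A worked example

```{r example, eval = FALSE}
library(cytomorph)

cfg <- scene_config(width_px = 512, height_px = 512, n_cells = 6,
                    polarized_fraction = 0.5, seed = 11,
                    param_ranges = list(
                      body_major_px = c(50, 70), body_aspect = c(1.2, 2),
                      protrusion_length_px = c(80, 140),
                      protrusion_width_px = c(6, 10),
                      nucleus_major_px = c(20, 28), nucleus_aspect = c(1, 1.6),
                      nucleus_offset_frac = c(0.3, 0.7)))
scene <- render_scene(cfg)
seg <- segment_scene(scene)
cells <- measure_cells(seg$cell_labels, seg$nucleus_labels,
                       calibration(cfg$scale_um_per_px))
cells[, c("cell_id", "phenotype", "CSI", "AR", "CL_um", "NP", "protrusion_um")]
```
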