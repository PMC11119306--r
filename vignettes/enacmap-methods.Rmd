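---
title: "enacmap: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{enacmap: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enacmap)
```

## The model

`enacmap` quantifies regional neuronal activation in coronal sections of
the extended nucleus accumbens (eNAc) imaged by four-channel multiplex
FISH (DAPI, Fos, Drd1, Drd2). The analysis is deliberately model-free:
no atlas registration, no parametric spatial model. Each section is
parcellated into a polar grid anchored on the anterior commissure (aco),
every DAPI-segmented nucleus is treated as one cell, per-cell positivity
is called from area-overlap fractions, and all downstream statistics
operate on per-region summary fractions.

The statistical unit ("case") is **one section from one mouse** — one
section per mouse per plane by default. Regional summaries are
unweighted means of per-case fractions, so large and small sections
contribute equally; a cell-count-weighted pooled alternative exists
behind `aggregate_condition(weighted = TRUE)`.

Assumptions worth stating explicitly:

* cells within a region are exchangeable for the purposes of the
  Fos fraction (no sub-regional structure below the grid scale);
* sections of the same mouse in different planes are treated as
  independent cases (no mixed-effects modeling of the mouse level);
* the four cohorts (saline/histamine × intact/clipped nails) are
  independent groups — every mouse belongs to exactly one.

## The coordinate system

Five concentric circles around the aco center bound four analysis
**zones**; zone 0 (inside circle 1, the aco itself) and zone 5 (outside
circle 5) are never analyzed. Eight 45° **sectors** are numbered
counter-clockwise, sector 1 immediately above the medial horizontal.
Three **planes** (rostral, intermed, caudal) complete the grid of
4 × 8 × 3 = 96 regions, addressed by a three-digit PZS code
(plane digit 1/2/3, then zone, then sector; `212` = intermed, zone 1,
sector 2).

Numerical conventions, chosen once and fixed:

* **Radial intervals are half-open on the left**: zone k is
  (R_k, R_{k+1}]. A cell exactly on a circle belongs to the inner zone.
* **Angular intervals are half-open on the right**: sector k spans
  [45(k−1)°, 45k°); a cell exactly on the medial horizontal is in
  sector 1.
* **Frames**: image coordinates have y growing downward; the anatomical
  frame (medial = +x, dorsal = +y) negates y. Sections are assumed
  imaged with dorsal up and the medial side to the right (right
  hemisphere); left-hemisphere images must be mirrored before input.
* Circle geometry is supplied per section (JSON sidecar); automatic aco
  detection is out of scope because the circles are defined by visual
  cell-density landmarks.

Default per-plane radii (px at 0.585 µm/px) are the study-wide means:
rostral 280/591/887/1310/1662, intermed 293/618/915/1324/1732, caudal
287/570/836/1147/1648. They matter only for the synthetic generator —
real sections carry their own measured radii.

A region of one section is **valid** when it contains at least
`min_dapi_per_region = 10` DAPI ROIs (inclusive). The source workflow
excluded under-covered regions without stating a numeric rule; 10 cells
is the smallest count at which a Fos fraction is meaningfully different
from noise (binomial SE ≤ 0.16). The default grid exclusion is zone 4,
sector 5 of the rostral plane (PZS 145), the region that lacked
sufficient coverage, which leaves the 95 regions used by the clustering.

## Segmentation stack

* **DAPI thresholding**: Huang's fuzzy-membership method — the threshold
  minimizes the summed Shannon entropy of the membership function
  µ(g) = 1/(1 + |g − µ_class|/C) over a 256-bin grey histogram (the
  binning convention of ImageJ-style auto-thresholders for 16-bit data).
  Pixels strictly above the returned intensity are foreground.
* **Signal thresholding**: a Rényi-entropy criterion — the threshold
  maximizes H_α(background) + H_α(foreground) with α = 2 by default
  (configurable). Equivalence with any specific ImageJ parameterization
  is *not* claimed, only the criterion family.
* **Watershed**: exact Euclidean distance transform
  (Felzenszwalb–Huttenlocher), seeds at EDT local maxima with greedy
  suppression of maxima closer than `min_peak_sep` (default: the radius
  of the median-area blob), then descending-distance region growing.
  The suppression prevents over-segmentation of single bumpy nuclei;
  priority ties break by insertion order, so labeling is deterministic.
* **Particle analysis**: area, centroid (0-based pixel centers),
  chain-code perimeter (Moore boundary tracing; axial steps weight 1,
  diagonal steps √2), circularity 4πA/P² capped at 1.0 (the digital
  perimeter of small or axis-aligned particles can push the raw ratio
  above 1; capping is the conventional fix). Calibration on ideal
  shapes: a disk of radius 20 px measures ≈ 0.91, a filled square
  ≈ 0.82 against the analytic π/4 ≈ 0.785 — tolerances in the test
  suite are set accordingly (disk within [0.88, 1.05], square within
  ±0.06). Particles failing the filters (defaults: area outside
  [30, 500] px², circularity < 0.3 — the source workflow set these
  interactively without publishing values) are **flagged**, never
  deleted; artifact regions are flagged by exclusion polygons supplied
  as data (replacing a manual drawing step).
* **Overlap**: per ROI and channel, the fraction of ROI pixels that are
  signal-positive after binarization. This is the quantity thresholded
  by the positivity rules.

## Positivity and tabulation

Calls are inclusive ("15% or more"): Drd1 ≥ 0.15, Fos ≥ 0.20,
Drd2 ≥ 0.30 of the ROI area. Every cell gets one of four receptor
patterns (D1±D2±); Fos-positive cells additionally carry their pattern
as the `fos_pattern` used in composition tests. Raising any threshold
can only shrink the corresponding positive set (tested as a property).

## Region statistics

* **t maps**: Welch's unequal-variance t by default (the source analysis
  says only "t values"; pooled variance is available via
  `var_equal = TRUE`). Positive t = higher in the second-listed
  condition. P-values are BH-adjusted in **one family across all
  testable regions of the comparison** (≈ 95 spanning the three planes),
  because a single Q threshold is applied to all planes at once.
  Classes: `increased` / `decreased` at Q < 0.1 by the sign of t,
  otherwise `insensitive`; regions with fewer than 2 valid cases per
  group are `not_testable`.
* **bh_fdr** is implemented from the step-up definition and verified
  against an independent brute-force oracle.
* **Receptor fractions by class**: Kruskal–Wallis omnibus plus
  Bonferroni-corrected pairwise Mann–Whitney with 3 classes,
  Mann–Whitney alone with 2. The Bonferroni factor is the number of
  class pairs (the source's "multiple comparison" procedure is not
  spelled out).
* **Composition**: Pearson chi-square (no continuity correction) on the
  classes × 4-pattern table of Fos-positive counts, omnibus plus
  Bonferroni-corrected pairwise; significance marker at P < 0.005.
  Expected counts below 1 attach a warning.
* **Scratch–Fos correlation**: per region and cohort, Spearman's rho
  (average ranks) between per-mouse 45-min scratch totals and regional
  Fos fractions; two-sided p via the t approximation for n ≥ 10 and
  exact permutation enumeration below that; significance at P < 0.1;
  regions with fewer than 4 mice or constant vectors are reported
  missing rather than forced.

## Clustering

The feature matrix has one row per region and four columns in fixed
order (saline-intact, saline-clipped, histamine-intact,
histamine-clipped); rows with any missing value are dropped and
reported. Distances are Euclidean (Minkowski order 2), linkage is
complete, so merge heights are monotone. The default cut is by cluster
count k = 5 — the number of response archetypes — rather than by the
(unpublished) height threshold; a height cut is supported. Fractions and
correlation coefficients are already commensurate within a matrix, so no
feature scaling is applied by default (z-scoring is available upstream
if wanted).

## Behavior

Bouts are binned by **onset** into half-open 5-minute bins over
[−15, +45] min; a bout at t = 0 belongs to the first post-injection bin.
The 45-min total counts onsets in [0, 2700) s. The pre-injection
duration reference limit defaults to the 90th percentile (linear,
type-7 interpolation) of pooled pre-injection durations; the phrase
"10%-upper confidential limit" is ambiguous, so a one-sided 90% upper
confidence bound of the mean is also implemented
(`method = "mean_ucl"`). Cohort comparisons: per-bin 2 × 2 factorial
ANOVA of per-mouse counts, one-way ANOVA on totals with Bonferroni
pairwise t tests, and per-bin Mann–Whitney tests of pooled durations
between nail groups within each injection arm. No multiplicity
correction is applied across the 12 time bins, mirroring the
presentation being reproduced.

## The synthetic world

The generator's defaults are the stated study conditions wherever those
exist, and documented guesses elsewhere:

| parameter | default | status |
|---|---|---|
| cohort sizes | 12 / 11 / 12 / 13 (sal-int / sal-clip / hist-int / hist-clip) | stated |
| circle radii | per-plane means above | stated |
| pixel size | 0.585 µm/px | stated |
| nuclei density | 8 per 10⁴ px² | guess: ≈ one nucleus per (20 µm)², typical striatal DAPI packing; gives thousands of nuclei per section |
| baseline Fos probability | 0.3 | guess, consistent with the reported high spontaneous Fos fractions |
| receptor pattern probabilities | 0.40 / 0.40 / 0.10 / 0.10 (D1+D2−, D1−D2+, D1+D2+, D1−D2−) | guess: the classic roughly even D1/D2 split of striatal projection neurons with minor co-expressing and double-negative pools |
| archetype effect map | five region blocks with per-cohort probabilities mirroring the described response clusters (one high-when-intact, one uniformly low, one low and nail-dependent, one high-except-clipped-saline, one histamine-up/clip-down) | qualitative |
| overlap margin | 0.1 | design choice: Beta-distributed overlaps kept one margin away from each calling threshold, so calls exercise the thresholds without being degenerate |
| scratch base rate | 1 bout/min | guess |
| histamine / clip rate multipliers | 4 / 1.5 | qualitative, reproduces the reference ordering |
| excess-rate decay half-life | 20 min | guess; exponential decay of the excess reproduces an early peak |
| bout durations | log-normal, meanlog log(0.16), sdlog 0.5; post-injection shifts +0.4 (histamine) and +0.25 (histamine+clipped) | chosen so the 90th percentile of pre-injection durations ≈ 0.3 s, the printed reference limit |

Nuclei are uniform in the annulus between circles 1 and 5, optionally
with a hard-core minimum separation (dart throwing) so that non-touching
segmentation fixtures are constructible; rendered images place one
bright disk per nucleus plus Gaussian noise, and signal channels cover a
chord cut of each positive nucleus matching its planted overlap
fraction.

**What is not emulated** — and therefore what a green test does not
establish: optical point-spread functions, autofluorescence and
stitching seams; spatial gradients of cell density within a region;
mouse-level random effects (sections of one mouse are conditionally
independent given the cohort); any correlation between a mouse's
scratching and its Fos expression (the planted effect map depends on
cohort only, so scratch–Fos correlation maps on default synthetic data
are null). Green acceptance tests establish that the machinery is
correct and calibrated, not that the biology is reproduced.

## Runtime scaling in the test suite

The FDR-calibration acceptance test runs at a single plane (32 regions)
and reduced nuclei density: BH's FDR control does not depend on family
size or per-region cell counts, and this keeps 200 null replicates of a
12-vs-12 study inside the time budget. The overlap-drawing fast path
(`simulate_cells(draw_overlaps = FALSE)`) sets margin-respecting
constant overlaps instead of Beta draws for the same reason; positivity
calling still runs on every cell.

## Known limitations

* No atlas registration or left/right handling beyond the mirroring
  convention; geometry must be annotated per section.
* No mixed-effects modeling of the mouse/section hierarchy (the analysis
  being reproduced does not use one).
* The Rényi-entropy binarization matches the criterion family, not any
  specific ImageJ implementation.
* The TIFF codec is a minimal baseline (uncompressed, little-endian,
  8/16-bit grayscale, multi-page) — sufficient for exchange with
  ImageJ-style tools, not a general reader.
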