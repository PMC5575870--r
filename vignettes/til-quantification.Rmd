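---
title: "Quantifying tumor-infiltrating lymphocytes: stereology, automated image analysis, and their concordance"
author: "TILcount"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor-infiltrating lymphocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TILcount)
```

## The quantification problem

The density of CD3+ and CD8+ tumor-infiltrating lymphocytes (TILs) in
colorectal cancer carries prognostic information, but most published counts
come from semi-quantitative scoring of a few hot spots. TILcount implements
two rigorous alternatives on the same regions of interest (ROIs) of an
IHC-stained section and the statistics needed to compare them:

1. **Design-based stereology** — a computer-assisted workflow in which the
   software draws a systematic uniform random sample (SURS) of fields of
   view (FOVs) and an observer counts labeled cell profiles with a 2D
   unbiased counting frame and a point grid. Here the observer is emulated
   by annotated ground-truth profiles.
2. **Automated image analysis** — artifact exclusion at low magnification
   followed by pixel classification of DAB-brown chromaticity, circular
   blob enhancement, watershed separation and object filtering.

Both produce, per ROI and marker, a *numerical density* $Q_A$ (cells/mm²)
and an *area fraction* (dimensionless), and the concordance layer computes
Spearman correlations, variance-ratio intraclass correlation coefficients
(ICC) and Bland–Altman limits of agreement between them.

## The stereological estimators

Within each sampled FOV a counting frame of area $a$ is applied. A profile
is counted (contributing to $\Sigma Q$) iff it intersects the open frame and
does not touch the exclusion boundary: the left edge, the bottom edge, and
their extensions — upward from the top-left corner and downward from the
bottom-right corner. With this staircase-shaped forbidden line, a complete
tiling of frames counts every profile exactly once, which is the defining
property of the unbiased counting rule; the package treats it as an exact
invariant and tests it by integer equality. A frame's reference corner point
(we use the upper right) contributes to $\Sigma P$ when it hits vital tumor
tissue, so

$$Q_A = \frac{\Sigma Q}{\Sigma P \cdot a},$$

the total count over the total sampled reference area. The area fraction
uses the point grid (test point = the upper-right corner of each cross):

$$AF = \frac{\Sigma P_{\mathrm{positive}}}{\Sigma P_{\mathrm{tumor}}},$$

with points on necrosis, mucin, clefts or folds contributing to neither
tally. Only profiles with a discernible nucleus and stain strength at or
above the observer threshold (default 0.3) are eligible, mirroring the
counting rule an observer applies.

### Sampling design and defaults

| parameter | default | why |
|---|---|---|
| frame area (CD3 / CD8) | 1575 / 2925 µm² | adapted to the two markers' densities; configurable |
| area per grid point | 559.69 µm² | square grid, spacing ≈ 23.66 µm |
| FOV size | 130 × 130 µm | yields ≈ 30 grid points per FOV, matching the worked example of 2 positive / 30 tumor points → AF 0.07 |
| FOVs per ROI | 100 / 40 / 25 (low/medium/high density) | pilot mapping aimed at counting ≥ 200 positive profiles |
| stain threshold | 0.3 | "clear-cut" staining is qualitative; exposed as config |

Counting fewer than 200 profiles triggers a warning rather than automatic
resampling: the minimum is an aim of the design, not an algorithm.

The FOV lattice step is chosen as $\sqrt{A_{ROI}/n_{FOV}}$ so the expected
number of lattice points inside the ROI matches the target; the lattice
phase is uniform in $[0,\mathrm{step})^2$, giving every point of the ROI
equal inclusion probability. The FOV phase and the grid phase are derived
from the design seed through a Lehmer-style integer hash. This matters:
deriving the two streams by small arithmetic offsets of the user seed
produced measurable correlation between a seeded cell pattern and "its"
sampling phase (a ≈1% bias in $Q_A$ over a thousand replicates), which the
hash removes.

### Numerical conventions

* Geometry lives in micrometers, origin top-left, y downward (image
  convention); polygon orientation is normalized on ingest.
* Point-in-polygon uses the even-odd rule with a half-open boundary
  convention (minimum-coordinate edges inside), so congruent tiles
  partition the plane — every boundary point belongs to exactly one tile.
* Profiles are ellipses. The counting rule is evaluated exactly by mapping
  each ellipse to the unit disk with an affine transform; frame edges map
  to segments and the test reduces to origin-to-segment distances.
* "Touching" an exclusion line means the closed boundary intersects it;
  touching an inclusion edge alone never excludes. Tangency cases are
  measure-zero under the continuous phase distribution.
* Degenerate inputs: an ROI smaller than one FOV yields the single covering
  FOV with a warning; $\Sigma P = 0$ (all sampled tissue excluded) raises an
  estimate-undefined error rather than returning 0/0.

## The detection pipeline

`runDetection()` composes, deterministically (no random initialization
anywhere):

1. `makeLowres()` — exact block-mean downsampling to ≈ 9 µm/pixel, the
   software-generated low-magnification representation.
2. `segmentArtifacts()` — a linear Bayesian (shared-covariance Gaussian)
   classifier on mean-filtered channel intensities labels each low-res
   pixel tissue / mucin / fold / necrosis; rule-based post-processing drops
   excluded blobs under 2000 µm² and fills enclosed analyzable holes under
   2000 µm².
3. `chromaticityFeatures()` — red chromaticity $R/(R+G+B)$, blue
   chromaticity $B/(R+G+B)$ and box-mean-filtered intensity; chromaticity
   of a black pixel is defined as 1/3.
4. `classifyPixels()` — two-class linear discriminant thresholded at
   posterior 0.5; a pixel exactly on the boundary resolves to negative
   (conservative toward weak-stain rejection).
5. `blobEnhance()` — a rotationally symmetric, scale-normalized
   Laplacian-of-Gaussian band-pass over radii mapped from micrometers
   ($\sigma = r/\sqrt2$), the standard open realization of a proprietary
   "polynomial blob" filter; the kernel is zero-sum so flat regions give
   exactly zero response.
6. `separateAndFilter()` — watershed flooding of the blob response within
   the positive mask. The maxima neighborhood is *half* the lower blob
   radius (at least 1 px): a neighborhood as large as the blob radius also
   fuses *disconnected* components that lie within it, which silently
   merged adjacent cells. Objects below `minObjectArea` (12 µm²) are
   relabeled `rejected_negative`; objects with mean red chromaticity below
   `weakStainCutoff` (0.38) become `rejected_weak`.

Density is accepted objects per mm² of analyzable area (ROI minus artifact
mask); area fraction is accepted-object pixel area over analyzable area.
Two asymmetries with stereology are intentional and mirror the two methods'
real behavior: the pipeline does not verify nucleus visibility, and it does
not exclude muscle or vessels.

Classifier parameters are closed-form sample moments of labeled pixels
(means, pooled covariance, priors), so training is deterministic and the
model serializes losslessly to JSON (`writeDetectionModel()`).

## What the synthetic generator emulates — and what it does not

`renderSection()` produces sections with hematoxylin-toned stroma,
counterstained immuno-negative nuclei, DAB-brown positive cells (darker
nuclear core when the nucleus is "discernible"), optional weakly stained
cells, and pale mucin pools, dark fold bands and mottled necrosis patches.
Cells are disks of radius 4–5 µm (8–10 µm lymphocytes) placed by Poisson
sampling with hard-core thinning; a boundary margin (default 1.5 µm) keeps
distinct profiles disjoint after rasterization at the default 0.904 µm/px —
at that resolution, profiles allowed to touch rasterize into connected
masks that no deterministic marker scheme can split exactly, which would
conflate a rendering artifact with a detection failure. The default render
resolution is 4× coarser than a 0.226 µm/px scanner to keep fixtures
desk-scale; all geometry flows through the pixel-size parameter, so tests
are resolution-independent.

`simulateCohort()` draws log-densities from the two-level hierarchy
$\log\lambda_{tsr} = \mu_r + a_t + b_{ts}$ with tumor-level variance 0.49
and section-level variance 0.21 (true ICC 0.7, the center of the regime the
method was characterized in), central-region mean $\log 350$ and an
invasive excess of +0.25 on the log scale; a 43 × 3 cohort then spans
roughly 50–2000 cells/mm². Weak-stain prevalence (default 0.1) and
background noise (SD 4 of 255) have no quantitative counterpart in real
calibration data; they are free parameters with these documented defaults.

The generator does **not** emulate scanner optics, stain-batch variation,
fixation artifacts, clustered (non-Poisson) infiltration, overlapping
profile stacks, or muscle/vessel structures. Passing tests therefore show
correctness of the estimators and pipeline logic under idealized optics,
not robustness to every pre-analytical confounder of clinical material.

## The concordance layer

* `spearmanConcordance()` — rank correlation with average ranks, per
  section or on per-tumor means of the three sections.
* `iccOneWay()` — one-way random-effects decomposition on natural-log
  values (zeros offset by half the smallest positive value, with warning);
  tumors are the random groups, sections the replicates;
  $ICC = \sigma^2_b/(\sigma^2_b+\sigma^2_w)$. For balanced data the REML
  solution is computed in closed form (identical to the numerical optimum,
  and exactly invariant under affine transforms of the data); unbalanced
  data fall back to lme4. The 95% CI uses the delta-method variance of the
  ratio via the implied mean squares, clipped to [0, 1]; an F-inversion
  alternative (`ci = "fstat"`) is kept swappable because the original
  post-estimation recipe is unpublished. At the 43 × 3 cohort shape and
  true ICC 0.7 the estimator's bias is about −0.01 and CI coverage ≈ 0.94
  (the acceptance suite recomputes this).
* `blandAltman()` — mean difference and ±1.96 SD limits of agreement;
  `concordanceReport()` assembles the method-comparison tables (Spearman by
  marker × region × grouping, ICC by marker × region × method, the pooled
  all-six-values-per-tumor ICC, and Bland–Altman rows including the
  invasive-vs-central contrast on per-tumor means). P-values are two-sided
  and uncorrected for multiplicity, matching the design they accompany.

## Design choices that were genuinely open

* **Frame areas.** The source protocol prints frame areas of "1.575 µm²"
  and "2.925 µm²", which cannot contain an 8–10 µm cell; the package reads
  these as 10³ µm² (1575 / 2925) and keeps them configurable.
* **Exclusion-line extent.** Full infinite exclusion lines on both axes
  would break the count-each-profile-once tiling property; the classical
  staircase (upward from top-left, downward from bottom-right) preserves
  it and is the convention implemented.
* **One corner point per frame.** The reference area is estimated by a
  single corner point per counting frame ($\Sigma P$ per frame ∈ {0, 1}),
  with the grid supplying the denser point set for area fractions.
* **FOV size.** Not stated by the source workflow; 130 × 130 µm reproduces
  the ≈ 30 grid points per FOV of the worked example.
* **Invasive-band geometry.** How the "outermost 1/5" of the invasive
  front was delineated is unspecified; ROIs are treated as given inputs and
  the generator simply lays out one central and one invasive ROI per
  section.
* **Density-class adaptation.** Whether the sampling fraction was adapted
  mid-count is unspecified; the class is chosen up front (or by the user),
  and the ≥ 200 aim is enforced only as a warning.

## Problem sizes used by the test and acceptance suites

Unbiasedness runs use a 2 × 2 mm ROI with a 160 µm collar of tissue beyond
the ROI boundary (ROIs are drawn inside tissue, so profiles exist on both
sides of the boundary), 500 sampling replicates per condition in the test
suite and 300 in the acceptance script. Detection validation uses 50 clean
fixtures (500 × 500 µm) plus 40 artifact-bearing ROIs spanning 50–2000
cells/mm²; ICC calibration uses 500 (tests) or 300 (script) simulated
43 × 3 cohorts. These sizes give Monte-Carlo standard errors comfortably
inside the asserted tolerances while keeping a full run in the minutes
range on a single core.

## Known limitations

* Stereology here consumes *annotated* profiles; there is no interactive
  counting UI, and inter-observer variability is out of scope.
* The artifact classifier sees three artifact archetypes; real folds,
  pen marks or out-of-focus regions require retraining on labeled data.
* 2D profile counts are not number densities in 3D: no disector, by
  design.
* Whole-slide pyramid formats are not read; images enter as flat rasters
  with a known pixel size.
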