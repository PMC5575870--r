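# TILcount

Dual quantification of tumor-infiltrating lymphocytes (TILs) in
IHC-stained colon-cancer sections, for pathologists and image-analysis
researchers who need counts they can defend statistically rather than
hot-spot scores.

The package implements two independent routes over the same regions of
interest (central tumor area and invasive area) and the statistics that
compare them:

* **Design-based stereology** — systematic uniform random sampling of
  fields of view, the 2D unbiased counting frame (inclusion edges top and
  right; exclusion lines left and bottom with their staircase extensions),
  and point-grid counting. Estimators:

  Q_A = ΣQ / (ΣP · a) — counted profiles over the sampled reference
  area (cells/mm²), and AF = ΣP_positive / ΣP_tumor — the area fraction
  of positive cells on vital tumor.

* **Automated image analysis** — low-resolution artifact exclusion
  (tissue folds, clefts, mucin, necrosis), red/blue chromaticity features,
  a linear Bayesian pixel classifier, scale-normalized
  Laplacian-of-Gaussian blob enhancement, watershed object separation,
  and object post-filters for weak or undersized objects.

* **Concordance statistics** — Spearman correlation (per section and on
  per-tumor means), intraclass correlation as a variance ratio
  σ²_between / (σ²_between + σ²_within) from a one-way random-effects
  model on log values with delta-method CIs, and Bland–Altman limits of
  agreement.

* **A synthetic section generator** — DAB-brown cells with nuclear cores
  on a hematoxylin-toned background, artifact regions, weak staining, and
  a two-level (tumor, section) log-normal density hierarchy — so every
  claim is testable against known ground truth with no external data.

## Worked example

```r
library(TILcount)

## render a synthetic section with known ground truth
sec <- renderSection(trueDensity = c(central = 600, invasive = 900),
                     artifactFraction = 0, weakFraction = 0, seed = 5)
sec$truth
#>     region analyzableAreaMm2 nEligible trueDensity trueAreaFraction
#> 1  central         0.1454440        79    543.1643       0.03497682
#> 2 invasive         0.1454457       121    831.9259       0.05409688

## route 1: stereology (annotated profiles stand in for the observer)
des <- samplingDesign(marker = "CD3", densityClass = "medium", seed = 17)
st <- runStereology(sec$rois$central, sec$cells, des)

## route 2: automated detection with a model trained on labeled sections
model <- defaultDetectionModel(seed = 99)
im <- runDetection(sec$image, sec$rois$central, model)
im
#> EstimateRecord [image_analysis] s1/central (CD3): Q_A = 543.2 cells/mm^2, AF = 0.0350
```

The detection estimate equals the section's realized ground truth (543.2
cells/mm², all 79 planted eligible cells recovered; area fraction 0.0350 vs
0.0350): on clean fixtures the pipeline recovers the planted count exactly,
while the stereological route on the same ROI returns a design-unbiased
estimate from its sampled fields (here 489.8 cells/mm² from 40 FOVs). The point-grid
arithmetic of the frame shown in the documentation — 2 grid points on
positive cells, 30 on tumor — gives
`areaFraction(data.frame(pPositive = 2, pTumor = 30))` = 0.0667, i.e. 0.07
at two decimals.

`estimateTable()` flattens any set of records to the CSV layout
(`method, section_id, roi_label, marker, q_a_per_mm2, area_fraction, ...`),
and `concordanceReport()` builds the Spearman / ICC / Bland–Altman tables
from it.

A thin command-line front end is installed with the package
(`inst/exec/tilcount`): subcommands `stereology`, `detect`, `train`,
`report` over GeoJSON ROIs/cells and PNG images.

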