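# PeriPos

Quantification of perinuclear versus peripheral positioning of fluorescent
puncta in 2D multi-channel micrographs of mosaic tissues.

## What it measures

When autophagosome–lysosome fusion is blocked, pre-fusion vesicles do not
stay dispersed: they collapse onto a perinuclear, non-centrosomal
microtubule-organizing centre, and breaking that transport spreads them
back toward the cell cortex. PeriPos turns this class of phenotype into a
per-cell number. Each cell's cytoplasm is split into a **perinuclear** and
a **peripheral** domain of *equal pixel area* (pixels ranked by exact
Euclidean distance to the nucleus mask, split at the half-area rank), the
channel of interest is thresholded, and the signed **distribution index**

```
D = (A_peri − A_periph) / A_total      ∈ [−1, +1]
```

is computed from the thresholded signal areas in the two domains: +1 is
perfectly perinuclear, 0 evenly dispersed, −1 perfectly peripheral.

Around this core statistic the package provides:

* puncta segmentation (global thresholding, 8-connected labeling, watershed
  splitting of touching vesicles) and per-cell QC (nucleus-in-plane gate);
* localization phenotype calls (perinuclear / dispersed / peripheral /
  ectopic focus) from the index plus centroid clustering;
* colocalization: structure-level double-positive counting, removal of
  overlapping structures so the non-colocalizing population can be scored,
  and pixel-level Pearson correlation with scatter export;
* size and intensity metrics: per-structure areas in µm², signal area
  fraction per cell, clone-versus-neighbour mean-intensity ratios;
* a normality-gated comparison protocol (D'Agostino & Pearson gate;
  t-test / ANOVA + Dunnett, or Mann-Whitney / Kruskal-Wallis + Dunn) with
  the conventional significance-star mapping;
* a synthetic mosaic-tissue generator with per-spot ground truth (Voronoi
  cell fields, configurable spot placement biases, noise model, TIFF/CSV
  round-trip), used by the whole test suite.

See `vignettes/quantifying-puncta-positioning.Rmd` for the full account of
the model, its parameters and its limitations.

## Worked example

Two synthetic cohorts of 10 clone cells each — one with dispersed puncta,
one with a strong (f = 0.9) perinuclear placement bias — scored and
compared end to end:

```r
library(PeriPos)

ctrl <- generateScene(
  sceneSpec(fieldSize = c(400L, 400L), nCells = 10L, cloneFraction = 1,
            seed = 11L),
  list(punctaSpec("puncta-A", "uniform", nSpots = 60L)))
rnai <- generateScene(
  sceneSpec(fieldSize = c(400L, 400L), nCells = 10L, cloneFraction = 1,
            seed = 12L),
  list(punctaSpec("puncta-A", "perinuclear", f = 0.9, nSpots = 60L)))

tabC <- cohortIndexTable(ctrl$scene, ctrl$rois, "puncta-A", threshold = 30)
tabR <- cohortIndexTable(rnai$scene, rnai$rois, "puncta-A", threshold = 30)

round(tabR$D, 3)
#>  [1] 0.875 0.728 0.786 0.645 0.901 0.833 0.818 0.817 0.864 0.640
summary(tabC$D)
#>     Min.  1st Qu.   Median     Mean  3rd Qu.     Max.
#> -0.27848 -0.20319 -0.12066 -0.09611  0.03235  0.10664

cmp <- compareGroups(c(tabC$D, tabR$D),
                     rep(c("control", "rnai"), each = 10),
                     control = "control")
cmp$test
#> [1] "unpaired two-tailed t-test"
cmp$comparisons
#>   group            p stars
#> 1  rnai 1.377773e-12  ****
```

The dispersed cohort scatters around 0 (per-cell sampling noise at 60
spots/cell is about ±0.13), the biased cohort sits near 2f − 1 = 0.8, and
the normality-gated protocol selects the parametric branch and reports the
difference in the strongest star category.

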