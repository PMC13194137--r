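# treedraw

Morphometric analysis of tree drawing projection tests.

In the tree drawing test (Baum test), a participant draws a tree on an A4
sheet with a dark pen; the drawing's structural features are then measured
and compared between clinical groups. Depression research in particular
reports that patients draw smaller crowns, narrower trunks and smaller
total areas than healthy controls, and that drawn area correlates
negatively with symptom severity (HDRS). `treedraw` is for researchers who
have a stack of scanned drawings and a participant roster and want the
full quantitative workflow: calibrated per-drawing measurements, group
comparison tables, severity correlations, and a power appendix — plus a
synthetic-drawing generator with analytic ground truth so the whole
pipeline can be validated without patient data.

## What it computes

**Measurement.** Each scan is binarized (Otsu threshold), cleaned of
specks and margin handwriting, reduced to its largest connected
component, closed and hole-filled into a solid silhouette, and split into
crown / trunk / roots at change points of its per-row width profile: the
crown ends where the profile collapses below `alpha` (default 0.45) of
its maximum and pinches onto the trunk plateau; roots begin where the
profile widens again past `beta` (default 1.6) times the trunk's median
width near the page baseline. Pixel quantities become physical units via
`pixels_per_cm` (from scan dpi metadata, `dpi / 2.54`, or by fitting the
page width to A4):

    area_cm2  = pixels / pixels_per_cm^2
    height_cm = row extent / pixels_per_cm
    width_cm  = max per-row extent / pixels_per_cm

The three component masks partition the silhouette exactly, so
`total_area = crown + trunk + root` holds by construction.

**Statistics.** Shapiro–Wilk normality gate, then pooled two-sample
t-test (`t = (m1 − m2) / (sp · sqrt(1/n1 + 1/n2))`, with
`sp² = ((n1−1)sd1² + (n2−1)sd2²)/(n1+n2−2)`) or Mann–Whitney U; the same
t statistic is computable straight from printed summary statistics with
`t_test_summary()`. Chi-square for categorical demography, Spearman
correlation (exact permutation p below n = 10 without ties) for
metric–severity association, Cohen's d effect sizes, and minimum sample
size via exact noncentral-t power (df = 2n − 2, noncentrality
`d·sqrt(n/2)`).

## Worked example

```r
library(treedraw)

# a synthetic drawing with known geometry stands in for a patient scan
spec <- synthetic_tree_spec(crown_semi_axes_cm = c(3, 2.4),
                            trunk_top_cm = 1.4, trunk_bottom_cm = 1.7,
                            trunk_height_cm = 6,
                            root = list(flare = 2.5, length_cm = 1.2),
                            noise_sigma = 8, dpi = 150, seed = 42)
drawing <- render_tree(spec)
write_image(drawing$image, "tree.png")

res <- measure_file("tree.png")
res$metrics
#> <tree_metrics> (cm / cm²)
#>   area : crown 22.66  trunk 9.36  root 3.60  total 35.62
#>   height: crown 4.71  trunk 6.05  root 1.20  total 11.96
#>   width : crown 6.20  trunk 1.69  total 6.20
```

The true crown area is `pi * 3 * 2.4 = 22.62` cm²: the pipeline recovers
it to 0.2% through scanner noise, and the root flare (true area 3.57 cm²
over 1.2 cm) is found within a pixel of its onset. Group statistics work
directly from printed table summaries as well as raw data:

```r
t_test_summary(39.63, 3.31, 43, 4.80, 2.83, 59)   # HDRS, patients vs controls
#> t = 57.124, df = 100, p = 3.71e-78, d = 11.45, stars = "***"
required_sample_size(d = 0.5, alpha = 0.05, power = 0.80)
#> [1] 64
```

Batch use from a shell (see `inst/scripts/treedraw.R`):

```sh
Rscript inst/scripts/treedraw.R simulate cohort.yaml --out sim/
Rscript inst/scripts/treedraw.R batch sim/images sim/roster.csv --out metrics.csv
Rscript inst/scripts/treedraw.R stats metrics.csv --out report/
```

`stats` writes demographic, comparison and correlation CSVs, a plain-text
report with the `**`/`***` footnote convention, and a provenance JSON
recording every threshold used.

## Layout

    R/               image_io, ink_extraction, segmentation, morphometry,
                     synthetic renderer/cohort, stats battery, pipeline, CLI
    tests/testthat/  unit, property and acceptance tests
    scripts/         acceptance.R
    vignettes/       methods vignette (models, parameters, validation scope)
    inst/scripts/    treedraw.R shell entry point
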