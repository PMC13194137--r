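---
title: "Measuring tree drawings: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring tree drawings: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treedraw)
```

## The measurement problem

In the tree drawing test (Baum test) a participant draws a tree on an A4
sheet with a dark pen; the page is scanned and the drawing's structural
features — how large the crown is, how wide the trunk, whether roots are
drawn — are measured and compared between clinical groups, most commonly in
depression screening, where patients tend to draw smaller, narrower trees
than controls. `treedraw` automates the measurement and the downstream
statistics. The measurement output is eleven calibrated quantities per
drawing: crown, trunk, root and total areas (cm²); crown, trunk, root and
total heights (cm); and crown, trunk and total widths (cm).

Two modelling commitments shape everything downstream:

* **Areas are filled-silhouette areas, not ink areas.** A drawn crown is an
  outline (sometimes scribbled full); what group comparisons in this
  literature respond to is the *region* the drawing occupies. Published
  control-group crown areas of ~90 cm² are only consistent with filled
  regions — the ink of a pen outline on A4 could never reach that. The
  pipeline therefore closes and hole-fills the drawing before measuring.
* **Crown, trunk and roots partition the silhouette by rows.** The page is
  a raster; row 0 is the top. The crown is everything above the crown/trunk
  boundary row, the roots everything at or below the trunk/root boundary
  row, the trunk the band between. This makes the additive identities
  (`total_area = crown + trunk + root`, and likewise heights) hold *by
  construction* rather than approximately, at the cost of assigning
  low-hanging branches that cross the boundary row to the crown.

## Pipeline stages and their parameters

`measure_file()` chains the stages; each is exported separately.

**Calibration.** Physical units come from a single scale factor
`pixels_per_cm`. Preference order: embedded scan metadata (`dpi / 2.54`),
then fitting the page width to A4 (`cols / 21.0 cm` portrait, `cols / 29.7
cm` when the page is wider than tall), then a manual override in the
config. Because the administration protocol fixes A4 paper, the page-fit
fallback is always available; `strict_calibration = TRUE` disables it for
workflows that must trust metadata only.

**Binarization.** Otsu's criterion on the grayscale histogram, ink = the
darker class. Pen-on-paper pages are strongly bimodal, so a global
parameter-free threshold suffices; the chosen threshold is recorded in the
audit output. A page with a single intensity value has no ink and errors
out rather than guessing.

**Cleaning.** Three defenses, in order: components smaller than
`min_speck_px` are dropped (default 25 px at 300 dpi, i.e. dust of about
0.13 mm²; the pipeline rescales it by `(pixels_per_cm / 118.11)²`);
components entirely inside the outer `margin_frac` (default 8%) of each
page edge are dropped — the protocol asks participants to write their age
and sex on the page, and that handwriting must not be measured; the
remaining ink is morphologically closed with a disc of radius
`closing_radius_px` (default 3 px) to bridge pen skips without merging the
tree with page borders. After cleaning, the largest 8-connected component
is taken as the tree (ties broken topmost-then-leftmost, so the choice is
deterministic).

**Silhouette and width profile.** The component is closed and hole-filled;
the per-row horizontal extent (rightmost − leftmost + 1) of the result is
the width profile. A centered moving average smooths it (window 2% of the
silhouette height, forced odd so boundaries suffer no phase shift; minimum
3 rows).

**Boundary detection.** The crown/trunk boundary starts from a coarse
detector: the first run of at least `run_rows` rows (default 1% of height,
minimum 3) below the profile maximum whose smoothed extent is at most
`alpha` (default 0.45) of that maximum. A threshold expressed relative to
the crown's width necessarily fires where the shrinking crown chord crosses
it — for an elliptical crown that is about `(1 − sqrt(1 − alpha²))` of the
crown height *above* the true junction — so the coarse row is refined: walk
down to where the smoothed profile meets the trunk plateau (1.15× the
median extent below), then snap to the raw-extent minimum in a short
window. The crown chord pinches to almost nothing right at the junction,
so that minimum *is* the junction row, and the refinement is what makes
junction recovery accurate to a few rows at any scan resolution. If the
profile never collapses (no crown narrowing at all — e.g. a bare
rectangle), the boundary falls back to the top row and the output carries a
`low-confidence-boundary` flag.

The trunk/root boundary mirrors this: root flares appear as the deepest run
of rows whose smoothed extent is at least `beta` (default 1.6) times the
trunk's median extent, accepted only if the run reaches the bottom quarter
of the trunk region (a wide band higher up is crown spill, not roots). The
`beta` threshold fires only part-way down a gradually widening flare, so
the onset is walked up on the raw profile while the backward few-row jump
is steeper than anything the trunk's own taper produces (3 px over
`run_rows` rows). No qualifying run means no roots — a sentinel one past
the bottom row, leaving the root mask empty.

**Measurement.** Area = pixel count / `pixels_per_cm`²; height = row
extent / `pixels_per_cm`; width = maximum single-row horizontal extent /
`pixels_per_cm` (robust to stray pixels, unlike a bounding-box width).
Totals are derived, never re-measured. Values stay at full precision
internally; the reporting layer rounds half-up to 2 decimals, matching
clinical table conventions.

## The synthetic renderer: what it emulates, what it does not

No scans from drawing-test studies are publicly deposited, so validation
rests on `render_tree()`: a jittered-ellipse crown (low-order harmonic
boundary perturbation, so the boundary finder is stressed but the area
stays analytic to first order) atop a trapezoidal trunk, with an optional
trapezoidal root flare, drawn filled or as outline strokes, plus Gaussian
scanner noise and a handwriting stand-in in the bottom margin. Ground
truth comes from the same geometry that drew the ink: exact component
masks and boundary rows, closed-form areas (`pi·a·b`, trapezoid rule), and
calibrated measurements of the ground-truth masks themselves.

The root flare is a single widening trapezoid rather than separate
fanned-out root strokes, and the crown is a perturbed ellipse rather than
a fractal canopy: in both cases analytic ground truth was preferred over
visual realism, because the generator's job is to make measurement error
attributable. Passing the recovery suite therefore demonstrates correct
geometry, calibration and partitioning on clean archetypes — it does *not*
demonstrate robustness to overlapping strokes, faint pencil, shading,
non-tree doodles, or drawings whose trunk is wider than their crown, all
of which real clinical scans contain. The `low-confidence-boundary` flag
and the overlay image (`write_overlay()`) exist precisely because a human
should review atypical pages.

`generate_cohort()` scales this up: per-group marginals for total drawn
area, crown:trunk ratio and HDRS/HAMA scores, with the area–HDRS rank
dependence induced by a Gaussian copula. The copula acts on normal scores
within each group, which is exactly the structure Spearman correlation —
the statistic used downstream — is sensitive to. The default group
parameters reproduce the study conditions this package models (82
depressed adolescents, 43 depressed adults, 59 controls; total areas
54.61 ± 5.03, 56.71 ± 4.20 and 114.53 ± 9.53 cm²; HDRS 26.73 ± 9.03,
39.63 ± 3.31 and 4.80 ± 2.83), with rank correlation −0.3 matching the
reported direction and magnitude class of the area–severity association.
Scores are rounded to integers and truncated at zero, which attenuates
the realized rank correlation slightly — tests of the copula use bands,
not point values.

## Statistical battery

The comparison workflow mirrors the reporting conventions of the clinical
tables it reproduces:

* Normality gate: Shapiro–Wilk per group at α = 0.05; both pass → pooled
  (Student) two-sample t-test; otherwise Mann–Whitney U. The pooled
  variant is the default because it is the one that reproduces published
  HDRS t statistics from their printed summaries; Welch is available by
  flag. `t_test_summary()` computes the identical statistic from printed
  means/SDs/ns, which is how published tables are audited without raw
  data.
* Mann–Whitney uses the exact U distribution when both groups have ≤ 20
  observations and no ties, the tie-corrected normal approximation
  otherwise. Spearman uses the exact permutation distribution below n =
  10 without ties, the t approximation otherwise — the exact small-sample
  path is what the brute-force enumeration tests pin down.
* Effect sizes are Cohen's d with pooled SD. Stars follow the footnote
  convention `**` p < 0.01, `***` p < 0.001 (strict inequalities). No
  multiple-testing correction is applied, and the report header says so:
  the package reproduces the field's reporting style rather than
  correcting it.
* `required_sample_size()` iterates n upward through the exact
  noncentral-t power of the pooled test (df = 2n − 2, noncentrality
  `d·sqrt(n/2)`). At d = 0.5, α = 0.05, power 0.80 it returns 64 per
  group; the test suite cross-validates the returned n against seeded
  Monte-Carlo power to within 0.02.

One caveat the package deliberately embraces: published tables in this
literature are not always internally consistent (component means that do
not sum to printed totals, t statistics irreproducible from their own
row summaries). `treedraw` enforces the additive identities on its own
output and reproduces only the arithmetic that is reproducible; it does
not treat printed component sums as an oracle.

## Numerical and design choices

* 8-connectivity throughout, so thin diagonal pen strokes stay connected.
* Ties in component selection: topmost, then leftmost bounding box.
* Smoothing windows are forced odd; the moving average shrinks its window
  at the profile ends instead of padding, so no NA handling leaks into
  boundary logic.
* All randomness in the generator flows from the spec seed (jitter from
  `seed`, noise from `seed + 1`, per-participant seeds derived
  arithmetically below 2³¹); rendering is bit-reproducible and the test
  suite relies on that.
* Degenerate inputs error with classed conditions
  (`treedraw_no_ink_error`, `treedraw_no_drawing_error`,
  `treedraw_degenerate_error`, …) and the pipeline attaches the failing
  stage name, so batch runs can log failures precisely and keep going.
* Problem sizes in the test suite: renderer fixtures run at 100–150 dpi
  (A4 at 100 dpi is 827 × 1169 px), the recovery suite uses 50 seeded
  trees, and the end-to-end cohort check uses 50 drawings per group at
  100 dpi; single-drawing examples also verify agreement between 150 and
  300 dpi rendering. These sizes were chosen as the smallest at which
  discretization error is clearly below the tolerances being tested.

## Worked example

```{r example, eval = FALSE}
spec <- synthetic_tree_spec(crown_semi_axes_cm = c(3, 2.4),
                            trunk_top_cm = 1.4, trunk_bottom_cm = 1.7,
                            trunk_height_cm = 6,
                            root = list(flare = 2.5, length_cm = 1.2),
                            noise_sigma = 8, dpi = 150, seed = 42)
drawing <- render_tree(spec)
path <- tempfile(fileext = ".png")
write_image(drawing$image, path)

res <- measure_file(path)
res$metrics
#> <tree_metrics> (cm / cm²)
#>   area : crown 22.66  trunk 9.36  root 3.60  total 35.62
#>   height: crown 4.71  trunk 6.05  root 1.20  total 11.96
#>   width : crown 6.20  trunk 1.69  total 6.20
drawing$metrics$crown_area_cm2   # analytic truth: pi * 3 * 2.4 = 22.62
```

## Known limitations

* Row-based partitioning cannot represent a trunk drawn overlapping the
  crown interior, asymmetric root systems, or multiple trees on one page
  (the largest component wins).
* De-skewing is out of scope: a rotated scan will measure a rotated tree.
* The normality gate at small n has low power, so the pooled t-test will
  be chosen for modestly non-normal small samples — the same behaviour as
  the clinical workflow it mirrors.
* The synthetic cohort validates directions and magnitude classes of
  group effects, not clinical effect sizes: real drawings vary far more
  than the generator's archetypes.
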