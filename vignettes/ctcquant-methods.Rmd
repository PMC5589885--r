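---
title: "Quantifying circulating tumor cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying circulating tumor cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcquant)
```

## The problem

Negative-depletion enrichment isolates circulating tumor cells (CTCs) from
whole blood by removing everything else: red cells and platelets by a
size-based microfluidic stage (deterministic lateral displacement, DLD),
then magnetically labeled white blood cells (WBCs) by two magnetophoresis
stages (MACS1, MACS2). Because nothing about the tumor cell itself is used
for capture, the product can be interrogated for exactly the properties
other technologies select on — cell size and epithelial antigen (EpCAM)
expression — without circularity. `ctcquant` implements that downstream
quantification: single-cell sizing and membrane expression from imaging
flow cytometry, rule-based event classification, and the population
statistics that compare an unbiased CTC sample against what a size gate or
an EpCAM gate would have kept.

Raw per-cell patient data for this assay class are not publicly deposited,
so the package is built around a ground-truthed synthetic generator: every
downstream stage is testable against planted truth, and the statistical
machinery can be exercised at any scale without external data.

## Sizing and membrane expression

Each event is a multichannel single-cell image at a fixed pixel scale
(0.5 µm/px by default). The measurement chain is:

1. **Segmentation.** The most uniform surface stain for the cell type
   (CD45/CD16 for WBCs, EpCAM for epithelial CTCs, CD146 for melanoma) is
   thresholded to remove background; the largest connected component is
   kept and its interior filled, because surface stains image as rings and
   the quantity of interest is the area enclosed by the perimeter.
2. **Equivalent diameter.** The enclosed pixel area \(A\) is converted
   assuming a circular cross-section:
   \(d = 2 s \sqrt{A/\pi}\), with \(s\) the pixel scale.
3. **Membrane mask.** The object mask dilated by 3 px minus the object
   mask eroded by 7 px gives an annulus (~10 px ≈ 5 µm across) straddling
   the membrane.
4. **Expression.** The membrane expression in arbitrary units (a.u.) is
   the arithmetic mean of the marker channel over the annulus, rescaled by
   the ratio of reference to measurement-day laser power.

The thresholding rule used by instrument software is not standardized, so
it is a policy parameter: Otsu's method by default, with fixed-value and
background-median + k·MAD alternatives. Morphology uses disk structuring
elements; connected components come from `EBImage::bwlabel`. Segmentation
targets here are convex blobs, for which the connectivity convention is
immaterial.

```{r sizing-example}
cfg <- synth_config(seed = 1, noise = FALSE)
cell <- sample_population(cfg, 1, c(CTC = 1))[1, ]
img <- render_cell_image(cell, cfg)
m <- measure_cell(img, "EpCAM", policy = "fixed", value = 0)
c(true = cell$true_diameter_um, measured = m$diameter_um)
```

## Calibration

Two instrument facts matter for interpretation. First, one a.u. of mean
membrane intensity corresponds to approximately **520 MESF** (molecules of
equivalent soluble fluorochrome) for the calibrated R-PE/EpCAM channel;
`au_to_mesf()` applies this line and is deliberately limited to the
calibrated channel. Second, fluorescence-based sizing **overestimates**
true size — about 16% on bright calibration beads, as much as 20% at high
intensity, shrinking toward zero as intensity falls. The bias-versus-
intensity curve is not published in functional form, so the default is a
saturating curve through (0, 0) anchored at 16% for bright beads and
capped at 20%, overridable by a measured two-column bead table. Reported
measurements in this assay family are conventionally *uncorrected*, so
`correct_size_bias()` is opt-in and off in the default pipeline
configuration.

## Classification rules

A CTC call requires a nucleus (DRAQ5+), negativity for all leukocyte
exclusion markers (CD45, CD66b, CD16), and lineage positivity: EpCAM for
breast/lung/prostate, CD146 **and** NG2 for melanoma. Positivity is strict
(`expression > threshold`), which is stable when a negative control is
identically zero; thresholds default to control mean + 3·MAD from a
designated negative-control population, except EpCAM, where the
CellSearch-equivalent threshold (below) is available.

The remaining nucleated events deconvolve into four contaminant classes by
their full six-marker signature over DRAQ5, CD45, CD16, Glycophorin A
(GlyA), Concanavalin A (ConA) and CD41:

| class | signature |
|---|---|
| leukocyte | DRAQ5+ / CD45+ / CD16+ / GlyA− / ConA− / CD41− |
| erythroblast | DRAQ5+ / GlyA+ / CD45− / CD16− / ConA− / CD41− |
| bare nucleus | DRAQ5+ / ConA+ / GlyA− / CD45− / CD16− / CD41− |
| megakaryocyte | DRAQ5+ / CD41+ / ConA− / GlyA− / CD45− / CD16− |

The four signatures are mutually exclusive; anything else is
`unclassified`. Megakaryocytes versus nucleated events carrying satellite
platelets (also CD41-bright) are distinguished in practice by bright-field
morphology and staining continuity — a qualitative criterion this package
does not infer; it is surfaced as an optional boolean
(`satellite_platelets`) that vetoes the megakaryocyte call, and absent
that flag a CD41+ nucleated event is a megakaryocyte.

**Dropout model.** Staining/detection failure is modeled as *dropout*:
each truly positive call is lost independently with probability *p*
(`drop_positive_calls()`). A marker that is not expressed cannot drop out,
so negatives are unaffected. Under dropout the archetype signatures cannot
mutate into one another (dropout only removes positives, and every class
requires at least one positive the others forbid), so the accounted
fraction among events still gated nucleated has the closed form
\(\sum_c w_c (1-p)^{k_c - 1}\), where \(k_c\) counts a class's positive
markers including DRAQ5 and \(w_c\) is the class mix. At the published
median contaminant mix and \(p = 0.05\) this is ≈ 93.5%, consistent with
the > 90% accounting the assay reports; the tests verify the simulated
fraction against this closed form.

## Population statistics

- **Size threshold.** The empirical quantile above which only 0.1% of
  WBCs lie (13.9 µm on the reference healthy-donor population). All
  quantiles are type-7 (linear interpolation), recorded in output
  metadata, since the convention is never stated upstream.
- **CellSearch-equivalent EpCAM threshold.** For a cell line with a
  published recovery yield *y* on an EpCAM positive-selection platform,
  the equivalent threshold is the (1−*y*) expression quantile; the
  consensus threshold is the median across lines (147 a.u. for the
  published triple, with the interval-valued line collapsed to its lower
  endpoint — the conservative choice, and the median of three is
  insensitive to it).
- **Below-threshold fractions and quadrants** use strict `<` below and
  `≥` above, so threshold ties conserve totals. Fractions are reported at
  one decimal, bin tallies at the nearest integer, matching the two
  reporting styles used in this literature.
- **Expected-yield curves.** The yield of a hypothetical single-parameter
  technology at threshold *t* is the fraction of the observed CTC
  population ≥ *t* (one minus the empirical CDF), so
  `yield(t) + fraction_below(t) = 100%` away from ties.
- **Rank-sum comparisons** are two-sided Mann–Whitney tests: exact
  enumeration when the smaller sample has ≤ 8 observations and there are
  no ties, normal approximation with tie correction otherwise. No
  multiplicity adjustment is applied by default, matching how such
  comparisons are conventionally reported; Holm correction can be applied
  by the caller via `p.adjust`.
- **Enrichment accounting.** Relative yield is product /(product + MACS
  wastes); WBC carryover is product WBCs per mL of input blood; spike
  concentration is the plain mean of four chamber counts; reagent rules
  are 180 µL antibody cocktail and 1.2 mg streptavidin beads per mL
  blood, and the concentration factor is product volume over concentrated
  volume (50× for 5.5 mL → 110 µL).

## The synthetic generator

`synth_config()` fixes the study conditions:

- **Sizes** are lognormal per class. The WBC law is solved so that its
  99.9% quantile is exactly 13.9 µm (median 9.5 µm, σ_log ≈ 0.123 —
  a realistic WBC scale). CTCs use median 12 µm, σ_log 0.30, spanning
  roughly 5.9–29.5 µm at ±3σ, the published patient range; erythroblasts,
  bare nuclei and megakaryocytes use 9, 7 and 18 µm medians.
- **Marker densities** are lognormal for each class's positive markers;
  CTC EpCAM is long-tailed (mean 250 a.u., σ_log 1.2) so that sampled
  populations span the published patient means (~163–525 a.u.).
- **Beads.** The bead-count law per WBC is not published, only the cutoff
  behavior; Poisson with configurable mean (default 7) is assumed. Cells
  without depletion-antigen expression carry zero beads.
- **Rendering.** Nuclear channel: filled disk (65% of cell diameter);
  surface channels: a 2 px annulus just inside the boundary (thin shell,
  consistent with surface staining) whose intensity equals the marker
  density; optional Gaussian blur; additive Gaussian background clipped at
  zero with mean 1.98 a.u. — the published empty-channel (WBC EpCAM)
  baseline. Frames auto-size with a 5 px margin unless fixed.
- **Enrichment simulation.** Each cell independently: transferred by DLD
  with probability 0.70, then removed to MACS waste if its bead count
  reaches the stage cutoffs (6, then 1). Routing is a partition — the
  three waste streams and the product always sum to the input.
- All randomness derives from one seed through named substreams, so the
  generator, renderer and simulator are individually reproducible and
  mutually independent.

What the generator does **not** emulate: bright-field morphology, focus
and debris artifacts, doublets, spectral spillover, bead aggregation, or
any flow physics — DLD is a single transfer probability. Passing tests
therefore demonstrate the correctness of the measurement and statistical
machinery on idealized images and event streams, not instrument-level
fidelity on real data.

## Numerical choices and problem sizes

Quantiles are type-7 throughout. Percent tallies keep full precision
internally and round only in reports. Segmentation failure on an empty
channel is an error that flags the event unmeasurable rather than a
silent drop. The test suite uses 10⁴-cell populations for threshold
recovery (bootstrap-CI checks), 10⁵–5·10⁵ cells for enrichment
Monte-Carlo closed-form checks, 100 random blobs for morphology
invariants, and a handful of rendered cells for image round-trips —
sizes at which every check is stable yet the whole suite runs in well
under a minute.

## Known limitations

- The a.u.→MESF line applies to the calibrated R-PE/EpCAM channel only;
  other channels have no bead anchor.
- The size-bias curve's functional form between its anchors is an
  assumption; supply a measured bead table where available.
- The Otsu default can over-segment extremely dim cells; for such events
  a fixed or k·MAD policy is preferable.
- Patient-level headline fractions (e.g., % of CTCs below threshold per
  disease) depend on the disease-specific CTC distributions, which are
  summarized, not deposited; synthetic populations reproduce their
  qualitative ordering, not the printed per-patient numbers.
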