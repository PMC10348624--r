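---
title: "Quantifying anti-satellite-glia-cell IgG: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying anti-satellite-glia-cell IgG: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgcquant)
```

## The assay and its scoring model

Serum or plasma from a patient is incubated with live satellite-glia-cell
(SGC)-enriched or neuron-enriched cultures, so that IgG can bind only
cell-surface antigens. Cells are identified by a marker channel
(glutamine synthase for SGCs, PGP 9.5 for neurons) and bound human IgG by
a second channel. The subject-level readouts are

* the percentage of marker-positive cells that are also IgG-positive, and
* the mean IgG *integrated density* across all marker-positive cells.

`sgcquant` implements that scoring chain on instance masks from any
segmenter, plus the downstream statistics, and ships a synthetic-data
module so that every stage can be tested against known ground truth.

### The experiment-wide threshold

For each channel, a minimum pixel-intensity threshold is set from the
pooled pixel population of *all* images of one experiment: with pooled
mean $\mu$ and standard deviation $\sigma$,

$$T = \mu + k\,\sigma, \qquad k = 8 \text{ by default.}$$

The phrase this rule descends from ("8 × SD of the mean pixel intensity
of all the images") is ambiguous between $\mu + 8\sigma$ and the literal
$8\sigma$. Both are supported (`rule = "mu_plus_k_sd"` or `"k_sd_only"`),
the default is $\mu + 8\sigma$, and the choice is echoed into every
output. For a near-zero fluorescence background the two nearly coincide.
Pooling is over pixels, not per-image means, so mixed image shapes are
fine; the statistics are accumulated from per-image sums, and an
"experiment" is exactly the set of images declared together (one
manifest, or one pipeline run).

Suprathreshold means *strictly above* $T$: the degenerate all-constant
image then yields $\sigma = 0$, $T$ equal to the constant, and zero
positive pixels, which is the sensible reading of a background-only
field.

### Per-cell measurement and positivity

Inside each cell mask and for each channel, the package records the
suprathreshold pixel count (`area_above`) and the sum of the *raw* pixel
values over those pixels (`intden`, the ImageJ integrated-density
convention -- values are not threshold-subtracted). A cell is positive
for a channel when `area_above >= min_area`. The source workflow states a
minimum-area rule without a number; the default is 5 px, configurable,
and always recorded. Thresholds are computed per channel independently
because the channels have unrelated gain.

A sample summary counts IgG-positive cells among marker-positive ones and
averages IgG integrated density over *all* marker-positive cells,
IgG-negative cells contributing zero. A sample with no marker-positive
cell is flagged unevaluable rather than scored 0.

### When the 8-SD rule works: a sparsity requirement

Because the pooled SD includes the cells themselves, the rule has an
implicit geometry assumption. If lit pixels make up a fraction $f$ of the
pooled population at typical amplitude $a$, then $\sigma \approx
a\sqrt{f}$ and the threshold sits near $\mu + 8a\sqrt{f}$; cells are
detectable only if $8\sqrt{f} < 1$, i.e. the lit fraction stays below
roughly 1.5%. Confocal fields of cultured DRG cells are sparse in exactly
this way. The synthetic defaults respect it (15 cells of ~4 px radius on
256 × 256 fields); packing the same cells into a 128 × 128 field pushes
the threshold above the cell amplitudes and positivity collapses. This is
a property of the published rule, not of this implementation, and it is
why the simulator's field size and cell density are not free dials if the
scoring is to behave like the original assay.

## Segmentation

The original workflow segments cells with an external deep-learning tool
and imports its ROIs. The package therefore treats segmentation as a
contract: any integer label-map TIFF (0 = background, positive integers =
instances) is accepted via `ingest_label_map()`, which rejects
floating-point or negative rasters and shape mismatches. For
self-contained synthetic work, `segment_baseline()` provides a
deterministic classical pipeline: Gaussian smoothing (default $\sigma$ =
1 px), a global threshold (Otsu by default, or mean + $k$ SD), connected
components, optional distance-transform watershed to split touching
cells, and a minimum-area filter (default 9 px). The *marker* channel is
segmented; IgG is only ever measured inside marker-derived masks.

Labels are always renumbered canonically (1..K by centroid row-major
order) so repeated runs and different label sources produce
byte-comparable tables. Cells touching the border are kept by default
(the emulated workflow states no exclusion rule); `exclude_border = TRUE`
is available.

## Tissue sections

On DRG tissue the unit is the object, not the cell: *soma* are
NF200-positive objects with area at least `soma_min_area` (default 200
px) and circularity $4\pi A/P^2 \ge 0.6$; *axons* are NF200-positive
objects failing the soma test; *SGCs* are GFAP-positive objects within an
adjacency radius (default 3 px dilation) of a soma, the geometric reading
of "perineuronal"; everything else in the foreground is *other*. Every
object receives exactly one class.

Perimeter is estimated from 4-neighbour boundary edge counts scaled by
$\pi/4$, which is exact for rasterized discs and well behaved for
1-px-thin tracts; contour tracing, by contrast, returns degenerate
perimeters for thin curvilinear objects and would misclassify axons as
round.

The IgG readout per object is the whole-object mean intensity divided by
the slide's background threshold. Two open choices are resolved as
follows and recorded in metadata: the background threshold reuses the
$\mu + k\sigma$ rule with a tissue default of $k = 2$ (the original
tissue pipeline's internal normalization is not published; this is a
deterministic, self-consistent stand-in), and the *whole-object* mean is
used rather than the suprathreshold-only mean. Donor summaries average
per-slide means with slides weighted equally -- a slide with ten times
more objects does not dominate -- matching the stated 5-slide averaging.

## Phenotype scores

Pressure pain thresholds are assessed bilaterally at 4 anatomical sites;
the subject score is the arithmetic mean of the 8 readings, and missing
readings are an error, never imputed. The conditioned pain modulation
score is $(\mathrm{PPT}_\mathrm{end} - \mathrm{PPT}_\mathrm{baseline}) /
\mathrm{PPT}_\mathrm{baseline}$; positive values represent pain
inhibition. The score is unitless and invariant to rescaling both
pressures. FIQ is ingested as a precomputed 0--100 total; VAS/NRS pain
scales are validated against 0--100.

## Statistics

Test selection follows the readout kind: proportion-like outcomes
(percent IgG-positive) use rank tests (Mann-Whitney for two groups,
Kruskal-Wallis plus Dunn's post hoc for more); intensity-like outcomes
(integrated density, titres, phenotype scores) use two-tailed t-tests or
one-way ANOVA with Tukey's post hoc. Everything is two-sided at
$\alpha = 0.05$, and **no multiple-testing correction is applied
anywhere** (Dunn adjustment exists behind a flag); output metadata
records this. Spearman correlation matrices use pairwise-complete
observations and mask entries at $p < \alpha$; constant columns yield
reported `NA`s.

Severity clustering is k-means with $k = 2$ on FIQ, average pain, and
maximum pain, z-scored first (the three scales share a 0--100 range but
not a variance; `scale = FALSE` is available), best of 25 restarts under
an explicit seed. The *severe* label goes to the cluster with the higher
mean standardized centroid, which makes labels independent of row order.

Plate effects in ELISA titres are removed with fixed sample effects plus
sum-to-zero plate offsets estimated by least squares. At this design
scale the fit is equivalent to the usual mixed-model plate correction
while remaining deterministic and exactly testable; the design must be
connected through bridging samples, and the observed grand mean is
restored exactly after correction.

## The synthetic-data module

### What it emulates

*Cultures*: fields of view with a Poisson number of cells (default 15 per
field, 5 fields, i.e. ~73 cells per sample), ~82% marker-positive, cell
radii ~4 px, amplitudes from a ±2.5-SD truncated normal (bright-cell
variability without a dim tail that would sit on the threshold), constant
background plus Gaussian read noise and optional Poisson shot noise, and
a Gaussian PSF folded into the cell profile. Cells are placed by
dart-throwing with a minimum center distance of 2.5 radii; an unplaceable
configuration is a reported error, never a silent omission. Images are
written as 16-bit unsigned TIFF with a clipping-fraction report.

*Tissue*: soma as large discs (NF200), perineuronal glia rings as annuli
(GFAP), gently curving axon tracts (NF200), and unlabeled blobs, with
per-class IgG amplitudes -- the knob used to inject class-specific serum
binding.

*Cohorts*: each subject carries a latent anti-SGC level $z \sim N(0,1)$,
shifted by `latent_effect` (default 1.0) in the FM group. Every severity
variable is a scale-affine transform of $c\,z + \sqrt{1-c^2}\,\varepsilon$
with an *independent* residual per variable and coupling $c$ =
`severity_coupling` (default 0.5); PPT couples with the opposite sign,
and CPM is deliberately uncoupled. The latent level maps to a binding
fraction through a floored sigmoid,
$$p(z) = 0.12 + 0.70 \cdot \mathrm{logit}^{-1}\!\big((z - 1.4)/0.35\big),$$
so most subjects sit near a common nonspecific floor and binding rises
mainly in the high-latent tail. This shape was chosen, once, to emulate
the qualitative epidemiology the pipeline targets: only a subset of
patients seropositive, occasional high-binding controls, and a mild
patient group resembling controls. A linear link cannot produce that
pattern -- it either separates mild patients from controls or removes the
group effect entirely.

### Two generator modes

The image-level path renders pixels and exercises segmentation and
thresholding. The measurement-level path (`simulate_sample_summaries()`)
draws the same per-cell binding outcomes directly -- binomial positivity
among marker-positive cells and per-cell integrated densities -- without
rendering. Both sample the same statistical model; replicate-heavy
calibration studies (type-I error over 1,000 cohorts, pattern-recovery
over 200 cohorts) use the measurement level, while image-level recovery
is verified separately across the full binding range (the imaging path
recovers the rendered truth fraction exactly at the standard SNR). Test
problem sizes were chosen so the full suite stays interactive: 512 × 512
four-field samples of ~200 cells for recovery, 256 × 256 sections for
tissue, 1,000 and 200 measurement-level replicates for calibration.

### What it does not emulate

Real optics beyond a Gaussian PSF, 3-D stacks (the analysis operates on
2-D projections), staining chemistry and antibody cross-reactivity,
segmentation-hostile morphologies (overlapping or irregular cells),
uneven illumination, batch and plate-position effects in imaging, and
missing phenotype data. Passing tests therefore demonstrate that the
*computational* chain is correct and calibrated under its stated model --
not that the assay itself is robust to those real-world effects.

## Numerical and degenerate-input choices

Suprathreshold is strictly `>`; constant images give zero positives.
Rank tests use mid-ranks with tie-corrected variances (exact p-values for
small untied samples via the underlying base implementations). Identical
paired donor values return $t = 0, p = 1$ by convention rather than an
error. Constant-in-all-groups comparisons return a degenerate-input
report with `p = NA`. Clustering refuses fewer than 4 subjects, missing
features, or all-identical feature vectors. Every stochastic routine
takes an explicit integer seed, restores the caller's RNG state, and
derives stage seeds from the master seed, so identical configs give
byte-identical outputs.

## Known limitations

* The joint "qualitative pattern" of the emulated study -- patients above
  controls, positive severity correlations, severe > mild with mild
  indistinguishable from controls, and a null anti-neuron comparison --
  cannot be reproduced in much more than ~60% of replicate synthetic
  studies at the default design, and its per-replicate probability has a
  hard ceiling near 0.90: two of its components are acceptances of a true
  null hypothesis at $\alpha = 0.05$, each holding with probability
  ~0.95 by construction. In addition, with severity coupling 0.5 the
  k-means split separates clusters by only ~1.1 SD of latent level
  against ~0.8 SD within-cluster spread, capping the severe-vs-mild
  rejection rate near 0.85 regardless of the binding link's shape (both
  the gap and the spread scale together with its slope). The replicate
  studies in the test suite compute these rates; the individual
  directional components each hold in well over 90% of replicates.
* The baseline segmenter is a stand-in for learned segmentation and is
  only validated on well-separated synthetic cells; real cultures should
  enter through external label maps.
* The tissue background normalization is a declared convention, not a
  reconstruction of the original pipeline's internals.
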