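---
title: "Quantifying perineuronal nets: detection, colocalization and phenotype classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying perineuronal nets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnnquant)
```

## The measurement problem

Perineuronal nets (PNNs) are condensed extracellular-matrix structures that
enwrap the soma and proximal dendrites of a subset of neurons, classically
parvalbumin-positive interneurons. In a single confocal plane stained with
*Wisteria floribunda* agglutinin (WFA), a PNN appears as a punctate ring
around the cell body. Many questions about PNN biology reduce to the same
measurements: How many rings are there? How big and how bright are they? And
when a second protein is stained in another channel, does its signal sit
*on* the net, and does its per-cell intensity co-vary with WFA intensity?

`pnnquant` automates that analysis: it detects ring candidates in the WFA
channel, accepts only candidates that surround a nucleus in the Hoechst
channel, segments the WFA-positive annulus of each accepted ring, measures
per-object mean intensities in every channel over that *identical* region,
and summarizes the result as an object-based colocalization coefficient, a
phenotype census, and culture-level group statistics.

## The pipeline, stage by stage

**Nucleus detection.** The nuclear channel is Gaussian-smoothed
(`nucleus_sigma = 2` px) and thresholded. The threshold is the larger of a
robust background offset (median + `nucleus_k` MAD, `nucleus_k = 4`) and
half the smoothed dynamic range. The second rule matters: a MAD-only
threshold sits just above the noise floor, so the smoothed skirt of a
nucleus passes it and the resulting mask is roughly twice its true radius;
the half-maximum rule tracks the edge of the stain itself. Connected
components are filtered by area (`nucleus_area_range = c(20, 2000)` px²)
and summarized by centroid and equivalent radius.

**Ring detection.** A circular accumulator over a radius range
(`r_min = 8`, `r_max = 30` px): the smoothed WFA channel is thresholded
into a foreground map (median + `fg_k = 3` MAD), and for every radius the
fraction of a one-pixel circle covered by foreground is computed at every
center by FFT convolution with a ring kernel. A candidate is a local
maximum of the per-pixel best score above `score_threshold = 0.35`. Two
suppression rules follow, both deterministic (ties broken by score, then
row, then column):

1. plain non-maximum suppression within `nms_spacing` (default `r_min`);
2. an *explaining-away* rule: a candidate is dropped when at least half of
   its own circle-path support lies within `overlap_band = 6` px of
   higher-scoring accepted circles. Without this rule, off-center circles
   that graze a thick ring (or thread between several rings) reach
   coverage scores of 0.4–0.7 and flood the candidate list; they explain
   no structure that an accepted ring has not already claimed.

Accepted candidates are refined to subpixel precision by an
intensity-weighted algebraic (Kåsa) circle fit to the foreground pixels of
the candidate annulus, iterated three times. On synthetic scenes at default
noise this yields center errors well under 1 px and radius errors under
0.5 px.

**Nuclear gating.** A candidate is kept if and only if at least one nucleus
centroid lies inside its circle (distance < `radius * gate_factor`,
`gate_factor = 1`). The nearest such nucleus is linked; each nucleus can
back at most one ring, best score first. The gate can only remove
candidates — detection counts never increase downstream.

**Ring segmentation.** The ring mask is the set of pixels in the annulus
`radius ± half_width` (`half_width = 2` px) whose WFA intensity exceeds a
local background threshold: median + `bg_k = 2` MAD of an annular shell
2–6 px outside the ring. Objects with an empty mask are dropped with a
logged reason. The half-width equals the rendered ring half-width of the
synthetic scenes; a wider annulus inflates mask areas systematically
because the blurred dot texture stays above the local threshold a pixel or
two beyond the ring proper.

**Measurement.** Per-object mean intensity is the plain arithmetic mean
over the ring mask, computed over the *same* mask in every channel, with no
background subtraction by default (an optional background shell subtraction
exists for unevenly stained material). Areas are mask pixel counts times
the pixel area.

**Colocalization.** The coefficient is the Spearman rank correlation of
the per-PNN mean intensities of two channels — an object-based statistic,
deliberately not a pixel-wise one. Records are pooled across images by
default, mirroring an analysis that pools ~20 nets per animal over several
animals into one coefficient; per-group coefficients are available via
`by =`. Degenerate input (fewer than 3 pairs, constant values) raises an
error instead of returning `NA`, because silent `NA`s corrupt batch
summaries. No p-value is attached by default; a seeded permutation p-value
(label shuffles) is available via `n_perm`.

**Phenotype classification.** Two independent boolean calls per PNN cell:

* *surface-positive*: the comparison-channel ring mean, expressed as a
  z-score against the image background (mean/SD of pixels outside all
  detected cells), reaches `k_surface = 3`.
* *intracellular-punctate*: at least `m = 3` local maxima of the lightly
  smoothed comparison channel inside the soma region (ring interior minus
  the nucleus, with a 3 px clearance from the ring so ring texture cannot
  masquerade as puncta), each exceeding the smoothed background by
  `k_puncta = 6` SD and separated by at least 3 px.

The puncta threshold is deliberately higher than the surface threshold.
The surface score is a *single* z-score per cell, where 3 SD is a
reasonable false-positive guard; the puncta rule scans hundreds of soma
pixels per cell for maxima, and at 3 SD the expected number of spurious
smoothed-noise maxima per soma is well above zero — enough to flip clean
somata to "punctate". At the default signal-to-noise ratio a real punctum
scores z ≈ 70, so 6 SD costs no sensitivity while making the
multiple-comparisons false-positive rate negligible.

The census reports the percentage of PNN-positive cells (the WFA-validated
denominator, which is recorded alongside) that carry each phenotype.

**Culture statistics.** `density_per_50mm2()` scales a count linearly to a
50 mm² reference area. "Relative" size and intensity are defined as
division by the control-group mean, so the control group has mean 1 by
construction — the convention behind "relative intensity" plots.
`compare_groups()` is the classic pooled-variance Student's t (Welch
optional) or a one-way ANOVA F; zero pooled variance with equal means
returns statistic 0 and p = 1 with an explicit degenerate flag.
`pv_pnn_fraction()` identifies parvalbumin-positive cells by soma-level
thresholding of the PV channel around each nucleus and reports the
percentage backed by a validated PNN.

## The synthetic scene generator

Because the analysis must be verifiable without microscope data, the
package ships a generator whose scenes carry complete ground truth. Each
scene has four channels — `nuclear`, `wfa`, `comparison`, `pv` — at a
configurable size (default 512 × 512 px at 0.3 µm/px; the recovery
experiments use 1024 × 1024, matching a typical confocal acquisition
format). Cells are placed by rejection sampling at a minimum center
spacing (default twice the outer ring radius plus 2 px, so rings never
overlap) and snapped to the pixel grid so that rendered patches and
geometric truth masks coincide exactly.

Per cell the generator renders:

* a soft-edged nuclear disc (radius 3.5–4.5 px, logistic edge);
* if the cell bears a PNN, a punctate annulus at radius 14–20 px
  (half-width 2 px): a minimum-spacing dot field in the annulus convolved
  with a small Gaussian, rescaled so that the noiseless mean over the
  geometric ring mask equals the cell's drawn WFA level *exactly*;
* if surface-positive, the same texture in the comparison channel scaled
  to the cell's comparison level — so the true per-cell rank coupling
  transfers to the rendered ring means;
* if intracellular-punctate, 4–7 Gaussian puncta (σ = 1.3 px, spacing
  ≥ 5 px) in the cytoplasmic band between nucleus and ring; the count
  actually placed is what the truth table records;
* if PV-positive, a filled soma disc in the `pv` channel.

Per-cell intensity levels are drawn from truncated-normal marginals
(WFA: mean 0.55, SD 0.12 on the [0, 1] scale; comparison: 0.50, 0.12;
bounds [0.15, 0.95]). The rank coupling between them is produced by a
Gaussian copula: correlated standard normal pairs at the Pearson value
`2·sin(π·ρ_s/6)` that induces the requested population Spearman `ρ_s` for
continuous marginals, mapped through the marginal quantile functions. This
controls the Spearman coefficient without constraining the marginals; at
`ρ_s = 1` the pairs are exactly comonotone and the sample coefficient is
exactly 1.

Phenotype fractions (`frac_pnn`, `frac_surface_positive`,
`frac_intracellular`, applied to PNN-bearing cells) are Bernoulli draws by
default; with `exact_counts = TRUE` exactly `round(frac · n)` cells are
positive, which removes binomial noise from fraction-recovery experiments.
Noise is additive Gaussian (σ = 0.02) with optional Poisson shot noise.
Scenes are bit-identical for a fixed `(config, seed)`.

The defaults are the package's study conditions: coupling 0.816 and
fractions 66% / 29% are the values the recovery experiments target, and
the noise level was chosen once so that single puncta are clearly resolved
(punctum z ≈ 70) — chosen for testability, since real acquisitions publish
neither absolute intensity scales nor SNR.

**What the generator does not emulate:** 3D stacks, a realistic point
spread function, photobleaching, uneven illumination, overlapping or
partial rings, autofluorescence, or intracellular puncta in cells without
PNNs. Passing recovery tests therefore demonstrate that the pipeline's
geometry, measurement and statistics are correct — not that the detector is
robust to every artefact of real tissue. On real images the detection
thresholds (`score_threshold`, `fg_k`, the radius range in pixels) are the
knobs to revisit first.

## Numerical choices and degenerate inputs

* All coordinates are `(row, col)` pixels, 0-based, origin top-left; radii
  in pixels; `pixel_size` (µm/px) converts areas to µm².
* Intensities live on [0, 1]; integer TIFFs are rescaled by dtype range at
  read time and all thresholds are expressed on that scale. Stacks are
  written as 16-bit TIFF (values clipped to [0, 1] only at write time) so
  noise addition cannot clip during simulation.
* Ordering contracts: nuclei sort by (row, col); ring candidates by
  (score desc, row, col); identical inputs give identical outputs — there
  is no randomness anywhere in detection or measurement.
* Empty ring masks drop the object with a logged reason; annuli entirely
  outside the image raise an error; a constant colocalization input raises
  an error; a zero-variance group comparison returns the flagged
  degenerate result described above.

## Experiment sizes used by the recovery suite

The acceptance experiments run the full pipeline on: 6 scenes of 90
PNN-bearing cells (540 pooled objects) for coefficient recovery at
coupling 0.816, tolerance ±0.05; 10 exact-count scenes of 100 PNN-positive
cells (1000 objects) for census recovery at 66%/29%, tolerance ±3
percentage points; 10 seeds of 25-cell scenes for detection recall and
precision (≥ 0.9 at 3 px / 3 px matching); 5000 replicates for t-test
type-I error (5% ± 1.5 pp) and power against the noncentral-t closed form
(± 5 pp); and 10 seeds of 20-PNN control/treated pairs with ring
intensities scaled ×0.3 for the enzyme-digestion direction check. These
sizes keep every stochastic check comfortably inside its tolerance (e.g.
the Spearman sampling SE at n = 540 is ≈ 0.015 against a ±0.05 band).

## A worked example

```{r example, eval = FALSE}
library(pnnquant)

# simulate one in-vivo-like scene with known truth
sc <- simulate_scene(scene_config(n_cells = 40, frac_pnn = 1,
                                  frac_surface_positive = 1, seed = 7))

# detect -> gate -> segment -> measure -> phenotype
det <- detect_pnns(sc$stack)
rec <- measure_pnns(sc$stack, det$pnns)
ph  <- phenotype_cells(sc$stack, det$pnns, det$nuclei, records = rec)

colocalize(rec)          # pooled Spearman coefficient
census(ph)               # phenotype percentages
plot_detections(sc$stack, det$pnns, det$nuclei)  # overlay
```

Multi-image runs go through `run_coloc()` (measurement, phenotype, census
and colocalization reports, optionally written as CSV/JSON) and
`run_culture()` (per-dish densities, relative sizes and intensities, and
group comparisons from a condition manifest). `recover_coloc()` and
`recover_census()` are the self-contained recovery experiments used by the
acceptance script.

## Known limitations

* Overlapping PNNs are not resolved; the generator never creates them, and
  on real tissue the explaining-away rule will keep only the
  higher-scoring ring of a touching pair.
* The nucleus detector assumes a reasonably bimodal nuclear channel; very
  dense fields would need a watershed split, which is out of scope.
* The phenotype thresholds are z-score rules, not learned classifiers;
  they are exposed in `pnn_params()` and should be recalibrated for stains
  whose background statistics differ strongly from the synthetic defaults.
* `run_culture()` treats each image as one dish; nested designs
  (several fields per dish) need aggregation before the group comparison.
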