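# pnnquant

Automated detection and quantification of **perineuronal nets (PNNs)** in
multi-channel fluorescence microscopy images.

PNNs are condensed extracellular-matrix lattices around the soma of a
subset of neurons (classically parvalbumin-positive interneurons). In a
single confocal plane stained with *Wisteria floribunda* agglutinin (WFA)
they appear as punctate rings. `pnnquant` is for labs that need to turn
such images into numbers: ring counts, sizes and intensities, object-based
colocalization with a second channel, and per-cell phenotype calls —
without drawing ROIs by hand.

## What it computes

Given an image stack with named channels (`nuclear`, `wfa`, `comparison`,
optionally `pv`):

1. **Nuclei** — smoothed thresholding + connected components in the
   Hoechst channel.
2. **Rings** — a circular accumulator over a radius range in the WFA
   channel (perimeter-coverage voting by FFT convolution), non-maximum and
   explaining-away suppression, then subpixel refinement by a weighted
   least-squares circle fit.
3. **Validation** — a ring is a PNN only if a nucleus centroid lies inside
   its circle; each nucleus backs at most one ring.
4. **Segmentation & measurement** — the WFA-positive annulus
   (`radius ± half_width`, local median+MAD threshold) becomes the ring
   mask; per-channel mean intensities are measured over that identical
   mask, areas in px² and µm².
5. **Colocalization** — the Spearman rank correlation ρ of per-PNN mean
   intensities between two channels, pooled across images:

   ρ = corr(rank(Ī_wfa), rank(Ī_cmp)) over detected PNNs.

6. **Phenotypes** — per PNN cell: *surface-positive* (comparison-channel
   ring mean ≥ background + 3 SD) and *intracellular-punctate* (≥ 3
   vesicle-like local maxima in the soma), censused as percentages of the
   PNN-positive population.
7. **Culture statistics** — PNNs per 50 mm², control-relative size and
   intensity, PV-gated PNN fractions, pooled-variance Student's t and
   one-way ANOVA comparisons.

A synthetic scene generator (`scene_config()` / `simulate_scene()`)
renders all four channels with complete per-cell ground truth — including
a Gaussian-copula rank coupling between WFA and comparison ring levels —
so every stage is testable without microscope data.

## Worked example

```r
library(pnnquant)

sc  <- simulate_scene(scene_config(n_cells = 40, frac_pnn = 1,
                                   frac_surface_positive = 1, seed = 7))
det <- detect_pnns(sc$stack)
rec <- measure_pnns(sc$stack, det$pnns)
ph  <- phenotype_cells(sc$stack, det$pnns, det$nuclei, records = rec)

det$counts
#>     nuclei candidates  validated  segmented
#>         40         41         40         40

colocalize(rec)
#> <pnn_coloc> rho = 0.821 (Spearman), n = 40 PNNs, wfa vs comparison

census(ph)
#> <pnn_census> n = 40 PNN cells: 100.0% surface-positive, 30.0% intracellular-punctate
```

All 40 generated rings survive the nuclear gate (one spurious candidate is
rejected); the recovered coefficient 0.821 sits next to the generator's
coupling setting of 0.816, and the phenotype census matches the simulated
fractions. `plot_detections(sc$stack, det$pnns, det$nuclei)` overlays the
fitted circles on the WFA channel; results carry `tidy()`/`glance()`
methods for downstream tables.

Multi-image runs: `run_coloc()` (measurements, phenotypes, census and
colocalization reports as CSV/JSON) and `run_culture()` (per-dish
densities, relative size/intensity and group comparisons from a condition
manifest). Real images enter via `read_stack(path, channel_map = c(nuclear
= 0, wfa = 1, comparison = 2, pv = 3), pixel_size = 0.57)`.

## Documentation

The methods vignette (`vignettes/pnn-quantification.Rmd`) describes the
model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and the
package's numerical conventions.
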