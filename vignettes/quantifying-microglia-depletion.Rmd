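---
title: "Quantifying regional microglia depletion: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying regional microglia depletion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliaquant)
```

## The measurement problem

Microglia-depletion studies compare cell densities across brain regions and
treatment groups: function-blocking antibodies against the CSF1R ligands
CSF1 and IL-34 (or a small-molecule CSF1R inhibitor) remove microglia
preferentially from white matter (e.g. the hippocampal fimbria) or gray
matter (e.g. cortex), and the readout is a per-animal density — microglia
per mm^3 of imaged two-photon stack, or per mm^2 of a stained section —
summarized per group as a depletion percentage against a shared control and
tested with one-way ANOVA plus Dunnett's many-to-one comparison.

This package implements that measurement chain end to end. Because the
imaging data behind such studies are rarely deposited, it also ships a
seeded synthetic-data generator that produces every input modality with
exact ground truth, so each stage — and the chain as a whole — is testable
against known answers.

## 3D stack quantification

**Model.** A two-photon stack is a 3D grid of arbitrary-unit intensities
with anisotropic voxels; the default geometry is 0.592 um/pixel in plane
and 1.5 um between slices, so one axial step spans ~2.5 in-plane pixels.
Microglia appear as bright somata with dimmer radiating processes over a
roughly constant background.

**Procedure.** `preprocess_stack()` subtracts a per-slice rolling-ball
background (grayscale opening with a disc, default radius 20 um) and
applies Gaussian smoothing with sigma given in micrometres and converted
per axis (default 1 um), so smoothing is physically isotropic despite the
anisotropic grid. `detect_cells_3d()` then:

1. thresholds globally (Otsu by default, fixed override available);
2. labels 26-connected components (compiled breadth-first search);
3. optionally splits components that contain several intensity maxima
   separated by an h-maxima depth — default 10% of the foreground dynamic
   range — by growing the maxima as seeds, each voxel joining its
   brightest already-labelled neighbour;
4. discards objects below `min_volume` (default 150 um^3, the scale below
   which an object cannot be a microglial soma).

One guard deserves mention: Otsu always returns *some* threshold, even on
an image containing only noise, and a noise-split mask yields dozens of
phantom objects. Detection therefore requires the threshold to exceed the
image median by three robust standard deviations (MAD); otherwise the
stack is declared signal-free and zero cells are returned. On synthetic
stacks this cleanly separates noise-only from signal-bearing images at the
default signal-to-noise ratio of 5.

Density is count over image volume (`compute_density()`), with the volume
taken as the product of the axis extents; `compute_density_2d()` is the
areal variant for single-plane spinal-cord imaging (default 2.3649
um/pixel). Cell size (`measure_cell_size()`) is the voxel count of the
mask — soma plus processes — times the single-voxel volume; on a
rasterized 10 um ball the measurement converges monotonically to the
analytic sphere volume as the voxel pitch shrinks 2 -> 1 -> 0.5 um, and is
within 5% at 0.5 um. Cells touching the stack border are kept for counting
but flagged, and excluded from size summaries, since their masks are
truncated.

## IHC slide quantification

Chromogenic slides carry DAB-brown positive cells on hematoxylin-tinted
tissue over a white background. `segment_tissue()` takes everything darker
than near-white luminance (default 0.92), cleans it with morphological
opening/closing (2 px disc) and hole filling. `segment_stain()` classifies
pixels by distance in *chromaticity* coordinates (RGB divided by the
channel sum), which cancels uniform brightness changes exactly — the mask
is bit-identical under a ±10% exposure change; the default cutoff 0.26
corresponds to the half-blend point between the DAB and hematoxylin
references. An optical-density projection mode (color deconvolution onto
the stain vector) is available as an alternative.

`count_positive_cells()` counts stained objects inside an ROI with a
minima-controlled watershed: the inverted, lightly smoothed (1 px)
luminance is flooded with EBImage's watershed at tolerance `h_depth`
(default 0.10 of the 8-bit range), so touching cells whose profiles retain
two minima basins of at least that depth are counted separately; objects
under `min_area` (default 20 um^2, a nucleus scale) are discarded. The
plain connected-component count is always a lower bound, and doubling the
ROI with no new cells exactly halves the reported density.
`intensity_histogram()` bins per-cell mean 8-bit intensity in 5-unit bins;
the terminal bin [250, 255] absorbs the 256th level.

## FISH quantification

Single-molecule in situ hybridization produces punctate dots; the headline
figure is the percent of tissue area stained. `percent_area_stained()`
computes `100 * |stain ∧ tissue ∧ roi| / |tissue ∧ roi|` — and, because it
is genuinely ambiguous whether such figures are normalized to the ROI or
to tissue within the ROI, both denominators are reported.
`detect_puncta()` band-pass filters at the dot scale (difference of
Gaussians, sigma 0.5 um vs twice that), takes local maxima above a
threshold (Otsu on the positive response by default), and refines centers
to sub-pixel precision by the 3x3 response centroid.

## The statistical layer

* `depletion_percent()`: `100 * (1 - mean_group / mean_control)` per
  region, with a delta-method standard error from the two group means;
  negative values (densities above control) are legitimate and preserved.
* `anova_dunnett()`: the one-way F test computed from group sums of
  squares, then Dunnett's single-step two-sided adjusted p-values from the
  multivariate t distribution with correlation `lambda_i * lambda_j`,
  `lambda_i = sqrt(n_i / (n_i + n_0))` and pooled-variance df `N - k`.
  Because that correlation matrix is a one-factor model, the probability
  reduces to a two-dimensional integral over the shared normal factor and
  the pooled-variance chi variable, evaluated by fixed 64 x 64 tensor
  Gauss quadrature — deterministic, ~3 ms per call, and within ~1e-6 of
  mvtnorm's randomized integrator (asserted in the tests, with
  multcomp::glht as a second reference). With one treatment group the test
  reduces exactly to the pooled two-sided t-test. Pooled variance across
  all groups is used throughout — the common textbook form.
* `ks_binned()`: the Kolmogorov-Smirnov D evaluated at bin boundaries of
  5-unit intensity histograms, with the asymptotic p at effective sample
  size `n_a n_b / (n_a + n_b)`. Per-cell values are never reconstructed
  from bins. Note the sample unit is cells, not animals; treating cells as
  independent overstates significance if animals differ systematically
  (pseudo-replication) — the caller decides what goes in.
* `concentration_response_r2()`: ordinary least-squares R^2 of response on
  tissue drug concentration.
* `fit_calibration()` / `back_calculate()`: the LC-MS quantitation model —
  analyte/internal-standard peak-area ratio vs nominal concentration with
  a 1/x-weighted quadratic; back-calculation takes the non-negative real
  root up to 5% above the top standard and flags (never drops) values
  below the LLOQ, default 0.0073 uM. The fitted curve is checked for
  monotonicity over the calibrated range and warns if it turns over.

## What the synthetic generator emulates — and what it does not

`generate_stack()` renders somata as uniform balls (radius 3.5-5 um) with
2-6 thin cylindrical processes (0.5 um radius, 8-15 um long) at 60% of the
soma intensity, blurs lightly (0.4 um) so profiles are smooth and
unimodal, and adds constant background plus Gaussian noise; the default
SNR (peak foreground over noise SD) is 5. Placement is rejection sampling
under a minimum centroid separation with a hard 10,000-attempt cap; an
overcrowded spec errors rather than looping. `generate_ihc_slide()` places
radially shaded stain-coloured cells on a quantile-thresholded smooth
random field (so tissue coverage is exact); a configurable fraction of
cells arrive as pairs at 1.3 radii separation — their masks merge into one
component while the intensity landscape keeps two minima, which is
precisely the case watershed counting must resolve.
`generate_fish_slide()` lays non-overlapping dots (2 px guard band) until
the exact pixel bookkeeping reaches the target coverage; one dot is far
smaller than 0.5% of the tissue, so the achieved percent area is within
0.5 points of target, and the exact value is returned as truth.
`generate_cohort()` draws per-animal densities as
`baseline * (1 - depletion_fraction)` times mean-preserving lognormal
noise at the stated between-animal CV; sexes alternate M/F as metadata
with no sex effect unless requested.

None of this is photorealistic microscopy: there is no point-spread
function, no optical sectioning physics, no vasculature, no staining
chemistry variation, and noise is Gaussian rather than Poisson-mixed.
Passing tests therefore demonstrate that the *computational chain* is
correct and unbiased under controlled conditions — not that any particular
biological image will segment perfectly. Intensity statistics of real
two-photon stacks are not published in this setting; the synthetic SNR
default is a stated choice, not an inference.

## Numerical choices and degenerate inputs

* Coordinates are 0-based voxel indices with centroids at voxel centers
  (physical coordinate = index x pitch + pitch/2); truth centroids
  round-trip um -> voxel -> um within one pitch.
* Constant images threshold to zero cells, not an error; empty stain
  masks count zero; an empty tissue-within-ROI denominator is an error.
* Per-animal densities over multiple stacks pool counts over pooled
  volume by default (mean-of-stacks available in the cohort tables).
* All generators are pure functions of (spec, seed): a single seeded
  Mersenne-Twister stream per call, caller RNG state restored.
* The pipeline writes a JSON manifest with the seed, config checksum and
  per-file MD5s; identical config + seed reproduce byte-identical CSVs.

## Problem sizes used in the validation suite

The shipped tests exercise: 20 full detection runs on 384 x 384 x 64-voxel
stacks with 50 cells each (the densest case that keeps rejection-sampling
placement comfortably below its jamming density); 1024 x 1024 IHC slides
with 100 cells and 10 touching pairs; FISH slides at the 2.08% coverage
level; 2,000 simulated 5-group null cohorts for the familywise error of
the Dunnett implementation; and 200 replicate cohorts at the 65%
programmed depletion level (n = 6/group, CV 10%). A full demo pipeline run
(`run_pipeline(default_config())`) renders 48 stacks (three per animal and
region, pooled into per-animal densities) plus one slide of each kind and
finishes in about 90 seconds on one CPU.

## Known limitations

* The 3D splitter assigns basin boundaries by brightest-neighbour growth
  from h-maxima seeds; on strongly concave merged objects a flooding
  watershed could place boundaries differently (counts and centroids,
  which the pipeline reports, are unaffected).
* EBImage's watershed is used only in 2D; its 3D mode floods across zero
  background and is avoided.
* Stain segmentation assumes two stains plus white background; no support
  for multiplexed chromogens.
* GFP-based and antibody-based densities measure different things in real
  tissue; no cross-calibration between them is attempted.
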