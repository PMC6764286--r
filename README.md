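# gliaquant

Quantification of regional microglia depletion from microscopy images, for
researchers measuring how interventions against CSF1R signalling (ligand-
blocking antibodies, small-molecule inhibitors) remove microglia from
white- vs gray-matter brain regions.

The package implements the full measurement chain such studies rely on:

* **3D two-photon stacks** — cell detection (background subtraction,
  anisotropy-aware smoothing, Otsu threshold, 26-connected labelling,
  h-maxima splitting of touching cells), volumetric density in cells/mm^3
  (`density = n / volume`, volume the product of axis extents at the
  acquisition pitch, default 0.592 um/px in plane and 1.5 um/slice), and
  per-cell mask size in um^3. A 2D variant covers spinal-cord sections
  (cells/mm^2).
* **Chromogenic IHC slides** — tissue and DAB-stain segmentation
  (brightness-invariant chromaticity thresholding), positive-cell counting
  with a minima-controlled watershed that resolves touching cell bodies,
  ROI-normalized densities, and per-cell 8-bit staining-intensity
  histograms in 5-unit bins.
* **FISH slides** — punctate-signal detection (difference-of-Gaussians +
  local maxima) and percent of tissue area stained,
  `100 · |stain ∧ tissue ∧ roi| / |tissue ∧ roi|`.
* **Statistics** — depletion percentage
  `100 · (1 − mean_treated / mean_control)` with delta-method SE; one-way
  ANOVA with Dunnett's many-to-one test (multivariate-t adjustment,
  correlation `λᵢλⱼ`, `λᵢ = √(nᵢ/(nᵢ+n₀))`, pooled df `N − k`);
  Kolmogorov–Smirnov comparison of binned intensity histograms; simple
  concentration–response R²; and LC-MS quantitation via a 1/x-weighted
  quadratic calibration curve with LLOQ-flagged back-calculation.
* **Synthetic data with exact ground truth** — seeded generators for
  stacks, IHC slides, FISH slides, and multi-animal cohorts with
  programmed regional depletion fractions, so every stage is testable
  without any external data.

## Worked example

A small end-to-end study: two groups (control and an anti-CSF1-like
treatment programmed to deplete 65% of microglia in the fimbria and none
in cortex), four animals per group, three synthetic stacks per animal and
region (counts pooled over pooled volume, as per-animal densities are
computed in practice), detection, densities, and the group comparison.
The run takes about 90 s on one CPU.

```r
library(gliaquant)
m <- run_pipeline(default_config(seed = 1), out_dir = "demo")
read.csv("demo/depletion.csv")
#>       group  region n mean_density percent_depletion       se
#> 1 anti-CSF1 fimbria 4     5593.529         60.949868 4.032972
#> 2 anti-CSF1  cortex 4    10355.587          9.570957 7.654754
read.csv("demo/dunnett.csv")[, c("region", "group", "t", "p_adjusted")]
#>    region     group          t   p_adjusted
#> 1 fimbria anti-CSF1 -10.712368 3.907087e-05
#> 2  cortex anti-CSF1  -1.166237 2.877737e-01
```

Reading: in the fimbria the pipeline measured a 60.9% depletion against
the programmed 65% (the density columns are cells/mm^3 measured from the
rendered stacks, not copied from the cohort table — about 36 cells per
treated animal are actually detected and divided by the imaged volume),
significant after Dunnett adjustment; the untouched cortex shows a small
non-significant difference of the size expected from counting noise at
n = 4. The run also writes `cohort.csv`, `image_densities.csv` (per
animal × region, with true vs detected counts), `ihc_counts.csv`,
`fish_area.csv`, and a `run_manifest.json` with the seed, config checksum
and per-file MD5s; re-running the same config and seed reproduces the
CSVs byte for byte.

Individual stages are plain functions, e.g.:

```r
g   <- generate_stack(stack_spec(), seed = 7)       # 50 cells, known truth
det <- detect_cells_3d(preprocess_stack(g$stack))
nrow(det$cells)                                      # 50
compute_density(nrow(det$cells), g$stack)$density_per_mm3
```

A thin command-line wrapper with the same stages is installed as
`exec/gliaquant` (`gliaquant run --config cfg.yaml --seed 1 --out dir`);
a ready-made config ships at `inst/extdata/demo_config.yaml`.

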