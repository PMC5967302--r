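# myoquant

Quantification of myotube morphogenesis, cortical actomyosin enrichment and
membrane mechanics.

Skeletal myotubes form when mononucleated myoblasts fuse into elongated,
multinucleated syncytia, a process shaped by mechanosensitive calcium
signalling and cortical actomyosin. Studies of this process quantify it
through a recurring set of readouts, and this package implements each of
them as tested, reusable R code for anyone analyzing myogenesis or
membrane-mechanics experiments:

* **Morphometry** — per-syncytium nucleus counts, areas and
  best-fit-ellipse aspect ratios from a label mask plus nuclei centroids,
  and the three field-level indices: *fusion index* (% of nuclei in
  multinucleate MyHC⁺ cells with ≥ N nuclei over all MyHC⁺ nuclei; N = 16,
  26 or 50 depending on the culture system), *polarized elongation index*
  (% of MyHC⁺ area in cells with aspect ratio ≥ 3) and *differentiation
  index* (% of nuclei in MyHC⁺ cells over all nuclei in the field).
* **Cortical enrichment** — the cortex/cytoplasm ratio: the cell edge is
  divided into rectangles orthogonal to the periphery, and the score
  averages (peak intensity 0–5 µm from the edge) / (mean intensity 2–7 µm
  from the peak position) over rectangles.
* **Trap mechanics** — passive trap-stiffness calibration by the
  equipartition theorem, k = k_B·T / ⟨x²⟩, with the variance from a
  Gaussian fit to the position histogram; force F = k·Δx; tether
  force-extension curves and a least-squares fit of their first linear
  region.
* **Trace statistics** — Fura2 Δratio (trace maximum minus the value at
  1 min), basal level, relative peak currents, median-intensity time
  courses, positive fractions against a negative-control gate, and
  2^−ΔΔCt fold changes.
* **Synthetic data** — generators with known ground truth for every input
  kind: exact Ornstein–Uhlenbeck trapped-bead tracks, series-spring tether
  pulls, multinucleated-cell fields, cortical-ring images, agonist-response
  traces and bimodal intensity populations.
* **Pipeline** — config-driven orchestration (`validate_config()`,
  `run_pipeline()`) reading/writing TIFF, CSV, YAML and JSON with seed- and
  checksum-tracked manifests.

## Worked example

Calibrate a simulated 10-s, 1000-frames/s trap recording generated at
7.29 pN/µm:

```r
library(myoquant)
trk <- simulate_trapped_bead(stiffness = 7.29, temperature = 296.15,
                             n_frames = 10000, seed = 7)
stiffness_equipartition(trk, temperature = 296.15)
#> Trap calibration (gaussian_fit, 10000 frames, T = 296.15 K)
#>   k_x = 7.062 pN/um (variance 0.000579 um^2)
```

One seed's estimate sits 0.23 pN/µm below the generating value — within the
±0.19 pN/µm single-recording spread of this protocol (and the ±0.50
reported for the real calibration); across 50 seeds the estimator is
unbiased (`analysis/04_trap_mechanics.R` prints mean 7.225 ± 0.185 for the
Gaussian fit, 7.284 ± 0.149 for the direct variance, 50/50 runs within
±0.50).

Morphometry of a synthetic field against its own ground truth:

```r
cfg <- morphometry_config(fusion_nuclei_threshold = 50L, pixel_size = 0.5,
                          myhc_threshold = 55)
fld <- generate_syncytium_field(random_field_cells(seed = 103),
                                pixel_size = 0.5, seed = 103, config = cfg)
analyze_field(fld$label_mask, fld$nuclei, cfg, channel = fld$channel)$summary
#>   fusion_index elongation_index differentiation_index n_syncytia n_nuclei_total
#> 1       73.797           68.646                   100          6            187
```

73.8% of the MyHC⁺ nuclei sit in syncytia with ≥ 50 nuclei, 68.6% of the
MyHC⁺ area is in cells with aspect ratio ≥ 3, and every nucleus lies in a
MyHC⁺ cell — all equal to `fld$truth_summary`, the generator's direct
count.

Cortical enrichment of a synthetic ring cell with 5× cortical contrast:

```r
ci <- generate_cortical_image(image_shape = c(220, 220), pixel_size = 0.5,
                              center = c(52, 52), semi_axes = c(45, 32),
                              orientation = 0.4, cortex_depth = 1.5,
                              cortex_level = 100, interior_level = 20,
                              noise_sd = 1, seed = 45)
cortex_cytoplasm_ratio(ci$image, ci$mask, 0.5)$ratio
#> [1] 5.013
```

## Analysis drivers

`analysis/01_simulate_fixtures.R` … `05_signal_traces.R` are thin numbered
drivers that generate datasets through the pipeline and run each analysis
over them, printing what they find and writing tables under `results/`
(per-field indices vs truth, contrast sweeps, calibration and tether-fit
tables, trace statistics). Run them from the repository root with
`Rscript analysis/01_simulate_fixtures.R`, etc.

## Scope

Masks and centroids are inputs: the package does not segment raw
micrographs, model microscope PSFs, parse cytometer FCS files, or convert
tether force to membrane tension (the latter needs a bending modulus that
the quantification procedures themselves do not define). See the methods
vignette (`vignettes/myotube-quantification-methods.Rmd`) for the models,
conventions, parameter defaults and known limitations.
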