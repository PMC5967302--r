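---
title: "Quantifying myotube morphogenesis, cortical actomyosin and membrane mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myotube morphogenesis, cortical actomyosin and membrane mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoquant)
```

Skeletal myotubes form when mononucleated myoblasts fuse into elongated,
multinucleated syncytia. Studies of this process — and of the
mechanosensitive signalling (PIEZO1, phospholipid flippases, cortical
actomyosin) that shapes it — rely on a small set of quantitative readouts:
field-level morphometric indices from stained cultures, an enrichment score
for peripheral actomyosin, optical-trap measurements of membrane mechanics,
and scalar statistics on calcium, current and cytometry traces. This package
implements each readout as tested code, together with synthetic-data
generators whose ground truth is known by construction, so the whole chain
is verifiable without microscope, trap or cytometer data.

## Morphometric indices

A microscopic field is summarized by per-syncytium records (nucleus count,
area, best-fit-ellipse aspect ratio, MyHC status) and three percentages:

* **Fusion index** — nuclei in multinucleate MyHC+ cells containing at least
  a threshold number of nuclei, over all nuclei in MyHC+ cells. The
  threshold depends on the culture system: 50 for C2C12 myoblasts, 16 for
  human primary myoblasts, 26 for mouse primary myoblasts. It is a
  configuration value, never hard-coded.
* **Polarized elongation index** — the area share of MyHC+ cells whose
  aspect ratio is at least 3.
* **Differentiation index** — nuclei in MyHC+ cells over all nuclei in the
  field.

The *best-fit ellipse* is defined by the second central moments of the
filled region: axes are $4\sqrt{\lambda_i}$ of the pixel-coordinate
covariance (with the standard $+1/12$ pixel-spread term per axis), the
aspect ratio their square-rooted ratio. This is the common image-moments
convention; the published procedure names only a software tool, so the
convention is stated here explicitly. On an ideal filled ellipse the
definition recovers the semi-axis ratio exactly; on rasterized masks the
residual error is a property of the raster, roughly 2% at a 20-pixel minor
axis and under 1% at 40 pixels. Nuclei are assigned to cells by centroid
pixel containment (deterministic for point-centroid inputs); background
centroids are reported as unassigned rather than dropped. Indices are
computed per field; pooling across fields is left to the caller, as the
published analyses report per-field values.

One definitional point is genuinely open: whether the elongation index
should consider every MyHC+ object or only multinucleated ones. The default
is every MyHC+ object — the area-weighted definition already discounts small
mononucleated cells — and `morphometry_config(multinucleated_only = TRUE)`
switches to the stricter reading.

Zero denominators (no MyHC+ nuclei, zero MyHC+ area, zero field nuclei) are
errors, not zeros: a field without MyHC+ material has undefined indices, and
silently returning 0 would bias averages.

## Cortical enrichment score

Peripheral actomyosin accumulation is scored by dividing the cell edge into
rectangles orthogonal to the periphery and reading, in each rectangle's
inward intensity profile, the **peak** intensity within 0–5 µm of the edge
and the **mean** intensity 2–7 µm deeper than the peak position. The score
is the average of peak/mean over rectangles.

The published definition fixes only the two bands. The remaining geometry is
configuration with these defaults: rectangle width 1 µm, anchor spacing
2 µm, profile depth 12 µm (the minimum that contains both bands), step
0.2 µm. Anchors are placed at equal arclength along the outer contour
(holes filled first); inward normals are the gradient of the
Gaussian-regularized Euclidean distance transform, sign-checked by probing
the mask a step inward — on a rasterized disk this points at the centre to
within a few degrees. Profiles use mask-aware bilinear interpolation:
weights of out-of-mask pixels are dropped and renormalized, so a uniform
cell yields an exactly flat profile and a ratio of exactly 1; the peak is
the maximum in-band sample without sub-pixel interpolation, the simplest
reproducible reading of "peak intensity". Rectangles whose bands fall
entirely outside the mask are flagged invalid and excluded; a non-positive
mean excludes the rectangle with a warning count.

The ratio is invariant to multiplicative intensity scaling but **not** to
additive offsets — background subtraction is the caller's responsibility.
On synthetic ring cells the score is monotone in the generator's
cortex/interior contrast and stable to about 2% under re-sampling the
contour from a shifted start point.

## Optical-trap mechanics

A bead in an optical trap sits in a harmonic potential $V_x = k_x x^2 / 2$.
Equipartition assigns $k_BT/2$ per degree of freedom, so the stiffness
follows from the thermal position variance:

$$k_x = \frac{k_B T}{\langle x^2 \rangle}.$$

(The variance enters, i.e. $\langle x^2\rangle$ of mean-centred positions;
writing the denominator as a squared mean would make the estimator diverge
for a centred signal.) The default estimator Gaussian-fits the position
histogram — Freedman–Diaconis binning, nonlinear least squares on bin
centres — because that is how the calibration was specified; the direct
unbiased sample variance is available as `method = "direct_variance"`, the
two agree within 2% on exact Gaussian samples, and the fit falls back to the
direct variance with a warning if it fails to converge. Temperature defaults
to 296.15 K (23 °C); the experiments were at unstated room temperature.
Force is $F = k_x\,\Delta x$ with $\Delta x$ the bead's deviation from its
pre-pull mean (first 0.5 s before stage motion, configurable).

Tether force-extension curves put the controlled quantity — stage
displacement from pull onset — on the x-axis by default; the tether
extension (stage minus bead displacement) is available via
`axis = "tether"`. The *first linear part* is found as the longest prefix
window from pull onset whose ordinary-least-squares $R^2$ reaches `r2_min`
(default 0.98) with at least `min_points` (default 10) samples. The end of
the detected region localizes a changepoint only as sharply as `r2_min`
demands: on a long dense prefix a handful of off-line points barely moves
$R^2$, so noiseless constructions should use a strict threshold (0.999
localizes to one sample in the tests), while noisy data need the looser
default.

Two deliberate limitations: the 1-ms camera exposure blurs positions and
biases the recovered stiffness high by under 4% at the bead's ~2-ms
relaxation time — no blur correction is applied, matching the published
procedure; and the conversion from tether force to membrane tension requires
a bending modulus and is not implemented — the analysis stops at the tether
force/slope, which is what the equations define.

## Trace statistics

* `delta_ratio()` — Fura2 response magnitude: trace maximum minus the value
  at 60 s from imaging start (nearest sample; the 10-s sampling grid puts
  60 s on-grid), non-negative by construction.
* `basal_level()` — mean over a pre-stimulus window, default the first
  60 s; the window is not specified in the published analyses and is
  configuration here.
* `relative_peak_current()` — |peak| of treated over control, the peak
  being the most negative sample for inward currents.
* `median_timecourse()` — per-timepoint population medians, lower-median
  convention for even sizes (integer-stable).
* `fraction_positive()` with `positive_threshold()` — percentage above a
  gate, defaulting to the 99th percentile of a negative-control population
  (standard practice; published histograms show no explicit gate).
* `fold_change_ddct()` — $2^{-\Delta\Delta C_t}$, log2-linear in the target
  Ct.

## Synthetic data: what it emulates and what it does not

Because the study's raw data are not publicly deposited, every analysis is
exercised on generated inputs whose truth is known by construction. The
generators' defaults are the recording conditions of the corresponding
experiments, and they are not tuned per test.

**Trapped bead.** The exact Ornstein–Uhlenbeck discretization
$x_{t+dt} = x_t e^{-dt/\tau} + \mathcal{N}(0,\sigma^2(1 - e^{-2dt/\tau}))$,
$\tau = \gamma/k$, $\sigma^2 = k_BT/k$, has no step-size bias, so the
generated stationary variance equals the equipartition value at any frame
rate. Drag defaults to Stokes' law for the 1.76-µm bead in water at 23 °C
(`stokes_drag()` ≈ 0.0155 pN s/µm, giving τ ≈ 2.1 ms at 7.29 pN/µm) and is
always an explicit parameter. Defaults: 1000 frames/s for 10 s. Camera
motion blur is *not* modelled.

**Tether pull.** The stage moves at 1 µm/s after a 0.5-s dwell (the dwell
gives the baseline window support; zero dwell recovers pure `speed * t`).
The tether is a Hookean spring in series with the trap — a deliberate
stand-in, since the experimental record specifies only the pull speed and
that the first part of the curve is linear; the ground-truth tether
stiffness is retained, and the series-spring slope $k k_t/(k+k_t)$ is the
oracle for the analysis chain.

**Syncytium fields.** Cells are filled ellipses rasterized into a label
mask; nuclei are rejection-sampled inside an eroded copy of each cell so
their containment is unambiguous; the MyHC channel is bright exactly in
MyHC+ cells. Ground truth is computed from the specification by direct
counting, with truth areas taken from the rasterized mask so pipeline
equality is exact integer/pixel arithmetic. The random-field sampler keeps
aspect ratios out of a guard band around the threshold of 3 (so truth
classification is unambiguous under rasterization), keeps minor semi-axes
at 7–10 µm — realistic myotube half-widths that are also well resolved at
the 0.5 µm/px default — and guarantees at least one MyHC+ cell per field,
as a field selected for analysis would have. No point-spread function,
uneven illumination or segmentation errors are modelled: passing tests show
the *indices* are computed correctly from masks and centroids, not that
segmentation of real micrographs would be accurate.

**Cortical cells, traces, populations.** The cortical generator labels
pixels within `cortex_depth` of the edge at one level and the interior at
another, plus optional noise clipped at zero (a detector floor). The Fura2
generator uses a saturating-rise/decay form normalized so its peak equals
the programmed amplitude exactly; with the default plateau (no decay) and
standard timing, the programmed delta-ratio is recovered to machine
precision. Intensity populations are two-component log-normal mixtures with
independent Bernoulli positivity. None of these model spectral bleed,
photobleaching or cytometer compensation.

All randomness flows from one integer seed per generator call; the caller's
RNG state is untouched, and identical (spec, seed) pairs reproduce outputs
bit-for-bit — the property the pipeline's manifest checksums verify.

## Problem sizes used in the tests

The test suite simulates 50 ten-second calibration tracks (10⁴ frames
each), 100 random morphometry fields at 400×400 px, ring cells at
220×220 px, and 10⁵-sample populations and variance checks; these sizes put
Monte-Carlo error comfortably below the assertion tolerances (e.g. the
variance of a 10⁴-frame track at τ ≈ 2 ms estimates stiffness to ±0.19
pN/µm, against the ±0.50 acceptance band) while keeping the whole suite
under a minute of simulation time.

## Worked example

```{r example, eval = FALSE}
# calibrate a simulated 10-s, 1000-frames/s recording
trk <- simulate_trapped_bead(stiffness = 7.29, temperature = 296.15,
                             n_frames = 10000, seed = 7)
stiffness_equipartition(trk, temperature = 296.15)

# morphometry of a random field, against its own ground truth
cfg <- morphometry_config(fusion_nuclei_threshold = 50L, pixel_size = 0.5,
                          myhc_threshold = 55)
fld <- generate_syncytium_field(random_field_cells(seed = 101),
                                pixel_size = 0.5, seed = 101, config = cfg)
analyze_field(fld$label_mask, fld$nuclei, cfg, channel = fld$channel)$summary
fld$truth_summary
```
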