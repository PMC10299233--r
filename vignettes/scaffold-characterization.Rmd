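---
title: "Quantifying freeze-cast scaffold microstructure, alignment and tensile behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying freeze-cast scaffold microstructure, alignment and tensile behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffoldquant)
```

Unidirectional freeze-casting templates a biopolymer suspension with growing
ice lamellae: after freeze-drying, the scaffold carries longitudinally
aligned micro-channels whose transversal cross-sections appear as elongated,
ovoid ("lamellar") pores. For nerve-guidance conduits this anisotropy is the
point — channels guide regenerating axons — so fabrication studies need to
*quantify* it rather than eyeball SEM images. `scaffoldquant` implements the
three quantitative legs of such a characterization, plus the statistical
layer that compares experimental conditions, plus seeded synthetic-data
generators that make every stage testable against known ground truth:

1. **Pore microstructure** from transversal-cut micrographs: binarization,
   connected-component labeling, per-pore geometry, normalized
   distributions.
2. **Micro-channel alignment** from longitudinal-cut micrographs:
   structure-tensor orientation with coherency weighting.
3. **Tensile behaviour** from traction-test logs: stress–strain conversion,
   region segmentation, and extraction of the viscoelastic modulus, maximum
   tensile strength and elongation at break.
4. **Group comparison**: factorial ANOVA with Tukey–Kramer post hoc tests.

A small orchestration layer (`run_pipeline()`) chains the stages over file
inputs, and `verify_ramp()` checks freeze-casting temperature logs against
the nominal ramp-and-hold protocol.

## Pore analysis

A grayscale micrograph (numeric matrix, intensities on an 8-bit scale) is
thresholded by Otsu's method — the threshold actually used is recorded for
audit, and a fixed threshold can be supplied instead — with a polarity flag
because SEM contrast varies between instruments. Connected foreground
regions are labeled under 8-connectivity by default (4 available); the
implementation builds the pixel-adjacency graph and extracts components, and
is output-equivalent to classic two-pass or flood-fill labeling, which the
test suite asserts against a brute-force oracle on hundreds of random masks.

Per pore we report the area (pixel count × squared pixel size), the
axis-aligned bounding box, and the **aspect ratio = bounding-box width /
height** — the raw ratio, deliberately *not* reordered to ≤ 1, so values
below 1 mean pores taller than wide. Components below `min_area_px`
(default 5 px) are dropped and counted; border-touching pores are retained
but flagged, since collapsed peripheral pores are real structures, not
artifacts. Holes inside pore walls are left unfilled. The physical pixel
scale is a required user input: it is never guessed from image metadata.

```{r pores}
pf <- gen_pore_field(pore_field_spec(n_pores = 40, seed = 1))
pores <- analyze_pores(pf$image)
pore_distribution(pores, "area_um2", binning = "log")
```

Pore areas across a section are approximately log-normal, so
`pore_distribution()` supports log-spaced bins (density normalized to unit
integral over the binned axis) and `lognormal_summary()` fits the
distribution and tests goodness of fit (Anderson–Darling on log values —
chosen over Shapiro–Wilk because sections easily exceed 5000 pores).

## Orientation analysis

Within a region of interest (default: full image minus a 3 px border — ROI
choice is explicit user input, as no automatic criterion is defensible),
3×3 Sobel filters estimate the intensity gradient; borders are handled by
reflection. The structure tensor is the Gaussian-smoothed outer product of
the gradient,

$$J = G_\sigma * \begin{pmatrix} g_x^2 & g_x g_y \\ g_x g_y & g_y^2 \end{pmatrix},$$

and the **feature orientation** is the direction of the eigenvector of the
*smaller* eigenvalue — perpendicular to the dominant gradient, i.e. *along*
the channel — mapped to [0, 180)° so that 90° means perfectly vertical
channels and 0°/180° horizontal ones. This 90° offset between gradient and
feature direction is the critical convention; a noise-free vertical-stripe
fixture pins it in the tests. **Coherency**
$(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)$ is 1 for perfectly oriented
texture, 0 for isotropic regions, and defined as 0 where the tensor
vanishes (flat images), so untextured pixels carry zero weight.

Histograms accumulate per-pixel coherency into 1° bins by default (bin
width must divide 180) and are normalized to a probability density **per
degree** (unit integral); this convention is recorded in the output
metadata since "density" could also plausibly mean weight-per-bin. The
tensor window defaults to `window_sigma = 2` px; `sigma = 0` degenerates to
the pointwise tensor whose coherency is 1 wherever the gradient is nonzero
— supported for completeness, discouraged in practice.

```{r orient}
img <- gen_channel_field(channel_field_spec(stripe_angle_deg = 90,
                                            noise_sd = 25, seed = 1))
h <- analyze_orientation(img)
attr(h, "peak_angle_deg")
```

`summarize_alignment()` reports mean ± SD of peak angles across replicates,
optionally grouped by scaffold position (bottom/middle/top). Peaks are
averaged arithmetically, which is appropriate near 90° but would wrap badly
for near-horizontal textures; a circular statistic is a known limitation.

## Mechanics

Traction logs (`time_s`, `displacement_mm`, `force_N`) are converted to
engineering stress–strain: the zero reference is the first sample at which
force reaches the pre-tension weight equivalent (default 3 g at standard
gravity, g = 9.80665 m/s²); displacement *and* force are tared there, which
makes the synthetic round trip exact and books the small pre-tension stress
(≈1.5 kPa on a Ø5 mm specimen) separately. Stress uses the nominal initial
cross-section πd²/4 (no area tracking is possible on hydrated scaffolds in
a submerged rig) and strain is engineering strain on the gauge length,
which must be supplied: the nominal specimen length includes gripped
material and is not a safe default.

Soft-tissue-like curves are J-shaped: a compliant **toe** (fibre
uncrimping), a **linear** elastic region whose slope is the viscoelastic
modulus, a **yield** region (defibrillation) where the slope decays to zero
at the stress peak, then failure. `segment_regions()` finds the linear
region as the contiguous plateau of the local slope: the plateau level is
anchored by a rolling least-squares slope over ~30% of the pre-peak span
(nearly noise-free even at 5% stress noise), and boundaries are where the
pointwise slope leaves a fractional band around it (4% on clean curves,
where Savitzky–Golay derivatives are nearly exact; 12% with a widened
window and dip-tolerant expansion when noise is detected — noise is
estimated from second differences, which ignore smooth curvature). A
straight-line fit over the detected region must reach R² ≥ 0.99 on the
smoothed curve, otherwise the segmentation falls back to the typical fixed
3–6% strain window and flags the result. Failure is the first sample where
stress drops more than 30% (configurable) below its running peak; if it
never does, the last sample is reported as a censored "end of course".

The modulus is the least-squares slope of raw stress versus strain over the
linear region (kPa per unit strain); the strength is the peak stress up to
failure, taken from the smoothed curve when noise is present (the raw
maximum of a noisy plateau is biased upward by roughly two noise standard
deviations) and from the raw curve otherwise, so noise-free inputs recover
the peak to machine precision.

```{r mech}
cv <- gen_stress_strain(curve_spec())
glance(fit_mechanics(cv))[, 1:4]
```

## Statistics

`anova_factorial()` fits factorial ANOVA for any number of factors
(three-way for pore metrics, two-way for mechanics, four-way for viability
readouts are the typical designs) with interactions up to `max_order`.
Unbalanced designs use Type II sums of squares by default (Type I/III
selectable) and the convention is recorded in every result — the choice
matters only when cells are unbalanced, and Type II is the conventional
default when interactions are not the primary question. `tukey_kramer()`
wraps the studentized-range all-pairs comparison with the Kramer unequal-n
correction; stars follow the conventional legend (ns > 0.05, \* < 0.05,
\*\* < 0.01, \*\*\* < 0.001) via `significance_stars()`, a pure threshold
function. The experimental unit is whatever the rows of the input table
are; the package deliberately does not second-guess whether pores or images
are the unit of replication.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of its spec, including the seed, and
carries its ground truth:

* `gen_pore_field()` renders non-overlapping ellipses ("ovoid" pores) with
  log-normal areas and a Gaussian bounding-box aspect-ratio distribution
  (default mean 0.67, spread 0.2 — the magnitudes typical of lamellar
  freeze-cast cross-sections). Non-overlap uses rejection sampling with a
  2 px clearance so 8-connected labeling cannot merge neighbours, bounded
  at 10,000 rejected placements before the packing is declared infeasible.
  The truth table stores analytic ellipse geometry, so the exact foreground
  mask can be re-rasterized (`rasterize_pore_truth()`), and rasterized
  areas differ from analytic areas by at most a perimeter-proportional
  band.
* `gen_channel_field()` renders periodic stripes at a controlled angle with
  a smooth (logistic) edge profile so orientation is well defined at
  sub-degree precision.
* `gen_stress_strain()` builds the J-curve piecewise: the toe is a
  quadratic ramp in slope (stress ∝ strain³) reaching the modulus exactly
  at the toe end; the linear region has slope exactly `modulus_kPa`; the
  yield segment is a cubic Hermite from (linear end, slope E) to (peak,
  UTS, slope 0), which has a monotonically decreasing slope iff its secant
  lies in [E/3, 2E/3] — specs outside that window are rejected with a
  diagnostic rather than silently rendered with a slope bump; an optional
  10% post-peak decline runs to the break strain. Defaults use the
  crosslinked 60/40 collagen/chitosan magnitudes (2499.5 kPa modulus,
  91.8 kPa strength); note those two numbers are incompatible with a linear
  region extending to a full 6% strain, so the default boundaries are
  3/5/6.5/7.5% — inside the "approximately 0–3 / 3–6 / 6–7%" layout.
  `sample_curve_specs()` draws recovery-study parameters (moduli
  500–4000 kPa, strengths 50–150 kPa, noise up to 5% of strength) and
  derives feasible boundaries from each draw.
* `gen_temperature_log()` samples the nominal freeze-casting profile
  (−1 °C/min from 20 °C to −40 °C, 90 min hold, 10 Hz) with optional
  control jitter; the change-point sample belongs to the ramp, so the
  default hold holds exactly 54,000 samples.

None of this is physically realistic SEM texture or ice-crystal physics:
passing tests demonstrate that the *analysis* recovers known structure
under the stated noise models, not that it is robust to charging artifacts,
depth-of-field blur, touching pores, or load-cell drift in real data.

## Numerical choices and limitations

* Convolution uses reflected borders throughout (Sobel, Gaussian window);
  histogram ties resolve to the lowest bin; labels are numbered by first
  occurrence in column-major order, making outputs deterministic.
* Otsu's threshold uses a 256-level histogram over the observed intensity
  range; constant images raise a degenerate-threshold error.
* The problem sizes in the test suite and acceptance script — 20 recovery
  fields of 10–200 pores, 200 recovery curves, 1000 null-ANOVA replicates,
  500 oracle masks — were chosen as the smallest sets whose sampling error
  is well inside the asserted tolerances.
* Wall-thickness measurement, 3-D pore reconstruction, Fourier/wavelet
  directionality, cyclic/relaxation mechanics and mixed-effects models are
  out of scope.
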