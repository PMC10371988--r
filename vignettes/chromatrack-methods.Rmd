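---
title: "Methods and modelling choices in chromatrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in chromatrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromatrack)
```

# Overview

`chromatrack` quantifies facultative, melanin-based colour change in
amphibian larvae and its morphological and physiological correlates. It
covers five analysis stages — spectral background matching, colour-change
kinetics, geometric-morphometric shape comparison, antioxidant-panel
statistics, and Raman pigment identification — plus a synthetic-data
module that can generate every input with known ground truth. This
vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic generators do and do not emulate.

# Spectral background matching

## Preprocessing

Reflectance spectra arrive on the instrument grid (360–740 nm, 1 nm
steps) and are:

1. **Trimmed** to the visible range, 400–700 nm (`lo`, `hi`).
2. **Smoothed** by local quadratic regression (`stats::loess`, degree 2,
   tricube weights, direct evaluation) with `span = 0.75`, i.e. each
   point's fit uses 75% of the points. Because the local model is a
   quadratic, any spectrum that is itself a polynomial of degree ≤ 2 is
   reproduced exactly — the property the test suite asserts. Negative
   smoothed reflectances are clipped to 0.
3. **Binned** into contiguous 15-nm bins, `[400, 415), …, [685, 700]`
   (last bin closed), 20 bins in total; a width that does not tile the
   window exactly is rejected rather than silently producing a partial
   final bin.

Replicate readings (three per specimen, emulating repositioned probe
measurements) are smoothed individually and averaged per specimen *after*
processing, because the downstream analyses operate on one point per
specimen. Whether smoothing precedes or follows replicate averaging is not
observable downstream for linear smoothers at identical grids; smoothing
first is the safer default when replicates have different support.

## Colorimetric indices

Following the standard reflectance-spectrum summaries:

* **B2 (brightness)** — mean reflectance over the trimmed range (%).
* **H1 (hue)** — wavelength of maximum reflectance (nm). Ties go to the
  smallest wavelength.
* **S8 (saturation)** — (max − min)/mean reflectance.

Very dark skins produce flat spectra with no meaningful peak; H1 and S8
are then numerically defined but biologically unreliable. `color_indices`
flags spectra whose spectral contrast falls below `flat_tol = 0.05`
(`flat_flag`), and reports `S8 = NA` when the mean reflectance is zero.
Index regressions (tadpole index on background index) are ordinary least
squares on per-treatment means with the standard overall F test on
(1, n − 2) degrees of freedom, matching a ten-background design's (1, 8).

## Colour space and mismatch

PCA is fitted by SVD on the combined matrix of tadpole specimen means and
background container means — both sets must live in one space for
distances between them to be meaningful. Centring is on; unit-variance
scaling is off, because overall reflectance magnitude (brightness) is the
biologically dominant axis and scaling would destroy it. A deterministic
sign convention (largest-magnitude loading element positive) makes results
reproducible across platforms.

The mismatch statistic is the Euclidean distance between a tadpole and its
own rearing background in the full score space. Since all components are
retained and loadings are orthonormal, this equals the distance between
centred bin vectors; the test suite asserts the identity to machine
precision. The normalized variant first subtracts each spectrum's mean bin
value, leaving only spectral shape — mismatch there isolates hue/saturation
differences.

# Colour-change kinetics

Dorsal brightness over time is summarised as Rec. 709 luma,
$Y = 0.2126R + 0.7152G + 0.0722B$ on channels in [0, 1] (8-bit inputs are
rescaled with a notice). The change model is the three-parameter
quadratic-plateau form

$$y(t) = a + bt + ct^2 \;(t \le x_s), \qquad y(t) = a + b x_s/2 \;(t > x_s),$$

with $c = -b/(2x_s)$ tied so the quadratic joins the plateau with zero
slope; the plateau level is $a + b x_s / 2$ by construction. At fixed
$x_s$ the model is linear in $(a, b)$, so the fitter profiles the residual
sum of squares over $x_s$: an exact two-parameter linear solve inside, a
coarse pass over observed time points, then bounded one-dimensional
refinement. This is global and deterministic — no starting values, no
self-start heuristics — and is verified against a brute-force 0.001-day
grid oracle.

The search is bounded by (second observed time, last observed time]. A
slow transition can genuinely plateau after the experiment ends (the
lightening direction does: breakpoint ≈ 80 days against a 60-day window),
in which case the optimum sits at the boundary and the fit carries
`boundary = TRUE` rather than silently extrapolating;
`allow_extrapolation = TRUE` extends the search to $5\,\max(t)$ when an
out-of-window breakpoint is wanted explicitly. Constant series leave the
join point unidentifiable and are reported with `converged = FALSE`.

# Geometric morphometrics

Configurations are 22 two-dimensional landmarks: 9 fixed points and 13
sliding semilandmarks in two curve chains along the dorsal and ventral
tail-fin margins, anchored at fixed landmarks. I/O is the TPS dialect
(`LM=`, optional `SCALE=`, `ID=`).

**Unbending.** Preserved specimens flex; curvature unrelated to treatment
is removed by fitting $y = q_0 + q_1 x + q_2 x^2$ to user-chosen axis
landmarks, re-expressing every landmark as (arc length along the curve,
signed normal offset) and laying those out on a straight axis. A straight
axis is a fixed point of the operation; a bend-then-unbend round trip
recovers the original to within 2% of centroid size for moderate curvature
(the residual is the second-order difference between a vertical shear and
the arc-length parameterisation).

**GPA.** Iterative centring, scaling to unit centroid size, least-squares
rotation to the consensus (SVD-based, reflections disallowed — landmark
data are consistently oriented), and consensus update until the consensus
change falls below `tol = 1e-8`. With sliding enabled, each outer
iteration slides semilandmarks along their local tangent (central
difference of chain neighbours; endpoints one-sided to their anchor) to
minimise either the thin-plate-spline bending energy against the consensus
(default, the convention of the field's standard toolchain) or the
Procrustes distance. Within an iteration — consensus held fixed — the
slide is an exact quadratic minimisation and can never increase the
criterion, which the tests assert per iteration. Across iterations the
consensus moves, and with the Procrustes-distance criterion semilandmarks
can crawl along their curves indefinitely at a vanishing rate; the loop
therefore also declares convergence when an iteration improves the
criterion by less than 0.1%.

**Procrustes ANOVA.** Specimen-level variance decomposition of the
flattened aligned coordinates: $F = (SS_B/df_B)/(SS_W/df_W)$ with
$df = (g-1, n-g)$ — (1, 8) for two groups of five. Significance is by
residual randomization under the reduced (grand-mean) model: residual rows
are permuted `n_perm` times, F recomputed, and
$p = (1 + \#\{F_\pi \ge F_{obs}\})/(1 + n_\pi)$ with the +1 correction.
The effect size Z is the observed F in standard deviates of the raw
permutation F distribution; toolchains that standardize a transformed
statistic will report different Z for identical data, so F and p are the
portable quantities. Note that with small n, permutations occasionally
reproduce the observed partition exactly; those genuine ties put the
attainable minimum p slightly above $1/(n_\pi + 1)$.

# Antioxidant panel

Enzyme activities (SOD, CAT, GR, GPx) are on heterogeneous assay scales,
so the enzyme PCA is centred **and unit-variance scaled** — unscaled, the
highest-magnitude assay would dominate PC1 regardless of biology. (If
reproducing published values, both settings should be compared, as
published analyses do not always state the choice.) Group differences are
tested with two-tailed Student's (pooled-variance) t-tests on the PC1
scores, on MDA, and on the GSH/GSSG ratio; the pooled form is used
deliberately in place of Welch's, matching the named test.

# Raman pigment identification

Raw spectra over 300–2500 cm⁻¹ carry a smooth fluorescence background.
The baseline estimator is a morphological opening — rolling minimum then
rolling maximum over a ±200 cm⁻¹ window — followed by a rolling mean, with
the signal linearly continued at the edges so truncated windows do not
bias sloped baselines. A plain min-then-mean estimator lags sloped
baselines by roughly its half-width and was rejected for that reason; the
opening tracks any locally-linear baseline exactly while ignoring bands
narrower than the window.

Peak detection lightly smooths the corrected signal (rolling mean, ±5 grid
points), finds local maxima, and thresholds topographic prominence at 5×
a robust noise scale estimated from the median absolute successive
difference (MAD-consistent for white noise). Both the prominence and the
threshold scale linearly with intensity, so calls are invariant to
rescaling.

Pigment calls require **both** strong diagnostic bands within a ±40 cm⁻¹
tolerance: 1380 and 1580 cm⁻¹ (the D/G graphite-like bands) for eumelanin,
1490 and 2000 cm⁻¹ for pheomelanin. The 500 cm⁻¹ band is shared by both
pigments; it is reported when matched but never decides a call, which
prevents cross-calling. The tolerance is a package choice — the source
band positions are approximate — and 40 cm⁻¹ keeps the 1490/1580 pair
separable.

# Synthetic data: what it emulates, and what it does not

The generators state a small, fixed world:

* **Spectra** (`spectra_scenario`): grey backgrounds are flat spectra;
  coloured backgrounds are Gaussian bumps (sd 40 nm) on a 15% pedestal,
  scaled to a target mean reflectance. Tadpoles are achromatic (flat)
  with expected brightness `floor + gain × background B2` — they track
  brightness, not hue, with an attenuated match on light backgrounds.
  Defaults `gain = 0.6`, `floor = 2%` place the perfect-match point at
  B2 = 5%, so mismatch grows monotonically with background brightness
  across the default grey series, the qualitative pattern of the real
  contrast. Replicate noise (sd 1% reflectance, applied as a shared
  per-replicate offset plus per-wavelength jitter) is a realistic
  repositioning error for a contact probe. Real spectra are not flat and
  real noise is wavelength-correlated; a green test here establishes the
  pipeline's arithmetic, not instrument realism.
* **Kinetics** (`kinetics_scenario`): the generative twin of the plateau
  model with defaults at the darkening estimates (a = 0.451, b = −0.057,
  xs = 12.673) on the transplant observation schedule (daily for a week,
  then every 3–4 days to day 60); noise sd 0.02 luma.
* **Shape** (`shape_scenario`): a stylised lateral tadpole template (unit
  body length) with the dark-group effect moving the dorsal fin insertion
  0.04 anteriorly and deepening the anterior fin margin by 0.02;
  digitisation noise sd 0.005. These magnitudes give a between-group F
  near 10 on five-plus-five specimens, the scale of the real contrast. An
  optional quadratic bend emulates specimen flexion.
* **Panel** (`panel_scenario`): normal draws per marker with dark/light
  mean shifts in the observed directions (GPx, CAT up; SOD, GR down;
  MDA slightly down; GSH/GSSG up in dark), truncated at 5% of the mean to
  keep activities positive.
* **Raman** (`raman_scenario`): Gaussian bands on a quadratic baseline
  with white noise; the default band set is the eumelanin profile with
  the 1380/1580 bands at amplitude 100 and the 500 band at 30.

All generators draw from one explicitly seeded generator and restore the
caller's RNG state; a fixed seed gives bit-identical output.

# Numerical notes and limitations

* Binning with a closed last bin gives that bin one extra grid point on a
  1-nm grid; the mean-of-bin-means therefore equals the grand mean only to
  ≈1%, not exactly.
* `optimize()` never returns interval endpoints, so the plateau fitter
  checks the window boundary explicitly before flagging `boundary`.
* The bending-energy linear system carries a 1e-10 ridge for numerical
  stability on near-degenerate reference shapes.
* The permutation Z statistic is distribution-dependent and not
  comparable across toolchains; compare F and p.
* 3D landmarks, allometry correction, receptor-noise visual models,
  quantitative melanin concentration, and acquisition-side processing
  (ROI extraction, white balance, assay calibration) are out of scope.
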