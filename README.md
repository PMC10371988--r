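# chromatrack

Quantitative analysis of facultative, melanin-based colour change in
amphibian larvae — for researchers studying background matching (crypsis)
and its morphological and physiological correlates in tadpoles or similar
aquatic larvae.

Tadpoles reared on backgrounds of different brightness adjust their dorsal
pigmentation to match. `chromatrack` implements the full quantitative
toolchain for such experiments:

* **Spectral background matching** — reflectance-spectrum preprocessing
  (trim to 400–700 nm, loess smoothing at span 0.75, 15-nm binning), the
  colorimetric indices *B2* (brightness, mean reflectance), *H1* (hue,
  wavelength of peak reflectance) and *S8* (saturation,
  (max − min)/mean), PCA colour spaces on raw and mean-zero-normalized
  spectra, and the tadpole–background Euclidean mismatch distance in full
  PC space.
* **Colour-change kinetics** — RGB channel means → Rec. 709 luma
  (0.2126 R + 0.7152 G + 0.0722 B), fitted with the three-parameter
  quadratic-plateau model *y(t) = a + bt − b/(2xₛ) t²* for *t ≤ xₛ*,
  constant *a + b xₛ/2* after, by exact profile least squares over the
  join point *xₛ*.
* **Geometric morphometrics** — TPS landmark I/O, quadratic unbending,
  generalized Procrustes analysis with sliding semilandmarks (bending
  energy or Procrustes distance), shape PCA, and Procrustes ANOVA with
  residual randomization.
* **Antioxidant panel** — PCA of SOD/CAT/GR/GPx activities with
  pooled-variance t-tests on PC1, MDA and the GSH/GSSG ratio.
* **Raman pigment calls** — baseline correction (morphological opening),
  SNR-thresholded peak detection, and eumelanin (1380 & 1580 cm⁻¹) versus
  pheomelanin (1490 & 2000 cm⁻¹) band-signature classification.
* **Synthetic data** — generators for every input with known ground
  truth, so each stage is testable end-to-end without instrument data.

See `vignettes/chromatrack-methods.Rmd` for models, assumptions and
parameter choices.

## Worked example

```r
library(chromatrack)

## spectral background matching on a synthetic grey series
sp <- gen_spectra(spectra_scenario(seed = 1))     # 7 greys x 5 tadpoles x 3 reps
ma <- mismatch_analysis(sp)
ma$model$variance_explained[1]    # 1.000: brightness dominates the raw space
head(ma$mismatch, 3)
#>   specimen_id background_id  distance
#> 1  bg01_tad01          bg01 5.6234496
#> 2  bg01_tad02          bg01 5.8869742
#> 3  bg01_tad03          bg01 0.8715931

## colour-change kinetics (darkening: light tadpole on a black background)
s <- gen_luma_series(kinetics_scenario(seed = 1)) # truth: a=0.451, b=-0.057, xs=12.673
fit_quadratic_plateau(s)
#> Quadratic-plateau fit (n = 23 )
#>   intercept a  = 0.4433 luma
#>   slope b      = -0.0528 luma/day
#>   join point   = 13.182 days
#>   plateau      = 0.0955 luma
#>   rss          = 0.00633

## shape divergence between dark- and light-reared tadpoles
cfgs <- gen_landmarks(shape_scenario(seed = 1))   # 5 + 5 specimens, 22 landmarks
fit <- gpa(cfgs, slide = TRUE)
procrustes_anova(fit, vapply(cfgs, `[[`, "", "group"), n_perm = 1000, seed = 1)
#> Procrustes ANOVA ( 1000 permutations, residual randomization)
#>   F = 9.138, Z = 6.607, Df = 1,8, p = 0.01399

## Raman pigment identification on a dark-skin spectrum
r <- gen_raman(raman_scenario(seed = 1))
classify_pigment(detect_peaks(baseline_correct(r)))
#> Pigment call (tolerance 40 cm^-1):
#>   eumelanin:   TRUE
#>   pheomelanin: FALSE
```

Interpretation: the mismatch distances are in percent-reflectance units of
the binned spectrum space (larger = poorer background match); the plateau
fit says the synthetic tadpole darkened from 0.44 luma to a 0.10-luma
plateau in about 13 days (the generating truth was 0.451 → 0.090 at
12.7 days); the Procrustes ANOVA detects the built-in tail-fin-insertion
shape shift; and the Raman call identifies the eumelanin D/G band
signature while correctly rejecting pheomelanin.

The whole pipeline can also run from one config:

```r
report <- run_study(default_study_config(seed = 1))
names(report)   # stages: spectra, kinetics, morpho, physio, raman
```

or from the command line (see `inst/cli/chromatrack.R`):

```sh
Rscript inst/cli/chromatrack.R simulate --out spectra.csv --seed 1
Rscript inst/cli/chromatrack.R mismatch --in spectra.csv --out mismatch.csv
```

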