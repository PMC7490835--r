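# msdeconv

Deconvolution and compensation of overlap (isobaric) interferences for
quadrupole mass-spectrometric gas analysis.

## What it is for

Field-portable quadrupole mass spectrometers quantify gas species in
environmental samples (groundwater, lakes, soil gas, ...) by **peak-height
comparison**: the ion current at a species' analysis m/z is ratioed against
the same peak measured with a reference gas of known composition. That only
works if the peak belongs to one species — and at many important m/z values
it does not. CH₄ must be analysed via its CH₃⁺ fragment at m/z 15, where
¹⁵N⁺ from N₂ also lands; ²⁰Ne⁺ at m/z 20 overlaps with ⁴⁰Ar⁺⁺ and with
²⁰(H₂O)⁺ from the water that persists in every vacuum system.

msdeconv removes such interferences in three steps:

1. **Deconvolution.** The measured peak-height spectrum *y(μⱼ) ± Δy(μⱼ)*
   (relative errors floored at 1 %) is modelled as a linear combination of
   max-normalised **basis spectra** *xᵢ(μ)* of the species present:

   *ỹ(μⱼ) = Σᵢ aᵢ xᵢ(μⱼ)*,  j = 1…M, i = 1…N, M ≥ N.

   The amplitudes *aᵢ* are estimated by error-weighted least squares,
   minimising χ² = Σⱼ ((ỹ(μⱼ) − y(μⱼ))/Δy(μⱼ))². If the minimised χ²
   exceeds χ²σ — the 68.2689 % quantile of the χ² distribution with M − N
   degrees of freedom — the stated errors were too small and all coefficient
   errors are rescaled by √(χ²/χ²σ).
2. **Compensation.** The fraction *fₜ = aₜxₜ(μₖ)/Σᵢ aᵢxᵢ(μₖ)* of the ion
   current at the analysis m/z that belongs to the target species is
   computed (errors by the delta method from the full coefficient
   covariance), and only *fₜ · y(μₖ)* is kept.
3. **Calibration.** The compensated sample peak is ratioed against the
   (equally compensated) reference-gas peak and scaled by the reference
   amount; all relative errors combine in quadrature.

The package also reads/writes a plain-text raw-readings dialect and the
single-line `DECONVOLUTION:` configuration block, aggregates repeated
PEAK/ZERO readings (with PEAK_DECONV/ZERO_DECONV helper readings that
constrain the fit but never enter calibration), simulates synthetic
readings for validation, and ships a small CLI (`inst/cli/msdeconv.R`).

## Worked example

Trace-level ²⁰Ne in a humid gas (GAS-IV), calibrated against a dry standard
(GAS-III, 326 ppm-vol ²⁰Ne), using the bundled electron-multiplier data:

```r
library(msdeconv)

bases <- read_basis_table(msdeconv_example("basis_spectra_ne_45eV.csv"))
peaks <- read_peak_table(msdeconv_example("peaks_ne_gases.csv"))
block <- deconvolution_block(20, "NE20", bases, detector = "M", ms_ee = 45)

sample   <- run_step(analysis_step(gas_peaks(peaks, "GAS-IV"),  block))
standard <- run_step(analysis_step(gas_peaks(peaks, "GAS-III"), block))

sample$targets[["NE20@20"]]$fractions
#> Ion-current fractions at m/z=20 (modelled total 1.37 nA)
#>  species contribution   fraction dfraction
#>      H2O     787.7 pA     57.49%        1%
#>     NE20     582.3 pA     42.51%        1%
#>       AR     1.735 fA 0.0001266%  2.2e-06%

run_calibration(sample, standard, c(NE20 = 326), units = "ppm")[
  , c("species", "fraction", "value", "dvalue")]
#>   species  fraction    value   dvalue
#> 1    NE20 0.4250655 343.9798 10.47535
```

Only 42.5 % of the m/z 20 current in the humid gas is neon — the rest is
²⁰(H₂O)⁺ and a trace of ⁴⁰Ar⁺⁺. The compensated comparison yields
344 ± 10 ppm, consistent with the 326 ppm actually present, whereas the raw
(uncompensated) ratio would give 597 ppm — almost a factor of two high.
`reproduce_examples()` recomputes all headline quantities of the two bundled
campaigns (CH₄ at m/z 15 on the Faraday cup; ²⁰Ne at m/z 20 on the electron
multiplier) with pass/fail flags, and the CLI exposes the same check as
`msdeconv.R validate`.

## Layout

- `R/` — basis spectra & peak tables (`spectra.R`, `peaks.R`), raw-readings
  dialect and DECONVOLUTION blocks (`readings.R`, `deconv-block.R`), the
  weighted-least-squares engine (`deconv.R`), compensation and calibration
  (`calib.R`), synthetic data (`synth.R`), the step pipeline
  (`pipeline.R`), bundled-example recomputation (`examples.R`).
- `inst/extdata/` — plain-text example data; `inst/cli/msdeconv.R` — CLI.
- `vignettes/interference-deconvolution.Rmd` — model, assumptions, design
  choices and limitations.
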