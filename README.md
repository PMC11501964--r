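# phasorflim

Label-free two-photon microscopy of tissue yields two complementary,
co-registered signals: a 16-channel emission spectrum per pixel (two-photon
excited autofluorescence, TPEF, plus collagen second-harmonic generation,
SHG, at 460 nm under 920 nm excitation) and a TCSPC photon-arrival histogram
per pixel over the 12.5 ns window of an 80 MHz laser. `phasorflim`
implements the full analysis chain used to turn those signals into tumor
pathology readouts — in skin, the delineation of basal cell carcinoma into
invasive (IR), near-invasive (NEIR) and non-invasive (NOIR) regions — and a
synthetic tissue phantom generator with exact ground truth for validating
every stage.

The two core transforms:

* **Spectral phasor.** Each pixel's spectrum `I_k` (k = 0…ω−1, ω = 16) maps
  to coordinates in the unit disk via its first Fourier harmonic,

  ```
  G = Σ I_k cos(2πnk/ω) / Σ I_k      S = Σ I_k sin(2πnk/ω) / Σ I_k
  ```

  Similar spectra cluster; geometric gates drawn in (G, S) segment the image
  without spectral unmixing.

* **Biexponential FLIM.** Each decay is fitted (Poisson-weighted
  Levenberg–Marquardt) with

  ```
  I(t)/I0 = a1 exp(−t/τ1) + a2 exp(−t/τ2)      τ_mean = (a1τ1 + a2τ2)/(a1 + a2)
  ```

  `τ_mean` and the amplitude ratio `a1/a2` are the metabolic readouts.

Around these sit RGB spectral encoding, region spectra with the SHG/TPEF
(Ch2/Ch7) and TPEF spectral (Ch4/Ch7) ratios, rule-based IR/NEIR/NOIR
classification from lifetime, SHG presence and the tumor boundary, per-field
one-way ANOVA + Tukey HSD with the usual star conventions, TIFF+JSON I/O,
20 %-overlap tile stitching, and a reproducible end-to-end pipeline
(`run_pipeline()`). The methods vignette
(`vignettes/phasorflim-methods.Rmd`) documents every model, default and
numerical choice.

## Worked example

Simulate a three-ring tumor phantom, segment it in phasor space, and measure
the invasive region's spectral ratios and lifetime:

```r
library(phasorflim)

channel_center(c(2, 4, 7))
#> [1] 460.0 485.0 522.5

phantom <- make_phantom("three_ring", dim = c(32, 32), seed = 7)
acq <- acquisition_config()
stack <- render_spectral_stack(phantom, acq)

field <- phasor_field(stack)
field
#> <phasor_field> 32 x 32 px, harmonic 1, 1024 valid pixels

labels <- apply_gates(field, phantom_gates(phantom, acq))
labels
#> <label_map> 32 x 32 px: IR=124, NEIR=324, NOIR=576

spectrum <- extract_region_spectrum(stack,
  phantom$label_map == phantom$legend[["NOIR"]])
shg_tpef_ratio(spectrum)      #> 2.406172
tpef_spectral_ratio(spectrum) #> 0.6214046

decays <- render_decay_stack(phantom, acq, channel = 7)
mask <- phantom$label_map == phantom$legend[["IR"]]
fit <- fit_decay(apply(decays$counts, 3, function(p) sum(p[mask])), acq,
                 irf = gaussian_irf(acq$irf_fwhm, acq))
glance(fit)
#> # A tibble: 1 × 5
#>   tau_mean amplitude_ratio chi2_reduced n_photons converged
#>      <dbl>           <dbl>        <dbl>     <dbl> <lgl>
#> 1     1.92           0.400         1.05     72020 TRUE
```

The gated label counts (124/324/576) reproduce the phantom's ground-truth
partition exactly, and the fitted invasive-region `τ_mean` of 1.92 ns
recovers the construction value of 1.9 ns (amplitude split 0.3/0.7 over
0.5/2.5 ns components) from ~7×10⁴ photons. `autoplot()` methods render the
phasor density, lifetime maps and group bar charts; `tidy()`/`glance()`
return tibbles from every fitted object.

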