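---
title: "Methods: spectral phasor and lifetime analysis of two-photon tissue images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral phasor and lifetime analysis of two-photon tissue images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasorflim)
```

## Scope and data model

`phasorflim` analyzes two co-registered measurements of a tissue section
acquired on a spectral- and time-resolved two-photon microscope:

* a **spectral stack** — an H x W x 16 array of photon counts, one band per
  detector channel, with centers 447.5-635 nm in 12.5 nm steps
  (`spectral_channels()`); channel 2 (460 nm) collects second-harmonic
  generation (SHG) from collagen under 920 nm excitation, channel 7
  (522.5 nm) is the maximum of the two-photon excited autofluorescence
  (TPEF, dominated by FAD in skin), and channel 4 (485 nm) is the
  short-wavelength TPEF band;
* a **decay stack** — an H x W x T array of TCSPC photon-arrival histograms
  over the 12.5 ns window set by the 80 MHz excitation repetition rate.

No public tissue dataset accompanies the analysis, so the package ships a
synthetic phantom generator with exact ground truth; every downstream claim
the test suite makes is a recovery statement about these phantoms.

## Spectral phasor transform

Each pixel's emission spectrum $I_k$, $k = 0,\dots,\omega-1$, is projected
onto the $n$-th Fourier harmonic:

$$G = \frac{\sum_k I_k \cos(2\pi n k/\omega)}{\sum_k I_k},\qquad
  S = \frac{\sum_k I_k \sin(2\pi n k/\omega)}{\sum_k I_k}.$$

This is the standard discrete spectral-phasor form on a uniform channel grid;
the default harmonic is $n = 1$. The phase origin is channel 1 — any other
origin (for example the band midpoint) only rotates the phasor plot rigidly,
so nothing downstream depends on the choice, and it is documented rather than
configurable. Three exact properties anchor the tests: $|G + iS| \le 1$ for
any nonnegative spectrum (convex combination of unit vectors), scale
invariance $\mathrm{phasor}(cI) = \mathrm{phasor}(I)$, and mixture linearity —
the phasor of $I_A + I_B$ lies on the segment between the two pure phasors at
fractional position $\sum I_B / (\sum I_A + \sum I_B)$.

Pixels with zero total intensity are masked invalid, never mapped to the
origin: an all-zero pixel carries no spectral information and plotting it at
$(0,0)$ would fabricate a cluster there.

Segmentation uses explicit geometric **gates** (circles or polygons) in
$(G,S)$, mirroring the manual cluster selection practised on phasor plots.
Gates are applied in list order, first match wins; a `strict` mode refuses
overlapping gates instead. Automated clustering is deliberately out of core —
it is an extension point, not part of the validated path.

## Biexponential lifetime fitting

Per-pixel decays follow the two-component model

$$I(t)/I_0 = a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2},\qquad
  \tau_{\mathrm{mean}} = \frac{a_1\tau_1 + a_2\tau_2}{a_1 + a_2},$$

with the short component read as free and the long component as
protein-bound fluorophore. Fitting (`fit_decay()`) is weighted least squares
with Poisson weights $1/\max(y_i, 1)$, solved by Levenberg-Marquardt
(`minpack.lm`). Numerical choices that matter:

* **Parameterization.** The optimizer works in log intensity, logit amplitude
  fraction and bounded lifetimes, so positivity and $a_1 + a_2 = 1$ are
  structural; reported amplitudes are fractions and $\tau_1 \le \tau_2$ is
  imposed by a swap that never changes the modeled curve.
* **Lifetime bounds.** Lifetimes are constrained to
  $[\Delta t,\; 4 T_{\mathrm{window}}]$ ($\Delta t$ = one time bin). A
  component faster than one bin is indistinguishable from a single-bin spike
  and lets the fit absorb one bin's Poisson noise with a spurious "instant"
  component; a component slower than several windows is flat and absorbs
  baseline noise with an unbounded lifetime. Both degeneracies were observed
  on simulated data and both distort $\tau_{\mathrm{mean}}$ badly if allowed.
* **Multi-start.** The weighted least-squares surface holds local minima
  (notably near-monoexponential data). Four documented starts — the
  tail-estimated split, fast-heavy, slow-heavy and near-equal lifetimes — are
  run and the best optimum kept.
* **IRF handling.** When an instrument response kernel is supplied the model
  is the causally convolved biexponential over the full grid. Without one,
  the classic tail fit is used: the origin is placed at the histogram peak,
  located on a 3-bin moving average so one noisy bin cannot steal the true
  first bin, and fitted amplitudes are referred back to $t = 0$ by
  $e^{t_{\mathrm{peak}}/\tau_i}$ (components pinned at the resolution floor
  are unresolvable spikes and get no correction).
* **Quality reporting.** Reduced $\chi^2$ uses $T - 4$ degrees of freedom
  ($I_0$, $a_1$, $\tau_1$, $\tau_2$ free; $a_2$ resolved by the constraint);
  the convergence flag is taken from the optimizer, not assumed. Histograms
  below `min_photons` (default 100) raise a typed error and are masked in
  image fits.

`fit_image()` optionally sums each pixel's neighborhood before fitting
(default radius 1, i.e. 3 x 3, the common TCSPC practice) — a variance/
resolution trade configurable down to pure per-pixel fits.

## Ratio statistics and region rules

Region spectra are channel-wise sums over a mask. Two unitless,
intensity-scale-invariant ratios summarize them: **SHG/TPEF** = Ch2/Ch7
(collagen relative to cellular autofluorescence) and the **TPEF spectral
ratio** = Ch4/Ch7 (spectral blue-shift tracking metabolic state). Zero
denominators yield `NA` with a warning and are excluded from group
statistics; no background subtraction is applied by default, since none is
prescribed for the source workflow.

Tumor regions are labeled by three deterministic rules applied in order:
**IR** (invasive) — inside the tumor boundary with
$\tau_{\mathrm{mean}} \ge$ `tau_threshold_long`; **NOIR** (non-invasive) —
outside the boundary where SHG is present; **NEIR** (near-invasive) — the
remaining pixels with $\tau_{\mathrm{mean}} \le$ `tau_threshold_short`.
The lifetime cuts have no published values and are therefore required,
explicit inputs (the shipped defaults 1.8/1.5 ns are calibrated on the
package's own phantoms and used only in tests and the demo pipeline). "SHG
present" is a configurable intensity quantile on channel 2 (default 0.9),
again because no printed threshold exists. Tumor boundaries are expert-drawn
in practice; the package takes them as a mask input and never infers them.

Group inference (`group_stats()`) is classical one-way ANOVA plus Tukey HSD
via `stats::aov()`/`stats::TukeyHSD()`, with star labels at the conventions
used in the figure annotations (`****` p < 1e-5 down to `ns`; boundary values
demoted). The statistical unit is a field of view, never a pixel: pixels
within a field are spatially and optically correlated, and pixel-level
inference would be pseudo-replicated by orders of magnitude.

## The phantom generator

`make_phantom()` builds a labeled geometry (horizontal bands, concentric
rings, quadrants, or an epidermis/dermis/tumor "bcc" layout) and attaches
per-class fluorophore models: Gaussian emission profiles sampled on the
channel grid, multi-exponential decays, and an expected photon budget per
pixel. SHG is a zero-width spectral line at 460 nm with an effectively
instantaneous (0.01 ns) decay. Rendering draws independent Poisson counts
around the class expectations — photon (shot) noise only; detector dark
counts, afterpulsing, optical blur, depth sectioning, photobleaching and
incomplete-decay wrap-around across the 12.5 ns period are all out of scope.
Every random draw flows from an explicit seed argument; there is no hidden
global state, and rendering is bit-reproducible.

The default class models encode the qualitative contrasts reported between
healthy skin and basal cell carcinoma regions, chosen once as the package's
study conditions: mean lifetime shortest in normal tissue and lower in NEIR
than NOIR/IR ($\tau_{\mathrm{mean}}$ 0.9 / 1.6 / 1.4 / 2.0 ns for
NORMAL/NOIR/NEIR/IR, built from a 0.5/2.5 ns pair with class-specific
amplitude splits); $a_1/a_2$ highest in normal tissue and higher in NEIR than
IR; TPEF spectral ratio decreasing NORMAL > NOIR > NEIR > IR (emission center
red-shifting 505 → 526 nm); SHG/TPEF equal for NORMAL and NOIR and collapsing
through NEIR to IR. Because the reported comparison finds normal tissue and
NOIR statistically indistinguishable in SHG/TPEF, and the generator's only
within-group variability is Poisson noise, the NOIR collagen brightness is
solved numerically at construction so the two *expected* ratios coincide
exactly — any systematic gap, however small, would otherwise be declared
significant at region-aggregate photon counts. The default TPEF budget is
3000 photons/pixel, a realistic per-pixel count for accumulated TCSPC
imaging; decay stacks can be rendered for a single detection channel, in
which case each species contributes its emission share in that channel (the
lifetime channel is Ch 7, which physically excludes SHG).

What passing tests do and do not show: recovery succeeds under Poisson noise
with correct forward models and known boundaries; real tissue adds optical
blur, spectral calibration error, autofluorescence species beyond two
components, and hand-drawn boundaries, none of which the phantoms emulate.

## Pipeline, I/O and stitching

`run_pipeline()` chains simulate → phasor → gates → FLIM → encode → ratios →
regions → statistics for a configured phantom over several fields of view,
writing TIFF artifacts with JSON sidecars, CSV tables, a JSON report and a
log; reruns with equal configurations are byte-identical. Stacks are stored
as multipage 32-bit TIFF scaled into [0, 1] by a power-of-two factor recorded
in the sidecar (integer counts round-trip exactly; the sidecar also records
seeds and a config hash for provenance). Gate circles for the demo are
centered on the analytic class phasors with radii capped below half the
nearest-neighbor distance so spectrally close classes never contend.
`stitch_tiles()` places equal tiles on a regular grid with fractional overlap
(default 0.2) and linear feather blending normalized by accumulated weight,
so constant inputs stitch to the same constant; grid positions are assumed
known (no registration search). The package's interface is its functions —
the pipeline entry point, not a shell wrapper.

## Problem sizes used in the validation suite

The suite exercises: 32 x 32 x 16 stacks against a brute-force per-pixel
phasor oracle (1e-12); 50 x 50 two-emitter phantoms at 1e4 photons/pixel for
gating recovery (>= 99 %); 200 replicate decay fits at 1e5 photons, T = 256
over 12.5 ns, for the <= 5 % median tau_mean contract; a 32 x 32 three-ring
phantom (about 2e4 photons in the lifetime channel) for the >= 99 %
classification contract; and an eight-field, 48 x 48 four-class study for the
end-to-end ordering and Tukey-contrast recovery. These sizes were chosen as
the smallest at which the contracts are comfortably identifiable, keeping the
whole suite at desk scale.

## Known limitations

Two-component decays only; no time-domain (lifetime) phasors; no spectral
unmixing beyond phasor gating; no reading of proprietary TCSPC container
formats (an SDT/PTU reader is an extension point); thresholds for the region
rules must come from the user or a calibration, not from the package.
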