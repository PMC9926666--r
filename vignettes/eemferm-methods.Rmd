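---
title: "Methods: 2D-fluorescence chemometrics for plate-scale fermentation monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 2D-fluorescence chemometrics for plate-scale fermentation monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eemferm)
```

## Scope and model

`eemferm` estimates offline cultivation parameters — glycerol concentration
(g/L), cell dry weight (g/L) and pH — from time-resolved 2D fluorescence
spectra of microtiter-plate batch cultures, with particular attention to
cultures limited in a secondary substrate (Mg²⁺, K⁺ or PO₄³⁻). Each
measurement is an excitation × emission intensity grid (excitation 280–700
nm in 10 nm steps; emission 278–720 nm at 0.45 nm by default) recorded per
well every 30 min. Two conventions for the emission axis circulate for this
instrument class (278–720 nm at 0.45 nm, and 275–725 nm at 0.44 nm); both
are available through `default_grid()`, with the former as the default
because it is the one consistently attached to published spectra of this
kind. Nothing downstream depends on the choice.

The estimator is PLS1 regression fitted with de Jong's SIMPLS algorithm,
implemented from scratch in `simpls()`. On mean-centered `X` (unfolded
spectra) and `y`, weight vectors maximizing covariance with the response are
extracted sequentially; the cross-product vector is deflated against an
orthonormal basis of the x-loadings, which keeps score vectors exactly
orthogonal and makes components nested — the model fitted with `A` latent
variables contains every smaller model, which the LV scan exploits (one fit,
`A` evaluations). Features are mean-centered but **not** variance-scaled:
all features share intensity units, and unit-variance scaling would inflate
noise-floor pixels far from any fluorophore into the same weight class as
genuine signal. One model is fitted per offline parameter. Predictions are
never clipped to physically admissible ranges; a PLS model extrapolating
outside its calibration span legitimately produces, say, negative
concentrations, and hiding that would mask exactly the failure mode the
validation scheme is designed to expose.

## Preprocessing chain

`preprocess_series()` applies five pure steps in a fixed order:

1. **Emission window** (−10 to +270 nm relative to excitation, inclusive):
   removes pixels that carry no Stokes-shifted fluorescence.
2. **Moving average** (25 pixels along the emission axis): noise reduction.
   The pixel count, not a nanometre width, defines the window. At row edges
   the window truncates to the available pixels rather than padding —
   truncation avoids inventing data beyond the grid. The mean is taken over
   unmasked pixels only; masked pixels stay masked.
3. **Downsampling** to 2 nm emission resolution by bin averaging: the output
   axis starts at the first emission wavelength, each output pixel is the
   mean of the valid native pixels in `[center − step/2, center + step/2)`,
   and an output pixel is masked only if all its contributors are. Averaging
   (rather than decimation) is the variance-reducing choice consistent with
   the preceding smoothing step.
4. **Scattered-light masking** (−10 to +13 nm relative to excitation, both
   ends inclusive; applied only in fluorescence-only mode): removes the
   elastic-scattering diagonal so models see fluorophores only.
5. **Referencing** (I − I₀): every spectrum minus the well's first spectrum,
   per pixel. This is deliberately the last step, after downsampling — the
   chain order is fixed and documented because smoothing and downsampling do
   not commute (asserted by a test), so "the same steps in another order" is
   a different method.

Masks only ever grow along the chain, every step is per-well (referencing is
per-well temporal, the rest are per-spectrum), and unfolding flattens the
valid pixels in excitation-major order with an invertible feature index.

## Alignment, validation scheme and LV selection

Offline samples are taken per condition (one well sampled per time point),
so replicate wells share one linearly interpolated offline trace.
Interpolation is exact at sample times and never extrapolates; spectra
outside the sampled span are dropped from response-bearing datasets.

The dual-RMSE scheme builds three datasets per parameter: calibration with
responses interpolated from a *sparse* schedule (6–8 samples at least 5 h
apart — selected from the full table by a deterministic greedy rule that
always keeps the first and last sample and otherwise takes the earliest
sample ≥ gap after the previous choice; the published experiments hand-picked
their points, so any deterministic stand-in is a design choice, and greedy
earliest-first is the simplest reproducible one), calibration with
*full*-schedule responses (identical spectra, only `y` differs), and
prediction on the held-out conditions. `lv_scan()` evaluates four errors per
LV count; `select_n_lv()` picks the first count where the sparse calibration
error still falls while the full calibration error rises (divergence rule,
stated verbally in the source methodology and operationalized here as a
first-index condition on consecutive LV pairs), falling back to the minimum
of the −100% prediction error (ties toward fewer LVs) when the divergence
never occurs — both outcomes are reported with the rule that produced them.
Relative RMSEs are percentages of the measured offline range of the
experiment; the package reports absolute and relative values side by side
because a relative value depends on which range one divides by.

## The synthetic generator

The generator exists so that every pipeline stage is testable without
instrument data. It is a *minimal* mechanism reproducing the qualitative
phases of secondary-substrate-limited batch cultivations, not a fitted model
of any strain:

- **Phase 1** (both glycerol S and secondary substrate M present): Monod
  growth, `mu = mu_max * S/(ks + S)`, with M consumed proportionally to
  growth (`yield_xm` encodes the elemental biomass content of the limited
  substrate: 0.33 gX/mg for Mg, 0.04 for K, 0.02 for PO₄).
- **Phase 2** (M depleted, S remaining): residual growth at a small specific
  rate (0.03 1/h) applied to the biomass present, plus maintenance glycerol
  uptake. A specific (per-biomass) rate was chosen over an absolute linear
  rate because only the former guarantees that a lower supplementation never
  ends with more biomass than a higher one — the ordering property the
  condition ladder must satisfy; on the cultivation time scale the resulting
  accretion still looks linear.
- **Phase 3** (S depleted): all rates stop; pH relaxes back toward its
  initial value at 0.1 1/h — slow, as expected under strong MES buffering.
- **GFP**: accumulates at `gfp_rate * X * k/(k + S)` — promoter derepression
  at low glycerol — modulated in phase 2 by a per-substrate mode: `stall`
  (Mg, K; the signal freezes at limitation onset), `burst` (PO₄; a final
  amplified increase), or `continue`.
- **pH**: `ph0 − 0.09 · (X − x0)` while glycerol lasts (ammonium uptake
  against the buffer), then the phase-3 recovery. With `ph0 = 6.0` and the
  default yields this puts the pH minimum near 5.46 over a ~0.5 unit range.
- **OTR**: `yos · qS · 1000/92.09` mmol/L/h with `yos` in mol O₂ per mol
  glycerol (92.09 g/mol) and `qS` the instantaneous glycerol consumption
  rate.

Integration uses `deSolve::lsoda` piecewise with root-triggered phase
transitions (the depleting pool is clamped to exactly zero at the root), so
mass balances close to integrator tolerance (1e-10) rather than to a step
size; a state more negative than 1e-6 aborts.

Defaults are the study conditions and were chosen once: initial glycerol 12
g/L (the measured ranges in such experiments are ≈12 g/L), `x0` 0.03 g/L
with 0.06 and 0.11 g/L variants for the fully supplemented magnesium
condition, `mu_max = 0.24` 1/h and `yos = 1.3` calibrated once so the fully
supplemented magnesium culture peaks near 34.5 mmol/L/h OTR at about 22.3 h,
and condition ladders exactly mirroring the published supplementation tables
(full concentrations 295.8, 2017.3 and 697.9 mg/L for Mg, K and PO₄; the
`media_design()` rounding convention — half-up, two decimals below 10 mg/L,
one above — reproduces every printed value). Offline measurement noise
follows stated analytical precisions: glycerol CV 0.2% (HPLC), CDW CV 3%,
pH sd 0.02.

Spectra are sums of separable Gaussian fluorophore peaks — GFP under the
420/530 nm readout pixel, NADH at 340/450 tracking actively growing biomass,
flavins at 450/530 tracking total biomass — plus a scattered-light ridge
along the diagonal whose amplitude saturates in biomass
(`a_sat · X/(K_x + X)`, `K_x = 15` g/L, so it is mildly nonlinear over the
0–6 g/L range, as a real scatter signal is), a flat baseline, and
heteroscedastic noise `N(0, 2 + 0.01·signal)` clipped at zero. The true
spectral shapes of any real strain and medium are unknown; only the channel
positions (420/530 for GFP, 600/600 for scatter) are anchored, the widths
are configuration. Headspace pO₂ traces are generated per well from the
simulated OTR through the inverted stop-flow balance (10 min sealed
measuring phases, 2.4 mL gas over 0.8 mL liquid at 30 °C), so
`otr_from_po2()` recovers the OTR peak from its own generator's traces —
a consistency check, not an independent validation.

What passing tests on this generator do **not** show: robustness to
inner-filter effects, Raman scattering, well-to-well optical variation,
fluorophores the library omits, non-Gaussian peak shapes, or real
instrument drift. They do show that the chain of windowing, smoothing,
downsampling, masking, referencing, alignment, SIMPLS, the dual-RMSE LV
selection and the reporting are implemented correctly and interact as
specified.

## Oxygen transfer

`stern_volmer_po2()` inverts optode quenching, `pO2 = (I0/I − 1)/Ksv`,
clamping small noise-induced negatives at zero with a warning.
`otr_from_po2()` applies an ideal-gas stop-flow headspace balance,
`OTR = −(dpO2/dt) · Vg/(Vl · R · T)`, with the decline slope estimated by
ordinary least squares over a window of points centered on each sealed
measuring phase, one OTR value per phase midpoint. The original
instrumentation literature defines its own balance; this implementation is a
standard, clearly-specified variant of the same idea (internal unit: bar;
% air saturation converts via 0.2095 bar O₂ at 1 atm), adequate for the
simulated traces this package produces and for any trace with marked
measuring/flushing phases.

## Numerical choices and degenerate inputs

- SIMPLS refuses `ncomp > n − 1` and reports the usable maximum when the
  deflated covariance collapses (rank deficiency); zero-variance responses
  are an error, not a NaN.
- PCA (via SVD) fixes signs so each loading's largest-magnitude element is
  positive; explained-variance ratios are taken against total variance.
- Sparse-schedule selection fails loudly (naming the achievable count) when
  the span cannot support six samples at the required gap.
- Band endpoints (emission window, scatter band) are inclusive on both ends.
- CSV round trips write doubles with `%.17g`, so written and re-read spectra
  are bit-identical.
- The 25-pixel smoothing window is sometimes quoted with a nanometre
  equivalent that does not match 25 × 0.45 nm; the pixel count is taken as
  authoritative.

## Problem sizes

The default magnesium plate — 8 conditions + blanks, duplicate wells, 61
spectra per well on the full 43 × 983 grid — runs through the complete
pipeline (both spectral variants, three parameters, LV scan to 10) in about
a minute. The test suite uses the same condition ladders on a coarse
spectral grid (7 × 69) for whole-plate properties and the full grid where
the spectral axes themselves are under test; property tests over random
matrices use 50–60 seeds. These sizes are the package's own choice of a
thorough-but-quick default; every size is a parameter.

## Known limitations

- No cross-validation, wavelength selection (interval PLS, evolutionary
  selectors) or nonlinear regressors; the LV scan against a dual reference
  is the only complexity control, by design.
- No inner-filter or Raman correction; the scatter band is masked, not
  modelled.
- The sparse-schedule generator is a deterministic stand-in for hand-picked
  sampling plans.
- The kinetic mechanism is qualitative; its parameters are plausibility
  anchors, not estimates, and transferability numbers obtained on synthetic
  plates say nothing quantitative about any real instrument.
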