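---
title: "Modelling wavelength-controlled pharmacology with chromoswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling wavelength-controlled pharmacology with chromoswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoswitch)
```

## The problem

Azobenzene photopharmaceuticals are applied as E/Z mixtures whose composition
is set by light. A classical *affinity switch* has one binding isomer, so its
bioactivity tracks the absolute concentration of that isomer — and therefore
varies with every inhomogeneity in compound delivery. An *ideal efficacy
switch* instead has two isomers that bind competitively with similar
affinity but opposing intrinsic efficacy (agonist vs inverse agonist, or
agonist vs silent binder). Once the receptor population is saturated by the
mixture, the only remaining control variable is the E/Z ratio, which the
illumination wavelength sets through the photostationary state (PSS). This
package provides a quantitative, testable model of that design principle and
the inference tools to recognise it in data.

## Photochemistry layer

Two-state kinetics under monochromatic flux:

$$\frac{df_Z}{dt} = k_{EZ}(1-f_Z) - (k_{ZE}+k_{th})f_Z, \qquad
k_{ij} = 0.23026\,\varepsilon_i(\lambda)\,\Phi_{ij}\,I$$

with $\varepsilon$ in M$^{-1}$cm$^{-1}$ and $I$ in mol photons
m$^{-2}$s$^{-1}$; the constant $1000\ln(10)\times10^{-4}$ converts molar
absorptivity and molar photon flux to a per-molecule excitation rate. The PSS
is $\varphi_\lambda = k_{EZ}/(k_{EZ}+k_{ZE}+k_{th})$, which for a bistable
switch ($k_{th}=0$, the default — the compounds modelled have stable
bidirectional PSSs) reduces to a flux-independent ratio of
absorptivity-weighted quantum yields.

Assumptions, each a deliberate design choice:

* **Monochromatic light.** LED bandwidth is ignored by default; a top-hat
  average over a finite bandwidth is available via the `bandwidth` argument
  of `eps_at()`/`compute_pss()` but off by default, since the
  electrophysiology experiments this emulates use narrow-band monochromated
  light.
* **Optically thin sample.** No inner-filter or depth attenuation; tissue
  optics are out of scope.
* **Piecewise-analytic propagation.** Each protocol segment relaxes
  exponentially toward its PSS at $k_{obs}$; `simulate_isomerization()`
  evaluates that closed form rather than calling an ODE solver, so traces
  are exact to machine precision and the sampling density
  (`samples_per_segment`, default 200) affects reporting only. Numerical ODE
  integration appears solely as an independent oracle in the test suite.

## Pharmacology layer

Occupancy is Gaddum competitive binding of the two isomers with free ligand
approximated by total ligand (nanomolar compound vs femtomolar receptor).
Binding equilibration is treated as instantaneous relative to photoswitching
and readout, consistent with second-scale fully reversible cycling.

Effect is produced in two stages. The stimulus

$$S = b\,\rho_{free} + \max(b+e_Z,0)\,\rho_Z + \max(b+e_E,0)\,\rho_E$$

encodes constitutive tone $b$ and signed intrinsic efficacies $e$;
inverse agonism ($e<0$) suppresses the tone of occupied receptors and is
clamped at zero stimulus because no quantitative model of deeper suppression
is available. The operational (Black–Leff) transduction
$E^* = (\tau S)^n/((\tau S)^n+1)$ then creates receptor reserve.

Key parameters and defaults:

| parameter | default | units | rationale |
|---|---|---|---|
| `tau` | 10 | – | enough reserve that plateau responses are dose independent over well beyond 100-fold |
| `hill_n` | 1 | – | with $n=1$ the concentration–effect curve is exactly a four-parameter logistic, making Hill-fit round trips exact |
| `basal` | 0.04 | fraction of max stimulus | chosen so that the E isomer's inverse agonism approximately cancels residual-Z agonism at the off-PSS, reproducing the observed near-complete return to baseline under 440-nm light |
| `eff_E` | −0.3 (presets) | – | inverse agonism of the E isomers is reported only qualitatively; the magnitude is a package convention and is flagged as such |
| occupancy criterion | 0.83 | fraction | the smallest integer kd-multiple satisfying $m/(m+1)\ge 0.83$ is 5, encoding the conventional "plateau from ~5 × EC50" rule |

**Potency pinning.** The bundled presets (`trpc4_azpico` 3.0 nM,
`trpc5_azpico` 4.0 nM, `trpc5_azhc` 6.4 nM) pin the published potencies to
the *response* EC50 at the 365-nm PSS. With receptor reserve the response
EC50 sits well below the dissociation constant; the presets therefore carry
kd ≈ 23 nM (for the 3.0 nM preset) rather than kd = 3 nM. Pinning kd
directly would contradict the published half-maximal concentrations, which
are response-level measurements; `response_ec50()` exposes the analytic
mapping (exact because stimulus is linear in a Langmuir total occupancy).

**Classification.** `classify_switch()` applies fixed conventions: affinity
ratio ≤ 3 counts as "very similar affinity", |efficacy| < 0.05 as a silent
binder, ratio > 10 as an affinity switch, and potency must clear a 50 nM
response-EC50 ceiling for the ideal label. These thresholds are package
conventions encoding qualitative published criteria, not measured constants.

## Action-spectrum models and inference

The two rival readings of a bioactivity-vs-wavelength spectrum are linear
models in transformed $\varphi_\lambda$: efficacy
$a + b(-\log_{10}\frac{\varphi}{1-\varphi})$ versus affinity
$a + b(-\log_{10}(\varphi c))$. Both have the same parameter count, so the
AIC comparison in `compare_action_models()` (Gaussian residuals,
$n\log(RSS/n)+2k$) is driven purely by fit quality; ties are declared below
ΔAIC = 2. The decisive experimental design is the two-concentration joint
fit: the affinity model predicts a $b\log_{10}2$ shift on dose doubling, the
efficacy model none. PSS values of exactly 0 or 1 are clamped to $10^{-6}$
with a warning, as physical photostationary states are never pure.

`hill_fit()` uses Levenberg–Marquardt (`minpack.lm`) on a log-EC50
parameterisation with seven log-spaced EC50 starts spanning the
concentration range, keeping the best converged fit; falling curves are
fitted with the mirrored logistic so the `top >= bottom` convention always
holds. Flat data and designs with fewer than five concentrations or under
two decades of span are rejected with diagnostics rather than fitted.

## What the synthetic generator emulates — and what it does not

`make_calibrated_spectra()` builds Gaussian-band absorption spectra
(wavelength domain, for simplicity) with the E isomer's strong π→π* band
near 348 nm and weak n→π* band near 440 nm, and solves the Z band amplitudes
*linearly* from PSS anchors — by default 95% Z at 360 nm and 82% E at
410 nm. Quantum yields default to Φ_EZ = 0.30, Φ_ZE = 0.45, typical of
bidirectional azobenzenes; since only the products εΦ enter the PSS, the
calibration compensates for any plausible quantum-yield choice. The result
is a synthetic stand-in with the published *switching behaviour*, not a
digitization of a measured compound spectrum. The default photon flux
(7×10⁻⁴ mol m⁻² s⁻¹) is a convention giving k_obs ≈ 1 s⁻¹ at 360 nm,
matching second-scale switching; absolute rig fluences are rarely reported.

Dose–response sets use a 12-point log ladder from 12 pM to 1.6 µM with
multiplicative lognormal noise (sd 5%, mean-unbiased) mirroring plate-reader
character; action spectra use additive Gaussian noise scaled to the
spectrum's dynamic range; every stochastic generator demands an explicit
seed and stores its clean ground truth for recovery scoring.

Passing tests on these data show that the *model pipeline* is correct and
that the inference machinery recovers known generating parameters. They do
not show that real FLIPR plates or patch-clamp recordings satisfy the
model's assumptions: real data add photobleaching, compound degradation,
plate-geometry artifacts, heteromeric channel populations and
non-multiplicative noise, none of which are simulated.

## Numerical choices and degenerate inputs

* Cycle statistics take per-cycle extrema within segment windows (peak from
  the high phase, trough from the low phase) so that the approach transient
  of the very first cycle does not contaminate its trough; the fatigue slope
  is reported as a fraction of the first-cycle fitted amplitude per cycle,
  making a programmed geometric 2%-per-cycle decay read out as ≈ −0.02.
* A single cycle has amplitude CV 0 by convention and an undefined (NA)
  fatigue slope.
* Dark segments with $k_{th}=0$ freeze the composition; `compute_pss()` with
  zero flux and no thermal pathway raises an undefined-steady-state error
  instead of returning an arbitrary value.
* The first-order (FLIPR-like, default lag 2 s) readout filter uses an exact
  exponential-integrator step against the trapezoidal mean of the input, so
  plateau values are unbiased and only sub-sample transition timing is
  approximate.
* Spectral calibration refuses (with residuals reported) rather than
  returning a best-effort spectrum when anchors are not representable by
  smooth bands to within 0.005 absolute in φ, or would require negative band
  amplitudes.

## Scope of the acceptance computations

The bundled `scripts/acceptance.R` evaluates the dose-independence fold
range on a 41-point concentration grid spanning four decades above the
saturation threshold, and cycling reproducibility over 36 cycles with
segments of 10/k_obs at 200 samples per segment — sizes chosen so the whole
script completes in about a second while leaving the reported quantities
grid-converged (the plateau variation bound is monotone in window width, and
segment plateaus are converged to well below 0.1%).

## Known limitations

* Single competitive site: the tetrameric architecture of the target
  channels (four binding sites) is not modelled; no subunit-occupancy gating
  data exist to parameterise it.
* The inverse-agonist magnitude (−0.3) and basal tone (0.04) are coupled
  conventions; only their combination is constrained by the observed
  return-to-baseline behaviour.
* With the anchored PSS values, photodeactivation at 400–420 nm is partial
  in this model (residual Z of 10–35% still agonises through the receptor
  reserve); near-complete deactivation requires the 430–480 nm window where
  residual Z falls to a few percent. Observed action spectra reporting full
  deactivation from 400 nm upward are steeper than this single-site model
  predicts at those intermediate wavelengths.
* No downstream tissue dynamics (oscillators, contractility) and no
  instrument vendor formats.
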