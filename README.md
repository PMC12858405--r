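# chromoswitch

Modelling toolkit for **ideal efficacy photoswitches** — photopharmacological
reagents whose E and Z isomers bind a receptor competitively with similar
affinity but opposing intrinsic efficacy, so that bioactivity is set purely by
the illumination wavelength ("chromocontrol") and not by the applied
concentration. The package is aimed at photopharmacologists and receptor
modellers who want to reason quantitatively about photostationary states,
wavelength-controlled dose–response surfaces, and how to tell an efficacy
switch from a classical affinity switch.

## The model

Three layers are composed:

1. **Photochemistry.** Two-state E⇌Z photoisomerization under monochromatic
   flux *I* with per-isomer absorptivities ε(λ) and quantum yields Φ:

       dfZ/dt = k_EZ (1 − fZ) − (k_ZE + k_th) fZ,
       k_EZ ∝ ε_E(λ) Φ_EZ I,   k_ZE ∝ ε_Z(λ) Φ_ZE I

   The photostationary state (PSS) is φ_λ = k_EZ / (k_EZ + k_ZE + k_th); for
   a bistable switch (k_th = 0) it is flux independent. Illumination
   protocols are propagated piecewise-analytically (exponential relaxation at
   k_obs = k_EZ + k_ZE + k_th per segment).

2. **Pharmacology.** Gaddum competitive occupancy of the two isomers at total
   concentration c split as (fZ, 1 − fZ), a stimulus
   S = basal·ρ_free + max(basal + eff_Z, 0)·ρ_Z + max(basal + eff_E, 0)·ρ_E
   (signed efficacies; inverse agonism suppresses constitutive tone), and a
   Black–Leff operational transduction E\* = (τS)ⁿ/((τS)ⁿ + 1) that creates
   receptor reserve. Above a saturation threshold (total occupancy ≥ 0.83,
   i.e. c ≳ 5 × EC50) the plateau effect depends only on φ_λ — the formal
   basis of concentration-independent chromocontrol.

3. **Instruments & inference.** Virtual cycling/wavelength-scan experiments
   with instantaneous (electrophysiology-like) or first-order-lagged
   (FLIPR-like) readouts; four-parameter logistic (Hill) fitting with
   multi-start Levenberg–Marquardt; and AIC comparison of the two rival
   action-spectrum models — efficacy (bioactivity ∝ −log₁₀([Z]/[E]),
   concentration invariant) versus affinity (bioactivity ∝ −log₁₀([Z]),
   shifts by b·log₁₀ r when the dose is scaled by r).

A seeded synthetic-data module generates isomer spectra calibrated to
published PSS anchors (95% Z at 360 nm, 82% E at 410 nm), dose–response
ladders, action spectra and cycling traces, always carrying their ground
truth for parameter-recovery scoring.

## Worked example

```r
library(chromoswitch)

spectra <- default_spectra()          # calibrated to the PSS anchors
phot    <- default_photophysics()
pharm   <- pharm_preset("trpc4_azpico")

compute_pss(spectra, phot, 360)       # 0.95   (95% Z: photoswitched on)
compute_pss(spectra, phot, 410)       # 0.18   (82% E: photoswitched off)

# potency at the 365-nm PSS, refit from the simulated dose-response curve
hill_fit(dose_response(pharm, compute_pss(spectra, phot, 365),
                       default_c_grid()))
#> <hill_fit> EC50 = 3e-09 M, n = 1.000 (rising), plateaus [0.286, 0.907]

# wavelength rheostat at a saturating 23 uM dose: strong on / weak on / off
c_sat <- 1e3 * pharm$kd_Z
sapply(c(360, 385, 440), function(l)
  chromo_response(c_sat, compute_pss(spectra, phot, l), pharm))
#> 0.908 0.879 0.296      (drug-free baseline: 0.286)

independence_threshold(pharm)$multiple   # 5  (plateau from ~5 x EC50)

# 36 deterministic 360/440-nm cycles: no fatigue
cycle_stats(make_cycle_trace(n_cycles = 36L))
#> <cycle_stats> 36 cycles: mean amplitude 0.4771, CV 1.11e-07,
#>               fatigue 3.00e-09/cycle
```

The EC50 of 3.0 nM is the pinned potency of the TRPC4/AzPico preset; the
plateau triplet shows wavelength-set activation levels that are independent
of dose above the ~5 × EC50 threshold; and the cycling statistics confirm the
two-state model photoswitches indefinitely without amplitude rundown.

A thin CLI wrapper is installed under `inst/cli/chromoswitch`
(subcommands `pss`, `simulate`, `fit`, `classify`, `actionspec`, `synth`).

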