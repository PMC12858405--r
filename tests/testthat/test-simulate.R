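sp <- fixture_spectra()
phot <- fixture_phot()
pharm <- pharm_preset("trpc4_azpico")

cycling_fixture <- function(n_cycles = 3L, c_tot = 10e-9, ...) {
  k_on <- switching_rate(sp, phot, 360)
  k_off <- switching_rate(sp, phot, 440)
  prot <- cycling_protocol(360, 440, n_cycles, default_flux(),
                           duration_on = 10 / k_on,
                           duration_off = 10 / k_off)
  list(protocol = prot,
       trace = run_experiment(prot, sp, phot, pharm, c_tot, ...))
}

test_that("cycling produces alternating plateaus with troughs at baseline", {
  fx <- cycling_fixture()
  tr <- fx$trace
  base <- baseline_response(pharm)
  seg_end <- vapply(seq_len(nrow(fx$protocol)), function(s)
    tail(tr$effect[tr$segment_id == s], 1), numeric(1))
  highs <- seg_end[c(1, 3, 5)]
  lows <- seg_end[c(2, 4, 6)]
  expect_true(all(highs > base + 0.3))
  # photoswitching off returns within 2% of the drug-free baseline
  expect_true(all(abs(lows - base) < 0.02))
})

test_that("zero-compound control is flat under any illumination", {
  fx <- cycling_fixture(c_tot = 0)
  expect_equal(fx$trace$effect, rep(baseline_response(pharm),
                                    nrow(fx$trace)), tolerance = 1e-12)
})

test_that("traces are continuous across segment boundaries and reach plateaus", {
  fx <- cycling_fixture()
  tr <- fx$trace
  # continuity: no sample-to-sample jump exceeds the within-segment scale
  expect_lt(max(abs(diff(tr$fz))), 0.05)
  # segments of length >= 7/k_obs end within 0.1% of the segment PSS plateau
  phi360 <- compute_pss(sp, phot, 360)
  phi440 <- compute_pss(sp, phot, 440)
  ends <- vapply(seq_len(6), function(s) tail(tr$fz[tr$segment_id == s], 1),
                 numeric(1))
  expect_true(all(abs(ends[c(1, 3, 5)] - phi360) < 1e-3 * phi360))
  expect_true(all(abs(ends[c(2, 4, 6)] - phi440) < 1e-3))
})

test_that("runs are deterministic: identical seeds give identical traces", {
  ro <- readout_model(noise_sd = 0.05)
  fx1 <- cycling_fixture(readout = ro, seed = 7L)
  fx2 <- cycling_fixture(readout = ro, seed = 7L)
  expect_identical(fx1$trace, fx2$trace)
  fx3 <- cycling_fixture(readout = ro, seed = 8L)
  expect_false(identical(fx1$trace$effect, fx3$trace$effect))
  expect_error(cycling_fixture(readout = ro), "seed")
})

test_that("first-order lagged readout matches the analytic RC-filter response", {
  # near-instantaneous photoswitching turns the effect into a square step;
  # the lagged reporter must then follow 1 - exp(-t/tau) exactly
  k_on <- switching_rate(sp, phot, 360, flux = 1)  # very fast switching
  prot <- illumination_protocol(c(440, 360), flux = 1,
                                duration = c(2, 10))
  tau <- 2
  tr <- run_experiment(prot, sp, phot, pharm, 1e-6,
                       readout = readout_model("first_order_lag",
                                               lag_tau = tau),
                       fz0 = compute_pss(sp, phot, 440, flux = 1),
                       samples_per_segment = 2000L)
  inst <- run_experiment(prot, sp, phot, pharm, 1e-6, fz0 = tr$fz[1],
                         samples_per_segment = 2000L)
  e0 <- inst$effect[1]
  e1 <- tail(inst$effect, 1)
  idx <- tr$segment_id == 2
  t2 <- tr$time_s[idx] - 2
  analytic <- e1 + (e0 - e1) * exp(-t2 / tau)
  expect_equal(tr$effect[idx], analytic, tolerance = 0.01)
  # lagged readout attenuates: partway through the step it lags the true effect
  mid <- which(idx)[50]
  expect_lt(tr$effect[mid], inst$effect[mid])
})

test_that("36-cycle reproducibility: constant amplitude, no fatigue", {
  fx <- cycling_fixture(n_cycles = 36L)
  cs <- cycle_stats(fx$trace, fx$protocol)
  expect_identical(cs$n_cycles, 36L)
  expect_lt(cs$amplitude_cv, 0.01)
  expect_lt(abs(cs$fatigue_slope), 1e-3)
  expect_gt(cs$reversibility, 0.97)
})

test_that("cycle statistics conventions and error checks", {
  fx <- cycling_fixture(n_cycles = 1L)
  cs <- cycle_stats(fx$trace, fx$protocol)
  expect_identical(cs$amplitude_cv, 0)
  other <- cycling_protocol(360, 440, 4, default_flux(), 5)
  expect_error(cycle_stats(fx$trace, other), "misalignment")
})

test_that("programmed per-cycle fatigue is recovered by the estimator", {
  tr <- make_cycle_trace(n_cycles = 12L, fatigue_per_cycle = 0.02)
  cs <- cycle_stats(tr)
  expect_equal(cs$fatigue_slope, -0.02, tolerance = 0.1)
})

test_that("wavelength scans localise the on and off bands as published", {
  lam_on <- seq(330, 430, by = 10)
  scan_on <- wavelength_scan(lam_on, 440, sp, phot, pharm, 10e-9,
                             mode = "on")
  best_on <- scan_on$wavelength_nm[which.max(scan_on$bioactivity)]
  expect_gte(best_on, 340)
  expect_lte(best_on, 370)
  # the full 340-370 band activates within 5% of the best plateau
  in_band <- scan_on$wavelength_nm >= 340 & scan_on$wavelength_nm <= 370
  expect_true(all(scan_on$bioactivity[in_band] >
                    max(scan_on$bioactivity) - 0.05))
  lam_off <- seq(380, 500, by = 10)
  scan_off <- wavelength_scan(lam_off, 360, sp, phot, pharm, 10e-9,
                              mode = "off")
  best_off <- scan_off$wavelength_nm[which.min(scan_off$bioactivity)]
  expect_gte(best_off, 400)
  expect_lte(best_off, 480)
  # deactivation deepens across 380-440 and is near-complete around the best
  # off wavelengths, where the residual Z fraction is a few percent
  base <- baseline_response(pharm)
  deep <- scan_off$wavelength_nm >= 430 & scan_off$wavelength_nm <= 480
  expect_true(all(abs(scan_off$bioactivity[deep] - base) < 0.04))
  shallow <- scan_off$bioactivity[scan_off$wavelength_nm == 380]
  expect_gt(shallow, max(scan_off$bioactivity[deep]) + 0.1)
})

test_that("identical scan and counter wavelengths give equal plateaus", {
  s <- wavelength_scan(360, 360, sp, phot, pharm, 10e-9, mode = "off")
  phi <- compute_pss(sp, phot, 360)
  expect_equal(s$bioactivity, chromo_response(10e-9, phi, pharm),
               tolerance = 1e-3)
})

test_that("dose-wavelength surface separates efficacy from affinity behaviour", {
  lam <- seq(340, 480, by = 20)
  c_min <- independence_threshold(pharm)$c_min
  cs <- exp(seq(log(c_min), log(100 * c_min), length.out = 9))
  surf <- dose_wavelength_surface(pharm, sp, phot, cs, lam)
  # efficacy preset: each wavelength's plateau varies < 5% of system max
  # across the 100-fold range above threshold
  expect_lt(max(apply(surf, 1, function(r) diff(range(r)))), 0.05)
  # zero concentration column is uniformly basal
  surf0 <- dose_wavelength_surface(pharm, sp, phot, c(0, 1e-9), lam)
  expect_equal(unname(surf0[, 1]), rep(baseline_response(pharm), length(lam)),
               tolerance = 1e-12)
  # affinity switch at the off-PSS: doubling c raises E* by the
  # Langmuir-predicted amount
  pa <- pharm_params(kd_E = Inf, kd_Z = 3e-9, eff_E = 0, eff_Z = 1,
                     basal = 0.04, tau = 10)
  fz_off <- compute_pss(sp, phot, 440)
  c1 <- 0.3 * 3e-9 / fz_off  # active isomer on the rising Langmuir flank
  e_pair <- chromo_response(c(c1, 2 * c1), fz_off, pa)
  pred <- vapply(c(c1, 2 * c1), function(ct)
    oracle_effect(ct, fz_off, Inf, 3e-9, 0, 1, 0.04, 10, 1), numeric(1))
  expect_equal(e_pair, pred, tolerance = 1e-12)
  expect_gt(e_pair[2] - e_pair[1], 0.05)
})
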