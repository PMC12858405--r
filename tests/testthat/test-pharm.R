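sp <- fixture_spectra()
phot <- fixture_phot()

test_that("competitive occupancy follows Gaddum algebra and conserves sites", {
  p <- pharm_params(kd_E = 2e-9, kd_Z = 8e-9, eff_E = -0.3, eff_Z = 1)
  occ <- competitive_occupancy(c(0, 1e-9, 1e-8, 1e-6), fz = 0.4, p)
  expect_equal(occ$rho_E + occ$rho_Z + occ$rho_free, rep(1, 4),
               tolerance = 1e-15)
  expect_equal(occ$rho_E[1], 0)
  expect_equal(occ$rho_Z[1], 0)
  # equal affinities: total occupancy at c = 5 kd is 5/6 regardless of fz
  pe <- pharm_params(kd_E = 3e-9, kd_Z = 3e-9, eff_E = -0.3, eff_Z = 1)
  for (fz in c(0, 0.2, 0.5, 1)) {
    occ5 <- competitive_occupancy(5 * 3e-9, fz, pe)
    expect_equal(occ5$rho_E + occ5$rho_Z, 5 / 6, tolerance = 1e-12)
  }
  # single-ligand Langmuir recovered at fz = 1
  occ1 <- competitive_occupancy(7e-9, 1, pe)
  expect_equal(occ1$rho_Z, 7e-9 / (7e-9 + 3e-9), tolerance = 1e-12)
  expect_error(competitive_occupancy(-1e-9, 0.5, pe), "non-negative")
  expect_error(competitive_occupancy(1e-9, 1.5, pe), "\\[0, 1\\]")
})

test_that("response equals the brute-force composed closed form on random draws", {
  set.seed(42)
  for (i in seq_len(1000)) {
    kd_E <- 10^runif(1, -10, -6)
    kd_Z <- 10^runif(1, -10, -6)
    eff_E <- runif(1, -1, 1)
    eff_Z <- runif(1, -1, 1)
    basal <- runif(1, 0, 0.3)
    tau <- runif(1, 0.5, 50)
    n <- runif(1, 1, 3)
    c_tot <- 10^runif(1, -11, -5)
    fz <- runif(1)
    p <- pharm_params(kd_E, kd_Z, eff_E, eff_Z, basal, tau, n)
    got <- chromo_response(c_tot, fz, p)
    want <- oracle_effect(c_tot, fz, kd_E, kd_Z, eff_E, eff_Z, basal, tau, n)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("effect is zero without stimulus and sub-basal under inverse agonism", {
  p0 <- pharm_params(3e-9, 3e-9, eff_E = 0, eff_Z = 1, basal = 0)
  expect_equal(receptor_response(competitive_occupancy(0, 0.5, p0), p0), 0)
  p <- pharm_preset("trpc4_azpico")
  # saturating mostly-E composition drives effect below the drug-free baseline
  e_sat_E <- chromo_response(1e-5, 0.0, p)
  expect_lt(e_sat_E, baseline_response(p))
})

test_that("440-nm off state returns the effect to the drug-free baseline", {
  p <- pharm_preset("trpc4_azpico")
  fz_off <- compute_pss(sp, phot, 440)
  for (c_tot in c(10e-9, 100e-9, 1e-6)) {
    # within 2% of the system maximum of the drug-free baseline
    expect_lt(abs(chromo_response(c_tot, fz_off, p) - baseline_response(p)),
              0.02)
  }
})

test_that("chromocontrol plateau depends only on the PSS composition", {
  p <- pharm_preset("trpc4_azpico")
  kd <- p$kd_Z
  for (fz in c(0.05, 0.3, 0.7, 0.95)) {
    e4 <- chromo_response(1e4 * kd, fz, p)
    e6 <- chromo_response(1e6 * kd, fz, p)
    expect_lt(abs(e4 - e6), 1e-4)
  }
})

test_that("wavelength rheostat: plateau effect is monotone in the Z fraction", {
  p <- pharm_preset("trpc4_azpico")
  c_plateau <- 1e3 * p$kd_Z
  phis <- seq(0.01, 0.99, by = 0.01)
  e <- chromo_response(c_plateau, phis, p)
  expect_true(all(diff(e) > 0))
  e360 <- chromo_response(c_plateau, compute_pss(sp, phot, 360), p)
  e385 <- chromo_response(c_plateau, compute_pss(sp, phot, 385), p)
  e440 <- chromo_response(c_plateau, compute_pss(sp, phot, 440), p)
  expect_true(e440 < e385 && e385 < e360)
})

test_that("dose-response is monotone, silent binders are flat, EC50 is as pinned", {
  p <- pharm_preset("trpc4_azpico")
  fz_on <- compute_pss(sp, phot, 365)
  dr <- dose_response(p, fz_on, default_c_grid())
  expect_true(all(diff(dr$response) > 0))
  # analytic half-max at the published potency
  expect_equal(response_ec50(p, fz_on), 3.0e-9, tolerance = 1e-6)
  # refit round trip recovers the generating EC50
  ft <- hill_fit(dr)
  expect_equal(ft$ec50, 3.0e-9, tolerance = 0.02)
  # silent-binder composition gives a flat curve at baseline
  psil <- pharm_params(p$kd_E, p$kd_Z, eff_E = 0, eff_Z = 0,
                       basal = p$basal, tau = p$tau)
  drs <- dose_response(psil, 0, default_c_grid())
  expect_equal(drs$response, rep(baseline_response(psil), 12),
               tolerance = 1e-12)
  expect_error(dose_response(p, 0.5, numeric(0)), "empty")
  expect_error(dose_response(p, 0.5, c(2e-9, 1e-9)), "increasing")
})

test_that("functional dynamic range: equal PSS gives zero; affinity switches collapse", {
  p <- pharm_preset("trpc4_azpico")
  expect_equal(functional_dynamic_range(p, 0.5, 0.5, 1e-8), 0)
  # ideal affinity switch: E does not bind, 20% residual Z in the off state
  pa <- pharm_params(kd_E = Inf, kd_Z = 3e-9, eff_E = 0, eff_Z = 1,
                     basal = 0.04, tau = 10)
  occ_off <- competitive_occupancy(100 * 3e-9, fz = 0.20, pa)
  expect_equal(occ_off$rho_Z, 20 / 21, tolerance = 1e-12)
  fdr_aff <- functional_dynamic_range(pa, 0.95, 0.20, 100 * 3e-9)
  # off-state occupancy 95% -> both states near the transduction ceiling
  expect_lt(abs(fdr_aff), 0.02)
  # ideal efficacy switch: FDR is concentration independent above threshold
  c_min <- independence_threshold(p)$c_min
  cs <- c_min * 10^seq(0, 2, by = 0.25)
  fdrs <- functional_dynamic_range(p, 0.95, 0.04, cs)
  expect_lt(diff(range(fdrs)) / max(abs(fdrs)), 0.05)
})

test_that("independence threshold encodes the ~5 x EC50 saturation rule", {
  p <- pharm_preset("trpc4_azpico")
  th <- independence_threshold(p)
  expect_identical(th$multiple, 5L)
  expect_equal(th$c_min / th$kd, 0.83 / 0.17, tolerance = 1e-12)
  expect_identical(independence_threshold(p, criterion = 0.5)$multiple, 1L)
  expect_error(independence_threshold(p, criterion = 1.2), "\\(0, 1\\)")
  pu <- pharm_params(kd_E = 9e-9, kd_Z = 3e-9, eff_E = -0.3, eff_Z = 1)
  expect_warning(independence_threshold(pu), "differ")
})

test_that("action-spectrum models: efficacy is concentration invariant, affinity shifts", {
  pss <- pss_curve(seq(340, 480, by = 20), c(0.95, 0.9, 0.7, 0.4, 0.2, 0.1,
                                             0.06, 0.04))
  pred_eff1 <- action_spectrum_model(pss, "efficacy", c_tot = 1e-8, b = 2)
  pred_eff2 <- action_spectrum_model(pss, "efficacy", c_tot = 2e-8, b = 2)
  expect_equal(pred_eff1$bioactivity, pred_eff2$bioactivity)
  pred_aff1 <- action_spectrum_model(pss, "affinity", c_tot = 1e-8, b = 2)
  pred_aff2 <- action_spectrum_model(pss, "affinity", c_tot = 2e-8, b = 2)
  expect_equal(pred_aff1$bioactivity - pred_aff2$bioactivity,
               rep(2 * log10(2), nrow(pss)), tolerance = 1e-12)
  # phi = 0.5 makes the isomer-ratio term vanish: prediction = offset
  pss5 <- pss_curve(c(350, 400, 450), rep(0.5, 3))
  expect_equal(action_spectrum_model(pss5, "efficacy", a = 0.7)$bioactivity,
               rep(0.7, 3))
  expect_warning(action_spectrum_model(pss_curve(c(350, 400, 450), c(0, 0.5, 1)),
                                       "efficacy"), "clamped")
})

test_that("switch classification applies the documented decision rules", {
  # AzPico-like: equal nanomolar affinity, opposing efficacies
  expect_identical(classify_switch(pharm_preset("trpc4_azpico"))$label,
                   "ideal_efficacy")
  expect_identical(
    classify_switch(pharm_params(3e-9, 3e-9, eff_E = -0.3, eff_Z = 1))$label,
    "ideal_efficacy")
  # classic affinity switch: 100-fold affinity ratio, Z-only binder
  cls_aff <- classify_switch(pharm_preset("affinity_switch"))
  expect_identical(cls_aff$label, "affinity")
  expect_gt(cls_aff$affinity_ratio, 10)
  # micromolar potency fails the ceiling despite opposing efficacies
  expect_identical(
    classify_switch(pharm_params(3e-6, 3e-6, eff_E = -0.3, eff_Z = 1))$label,
    "nonideal_efficacy")
  # both isomers silent
  expect_identical(classify_switch(pharm_preset("trpc4_azhc_inactive"))$label,
                   "inactive")
  # silent binder + strong agonist at equal affinity is still ideal
  expect_identical(
    classify_switch(pharm_params(3e-9, 3e-9, eff_E = 0, eff_Z = 1))$label,
    "ideal_efficacy")
})

test_that("preset potencies match the published values", {
  fz_on <- compute_pss(sp, phot, 365)
  expect_equal(response_ec50(pharm_preset("trpc4_azpico"), fz_on), 3.0e-9,
               tolerance = 1e-9)
  expect_equal(response_ec50(pharm_preset("trpc5_azpico"), fz_on), 4.0e-9,
               tolerance = 1e-9)
  expect_equal(response_ec50(pharm_preset("trpc5_azhc"), fz_on), 6.4e-9,
               tolerance = 1e-9)
})
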