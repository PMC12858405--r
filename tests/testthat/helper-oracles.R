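# Independent oracles used across the suite. These re-derive expected values
# from first principles (ODE integration, explicit Euler stepping, direct
# formula evaluation) without calling the package's analytic propagation
# paths they are checking.

# Rate constants recomputed from scratch (same physical convention as the
# package documents: 1000 * ln(10) * 1e-4 per M^-1 cm^-1 per mol m^-2 s^-1).
oracle_rates <- function(spectra, phot, wavelength, flux) {
  conv <- 1000 * log(10) * 1e-4
  interp <- function(y) approx(spectra$wavelengths, y, xout = wavelength)$y
  k_EZ <- conv * interp(spectra$eps_E) * phot$phi_EZ * flux
  k_ZE <- conv * interp(spectra$eps_Z) * phot$phi_ZE * flux
  list(k_EZ = k_EZ, k_ZE = k_ZE + phot$k_thermal)
}

# Steady state of dfz/dt = k_EZ (1-fz) - k_ZE' fz by numerical ODE
# integration (deSolve lsoda), run long enough to converge.
ode_steady_fz <- function(spectra, phot, wavelength, flux, fz0 = 0.5,
                          t_end = NULL) {
  r <- oracle_rates(spectra, phot, wavelength, flux)
  k_obs <- r$k_EZ + r$k_ZE
  if (is.null(t_end)) t_end <- 40 / k_obs
  sol <- deSolve::lsoda(
    y = c(fz = fz0), times = c(0, t_end),
    func = function(t, y, p) list(r$k_EZ * (1 - y[1]) - r$k_ZE * y[1]),
    rtol = 1e-10, atol = 1e-12)
  unname(sol[nrow(sol), "fz"])
}

# Explicit Euler trajectory through an illumination protocol at a fixed
# timestep fraction of 1/k_obs per segment.
euler_trajectory <- function(protocol, spectra, phot, fz0, times) {
  fz_fun <- stepfun(cumsum(protocol$duration)[-nrow(protocol)],
                    seq_len(nrow(protocol)))
  seg_rates <- lapply(seq_len(nrow(protocol)), function(s)
    oracle_rates(spectra, phot, protocol$wavelength[s], protocol$flux[s]))
  fz <- numeric(length(times))
  cur <- fz0
  fz[1] <- cur
  for (i in 2:length(times)) {
    s <- fz_fun(times[i - 1])
    r <- seg_rates[[s]]
    k_obs <- r$k_EZ + r$k_ZE
    dt_full <- times[i] - times[i - 1]
    # substep so that the Euler step is ~2e-4 / k_obs (first-order global
    # error then stays an order below the 1e-4 comparison bound)
    nsub <- max(1L, ceiling(dt_full * max(k_obs, 1e-12) / 2e-4))
    dt <- dt_full / nsub
    for (j in seq_len(nsub)) {
      cur <- cur + dt * (r$k_EZ * (1 - cur) - r$k_ZE * cur)
    }
    fz[i] <- cur
  }
  fz
}

# Direct evaluation of the composed occupancy -> stimulus -> transduction
# expression, written out long-hand.
oracle_effect <- function(c_tot, fz, kd_E, kd_Z, eff_E, eff_Z, basal, tau, n) {
  xZ <- fz * c_tot / kd_Z
  xE <- (1 - fz) * c_tot / kd_E
  rho_Z <- xZ / (1 + xZ + xE)
  rho_E <- xE / (1 + xZ + xE)
  rho_free <- 1 - rho_Z - rho_E
  S <- basal * rho_free + max(basal + eff_Z, 0) * rho_Z +
    max(basal + eff_E, 0) * rho_E
  (tau * S)^n / ((tau * S)^n + 1)
}

# Shared fixtures ------------------------------------------------------------

fixture_spectra <- function() default_spectra()
fixture_phot <- function() default_photophysics()

# Small hand-built spectrum pair for edge cases (flat absorptivities).
flat_spectra <- function(eps_E = 10000, eps_Z = 5000) {
  w <- seq(300, 550, by = 5)
  isomer_spectra(w, rep(eps_E, length(w)), rep(eps_Z, length(w)))
}
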