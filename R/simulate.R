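# Coupled photochemistry-pharmacology virtual experiments. Binding
# equilibration is treated as instantaneous relative to photoswitching and
# readout (quasi-equilibrium), so the effect at any instant is the
# steady-state response at the instantaneous E/Z composition.

#' Run a virtual photoswitching experiment
#'
#' Propagates the isomer composition through the illumination protocol
#' ([simulate_isomerization()]), maps it to effect through the competitive
#' occupancy / operational transduction model, and optionally passes the
#' effect through a first-order reporter lag (FLIPR-like readout) and
#' multiplicative measurement noise.
#'
#' @param protocol An [illumination_protocol]; all wavelengths must lie inside
#'   the spectrum grid.
#' @param spectra An [isomer_spectra] object.
#' @param phot A [photophysics] object.
#' @param pharm A [pharm_params] object.
#' @param c_tot Total photoswitch concentration (M), >= 0.
#' @param readout A [readout_model]; default instantaneous and noise-free.
#' @param fz0 Initial Z fraction; default 0 (pure E, the dark-adapted state).
#' @param samples_per_segment Reported samples per protocol segment.
#' @param seed Integer seed, required when `readout$noise_sd > 0`.
#' @return An object of class `response_trace`: data frame with columns
#'   `time_s`, `fz`, `effect`, `segment_id`, and attributes `protocol`,
#'   `baseline` (ligand-free effect) and `readout`.
#' @export
run_experiment <- function(protocol, spectra, phot, pharm, c_tot,
                           readout = readout_model(), fz0 = 0,
                           samples_per_segment = 200L, seed = NULL) {
  stopifnot(inherits(pharm, "pharm_params"), inherits(readout, "readout_model"))
  if (!is.numeric(c_tot) || length(c_tot) != 1L || c_tot < 0)
    stop("c_tot must be a single non-negative concentration")
  w <- spectra$wavelengths
  bad <- protocol$wavelength < w[1L] | protocol$wavelength > w[length(w)]
  if (any(bad))
    stop("protocol wavelength outside the spectrum grid")
  iso <- simulate_isomerization(protocol, spectra, phot, fz0,
                                samples_per_segment)
  effect <- chromo_response(c_tot, iso$fz, pharm)
  if (readout$mode == "first_order_lag") {
    effect <- first_order_filter(iso$time, effect, readout$lag_tau)
  }
  if (readout$noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required for a noisy readout")
    set.seed(seed)
    effect <- apply_noise(effect,
                          noise_model("multiplicative_lognormal",
                                      readout$noise_sd))
  }
  res <- data.frame(time_s = iso$time, fz = iso$fz,
                    effect = pmin(pmax(effect, 0), 1),
                    segment_id = iso$segment_id)
  attr(res, "protocol") <- protocol
  attr(res, "baseline") <- baseline_response(pharm)
  attr(res, "readout") <- readout
  class(res) <- c("response_trace", "data.frame")
  res
}

# Exact exponential-integrator step for dR/dt = (x - R)/tau assuming x is
# constant over each sampling interval at its trapezoidal mean. Initialised
# at the first input value (reporter equilibrated to the starting effect).
first_order_filter <- function(time, x, tau) {
  n <- length(x)
  r <- numeric(n)
  r[1L] <- x[1L]
  for (i in 2:n) {
    dt <- time[i] - time[i - 1L]
    a <- exp(-dt / tau)
    xm <- (x[i] + x[i - 1L]) / 2
    r[i] <- xm + (r[i - 1L] - xm) * a
  }
  r
}

#' Per-cycle statistics of a photoswitching trace
#'
#' Splits the trace into on/off cycles (consecutive segment pairs), extracts
#' per-cycle peak, trough and amplitude, and summarises reproducibility:
#' amplitude coefficient of variation, a fatigue slope (relative amplitude
#' change per cycle from a linear fit, as a fraction of the first-cycle fitted
#' amplitude) and reversibility (fraction of the peak-to-baseline excursion
#' recovered at the trough).
#'
#' @param trace A `response_trace` from [run_experiment()].
#' @param protocol The generating [illumination_protocol]; must match the
#'   trace's segment count.
#' @return An object of class `cycle_stats`: list with `per_cycle` (data frame
#'   `cycle`, `peak`, `trough`, `amplitude`), `n_cycles`, `amplitude_cv`,
#'   `fatigue_slope`, `reversibility`.
#' @export
cycle_stats <- function(trace, protocol = attr(trace, "protocol")) {
  stopifnot(inherits(trace, "response_trace"))
  if (is.null(protocol)) stop("protocol required (none attached to trace)")
  n_seg <- nrow(protocol)
  if (max(trace$segment_id) != n_seg)
    stop("trace/protocol misalignment: segment counts differ")
  if (n_seg < 2L) stop("protocol must contain at least one on/off cycle")
  n_cycles <- n_seg %/% 2L
  # extrema are taken within segment windows: the peak from the cycle's
  # high-effect phase, the trough from its low-effect phase, so that the
  # approach transient of the very first cycle does not contaminate its trough
  per <- do.call(rbind, lapply(seq_len(n_cycles), function(i) {
    e_a <- trace$effect[trace$segment_id == 2L * i - 1L]
    e_b <- trace$effect[trace$segment_id == 2L * i]
    if (mean(e_a) < mean(e_b)) { tmp <- e_a; e_a <- e_b; e_b <- tmp }
    data.frame(cycle = i, peak = max(e_a), trough = min(e_b),
               amplitude = max(e_a) - min(e_b))
  }))
  cv <- if (n_cycles > 1L) stats::sd(per$amplitude) / mean(per$amplitude) else 0
  slope <- NA_real_
  if (n_cycles > 1L) {
    fit <- stats::lm(amplitude ~ cycle, data = per)
    a1 <- as.numeric(stats::predict(fit, data.frame(cycle = 1)))
    slope <- as.numeric(stats::coef(fit)[2L]) / a1
  }
  base <- attr(trace, "baseline")
  rev_frac <- if (!is.null(base)) {
    with(per, mean(ifelse(peak > base, (peak - trough) / (peak - base), NA)))
  } else NA_real_
  structure(list(per_cycle = per, n_cycles = n_cycles,
                 amplitude_cv = cv, fatigue_slope = slope,
                 reversibility = rev_frac),
            class = "cycle_stats")
}

#' @export
print.cycle_stats <- function(x, ...) {
  cat(sprintf(
    "<cycle_stats> %d cycles: mean amplitude %.4f, CV %.2e, fatigue %s/cycle\n",
    x$n_cycles, mean(x$per_cycle$amplitude), x$amplitude_cv,
    if (is.na(x$fatigue_slope)) "NA" else sprintf("%.2e", x$fatigue_slope)))
  invisible(x)
}

#' Wavelength scan of photoswitching on or off
#'
#' For each scan wavelength, runs alternating cycles against a fixed
#' counter-wavelength and records the plateau effect at the end of the last
#' scan-wavelength segment. An `"on"` scan (cycles of lambda_scan / fixed
#' deactivating wavelength) maps the photoactivation spectrum; an `"off"` scan
#' (fixed activating wavelength / lambda_scan) maps photodeactivation.
#'
#' @param lambdas Scan wavelengths (nm), inside the spectrum grid.
#' @param fixed_wavelength Counter-wavelength (nm) of the alternating phase.
#' @param spectra,phot,pharm,c_tot As in [run_experiment()].
#' @param mode `"on"` or `"off"`.
#' @param flux Photon flux.
#' @param n_cycles Cycles per scan wavelength (plateaus settle after the
#'   first; default 3).
#' @param cycles_per_kobs Segment length in units of `1/k_obs`; default 10.
#' @return An `action_spectrum_set` data frame (`wavelength_nm`,
#'   `bioactivity`, `conc_M`) with attribute `mode`; bioactivity is the
#'   plateau effect E*.
#' @export
wavelength_scan <- function(lambdas, fixed_wavelength, spectra, phot, pharm,
                            c_tot, mode = c("on", "off"),
                            flux = default_flux(), n_cycles = 3L,
                            cycles_per_kobs = 10) {
  mode <- match.arg(mode)
  vals <- vapply(lambdas, function(l) {
    k_scan <- switching_rate(spectra, phot, l, flux)
    k_fix <- switching_rate(spectra, phot, fixed_wavelength, flux)
    if (mode == "on") {
      prot <- cycling_protocol(l, fixed_wavelength, n_cycles, flux,
                               cycles_per_kobs / k_scan,
                               cycles_per_kobs / k_fix)
      scan_segments <- seq(1L, 2L * n_cycles, by = 2L)
    } else {
      prot <- cycling_protocol(fixed_wavelength, l, n_cycles, flux,
                               cycles_per_kobs / k_fix,
                               cycles_per_kobs / k_scan)
      scan_segments <- seq(2L, 2L * n_cycles, by = 2L)
    }
    tr <- run_experiment(prot, spectra, phot, pharm, c_tot,
                         samples_per_segment = 50L)
    last_scan <- max(scan_segments)
    e <- tr$effect[tr$segment_id == last_scan]
    e[length(e)]
  }, numeric(1L))
  res <- data.frame(wavelength_nm = lambdas, bioactivity = vals,
                    conc_M = c_tot)
  attr(res, "mode") <- mode
  class(res) <- c("action_spectrum_set", "data.frame")
  res
}

#' Dose-wavelength response surface
#'
#' Plateau effect E* at every combination of illumination wavelength (through
#' its photostationary composition) and total concentration. For an ideal
#' efficacy switch the surface's wavelength profile is concentration
#' independent above the saturation threshold; for an affinity switch it
#' shifts strongly with concentration.
#'
#' @param pharm A [pharm_params] object.
#' @param spectra,phot Photochemistry.
#' @param c_grid Concentrations (M), positive sorted increasing.
#' @param lambda_grid Wavelengths (nm), sorted increasing, inside the grid.
#' @param flux Photon flux.
#' @return A numeric matrix (rows = wavelengths, columns = concentrations,
#'   dimnames set accordingly) of class `dose_wavelength_surface`.
#' @export
dose_wavelength_surface <- function(pharm, spectra, phot, c_grid, lambda_grid,
                                    flux = default_flux()) {
  if (any(c_grid < 0) || is.unsorted(c_grid))
    stop("c_grid must be non-negative and sorted")
  if (is.unsorted(lambda_grid))
    stop("lambda_grid must be sorted")
  phi <- vapply(lambda_grid, function(l)
    compute_pss(spectra, phot, l, flux), numeric(1L))
  m <- t(vapply(phi, function(p)
    chromo_response(c_grid, p, pharm), numeric(length(c_grid))))
  dimnames(m) <- list(wavelength = signif(lambda_grid, 6),
                      conc_M = signif(c_grid, 6))
  class(m) <- c("dose_wavelength_surface", class(m))
  m
}
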