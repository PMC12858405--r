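#' Per-isomer absorption spectrum pair
#'
#' Molar absorptivities of the E and Z isomers of an azobenzene photoswitch on
#' a shared, strictly increasing wavelength grid. The grid must cover at least
#' 300--550 nm so that photostationary states can be evaluated across the
#' near-UV/visible window used for bidirectional switching.
#'
#' @param wavelengths Numeric vector of wavelengths (nm), strictly increasing.
#' @param eps_E,eps_Z Molar absorptivities (M^-1 cm^-1) of the E and Z isomers
#'   at each wavelength; non-negative, same length as `wavelengths`.
#' @return An object of class `isomer_spectra`.
#' @export
isomer_spectra <- function(wavelengths, eps_E, eps_Z) {
  wavelengths <- as.numeric(wavelengths)
  eps_E <- as.numeric(eps_E)
  eps_Z <- as.numeric(eps_Z)
  if (length(wavelengths) < 2L)
    stop("spectrum grid needs at least two wavelengths")
  if (length(eps_E) != length(wavelengths) || length(eps_Z) != length(wavelengths))
    stop("eps_E and eps_Z must match the wavelength grid length")
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0))
    stop("wavelength grid must be finite and strictly increasing")
  if (any(!is.finite(eps_E)) || any(!is.finite(eps_Z)) ||
      any(eps_E < 0) || any(eps_Z < 0))
    stop("absorptivities must be finite and non-negative")
  if (wavelengths[1L] > 300 || wavelengths[length(wavelengths)] < 550)
    stop("spectrum grid must cover at least 300-550 nm")
  structure(
    list(wavelengths = wavelengths, eps_E = eps_E, eps_Z = eps_Z),
    class = "isomer_spectra"
  )
}

#' @export
print.isomer_spectra <- function(x, ...) {
  rng <- range(x$wavelengths)
  cat(sprintf("<isomer_spectra> %d points, %g-%g nm\n",
              length(x$wavelengths), rng[1L], rng[2L]))
  cat(sprintf("  eps_E peak %.0f at %g nm; eps_Z peak %.0f at %g nm\n",
              max(x$eps_E), x$wavelengths[which.max(x$eps_E)],
              max(x$eps_Z), x$wavelengths[which.max(x$eps_Z)]))
  invisible(x)
}

#' Interpolate a molar absorptivity at a wavelength
#'
#' Linear interpolation on the spectrum grid; optionally a top-hat average over
#' a finite illumination bandwidth.
#'
#' @param spectra An [isomer_spectra] object.
#' @param wavelength Wavelength (nm), inside the grid.
#' @param isomer `"E"` or `"Z"`.
#' @param bandwidth Full illumination bandwidth (nm); `0` (default) means
#'   monochromatic, otherwise the absorptivity is averaged top-hat over
#'   `wavelength +/- bandwidth/2` (truncated at the grid edges).
#' @return Molar absorptivity (M^-1 cm^-1).
#' @export
eps_at <- function(spectra, wavelength, isomer = c("E", "Z"), bandwidth = 0) {
  stopifnot(inherits(spectra, "isomer_spectra"))
  isomer <- match.arg(isomer)
  w <- spectra$wavelengths
  if (any(wavelength < w[1L]) || any(wavelength > w[length(w)]))
    stop(sprintf("wavelength outside spectrum grid (%g-%g nm)",
                 w[1L], w[length(w)]))
  y <- if (isomer == "E") spectra$eps_E else spectra$eps_Z
  if (bandwidth <= 0)
    return(stats::approx(w, y, xout = wavelength, rule = 1L)$y)
  vapply(wavelength, function(l) {
    lo <- max(l - bandwidth / 2, w[1L])
    hi <- min(l + bandwidth / 2, w[length(w)])
    grid <- seq(lo, hi, length.out = 21L)
    mean(stats::approx(w, y, xout = grid, rule = 1L)$y)
  }, numeric(1L))
}

#' Photoswitch photophysical parameters
#'
#' Quantum yields for the two photoisomerization directions and the thermal
#' Z-to-E relaxation rate. Bistable azobenzenes (the default) have
#' `k_thermal = 0`, so both photostationary states are stable in the dark.
#'
#' @param phi_EZ,phi_ZE Quantum yields for E->Z and Z->E photoisomerization,
#'   each in (0, 1].
#' @param k_thermal Thermal Z->E relaxation rate (s^-1), >= 0.
#' @return An object of class `photophysics`.
#' @export
photophysics <- function(phi_EZ = 0.30, phi_ZE = 0.45, k_thermal = 0) {
  if (!is.numeric(phi_EZ) || length(phi_EZ) != 1L || phi_EZ <= 0 || phi_EZ > 1)
    stop("phi_EZ must be a single value in (0, 1]")
  if (!is.numeric(phi_ZE) || length(phi_ZE) != 1L || phi_ZE <= 0 || phi_ZE > 1)
    stop("phi_ZE must be a single value in (0, 1]")
  if (!is.numeric(k_thermal) || length(k_thermal) != 1L || k_thermal < 0)
    stop("k_thermal must be a single non-negative rate (s^-1)")
  structure(list(phi_EZ = phi_EZ, phi_ZE = phi_ZE, k_thermal = k_thermal),
            class = "photophysics")
}

#' @export
print.photophysics <- function(x, ...) {
  cat(sprintf("<photophysics> Phi_EZ = %g, Phi_ZE = %g, k_thermal = %g s^-1\n",
              x$phi_EZ, x$phi_ZE, x$k_thermal))
  invisible(x)
}

#' Illumination protocols
#'
#' An illumination protocol is an ordered list of monochromatic segments, each
#' a (wavelength, photon flux, duration) triple. Dark periods are segments with
#' zero flux.
#'
#' @param wavelength Wavelength (nm) of each segment.
#' @param flux Photon flux (mol photons m^-2 s^-1), >= 0; `0` means dark.
#' @param duration Segment duration (s), > 0.
#' @return An object of class `illumination_protocol` (a data frame with
#'   columns `wavelength`, `flux`, `duration`).
#' @export
illumination_protocol <- function(wavelength, flux, duration) {
  n <- max(length(wavelength), length(flux), length(duration))
  wavelength <- rep_len(as.numeric(wavelength), n)
  flux <- rep_len(as.numeric(flux), n)
  duration <- rep_len(as.numeric(duration), n)
  if (n < 1L) stop("protocol must contain at least one segment")
  if (any(!is.finite(duration)) || any(duration <= 0))
    stop("segment durations must be positive")
  if (any(!is.finite(flux)) || any(flux < 0))
    stop("photon fluxes must be non-negative")
  structure(
    data.frame(wavelength = wavelength, flux = flux, duration = duration),
    class = c("illumination_protocol", "data.frame")
  )
}

#' @export
print.illumination_protocol <- function(x, ...) {
  cat(sprintf("<illumination_protocol> %d segments, total %g s\n",
              nrow(x), sum(x$duration)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more segments\n", nrow(x) - 6L))
  invisible(x)
}

#' Alternating two-wavelength cycling protocol
#'
#' Convenience constructor for the on/off cycling protocols used throughout
#' photoswitching experiments (e.g. 360/440-nm cycles).
#'
#' @param lambda_on,lambda_off Wavelengths (nm) of the two alternating phases.
#' @param n_cycles Number of on/off cycles (>= 1).
#' @param flux Photon flux for both phases (mol photons m^-2 s^-1).
#' @param duration_on,duration_off Phase durations (s).
#' @return An [illumination_protocol] with `2 * n_cycles` segments, on-phase
#'   first.
#' @export
cycling_protocol <- function(lambda_on, lambda_off, n_cycles,
                             flux, duration_on, duration_off = duration_on) {
  if (n_cycles < 1L) stop("n_cycles must be >= 1")
  illumination_protocol(
    wavelength = rep(c(lambda_on, lambda_off), n_cycles),
    flux = flux,
    duration = rep(c(duration_on, duration_off), n_cycles)
  )
}

#' Photostationary-state curve
#'
#' The mapping from illumination wavelength to the photostationary Z fraction
#' phi_lambda.
#'
#' @param wavelengths Wavelengths (nm).
#' @param fz Photostationary Z fraction at each wavelength, in [0, 1].
#' @return An object of class `pss_curve` (a data frame with columns
#'   `wavelength` and `fz`).
#' @export
pss_curve <- function(wavelengths, fz) {
  wavelengths <- as.numeric(wavelengths)
  fz <- as.numeric(fz)
  if (length(wavelengths) != length(fz))
    stop("wavelengths and fz must have equal length")
  if (any(!is.finite(fz)) || any(fz < 0) || any(fz > 1))
    stop("photostationary Z fractions must lie in [0, 1]")
  structure(data.frame(wavelength = wavelengths, fz = fz),
            class = c("pss_curve", "data.frame"))
}

#' @export
print.pss_curve <- function(x, ...) {
  cat(sprintf("<pss_curve> %d wavelengths, phi in [%.3f, %.3f]\n",
              nrow(x), min(x$fz), max(x$fz)))
  invisible(x)
}

#' Per-isomer receptor pharmacology
#'
#' Parameters of the competitive two-isomer receptor model: per-isomer
#' equilibrium dissociation constants and intrinsic efficacies, the receptor's
#' constitutive (basal) tone, and the operational transduction parameters
#' (amplification `tau` and steepness `hill_n`) that create receptor reserve.
#'
#' Intrinsic efficacy is signed: positive values are agonism, negative values
#' inverse agonism (suppression of constitutive tone), and values near zero
#' describe silent binders. The receptor stimulus contributed by an occupied
#' isomer is `max(basal + eff, 0)`, so inverse agonism is clamped at zero
#' stimulus.
#'
#' @param kd_E,kd_Z Dissociation constants (M), > 0; `Inf` encodes a
#'   non-binding isomer.
#' @param eff_E,eff_Z Intrinsic efficacies, each in [-1, 1].
#' @param basal Constitutive receptor tone as a fraction of maximal stimulus,
#'   in [0, 1].
#' @param tau Operational amplification (receptor reserve) factor, > 0.
#' @param hill_n Transduction steepness, >= 1.
#' @return An object of class `pharm_params`.
#' @export
pharm_params <- function(kd_E, kd_Z, eff_E, eff_Z,
                         basal = 0.04, tau = 10, hill_n = 1) {
  for (nm in c("kd_E", "kd_Z")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop(nm, " must be a single positive dissociation constant (M)")
  }
  for (nm in c("eff_E", "eff_Z")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < -1 || v > 1)
      stop(nm, " must be a single efficacy in [-1, 1]")
  }
  if (!is.numeric(basal) || length(basal) != 1L || basal < 0 || basal > 1)
    stop("basal must be a single tone in [0, 1]")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("tau must be a single positive amplification factor")
  if (!is.numeric(hill_n) || length(hill_n) != 1L || hill_n < 1)
    stop("hill_n must be a single steepness >= 1")
  structure(
    list(kd_E = kd_E, kd_Z = kd_Z, eff_E = eff_E, eff_Z = eff_Z,
         basal = basal, tau = tau, hill_n = hill_n),
    class = "pharm_params"
  )
}

#' @export
print.pharm_params <- function(x, ...) {
  cat("<pharm_params>\n")
  cat(sprintf("  kd_E = %.3g M, kd_Z = %.3g M (affinity ratio %.2g)\n",
              x$kd_E, x$kd_Z, affinity_ratio(x)))
  cat(sprintf("  eff_E = %+.2f, eff_Z = %+.2f, basal = %.3f\n",
              x$eff_E, x$eff_Z, x$basal))
  cat(sprintf("  transduction: tau = %g, n = %g\n", x$tau, x$hill_n))
  invisible(x)
}

#' Affinity ratio of the two isomers
#'
#' @param pharm A [pharm_params] object.
#' @return `max(kd) / min(kd)`; `Inf` if one isomer does not bind.
#' @export
affinity_ratio <- function(pharm) {
  stopifnot(inherits(pharm, "pharm_params"))
  kds <- c(pharm$kd_E, pharm$kd_Z)
  max(kds) / min(kds)
}

#' Readout (instrument) model
#'
#' Describes how an instrument reports the underlying biological effect.
#' Electrophysiology resolves currents essentially instantaneously; plate-scale
#' fluorometric calcium assays (FLIPR-like) behave as a delayed first-order
#' reporter that attenuates fast transitions.
#'
#' @param mode `"instantaneous"` or `"first_order_lag"`.
#' @param lag_tau Reporter time constant (s); required > 0 for the lagged mode.
#' @param noise_sd Multiplicative lognormal noise, as a fraction of signal
#'   (0 = deterministic).
#' @return An object of class `readout_model`.
#' @export
readout_model <- function(mode = c("instantaneous", "first_order_lag"),
                          lag_tau = 2, noise_sd = 0) {
  mode <- match.arg(mode)
  if (mode == "first_order_lag" && (!is.numeric(lag_tau) || lag_tau <= 0))
    stop("lag_tau must be > 0 for a first-order-lag readout")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("noise_sd must be a single non-negative fraction")
  structure(list(mode = mode, lag_tau = lag_tau, noise_sd = noise_sd),
            class = "readout_model")
}

#' Noise model for synthetic datasets
#'
#' @param kind `"none"`, `"additive_gaussian"` or `"multiplicative_lognormal"`.
#' @param sd Noise magnitude as a fraction (of the signal for the
#'   multiplicative kind; of the signal's dynamic range for the additive kind).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("multiplicative_lognormal", "additive_gaussian",
                                 "none"),
                        sd = 0.05) {
  kind <- match.arg(kind)
  if (!is.numeric(sd) || length(sd) != 1L || sd < 0)
    stop("sd must be a single non-negative fraction")
  if (kind == "none") sd <- 0
  structure(list(kind = kind, sd = sd), class = "noise_model")
}

#' Apply a noise model to a signal vector
#'
#' Multiplicative lognormal noise is mean-unbiased (the lognormal is centred so
#' that `E[noisy] = clean`). Callers are responsible for seeding the RNG.
#'
#' @param x Clean signal.
#' @param noise A [noise_model].
#' @param scale Dynamic-range scale used by the additive kind; defaults to
#'   `diff(range(x))` (or 1 when the signal is flat).
#' @return Noisy signal, same length as `x`.
#' @export
apply_noise <- function(x, noise, scale = NULL) {
  stopifnot(inherits(noise, "noise_model"))
  if (noise$kind == "none" || noise$sd == 0) return(x)
  if (noise$kind == "additive_gaussian") {
    if (is.null(scale)) {
      scale <- diff(range(x))
      if (scale == 0) scale <- 1
    }
    return(x + stats::rnorm(length(x), 0, noise$sd * scale))
  }
  sdlog <- sqrt(log1p(noise$sd^2))
  x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
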