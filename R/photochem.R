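# Two-state E <-> Z photoisomerization kinetics.
#
# Under monochromatic illumination at photon flux I (mol photons m^-2 s^-1)
# the per-molecule excitation rates are
#   k_EZ = EPS_TO_RATE * eps_E(lambda) * Phi_EZ * I
#   k_ZE = EPS_TO_RATE * eps_Z(lambda) * Phi_ZE * I
# and dfz/dt = k_EZ (1 - fz) - (k_ZE + k_thermal) fz, which relaxes
# exponentially to the photostationary state at rate k_obs = k_EZ + k_ZE +
# k_thermal.

# Absorptivity -> rate conversion: sigma (cm^2 molecule^-1) =
# 1000 ln(10) eps / N_A, photon flux in photons cm^-2 s^-1 = I * N_A * 1e-4;
# the Avogadro constants cancel, leaving 1000 * ln(10) * 1e-4 = 0.23026 per
# (M^-1 cm^-1 * mol m^-2 s^-1). Only rate ratios matter for the PSS when
# k_thermal = 0.
EPS_TO_RATE <- 1000 * log(10) * 1e-4

photo_rates <- function(spectra, phot, wavelength, flux, bandwidth = 0) {
  if (!is.numeric(flux) || length(flux) != 1L || flux < 0)
    stop("flux must be a single non-negative photon flux")
  k_EZ <- EPS_TO_RATE * eps_at(spectra, wavelength, "E", bandwidth) *
    phot$phi_EZ * flux
  k_ZE <- EPS_TO_RATE * eps_at(spectra, wavelength, "Z", bandwidth) *
    phot$phi_ZE * flux
  list(k_EZ = k_EZ, k_ZE = k_ZE, k_obs = k_EZ + k_ZE + phot$k_thermal)
}

#' Photostationary Z fraction at a wavelength
#'
#' Steady state of the two-state photoisomerization kinetics:
#' `phi = k_EZ / (k_EZ + k_ZE + k_thermal)`. For a bistable switch
#' (`k_thermal = 0`) this reduces to the flux-independent closed form
#' `eps_E Phi_EZ / (eps_E Phi_EZ + eps_Z Phi_ZE)` evaluated at the probe
#' wavelength.
#'
#' @param spectra An [isomer_spectra] object.
#' @param phot A [photophysics] object.
#' @param wavelength Probe wavelength (nm), inside the spectrum grid.
#' @param flux Photon flux (mol photons m^-2 s^-1). Irrelevant to the steady
#'   state when `k_thermal = 0`, but must be positive in that case for the
#'   steady state to exist.
#' @param bandwidth Top-hat illumination bandwidth (nm); 0 = monochromatic.
#' @return The photostationary Z fraction `phi_lambda` in [0, 1].
#' @export
#' @examples
#' sp <- default_spectra()
#' compute_pss(sp, default_photophysics(), 360)
#' compute_pss(sp, default_photophysics(), 440)
compute_pss <- function(spectra, phot, wavelength, flux = default_flux(),
                        bandwidth = 0) {
  stopifnot(inherits(phot, "photophysics"))
  r <- photo_rates(spectra, phot, wavelength, flux, bandwidth)
  if (any(r$k_obs == 0))
    stop("undefined steady state: no photon absorption and k_thermal = 0")
  r$k_EZ / r$k_obs
}

#' Observed photoswitching rate constant
#'
#' Rate of exponential approach to the photostationary state:
#' `k_obs = k_EZ + k_ZE + k_thermal`. Linear in photon flux, and never below
#' `k_thermal`.
#'
#' @inheritParams compute_pss
#' @return Rate constant (s^-1).
#' @export
switching_rate <- function(spectra, phot, wavelength, flux = default_flux(),
                           bandwidth = 0) {
  stopifnot(inherits(phot, "photophysics"))
  photo_rates(spectra, phot, wavelength, flux, bandwidth)$k_obs
}

#' Photostationary-state curve across wavelengths
#'
#' Evaluates [compute_pss()] on a wavelength grid.
#'
#' @inheritParams compute_pss
#' @param wavelengths Wavelengths (nm) at which to evaluate the PSS.
#' @return A [pss_curve].
#' @export
pss_curve_from_spectra <- function(spectra, phot, wavelengths,
                                   flux = default_flux(), bandwidth = 0) {
  fz <- vapply(wavelengths, function(l)
    compute_pss(spectra, phot, l, flux, bandwidth), numeric(1L))
  pss_curve(wavelengths, fz)
}

#' Time-resolved isomer fractions under an illumination protocol
#'
#' Propagates the Z fraction through each protocol segment with the exact
#' piecewise solution `fz(t) = phi + (fz0 - phi) exp(-k_obs t)`, where `phi`
#' and `k_obs` are the segment's photostationary state and observed rate. Dark
#' segments with `k_thermal = 0` leave the composition frozen; with
#' `k_thermal > 0` they relax thermally toward pure E. The trajectory is
#' continuous across segment boundaries and conserves mass (`f_E + f_Z = 1`).
#'
#' @param protocol An [illumination_protocol].
#' @param spectra An [isomer_spectra] object.
#' @param phot A [photophysics] object.
#' @param fz0 Initial Z fraction in [0, 1].
#' @param samples_per_segment Number of reported time points per segment (the
#'   propagation itself is analytic, so this affects reporting only).
#' @return A data frame of class `isomer_trace` with columns `time` (s), `fz`
#'   and `segment_id`.
#' @export
simulate_isomerization <- function(protocol, spectra, phot, fz0 = 0,
                                   samples_per_segment = 200L) {
  stopifnot(inherits(protocol, "illumination_protocol"),
            inherits(phot, "photophysics"))
  if (nrow(protocol) < 1L) stop("empty illumination protocol")
  if (!is.numeric(fz0) || length(fz0) != 1L || fz0 < 0 || fz0 > 1)
    stop("fz0 must be a single fraction in [0, 1]")
  t0 <- 0
  fz_cur <- fz0
  out <- vector("list", nrow(protocol))
  for (s in seq_len(nrow(protocol))) {
    seg <- protocol[s, ]
    r <- photo_rates(spectra, phot, seg$wavelength, seg$flux)
    tloc <- seq(0, seg$duration, length.out = samples_per_segment + 1L)
    if (s > 1L) tloc <- tloc[-1L]  # boundary point already reported
    if (r$k_obs == 0) {
      fz <- rep(fz_cur, length(tloc))
    } else {
      phi <- r$k_EZ / r$k_obs
      fz <- phi + (fz_cur - phi) * exp(-r$k_obs * tloc)
    }
    out[[s]] <- data.frame(time = t0 + tloc, fz = fz, segment_id = s)
    t0 <- t0 + seg$duration
    fz_cur <- fz[length(fz)]
  }
  res <- do.call(rbind, out)
  res$fz <- pmin(pmax(res$fz, 0), 1)
  class(res) <- c("isomer_trace", "data.frame")
  res
}

#' Default photophysics for the bundled synthetic photoswitch
#'
#' Quantum yields in the typical range for bidirectional azobenzene
#' photoswitches; thermal relaxation zero (bistable). These are package
#' conventions for the synthetic calibrated spectra, not measured values for
#' any particular compound: the spectral calibration compensates so that the
#' published photostationary-state anchors are met regardless.
#'
#' @return A [photophysics] object with `phi_EZ = 0.30`, `phi_ZE = 0.45`,
#'   `k_thermal = 0`.
#' @export
default_photophysics <- function() photophysics(0.30, 0.45, 0)

#' Default photon flux
#'
#' A convention chosen so that the observed photoswitching rate with the
#' default calibrated spectra is about 1 s^-1 at 360 nm, matching the
#' second-scale switching seen in live-cell photopharmacology rigs whose
#' absolute fluences are rarely reported.
#'
#' @return Photon flux (mol photons m^-2 s^-1).
#' @export
default_flux <- function() 7e-4
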