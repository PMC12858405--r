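# Synthetic-data generators: calibrated isomer spectra and seeded
# experimental-shaped datasets with ground truth retained for recovery
# scoring. Every generator is a pure function of (configuration, seed).

gauss_band <- function(wavelengths, center, width, peak) {
  peak * exp(-(wavelengths - center)^2 / (2 * width^2))
}

bands_to_eps <- function(bands, wavelengths) {
  m <- vapply(seq_len(nrow(bands)), function(i)
    gauss_band(wavelengths, bands$center[i], bands$width[i], bands$peak[i]),
    numeric(length(wavelengths)))
  rowSums(matrix(m, nrow = length(wavelengths)))
}

#' Default Gaussian band model for an azobenzene-like photoswitch
#'
#' The E isomer carries the strong pi-pi* band near 350 nm and a weak n-pi*
#' band near 440 nm typical of E-azobenzenes; the Z isomer's pi-pi* band is
#' blue-shifted and attenuated while its n-pi* band is stronger. The Z band
#' amplitudes are placeholders -- [make_calibrated_spectra()] solves them from
#' photostationary-state anchors.
#'
#' @return A list with data frames `E` and `Z` (columns `center`, `width`,
#'   `peak`, all nm / M^-1 cm^-1).
#' @export
default_band_model <- function() {
  list(
    E = data.frame(center = c(348, 440), width = c(30, 35),
                   peak = c(22000, 800)),
    Z = data.frame(center = c(310, 440), width = c(28, 30),
                   peak = c(1200, 15000))
  )
}

# Moore-Penrose solve via SVD; handles under- and over-determined anchor
# systems (minimum-norm / least-squares respectively).
pinv_solve <- function(G, y) {
  sv <- svd(G)
  tol <- max(dim(G)) * max(sv$d) * .Machine$double.eps
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  sv$v %*% (dinv * (t(sv$u) %*% y))
}

#' Synthetic isomer spectra calibrated to photostationary-state anchors
#'
#' Builds an azobenzene-like E spectrum from the default band model and solves
#' the Z band amplitudes so that the bistable photostationary state
#' `phi = eps_E Phi_EZ / (eps_E Phi_EZ + eps_Z Phi_ZE)` reproduces each anchor
#' `(wavelength, phi)` exactly. With the default two anchors (95% Z at 360 nm,
#' 18% Z, i.e. 82% E, at 410 nm) this is a 2x2 linear system in the two Z band
#' amplitudes. Deterministic; no randomness involved.
#'
#' The result is a synthetic stand-in with the published switching behaviour,
#' not a digitization of any measured compound spectrum.
#'
#' @param anchors Data frame with columns `wavelength` (nm) and `fz` (target
#'   photostationary Z fraction, strictly inside (0, 1)); at least one row,
#'   distinct wavelengths.
#' @param phot A [photophysics] object (its quantum-yield ratio enters the
#'   calibration).
#' @param wavelengths Output grid (nm); default 300-550 at 1 nm.
#' @param band_model Band model as from [default_band_model()]; the Z `peak`
#'   column is overwritten by the calibration.
#' @param tol Maximal absolute residual in phi allowed at each anchor.
#' @return An [isomer_spectra] object with a `calibration` attribute recording
#'   anchors, solved amplitudes and residuals.
#' @export
make_calibrated_spectra <- function(anchors = data.frame(
                                      wavelength = c(360, 410),
                                      fz = c(0.95, 0.18)),
                                    phot = default_photophysics(),
                                    wavelengths = 300:550,
                                    band_model = default_band_model(),
                                    tol = 0.005) {
  stopifnot(inherits(phot, "photophysics"))
  if (!all(c("wavelength", "fz") %in% names(anchors)) || nrow(anchors) < 1L)
    stop("anchors must have columns wavelength and fz, with >= 1 row")
  if (anyDuplicated(anchors$wavelength))
    stop("anchor wavelengths must be distinct")
  if (any(anchors$fz <= 0) || any(anchors$fz >= 1))
    stop("anchor PSS fractions must lie strictly inside (0, 1)")
  eps_E <- bands_to_eps(band_model$E, wavelengths)
  eps_E_anch <- bands_to_eps(band_model$E, anchors$wavelength)
  # required Z absorptivity at each anchor from the bistable PSS closed form
  eps_Z_req <- eps_E_anch * phot$phi_EZ * (1 - anchors$fz) /
    (phot$phi_ZE * anchors$fz)
  G <- vapply(seq_len(nrow(band_model$Z)), function(i)
    gauss_band(anchors$wavelength, band_model$Z$center[i],
               band_model$Z$width[i], 1),
    numeric(nrow(anchors)))
  G <- matrix(G, nrow = nrow(anchors))
  amps <- drop(pinv_solve(G, eps_Z_req))
  amps[amps < 0 & amps > -1e-9] <- 0
  if (any(amps < 0))
    stop(sprintf(
      "calibration failure: anchors require a negative Z band amplitude (%s)",
      paste(signif(amps, 3), collapse = ", ")))
  band_model$Z$peak <- amps
  eps_Z <- bands_to_eps(band_model$Z, wavelengths)
  sp <- isomer_spectra(wavelengths, eps_E, eps_Z)
  achieved <- vapply(anchors$wavelength, function(l)
    compute_pss(sp, photophysics(phot$phi_EZ, phot$phi_ZE, 0), l, flux = 1),
    numeric(1L))
  resid <- achieved - anchors$fz
  if (any(abs(resid) > tol))
    stop(sprintf("calibration failure: anchor residuals %s exceed %g",
                 paste(signif(resid, 3), collapse = ", "), tol))
  attr(sp, "calibration") <- list(anchors = anchors, amplitudes = amps,
                                  residuals = resid)
  sp
}

#' Default calibrated spectra
#'
#' [make_calibrated_spectra()] with the published anchors (95% Z at 360 nm,
#' 82% E at 410 nm); cached after the first call.
#'
#' @return An [isomer_spectra] object.
#' @export
default_spectra <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_calibrated_spectra()
    val
  }
})

#' Default concentration ladder
#'
#' Twelve log-spaced concentrations from 12 pM to 1.6 uM (close to half-log
#' steps), the plate-assay ladder shape used for potency determination.
#'
#' @return Concentrations (M), increasing.
#' @export
default_c_grid <- function() {
  exp(seq(log(12e-12), log(1.6e-6), length.out = 12L))
}

#' Synthetic dose-response dataset
#'
#' Ground-truth responses from [dose_response()] plus seeded replicate noise.
#' The clean curve, generating parameters and seed are retained as attributes
#' so that parameter-recovery studies can score estimates against truth.
#'
#' @param pharm A [pharm_params] object.
#' @param fz Z fraction of the applied mixture.
#' @param c_grid Concentrations (M); default [default_c_grid()].
#' @param noise A [noise_model]; default 5% multiplicative lognormal.
#' @param n_replicates Replicates per concentration.
#' @param seed Integer seed; required whenever the noise model is stochastic.
#' @return A `dose_response_set` data frame (`conc_M`, `response`,
#'   `replicate`) with attributes `truth` (clean curve), `pharm`, `fz`,
#'   `seed`.
#' @export
make_dose_response <- function(pharm, fz, c_grid = default_c_grid(),
                               noise = noise_model(), n_replicates = 3L,
                               seed = NULL) {
  clean <- dose_response(pharm, fz, c_grid)
  if (noise$kind != "none" && noise$sd > 0) {
    if (is.null(seed)) stop("a seed is required for stochastic noise")
    set.seed(seed)
  }
  res <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    data.frame(conc_M = clean$conc_M,
               response = apply_noise(clean$response, noise),
               replicate = r)
  }))
  res$response <- pmin(pmax(res$response, 0), 1)
  attr(res, "truth") <- data.frame(conc_M = clean$conc_M,
                                   response = clean$response)
  attr(res, "pharm") <- pharm
  attr(res, "fz") <- fz
  attr(res, "seed") <- seed
  class(res) <- c("dose_response_set", "data.frame")
  res
}

#' Synthetic action spectrum under a declared generating model
#'
#' Bioactivity-versus-wavelength data generated under either the efficacy
#' model (bioactivity tracks `-log10(Z/E)`) or the affinity model (bioactivity
#' tracks `-log10([Z])`), with seeded noise. The generating model label and
#' clean values are retained for model-comparison scoring. Multiple total
#' concentrations may be supplied to create the concentration-shift
#' discriminator design.
#'
#' @param true_model `"efficacy"` or `"affinity"`.
#' @param pss A [pss_curve] covering `lambda_grid`.
#' @param c_tot Total concentrations (M); one row set per concentration.
#' @param noise A [noise_model]; additive noise scales with the clean
#'   spectrum's dynamic range.
#' @param lambda_grid Wavelengths (nm) to sample; default the PSS curve's own
#'   grid.
#' @param a,b Offset and scale of the bioactivity mapping.
#' @param seed Integer seed; required when noise is stochastic.
#' @return A data frame (`wavelength_nm`, `bioactivity`, `conc_M`) of class
#'   `action_spectrum_set` with attributes `true_model`, `truth`, `seed`.
#' @export
make_action_spectrum <- function(true_model = c("efficacy", "affinity"),
                                 pss, c_tot, noise = noise_model(
                                   "additive_gaussian", 0.05),
                                 lambda_grid = NULL, a = 0, b = 1,
                                 seed = NULL) {
  true_model <- match.arg(true_model)
  stopifnot(inherits(pss, "pss_curve"))
  if (!is.null(lambda_grid)) {
    fz <- stats::approx(pss$wavelength, pss$fz, xout = lambda_grid,
                        rule = 1L)$y
    if (any(is.na(fz))) stop("lambda_grid outside the PSS curve's coverage")
    pss <- pss_curve(lambda_grid, fz)
  }
  clean <- do.call(rbind, lapply(c_tot, function(ct)
    action_spectrum_model(pss, true_model, c_tot = ct, a = a, b = b)))
  if (noise$kind != "none" && noise$sd > 0) {
    if (is.null(seed)) stop("a seed is required for stochastic noise")
    set.seed(seed)
  }
  res <- clean
  res$bioactivity <- apply_noise(clean$bioactivity, noise,
                                 scale = diff(range(clean$bioactivity)))
  attr(res, "true_model") <- true_model
  attr(res, "truth") <- clean
  attr(res, "seed") <- seed
  class(res) <- c("action_spectrum_set", "data.frame")
  res
}

#' Synthetic photoswitching cycling trace
#'
#' An alternating two-wavelength cycling experiment simulated with
#' [run_experiment()], optionally with a programmed per-cycle fatigue applied
#' to the effect amplitude above baseline (for testing fatigue estimators; the
#' physical two-state model itself has none).
#'
#' @param n_cycles Number of on/off cycles; default 36.
#' @param pharm A [pharm_params] object; default the TRPC4/AzPico preset.
#' @param spectra,phot Photochemistry; defaults as calibrated.
#' @param c_tot Total concentration (M); default 10 nM.
#' @param lambda_on,lambda_off Cycle wavelengths (nm); default 360/440.
#' @param flux Photon flux; default [default_flux()].
#' @param cycles_per_kobs Segment length in units of `1/k_obs` (slowest of the
#'   two wavelengths); default 10, comfortably reaching each photostationary
#'   plateau.
#' @param fatigue_per_cycle Programmed fractional amplitude loss per cycle
#'   (0 = none).
#' @param readout A [readout_model].
#' @param seed Integer seed, required when the readout has noise.
#' @return A `response_trace` (see [run_experiment()]) with attributes
#'   `protocol`, `fatigue_per_cycle`, `seed`.
#' @export
make_cycle_trace <- function(n_cycles = 36L, pharm = pharm_preset("trpc4_azpico"),
                             spectra = default_spectra(),
                             phot = default_photophysics(),
                             c_tot = 10e-9, lambda_on = 360, lambda_off = 440,
                             flux = default_flux(), cycles_per_kobs = 10,
                             fatigue_per_cycle = 0,
                             readout = readout_model(), seed = NULL) {
  k_on <- switching_rate(spectra, phot, lambda_on, flux)
  k_off <- switching_rate(spectra, phot, lambda_off, flux)
  dur <- cycles_per_kobs / min(k_on, k_off)
  protocol <- cycling_protocol(lambda_on, lambda_off, n_cycles, flux, dur)
  trace <- run_experiment(protocol, spectra, phot, pharm, c_tot,
                          readout = readout, seed = seed)
  if (fatigue_per_cycle > 0) {
    base <- attr(trace, "baseline")
    cycle <- ceiling(trace$segment_id / 2)
    trace$effect <- base +
      (trace$effect - base) * (1 - fatigue_per_cycle)^(cycle - 1)
  }
  attr(trace, "fatigue_per_cycle") <- fatigue_per_cycle
  attr(trace, "seed") <- seed
  trace
}
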