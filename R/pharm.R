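# Competitive two-isomer receptor pharmacology with operational transduction.
#
# Both isomers of the photoswitch compete for one binding site (Gaddum
# occupancy, no ligand depletion). Each occupied state contributes a stimulus
# set by the receptor's constitutive tone plus the isomer's signed intrinsic
# efficacy, clamped at zero (inverse agonism cannot drive stimulus negative).
# Stimulus is mapped to effect through a Black-Leff operational transduction
# E* = (tau S)^n / ((tau S)^n + 1), whose amplification tau creates receptor
# reserve.

clamp0 <- function(x) pmax(x, 0)

transduce <- function(S, pharm) {
  ts <- (pharm$tau * clamp0(S))^pharm$hill_n
  ts / (ts + 1)
}

#' Fractional occupancies of the E and Z isomers
#'
#' Gaddum competitive binding of the two isomers at total photoswitch
#' concentration `c_tot` split into Z fraction `fz` and E fraction `1 - fz`:
#' `rho_Z = (fz c / kd_Z) / (1 + fz c / kd_Z + (1 - fz) c / kd_E)`, and
#' symmetrically for E. Free ligand is approximated by total ligand (receptor
#' concentrations are far below ligand concentrations in the assays modelled).
#'
#' @param c_tot Total photoswitch concentration (M), >= 0; vectorized.
#' @param fz Z fraction of the applied E/Z mixture, in [0, 1]; scalar or
#'   vector recycled against `c_tot`.
#' @param pharm A [pharm_params] object.
#' @return An object of class `occupancy_state`: a data frame with columns
#'   `rho_E`, `rho_Z` and `rho_free`, summing to 1 row-wise.
#' @export
competitive_occupancy <- function(c_tot, fz, pharm) {
  stopifnot(inherits(pharm, "pharm_params"))
  if (any(!is.finite(c_tot)) || any(c_tot < 0))
    stop("c_tot must be non-negative and finite")
  if (any(!is.finite(fz)) || any(fz < 0) || any(fz > 1))
    stop("fz must lie in [0, 1]")
  n <- max(length(c_tot), length(fz))
  c_tot <- rep_len(c_tot, n)
  fz <- rep_len(fz, n)
  xZ <- fz * c_tot / pharm$kd_Z        # kd = Inf encodes a non-binder: x = 0
  xE <- (1 - fz) * c_tot / pharm$kd_E
  denom <- 1 + xZ + xE
  res <- data.frame(rho_E = xE / denom, rho_Z = xZ / denom,
                    rho_free = 1 / denom)
  class(res) <- c("occupancy_state", "data.frame")
  res
}

#' Biological effect from an occupancy state
#'
#' Receptor stimulus
#' `S = basal rho_free + max(basal + eff_Z, 0) rho_Z + max(basal + eff_E, 0) rho_E`
#' passed through the operational transduction
#' `E* = (tau S)^n / ((tau S)^n + 1)`. A saturating full agonist drives E*
#' towards 1 (to within the transduction ceiling `tau/(tau + 1)`); a
#' saturating inverse agonist drives E* below the ligand-free basal level.
#'
#' @param occ An `occupancy_state` from [competitive_occupancy()].
#' @param pharm A [pharm_params] object.
#' @return Effect E* in [0, 1], one value per occupancy row.
#' @export
receptor_response <- function(occ, pharm) {
  stopifnot(inherits(occ, "occupancy_state"), inherits(pharm, "pharm_params"))
  S <- pharm$basal * occ$rho_free +
    clamp0(pharm$basal + pharm$eff_Z) * occ$rho_Z +
    clamp0(pharm$basal + pharm$eff_E) * occ$rho_E
  transduce(S, pharm)
}

#' Effect at a concentration and photostationary composition
#'
#' Convenience composition of [competitive_occupancy()] and
#' [receptor_response()].
#'
#' @inheritParams competitive_occupancy
#' @return Effect E* in [0, 1], vectorized over `c_tot`/`fz`.
#' @export
chromo_response <- function(c_tot, fz, pharm) {
  receptor_response(competitive_occupancy(c_tot, fz, pharm), pharm)
}

#' Ligand-free baseline effect
#'
#' @param pharm A [pharm_params] object.
#' @return E* with no compound present (constitutive tone only).
#' @export
baseline_response <- function(pharm) {
  stopifnot(inherits(pharm, "pharm_params"))
  transduce(pharm$basal, pharm)
}

#' Dose-response curve at a fixed photostationary composition
#'
#' @param pharm A [pharm_params] object.
#' @param fz Z fraction of the applied mixture, in [0, 1].
#' @param c_grid Concentrations (M), positive and sorted increasing.
#' @return An object of class `dose_response_set`: a data frame with columns
#'   `conc_M`, `response` and `replicate` (all 1), carrying the generating
#'   `pharm` and `fz` as attributes.
#' @export
dose_response <- function(pharm, fz, c_grid) {
  stopifnot(inherits(pharm, "pharm_params"))
  if (length(c_grid) < 1L) stop("empty concentration grid")
  if (any(!is.finite(c_grid)) || any(c_grid <= 0))
    stop("concentrations must be positive and finite")
  if (is.unsorted(c_grid, strictly = TRUE))
    stop("concentration grid must be strictly increasing")
  res <- data.frame(conc_M = c_grid,
                    response = chromo_response(c_grid, fz, pharm),
                    replicate = 1L)
  attr(res, "pharm") <- pharm
  attr(res, "fz") <- fz
  class(res) <- c("dose_response_set", "data.frame")
  res
}

# Effective single-ligand reduction of the competitive mixture at fixed fz:
# total occupancy is a Langmuir isotherm in c with kd_eff = 1/(fz/kd_Z +
# (1-fz)/kd_E), and the stimulus is linear in total occupancy with slope
# `gain` below.
mixture_params <- function(pharm, fz) {
  aZ <- fz / pharm$kd_Z
  aE <- (1 - fz) / pharm$kd_E
  A <- aZ + aE
  if (A == 0)
    return(list(kd_eff = Inf, gain = 0))
  wZ <- aZ / A
  gain <- clamp0(pharm$basal + pharm$eff_Z) * wZ +
    clamp0(pharm$basal + pharm$eff_E) * (1 - wZ) - pharm$basal
  list(kd_eff = 1 / A, gain = gain)
}

#' Half-maximal response concentration (analytic)
#'
#' The concentration at which the effect is halfway between its ligand-free
#' baseline and its saturating plateau, for a fixed E/Z composition. Because
#' the stimulus is linear in total occupancy and occupancy is a Langmuir
#' isotherm in concentration, this half-maximal point is exact for any
#' transduction steepness; for `hill_n = 1` the whole curve is exactly a
#' four-parameter logistic with this EC50 and unit slope.
#'
#' @param pharm A [pharm_params] object.
#' @param fz Z fraction of the applied mixture.
#' @return The half-maximal concentration (M), or `NA` if the composition
#'   produces no response change (silent mixture).
#' @export
response_ec50 <- function(pharm, fz) {
  stopifnot(inherits(pharm, "pharm_params"))
  mp <- mixture_params(pharm, fz)
  if (mp$gain == 0 || !is.finite(mp$kd_eff)) return(NA_real_)
  E0 <- transduce(pharm$basal, pharm)
  Einf <- transduce(pharm$basal + mp$gain, pharm)
  Emid <- (E0 + Einf) / 2
  S_mid <- (Emid / (1 - Emid))^(1 / pharm$hill_n) / pharm$tau
  rho_mid <- (S_mid - pharm$basal) / mp$gain
  mp$kd_eff * rho_mid / (1 - rho_mid)
}

# Solves for the common dissociation constant that yields a target
# half-maximal response concentration at composition fz (equal-affinity
# switch). Used to pin the bundled presets to published potencies.
kd_for_response_ec50 <- function(target_ec50, fz, eff_E, eff_Z,
                                 basal = 0.04, tau = 10, hill_n = 1) {
  probe <- pharm_params(kd_E = 1e-9, kd_Z = 1e-9, eff_E = eff_E, eff_Z = eff_Z,
                        basal = basal, tau = tau, hill_n = hill_n)
  # response_ec50 scales linearly in the common kd
  ec50_at_unit <- response_ec50(probe, fz)
  if (is.na(ec50_at_unit)) stop("composition produces no response; cannot pin EC50")
  1e-9 * target_ec50 / ec50_at_unit
}

#' Functional dynamic range between two photostationary states
#'
#' Signed difference of the effect at the photoswitched-on and
#' photoswitched-off compositions at a common total concentration. For an
#' affinity switch the off-state is degraded by residual active isomer as
#' concentration grows; for an ideal efficacy switch the FDR is set by the two
#' PSS compositions alone once the receptor is saturated.
#'
#' @param pharm A [pharm_params] object.
#' @param fz_on,fz_off Z fractions of the on- and off-photostationary states.
#' @param c_tot Total concentration (M); vectorized.
#' @return `E*_on - E*_off`, vectorized over `c_tot`.
#' @export
functional_dynamic_range <- function(pharm, fz_on, fz_off, c_tot) {
  chromo_response(c_tot, fz_on, pharm) - chromo_response(c_tot, fz_off, pharm)
}

#' Concentration threshold for dose-independent chromocontrol
#'
#' The smallest total concentration at which competitive occupancy by any E/Z
#' mixture reaches the near-saturation criterion, above which bioactivity is
#' set by the photostationary composition alone. With the default criterion
#' (total occupancy >= 0.83) the integer multiple of the half-saturation
#' constant is 5, the conventional "plateau from ~5 x EC50" rule.
#'
#' @param pharm A [pharm_params] object. If the isomer affinities differ, the
#'   weaker (larger) kd is used, with a warning.
#' @param criterion Near-saturation occupancy criterion, in (0, 1); default
#'   0.83.
#' @return A list with `c_min` (M, continuous solution
#'   `kd * criterion / (1 - criterion)`), `multiple` (smallest integer m with
#'   `m/(m+1) >= criterion`), `c_min_integer` (`multiple * kd`) and the `kd`
#'   used.
#' @export
independence_threshold <- function(pharm, criterion = 0.83) {
  stopifnot(inherits(pharm, "pharm_params"))
  if (!is.numeric(criterion) || length(criterion) != 1L ||
      criterion <= 0 || criterion >= 1)
    stop("criterion must lie strictly inside (0, 1)")
  kds <- c(pharm$kd_E, pharm$kd_Z)
  kd <- min(kds)
  if (max(kds) / min(kds) > 1.5) {
    warning("isomer affinities differ; using the weaker (larger) kd")
    kd <- max(kds[is.finite(kds)])
  }
  m <- ceiling(criterion / (1 - criterion) - 1e-12)
  list(c_min = kd * criterion / (1 - criterion),
       multiple = as.integer(m),
       c_min_integer = m * kd,
       kd = kd)
}

#' Rival action-spectrum models for photoswitch bioactivity
#'
#' Predicted bioactivity as a function of wavelength under the two competing
#' mechanistic readings of an action spectrum. For an efficacy switch,
#' bioactivity tracks the photostationary E/Z ratio:
#' `a + b * (-log10(phi / (1 - phi)))`. For an affinity switch, bioactivity
#' tracks the absolute concentration of the active (Z) isomer:
#' `a + b * (-log10(phi * c_tot))`, and therefore shifts by `b * log10(r)`
#' when the total concentration is scaled by `r` -- the efficacy model is
#' concentration invariant.
#'
#' @param pss A [pss_curve].
#' @param model `"efficacy"` or `"affinity"`.
#' @param c_tot Total concentration (M); required for the affinity model.
#' @param a,b Offset and scale of the linear bioactivity mapping.
#' @return A data frame with columns `wavelength_nm`, `bioactivity`, `conc_M`.
#' @export
action_spectrum_model <- function(pss, model = c("efficacy", "affinity"),
                                  c_tot = NA_real_, a = 0, b = 1) {
  stopifnot(inherits(pss, "pss_curve"))
  model <- match.arg(model)
  phi <- clamp_phi(pss$fz)
  x <- if (model == "efficacy") {
    -log10(phi / (1 - phi))
  } else {
    if (!is.finite(c_tot) || c_tot <= 0)
      stop("affinity model requires a positive c_tot")
    -log10(phi * c_tot)
  }
  data.frame(wavelength_nm = pss$wavelength, bioactivity = a + b * x,
             conc_M = c_tot)
}

# PSS fractions of exactly 0 or 1 make the isomer-ratio term singular; they
# are clamped to an epsilon with a warning, as real photostationary states
# are never perfectly pure.
clamp_phi <- function(phi, eps = 1e-6) {
  if (any(phi <= 0) || any(phi >= 1))
    warning("PSS fraction at 0 or 1 clamped to epsilon = 1e-6")
  pmin(pmax(phi, eps), 1 - eps)
}

#' Classify a photoswitch as affinity, efficacy or inactive
#'
#' Decision rules: `inactive` if both isomers are silent
#' (|efficacy| < 0.05); `affinity` if the isomer affinities differ more than
#' 10-fold; `ideal_efficacy` if the affinities are similar (ratio <=
#' `affinity_ratio_max`), the efficacies oppose in sign (or one isomer is a
#' silent binder while the other has |efficacy| >= 0.5), and both isomers are
#' potent (response EC50 below `potency_ceiling`, so that saturating plateau
#' concentrations of 10-100 x EC50 are practical); otherwise
#' `nonideal_efficacy`. Thresholds are package conventions encoding the
#' qualitative "identical or very similar affinity" and "both EC50 < 50 nM"
#' requirements.
#'
#' A silent isomer's potency is judged by its binding kd (it has no response
#' EC50); an active isomer's by its single-isomer response EC50.
#'
#' @param pharm A [pharm_params] object.
#' @param potency_ceiling Potency ceiling (M); default 50 nM.
#' @param affinity_ratio_max Maximal kd ratio still counted as "very similar
#'   affinity"; default 3.
#' @return An object of class `switch_class`: list with `label` (one of
#'   `"ideal_efficacy"`, `"nonideal_efficacy"`, `"affinity"`, `"inactive"`),
#'   `affinity_ratio`, `potency_ok` and the per-isomer potencies.
#' @export
classify_switch <- function(pharm, potency_ceiling = 50e-9,
                            affinity_ratio_max = 3) {
  stopifnot(inherits(pharm, "pharm_params"))
  ratio <- affinity_ratio(pharm)
  silent_E <- abs(pharm$eff_E) < 0.05
  silent_Z <- abs(pharm$eff_Z) < 0.05
  pot_E <- if (silent_E) pharm$kd_E else response_ec50(pharm, fz = 0)
  pot_Z <- if (silent_Z) pharm$kd_Z else response_ec50(pharm, fz = 1)
  potency_ok <- is.finite(pot_E) && is.finite(pot_Z) &&
    pot_E < potency_ceiling && pot_Z < potency_ceiling
  opposing <- sign(pharm$eff_E) * sign(pharm$eff_Z) < 0
  silent_pair <- (silent_E && abs(pharm$eff_Z) >= 0.5) ||
    (silent_Z && abs(pharm$eff_E) >= 0.5)
  label <- if (silent_E && silent_Z) {
    "inactive"
  } else if (ratio > 10) {
    "affinity"
  } else if (ratio <= affinity_ratio_max && (opposing || silent_pair) &&
             potency_ok) {
    "ideal_efficacy"
  } else {
    "nonideal_efficacy"
  }
  structure(list(label = label, affinity_ratio = ratio,
                 potency_ok = potency_ok,
                 potency_E = pot_E, potency_Z = pot_Z),
            class = "switch_class")
}

#' @export
print.switch_class <- function(x, ...) {
  cat(sprintf("<switch_class> %s (affinity ratio %.3g, potency %s)\n",
              x$label, x$affinity_ratio,
              if (x$potency_ok) "ok" else "insufficient"))
  invisible(x)
}

#' Bundled pharmacology presets
#'
#' Equal-affinity, Z-agonist / E-inverse-agonist parameter sets pinned so that
#' the response EC50 at the 365-nm photostationary composition (with the
#' default calibrated spectra) equals the published potencies: 3.0 nM
#' (TRPC4/AzPico), 4.0 nM (TRPC5/AzPico) and 6.4 nM (TRPC5/AzHC). The
#' `trpc4_azhc_inactive` preset encodes AzHC's lack of TRPC4 activity (both
#' isomers silent binders into the micromolar range). The inverse-agonist
#' efficacy magnitude (-0.3) is a convention: inverse agonism of the E isomers
#' is reported qualitatively, without a measured magnitude.
#'
#' An `affinity_switch` preset (Z-only binder, 100-fold affinity ratio) is
#' included as the classic affinity-switch comparator.
#'
#' @param name One of `"trpc4_azpico"`, `"trpc5_azpico"`, `"trpc5_azhc"`,
#'   `"trpc4_azhc_inactive"`, `"affinity_switch"`.
#' @return A [pharm_params] object.
#' @export
pharm_preset <- function(name = c("trpc4_azpico", "trpc5_azpico", "trpc5_azhc",
                                  "trpc4_azhc_inactive", "affinity_switch")) {
  name <- match.arg(name)
  if (name == "trpc4_azhc_inactive")
    return(pharm_params(kd_E = 1e-6, kd_Z = 1e-6, eff_E = 0, eff_Z = 0))
  if (name == "affinity_switch") {
    # Z binds and fully activates; E binds 100x more weakly and is silent.
    kd <- kd_for_response_ec50(3.0e-9, fz = preset_fz_on(),
                               eff_E = 0, eff_Z = 1)
    return(pharm_params(kd_E = 100 * kd, kd_Z = kd, eff_E = 0, eff_Z = 1))
  }
  ec50 <- switch(name,
                 trpc4_azpico = 3.0e-9,
                 trpc5_azpico = 4.0e-9,
                 trpc5_azhc = 6.4e-9)
  kd <- kd_for_response_ec50(ec50, fz = preset_fz_on(),
                             eff_E = -0.3, eff_Z = 1)
  pharm_params(kd_E = kd, kd_Z = kd, eff_E = -0.3, eff_Z = 1)
}

# PSS Z fraction at the 365-nm activation wavelength of the default
# calibrated spectra; cached since presets are built repeatedly.
preset_fz_on <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- compute_pss(default_spectra(), default_photophysics(), 365)
    val
  }
})
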