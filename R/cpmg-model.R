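# Carver-Richards two-state exchange forward model for constant-time CPMG
# relaxation dispersion, plus the intensity -> R2eff conversion and the
# dispersion-profile container.

#' Default CPMG refocusing-frequency schedules
#'
#' Returns the nu_cpmg schedule (Hz) used at each static field: at 11.7 T,
#' 50, 100, 150, 200, 300, 400, 500, 650, 800 and 950 Hz; at 14.1 T, 50, 100,
#' 300 (duplicated), 400, 500, 600, 700, 800, 900, 1000 and 1100 Hz. The
#' reference (0 Hz) planes enter only through the intensity-to-R2eff
#' conversion and are not part of the returned lists.
#'
#' @param field_T static field in tesla (11.7 or 14.1)
#' @return numeric vector of nu_cpmg values in Hz (duplicates = repeat points)
#' @export
cpmg_nu_schedule <- function(field_T) {
  if (isTRUE(all.equal(field_T, 11.7))) {
    c(50, 100, 150, 200, 300, 400, 500, 650, 800, 950)
  } else if (isTRUE(all.equal(field_T, 14.1))) {
    c(50, 100, 300, 300, 400, 500, 600, 700, 800, 900, 1000, 1100)
  } else {
    stop("cpmg_nu_schedule(): no embedded schedule for field ", field_T, " T")
  }
}

#' Effective transverse relaxation rate from constant-time peak intensities
#'
#' R2eff = -ln(I / I0) / T_CT, the standard constant-time CPMG conversion.
#' The uncertainty is propagated to first order from the intensity
#' uncertainties: sigma_R2 = sqrt((sI/I)^2 + (sI0/I0)^2) / T_CT.
#'
#' @param intensity peak intensity at a given nu_cpmg (arbitrary units, > 0)
#' @param reference_intensity intensity of the reference (0 Hz) plane (> 0)
#' @param constant_time_s constant-time relaxation period in seconds
#'   (default 0.040)
#' @param sigma_intensity,sigma_reference intensity uncertainties (same units)
#' @return data.frame with columns `r2eff_s1` and `sigma_s1`
#' @export
#' @examples
#' r2eff_from_intensities(exp(-1), 1, 0.040)  # R2eff = 25 /s
r2eff_from_intensities <- function(intensity, reference_intensity,
                                   constant_time_s = 0.040,
                                   sigma_intensity = 0,
                                   sigma_reference = 0) {
  stopifnot(constant_time_s > 0)
  bad <- which(intensity <= 0 | reference_intensity <= 0)
  if (length(bad)) {
    stop("r2eff_from_intensities(): non-positive intensity at point(s) ",
         paste(bad, collapse = ", "))
  }
  r2 <- -log(intensity / reference_intensity) / constant_time_s
  s <- sqrt((sigma_intensity / intensity)^2 +
              (sigma_reference / reference_intensity)^2) / constant_time_s
  data.frame(r2eff_s1 = r2, sigma_s1 = s)
}

#' Two-state exchange parameters
#'
#' k_ex = k_1 + k_-1 is the sum of forward and reverse rate constants
#' (k_on\[L\] + k_off for ligand binding); p_F is the population of the minor
#' free state (p_B = 1 - p_F). r20 is the exchange-free limiting relaxation
#' rate; one value per profile is supplied at fit time.
#'
#' @param k_ex_s1 exchange rate constant sum in 1/s (> 0)
#' @param p_F free-state population, in (0, 0.5): the free state is minor
#' @param r20_s1 optional exchange-free relaxation rate(s), 1/s
#' @return object of class `exchange_parameters`
#' @export
exchange_parameters <- function(k_ex_s1, p_F, r20_s1 = NULL) {
  stopifnot(k_ex_s1 > 0, p_F > 0, p_F < 0.5)
  if (!is.null(r20_s1)) stopifnot(all(r20_s1 > 0))
  structure(
    list(k_ex_s1 = k_ex_s1, p_F = p_F, r20_s1 = r20_s1),
    class = "exchange_parameters"
  )
}

#' @export
print.exchange_parameters <- function(x, ...) {
  cat(sprintf("Two-state exchange: k_ex = %.1f /s, p_F = %.3f (p_B = %.3f)\n",
              x$k_ex_s1, x$p_F, 1 - x$p_F))
  invisible(x)
}

# log(2x) for x = dplus*cosh(etap) - dminus*cos(etam), computed without
# overflow for large etap: 2x = dplus*e^etap*(1 + e^(-2 etap)
#                                             - 2 (dminus/dplus) cos(etam) e^(-etap))
log_2arg <- function(dplus, dminus, etap, etam) {
  etap + log(dplus) +
    log1p(exp(-2 * etap) - 2 * (dminus / dplus) * cos(etam) * exp(-etap))
}

#' Carver-Richards R2eff for two-state exchange
#'
#' Closed-form effective transverse relaxation rate for a spin exchanging
#' between two states under a CPMG pulse train with pulse spacing
#' tau = 1/(2 nu_cpmg):
#' R2eff = R20 + (k_ex - acosh(D+ cosh(eta+) - D- cos(eta-)) / tau) / 2,
#' with psi = k_ex^2 - domega^2, zeta = -2 domega k_ex (1 - 2 p_F),
#' D+- = (+-1 + (psi + 2 domega^2)/sqrt(psi^2 + zeta^2)) / 2 and
#' eta+- = (tau/sqrt(2)) sqrt(+-psi + sqrt(psi^2 + zeta^2)). The acosh is
#' evaluated in log form so the expression stays finite for slow pulsing and
#' fast relaxation (where cosh(eta+) would overflow).
#'
#' @param r20_s1 exchange-free relaxation rate, 1/s
#' @param k_ex_s1 exchange rate sum, 1/s
#' @param p_F population of the minor (free) state, in (0, 1)
#' @param delta_omega_rad_s chemical shift difference between states, rad/s
#' @param nu_cpmg_Hz CPMG refocusing frequency (vectorized), Hz, > 0
#' @return R2eff in 1/s, same length as `nu_cpmg_Hz`
#' @export
#' @examples
#' carver_richards_r2eff(10, 377, 0.05, 635, c(50, 200, 800))
carver_richards_r2eff <- function(r20_s1, k_ex_s1, p_F, delta_omega_rad_s,
                                  nu_cpmg_Hz) {
  stopifnot(k_ex_s1 > 0, p_F > 0, p_F < 1, r20_s1 > 0)
  if (any(nu_cpmg_Hz <= 0)) {
    stop("carver_richards_r2eff(): nu_cpmg must be > 0; 0 Hz entries are ",
         "reference planes, handled by r2eff_from_intensities()")
  }
  tau <- 1 / (2 * nu_cpmg_Hz)
  psi <- k_ex_s1^2 - delta_omega_rad_s^2
  zeta <- -2 * delta_omega_rad_s * k_ex_s1 * (1 - 2 * p_F)
  root <- sqrt(psi^2 + zeta^2)
  dplus <- 0.5 * (1 + (psi + 2 * delta_omega_rad_s^2) / root)
  dminus <- 0.5 * (-1 + (psi + 2 * delta_omega_rad_s^2) / root)
  etap <- (tau / sqrt(2)) * sqrt(psi + root)
  etam <- (tau / sqrt(2)) * sqrt(pmax(root - psi, 0))
  # acosh(x) = log(2x) - log(1 + sqrt(1 - 1/x^2)) + log(2)/... use stable split
  l2x <- log_2arg(dplus, dminus, etap, etam)
  x_small <- l2x < 30  # safe to evaluate directly
  ac <- numeric(length(tau))
  if (any(x_small)) {
    x <- dplus * cosh(etap[x_small]) - dminus * cos(etam[x_small])
    x <- pmax(x, 1)  # guard rounding just below 1 (no exchange limit)
    ac[x_small] <- acosh(x)
  }
  if (any(!x_small)) {
    # acosh(x) -> log(2x) for large x
    ac[!x_small] <- l2x[!x_small]
  }
  r20_s1 + 0.5 * (k_ex_s1 - ac / tau)
}

#' CPMG dispersion profile
#'
#' One residue at one static field: dispersion points (nu_cpmg, R2eff, sigma)
#' with the residue's chemical-shift difference between free and bound states
#' fixed from spectra, supplied in ppm and converted to rad/s at the
#' profile's field.
#'
#' @param residue residue label, e.g. `"I145"`
#' @param field_T static field in tesla
#' @param delta_omega_ppm shift difference between exchanging states, ppm
#' @param nu_cpmg_Hz vector of refocusing frequencies, Hz (>= 6 points)
#' @param r2eff_s1 effective relaxation rates, 1/s
#' @param sigma_s1 point uncertainties, 1/s (> 0)
#' @param constant_time_s constant-time relaxation period, s
#' @return object of class `dispersion_profile`
#' @export
dispersion_profile <- function(residue, field_T, delta_omega_ppm,
                               nu_cpmg_Hz, r2eff_s1, sigma_s1,
                               constant_time_s = 0.040) {
  stopifnot(length(nu_cpmg_Hz) == length(r2eff_s1),
            length(nu_cpmg_Hz) >= 6,
            all(nu_cpmg_Hz >= 0), field_T > 0)
  sigma_s1 <- rep_len(sigma_s1, length(r2eff_s1))
  stopifnot(all(sigma_s1 > 0))
  structure(
    list(residue = as.character(residue), field_T = field_T,
         delta_omega_ppm = delta_omega_ppm,
         delta_omega_rad_s = ppm_to_rad_s(delta_omega_ppm, field_T),
         nu_cpmg_Hz = nu_cpmg_Hz, r2eff_s1 = r2eff_s1, sigma_s1 = sigma_s1,
         constant_time_s = constant_time_s),
    class = "dispersion_profile"
  )
}

#' @export
print.dispersion_profile <- function(x, ...) {
  cat(sprintf(
    "CPMG profile %s @ %.1f T: %d points, domega = %.2f ppm (%.0f rad/s)\n",
    x$residue, x$field_T, length(x$nu_cpmg_Hz), x$delta_omega_ppm,
    x$delta_omega_rad_s))
  invisible(x)
}
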