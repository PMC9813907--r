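# DMSO-water viscosity model and the diffusion-limited association rate of
# two spheres (Smoluchowski encounter rate with Stokes-Einstein diffusion).

#' Dynamic viscosity of pure water
#'
#' Vogel-type correlation eta = 2.414e-5 * 10^(247.8/(T - 140)) Pa s, which
#' reproduces tabulated water viscosities to better than 1% between 273 and
#' 313 K.
#'
#' @param temperature_K temperature in kelvin (278-320 K supported)
#' @return dynamic viscosity in Pa s
#' @export
#' @examples
#' water_viscosity(301)  # ~8.3e-4 Pa s
water_viscosity <- function(temperature_K) {
  stopifnot(is.numeric(temperature_K))
  if (any(temperature_K < 278 | temperature_K > 320)) {
    stop("water_viscosity(): temperature outside calibrated range 278-320 K")
  }
  2.414e-5 * 10^(247.8 / (temperature_K - 140))
}

#' Dynamic viscosity of dilute DMSO-water mixtures
#'
#' In the dilute regime the viscosity of DMSO-water mixtures grows nearly
#' linearly with the DMSO volume fraction, reaching three times the pure-water
#' value at 20% (v/v). The mixture viscosity is modelled as the pure-water
#' viscosity at the given temperature multiplied by the relative factor
#' g(f) = 1 + 10 f, so g(0) = 1 and g(0.2) = 3. The relative increase is
#' treated as temperature independent to first order.
#'
#' @param dmso_fraction DMSO volume fraction, in \[0, 0.2\]
#' @param temperature_K temperature in kelvin (278-320 K)
#' @return dynamic viscosity of the mixture in Pa s
#' @export
#' @examples
#' solvent_viscosity(0.10, 301)
solvent_viscosity <- function(dmso_fraction, temperature_K) {
  stopifnot(is.numeric(dmso_fraction))
  if (any(dmso_fraction < 0 | dmso_fraction > 0.2)) {
    stop("solvent_viscosity(): DMSO volume fraction outside calibrated range [0, 0.2]; ",
         "the embedded calibration does not extrapolate")
  }
  water_viscosity(temperature_K) * (1 + 10 * dmso_fraction)
}

#' Solvent condition descriptor
#'
#' Bundles a DMSO volume fraction, a temperature and the corresponding dynamic
#' viscosity. The viscosity is computed from the embedded DMSO-water
#' calibration unless an explicit `viscosity_Pa_s` override is supplied, in
#' which case the override is used exactly (e.g. for measured viscosities).
#'
#' @param dmso_fraction DMSO volume fraction in \[0, 0.2\]
#' @param temperature_K temperature in kelvin
#' @param viscosity_Pa_s optional measured viscosity override in Pa s
#' @return an object of class `solvent_condition` with fields `dmso_fraction`,
#'   `temperature_K`, `viscosity_Pa_s`
#' @export
#' @examples
#' solvent_condition(0.10, 301)
solvent_condition <- function(dmso_fraction, temperature_K,
                              viscosity_Pa_s = NULL) {
  stopifnot(length(dmso_fraction) == 1, length(temperature_K) == 1)
  eta <- if (is.null(viscosity_Pa_s)) {
    solvent_viscosity(dmso_fraction, temperature_K)
  } else {
    stopifnot(is.numeric(viscosity_Pa_s), viscosity_Pa_s > 0)
    viscosity_Pa_s
  }
  structure(
    list(dmso_fraction = dmso_fraction,
         temperature_K = temperature_K,
         viscosity_Pa_s = eta),
    class = "solvent_condition"
  )
}

#' @export
print.solvent_condition <- function(x, ...) {
  cat(sprintf("Solvent condition: %.0f%% DMSO (v/v), %.1f K, eta = %.3g Pa s\n",
              100 * x$dmso_fraction, x$temperature_K, x$viscosity_Pa_s))
  invisible(x)
}

#' Spherical protein-ligand pair
#'
#' Hydrodynamic radii of the ligand and protein treated as spheres; used for
#' the diffusion-limited encounter rate.
#'
#' @param radius_ligand_A ligand radius in angstrom
#' @param radius_protein_A protein radius in angstrom
#' @return object of class `spherical_pair` with radii in metres
#' @export
#' @examples
#' spherical_pair(6, 16)
spherical_pair <- function(radius_ligand_A = 6, radius_protein_A = 16) {
  stopifnot(radius_ligand_A > 0, radius_protein_A > 0)
  structure(
    list(radius_ligand_m = angstrom_to_m(radius_ligand_A),
         radius_protein_m = angstrom_to_m(radius_protein_A)),
    class = "spherical_pair"
  )
}

#' Dimensionless prefactor of the diffusion-limited on-rate
#'
#' For two spheres with Stokes-Einstein diffusion coefficients, the
#' Smoluchowski rate 4 pi (R_L + R_P)(D_L + D_P) reduces to
#' (2/3)(2 + R_L/R_P + R_P/R_L) * k_B T / eta. This returns the dimensionless
#' prefactor, which is symmetric in the two radii and minimal (8/3) for equal
#' radii.
#'
#' @param pair a [spherical_pair()]
#' @return dimensionless prefactor (multiple of k_B T / eta)
#' @export
#' @examples
#' diffusion_prefactor(spherical_pair(6, 16))  # 3.36
diffusion_prefactor <- function(pair) {
  stopifnot(inherits(pair, "spherical_pair"))
  # evaluate in sorted order so the result is exactly symmetric in the radii
  r1 <- min(pair$radius_ligand_m, pair$radius_protein_m)
  r2 <- max(pair$radius_ligand_m, pair$radius_protein_m)
  (2 / 3) * (2 + r1 / r2 + r2 / r1)
}

#' Diffusion-limited association rate of two spheres
#'
#' Computes k_onD = prefactor * k_B T / eta, converted to molar units by
#' multiplying with Avogadro's number and 10^3 L/m^3. The product
#' k_onD * eta (the slope of k_onD against inverse viscosity) is also
#' returned in the conventional unit (10^6 M^-1 s^-1) Pa s, directly
#' comparable to slopes of observed on-rates against 1/eta.
#'
#' @param pair a [spherical_pair()]
#' @param condition a [solvent_condition()]
#' @return list with `prefactor` (dimensionless), `k_on_D` (M^-1 s^-1),
#'   `slope_1e6` (k_on_D * eta in (10^6 M^-1 s^-1) Pa s)
#' @export
#' @examples
#' diffusion_limited_kon(spherical_pair(6, 16), solvent_condition(0, 301))
diffusion_limited_kon <- function(pair, condition) {
  stopifnot(inherits(condition, "solvent_condition"))
  pref <- diffusion_prefactor(pair)
  # k_B*T/eta has units m^3/s per pair; x N_A x 1e3 L/m^3 -> M^-1 s^-1
  kon_d <- pref * bk_constants$k_B * condition$temperature_K /
    condition$viscosity_Pa_s * bk_constants$N_A * 1e3
  list(prefactor = pref,
       k_on_D = kon_d,
       slope_1e6 = kon_d * condition$viscosity_Pa_s / 1e6)
}
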