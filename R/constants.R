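# Physical constants (CODATA 2018) and unit conversions used across modules.

#' Physical constants used by bindkin
#'
#' CODATA 2018 values for the Boltzmann constant, Avogadro number and molar
#' gas constant, plus the 15N gyromagnetic ratio and the calorie.
#'
#' @format A named list:
#' \describe{
#'   \item{k_B}{Boltzmann constant, J/K}
#'   \item{N_A}{Avogadro constant, 1/mol}
#'   \item{R}{molar gas constant, J/(mol K)}
#'   \item{gamma_15N}{15N gyromagnetic ratio magnitude, rad/(s T)}
#'   \item{joule_per_ucal}{joules per microcalorie}
#' }
#' @export
bk_constants <- list(
  k_B = 1.380649e-23,
  N_A = 6.02214076e23,
  R = 8.31446261815324,
  gamma_15N = 2.7126e7,   # magnitude; sign irrelevant for |delta omega|
  joule_per_ucal = 4.184e-6
)

#' @keywords internal
angstrom_to_m <- function(x) x * 1e-10

#' Convert a 15N chemical-shift difference from ppm to rad/s
#'
#' The shift difference between exchanging states scales linearly with the
#' static field, so a single ppm value serves dispersion data recorded at
#' several spectrometers.
#'
#' @param ppm chemical shift difference in ppm
#' @param field_T static magnetic field strength in tesla
#' @return angular frequency difference in rad/s
#' @export
#' @examples
#' ppm_to_rad_s(2, 11.7)
ppm_to_rad_s <- function(ppm, field_T) {
  stopifnot(is.numeric(ppm), is.numeric(field_T), field_T > 0)
  ppm * 1e-6 * bk_constants$gamma_15N * field_T
}
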