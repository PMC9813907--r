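# Single-site ITC forward model: perfusion-cell dilution bookkeeping, the
# Wiseman isotherm with binding-competent fraction n, and the derived
# thermodynamic profile.

#' ITC titration protocol
#'
#' Injection schedule and concentrations for a perfusion (overflow) cell
#' titration. Defaults mirror the study protocol: 150 uM protein in a 200 uL
#' cell, 1.5 mM ligand in the syringe, two concatenated 10-injection runs of
#' 0.4 uL + 9 x 4 uL at 301 K, with the first (0.4 uL) injection of each run
#' flagged for discard.
#'
#' @param cell_volume_uL active cell volume V0 in microlitres
#' @param injection_volumes_uL vector of injection volumes in microlitres
#' @param syringe_ligand_conc_M total ligand concentration in the syringe (M)
#' @param cell_protein_conc_M initial total protein concentration in the cell (M)
#' @param temperature_K temperature in kelvin
#' @param discard_idx indices of injections excluded from fitting (initial
#'   small injections); their dilution effect is still tracked
#' @return object of class `titration_protocol`
#' @export
#' @examples
#' titration_protocol()
titration_protocol <- function(cell_volume_uL = 200,
                               injection_volumes_uL = rep(c(0.4, rep(4, 9)), 2),
                               syringe_ligand_conc_M = 1.5e-3,
                               cell_protein_conc_M = 150e-6,
                               temperature_K = 301,
                               discard_idx = which(injection_volumes_uL ==
                                                     min(injection_volumes_uL))) {
  stopifnot(cell_volume_uL > 0, all(injection_volumes_uL > 0),
            syringe_ligand_conc_M > 0, cell_protein_conc_M > 0)
  if (sum(injection_volumes_uL) >= cell_volume_uL) {
    stop("titration_protocol(): total injected volume must be below the cell volume")
  }
  if (length(discard_idx) &&
      any(discard_idx < 1 | discard_idx > length(injection_volumes_uL))) {
    stop("titration_protocol(): discard_idx outside the injection schedule")
  }
  structure(
    list(cell_volume_L = cell_volume_uL * 1e-6,
         injection_volumes_L = injection_volumes_uL * 1e-6,
         syringe_ligand_conc_M = syringe_ligand_conc_M,
         cell_protein_conc_M = cell_protein_conc_M,
         temperature_K = temperature_K,
         discard_idx = as.integer(discard_idx)),
    class = "titration_protocol"
  )
}

#' @export
print.titration_protocol <- function(x, ...) {
  cat(sprintf(
    "ITC protocol: %d injections into %.0f uL cell, P0 = %.0f uM, [L]syr = %.2f mM, %.0f K (%d discarded)\n",
    length(x$injection_volumes_L), x$cell_volume_L * 1e6,
    x$cell_protein_conc_M * 1e6, x$syringe_ligand_conc_M * 1e3,
    x$temperature_K, length(x$discard_idx)))
  invisible(x)
}

#' Total cell concentrations along a titration
#'
#' Perfusion-cell dilution bookkeeping: each injection of volume v displaces
#' cell content, scaling existing concentrations by (1 - v/V0), and delivers
#' ligand (v/V0) * \[L\]syringe. Protein decreases and ligand increases
#' monotonically.
#'
#' @param protocol a [titration_protocol()]
#' @param injection_index injection number, 0 (before any injection) up to the
#'   number of injections; defaults to the full schedule
#' @return data.frame with columns `injection`, `P_M` (total protein, M),
#'   `L_M` (total ligand, M), one row per requested index
#' @export
cell_concentrations <- function(protocol,
                                injection_index = seq_along(protocol$injection_volumes_L)) {
  stopifnot(inherits(protocol, "titration_protocol"))
  n_inj <- length(protocol$injection_volumes_L)
  if (any(injection_index < 0 | injection_index > n_inj)) {
    stop("cell_concentrations(): injection_index outside the schedule (0..",
         n_inj, ")")
  }
  dil <- 1 - protocol$injection_volumes_L / protocol$cell_volume_L
  p <- protocol$cell_protein_conc_M * cumprod(dil)
  l <- numeric(n_inj)
  l_cur <- 0
  for (i in seq_len(n_inj)) {
    l_cur <- l_cur * dil[i] +
      protocol$injection_volumes_L[i] / protocol$cell_volume_L *
        protocol$syringe_ligand_conc_M
    l[i] <- l_cur
  }
  p <- c(protocol$cell_protein_conc_M, p)
  l <- c(0, l)
  data.frame(injection = injection_index,
             P_M = p[injection_index + 1L],
             L_M = l[injection_index + 1L])
}

#' Single-site binding model parameters
#'
#' @param delta_H_J_mol binding enthalpy in J/mol
#' @param K_d_M dissociation constant in M (> 0)
#' @param n_competent fraction of binding-competent protein, in (0, 1.5\]
#' @param Q_off_J per-injection heat-of-mixing offset in joules
#' @return object of class `binding_model_params`
#' @export
binding_model_params <- function(delta_H_J_mol, K_d_M, n_competent = 1,
                                 Q_off_J = 0) {
  stopifnot(K_d_M > 0, n_competent > 0, n_competent <= 1.5)
  structure(
    list(delta_H_J_mol = delta_H_J_mol, K_d_M = K_d_M,
         n_competent = n_competent, Q_off_J = Q_off_J),
    class = "binding_model_params"
  )
}

# Complex concentration [PL] from the single-site quadratic with
# alpha = n*P + L + Kd. Numerically stable root (multiply out the subtraction).
complex_concentration <- function(P_M, L_M, K_d_M, n_competent) {
  np <- n_competent * P_M
  alpha <- np + L_M + K_d_M
  disc <- alpha^2 - 4 * np * L_M
  if (any(disc < -1e-30)) {
    stop("complex_concentration(): negative discriminant; invalid inputs")
  }
  disc <- pmax(disc, 0)
  # (alpha - sqrt(disc))/2 rewritten to avoid cancellation when Kd is small
  2 * np * L_M / (alpha + sqrt(disc))
}

#' Predicted per-injection ITC heats
#'
#' Forward model for the observed heat of each injection. The cumulative heat
#' content of the cell after injection i is Q_i = dH * V0 * \[PL\]_i with the
#' bound concentration from the single-site quadratic
#' (alpha - sqrt(alpha^2 - 4 n P_i L_i))/2, alpha = n P_i + L_i + K_d. The
#' observable for injection i applies the standard perfusion displacement
#' correction,
#' dQ_i = Q_i - Q_(i-1) + (V_i/V0) * (Q_i + Q_(i-1))/2 + Q_off.
#'
#' @param params a [binding_model_params()]
#' @param protocol a [titration_protocol()]
#' @param keep `"retained"` (default) drops the injections in
#'   `protocol$discard_idx`; `"all"` returns every injection
#' @return numeric vector of per-injection heats in joules
#' @export
predicted_injection_heats <- function(params, protocol, keep = c("retained", "all")) {
  stopifnot(inherits(params, "binding_model_params"),
            inherits(protocol, "titration_protocol"))
  keep <- match.arg(keep)
  conc <- cell_concentrations(protocol,
                              0:length(protocol$injection_volumes_L))
  pl <- complex_concentration(conc$P_M, conc$L_M, params$K_d_M,
                              params$n_competent)
  q_cum <- params$delta_H_J_mol * protocol$cell_volume_L * pl
  i <- seq_along(protocol$injection_volumes_L)
  vratio <- protocol$injection_volumes_L / protocol$cell_volume_L
  dq <- q_cum[i + 1L] - q_cum[i] +
    vratio * (q_cum[i + 1L] + q_cum[i]) / 2 + params$Q_off_J
  if (keep == "retained" && length(protocol$discard_idx)) {
    dq <- dq[-protocol$discard_idx]
  }
  dq
}

#' Thermodynamic profile from K_d and binding enthalpy
#'
#' dG = R T ln(K_d / 1 M) and -T dS = dG - dH, so the identity
#' dG = dH + (-T dS) holds exactly by construction.
#'
#' @param K_d_M dissociation constant in M
#' @param delta_H_J_mol binding enthalpy in J/mol
#' @param temperature_K temperature in kelvin
#' @return object of class `thermodynamic_profile` with fields in J/mol
#' @export
#' @examples
#' thermodynamic_profile(5.6e-6, -49.1e3, 301)
thermodynamic_profile <- function(K_d_M, delta_H_J_mol, temperature_K) {
  stopifnot(K_d_M > 0, temperature_K > 0)
  dg <- bk_constants$R * temperature_K * log(K_d_M)
  structure(
    list(delta_G_J_mol = dg,
         delta_H_J_mol = delta_H_J_mol,
         minus_T_delta_S_J_mol = dg - delta_H_J_mol,
         K_d_M = K_d_M,
         temperature_K = temperature_K),
    class = "thermodynamic_profile"
  )
}

#' @export
print.thermodynamic_profile <- function(x, ...) {
  cat(sprintf(
    "Thermodynamic profile at %.0f K: dG = %.1f, dH = %.1f, -TdS = %.1f kJ/mol; Kd = %.2g uM\n",
    x$temperature_K, x$delta_G_J_mol / 1e3, x$delta_H_J_mol / 1e3,
    x$minus_T_delta_S_J_mol / 1e3, x$K_d_M * 1e6))
  invisible(x)
}
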