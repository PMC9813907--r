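# Global (simultaneous) weighted least-squares fit of the single-site model
# to replicate ITC titrations: dH, Kd, n shared across replicates, Q_off per
# replicate.

#' ITC titration experiment
#'
#' Observed per-injection heats for one titration, paired with its protocol.
#' Heats correspond to the retained injections only (the protocol's
#' `discard_idx` injections are excluded, but their dilution is tracked).
#'
#' @param protocol a [titration_protocol()]
#' @param heats_J observed heats in joules, one per retained injection
#' @param sigma_J measurement uncertainty per heat (joules); scalar or vector
#' @return object of class `titration_experiment`
#' @export
titration_experiment <- function(protocol, heats_J, sigma_J) {
  stopifnot(inherits(protocol, "titration_protocol"))
  n_ret <- length(protocol$injection_volumes_L) - length(protocol$discard_idx)
  if (length(heats_J) != n_ret) {
    stop("titration_experiment(): expected ", n_ret,
         " retained heats, got ", length(heats_J))
  }
  sigma_J <- rep_len(sigma_J, length(heats_J))
  stopifnot(all(sigma_J > 0))
  structure(
    list(protocol = protocol, heats_J = heats_J, sigma_J = sigma_J),
    class = "titration_experiment"
  )
}

#' @export
print.titration_experiment <- function(x, ...) {
  cat(sprintf("ITC experiment: %d retained heats, range %.2f to %.2f ucal\n",
              length(x$heats_J),
              min(x$heats_J) / bk_constants$joule_per_ucal,
              max(x$heats_J) / bk_constants$joule_per_ucal))
  invisible(x)
}

itc_residuals <- function(par, experiments, n_fixed = NULL) {
  # par (all O(1) for a well-conditioned Jacobian): dH in 100 kJ/mol,
  # log10 Kd, [n unless fixed], then one Q_off (ucal) per experiment
  fix_n <- !is.null(n_fixed)
  n_comp <- if (fix_n) n_fixed else par[3]
  off0 <- if (fix_n) 2L else 3L
  unlist(lapply(seq_along(experiments), function(j) {
    e <- experiments[[j]]
    p <- binding_model_params(par[1] * 1e5, 10^par[2], n_comp,
                              par[off0 + j] * bk_constants$joule_per_ucal)
    (predicted_injection_heats(p, e$protocol) - e$heats_J) / e$sigma_J
  }))
}

#' Fit the single-site binding model to replicate ITC titrations
#'
#' Simultaneous weighted least squares across all experiments: the binding
#' enthalpy, dissociation constant and competent fraction n are global, while
#' the heat-of-mixing offset Q_off is per experiment. Optimization uses
#' Levenberg-Marquardt ([minpack.lm::nls.lm]) in (dH, log10 Kd, n, Q_off...)
#' with multi-start over log10 Kd in \[-8, -3\]; ties are broken by the lowest
#' chi-square. Parameter uncertainties are symmetric, from the curvature
#' (covariance) at the optimum.
#'
#' A `c_value` diagnostic (n P0 / Kd at the optimum) is reported; fits with
#' c << 1 are flagged as weakly identifiable via `identifiable = FALSE`.
#'
#' @param experiments list of [titration_experiment()] (or a single one)
#' @param n_fixed optionally fix the competent fraction n to this value
#' @return object of class `itc_fit`: list with `params`
#'   ([binding_model_params()] at the optimum, Q_off of the first experiment),
#'   `Q_off_J` per experiment, `se` (named standard errors: delta_H_J_mol,
#'   log10_K_d, K_d_M, n_competent), `chi2`, `dof`, `c_value`, `identifiable`,
#'   `profile` (thermodynamic profile at the protocol temperature), `fit`
#'   (the nls.lm object)
#' @export
fit_single_site <- function(experiments, n_fixed = NULL) {
  if (inherits(experiments, "titration_experiment")) {
    experiments <- list(experiments)
  }
  stopifnot(length(experiments) >= 1,
            all(vapply(experiments, inherits, TRUE, "titration_experiment")))
  n_exp <- length(experiments)
  n_pts <- sum(vapply(experiments, function(e) length(e$heats_J), 1L))

  # crude dH scale from the early-saturation heats of the first experiment
  e1 <- experiments[[1]]
  v <- e1$protocol$injection_volumes_L
  keep <- setdiff(seq_along(v), e1$protocol$discard_idx)
  mol_first <- v[keep[1]] * e1$protocol$syringe_ligand_conc_M
  dh0 <- min(e1$heats_J[1] / mol_first / 1e5, -0.01)  # 100 kJ/mol units

  fix_n <- !is.null(n_fixed)
  lower <- c(-100, -8, if (!fix_n) 1e-3, rep(-250, n_exp))
  upper <- c(100, -3, if (!fix_n) 1.5, rep(250, n_exp))

  best <- NULL
  for (lk in seq(-8, -3, by = 1)) {
    start <- c(dh0, lk, if (!fix_n) 1, rep(0, n_exp))
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start, lower = lower, upper = upper,
        fn = itc_residuals, experiments = experiments, n_fixed = n_fixed,
        control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (is.null(fit)) next
    chi2 <- sum(fit$fvec^2)
    if (is.null(best) || chi2 < best_chi2 - 1e-12) {
      best <- fit
      best_chi2 <- chi2
    }
  }
  if (is.null(best)) {
    stop("fit_single_site(): no optimizer start converged")
  }

  par <- best$par
  n_comp <- if (fix_n) n_fixed else par[3]
  off0 <- if (fix_n) 2L else 3L
  dof <- n_pts - length(par)
  # curvature-based symmetric errors: cov = (J'J)^-1 * chi2/dof on the
  # sigma-weighted residuals
  se <- tryCatch({
    covm <- solve(best$hessian) * best_chi2 / dof
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) rep(NA_real_, length(par)))
  kd <- 10^par[2]
  se_kd <- se[2] * log(10) * kd  # delta method on log10 Kd
  c_value <- n_comp * experiments[[1]]$protocol$cell_protein_conc_M / kd
  identifiable <- is.finite(c_value) && c_value > 1
  if (!identifiable) {
    warning("fit_single_site(): c-value ", signif(c_value, 2),
            " <= 1; Kd weakly identifiable from this isotherm")
  }
  structure(
    list(params = binding_model_params(
           par[1] * 1e5, kd, n_comp,
           par[off0 + 1L] * bk_constants$joule_per_ucal),
         Q_off_J = par[off0 + seq_len(n_exp)] * bk_constants$joule_per_ucal,
         se = c(delta_H_J_mol = se[1] * 1e5, log10_K_d = se[2], K_d_M = se_kd,
                n_competent = if (fix_n) 0 else se[3]),
         chi2 = best_chi2, dof = dof, c_value = c_value,
         identifiable = identifiable,
         profile = thermodynamic_profile(kd, par[1] * 1e5,
                                         experiments[[1]]$protocol$temperature_K),
         fit = best),
    class = "itc_fit"
  )
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("Global single-site ITC fit\n")
  cat(sprintf("  dH  = %.1f +/- %.1f kJ/mol\n",
              x$params$delta_H_J_mol / 1e3, x$se[["delta_H_J_mol"]] / 1e3))
  cat(sprintf("  Kd  = %.2f +/- %.2f uM\n",
              x$params$K_d_M * 1e6, x$se[["K_d_M"]] * 1e6))
  cat(sprintf("  n   = %.3f +/- %.3f\n",
              x$params$n_competent, x$se[["n_competent"]]))
  cat(sprintf("  chi2 = %.1f on %d dof (c = %.0f)\n", x$chi2, x$dof, x$c_value))
  invisible(x)
}
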