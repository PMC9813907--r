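# Synthetic-data generators emulating the experimental protocols: replicate
# ITC titrations, two-field CPMG dispersion data, and an internally
# consistent four-condition DMSO study.

#' Default per-residue shift differences (ppm)
#'
#' Synthetic stand-ins for the spectrally measured free-vs-bound 15N shift
#' differences of the three reporter residues; the true values are not
#' tabulated, so plausible magnitudes spanning small-to-large dispersion
#' steps are used.
#' @export
default_delta_omega_ppm <- c(I145 = 2.0, L147 = 1.0, E185 = 3.0)

#' Simulate replicate ITC titrations
#'
#' Observed heats are the single-site forward model plus iid Gaussian noise.
#' Deterministic under a fixed seed.
#'
#' @param truth a [binding_model_params()]
#' @param protocol a [titration_protocol()] (default: the study protocol)
#' @param noise_sigma_ucal Gaussian heat noise per injection, microcalories
#'   (default 0.2)
#' @param n_replicates number of replicate titrations (default 3)
#' @param seed integer seed
#' @return list of [titration_experiment()]
#' @export
generate_itc_dataset <- function(truth, protocol = titration_protocol(),
                                 noise_sigma_ucal = 0.2, n_replicates = 3,
                                 seed = 1) {
  stopifnot(inherits(truth, "binding_model_params"), n_replicates >= 1,
            noise_sigma_ucal >= 0)
  sigma_J <- noise_sigma_ucal * bk_constants$joule_per_ucal
  model <- predicted_injection_heats(truth, protocol)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lapply(seq_len(n_replicates), function(i) {
    titration_experiment(
      protocol,
      heats_J = model + stats::rnorm(length(model), 0, sigma_J),
      sigma_J = max(sigma_J, 1e-12))
  })
}

#' Simulate a two-field CPMG dispersion data set
#'
#' R2eff values are the Carver-Richards forward model plus iid Gaussian
#' noise; repeated nu_cpmg entries in a schedule are drawn independently.
#' Each residue's ppm shift difference is converted to rad/s at each field.
#'
#' @param k_ex_s1 true exchange rate sum, 1/s
#' @param p_F true free-state population
#' @param delta_omega_ppm named vector of per-residue shift differences (ppm)
#' @param fields_T static fields in tesla (default c(11.7, 14.1))
#' @param r20_s1 exchange-free rate used for every profile (default 12)
#' @param noise_sigma_s1 Gaussian R2eff noise, 1/s (default 0.2)
#' @param seed integer seed
#' @return list of [dispersion_profile()], one per residue x field
#' @export
generate_cpmg_dataset <- function(k_ex_s1, p_F,
                                  delta_omega_ppm = default_delta_omega_ppm,
                                  fields_T = c(11.7, 14.1),
                                  r20_s1 = 12, noise_sigma_s1 = 0.2,
                                  seed = 1) {
  stopifnot(k_ex_s1 > 0, p_F > 0, p_F < 0.5, noise_sigma_s1 >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  out <- list()
  for (field in fields_T) {
    nu <- cpmg_nu_schedule(field)
    for (res in names(delta_omega_ppm)) {
      dw <- ppm_to_rad_s(delta_omega_ppm[[res]], field)
      model <- carver_richards_r2eff(r20_s1, k_ex_s1, p_F, dw, nu)
      out[[length(out) + 1L]] <- dispersion_profile(
        residue = res, field_T = field,
        delta_omega_ppm = delta_omega_ppm[[res]],
        nu_cpmg_Hz = nu,
        r2eff_s1 = model + stats::rnorm(length(nu), 0, noise_sigma_s1),
        sigma_s1 = max(noise_sigma_s1, 1e-6))
    }
  }
  out
}

#' Simulate the full four-condition viscosity study
#'
#' Builds an internally consistent "truth" across DMSO volume fractions 0,
#' 2, 6 and 10% at 301 K and generates ITC and CPMG data for each condition:
#'
#' * K_d per condition: 5.6, 6.5, 7.3, 13 uM; binding enthalpies near
#'   -49 kJ/mol.
#' * true k_on values lie exactly on a line in 1/eta with the given slope
#'   and intercept (defaults 0.009 and -4.0 in 10^6 /M/s units, chosen so
#'   the end-member on-rates match the observed range);
#' * k_off = k_on * K_d and k_ex = k_off / p_F with p_F = 1 - p_B
#'   (p_B = 0.95, the target saturation);
#' * the exchange-free rate R20 scales with the relative solvent viscosity,
#'   mimicking the slower rotational diffusion at higher DMSO.
#'
#' @param seed integer seed (split internally per condition and data type)
#' @param slope_1e6 true slope of k_on vs 1/eta, (10^6 /M/s) Pa s
#' @param intercept_1e6 true intercept, 10^6 /M/s
#' @param p_B bound-state population (default 0.95)
#' @param temperature_K temperature (default 301)
#' @param noise_sigma_ucal ITC heat noise (default 0.2 ucal)
#' @param noise_sigma_s1 CPMG R2eff noise (default 0.2 /s)
#' @param r20_base_s1 exchange-free rate at 0% DMSO (default 12)
#' @return object of class `study_bundle`: per condition a list with
#'   `condition`, `itc_truth`, `k_ex_s1`, `p_F`, `k_on_true_M1s1`,
#'   `itc_experiments`, `cpmg_profiles`; plus `truth` (data.frame summary)
#'   and the generator settings
#' @export
generate_full_study <- function(seed = 1, slope_1e6 = 0.009,
                                intercept_1e6 = -4.0, p_B = 0.95,
                                temperature_K = 301,
                                noise_sigma_ucal = 0.2,
                                noise_sigma_s1 = 0.2,
                                r20_base_s1 = 12) {
  fractions <- c(0, 0.02, 0.06, 0.10)
  kd_uM <- c(5.6, 6.5, 7.3, 13)
  dh_kJ <- c(-49.1, -49.8, -49.8, -49.4)
  p_F <- 1 - p_B

  conditions <- vector("list", length(fractions))
  truth <- data.frame(dmso_fraction = fractions, K_d_uM = kd_uM,
                      delta_H_kJ_mol = dh_kJ, k_on_1e6 = NA_real_,
                      k_off_s1 = NA_real_, k_ex_s1 = NA_real_,
                      eta_Pa_s = NA_real_)
  for (i in seq_along(fractions)) {
    cond <- solvent_condition(fractions[i], temperature_K)
    kon_1e6 <- slope_1e6 / cond$viscosity_Pa_s + intercept_1e6
    if (kon_1e6 <= 0) {
      stop("generate_full_study(): chosen line gives non-positive k_on at ",
           fractions[i] * 100, "% DMSO")
    }
    kon <- kon_1e6 * 1e6
    koff <- kon * kd_uM[i] * 1e-6
    kex <- koff / p_F
    itc_truth <- binding_model_params(dh_kJ[i] * 1e3, kd_uM[i] * 1e-6, 1, 0)
    conditions[[i]] <- list(
      condition = cond,
      itc_truth = itc_truth,
      k_ex_s1 = kex, p_F = p_F, k_on_true_M1s1 = kon,
      itc_experiments = generate_itc_dataset(
        itc_truth, titration_protocol(temperature_K = temperature_K),
        noise_sigma_ucal = noise_sigma_ucal, seed = seed * 100L + i),
      cpmg_profiles = generate_cpmg_dataset(
        kex, p_F, r20_s1 = r20_base_s1 * (1 + 10 * fractions[i]),
        noise_sigma_s1 = noise_sigma_s1, seed = seed * 100L + 50L + i))
    truth$k_on_1e6[i] <- kon_1e6
    truth$k_off_s1[i] <- koff
    truth$k_ex_s1[i] <- kex
    truth$eta_Pa_s[i] <- cond$viscosity_Pa_s
  }
  structure(
    list(conditions = conditions, truth = truth, seed = seed,
         slope_1e6 = slope_1e6, intercept_1e6 = intercept_1e6, p_B = p_B,
         temperature_K = temperature_K),
    class = "study_bundle"
  )
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf(
    "Synthetic viscosity study: %d conditions, true slope %.4f (10^6/M/s) Pa s, seed %d\n",
    length(x$conditions), x$slope_1e6, x$seed))
  print(x$truth, digits = 4)
  invisible(x)
}
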