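# End-to-end pipeline: ITC fits per condition -> global CPMG fits per
# condition -> rate constants -> k_on vs 1/eta regression -> encounter
# success rate, with one top-level seed and a machine-readable report.

#' Pipeline configuration
#'
#' Builds a validated configuration list with the defaults matching the
#' study conditions. Any field can be overridden; unknown fields error.
#'
#' @param ... overrides for the defaults:
#' \describe{
#'   \item{seed}{top-level seed; all stage seeds derive from it (default 1)}
#'   \item{solvent.temperature_K}{temperature, K (default 301)}
#'   \item{geometry.R_L_angstrom,geometry.R_P_angstrom}{sphere radii (6, 16)}
#'   \item{cpmg.mode}{`"fixed"` or `"free"` population fit (default "fixed")}
#'   \item{cpmg.fixed_pB}{bound population for fixed fits (default 0.95)}
#'   \item{cpmg.mc_sets}{Monte Carlo sets for CPMG errors (default 1000)}
#'   \item{regression.n_mc}{Monte Carlo sets for the slope (default 100000)}
#'   \item{regression.intercept}{fit an intercept (default TRUE)}
#'   \item{f_test.alpha}{model-selection threshold (default 0.001)}
#'   \item{study.slope_1e6,study.intercept_1e6}{truth line for simulation}
#'   \item{study.noise_sigma_ucal,study.noise_sigma_s1}{noise levels}
#' }
#' @return named list of class `pipeline_config`
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    solvent.temperature_K = 301,
    geometry.R_L_angstrom = 6,
    geometry.R_P_angstrom = 16,
    cpmg.mode = "fixed",
    cpmg.fixed_pB = 0.95,
    cpmg.mc_sets = 1000L,
    regression.n_mc = 100000L,
    regression.intercept = TRUE,
    f_test.alpha = 0.001,
    study.slope_1e6 = 0.009,
    study.intercept_1e6 = -4.0,
    study.noise_sigma_ucal = 0.2,
    study.noise_sigma_s1 = 0.2
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("pipeline_config(): unknown field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  stopifnot(cfg$cpmg.mode %in% c("fixed", "free"))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys use the same dotted names as [pipeline_config()].
#'
#' @param path YAML file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Run the full binding-kinetics pipeline
#'
#' Executes the complete analysis chain on a four-condition study: fit the
#' single-site model to each condition's ITC triplicate, globally fit the
#' Carver-Richards model to each condition's two-field dispersion data
#' (with flat-model F-test), derive k_off and k_on, regress k_on against
#' inverse viscosity, and compare with the diffusion-limited slope to obtain
#' the encounter success rate. If `study` is NULL a synthetic study is
#' generated from the configuration's truth line and seed.
#'
#' Any stage failure is re-raised with the stage and condition named.
#'
#' @param config a [pipeline_config()] (or path to a YAML file)
#' @param study optionally a pre-built `study_bundle` (e.g. from
#'   [generate_full_study()] or assembled from measured data)
#' @param mc_errors run the CPMG Monte Carlo error estimation (default TRUE;
#'   the regression always uses Monte Carlo)
#' @return report list of class `pipeline_report` with elements `seed`,
#'   `config_hash`, `conditions` (per-condition thermodynamics, exchange
#'   parameters, rate constants and F-test), `regression`, `diffusion`,
#'   `success_rate`
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL,
                         mc_errors = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))

  stage <- function(name, cond, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed",
           if (!is.null(cond)) paste0(" at condition ", cond) else "",
           ": ", conditionMessage(e), call. = FALSE)
    })
  }

  if (is.null(study)) {
    study <- stage("simulate", NULL, generate_full_study(
      seed = config$seed,
      slope_1e6 = config$study.slope_1e6,
      intercept_1e6 = config$study.intercept_1e6,
      p_B = config$cpmg.fixed_pB,
      temperature_K = config$solvent.temperature_K,
      noise_sigma_ucal = config$study.noise_sigma_ucal,
      noise_sigma_s1 = config$study.noise_sigma_s1))
  }
  stopifnot(inherits(study, "study_bundle"))

  rates <- list()
  cond_reports <- list()
  for (i in seq_along(study$conditions)) {
    cd <- study$conditions[[i]]
    label <- sprintf("%.0f%%", 100 * cd$condition$dmso_fraction)

    itc <- stage("fit-itc", label, fit_single_site(cd$itc_experiments))
    cpmg <- stage("fit-cpmg", label, fit_dispersion_global(
      cd$cpmg_profiles, mode = config$cpmg.mode,
      fixed_pB = config$cpmg.fixed_pB))
    flat <- fit_dispersion_flat(cd$cpmg_profiles)
    ftest <- f_test_model_selection(cpmg$chi2, cpmg$dof, flat$chi2, flat$dof,
                                    alpha = config$f_test.alpha)
    mc <- NULL
    if (mc_errors) {
      mc <- stage("mc-errors", label, monte_carlo_uncertainty(
        cpmg, n_sets = config$cpmg.mc_sets, seed = config$seed * 1000L + i))
    }
    sigma_kex <- if (!is.null(mc)) mc$sd[["k_ex_s1"]] else 0
    sigma_pf <- if (!is.null(mc) && cpmg$mode == "free") mc$sd[["p_F"]] else 0

    rk <- stage("derive-rates", label, derive_rate_constants(
      cpmg$k_ex_s1, cpmg$p_F, itc$params$K_d_M,
      sigma_k_ex = sigma_kex, sigma_p_F = sigma_pf,
      sigma_K_d = itc$se[["K_d_M"]], condition = cd$condition))
    rates[[i]] <- rk

    cond_reports[[i]] <- list(
      dmso_fraction = cd$condition$dmso_fraction,
      viscosity = list(value = cd$condition$viscosity_Pa_s, units = "Pa s"),
      thermodynamics = list(
        delta_H_kJ_mol = list(value = itc$params$delta_H_J_mol / 1e3,
                              sigma = itc$se[["delta_H_J_mol"]] / 1e3,
                              units = "kJ/mol"),
        K_d_uM = list(value = itc$params$K_d_M * 1e6,
                      sigma = itc$se[["K_d_M"]] * 1e6, units = "uM"),
        n_competent = list(value = itc$params$n_competent,
                           sigma = itc$se[["n_competent"]], units = "1"),
        delta_G_kJ_mol = list(value = itc$profile$delta_G_J_mol / 1e3,
                              sigma = NA, units = "kJ/mol"),
        minus_T_delta_S_kJ_mol = list(
          value = itc$profile$minus_T_delta_S_J_mol / 1e3,
          sigma = NA, units = "kJ/mol")),
      exchange = list(
        k_ex_s1 = list(value = cpmg$k_ex_s1, sigma = sigma_kex, units = "1/s"),
        p_B = list(value = cpmg$p_B, sigma = sigma_pf, units = "1"),
        mode = cpmg$mode,
        chi2 = cpmg$chi2, dof = cpmg$dof,
        f_test = list(F = ftest$F, p_value = ftest$p_value,
                      selected = ftest$selected)),
      rates = list(
        k_off_s1 = list(value = rk$k_off_s1, sigma = rk$sigma_k_off_s1,
                        units = "1/s"),
        k_on_1e6_M1s1 = list(value = rk$k_on_M1s1 / 1e6,
                             sigma = rk$sigma_k_on_M1s1 / 1e6,
                             units = "10^6/M/s")))
  }

  reg <- stage("regression", NULL, regress_kon_vs_fluidity(
    rates, n_mc = config$regression.n_mc, seed = config$seed,
    intercept = config$regression.intercept))

  pair <- spherical_pair(config$geometry.R_L_angstrom,
                         config$geometry.R_P_angstrom)
  diff0 <- diffusion_limited_kon(
    pair, solvent_condition(0, config$solvent.temperature_K))
  sr <- stage("success-rate", NULL,
              success_rate(reg$slope_1e6, diff0$slope_1e6))

  report <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    conditions = cond_reports,
    regression = list(
      slope = list(value = reg$slope_1e6, sigma = reg$slope_sigma,
                   units = "(10^6/M/s) Pa s"),
      intercept = list(value = reg$intercept_1e6, sigma = NA,
                       units = "10^6/M/s"),
      n_mc = reg$n_mc),
    diffusion = list(
      prefactor = list(value = diff0$prefactor, sigma = NA, units = "1"),
      slope = list(value = diff0$slope_1e6, sigma = NA,
                   units = "(10^6/M/s) Pa s")),
    success_rate = list(
      rho_percent = list(value = sr$rho_percent, sigma = NA, units = "%"),
      encounters_per_success = list(value = sr$encounters_per_success,
                                    sigma = NA, units = "1")))
  class(report) <- c("pipeline_report", "list")
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Binding-kinetics pipeline report (seed ", x$seed, ")\n", sep = "")
  for (cd in x$conditions) {
    cat(sprintf(
      "  %3.0f%% DMSO: Kd = %5.1f uM, k_ex = %6.1f /s, k_on = %5.2f x10^6 /M/s [%s]\n",
      100 * cd$dmso_fraction, cd$thermodynamics$K_d_uM$value,
      cd$exchange$k_ex_s1$value, cd$rates$k_on_1e6_M1s1$value,
      cd$exchange$f_test$selected))
  }
  cat(sprintf("  slope(k_on vs 1/eta) = %.4f +/- %.4f (10^6/M/s) Pa s\n",
              x$regression$slope$value, x$regression$slope$sigma))
  cat(sprintf("  diffusion-limited slope = %.2f; rho = %.2f%% (1 success per %.0f encounters)\n",
              x$diffusion$slope$value, x$success_rate$rho_percent$value,
              x$success_rate$encounters_per_success$value))
  invisible(x)
}
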