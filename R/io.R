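# Plain-text I/O: CSV schemas for ITC heats and CPMG dispersion data, and
# JSON reports.

#' Write/read an ITC experiment as CSV
#'
#' Schema: `injection_index, volume_uL, heat_ucal, sigma_ucal`, one row per
#' retained injection (discarded initial injections are not written; their
#' volumes are part of the protocol).
#'
#' @param experiment a [titration_experiment()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_itc_csv <- function(experiment, path) {
  stopifnot(inherits(experiment, "titration_experiment"))
  pr <- experiment$protocol
  keep <- setdiff(seq_along(pr$injection_volumes_L), pr$discard_idx)
  df <- data.frame(
    injection_index = keep,
    volume_uL = pr$injection_volumes_L[keep] * 1e6,
    heat_ucal = experiment$heats_J / bk_constants$joule_per_ucal,
    sigma_ucal = experiment$sigma_J / bk_constants$joule_per_ucal)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_itc_csv
#' @param protocol the [titration_protocol()] the heats belong to; the CSV
#'   stores only retained injections, so the schedule must be supplied
#' @export
read_itc_csv <- function(path, protocol) {
  df <- utils::read.csv(path)
  need <- c("injection_index", "volume_uL", "heat_ucal", "sigma_ucal")
  if (!all(need %in% names(df))) {
    stop("read_itc_csv(): expected columns ", paste(need, collapse = ", "))
  }
  titration_experiment(
    protocol,
    heats_J = df$heat_ucal * bk_constants$joule_per_ucal,
    sigma_J = df$sigma_ucal * bk_constants$joule_per_ucal)
}

#' Write/read CPMG dispersion profiles as CSV
#'
#' Schema: `residue, field_T, delta_omega_ppm, nu_cpmg_Hz, r2eff_s1,
#' sigma_s1`; one file can hold any number of residue/field profiles.
#'
#' @param profiles list of [dispersion_profile()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_cpmg_csv <- function(profiles, path) {
  if (inherits(profiles, "dispersion_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(residue = p$residue, field_T = p$field_T,
               delta_omega_ppm = p$delta_omega_ppm,
               nu_cpmg_Hz = p$nu_cpmg_Hz,
               r2eff_s1 = p$r2eff_s1, sigma_s1 = p$sigma_s1)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cpmg_csv
#' @export
read_cpmg_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("residue", "field_T", "delta_omega_ppm", "nu_cpmg_Hz",
            "r2eff_s1", "sigma_s1")
  if (!all(need %in% names(df))) {
    stop("read_cpmg_csv(): expected columns ", paste(need, collapse = ", "))
  }
  parts <- split(df, interaction(df$residue, df$field_T, drop = TRUE))
  unname(lapply(parts, function(d) {
    dispersion_profile(d$residue[1], d$field_T[1], d$delta_omega_ppm[1],
                       d$nu_cpmg_Hz, d$r2eff_s1, d$sigma_s1)
  }))
}

#' Write a pipeline report as JSON
#'
#' @param report a list (e.g. from [run_pipeline()])
#' @param path output file
#' @return `path`, invisibly
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE,
                      simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}
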