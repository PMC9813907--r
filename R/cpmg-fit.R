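# Global Carver-Richards fit across residues and fields, nested-model F-test,
# and Monte Carlo parameter uncertainties.

cpmg_pack <- function(par, profiles, mode, fixed_pF) {
  # par layout: [k_ex_log10, (p_F if free), r20 per profile]
  k_ex <- 10^par[1]
  p_F <- if (mode == "free") par[2] else fixed_pF
  r20 <- par[(if (mode == "free") 2 else 1) + seq_along(profiles)]
  list(k_ex = k_ex, p_F = p_F, r20 = r20)
}

cpmg_residuals <- function(par, profiles, mode, fixed_pF) {
  p <- cpmg_pack(par, profiles, mode, fixed_pF)
  unlist(lapply(seq_along(profiles), function(j) {
    pr <- profiles[[j]]
    model <- carver_richards_r2eff(p$r20[j], p$k_ex, p$p_F,
                                   pr$delta_omega_rad_s, pr$nu_cpmg_Hz)
    (model - pr$r2eff_s1) / pr$sigma_s1
  }))
}

#' Global two-state exchange fit of CPMG dispersion profiles
#'
#' Fits the Carver-Richards model simultaneously to all supplied profiles
#' (residues x fields): k_ex, and p_F when `mode = "free"`, are shared
#' globally; one exchange-free rate R20 is fitted per profile; each residue's
#' shift difference is held fixed at its spectrally determined ppm value.
#' Residuals are weighted by the per-point sigmas. Optimization is
#' Levenberg-Marquardt with a multi-start grid
#' k_ex in \{100, 300, 1000, 3000\} /s x p_F in \{0.03, 0.07, 0.15\}
#' (p_F starts only in free mode); the lowest chi-square wins, ties going to
#' the smallest k_ex.
#'
#' @param profiles list of [dispersion_profile()]
#' @param mode `"fixed"`: hold p_F at `fixed_pB`'s complement; `"free"`: fit
#'   p_F globally in (0, 0.5)
#' @param fixed_pB bound-state population used when `mode = "fixed"`
#'   (default 0.95, the target saturation)
#' @param kex_starts,pf_starts multi-start grids; the defaults cover the
#'   slow-to-fast exchange range. Refits from a known optimum (e.g. Monte
#'   Carlo resampling) may pass single values
#' @return object of class `cpmg_fit`: `k_ex_s1`, `p_F`, `p_B`, `r20_s1`
#'   (named per profile), `chi2`, `dof`, `mode`, `fit` (nls.lm object),
#'   `profiles`
#' @export
fit_dispersion_global <- function(profiles, mode = c("fixed", "free"),
                                  fixed_pB = 0.95,
                                  kex_starts = c(100, 300, 1000, 3000),
                                  pf_starts = c(0.03, 0.07, 0.15)) {
  mode <- match.arg(mode)
  if (inherits(profiles, "dispersion_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, TRUE, "dispersion_profile")))
  fixed_pF <- 1 - fixed_pB
  if (mode == "fixed") stopifnot(fixed_pF > 0, fixed_pF < 0.5)
  n_pts <- sum(vapply(profiles, function(p) length(p$nu_cpmg_Hz), 1L))
  n_par <- 1L + (mode == "free") + length(profiles)
  if (n_pts <= n_par) {
    stop("fit_dispersion_global(): fewer data points (", n_pts,
         ") than parameters (", n_par, ")")
  }

  r20_start <- vapply(profiles, function(p) max(min(p$r2eff_s1), 0.5), 1)
  kex_grid <- kex_starts
  pf_grid <- if (mode == "free") pf_starts else NA_real_
  lower <- c(0, if (mode == "free") 1e-4, rep(1e-3, length(profiles)))
  upper <- c(5, if (mode == "free") 0.5 - 1e-6, rep(200, length(profiles)))

  best <- NULL
  best_chi2 <- Inf
  best_kex <- Inf
  for (k0 in kex_grid) {
    for (pf0 in pf_grid) {
      start <- c(log10(k0), if (mode == "free") pf0, r20_start)
      fit <- tryCatch(
        minpack.lm::nls.lm(
          par = start, lower = lower, upper = upper,
          fn = cpmg_residuals, profiles = profiles, mode = mode,
          fixed_pF = fixed_pF,
          control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) NULL)
      if (is.null(fit)) next
      chi2 <- sum(fit$fvec^2)
      kex_hat <- 10^fit$par[1]
      better <- chi2 < best_chi2 - 1e-9 ||
        (abs(chi2 - best_chi2) <= 1e-9 && kex_hat < best_kex)
      if (better) {
        best <- fit
        best_chi2 <- chi2
        best_kex <- kex_hat
      }
    }
  }
  if (is.null(best)) {
    stop("fit_dispersion_global(): no multi-start point converged; starts ",
         "k_ex in {", paste(kex_grid, collapse = ", "), "}")
  }
  p <- cpmg_pack(best$par, profiles, mode, fixed_pF)
  r20 <- p$r20
  names(r20) <- vapply(profiles, function(x) {
    paste0(x$residue, "@", format(x$field_T), "T")
  }, "")
  structure(
    list(k_ex_s1 = p$k_ex, p_F = p$p_F, p_B = 1 - p$p_F, r20_s1 = r20,
         chi2 = best_chi2, dof = n_pts - n_par, mode = mode,
         fit = best, profiles = profiles),
    class = "cpmg_fit"
  )
}

#' @export
print.cpmg_fit <- function(x, ...) {
  cat(sprintf("Global Carver-Richards fit (%s p_F): k_ex = %.1f /s, p_B = %.3f\n",
              x$mode, x$k_ex_s1, x$p_B))
  cat(sprintf("  %d profiles, chi2 = %.1f on %d dof\n",
              length(x$r20_s1), x$chi2, x$dof))
  invisible(x)
}

#' Nested-model F-test between exchange and flat dispersion models
#'
#' Compares the Carver-Richards exchange fit against the simpler flat model
#' (a constant R20 per profile, no exchange) using the standard F statistic
#' for nested least squares,
#' F = ((chi2_flat - chi2_ex)/(dof_flat - dof_ex)) / (chi2_ex/dof_ex).
#' The exchange model is selected iff p < `alpha`.
#'
#' @param chi2_exchange,dof_exchange chi-square and degrees of freedom of the
#'   exchange fit
#' @param chi2_flat,dof_flat chi-square and dof of the flat fit (dof_flat >
#'   dof_exchange)
#' @param alpha selection threshold (default 0.001)
#' @return list with `F`, `p_value`, `selected` (`"exchange"` or `"flat"`)
#' @export
f_test_model_selection <- function(chi2_exchange, dof_exchange,
                                   chi2_flat, dof_flat, alpha = 0.001) {
  stopifnot(dof_flat > dof_exchange, chi2_exchange >= 0, chi2_flat >= 0,
            dof_exchange > 0)
  if (chi2_exchange > chi2_flat) {
    warning("f_test_model_selection(): exchange fit has higher chi2 than ",
            "the nested flat fit; selecting the flat model")
    return(list(F = 0, p_value = 1, selected = "flat"))
  }
  fstat <- ((chi2_flat - chi2_exchange) / (dof_flat - dof_exchange)) /
    (chi2_exchange / dof_exchange)
  p <- stats::pf(fstat, dof_flat - dof_exchange, dof_exchange,
                 lower.tail = FALSE)
  list(F = fstat, p_value = p,
       selected = if (p < alpha) "exchange" else "flat")
}

#' Flat (no-exchange) fit of dispersion profiles
#'
#' Weighted mean R2eff per profile; the nested null model for
#' [f_test_model_selection()].
#'
#' @param profiles list of [dispersion_profile()]
#' @return list with `r20_s1` per profile, `chi2`, `dof`
#' @export
fit_dispersion_flat <- function(profiles) {
  if (inherits(profiles, "dispersion_profile")) profiles <- list(profiles)
  res <- lapply(profiles, function(p) {
    w <- 1 / p$sigma_s1^2
    m <- sum(w * p$r2eff_s1) / sum(w)
    list(r20 = m, chi2 = sum(w * (p$r2eff_s1 - m)^2),
         n = length(p$r2eff_s1))
  })
  list(r20_s1 = vapply(res, `[[`, 1, "r20"),
       chi2 = sum(vapply(res, `[[`, 1, "chi2")),
       dof = sum(vapply(res, `[[`, 1L, "n")) - length(profiles))
}

#' Monte Carlo uncertainties for a global dispersion fit
#'
#' Parametric bootstrap: each synthetic data set redraws every dispersion
#' point from Normal(model value, sigma), refits with the same mode and
#' settings, and the standard deviation of the refitted parameters over all
#' sets is reported. Reproducible under a fixed seed.
#'
#' @param fit a [fit_dispersion_global()] result
#' @param n_sets number of synthetic data sets (default 1000)
#' @param seed integer seed
#' @param max_failure_frac error out if more than this fraction of refits
#'   fail to converge (default 0.05)
#' @return list with `sd` (named: k_ex_s1, p_F when free), `samples`
#'   (data.frame of refitted k_ex and p_F), `n_failed`
#' @export
monte_carlo_uncertainty <- function(fit, n_sets = 1000, seed = 1,
                                    max_failure_frac = 0.05) {
  stopifnot(inherits(fit, "cpmg_fit"), n_sets >= 2)
  profiles <- fit$profiles
  model_vals <- lapply(seq_along(profiles), function(j) {
    pr <- profiles[[j]]
    carver_richards_r2eff(fit$r20_s1[j], fit$k_ex_s1, fit$p_F,
                          pr$delta_omega_rad_s, pr$nu_cpmg_Hz)
  })
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  kex <- pf <- rep(NA_real_, n_sets)
  n_failed <- 0L
  for (s in seq_len(n_sets)) {
    synth <- lapply(seq_along(profiles), function(j) {
      pr <- profiles[[j]]
      pr$r2eff_s1 <- stats::rnorm(length(model_vals[[j]]), model_vals[[j]],
                                  pr$sigma_s1)
      pr
    })
    rf <- tryCatch(
      fit_dispersion_global(synth, mode = fit$mode, fixed_pB = fit$p_B,
                            kex_starts = fit$k_ex_s1, pf_starts = fit$p_F),
      error = function(e) NULL)
    if (is.null(rf)) {
      n_failed <- n_failed + 1L
    } else {
      kex[s] <- rf$k_ex_s1
      pf[s] <- rf$p_F
    }
  }
  if (n_failed > max_failure_frac * n_sets) {
    stop("monte_carlo_uncertainty(): ", n_failed, "/", n_sets,
         " refits failed to converge")
  }
  sd_out <- c(k_ex_s1 = stats::sd(kex, na.rm = TRUE))
  if (fit$mode == "free") {
    sd_out <- c(sd_out, p_F = stats::sd(pf, na.rm = TRUE))
  }
  list(sd = sd_out,
       samples = data.frame(k_ex_s1 = kex, p_F = pf),
       n_failed = n_failed)
}

# save/restore the RNG state so seeded helpers do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
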