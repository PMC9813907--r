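# From exchange parameters to rate constants, the on-rate vs inverse
# viscosity regression, and the encounter success rate.

#' Rate constants from exchange parameters and affinity
#'
#' For ligand binding at high saturation, k_off = k_ex * p_F and
#' k_on = k_off / K_d. Uncertainties combine the k_ex, p_F and K_d errors by
#' first-order propagation.
#'
#' @param k_ex_s1 exchange rate sum, 1/s
#' @param p_F free-state population in (0, 1)
#' @param K_d_M dissociation constant, M
#' @param sigma_k_ex,sigma_p_F,sigma_K_d uncertainties (default 0)
#' @param condition optional [solvent_condition()] attached to the result
#' @return object of class `rate_constants`: `k_off_s1`, `k_on_M1s1` with
#'   `sigma_k_off_s1`, `sigma_k_on_M1s1`, plus the inputs
#' @export
#' @examples
#' derive_rate_constants(1420, 0.068, 5.6e-6)  # k_off ~ 96.6 /s, k_on ~ 17e6
derive_rate_constants <- function(k_ex_s1, p_F, K_d_M,
                                  sigma_k_ex = 0, sigma_p_F = 0,
                                  sigma_K_d = 0, condition = NULL) {
  stopifnot(p_F >= 0, p_F < 1, K_d_M > 0, k_ex_s1 >= 0)
  k_off <- k_ex_s1 * p_F
  k_on <- k_off / K_d_M
  s_koff <- sqrt((p_F * sigma_k_ex)^2 + (k_ex_s1 * sigma_p_F)^2)
  s_kon <- if (k_off > 0) {
    k_on * sqrt((s_koff / k_off)^2 + (sigma_K_d / K_d_M)^2)
  } else 0
  structure(
    list(k_off_s1 = k_off, k_on_M1s1 = k_on,
         sigma_k_off_s1 = s_koff, sigma_k_on_M1s1 = s_kon,
         k_ex_s1 = k_ex_s1, p_F = p_F, K_d_M = K_d_M,
         condition = condition),
    class = "rate_constants"
  )
}

#' @export
print.rate_constants <- function(x, ...) {
  cat(sprintf("Rate constants: k_off = %.1f +/- %.1f /s, k_on = %.2g +/- %.2g /M/s\n",
              x$k_off_s1, x$sigma_k_off_s1, x$k_on_M1s1, x$sigma_k_on_M1s1))
  invisible(x)
}

#' Weighted regression of the on-rate against inverse viscosity
#'
#' Fits k_on (in 10^6 /M/s) against 1/eta (1/(Pa s)) by weighted least
#' squares with weights 1/sigma(k_on)^2 (viscosities treated as exact), then
#' characterizes the slope uncertainty with a Monte Carlo in which each k_on
#' is redrawn from Normal(k_on, sigma) and the line refitted. The slope is in
#' (10^6 /M/s) Pa s, directly comparable to the diffusion-limited value
#' k_onD * eta.
#'
#' @param rates list of [derive_rate_constants()] results, each carrying a
#'   `condition` with its viscosity; at least 3 distinct viscosities
#' @param n_mc number of Monte Carlo data sets (default 100000)
#' @param seed integer seed for the Monte Carlo
#' @param intercept fit an intercept (default TRUE)
#' @return object of class `kon_regression`: `slope_1e6`, `intercept_1e6`,
#'   `slope_sigma` (MC standard deviation), `mc_quantiles` (2.5/50/97.5%),
#'   `points` (data.frame), `n_mc`, `seed`
#' @export
regress_kon_vs_fluidity <- function(rates, n_mc = 100000, seed = 1,
                                    intercept = TRUE) {
  stopifnot(length(rates) >= if (intercept) 3 else 2,
            all(vapply(rates, inherits, TRUE, "rate_constants")))
  eta <- vapply(rates, function(r) {
    if (is.null(r$condition)) {
      stop("regress_kon_vs_fluidity(): every rate needs a solvent condition")
    }
    r$condition$viscosity_Pa_s
  }, 1)
  if (length(unique(signif(eta, 12))) < 2) {
    stop("regress_kon_vs_fluidity(): conditions must span distinct viscosities")
  }
  x <- 1 / eta
  y <- vapply(rates, function(r) r$k_on_M1s1, 1) / 1e6
  s <- vapply(rates, function(r) r$sigma_k_on_M1s1, 1) / 1e6
  w <- if (all(s > 0)) 1 / s^2 else rep(1, length(y))

  wls <- function(yy) {
    if (intercept) {
      xb <- sum(w * x) / sum(w)
      yb <- sum(w * yy) / sum(w)
      sl <- sum(w * (x - xb) * (yy - yb)) / sum(w * (x - xb)^2)
      c(slope = sl, intercept = yb - sl * xb)
    } else {
      c(slope = sum(w * x * yy) / sum(w * x^2), intercept = 0)
    }
  }
  est <- wls(y)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  noise <- matrix(stats::rnorm(length(y) * n_mc, 0, s), nrow = length(y))
  # slope is linear in y for fixed weights: slope_s = c . y_s
  xb <- if (intercept) sum(w * x) / sum(w) else 0
  cvec <- w * (x - xb) / sum(w * (x - xb)^2)
  slopes <- est[["slope"]] + as.numeric(crossprod(cvec, noise))

  structure(
    list(slope_1e6 = est[["slope"]], intercept_1e6 = est[["intercept"]],
         slope_sigma = stats::sd(slopes),
         mc_quantiles = stats::quantile(slopes, c(0.025, 0.5, 0.975)),
         mc_mean = mean(slopes),
         points = data.frame(inv_eta = x, k_on_1e6 = y, sigma_1e6 = s),
         n_mc = n_mc, seed = seed),
    class = "kon_regression"
  )
}

#' @export
print.kon_regression <- function(x, ...) {
  cat(sprintf(
    "k_on vs 1/eta: slope = %.4f +/- %.4f (10^6/M/s) Pa s, intercept = %.2f (10^6/M/s)\n",
    x$slope_1e6, x$slope_sigma, x$intercept_1e6))
  invisible(x)
}

#' Success rate of complex formation per diffusive encounter
#'
#' Compares the observed slope of k_on against 1/eta with the slope of the
#' diffusion-limited on-rate (k_onD * eta). With r = slope_obs/slope_diff =
#' k_on/k_onD, the branching ratio of the encounter complex is
#' rho = k_s/k_dis = r/(1 - r), and 1/rho is the mean number of transient
#' encounters per successful binding event. When r << 1, rho ~ r
#' (`small_ratio_regime` flags r < 0.01, where the approximation error is
#' below 1%).
#'
#' @param slope_observed slope of k_on vs 1/eta, (10^6 /M/s) Pa s
#' @param slope_diffusion slope of k_onD vs 1/eta, same units
#' @return object of class `success_rate`: `ratio`, `rho`, `rho_percent`,
#'   `encounters_per_success`, `small_ratio_regime`
#' @export
#' @examples
#' success_rate(0.009, 8.3)  # rho ~ 0.1%
success_rate <- function(slope_observed, slope_diffusion) {
  stopifnot(slope_observed > 0, slope_diffusion > 0)
  r <- slope_observed / slope_diffusion
  if (r >= 1) {
    stop("success_rate(): observed slope exceeds the diffusion limit ",
         "(ratio >= 1)")
  }
  rho <- r / (1 - r)
  structure(
    list(ratio = r, rho = rho, rho_percent = 100 * rho,
         encounters_per_success = 1 / rho,
         small_ratio_regime = r < 0.01),
    class = "success_rate"
  )
}

#' @export
print.success_rate <- function(x, ...) {
  cat(sprintf(
    "Encounter success rate: rho = %.2f%% (%.0f encounters per binding event)\n",
    x$rho_percent, x$encounters_per_success))
  invisible(x)
}
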