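test_that("rate-constant bookkeeping reproduces the study numbers", {
  # free-population fit, 0% DMSO: k_ex = 1420 /s, p_F = 0.068 -> 96.6 /s
  rc <- derive_rate_constants(1420, 0.068, 5.6e-6)
  expect_equal(rc$k_off_s1, 96.6, tolerance = 1e-3)
  expect_equal(rc$k_on_M1s1 / 1e6, 17.25, tolerance = 1e-3)
  # k_on Kd = k_off round-trips to machine precision
  expect_equal(rc$k_on_M1s1 * rc$K_d_M, rc$k_off_s1, tolerance = 1e-14)
  expect_equal(derive_rate_constants(1000, 0, 1e-6)$k_off_s1, 0)
})

test_that("rate uncertainties follow first-order propagation", {
  rc <- derive_rate_constants(1000, 0.05, 1e-5,
                              sigma_k_ex = 20, sigma_p_F = 0.002,
                              sigma_K_d = 1e-6)
  expect_equal(rc$sigma_k_off_s1, sqrt((0.05 * 20)^2 + (1000 * 0.002)^2))
  expect_equal(rc$sigma_k_on_M1s1 / rc$k_on_M1s1,
               sqrt((rc$sigma_k_off_s1 / 50)^2 + 0.1^2))
})

test_that("two exact points give the exact line and order does not matter", {
  mk <- function(kon_1e6, eta) {
    kd <- 1e-6
    pf <- 0.5
    kex <- kon_1e6 * 1e6 * kd / pf
    derive_rate_constants(kex, pf, kd, sigma_k_ex = 0.02 * kex,
                          condition = solvent_condition(0, 301,
                                                        viscosity_Pa_s = eta))
  }
  # line k_on = 0.01 * (1/eta) + 1 through eta = 1e-3 and 2e-3
  r1 <- mk(0.01 * 1000 + 1, 1e-3)
  r2 <- mk(0.01 * 500 + 1, 2e-3)
  r3 <- mk(0.01 * 250 + 1, 4e-3)
  reg <- regress_kon_vs_fluidity(list(r1, r2, r3), n_mc = 1000, seed = 1)
  expect_equal(reg$slope_1e6, 0.01, tolerance = 1e-9)
  expect_equal(reg$intercept_1e6, 1, tolerance = 1e-9)

  reg_perm <- regress_kon_vs_fluidity(list(r3, r1, r2), n_mc = 1000, seed = 1)
  expect_equal(reg_perm$slope_1e6, reg$slope_1e6)

  # seed reproducibility of the Monte Carlo
  rega <- regress_kon_vs_fluidity(list(r1, r2, r3), n_mc = 5000, seed = 7)
  regb <- regress_kon_vs_fluidity(list(r1, r2, r3), n_mc = 5000, seed = 7)
  expect_identical(rega$slope_sigma, regb$slope_sigma)
  expect_identical(rega$mc_quantiles, regb$mc_quantiles)

  # MC mean consistent with the point estimate
  expect_lt(abs(rega$mc_mean - rega$slope_1e6), rega$slope_sigma)

  # identical viscosities are a singular design
  expect_error(regress_kon_vs_fluidity(list(r1, r1, r1)), "distinct")
})

test_that("success rate arithmetic matches the slope comparison", {
  s1 <- success_rate(0.009, 8.3)
  expect_equal(s1$rho, (0.009 / 8.3) / (1 - 0.009 / 8.3))
  expect_equal(round(s1$rho_percent, 1), 0.1)
  expect_true(s1$small_ratio_regime)

  s2 <- success_rate(0.020, 8.3)
  expect_equal(round(s2$rho_percent, 1), 0.2)
  expect_gt(s2$encounters_per_success, 400)
  expect_lt(s2$encounters_per_success, 420)

  expect_equal(success_rate(4.15, 8.3)$rho, 1)
  expect_error(success_rate(9, 8.3), "diffusion limit")

  # small-ratio approximation: rho ~ ratio with relative error ratio/(1-ratio)
  for (ratio in c(1e-4, 1e-3, 5e-3)) {
    s <- success_rate(ratio * 8.3, 8.3)
    expect_lt(abs(s$rho - s$ratio) / s$ratio, ratio / (1 - ratio) + 1e-12)
  }
})
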