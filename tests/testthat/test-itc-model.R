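test_that("perfusion-cell dilution bookkeeping follows the closed-form product", {
  pr <- titration_protocol()
  c0 <- cell_concentrations(pr, 0)
  expect_equal(c0$P_M, 150e-6)
  expect_equal(c0$L_M, 0)

  # single 4 uL injection into 200 uL: P = 150 * (1 - 4/200) = 147 uM
  pr1 <- titration_protocol(injection_volumes_uL = 4, discard_idx = integer())
  expect_equal(cell_concentrations(pr1, 1)$P_M, 147e-6)

  # full schedule vs independent product / incremental mass balance
  conc <- cell_concentrations(pr)
  v <- pr$injection_volumes_L
  expect_equal(conc$P_M, 150e-6 * cumprod(1 - v / pr$cell_volume_L))
  l <- 0
  for (i in seq_along(v)) {
    l <- l * (1 - v[i] / pr$cell_volume_L) +
      v[i] / pr$cell_volume_L * pr$syringe_ligand_conc_M
    expect_equal(conc$L_M[i], l)
  }
  expect_true(all(diff(conc$P_M) < 0))
  expect_true(all(diff(conc$L_M) > 0))
  expect_error(cell_concentrations(pr, 99), "schedule")
})

test_that("protocol validation rejects unphysical schedules", {
  expect_error(titration_protocol(cell_volume_uL = 10), "below the cell volume")
  expect_error(titration_protocol(discard_idx = 50), "discard_idx")
})

test_that("predicted heats reduce to the offset when the enthalpy is zero", {
  pr <- titration_protocol()
  p <- binding_model_params(0, 5.6e-6, 1, Q_off_J = 3e-7)
  expect_equal(predicted_injection_heats(p, pr),
               rep(3e-7, 18))
})

test_that("tight binding with ligand excess saturates at n P V0 dH", {
  # Kd -> 0: binding is stoichiometric, so the cumulative cell heat ends at
  # dH * V0 * n * P_final. Invert the documented per-injection observable
  # dq_i = Q_i - Q_(i-1) + (V_i/V0)(Q_i + Q_(i-1))/2 to recover Q_N.
  pr <- titration_protocol(discard_idx = integer())
  p <- binding_model_params(-50e3, 1e-12, 1, 0)
  heats <- predicted_injection_heats(p, pr)
  vr <- pr$injection_volumes_L / pr$cell_volume_L
  q <- 0
  for (i in seq_along(heats)) {
    q <- (heats[i] + q * (1 - vr[i] / 2)) / (1 + vr[i] / 2)
  }
  conc <- cell_concentrations(pr)
  n_inj <- length(pr$injection_volumes_L)
  q_final <- p$delta_H_J_mol * pr$cell_volume_L * conc$P_M[n_inj]
  expect_equal(q, q_final, tolerance = 1e-6)
  # bookkeeping identity: the same inversion reproduces the cumulative heat
  # for generic parameters too (exact, not just in the tight limit)
  p2 <- binding_model_params(-49.1e3, 5.6e-6, 1, 0)
  heats2 <- predicted_injection_heats(p2, pr)
  q <- 0
  for (i in seq_along(heats2)) {
    q <- (heats2[i] + q * (1 - vr[i] / 2)) / (1 + vr[i] / 2)
  }
  q_oracle <- bisect_cumulative_heats(p2, pr)
  expect_equal(q, q_oracle[n_inj], tolerance = 1e-6)
})

test_that("forward model matches an independent bisection equilibrium solver", {
  pr <- titration_protocol()
  p <- binding_model_params(-49.1e3, 5.6e-6, 1, 0)
  q_oracle <- bisect_cumulative_heats(p, pr)
  q_cum <- c(0, q_oracle)
  i <- seq_along(pr$injection_volumes_L)
  vr <- pr$injection_volumes_L / pr$cell_volume_L
  dq_oracle <- (q_cum[i + 1] - q_cum[i] + vr * (q_cum[i + 1] + q_cum[i]) / 2)
  dq_oracle <- dq_oracle[-pr$discard_idx]
  dq <- predicted_injection_heats(p, pr)
  expect_equal(dq, dq_oracle, tolerance = 1e-3)
})

test_that("heat magnitude decreases after the equivalence point for n = 1", {
  # uniform injection volumes so successive heats are comparable
  pr <- titration_protocol(injection_volumes_uL = rep(4, 20),
                           discard_idx = integer())
  p <- binding_model_params(-49.1e3, 5.6e-6, 1, 0)
  heats <- abs(predicted_injection_heats(p, pr))
  conc <- cell_concentrations(pr)
  past <- which(conc$L_M > conc$P_M)  # beyond 1:1 equivalence
  expect_true(all(diff(heats[past]) <= 1e-12))
})

test_that("thermodynamic profile reproduces the printed study values and its identity", {
  p0 <- thermodynamic_profile(5.6e-6, -49.1e3, 301)
  expect_equal(p0$delta_G_J_mol / 1e3, -30.3, tolerance = 0.1 / 30.3)
  expect_equal(p0$minus_T_delta_S_J_mol / 1e3, 18.8, tolerance = 0.1 / 18.8)

  p10 <- thermodynamic_profile(13e-6, -49.4e3, 301)
  expect_equal(p10$delta_G_J_mol / 1e3, -28.2, tolerance = 0.1 / 28.2)
  expect_equal(p10$minus_T_delta_S_J_mol / 1e3, 21.3, tolerance = 0.1 / 21.3)

  expect_equal(thermodynamic_profile(1, 123, 301)$delta_G_J_mol, 0)

  set.seed(11)
  for (i in 1:20) {
    pp <- thermodynamic_profile(10^stats::runif(1, -9, 0),
                                stats::rnorm(1, 0, 5e4),
                                stats::runif(1, 278, 320))
    expect_equal(pp$delta_G_J_mol,
                 pp$delta_H_J_mol + pp$minus_T_delta_S_J_mol,
                 tolerance = 1e-14)
  }
})
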