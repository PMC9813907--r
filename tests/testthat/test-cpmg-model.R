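test_that("intensity conversion gives the closed-form R2eff and propagated errors", {
  expect_equal(r2eff_from_intensities(1, 1, 0.040)$r2eff_s1, 0)
  expect_equal(r2eff_from_intensities(exp(-1), 1, 0.040)$r2eff_s1, 25)
  expect_error(r2eff_from_intensities(c(1, -2, 3), 1, 0.04), "point\\(s\\) 2")

  # first-order propagation vs numerical perturbation
  i0 <- 1.7
  i1 <- 0.62
  s1 <- 0.02
  s0 <- 0.015
  got <- r2eff_from_intensities(i1, i0, 0.040, sigma_intensity = s1,
                                sigma_reference = s0)$sigma_s1
  r2 <- function(ii, rr) -log(ii / rr) / 0.040
  h <- 1e-6
  d_i <- (r2(i1 + h, i0) - r2(i1 - h, i0)) / (2 * h)
  d_r <- (r2(i1, i0 + h) - r2(i1, i0 - h)) / (2 * h)
  expect_equal(got, sqrt((d_i * s1)^2 + (d_r * s0)^2), tolerance = 0.01)
})

test_that("exchange-free limits collapse to R20", {
  nus <- cpmg_nu_schedule(11.7)
  # no shift difference
  expect_equal(carver_richards_r2eff(10, 500, 0.05, 0, nus), rep(10, 10))
  # vanishing minor population
  expect_equal(carver_richards_r2eff(10, 500, 1e-7, 800, nus), rep(10, 10),
               tolerance = 1e-4)
  # infinitely fast pulsing
  expect_equal(carver_richards_r2eff(12, 377, 0.05, 1200, 1e5), 12,
               tolerance = 0.1 / 12)
})

test_that("dispersion profiles are monotonically non-increasing in nu_cpmg", {
  for (kex in c(100, 500, 2000)) {
    for (pf in c(0.03, 0.1, 0.3)) {
      for (dw in c(200, 800, 2000)) {
        r2 <- carver_richards_r2eff(10, kex, pf, dw,
                                    c(25, 50, 100, 200, 400, 800, 1600))
        expect_true(all(diff(r2) <= 1e-9))
        expect_true(all(is.finite(r2)))
      }
    }
  }
})

test_that("fast-exchange limit approaches pF (1-pF) dw^2 / kex", {
  kex <- 5e4
  pf <- 0.1
  dw <- 500
  rex <- carver_richards_r2eff(10, kex, pf, dw, 25) - 10
  expect_equal(rex, pf * (1 - pf) * dw^2 / kex, tolerance = 0.05)
})

test_that("slow pulsing with fast relaxation stays finite (overflow guard)", {
  # naive cosh would overflow: eta+ ~ tau * kex ~ 500 at nu = 5 Hz, kex = 5000
  r2 <- carver_richards_r2eff(10, 5000, 0.2, 3000, c(5, 10, 25))
  expect_true(all(is.finite(r2)))
  expect_true(all(r2 > 10))
})

test_that("Carver-Richards matches the propagated Bloch-McConnell decay rate", {
  # compact grid here; the full grid runs in the acceptance suite
  for (kex in c(100, 1000)) {
    for (pf in c(0.05, 0.2)) {
      for (dw in c(300, 1500)) {
        for (nu in c(50, 300, 1100)) {
          cr <- carver_richards_r2eff(10, kex, pf, dw, nu)
          bm <- bm_block_r2eff(10, kex, pf, dw, nu)
          rex <- bm - 10
          if (rex > 0.1) {
            expect_lt(abs(cr - bm) / rex, 0.02)
          } else {
            expect_lt(abs(cr - bm), 0.01)
          }
        }
      }
    }
  }
})

test_that("finite constant-time readout deviates only by bounded projection effects", {
  # the closed form is the asymptotic decay rate of the CPMG block; intensity
  # detection after a finite 40 ms constant time adds mode-projection effects.
  # In the study regime these stay below 10% of the largest exchange
  # contribution of the profile.
  for (kex in c(377, 855, 1420)) {
    for (pf in c(0.05, 0.1)) {
      for (ppm in c(2, 3)) {
        for (field in c(11.7, 14.1)) {
          nus <- cpmg_nu_schedule(field)
          dw <- ppm_to_rad_s(ppm, field)
          cr <- carver_richards_r2eff(12, kex, pf, dw, nus)
          bm <- vapply(nus, function(nu) bm_ct_r2eff(12, kex, pf, dw, nu), 1)
          expect_lt(max(abs(cr - bm)), 0.10 * max(bm - 12))
        }
      }
    }
  }
})

test_that("profile container enforces ppm-to-rad/s field scaling", {
  nus11 <- cpmg_nu_schedule(11.7)
  nus14 <- cpmg_nu_schedule(14.1)
  p1 <- dispersion_profile("I145", 11.7, 2.0, nus11, rep(10, 10), 0.2)
  p2 <- dispersion_profile("I145", 14.1, 2.0, nus14, rep(10, 12), 0.2)
  expect_equal(p2$delta_omega_rad_s / p1$delta_omega_rad_s, 14.1 / 11.7)
  expect_error(dispersion_profile("X", 11.7, 2, c(50, 100), c(10, 10), 0.2),
               ">= 6")
  expect_error(carver_richards_r2eff(10, 500, 0.05, 300, c(0, 50)),
               "reference planes")
})
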