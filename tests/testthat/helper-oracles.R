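# Independent numerical oracles. These deliberately avoid the package's
# closed-form code paths: matrix exponentials and propagation for CPMG,
# bisection for the binding equilibrium, a published viscosity table for
# water.

# exp(A) for a small complex matrix, via eigendecomposition
cexpm <- function(A) {
  e <- eigen(A)
  e$vectors %*% diag(exp(e$values), nrow(A)) %*% solve(e$vectors)
}

# Two-site Bloch-McConnell generator for transverse magnetization (complex
# representation), free state F carrying the offset dw, bound state B on
# resonance. Equal intrinsic R2.
bm_generator <- function(r20, kex, p_f, dw) {
  kfb <- (1 - p_f) * kex  # F -> B
  kbf <- p_f * kex        # B -> F
  matrix(c(-r20 - kfb + 1i * dw, kbf,
           kfb, -r20 - kbf + 0i), 2, 2, byrow = TRUE)
}

# R2eff as the decay rate of the slowest-decaying magnetization mode of the
# numerically propagated CPMG block (delta - 180 - delta per echo, delta =
# tau/2): the per-block linear map over two echoes is built from matrix
# exponentials and explicit 180-degree conjugations, and its dominant
# eigenvalue modulus gives the asymptotic decay per unit time.
bm_block_r2eff <- function(r20, kex, p_f, dw, nu) {
  A <- bm_generator(r20, kex, p_f, dw)
  delta <- 1 / (4 * nu)
  P <- cexpm(A * delta)
  two_echo <- P %*% Conj(P) %*% Conj(P) %*% P   # conj implements the 180s
  lam <- max(Mod(eigen(two_echo, only.values = TRUE)$values))
  -log(lam) / (4 * delta)
}

# R2eff from finite constant-time propagation with population-weighted
# starting magnetization, reading out the observed (bound) component. This
# includes the mode-projection ("end") effects absent from the asymptotic
# rate.
bm_ct_r2eff <- function(r20, kex, p_f, dw, nu, tct = 0.040) {
  A <- bm_generator(r20, kex, p_f, dw)
  n180 <- round(2 * tct * nu)
  stopifnot(abs(2 * tct * nu - n180) < 1e-9)  # schedule fits the CT period
  delta <- tct / (2 * n180)
  P <- cexpm(A * delta)
  M <- c(p_f, 1 - p_f)
  for (j in seq_len(n180)) {
    M <- P %*% M
    M <- Conj(M)
    M <- P %*% M
  }
  -log(Mod(M[2]) / (1 - p_f)) / tct
}

# Bound-complex concentration by bisection on the mass-balance equation
# (n pt - x)(lt - x) = Kd x, independent of the closed-form quadratic.
bisect_complex <- function(p_tot, l_tot, kd, n_comp = 1, tol = 1e-16) {
  np <- n_comp * p_tot
  lo <- 0
  hi <- min(np, l_tot)
  if (hi == 0) return(0)
  f <- function(x) (np - x) * (l_tot - x) - kd * x
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol * max(hi, 1e-30)) break
  }
  (lo + hi) / 2
}

# Cumulative cell heats from the bisection equilibrium, given the package's
# dilution bookkeeping (concentrations are shared plumbing, the equilibrium
# solve is the independent part).
bisect_cumulative_heats <- function(params, protocol) {
  conc <- cell_concentrations(protocol)
  vapply(seq_len(nrow(conc)), function(i) {
    pl <- bisect_complex(conc$P_M[i], conc$L_M[i], params$K_d_M,
                         params$n_competent)
    params$delta_H_J_mol * protocol$cell_volume_L * pl
  }, 1)
}

# Dynamic viscosity of water (mPa s) by log-linear interpolation of a
# published table (5 degC steps).
water_table_viscosity <- function(temperature_K) {
  tc <- c(10, 15, 20, 25, 30, 35, 40)
  eta <- c(1.3059, 1.1374, 1.0016, 0.8900, 0.7972, 0.7190, 0.6527)
  t <- temperature_K - 273.15
  stopifnot(t >= min(tc), t <= max(tc))
  exp(stats::approx(tc, log(eta), xout = t)$y) * 1e-3
}
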