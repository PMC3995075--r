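# Shared fixtures and independent oracles for the test suite.

# Independent Bessel-J0 oracle: the defining power series, truncated far
# beyond double precision for |z| <= 10.
bessel_j0_series <- function(z) {
  k <- 0:40
  vapply(z, function(zz) sum((-1)^k * (zz / 2)^(2 * k) / factorial(k)^2),
         numeric(1))
}

# Canonical regime parameter sets (B = 10, L_eff/R = 100, horizontal clamp).
regime_params <- function(gamma_tilde, growth_mode) {
  model_params(gamma_tilde = gamma_tilde, B = 10, R = 1, E0 = 1,
               L0 = 100, Lgz = 100, growth_mode = growth_mode)
}

# Zero-sensitivity parameters: Delta == 0 identically (pure elongation).
null_params <- function(E0 = 1, R = 1, ...) {
  model_params(gamma_tilde = 0, beta_tilde = 0, R = R, E0 = E0, ...)
}

# Midline of the non-elongating model's steady state: straight clamped
# basal part of length L - L_eff, exponential-decay profile over the
# apical sensing zone. Built from the closed form, not the simulator.
ac_steady_state <- function(B, L_eff = 100, L = 2 * L_eff, A0 = pi / 2,
                            N = 400) {
  ds <- rep(L / N, N)
  smid <- cumsum(ds) - ds / 2
  s0 <- L - L_eff
  A <- ifelse(smid <= s0, A0, ac_profile(smid - s0, A0, B, L_eff))
  C <- ifelse(smid <= s0, 0, -B / L_eff * A)  # dA/ds of the closed form
  organ_state(ds = ds, C = C, A0 = A0)
}

# Render an angle profile A(s) (element midpoints) into midline points.
points_from_angles <- function(A, ds, base = c(0, 0)) {
  cbind(x = base[1] + c(0, cumsum(sin(A) * ds)),
        y = base[2] + c(0, cumsum(cos(A) * ds)))
}
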