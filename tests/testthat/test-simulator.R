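test_that("init_tilted builds the clamped straight organ", {
  p <- regime_params(10, "exponential")
  st <- init_tilted(p, N = 200)
  expect_equal(sum(st$ds), 100)
  expect_equal(st$C, rep(0, 200))
  expect_equal(angles_from_curvature(st), rep(pi / 2, 201))
  expect_error(init_tilted(p, N = 1), "N must be")
  st2 <- init_tilted(p, N = 2)
  expect_length(st2$ds, 2)
})

test_that("pure elongation conserves curvature exactly and grows elements", {
  p <- null_params()  # Delta == 0
  pr <- growth_profile("exponential", E0 = 1, Lgz = 100)
  st <- organ_state(ds = rep(0.5, 50), C = runif(50, -0.05, 0.05), A0 = pi / 2)
  st1 <- step_ace(st, p, pr, dt = 0.05)
  expect_identical(st1$C, st$C)                       # machine-exact
  expect_equal(st1$ds, st$ds * exp(1 * 0.05), tolerance = 1e-14)
  # degenerate profile: no growth, nothing moves
  pr0 <- growth_profile("exponential", E0 = 0, Lgz = 100)
  pb <- regime_params(10, "exponential")
  st2 <- step_ace(init_tilted(pb, 20), pb, pr0, dt = 0.05)
  expect_equal(st2$C, rep(0, 20))
  expect_equal(sum(st2$ds), 100)
})

test_that("one Euler step from the horizontal matches the hand formula", {
  p <- regime_params(10, "exponential")  # beta_tilde = 1
  pr <- profile_from_params(p)
  dt <- 1e-3
  st1 <- step_ace(init_tilted(p, 50), p, pr, dt = dt)
  # straight horizontal: Delta = -beta_tilde*A0, DC/Dt = E0*Delta/R uniform
  expected_C <- dt * p$E0 * (-p$beta_tilde * pi / 2) / p$R
  expect_equal(st1$C, rep(expected_C, 50), tolerance = 1e-12)
  expect_true(all(st1$C < 0))
})

test_that("measured drift of the angle difference matches the kinematic law", {
  p <- null_params()
  pr <- growth_profile("exponential", E0 = 1, Lgz = 100)
  C0 <- seq(-0.04, 0.04, length.out = 40); C0[C0 == 0] <- 0.01
  st <- organ_state(ds = rep(0.25, 40), C = C0, A0 = pi / 2)
  dt <- 1e-3
  st1 <- step_ace(st, p, pr, dt = dt)
  measured <- (st1$C * st1$ds - st$C * st$ds) / dt
  predicted <- drift_rate(st$C, 0, E0 = 1, ds = st$ds, R = 1)
  expect_true(all(abs(measured - predicted) <= 0.01 * abs(predicted)))
})

test_that("timestep above the stability bound is rejected by name", {
  p <- regime_params(10, "exponential")
  st <- init_tilted(p, 50)
  expect_error(step_ace(st, p, profile_from_params(p), dt = 1),
               "stability bound")
  pa <- model_params(beta = 0.1, gamma = 1, gamma_tilde = 1, beta_tilde = 0.1,
                     R = 1, E0 = 1, Lgz = 100, L0 = 100)
  expect_error(step_ac(init_tilted(pa, 50), pa, dt = 10), "stability bound")
})

test_that("non-elongating model: uniform initial rate and fixed point", {
  pa <- model_params(gamma_tilde = 10, B = 3, R = 1, E0 = 1, Lgz = 100,
                     L0 = 100, growth_mode = "subapical_step")
  st <- init_tilted(pa, 50)
  dt <- 1e-3
  st1 <- step_ac(st, pa, dt)
  # straight horizontal: dC/dt = -beta*A0 uniformly
  expect_equal(st1$C, rep(-pa$beta * pi / 2 * dt, 50), tolerance = 1e-12)
  expect_equal(st1$ds, st$ds)  # never elongates
  # vertical straight organ is a fixed point
  stv <- organ_state(ds = rep(2, 50), C = rep(0, 50), A0 = 0)
  expect_equal(step_ac(stv, pa, dt)$C, rep(0, 50))
})

test_that("remesh splits conservatively and is idempotent", {
  st <- organ_state(ds = c(1, 2.5, 1, 3), C = c(0.1, -0.2, 0.3, 0),
                    frozen = c(TRUE, FALSE, FALSE, FALSE), A0 = 0.7)
  r <- remesh(st, ds_max = 2)
  expect_length(r$ds, 6)
  expect_equal(sum(r$ds), sum(st$ds))
  expect_equal(r$C, c(0.1, -0.2, -0.2, 0.3, 0, 0))
  expect_equal(r$frozen, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  # node angles of the original nodes preserved exactly
  expect_equal(angles_from_curvature(r)[c(1, 2, 4, 5, 7)],
               angles_from_curvature(st))
  expect_identical(remesh(r, 2), r)   # idempotent
  expect_identical(remesh(st, 10), st)
})

test_that("freezing is latched and the fixed zone grows linearly", {
  p <- regime_params(10, "subapical_step")
  tr <- simulate_organ(p, mode = "ace", t_max = 1, N = 100)
  # frozen curvature never changes after exit (exact)
  last <- tr$snapshots[[length(tr$snapshots)]]
  mid <- tr$snapshots[[ceiling(length(tr$snapshots) / 2)]]
  nfro <- sum(mid$frozen)
  expect_gt(nfro, 0)
  expect_identical(last$C[seq_len(nfro)], mid$C[seq_len(nfro)])
  expect_true(all(last$frozen[seq_len(nfro)]))
  # L_f(t) = Lgz*E0*t within one element length while the zone is full
  d <- tr$diagnostics
  el <- max(vapply(tr$snapshots, function(s) max(s$ds), numeric(1)))
  expect_true(all(abs(d$Lf - p$Lgz * p$E0 * d$t) <= el + 1e-9))
  # organ length for the subapical profile is linear in time (the
  # midpoint rule for zone membership adds O(ds/L) relative error)
  expect_equal(d$L, p$Lgz * (1 + p$E0 * d$t), tolerance = 1e-3)
})

test_that("trajectory invariants: times increase, L and N never decrease", {
  p <- regime_params(10, "exponential")
  tr <- simulate_organ(p, mode = "ace", t_max = 1, N = 50)
  expect_true(all(diff(tr$times) > 0))
  expect_true(all(diff(tr$diagnostics$L) >= 0))
  expect_true(all(diff(tr$diagnostics$n_elements) >= 0))
  # exponential growth with exact element update: L(t) = L0*exp(E0*t)
  expect_equal(tr$diagnostics$L, 100 * exp(tr$diagnostics$t),
               tolerance = 1e-9)
})

test_that("halving the step changes final node angles by < 0.1%", {
  p <- regime_params(10, "subapical_step")
  run <- function(dt) {
    tr <- simulate_organ(p, mode = "ace", t_max = 0.4, dt = dt, N = 100,
                         record_every = 1e6)
    st <- tr$snapshots[[length(tr$snapshots)]]
    stats::approx(cumsum(st$ds) - st$ds / 2, midpoint_angles(st),
                  xout = seq(1, 99, length.out = 50))$y
  }
  a1 <- run(2e-4); a2 <- run(1e-4)
  expect_lt(max(abs(a1 - a2)), 1e-3 * max(abs(a1)))
})

test_that("steady-state detection on settled and divergent runs", {
  p <- regime_params(10, "exponential")
  tr <- simulate_organ(p, mode = "ace", t_max = 2)
  expect_false(is.na(tr$converged_at))
  # convergence happens within a few proprioceptive times 1/(E0*gt)
  expect_lt(tr$converged_at, 10 * convergence_time(p$E0, p$gamma_tilde))
  pdiv <- regime_params(0.1, "exponential")
  trd <- simulate_organ(pdiv, mode = "ace", t_max = 3)
  expect_true(is.na(trd$converged_at))
  # a trajectory that never moves converges at its first recorded time
  pnull <- null_params(Lgz = 100, L0 = 100)
  tr0 <- simulate_organ(pnull, mode = "ace", t_max = 2, N = 20)
  expect_equal(tr0$converged_at, 0)
  expect_error(detect_steady_state(tr, tol = -1), "tol")
})

test_that("growth-driven model approaches the non-elongating one as E0 -> 0", {
  # dimensional sensitivities held fixed; E0 scanned downward
  beta <- 0.1; gamma <- 1
  angles_at <- function(tr, xout) {
    st <- tr$snapshots[[length(tr$snapshots)]]
    stats::approx(cumsum(st$ds) - st$ds / 2, midpoint_angles(st),
                  xout = xout)$y
  }
  pa <- model_params(beta = beta, gamma = gamma, gamma_tilde = gamma,
                     beta_tilde = beta, R = 1, E0 = 1, Lgz = 50, L0 = 100,
                     growth_mode = "subapical_step")
  xout <- seq(0.5, 99, length.out = 80)
  tr_ac <- simulate_organ(pa, mode = "ac", t_max = 2, dt = 0.005, N = 200)
  ref <- angles_at(tr_ac, xout)
  errs <- vapply(c(0.2, 0.1, 0.05), function(E0) {
    p <- model_params(beta = beta, gamma = gamma, R = 1, E0 = E0,
                      Lgz = 50, L0 = 100, growth_mode = "subapical_step")
    tr <- simulate_organ(p, mode = "ace", t_max = 2, dt = 0.005, N = 200)
    max(abs(angles_at(tr, xout) - ref))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))      # monotone improvement
  expect_lt(errs[3], 0.5 * errs[1])     # roughly first order in E0
  expect_lt(errs[3], 0.2)
})
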