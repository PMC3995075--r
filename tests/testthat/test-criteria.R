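test_that("active-control condition is strict at the boundary", {
  expect_true(active_control_ok(10))
  expect_false(active_control_ok(0.1))
  expect_false(active_control_ok(1))
  expect_error(active_control_ok(-1))
})

test_that("timescales: convergence, fixation, and their ratio", {
  expect_equal(convergence_time(1, 10), 0.1)
  expect_equal(convergence_time(2, 10), 0.05)      # doubling E0 halves Tc
  expect_error(convergence_time(0, 10), "E0")

  expect_equal(fixation_time(1, beta_tilde = 2, Lgz = 1, R = 1), 1)
  # quadrupling Lgz halves Tf
  expect_equal(fixation_time(1, 1, Lgz = 4, R = 1),
               fixation_time(1, 1, Lgz = 1, R = 1) / 2)
  # identity Tc/Tf = (1/gt) * sqrt(bt*Lgz/(2R)) to 1e-12
  for (gt in c(0.5, 2, 10)) for (bt in c(0.1, 1)) {
    Tc <- convergence_time(1.3, gt)
    Tf <- fixation_time(1.3, bt, Lgz = 70, R = 2)
    expect_equal(Tc / Tf, sqrt(bt * 70 / (2 * 2)) / gt, tolerance = 1e-12)
  }
})

test_that("fixation-negligible criterion and its timescale consistency", {
  expect_true(fixation_negligible(10, Lgz = 100, R = 1))    # 10 < sqrt(200)
  expect_false(fixation_negligible(15, Lgz = 100, R = 1))
  expect_true(fixation_negligible(0, Lgz = 100, R = 1))
  # with beta_tilde = 1 and gt = Lgz/(B*R): criterion <=> Tc/Tf < 1
  for (B in c(2, 5, 14, 20)) {
    Lgz <- 100; R <- 1
    gt <- Lgz / (B * R)
    ratio <- convergence_time(1, gt) / fixation_time(1, 1, Lgz, R)
    expect_equal(fixation_negligible(B, Lgz, R), ratio < 1)
  }
})

test_that("fixed zone bookkeeping during linear growth", {
  fz <- fixed_zone(0, E0 = 1, Lgz = 100)
  expect_equal(fz, list(L = 100, Lf = 0))
  fz1 <- fixed_zone(1, E0 = 1, Lgz = 100)
  expect_equal(fz1, list(L = 200, Lf = 100))
  expect_error(fixed_zone(-1, 1, 100))
})

test_that("maximal-bending bound on exiting elements", {
  b <- fixed_profile_bound(0, pi / 2, 1, 1, 100, 1)
  expect_equal(b, list(C_exit = 0, A_exit = pi / 2))
  # by construction, the bound reaches vertical exactly at Tf
  bt <- 0.05; Lgz <- 100; R <- 1; E0 <- 1
  Tf <- fixation_time(E0, bt, Lgz, R)
  bTf <- fixed_profile_bound(Tf, pi / 2, bt, E0, Lgz, R)
  expect_equal(bTf$A_exit, 0, tolerance = 1e-12)
})

test_that("regime report collects consistent diagnostics", {
  p <- model_params(gamma_tilde = 10, B = 4, R = 1, E0 = 2, Lgz = 100,
                    L0 = 100, growth_mode = "subapical_step")
  rep <- regime_report(p)
  expect_s3_class(rep, "grav_regime")
  expect_equal(rep$B, 4, tolerance = 1e-12)
  expect_true(rep$active_control_ok)
  expect_true(rep$exp_growth_negligible)   # 100 > 6.2*4
  expect_true(rep$fixation_negligible)     # 4 < sqrt(200)
  expect_equal(rep$Tc_over_Tf, rep$Tc / rep$Tf, tolerance = 1e-12)
  expect_gt(rep$Tc, 0); expect_gt(rep$Tf, 0)
})

test_that("simulated exit times and curvatures respect the bounds", {
  # overshooting subapical run: B = 10, gt = 0.5, Lgz/R = 100
  p <- model_params(gamma_tilde = 0.5, B = 10, R = 1, E0 = 1, Lgz = 100,
                    L0 = 100, growth_mode = "subapical_step")
  tr <- simulate_organ(p, mode = "ace", t_max = 2.5, N = 200)
  Tf <- fixation_time(p$E0, p$beta_tilde, p$Lgz, p$R)
  expect_false(is.na(tr$first_vertical_frozen))
  expect_gte(tr$first_vertical_frozen, Tf)   # Tf is a lower bound
  # exiting elements never bend beyond the maximal-rate bound
  bound <- abs(fixed_profile_bound(tr$exits$t, p$A0, p$beta_tilde, p$E0,
                                   p$Lgz, p$R)$C_exit)
  expect_true(all(abs(tr$exits$C) <= bound + 1e-9))
})

test_that("fixation criterion separates clean from oscillation-fixing runs", {
  frozen_inflections <- function(tr, amp = 1e-4) {
    st <- tr$snapshots[[length(tr$snapshots)]]
    Cf <- st$C[st$frozen]
    Cf <- Cf[abs(Cf) > amp]
    if (length(Cf) < 2) 0L else sum(diff(sign(Cf)) != 0)
  }
  # clean regime: B = 10 < sqrt(200), high gain
  p_ok <- regime_params(10, "subapical_step")
  expect_true(fixation_negligible(bending_number(p_ok), p_ok$Lgz, p_ok$R))
  tr_ok <- simulate_organ(p_ok, mode = "ace", t_max = 1.5)
  expect_identical(frozen_inflections(tr_ok), 0L)
  # violating regime: low gain fixes at least one inflection
  p_bad <- regime_params(0.1, "subapical_step")
  tr_bad <- simulate_organ(p_bad, mode = "ace", t_max = 3)
  expect_gte(frozen_inflections(tr_bad), 1L)
})
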