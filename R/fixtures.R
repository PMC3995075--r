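#' Render an organ state as a midline point sequence
#'
#' Integrates the unit tangent `(sin A, cos A)` (inclination measured from
#' the vertical +y axis) over the material elements from the base point,
#' using the element-midpoint inclination so the chord of each element is
#' accurate to second order in the element length.
#'
#' @param state A [organ_state()].
#' @param base_xy Base point (length-2 numeric; default origin).
#' @return Matrix of (x, y) node coordinates, `n + 1` rows, base first.
#' @export
render_midline <- function(state, base_xy = c(0, 0)) {
  stopifnot(inherits(state, "grav_state"), length(base_xy) == 2L)
  Amid <- midpoint_angles(state)
  x <- base_xy[1] + c(0, cumsum(sin(Amid) * state$ds))
  y <- base_xy[2] + c(0, cumsum(cos(Amid) * state$ds))
  cbind(x = x, y = y)
}

#' Named simulation scenarios for synthetic data
#'
#' Pins the parameter sets of the four canonical regimes (all with
#' `B = 10`, `L_eff/R = 100`, horizontal clamp):
#' \describe{
#'   \item{exp_divergent}{whole-organ exponential growth,
#'     `gamma_tilde = 0.1`: passive orientation drift wins, undulations
#'     grow, no steady state.}
#'   \item{exp_convergent}{exponential growth, `gamma_tilde = 10`: the
#'     organ reaches a dynamic steady state while still elongating.}
#'   \item{subapical_fixing}{subapical growth, `gamma_tilde = 0.1`:
#'     transient oscillations are convected out of the growth zone and
#'     fixed on the final shape.}
#'   \item{subapical_clean}{subapical growth, `gamma_tilde = 10`:
#'     convergence beats fixation, no oscillation is fixed.}
#'   \item{ac_reference}{non-elongating model, `B = 3`,
#'     `gamma_tilde = 10`-equivalent gains, for phenotyping references.}
#' }
#'
#' @param scenario Scenario name (or `"custom"` with `params` supplied).
#' @param params A [model_params()] for `scenario = "custom"`.
#' @param noise_sd Sd of the angular digitization noise (rad; default
#'   0.05, the stated measurement error).
#' @param n_frames Number of rendered frames (default 8).
#' @param seed Integer seed (default 1).
#' @param t_max Simulated time; defaults per scenario.
#' @param N Initial element count (default 200).
#' @return An object of class `grav_fixture_spec`.
#' @export
fixture_spec <- function(scenario = c("exp_divergent", "exp_convergent",
                                      "subapical_fixing", "subapical_clean",
                                      "ac_reference", "custom"),
                         params = NULL, noise_sd = 0.05, n_frames = 8L,
                         seed = 1L, t_max = NULL, N = 200L) {
  scenario <- match.arg(scenario)
  stopifnot(noise_sd >= 0, n_frames >= 2L)
  mode <- "ace"
  if (is.null(params)) {
    params <- switch(scenario,
      exp_divergent = model_params(gamma_tilde = 0.1, B = 10, R = 1, E0 = 1,
                                   L0 = 100, Lgz = 100,
                                   growth_mode = "exponential"),
      exp_convergent = model_params(gamma_tilde = 10, B = 10, R = 1, E0 = 1,
                                    L0 = 100, Lgz = 100,
                                    growth_mode = "exponential"),
      subapical_fixing = model_params(gamma_tilde = 0.1, B = 10, R = 1,
                                      E0 = 1, Lgz = 100, L0 = 100,
                                      growth_mode = "subapical_step"),
      subapical_clean = model_params(gamma_tilde = 10, B = 10, R = 1,
                                     E0 = 1, Lgz = 100, L0 = 100,
                                     growth_mode = "subapical_step"),
      ac_reference = model_params(gamma_tilde = 10, B = 3, R = 1, E0 = 1,
                                  Lgz = 100, L0 = 200,
                                  growth_mode = "subapical_step"),
      custom = stop("scenario = 'custom' needs params"))
  }
  if (scenario == "ac_reference") mode <- "ac"
  if (is.null(t_max))
    t_max <- switch(scenario,
                    exp_divergent = 4, exp_convergent = 2,
                    subapical_fixing = 3, subapical_clean = 1.5,
                    ac_reference = 5 / params$gamma, 2)
  structure(list(scenario = scenario, params = params, mode = mode,
                 noise_sd = noise_sd, n_frames = as.integer(n_frames),
                 seed = as.integer(seed), t_max = t_max, N = as.integer(N)),
            class = "grav_fixture_spec")
}

#' Generate a synthetic midline series with known ground truth
#'
#' Runs the simulator for the scenario, renders `n_frames` snapshots
#' (equally spaced in recorded time, always including the first and last),
#' and perturbs each rendered midline with seeded zero-mean Gaussian noise
#' of sd `noise_sd` applied to the tangent angles and re-integrated --
#' mimicking digitization error of orientation rather than independent
#' point jitter. The clamped base point is exact.
#'
#' @param spec A [fixture_spec()].
#' @return List with `series` (a [midline_series()]), `truth` (true `B`,
#'   `gamma_tilde`, `beta_tilde`, `Lgz`, `L0`, `R`, `L_eff`, `noise_sd`,
#'   `seed`, `converged_at`) and `trajectory` (the full simulation).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "grav_fixture_spec"))
  p <- spec$params
  traj <- simulate_organ(p, mode = spec$mode, t_max = spec$t_max, N = spec$N)
  ns <- length(traj$snapshots)
  idx <- unique(round(seq(1, ns, length.out = spec$n_frames)))
  set.seed(spec$seed)
  frames <- lapply(idx, function(i) {
    st <- traj$snapshots[[i]]
    Amid <- midpoint_angles(st)
    if (spec$noise_sd > 0)
      Amid <- Amid + stats::rnorm(length(Amid), 0, spec$noise_sd)
    cbind(x = c(0, cumsum(sin(Amid) * st$ds)),
          y = c(0, cumsum(cos(Amid) * st$ds)))
  })
  series <- midline_series(traj$times[idx], frames)
  truth <- list(scenario = spec$scenario, B = bending_number(p),
                gamma_tilde = p$gamma_tilde, beta_tilde = p$beta_tilde,
                Lgz = p$Lgz, L0 = p$L0, R = p$R,
                L_eff = effective_length_of(p),
                noise_sd = spec$noise_sd, seed = spec$seed,
                converged_at = traj$converged_at)
  list(series = series, truth = truth, trajectory = traj)
}
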