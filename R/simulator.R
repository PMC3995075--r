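#' @keywords internal
#' Explicit-Euler stability bound for the growth-driven model.
#' The stiffness of the linearized dynamics scales with gamma_tilde
#' (proprioceptive relaxation) and with beta_tilde times the size of the
#' dynamically coupled region (graviceptive coupling through the angle
#' integral). In subapical mode frozen tissue contributes no stiffness, so
#' the coupled length is capped at Lgz.
ace_dt_bound <- function(params, profile, L) {
  E0 <- profile$E0
  if (E0 <= 0) return(Inf)
  Ldyn <- if (profile$mode == "subapical_step") min(L, profile$Lgz) else L
  0.1 * min(1 / (E0 * max(params$gamma_tilde, 1e-300)),
            1 / (E0 * max(params$beta_tilde * Ldyn / params$R, 1e-300)),
            1 / E0)
}

ac_dt_bound <- function(params, L) {
  Ldyn <- min(L, effective_length_of(params))
  0.1 * min(1 / max(params$gamma, 1e-300),
            1 / max(params$beta * Ldyn, 1e-300))
}

warn_large_curvature <- function(state, params) {
  if (params$prefactor == "small_curvature" &&
      any(abs(state$C) * params$R >= 1))
    warning("|C|*R >= 1: outside the small-curvature regime the ",
            "small_curvature prefactor is not a controlled approximation",
            call. = FALSE)
  invisible(NULL)
}

#' One explicit-Euler step of the growth-driven (ACE-type) model
#'
#' Advances every material element by `dt`: the local elongation rate is
#' evaluated at the element midpoint, the differential-growth fraction from
#' the graviproprioceptive law, the curvature updated by the material rate
#' (frozen elements never change), and the element length grown by the exact
#' factor `exp(Edot*dt)`. Because the grid is material, the convective part
#' of the material derivative is realized by the grid itself; no convection
#' term is discretized. In subapical mode, elements whose midpoint lies
#' farther than `Lgz` from the apex after the step are latched frozen.
#'
#' @param state A [organ_state()].
#' @param params A [model_params()] (needs `E0 > 0` via the profile).
#' @param profile A [growth_profile()].
#' @param dt Time step (> 0, at or below the stability bound
#'   `0.1 * min(1/(E0*gamma_tilde), R/(E0*beta_tilde*L), 1/E0)`).
#' @param check Validate `dt` against the stability bound (default `TRUE`).
#' @param warn_curvature Warn when `|C|*R >= 1` in small-curvature mode.
#' @return The advanced `grav_state`.
#' @export
step_ace <- function(state, params, profile, dt, check = TRUE,
                     warn_curvature = TRUE) {
  stopifnot(inherits(state, "grav_state"), inherits(params, "grav_params"),
            inherits(profile, "grav_profile"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a positive number")
  L <- sum(state$ds)
  if (check) {
    bound <- ace_dt_bound(params, profile, L)
    if (dt > bound * (1 + 1e-12))
      stop(sprintf("dt = %g exceeds the explicit-Euler stability bound %g = 0.1*min(1/(E0*gamma_tilde), R/(E0*beta_tilde*L), 1/E0)",
                   dt, bound))
  }
  if (warn_curvature) warn_large_curvature(state, params)
  smid <- cumsum(state$ds) - state$ds / 2
  Edot <- elongation_field(smid, L, profile)
  Amid <- midpoint_angles(state)
  Delta <- delta_response(Amid, state$C, params)
  rate <- curvature_rate(state$C, Edot, Delta, params$R, params$prefactor)
  C_new <- ifelse(state$frozen, state$C, state$C + dt * rate)
  ds_new <- state$ds * exp(Edot * dt)
  frozen_new <- state$frozen
  if (profile$mode == "subapical_step") {
    L_new <- sum(ds_new)
    smid_new <- cumsum(ds_new) - ds_new / 2
    frozen_new <- state$frozen | ((L_new - smid_new) > profile$Lgz)
  }
  organ_state(ds = ds_new, C = C_new, frozen = frozen_new,
              t = state$t + dt, A0 = state$A0, R = state$R)
}

#' One explicit-Euler step of the non-elongating (AC-type) model
#'
#' The classical graviproprioceptive model without growth:
#' `dC/dt = -beta*A - gamma*C` applied to elements within the sensing zone
#' of length `L_eff` from the apex; element lengths never change.
#'
#' @inheritParams step_ace
#' @param params A [model_params()] with dimensional `beta`, `gamma`.
#' @return The advanced `grav_state`.
#' @export
step_ac <- function(state, params, dt, check = TRUE, warn_curvature = TRUE) {
  stopifnot(inherits(state, "grav_state"), inherits(params, "grav_params"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a positive number")
  L <- sum(state$ds)
  if (check) {
    bound <- ac_dt_bound(params, L)
    if (dt > bound * (1 + 1e-12))
      stop(sprintf("dt = %g exceeds the explicit-Euler stability bound %g = 0.1*min(1/gamma, 1/(beta*L))",
                   dt, bound))
  }
  if (warn_curvature) warn_large_curvature(state, params)
  smid <- cumsum(state$ds) - state$ds / 2
  active <- (L - smid) <= effective_length_of(params)
  Amid <- midpoint_angles(state)
  g <- if (params$graviception == "sine") sin(Amid) else Amid
  rate <- ifelse(active, -params$beta * g - params$gamma * state$C, 0)
  organ_state(ds = state$ds, C = state$C + dt * rate, frozen = state$frozen,
              t = state$t + dt, A0 = state$A0, R = state$R)
}

#' Simulate gravitropic bending of a growing organ
#'
#' Integrates either the growth-driven model (`mode = "ace"`, explicit Euler
#' on a Lagrangian material grid with remeshing and element freezing) or the
#' non-elongating model (`mode = "ac"`) from the straight tilted initial
#' condition. When `dt` is `NULL` the step is recomputed from the stability
#' bound as the organ grows; a supplied `dt` is used throughout and
#' validated against the bound at every step.
#'
#' @param params A [model_params()] object.
#' @param profile A [growth_profile()]; defaults to the one implied by
#'   `params` (`mode = "ace"` only).
#' @param mode `"ace"` (growth-driven) or `"ac"` (non-elongating).
#' @param t_max Total simulated time (> 0).
#' @param dt Time step, or `NULL` for the adaptive stability-bound step.
#' @param record_every Record a snapshot every this many steps (default 50).
#' @param N Initial number of elements (default 200).
#' @param init Optional initial `grav_state` (defaults to [init_tilted()]).
#' @param ss_tol Angular tolerance handed to [detect_steady_state()].
#' @return A `grav_trajectory`: list with `snapshots` (list of states),
#'   `times`, `params`, `profile`, `mode`, `converged_at` (time or `NA`),
#'   `diagnostics` (one row per snapshot: time, organ length, frozen length,
#'   element count, tip angle, max dimensionless material curvature rate,
#'   undulation amplitude), `exits` (time, curvature and angle of each
#'   element as it froze) and `first_vertical_frozen` (earliest time a
#'   frozen element was at or past the vertical, or `NA`).
#' @export
simulate_organ <- function(params, profile = NULL,
                           mode = c("ace", "ac"), t_max,
                           dt = NULL, record_every = 50L, N = 200L,
                           init = NULL, ss_tol = 1e-2) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "grav_params"),
            is.numeric(t_max), length(t_max) == 1L, t_max > 0)
  if (is.null(profile)) profile <- profile_from_params(params)
  state <- if (is.null(init)) init_tilted(params, N) else init
  ds_init <- sum(state$ds) / length(state$ds)
  ds_max <- 2 * ds_init
  record_every <- max(1L, as.integer(record_every))

  snapshots <- list(state)
  times <- state$t
  exits_t <- exits_C <- exits_A <- numeric(0)
  first_vertical <- NA_real_
  warned <- FALSE
  step_i <- 0L
  t_end <- state$t + t_max

  while (state$t < t_end - 1e-12 * t_max) {
    bound <- if (mode == "ace") ace_dt_bound(params, profile, sum(state$ds))
             else ac_dt_bound(params, sum(state$ds))
    h <- if (is.null(dt)) bound else dt
    h <- min(h, t_end - state$t)
    if (!is.finite(h) || h <= 0)
      stop("degenerate time step; supply dt explicitly")
    if (!warned && params$prefactor == "small_curvature" &&
        any(abs(state$C) * params$R >= 1)) {
      warning("|C|*R >= 1 reached: small-curvature prefactor outside its ",
              "regime of validity", call. = FALSE)
      warned <- TRUE
    }
    prev_frozen <- state$frozen
    state <- if (mode == "ace")
      step_ace(state, params, profile, h, check = !is.null(dt),
               warn_curvature = FALSE)
    else
      step_ac(state, params, h, check = !is.null(dt), warn_curvature = FALSE)
    newly <- state$frozen & !prev_frozen
    if (any(newly)) {
      Amid <- midpoint_angles(state)
      exits_t <- c(exits_t, rep(state$t, sum(newly)))
      exits_C <- c(exits_C, state$C[newly])
      exits_A <- c(exits_A, Amid[newly])
      if (is.na(first_vertical) && any(Amid[newly] <= 0))
        first_vertical <- state$t
    }
    if (any(state$ds > ds_max)) state <- remesh(state, ds_max)
    step_i <- step_i + 1L
    if (step_i %% record_every == 0L || state$t >= t_end - 1e-12 * t_max) {
      snapshots[[length(snapshots) + 1L]] <- state
      times <- c(times, state$t)
    }
  }

  diagnostics <- trajectory_diagnostics(snapshots, times, params, profile, mode)
  traj <- structure(list(
    snapshots = snapshots, times = times, params = params, profile = profile,
    mode = mode, diagnostics = diagnostics,
    exits = data.frame(t = exits_t, C = exits_C, A = exits_A),
    first_vertical_frozen = first_vertical, converged_at = NA_real_
  ), class = "grav_trajectory")
  traj$converged_at <- detect_steady_state(traj, tol = ss_tol)
  traj
}

trajectory_diagnostics <- function(snapshots, times, params, profile, mode) {
  rows <- lapply(snapshots, function(st) {
    L <- sum(st$ds)
    A <- angles_from_curvature(st)
    smid <- cumsum(st$ds) - st$ds / 2
    if (mode == "ace") {
      Edot <- elongation_field(smid, L, profile)
      Delta <- delta_response(midpoint_angles(st), st$C, params)
      rate <- curvature_rate(st$C, Edot, Delta, params$R, params$prefactor)
      rate[st$frozen] <- 0
      rate_nd <- max(abs(rate)) * params$R / max(profile$E0, 1e-300)
    } else {
      Amid <- midpoint_angles(st)
      g <- if (params$graviception == "sine") sin(Amid) else Amid
      rate <- -params$beta * g - params$gamma * st$C
      rate_nd <- max(abs(rate)) * params$R / max(params$gamma, 1e-300)
    }
    undulation <- sum(abs(diff(A))) - abs(A[length(A)] - A[1])
    data.frame(t = st$t, L = L,
               Lf = if (profile$mode == "subapical_step")
                 sum(st$ds[st$frozen]) else 0,
               n_elements = length(st$ds),
               tip_angle = A[length(A)], rate_max = rate_nd,
               undulation = undulation)
  })
  do.call(rbind, rows)
}

#' Detect convergence to a (dynamic) steady state
#'
#' A growing organ converges to a dynamic steady state: the Eulerian shape
#' A(s) becomes stationary even though material elements keep flowing
#' through it (their curvature keeps changing, so a material-rate criterion
#' cannot fire). The detector therefore works on shape settledness: the
#' earliest recorded time `t_k` such that every later snapshot agrees with
#' the snapshot at `t_k` to within `tol` radians at every common arclength
#' position (and in tip angle), with at least one dimensionless time unit
#' (`1/E0`, or `1/gamma` for the non-elongating model) observed after
#' `t_k`.
#'
#' @param traj A `grav_trajectory`.
#' @param tol Angular tolerance (rad, > 0).
#' @return The convergence time, or `NA_real_` if never satisfied.
#' @export
detect_steady_state <- function(traj, tol = 1e-2) {
  stopifnot(inherits(traj, "grav_trajectory"))
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0)
    stop("tol must be > 0")
  ns <- length(traj$snapshots)
  if (ns < 2L) stop("need at least 2 snapshots")
  scale <- if (traj$mode == "ace") traj$profile$E0 else traj$params$gamma
  if (scale <= 0) return(NA_real_)
  tips <- traj$diagnostics$tip_angle
  prof <- lapply(traj$snapshots, function(st)
    list(s = cumsum(st$ds) - st$ds / 2, A = midpoint_angles(st),
         L = sum(st$ds)))
  t_unit <- 1 / scale
  shape_diff <- function(k, j) {
    grid <- prof[[k]]$s[prof[[k]]$s <= min(prof[[k]]$L, prof[[j]]$L)]
    if (length(grid) < 2L) return(Inf)
    max(abs(stats::approx(prof[[j]]$s, prof[[j]]$A, xout = grid, rule = 2)$y -
              stats::approx(prof[[k]]$s, prof[[k]]$A, xout = grid, rule = 2)$y))
  }
  for (k in seq_len(ns - 1L)) {
    if (traj$times[ns] < traj$times[k] + t_unit) break
    if (max(abs(tips[k:ns] - tips[ns])) >= tol) next
    ok <- TRUE
    for (j in (k + 1L):ns) {
      if (shape_diff(k, j) >= tol) { ok <- FALSE; break }
    }
    if (ok) return(traj$times[k])
  }
  NA_real_
}

#' @export
print.grav_trajectory <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("Gravitropic trajectory (%s model): %d snapshots, t in [%g, %g]\n",
              x$mode, length(x$snapshots), min(x$times), max(x$times)))
  cat(sprintf("  L: %g -> %g | elements: %d -> %d | tip angle: %.3f -> %.3f rad\n",
              d$L[1], d$L[nrow(d)], d$n_elements[1], d$n_elements[nrow(d)],
              d$tip_angle[1], d$tip_angle[nrow(d)]))
  if (is.na(x$converged_at)) cat("  no steady state detected\n")
  else cat(sprintf("  converged at t = %g\n", x$converged_at))
  invisible(x)
}

#' Deviation of a simulated trajectory from the closed-form steady profile
#'
#' For exponential-growth runs, measures at each snapshot the maximum over
#' material nodes of the absolute difference between the simulated
#' inclination and the Bessel-type steady profile [ace_profile()]. The
#' late-time growth rate of this deviation classifies the run: decaying
#' deviation means the steady shape attracts (proprioception beats passive
#' orientation drift), growing deviation means spatial undulations are
#' amplified by growth.
#'
#' @param traj A `grav_trajectory` from an exponential-growth run.
#' @param window Dimensionless time window at the end of the run over which
#'   the log-deviation slope is regressed (default 2).
#' @return List with `dev` (per-snapshot deviation), `tau` (dimensionless
#'   times), `slope` (d log dev / d tau over the window), and `convergent`
#'   (`TRUE` when the final deviation is below 0.05 rad or the slope is
#'   negative).
#' @export
steady_deviation <- function(traj, window = 2) {
  stopifnot(inherits(traj, "grav_trajectory"))
  p <- traj$params
  dev <- vapply(traj$snapshots, function(st) {
    smid <- cumsum(st$ds) - st$ds / 2
    max(abs(midpoint_angles(st) -
              ace_profile(smid, p$A0, p$beta_tilde, p$gamma_tilde, p$R)))
  }, numeric(1))
  tau <- traj$profile$E0 * traj$times
  sel <- tau >= max(tau) - window
  slope <- if (sum(sel) >= 3 && all(dev[sel] > 0))
    unname(stats::coef(stats::lm(log(dev[sel]) ~ tau[sel]))[2]) else NA_real_
  list(dev = dev, tau = tau, slope = slope,
       convergent = isTRUE(dev[length(dev)] < 0.05 || (!is.na(slope) && slope < 0)))
}
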