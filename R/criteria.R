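#' Can proprioception overcome passive orientation drift?
#'
#' Elongation of a curved element spreads its curvature over a longer arc
#' and so drifts its end-to-end orientation even without differential
#' growth. Active control is possible only when the proprioceptive term
#' overreaches this drift for any inclination, which reduces to the strict
#' condition `gamma_tilde > 1`: the proprioceptive convergence time
#' `1/(E0*gamma_tilde)` must beat the expansion time `1/E0`.
#'
#' @param gamma_tilde Dimensionless proprioceptive sensitivity (>= 0).
#' @return Logical.
#' @export
active_control_ok <- function(gamma_tilde) {
  stopifnot(all(gamma_tilde >= 0))
  gamma_tilde > 1
}

#' Convergence time to the steady state
#'
#' Approximated from the proprioceptive term that dominates near
#' convergence: `Tc = 1 / (E0 * gamma_tilde)`.
#'
#' @param E0 Relative elongation rate (> 0).
#' @param gamma_tilde Dimensionless proprioceptive sensitivity (> 0).
#' @return Time.
#' @export
convergence_time <- function(E0, gamma_tilde) {
  if (any(E0 <= 0)) stop("E0 must be > 0 (no growth, no tropic motion)")
  stopifnot(all(gamma_tilde > 0))
  1 / (E0 * gamma_tilde)
}

#' Minimal time for a vertical element to leave the growth zone
#'
#' A lower bound on the time at which a vertical element can first be
#' convected out of the growth zone, obtained by assuming the maximal
#' graviceptive bending rate at the initial inclination throughout:
#' `Tf = E0^-1 * sqrt(2R / (beta_tilde * Lgz))`. Any simulated
#' first-vertical-exit time is at or above this bound.
#'
#' @param E0 Relative elongation rate (> 0).
#' @param beta_tilde Dimensionless graviceptive sensitivity (> 0).
#' @param Lgz Growth-zone length (> 0).
#' @param R Organ radius (> 0).
#' @return Time.
#' @export
fixation_time <- function(E0, beta_tilde, Lgz, R) {
  stopifnot(all(E0 > 0), all(beta_tilde > 0), all(Lgz > 0), all(R > 0))
  sqrt(2 * R / (beta_tilde * Lgz)) / E0
}

#' Is curvature fixation negligible?
#'
#' `TRUE` when the organ converges before curved transients are frozen at
#' the base: `B < sqrt(const * Lgz / R)` with `const = 2` from the exact
#' integration of the maximal-bending bound. Equivalent (with graviceptive
#' sensitivity of order one) to the timescale condition `Tc/Tf < 1`.
#'
#' @param B Bending number.
#' @param Lgz Growth-zone length (> 0).
#' @param R Organ radius (> 0).
#' @param const Numerator constant of the bound (default 2).
#' @return Logical.
#' @export
fixation_negligible <- function(B, Lgz, R, const = 2) {
  stopifnot(all(Lgz > 0), all(R > 0), const > 0)
  B < sqrt(const * Lgz / R)
}

#' Organ and fixed-zone lengths during linear growth
#'
#' For an organ that starts exactly filling its growth zone (`L0 = Lgz`),
#' subapical elongation gives linear growth `L(t) = Lgz * (1 + E0*t)` and a
#' fixed (mature) zone `Lf(t) = Lgz * E0 * t` convected out of the growth
#' zone. General initial lengths are handled by the simulator, not by this
#' closed form.
#'
#' @param t Time (>= 0, vectorized).
#' @param E0 Relative elongation rate.
#' @param Lgz Growth-zone length.
#' @return List with `L` and `Lf`.
#' @export
fixed_zone <- function(t, E0, Lgz) {
  stopifnot(all(t >= 0))
  list(L = Lgz * (1 + E0 * t), Lf = Lgz * E0 * t)
}

#' Maximal-bending bound on the fixed profile
#'
#' Under the maximal graviceptive bending rate at the initial inclination,
#' the element leaving the growth zone at time `t` carries curvature
#' `C_exit * R = -beta_tilde * A0 * E0 * t` and the angle reached outside
#' the growth zone is the exact integral of that curvature over the fixed
#' zone: `A_exit = A0 * (1 - beta_tilde * Lgz * (E0*t)^2 / (2R))`, so that
#' `A_exit = 0` exactly at the fixation time [fixation_time()].
#'
#' @param t Time (>= 0, vectorized).
#' @param A0 Initial inclination (rad).
#' @param beta_tilde Dimensionless graviceptive sensitivity.
#' @param E0 Relative elongation rate.
#' @param Lgz Growth-zone length.
#' @param R Organ radius.
#' @return List with `C_exit` (1/length) and `A_exit` (rad).
#' @export
fixed_profile_bound <- function(t, A0, beta_tilde, E0, Lgz, R) {
  stopifnot(all(t >= 0))
  list(C_exit = -beta_tilde * A0 * E0 * t / R,
       A_exit = A0 * (1 - beta_tilde * Lgz * (E0 * t)^2 / (2 * R)))
}

#' Regime diagnostics for a parameter set
#'
#' Collects the dimensionless regime criteria and timescales: whether
#' proprioception can overcome passive orientation drift
#' (`gamma_tilde > 1`), whether whole-organ exponential growth is
#' negligible (`Lgz/R > 6.2 B`), whether curvature fixation is negligible
#' (`B < sqrt(2 Lgz/R)`), the convergence time `Tc`, the fixation time
#' `Tf`, and their ratio.
#'
#' @param params A [model_params()] object with `E0 > 0`.
#' @return An object of class `grav_regime` (a list).
#' @export
regime_report <- function(params) {
  stopifnot(inherits(params, "grav_params"))
  if (!(params$E0 > 0)) stop("regime diagnostics need E0 > 0")
  B <- bending_number(params)
  Tc <- convergence_time(params$E0, params$gamma_tilde)
  Tf <- fixation_time(params$E0, params$beta_tilde, params$Lgz, params$R)
  structure(list(
    gamma_tilde = params$gamma_tilde, B = B,
    Lgz_over_R = params$Lgz / params$R,
    active_control_ok = active_control_ok(params$gamma_tilde),
    exp_growth_negligible = exp_growth_negligible(params$Lgz, params$R, B),
    fixation_negligible = fixation_negligible(B, params$Lgz, params$R),
    Tc = Tc, Tf = Tf, Tc_over_Tf = Tc / Tf
  ), class = "grav_regime")
}

#' @export
print.grav_regime <- function(x, ...) {
  cat("Gravitropic regime diagnostics\n")
  cat(sprintf("  gamma_tilde = %g, B = %g, Lgz/R = %g\n",
              x$gamma_tilde, x$B, x$Lgz_over_R))
  cat(sprintf("  active control (gamma_tilde > 1):        %s\n", x$active_control_ok))
  cat(sprintf("  exponential growth negligible:           %s\n", x$exp_growth_negligible))
  cat(sprintf("  curvature fixation negligible:           %s\n", x$fixation_negligible))
  cat(sprintf("  Tc = %g, Tf = %g, Tc/Tf = %g\n", x$Tc, x$Tf, x$Tc_over_Tf))
  invisible(x)
}
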