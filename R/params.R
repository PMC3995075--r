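#' Model parameters for graviproprioceptive bending
#'
#' Bundles the sensitivities and geometry of a rod-like shoot organ whose
#' curvature dynamics are driven by graviception (local inclination sensing)
#' and proprioception (local curvature sensing). The dimensionless
#' sensitivities `beta_tilde` and `gamma_tilde` weight the inclination and
#' the scaled curvature `C*R` inside the differential-growth response; their
#' dimensional counterparts are `beta = beta_tilde * E0 / R`
#' (1/(length*time)) and `gamma = gamma_tilde * E0` (1/time), used by the
#' non-elongating model.
#'
#' Exactly one of `beta_tilde`, `beta` or `B` must pin down the graviceptive
#' side (supplying several is allowed only when they are mutually consistent
#' to 1e-9 relative). When `B` (the bending number) is supplied, the
#' graviceptive sensitivity is recovered from
#' `B = beta_tilde * L_eff / (gamma_tilde * R)`, where the effective length
#' `L_eff` is the initial organ length `L0` under whole-organ exponential
#' growth and the growth-zone length `Lgz` under subapical growth.
#'
#' @param gamma_tilde Dimensionless proprioceptive sensitivity (>= 0).
#' @param beta_tilde Dimensionless graviceptive sensitivity (>= 0).
#' @param B Bending number; alternative way to set the graviceptive side.
#' @param beta,gamma Dimensional sensitivities; alternative to the tilde
#'   forms (required when `E0 = 0`, where the tilde forms are undefined).
#' @param R Organ radius (length > 0).
#' @param E0 Relative elemental elongation rate of the median line (1/time,
#'   >= 0). `E0 = 0` describes a non-elongating organ.
#' @param Lgz Growth-zone length (length > 0).
#' @param L0 Initial organ length (length > 0).
#' @param A0 Basal clamp angle from the vertical (rad). The experiments the
#'   model describes tilt the organ horizontal, so the default is `pi/2`.
#' @param growth_mode `"subapical_step"` (elongation confined to a zone of
#'   length `Lgz` below the apex) or `"exponential"` (whole-organ uniform
#'   elongation). Determines `L_eff`.
#' @param graviception `"linear"` (response proportional to A) or `"sine"`
#'   (sine law of gravitropism).
#' @param prefactor `"small_curvature"` (curvature rate `E*Delta/R`) or
#'   `"full_quadratic"` (keeps the geometric factor `1 - C^2 R^2`).
#' @param saturate_delta If `TRUE`, the differential-growth fraction is
#'   clipped to `[-1, 1]` (no flank shrinkage). Off by default: the
#'   linearized model is unsaturated.
#' @return An object of class `grav_params`.
#' @examples
#' p <- model_params(B = 10, gamma_tilde = 10, Lgz = 100, R = 1)
#' bending_number(p)
#' @export
model_params <- function(gamma_tilde = NULL, beta_tilde = NULL, B = NULL,
                         beta = NULL, gamma = NULL,
                         R = 1, E0 = 1, Lgz = 100 * R, L0 = Lgz,
                         A0 = pi / 2,
                         growth_mode = c("subapical_step", "exponential"),
                         graviception = c("linear", "sine"),
                         prefactor = c("small_curvature", "full_quadratic"),
                         saturate_delta = FALSE) {
  growth_mode <- match.arg(growth_mode)
  graviception <- match.arg(graviception)
  prefactor <- match.arg(prefactor)
  stopifnot(is.numeric(R), length(R) == 1L, is.finite(R), R > 0)
  stopifnot(is.numeric(E0), length(E0) == 1L, is.finite(E0), E0 >= 0)
  stopifnot(is.numeric(Lgz), length(Lgz) == 1L, is.finite(Lgz), Lgz > 0)
  stopifnot(is.numeric(L0), length(L0) == 1L, is.finite(L0), L0 > 0)
  stopifnot(is.numeric(A0), length(A0) == 1L, is.finite(A0))
  L_eff <- if (growth_mode == "exponential") L0 else Lgz

  # proprioceptive side
  if (is.null(gamma_tilde) && is.null(gamma))
    stop("supply gamma_tilde (or gamma)")
  if (!is.null(gamma) && E0 > 0) {
    gt_from_gamma <- gamma / E0
    if (!is.null(gamma_tilde) &&
        !isTRUE(rel_close(gamma_tilde, gt_from_gamma, 1e-9)))
      stop("gamma_tilde and gamma are inconsistent (gamma_tilde = gamma/E0)")
    gamma_tilde <- gt_from_gamma
  }
  if (is.null(gamma_tilde)) gamma_tilde <- NA_real_  # E0 = 0, gamma given
  if (!is.na(gamma_tilde) && (!is.finite(gamma_tilde) || gamma_tilde < 0))
    stop("gamma_tilde must be finite and >= 0")
  if (is.null(gamma)) gamma <- if (E0 > 0) gamma_tilde * E0 else NA_real_

  # graviceptive side: beta_tilde / beta / B
  bt_candidates <- list()
  if (!is.null(beta_tilde)) bt_candidates$beta_tilde <- beta_tilde
  if (!is.null(beta) && E0 > 0) bt_candidates$beta <- beta * R / E0
  if (!is.null(B)) {
    if (is.na(gamma_tilde))
      stop("B parameterization requires E0 > 0 (dimensionless sensitivities)")
    bt_candidates$B <- B * gamma_tilde * R / L_eff
  }
  if (length(bt_candidates) == 0L && !(is.null(B) && !is.null(beta) && E0 == 0))
    if (is.null(beta)) stop("supply one of beta_tilde, beta or B")
  if (length(bt_candidates) > 1L) {
    v <- unlist(bt_candidates)
    if (!all(vapply(v[-1], rel_close, logical(1), b = v[[1]], tol = 1e-9)))
      stop("inconsistent graviceptive parameterization (beta_tilde/beta/B ",
           "disagree beyond 1e-9 relative)")
  }
  if (length(bt_candidates) >= 1L) beta_tilde <- bt_candidates[[1]]
  if (is.null(beta_tilde)) beta_tilde <- NA_real_
  if (!is.na(beta_tilde) && (!is.finite(beta_tilde) || beta_tilde < 0))
    stop("beta_tilde must be finite and >= 0")
  if (is.null(beta)) beta <- if (E0 > 0) beta_tilde * E0 / R else NA_real_
  if (E0 == 0 && (is.na(beta) || is.na(gamma)))
    stop("with E0 = 0 the dimensional beta and gamma must be supplied")

  structure(list(
    beta_tilde = beta_tilde, gamma_tilde = gamma_tilde,
    beta = beta, gamma = gamma,
    R = R, E0 = E0, Lgz = Lgz, L0 = L0, A0 = A0,
    growth_mode = growth_mode, graviception = graviception,
    prefactor = prefactor, saturate_delta = saturate_delta
  ), class = "grav_params")
}

rel_close <- function(a, b, tol) {
  is.finite(a) && is.finite(b) && abs(a - b) <= tol * max(abs(a), abs(b), 1e-300)
}

#' Effective length of a parameter set
#'
#' `L0` under whole-organ exponential growth, `Lgz` under subapical growth.
#' @param params A `grav_params` object.
#' @return Length.
#' @export
effective_length_of <- function(params) {
  stopifnot(inherits(params, "grav_params"))
  if (params$growth_mode == "exponential") params$L0 else params$Lgz
}

#' Bending number
#'
#' The dimensionless ratio of graviceptive to proprioceptive drive over the
#' effective length, `B = beta_tilde * L_eff / (gamma_tilde * R)`. It equals
#' the ratio `L_eff / L_c` of the effective length to the convergence length
#' of the steady angle profile, and controls both the transient dynamics and
#' the steady shape.
#' @param params A `grav_params` object.
#' @return Dimensionless number.
#' @export
bending_number <- function(params) {
  stopifnot(inherits(params, "grav_params"))
  params$beta_tilde * effective_length_of(params) / (params$gamma_tilde * params$R)
}

#' @export
print.grav_params <- function(x, ...) {
  cat("Graviproprioceptive model parameters\n")
  cat(sprintf("  beta_tilde = %g, gamma_tilde = %g  (beta = %g, gamma = %g)\n",
              x$beta_tilde, x$gamma_tilde, x$beta, x$gamma))
  cat(sprintf("  R = %g, E0 = %g, Lgz = %g, L0 = %g, A0 = %g rad\n",
              x$R, x$E0, x$Lgz, x$L0, x$A0))
  cat(sprintf("  growth: %s | graviception: %s | prefactor: %s%s\n",
              x$growth_mode, x$graviception, x$prefactor,
              if (x$saturate_delta) " | Delta clipped to [-1,1]" else ""))
  if (!is.na(x$beta_tilde) && !is.na(x$gamma_tilde) && x$gamma_tilde > 0)
    cat(sprintf("  bending number B = %g\n", bending_number(x)))
  invisible(x)
}

#' Growth profile: the spatial elongation-rate field
#'
#' Describes the relative elemental elongation rate along the organ. In
#' `"exponential"` mode the whole organ elongates at the plateau rate `E0`
#' (organ length grows exponentially). In `"subapical_step"` mode elongation
#' is a step profile confined to the growth zone of length `Lgz` below the
#' apex: zero for `s < L - Lgz`, `E0` above; material convected out of the
#' zone is fixed and can no longer bend.
#'
#' @param mode `"exponential"` or `"subapical_step"`.
#' @param E0 Plateau relative elongation rate (1/time, >= 0).
#' @param Lgz Growth-zone length (length > 0).
#' @return An object of class `grav_profile`.
#' @export
growth_profile <- function(mode = c("exponential", "subapical_step"),
                           E0 = 1, Lgz = 100) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(E0), length(E0) == 1L, is.finite(E0), E0 >= 0)
  stopifnot(is.numeric(Lgz), length(Lgz) == 1L, is.finite(Lgz), Lgz > 0)
  structure(list(mode = mode, E0 = E0, Lgz = Lgz), class = "grav_profile")
}

#' @export
print.grav_profile <- function(x, ...) {
  cat(sprintf("Growth profile: %s, E0 = %g, Lgz = %g\n", x$mode, x$E0, x$Lgz))
  invisible(x)
}

#' Build the growth profile implied by a parameter set
#' @param params A `grav_params` object.
#' @return A `grav_profile`.
#' @export
profile_from_params <- function(params) {
  stopifnot(inherits(params, "grav_params"))
  growth_profile(params$growth_mode, E0 = params$E0, Lgz = params$Lgz)
}

#' Elongation-rate field
#'
#' Evaluates the relative elemental elongation rate at arclength positions
#' `s` on an organ of current length `L`. For the subapical step profile the
#' boundary point `s = L - Lgz` belongs to the growing (apical) side, so the
#' growth zone has length exactly `Lgz`.
#'
#' @param s Arclength positions (vector), `0 <= s <= L`.
#' @param L Current organ length.
#' @param profile A `grav_profile`.
#' @return Vector of elongation rates (1/time).
#' @export
elongation_field <- function(s, L, profile) {
  stopifnot(inherits(profile, "grav_profile"),
            is.numeric(s), is.numeric(L), length(L) == 1L, L > 0)
  if (any(!is.finite(s)) || any(s < 0) || any(s > L))
    stop("arclength s must lie within [0, L]")
  if (profile$mode == "exponential") {
    rep(profile$E0, length(s))
  } else {
    ifelse(s >= L - profile$Lgz, profile$E0, 0)
  }
}
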