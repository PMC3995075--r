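#' Differential-growth response to graviception and proprioception
#'
#' The graviproprioceptive control law acting on the differential-growth
#' fraction: `Delta = -beta_tilde * g(A) - gamma_tilde * C * R`, with
#' `g(A) = A` for the linear law and `g(A) = sin(A)` for the sine law of
#' gravitropism. Perception drives only the distribution of growth between
#' the two flanks, not the median elongation rate.
#'
#' @param A Local inclination from the vertical (rad), vectorized.
#' @param C Local curvature (1/length), vectorized.
#' @param params A [model_params()] object.
#' @return Dimensionless differential-growth fraction(s). Clipped to
#'   `[-1, 1]` only when `params$saturate_delta` is `TRUE` (flanks of a
#'   non-shrinking organ cannot produce `|Delta| > 1`).
#' @export
delta_response <- function(A, C, params) {
  stopifnot(inherits(params, "grav_params"))
  if (any(!is.finite(A)) || any(!is.finite(C)))
    stop("non-finite inclination or curvature")
  g <- if (params$graviception == "sine") sin(A) else A
  d <- -params$beta_tilde * g - params$gamma_tilde * C * params$R
  if (params$saturate_delta) d <- pmin(1, pmax(-1, d))
  d
}

#' Material rate of curvature change from differential growth
#'
#' Growth is the motor of bending: the curvature of a material element
#' changes only when the differential-growth fraction is non-zero. In the
#' small-curvature regime (`C*R << 1`) the rate is `Edot * Delta / R`; the
#' full form keeps the geometric prefactor `(1 - C^2 R^2)`.
#'
#' @param C Curvature (1/length).
#' @param Edot Relative elemental elongation rate (1/time, >= 0).
#' @param Delta Differential-growth fraction (dimensionless).
#' @param R Organ radius.
#' @param prefactor `"small_curvature"` or `"full_quadratic"`.
#' @return Curvature rate DC/Dt (1/(length*time)).
#' @export
curvature_rate <- function(C, Edot, Delta, R,
                           prefactor = c("small_curvature", "full_quadratic")) {
  prefactor <- match.arg(prefactor)
  if (any(!is.finite(C)) || any(!is.finite(Edot)) || any(!is.finite(Delta)))
    stop("non-finite inputs")
  if (prefactor == "small_curvature") {
    0 * C + Edot * Delta / R   # recycle to the curvature's length
  } else {
    (1 - C^2 * R^2) * Edot * Delta / R
  }
}

#' Flank elongation rates from median rate and differential fraction
#'
#' The two flanks of the cylindrical element elongate at
#' `eps1 = Edot * (1 - Delta)` and `eps2 = Edot * (1 + Delta)`; their mean
#' is the median rate and their normalized difference is `Delta`.
#'
#' @param Edot Median relative elongation rate.
#' @param Delta Differential-growth fraction.
#' @return List with components `eps1`, `eps2`.
#' @seealso [flank_decompose()] for the inverse map.
#' @export
flank_rates <- function(Edot, Delta) {
  list(eps1 = Edot * (1 - Delta), eps2 = Edot * (1 + Delta))
}

#' Median rate and differential fraction from flank rates
#' @param eps1,eps2 Flank relative elongation rates.
#' @return List with components `Edot = (eps1 + eps2)/2` and
#'   `Delta = (eps2 - eps1)/(eps1 + eps2)`.
#' @export
flank_decompose <- function(eps1, eps2) {
  list(Edot = (eps1 + eps2) / 2, Delta = (eps2 - eps1) / (eps1 + eps2))
}

#' Orientation drift rate of an elongating material element
#'
#' The difference in orientation across a short material element of length
#' `ds` is `A' = C * ds`. Under elongation it changes at rate
#' `dA'/dt = E0 * (Delta + C*R) * ds / R`; with `Delta = 0` this is the pure
#' passive orientation drift `E0 * C * ds`: elongation spreads existing
#' curvature over a longer element without changing the curvature itself.
#'
#' @param C Element curvature (1/length).
#' @param Delta Differential-growth fraction.
#' @param E0 Relative elongation rate (1/time).
#' @param ds Material element length (> 0).
#' @param R Organ radius.
#' @return Rate of change of the across-element angle difference (rad/time).
#' @export
drift_rate <- function(C, Delta, E0, ds, R) {
  stopifnot(all(ds > 0))
  E0 * (Delta + C * R) * ds / R
}

#' Node angles reconstructed from element curvatures
#'
#' Discretizes `C = dA/ds` with the base clamped at `A0`: node `i` has angle
#' `A0 + sum_{j<=i} C_j * ds_j`. Returns the `n+1` node angles for `n`
#' elements (base node first).
#'
#' @param state An [organ_state()], or a list with `ds` and `C`.
#' @param A0 Basal clamp angle (rad); defaults to the state's.
#' @return Numeric vector of node angles, length `n + 1`.
#' @export
angles_from_curvature <- function(state, A0 = state$A0) {
  if (length(state$ds) != length(state$C))
    stop("ds and C must have the same length")
  c(A0, A0 + cumsum(state$C * state$ds))
}
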