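#' Lagrangian state of the organ midline at one time
#'
#' The midline is discretized into material elements, base to apex. Each
#' element carries its current length `ds`, its curvature `C`, and a latched
#' `frozen` flag set once the element has been convected out of the growth
#' zone (after which its curvature can never change again). Angles are not
#' stored: they are reconstructed from the clamped base angle `A0` and the
#' curvature field via [angles_from_curvature()].
#'
#' @param ds Material element lengths (all > 0, length >= 2).
#' @param C Element curvatures (1/length), same length as `ds`.
#' @param frozen Logical flags, same length as `ds`.
#' @param t Time stamp.
#' @param A0 Basal clamp angle (rad).
#' @param R Organ radius carried for the small-curvature validity check
#'   (`|C|*R < 1`); optional.
#' @return An object of class `grav_state`.
#' @export
organ_state <- function(ds, C, frozen = rep(FALSE, length(ds)), t = 0,
                        A0 = pi / 2, R = NULL) {
  n <- length(ds)
  if (n < 2L) stop("an organ state needs at least 2 elements")
  if (length(C) != n || length(frozen) != n)
    stop("ds, C and frozen must share one length")
  if (any(!is.finite(ds)) || any(ds <= 0)) stop("all element lengths must be > 0")
  if (any(!is.finite(C))) stop("curvatures must be finite")
  structure(list(t = t, ds = as.numeric(ds), C = as.numeric(C),
                 frozen = as.logical(frozen), A0 = A0, R = R),
            class = "grav_state")
}

#' @export
print.grav_state <- function(x, ...) {
  A <- angles_from_curvature(x)
  cat(sprintf(
    "Organ state at t = %g: %d elements, L = %g, tip angle = %.4f rad, %d frozen\n",
    x$t, length(x$ds), sum(x$ds), A[length(A)], sum(x$frozen)))
  invisible(x)
}

#' Total organ length
#' @param state A `grav_state`.
#' @return Length.
#' @export
organ_length <- function(state) sum(state$ds)

#' Element midpoint arclengths
#' @param state A `grav_state`.
#' @return Vector of cumulative midpoint arclengths, base to apex.
#' @export
midpoint_arclength <- function(state) cumsum(state$ds) - state$ds / 2

#' Element midpoint inclinations
#'
#' Angle from the vertical at each element midpoint, reconstructed from the
#' clamped base: trapezoid of `C` up to the midpoint.
#' @param state A `grav_state`.
#' @return Vector of angles (rad), one per element.
#' @export
midpoint_angles <- function(state) {
  inc <- state$C * state$ds
  state$A0 + cumsum(inc) - inc / 2
}

#' Straight tilted initial organ
#'
#' The experimental initial condition: a straight organ clamped at the base
#' at angle `A0` (horizontal by default), zero curvature everywhere, length
#' `L0`, discretized into `N` equal material elements.
#'
#' @param params A [model_params()] object.
#' @param N Number of elements (>= 2; default 200).
#' @return A `grav_state` at `t = 0`.
#' @export
init_tilted <- function(params, N = 200L) {
  stopifnot(inherits(params, "grav_params"))
  N <- as.integer(N)
  if (is.na(N) || N < 2L) stop("N must be an integer >= 2")
  organ_state(ds = rep(params$L0 / N, N), C = rep(0, N),
              t = 0, A0 = params$A0, R = params$R)
}

#' Split over-long elements in two
#'
#' Every element longer than `ds_max` is split into two equal halves that
#' inherit its curvature and frozen flag. Total length, every node angle and
#' the piecewise-linear A(s) polyline are preserved exactly; element count
#' never decreases. Repeated application is idempotent once all elements
#' satisfy the bound.
#'
#' @param state A `grav_state`.
#' @param ds_max Maximum allowed element length (> 0).
#' @return A `grav_state`.
#' @export
remesh <- function(state, ds_max) {
  stopifnot(is.numeric(ds_max), length(ds_max) == 1L, ds_max > 0)
  big <- state$ds > ds_max
  if (!any(big)) return(state)
  reps <- ifelse(big, 2L, 1L)
  idx <- rep.int(seq_along(state$ds), reps)
  organ_state(ds = state$ds[idx] / rep.int(reps, reps),
              C = state$C[idx], frozen = state$frozen[idx],
              t = state$t, A0 = state$A0, R = state$R)
}
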