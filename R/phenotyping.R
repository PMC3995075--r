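#' Arclength, inclination and curvature of a digitized midline
#'
#' Converts an ordered base-to-apex point sequence into kinematic fields:
#' arclength by cumulative chord length, inclination as the signed tangent
#' angle from the vertical (`A = atan2(dx, dy)`, positive counterclockwise
#' with the vertical along +y), and curvature by centered differences of
#' `A` over `s`. The midline is first resampled to a uniform spacing
#' (default `L / n_resample`) so the finite differences are well
#' conditioned.
#'
#' @param points Two-column matrix or data frame of (x, y), base to apex,
#'   at least 3 points, no duplicate consecutive points.
#' @param n_resample Number of uniform segments after resampling
#'   (default 200).
#' @return List with `s` (segment-midpoint arclengths), `A` (segment
#'   inclinations, rad), `C` (curvature at the same positions, 1/length),
#'   `L` (total length) and `base` (the base point).
#' @export
midline_geometry <- function(points, n_resample = 200L) {
  xy <- as.matrix(points)
  if (ncol(xy) < 2L) stop("points must have x and y columns")
  xy <- xy[, 1:2, drop = FALSE]
  if (nrow(xy) < 3L) stop("need at least 3 points")
  seg <- sqrt(rowSums(diff(xy)^2))
  if (any(seg == 0)) stop("duplicate consecutive points")
  s_node <- c(0, cumsum(seg))
  L <- s_node[length(s_node)]
  grid <- seq(0, L, length.out = n_resample + 1L)
  xs <- stats::approx(s_node, xy[, 1], xout = grid)$y
  ys <- stats::approx(s_node, xy[, 2], xout = grid)$y
  dx <- diff(xs); dy <- diff(ys)
  A <- atan2(dx, dy)
  s_mid <- (grid[-1] + grid[-length(grid)]) / 2
  h <- L / n_resample
  n <- length(A)
  C <- numeric(n)
  if (n >= 2L) {
    C[1] <- (A[2] - A[1]) / h
    C[n] <- (A[n] - A[n - 1]) / h
    if (n >= 3L) C[2:(n - 1)] <- (A[3:n] - A[1:(n - 2)]) / (2 * h)
  }
  list(s = s_mid, A = A, C = C, L = L, base = xy[1, ])
}

#' Effective length by superposition of first and last frames
#'
#' The effective length is the distance from the point where the organ
#' starts to curve to the apex in the first image. It is found by
#' base-aligned superposition: the inclination profiles of the first and
#' last frames are compared on the first frame's arclength grid, and the
#' smallest arclength where they differ by more than `tol_angle` marks the
#' onset of curving. If the profiles never diverge the whole first-frame
#' length is returned.
#'
#' Because the threshold acts pointwise, both profiles are first smoothed
#' with a short running mean (window `smooth_frac` of the organ, default
#' 2.5%): the numerical analogue of superimposing the two images by eye,
#' which is insensitive to high-frequency digitization noise.
#'
#' @param first,last Point matrices (base to apex) or outputs of
#'   [midline_geometry()].
#' @param tol_angle Divergence threshold (rad; default 0.05, the angular
#'   measurement error).
#' @param base_tol Relative tolerance on the shared (clamped) base point.
#' @param smooth_frac Running-mean window as a fraction of the profile
#'   length (default 0.025; 0 disables smoothing).
#' @return Effective length (same units as the coordinates).
#' @export
effective_length <- function(first, last, tol_angle = 0.05, base_tol = 1e-6,
                             smooth_frac = 0.025) {
  g1 <- if (is.list(first) && !is.null(first$s)) first else midline_geometry(first)
  g2 <- if (is.list(last) && !is.null(last$s)) last else midline_geometry(last)
  scale <- max(g1$L, g2$L)
  if (sqrt(sum((g1$base - g2$base)^2)) > base_tol * scale)
    stop("frames do not share a base point (the base must be clamped)")
  A2 <- stats::approx(g2$s, g2$A, xout = g1$s, rule = 2)$y
  k <- max(1L, round(smooth_frac * length(g1$A)))
  d <- abs(running_mean(A2, k) - running_mean(g1$A, k))
  # onset of sustained divergence: the last position still within
  # tolerance (isolated noise excursions below it do not count)
  onset <- divergence_onset(d, tol_angle)
  if (is.na(onset)) return(g1$L)
  g1$L - g1$s[onset]
}

# First index from which |d| departs for good: one past the last index
# within tolerance. NA when there is no sustained departure.
divergence_onset <- function(d, tol) {
  within <- which(d <= tol)
  if (length(within) == 0L) return(1L)
  last_in <- within[length(within)]
  if (last_in >= length(d)) return(NA_integer_)
  last_in + 1L
}

running_mean <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(0L, seq_len(n) - 1L - (k %/% 2L))
  hi <- pmin(n, seq_len(n) + (k %/% 2L))
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Fit the convergence length of a steady inclination profile
#'
#' Fits `A(s) = A0 * exp(-s / L_c)` by nonlinear least squares to the
#' curved zone of a steady-state profile. The curved-zone onset is the
#' position where the (lightly smoothed) inclination departs from its
#' basal value by more than `onset_tol` for good -- one past the last
#' position still within tolerance, so isolated noise excursions do not
#' trigger it; arclength is re-origined there before fitting.
#' Both `A0` and `L_c` are fitted (a log-linear fit would be undefined
#' where noise takes `A` through zero); the fit runs to the apex and the
#' range used is reported.
#'
#' @param s Arclength grid (increasing).
#' @param A Inclination profile (rad).
#' @param A0_known Optional fixed amplitude; when supplied only `L_c` is
#'   fitted.
#' @param onset_tol Curved-zone detection threshold (rad; default 0.05).
#' @return List with `A0_fit`, `L_c`, `rmse` (rad) and `range` (the
#'   original-coordinate fit interval).
#' @export
fit_convergence_length <- function(s, A, A0_known = NULL, onset_tol = 0.05) {
  stopifnot(length(s) == length(A), length(s) >= 5L)
  k <- max(1L, round(0.025 * length(A)))
  As <- running_mean(A, k)
  i0 <- divergence_onset(abs(As - As[1]), onset_tol)
  if (is.na(i0))
    stop("no convergence zone: the profile never departs from its basal value")
  ss <- s[i0:length(s)] - s[i0]
  aa <- A[i0:length(A)]
  if (length(ss) < 5L)
    stop("no convergence zone: fewer than 5 points beyond the curved-zone onset")
  nhead <- max(3L, ceiling(length(aa) / 5))
  if (mean(abs(utils::tail(aa, nhead))) >= mean(abs(utils::head(aa, nhead))))
    stop("no convergence zone: |A| does not decay along the organ")
  a0_start <- aa[1]
  # log-linear initialization on the positive part
  pos <- aa / sign(a0_start) > 1e-6
  Lc_start <- if (sum(pos) >= 3) {
    sl <- stats::coef(stats::lm(log(abs(aa[pos])) ~ ss[pos]))[2]
    unname(if (is.finite(sl) && sl < 0) -1 / sl else max(ss) / 2)
  } else max(ss) / 2
  sqloss_fit <- function() {
    if (is.null(A0_known)) {
      obj <- function(p) sum((aa - p[1] * exp(-ss / exp(p[2])))^2)
      o <- stats::optim(c(a0_start, log(Lc_start)), obj)
      list(A0 = o$par[1], Lc = exp(o$par[2]))
    } else {
      obj <- function(p) sum((aa - A0_known * exp(-ss / exp(p)))^2)
      o <- stats::optimize(obj, log(c(max(ss) / 1e4, max(ss) * 1e2)))
      list(A0 = A0_known, Lc = exp(o$minimum))
    }
  }
  fit <- tryCatch({
    if (is.null(A0_known)) {
      m <- stats::nls(aa ~ a0 * exp(-ss / lc),
                      start = list(a0 = a0_start, lc = Lc_start),
                      control = stats::nls.control(warnOnly = TRUE, scaleOffset = 1))
      cf <- stats::coef(m)
      list(A0 = unname(cf["a0"]), Lc = unname(cf["lc"]))
    } else {
      m <- stats::nls(aa ~ A0_known * exp(-ss / lc),
                      start = list(lc = Lc_start),
                      control = stats::nls.control(warnOnly = TRUE, scaleOffset = 1))
      list(A0 = A0_known, Lc = unname(stats::coef(m)["lc"]))
    }
  }, error = function(e) sqloss_fit())
  if (!is.finite(fit$Lc) || fit$Lc <= 0) fit <- sqloss_fit()
  resid <- aa - fit$A0 * exp(-ss / fit$Lc)
  list(A0_fit = fit$A0, L_c = fit$Lc,
       rmse = sqrt(mean(resid^2)),
       range = c(s[i0], s[length(s)]))
}

#' Midline time series
#'
#' An ordered set of digitized midlines of one organ, sharing a clamped
#' base point.
#'
#' @param times Frame times (strictly increasing, length >= 2).
#' @param frames List of two-column point matrices, base to apex, one per
#'   time, each with at least 3 points and a common base point.
#' @param base_tol Relative tolerance on the shared base point.
#' @return An object of class `grav_midlines`.
#' @export
midline_series <- function(times, frames, base_tol = 1e-6) {
  stopifnot(length(times) == length(frames), length(frames) >= 2L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  frames <- lapply(frames, function(f) {
    m <- as.matrix(f)[, 1:2, drop = FALSE]
    if (nrow(m) < 3L) stop("each frame needs at least 3 points")
    m
  })
  bases <- t(vapply(frames, function(f) f[1, ], numeric(2)))
  scale <- max(vapply(frames, function(f)
    sum(sqrt(rowSums(diff(f)^2))), numeric(1)))
  if (max(abs(sweep(bases, 2, bases[1, ]))) > base_tol * scale)
    stop("all frames must share the clamped base point")
  structure(list(times = as.numeric(times), frames = frames),
            class = "grav_midlines")
}

#' @export
print.grav_midlines <- function(x, ...) {
  cat(sprintf("Midline series: %d frames, t in [%g, %g]\n",
              length(x$frames), min(x$times), max(x$times)))
  invisible(x)
}

#' Kinematic phenotyping of the bending number
#'
#' Replicates the experimental measurement procedure on a midline time
#' series: the effective length from base-aligned superposition of the
#' first and last frames, the convergence length from an exponential fit
#' to the final (steady) inclination profile, and the bending number
#' `B = L_eff / L_c`. When the organ radius `R` is supplied, a
#' [regime_report()] is attached using `L_eff` as the growth-zone length
#' and `gamma_tilde = L_eff / (B R)` (graviceptive sensitivity of order
#' one).
#'
#' @param series A [midline_series()] (or list of frames plus times).
#' @param R Optional organ radius for the regime diagnostics.
#' @param E0 Relative elongation rate used in the attached diagnostics
#'   (default 1; only scales the timescales, not the booleans).
#' @param n_resample Resampling resolution for [midline_geometry()].
#' @param tol_angle Divergence / onset threshold (rad; default 0.05).
#' @param steady_tol Warn when the last two frames differ by more than
#'   this in root-mean-square (rad; default 0.05): the fit assumes a
#'   steady state. RMS rather than sup, so that digitization noise alone
#'   does not trigger the warning.
#' @return An object of class `grav_phenotype`: `L_eff`, `L_c`, `A0_fit`,
#'   `B`, `fit_rmse`, `fit_range`, and `report` (or `NULL`).
#' @export
phenotype <- function(series, R = NULL, E0 = 1, n_resample = 200L,
                      tol_angle = 0.05, steady_tol = 0.05) {
  stopifnot(inherits(series, "grav_midlines"))
  geoms <- lapply(series$frames, midline_geometry, n_resample = n_resample)
  nf <- length(geoms)
  gl <- geoms[[nf]]
  gp <- geoms[[nf - 1L]]
  Ap <- stats::approx(gp$s, gp$A, xout = gl$s, rule = 2)$y
  ksm <- max(1L, round(0.025 * length(gl$A)))
  if (sqrt(mean((running_mean(Ap, ksm) - running_mean(gl$A, ksm))^2)) >
        steady_tol)
    warning("last two frames still differ by more than ", steady_tol,
            " rad: the final frame may not be at steady state", call. = FALSE)
  L_eff <- effective_length(geoms[[1]], gl, tol_angle = tol_angle)
  fit <- fit_convergence_length(gl$s, gl$A, onset_tol = tol_angle)
  B <- L_eff / fit$L_c
  report <- NULL
  if (!is.null(R)) {
    gt <- L_eff / (B * R)
    report <- regime_report(model_params(
      gamma_tilde = gt, B = B, R = R, E0 = E0, Lgz = L_eff, L0 = L_eff,
      A0 = fit$A0_fit, growth_mode = "subapical_step"))
  }
  structure(list(L_eff = L_eff, L_c = fit$L_c, A0_fit = fit$A0_fit, B = B,
                 fit_rmse = fit$rmse, fit_range = fit$range, report = report),
            class = "grav_phenotype")
}

#' @export
print.grav_phenotype <- function(x, ...) {
  cat("Kinematic phenotype\n")
  cat(sprintf("  L_eff = %g, L_c = %g, B = L_eff/L_c = %.3f\n",
              x$L_eff, x$L_c, x$B))
  cat(sprintf("  A0_fit = %.3f rad, fit rmse = %.4f rad over s in [%g, %g]\n",
              x$A0_fit, x$fit_rmse, x$fit_range[1], x$fit_range[2]))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
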