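#' Write a trajectory to CSV with a JSON sidecar
#'
#' One row per element midpoint per snapshot, columns `t, s, A, C, frozen`,
#' values printed with 9 significant digits. A JSON sidecar
#' (`<path>.json`) records the parameters, growth profile, convergence
#' metadata and package version.
#'
#' @param traj A `grav_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "grav_trajectory"))
  rows <- lapply(traj$snapshots, function(st) {
    data.frame(t = st$t, s = cumsum(st$ds) - st$ds / 2,
               A = midpoint_angles(st), C = st$C, frozen = st$frozen)
  })
  df <- do.call(rbind, rows)
  for (cl in c("t", "s", "A", "C")) df[[cl]] <- signif(df[[cl]], 9)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(params = unclass(traj$params),
                  profile = unclass(traj$profile), mode = traj$mode,
                  converged_at = traj$converged_at,
                  first_vertical_frozen = traj$first_vertical_frozen,
                  package = "gravibend",
                  version = as.character(utils::packageVersion("gravibend")))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Write / read a midline series as long-format CSV
#'
#' Header `t,x,y`; rows grouped by frame time, ordered base to apex;
#' 9 significant digits.
#'
#' @param series A [midline_series()].
#' @param path CSV path.
#' @return `path` invisibly (write); a `grav_midlines` (read).
#' @export
write_midline_csv <- function(series, path) {
  stopifnot(inherits(series, "grav_midlines"))
  rows <- mapply(function(t, f)
    data.frame(t = t, x = f[, 1], y = f[, 2]),
    series$times, series$frames, SIMPLIFY = FALSE)
  df <- do.call(rbind, rows)
  for (cl in names(df)) df[[cl]] <- signif(df[[cl]], 9)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_midline_csv
#' @export
read_midline_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t", "x", "y") %in% names(df)))
    stop("midline CSV needs columns t, x, y")
  times <- unique(df$t)
  frames <- lapply(times, function(tt)
    as.matrix(df[df$t == tt, c("x", "y")]))
  midline_series(times, frames)
}

config_defaults <- function() {
  list(R = 1, E0 = 1, A0 = pi / 2, mode = "subapical_step",
       model = "ace", graviception = "linear", prefactor = "small_curvature",
       saturate_delta = FALSE, N = 200L, t_max = 2, dt = NULL,
       record_every = 50L, ss_tol = 1e-3)
}

#' Load and validate a run configuration (JSON)
#'
#' Accepts either dimensionless sensitivities directly (`beta_tilde`,
#' `gamma_tilde`) or the bending number (`B`, `gamma_tilde`), plus geometry
#' as `Leff_over_R` (or explicit `L0` / `Lgz`). Unknown keys are an error
#' (they are almost always typos); all defaults are made explicit in the
#' returned configuration.
#'
#' @param path Path to a JSON file.
#' @return A list with `params` ([model_params()]), `mode` (`"ace"` or
#'   `"ac"`), numerics (`N`, `t_max`, `dt`, `record_every`, `ss_tol`) and
#'   the fully-expanded `config` echo.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c("beta_tilde", "gamma_tilde", "B", "beta", "gamma",
             "R", "E0", "A0", "Leff_over_R", "L0", "Lgz", "mode", "model",
             "graviception", "prefactor", "saturate_delta",
             "N", "t_max", "dt", "record_every", "ss_tol")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(config_defaults(), raw, keep.null = TRUE)
  if (!cfg$mode %in% c("subapical_step", "exponential"))
    stop("config error in keys: mode (must be subapical_step or exponential)")
  if (!cfg$model %in% c("ace", "ac"))
    stop("config error in keys: model (must be ace or ac)")
  if (!is.null(cfg$Leff_over_R)) {
    if (cfg$mode == "exponential") cfg$L0 <- cfg$Leff_over_R * cfg$R
    else cfg$Lgz <- cfg$Leff_over_R * cfg$R
  }
  if (is.null(cfg$Lgz)) cfg$Lgz <- if (!is.null(cfg$L0)) cfg$L0 else 100 * cfg$R
  if (is.null(cfg$L0)) cfg$L0 <- cfg$Lgz
  bad <- c(if (!is.numeric(cfg$R) || cfg$R <= 0) "R",
           if (!is.numeric(cfg$E0) || cfg$E0 < 0) "E0",
           if (!is.numeric(cfg$Lgz) || cfg$Lgz <= 0) "Lgz",
           if (!is.numeric(cfg$L0) || cfg$L0 <= 0) "L0",
           if (!is.numeric(cfg$t_max) || cfg$t_max <= 0) "t_max",
           if (!is.numeric(cfg$N) || cfg$N < 2) "N")
  if (length(bad)) stop("config error in keys: ", paste(bad, collapse = ", "))
  params <- model_params(
    gamma_tilde = cfg$gamma_tilde, beta_tilde = cfg$beta_tilde, B = cfg$B,
    beta = cfg$beta, gamma = cfg$gamma,
    R = cfg$R, E0 = cfg$E0, Lgz = cfg$Lgz, L0 = cfg$L0, A0 = cfg$A0,
    growth_mode = cfg$mode, graviception = cfg$graviception,
    prefactor = cfg$prefactor, saturate_delta = isTRUE(cfg$saturate_delta))
  echo <- cfg
  echo$beta_tilde <- params$beta_tilde
  echo$gamma_tilde <- params$gamma_tilde
  echo$B <- if (params$E0 > 0) bending_number(params) else NULL
  list(params = params, mode = cfg$model,
       N = as.integer(cfg$N), t_max = cfg$t_max, dt = cfg$dt,
       record_every = as.integer(cfg$record_every), ss_tol = cfg$ss_tol,
       config = echo)
}

#' Save a run configuration echo as JSON
#' @param config The `config` element returned by [load_config()] (or any
#'   named list of scalar settings).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

write_provenance <- function(out_prefix, extra = list()) {
  prov <- c(list(package = "gravibend",
                 version = as.character(utils::packageVersion("gravibend")),
                 timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)),
            extra)
  jsonlite::write_json(prov, paste0(out_prefix, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
}
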