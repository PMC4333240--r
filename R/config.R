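#' Simulation configuration
#'
#' Builds the nested configuration list driving a simulation run. Two profiles
#' ship with the package: `"full"`, the calibrated 5000 x 1000 um gut-strip
#' baseline, and `"test"`, a 1000 x 400 um desk-scale profile with the same
#' cell-level parameters, intended for fast exploratory and unit-test runs.
#'
#' All lengths are in micrometres, times in the units given by the key names
#' (`dt_min` in minutes, schedule times in hours since E14.5). The `input`
#' block controls cumulative cell entry: `fraction_pct` is the percentage of
#' gut surface area occupied by LTin cells at E15.5 (t = 24 h; the model's
#' single empirical anchor, 0.45 at baseline), `fold` a multiplier on the
#' resulting count, and `form` one of `"linear"`, `"exponential"`, `"sqrt"`.
#' LTi cells enter on their own (by default linear, baseline-sized) schedule
#' so the two assumption experiments perturb LTin input only.
#'
#' @param profile `"full"` or `"test"`.
#' @param ... named sub-lists (`environment`, `cells`, `adhesion`,
#'   `chemokine`, `input`, `patches`) or top-level scalars (`dt_min`,
#'   `profile`) overriding individual defaults, e.g.
#'   `sim_config("full", input = list(fraction_pct = 0.25))`.
#' @return A validated configuration list of class `pp_config`.
#' @seealso [load_config()], [run_simulation()]
#' @examples
#' cfg <- sim_config("test")
#' cfg$input$fraction_pct
#' @export
sim_config <- function(profile = c("full", "test"), ...) {
  profile <- match.arg(profile)
  cfg <- default_config(profile)
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("configuration error: overrides must be named", call. = FALSE)
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("configuration error: unknown keys: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    for (nm in names(dots)) {
      if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
        bad <- setdiff(names(dots[[nm]]), names(cfg[[nm]]))
        if (length(bad))
          stop("configuration error: unknown keys: ",
               paste(paste0(nm, ".", bad), collapse = ", "), call. = FALSE)
        cfg[[nm]] <- modifyList(cfg[[nm]], dots[[nm]])
      } else {
        cfg[[nm]] <- dots[[nm]]
      }
    }
  }
  validate_config(cfg, warn_grid = TRUE)
}

default_config <- function(profile) {
  env <- if (profile == "full") {
    list(width_um = 5000, height_um = 1000, lto_count = 12L,
         lto_radius_um = 10)
  } else {
    list(width_um = 1000, height_um = 400, lto_count = 4L,
         lto_radius_um = 10)
  }
  structure(list(
    profile = profile,
    dt_min = 1,
    environment = env,
    cells = list(motile_radius_um = 5, speed_um_per_min = 5),
    adhesion = list(r_adh_um = 15, l0 = 0.2, dl = 0.005),
    chemokine = list(r_chem_um = 200, threshold = 0.3, fd_step_um = 1),
    input = list(form = "linear", fraction_pct = 0.45, fold = 1,
                 k_per_hour = log(2) / 24, t_end_hours = 72,
                 lti_form = "linear", lti_fraction_pct = 0.45),
    patches = list(linking_distance_um = 20, min_size = 5L, basis = "cells")
  ), class = "pp_config")
}

config_keys <- function() {
  d <- unclass(default_config("full"))
  d <- Filter(is.list, d)
  lapply(d, names)
}

#' Validate a simulation configuration
#'
#' Checks types, ranges and structural invariants (positive geometry, a step
#' size that divides the 72-h window, known schedule forms). Returns the
#' configuration with counts coerced to integer so that a written-then-read
#' YAML round trip is `identical()` to the original.
#'
#' @param config a configuration list as produced by [sim_config()].
#' @param warn_grid warn when the LTin input lies outside the explored
#'   perturbation grid (fraction below 0.05 % or fold above 5).
#' @return The normalised `pp_config` object.
#' @export
validate_config <- function(config, warn_grid = FALSE) {
  if (!is.list(config))
    stop("configuration error: config must be a list", call. = FALSE)
  need <- c("profile", "dt_min", "environment", "cells", "adhesion",
            "chemokine", "input", "patches")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("configuration error: missing keys: ",
         paste(missing, collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(config), need)
  if (length(unknown))
    stop("configuration error: unknown keys: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  keys <- config_keys()
  for (blk in names(keys)) {
    if (!is.list(config[[blk]]))
      stop("configuration error: '", blk, "' must be a list", call. = FALSE)
    bad <- setdiff(names(config[[blk]]), keys[[blk]])
    if (length(bad))
      stop("configuration error: unknown keys: ",
           paste(paste0(blk, ".", bad), collapse = ", "), call. = FALSE)
    miss <- setdiff(keys[[blk]], names(config[[blk]]))
    if (length(miss))
      stop("configuration error: missing keys: ",
           paste(paste0(blk, ".", miss), collapse = ", "), call. = FALSE)
  }

  num1 <- function(x, key, lo = -Inf) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lo)
      stop("configuration error: invalid value for ", key, call. = FALSE)
    as.numeric(x)
  }
  e <- config$environment
  e$width_um <- num1(e$width_um, "environment.width_um", lo = 1e-9)
  e$height_um <- num1(e$height_um, "environment.height_um", lo = 1e-9)
  e$lto_count <- as.integer(num1(e$lto_count, "environment.lto_count", lo = 0))
  e$lto_radius_um <- num1(e$lto_radius_um, "environment.lto_radius_um",
                          lo = 1e-9)
  config$environment <- e

  config$dt_min <- num1(config$dt_min, "dt_min", lo = 1e-9)
  config$cells$motile_radius_um <-
    num1(config$cells$motile_radius_um, "cells.motile_radius_um", lo = 1e-9)
  config$cells$speed_um_per_min <-
    num1(config$cells$speed_um_per_min, "cells.speed_um_per_min", lo = 0)
  config$adhesion$r_adh_um <-
    num1(config$adhesion$r_adh_um, "adhesion.r_adh_um", lo = 1e-9)
  config$adhesion$l0 <- num1(config$adhesion$l0, "adhesion.l0", lo = 0)
  config$adhesion$dl <- num1(config$adhesion$dl, "adhesion.dl", lo = 0)
  if (config$adhesion$l0 > 1)
    stop("configuration error: adhesion.l0 must lie in [0, 1]", call. = FALSE)
  config$chemokine$r_chem_um <-
    num1(config$chemokine$r_chem_um, "chemokine.r_chem_um", lo = 1e-9)
  config$chemokine$threshold <-
    num1(config$chemokine$threshold, "chemokine.threshold", lo = 0)
  config$chemokine$fd_step_um <-
    num1(config$chemokine$fd_step_um, "chemokine.fd_step_um", lo = 1e-12)

  inp <- config$input
  if (!inp$form %in% c("linear", "exponential", "sqrt"))
    stop("configuration error: unknown input.form '", inp$form, "'",
         call. = FALSE)
  if (!inp$lti_form %in% c("linear", "exponential", "sqrt"))
    stop("configuration error: unknown input.lti_form '", inp$lti_form, "'",
         call. = FALSE)
  inp$fraction_pct <- num1(inp$fraction_pct, "input.fraction_pct", lo = 0)
  inp$lti_fraction_pct <- num1(inp$lti_fraction_pct,
                               "input.lti_fraction_pct", lo = 0)
  if (inp$fraction_pct > 100 || inp$lti_fraction_pct > 100)
    stop("configuration error: surface fractions are percentages in [0, 100]",
         call. = FALSE)
  inp$fold <- num1(inp$fold, "input.fold", lo = 0)
  inp$k_per_hour <- num1(inp$k_per_hour, "input.k_per_hour", lo = 1e-12)
  inp$t_end_hours <- num1(inp$t_end_hours, "input.t_end_hours", lo = 24)
  config$input <- inp

  p <- config$patches
  p$linking_distance_um <- num1(p$linking_distance_um,
                                "patches.linking_distance_um", lo = 1e-9)
  p$min_size <- as.integer(num1(p$min_size, "patches.min_size", lo = 1))
  if (!p$basis %in% c("cells", "lto"))
    stop("configuration error: patches.basis must be 'cells' or 'lto'",
         call. = FALSE)
  config$patches <- p

  n_steps <- config$input$t_end_hours * 60 / config$dt_min
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("configuration error: dt_min must divide the simulated window into ",
         "whole steps", call. = FALSE)

  if (warn_grid &&
      (inp$fraction_pct < 0.05 - 1e-12 || inp$fold > 5 + 1e-12))
    warning("LTin input (fraction ", inp$fraction_pct, " %, fold ", inp$fold,
            ") lies outside the explored perturbation grid", call. = FALSE)

  class(config) <- "pp_config"
  config
}

#' Read a simulation configuration from YAML
#'
#' Missing keys fall back to the profile defaults; unknown keys are an error
#' listing the offending names, so that typos do not silently revert a
#' parameter to its default. `load_config(write_config(cfg, f))` returns a
#' configuration `identical()` to `cfg`.
#'
#' @param path path to a YAML file.
#' @return A `pp_config` object.
#' @export
load_config <- function(path) {
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("configuration error: malformed YAML in '", path, "': ",
         conditionMessage(e), call. = FALSE))
  if (!is.list(raw))
    stop("configuration error: YAML root must be a mapping", call. = FALSE)
  profile <- raw$profile %||% "full"
  if (!profile %in% c("full", "test"))
    stop("configuration error: unknown profile '", profile, "'",
         call. = FALSE)
  cfg <- default_config(profile)
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown))
    stop("configuration error: unknown keys: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (nm in setdiff(names(raw), "profile")) {
    if (is.list(cfg[[nm]])) {
      if (!is.list(raw[[nm]]))
        stop("configuration error: '", nm, "' must be a mapping",
             call. = FALSE)
      bad <- setdiff(names(raw[[nm]]), names(cfg[[nm]]))
      if (length(bad))
        stop("configuration error: unknown keys: ",
             paste(paste0(nm, ".", bad), collapse = ", "), call. = FALSE)
      cfg[[nm]] <- modifyList(cfg[[nm]], raw[[nm]])
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  validate_config(cfg, warn_grid = TRUE)
}

#' Write a simulation configuration to YAML
#'
#' @param config a `pp_config` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config <- validate_config(config)
  yaml::write_yaml(unclass(config), path, precision = 18)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pp_config <- function(x, ...) {
  cat("Peyer's patch simulation configuration (profile: ", x$profile, ")\n",
      sep = "")
  cat(sprintf("  domain: %g x %g um, %d LTo cells (radius %g um)\n",
              x$environment$width_um, x$environment$height_um,
              x$environment$lto_count, x$environment$lto_radius_um))
  cat(sprintf("  LTin input: %s, %g %% of surface at E15.5, fold %g\n",
              x$input$form, x$input$fraction_pct, x$input$fold))
  cat(sprintf("  LTi input: %s, %g %% of surface at E15.5\n",
              x$input$lti_form, x$input$lti_fraction_pct))
  cat(sprintf("  window: %g h in %g-min steps\n",
              x$input$t_end_hours, x$dt_min))
  invisible(x)
}
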