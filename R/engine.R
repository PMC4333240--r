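#' Run one simulation of the 72-hour developmental window
#'
#' Simulates Peyer's patch formation from E14.5 (t = 0) to E17.5 (t = 72 h)
#' in steps of `dt_min` minutes. Each step: (1) newly arriving LTin and LTi
#' cells are injected at uniformly random positions according to the input
#' schedules; (2) every motile cell is updated in a freshly shuffled order
#' (random-walk or chemokine-biased move, contact detection, arrest check);
#' (3) the step's contact events are applied to the LTo cells synchronously
#' (see [handle_contact()]). At the end of the window arrested cells are
#' clustered into patches and summarised (see [summarise_run()]).
#'
#' All randomness flows through R's RNG seeded with `seed`, so an identical
#' `(config, seed)` pair reproduces the run bitwise.
#'
#' @param config a `pp_config` object.
#' @param seed integer RNG seed for this run.
#' @param keep_state keep the final environment state (cell and LTo tables)
#'   on the result, e.g. for plotting.
#' @param record record per-step diagnostics (cell counts, arrests,
#'   differentiated LTo, active chemokine sources).
#' @return An object of class `pp_run`: `patch_count`,
#'   `median_patch_area_um2`, `total_cells_in`, `seed`, plus bookkeeping
#'   fields (`n_arrested`, `n_lto_differentiated`) and, when requested,
#'   `state` and `diagnostics`.
#' @examples
#' r <- run_simulation(sim_config("test"), seed = 1)
#' r$patch_count
#' @export
run_simulation <- function(config, seed, keep_state = FALSE, record = FALSE) {
  config <- validate_config(config)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  set.seed(as.integer(seed))

  env <- create_environment(config)
  n_steps <- as.integer(round(config$input$t_end_hours * 60 / config$dt_min))
  sch <- schedules_from_config(config)
  inj_ltin <- injection_counts(sch$ltin, config$dt_min, n_steps)
  inj_lti <- injection_counts(sch$lti, config$dt_min, n_steps)

  res <- cpp_run(env$lto$x, env$lto$y, inj_ltin, inj_lti,
                 env$width, env$height, config$dt_min,
                 config$cells$speed_um_per_min,
                 config$cells$motile_radius_um,
                 config$environment$lto_radius_um,
                 config$adhesion$r_adh_um, config$adhesion$l0,
                 config$adhesion$dl,
                 config$chemokine$r_chem_um, config$chemokine$threshold,
                 config$chemokine$fd_step_um, record)

  env$lto$differentiated <- res$lto_differentiated
  env$lto$expression <- res$lto_expression
  env$lto$lti_contacts <- res$lto_contacts
  env$motile <- data.frame(
    x = res$x, y = res$y,
    kind = c("LTin", "LTi")[res$kind + 1L],
    radius = rep(config$cells$motile_radius_um, length(res$x)),
    state = c("migrating", "arrested")[res$state + 1L],
    entry_time = res$entry_time,
    stringsAsFactors = FALSE)

  state <- structure(list(env = env, config = config), class = "pp_state")
  run <- summarise_run(state)
  run$seed <- as.integer(seed)
  if (keep_state) run$state <- state
  if (record) {
    diag <- as.data.frame(res$diagnostics)
    names(diag) <- c("t_hours", "n_cells", "n_arrested",
                     "n_lto_differentiated", "n_chemokine_sources")
    run$diagnostics <- diag
  }
  run
}

#' Summarise a completed run into patch statistics
#'
#' Detects patches among the arrested cells (or, with
#' `patches.basis = "lto"`, among differentiated LTo cells) via single-linkage
#' clustering under the wrapped distance, and reports the patch count and the
#' median patch area. The median of an even-length set is the mean of the two
#' central values; a run with no patches reports a median area of 0 so that
#' every run contributes a comparable value to the A-Test distributions.
#'
#' @param state a `pp_state` (as held on a [run_simulation()] result with
#'   `keep_state = TRUE`).
#' @return A `pp_run` object (without a seed, which the engine attaches).
#' @export
summarise_run <- function(state) {
  stopifnot(inherits(state, "pp_state"))
  config <- state$config
  env <- state$env
  pc <- config$patches

  if (pc$basis == "cells") {
    sel <- env$motile[env$motile$state == "arrested", , drop = FALSE]
    unit_radius <- config$cells$motile_radius_um
  } else {
    sel <- env$lto[env$lto$differentiated, , drop = FALSE]
    unit_radius <- config$environment$lto_radius_um
  }

  patches <- detect_patches(sel, pc$linking_distance_um, pc$min_size, env)
  areas <- vapply(patches, patch_area, numeric(1), cell_radius = unit_radius)

  structure(list(
    patch_count = length(patches),
    median_patch_area_um2 = if (length(areas)) median(areas) else 0,
    total_cells_in = nrow(env$motile),
    n_arrested = sum(env$motile$state == "arrested"),
    n_lto_differentiated = sum(env$lto$differentiated),
    patches = patches,
    seed = NA_integer_
  ), class = "pp_run")
}

#' Run independent replicate simulations of one condition
#'
#' Executes `n` runs whose seeds are derived deterministically and
#' collision-free from `base_seed` (see [derive_seeds()]), producing the
#' distribution of per-run results that the A-Test comparisons operate on.
#'
#' @param config a `pp_config`.
#' @param n number of replicates (`>= 1`).
#' @param base_seed base seed for the condition.
#' @param label optional condition label recorded on the result.
#' @return An object of class `pp_condition`: a data frame with one row per
#'   run (`replicate`, `seed`, `patch_count`, `median_patch_area_um2`,
#'   `total_cells_in`) carrying the config, label and base seed as attributes.
#' @export
run_replicates <- function(config, n, base_seed, label = NULL) {
  config <- validate_config(config)
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("domain error: n must be a single count >= 1", call. = FALSE)
  n <- as.integer(n)
  seeds <- derive_seeds(base_seed, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    r <- run_simulation(config, seeds[i])
    rows[[i]] <- data.frame(replicate = i, seed = seeds[i],
                            patch_count = r$patch_count,
                            median_patch_area_um2 = r$median_patch_area_um2,
                            total_cells_in = r$total_cells_in)
  }
  df <- do.call(rbind, rows)
  structure(df, class = c("pp_condition", "data.frame"),
            config = config, label = label %||% "condition",
            base_seed = as.integer(base_seed))
}

#' Derive replicate seeds from a base seed
#'
#' Counter-based mix `(base * 48271 + index * 1234567) mod (2^31 - 1)`. The
#' modulus is prime and the index multiplier coprime to it, so for a fixed
#' base the map is injective in the index: replicate seeds never collide.
#' Seeds are recorded in all outputs for audit.
#'
#' @param base_seed integer base seed.
#' @param n number of seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(base_seed, n) {
  m <- 2147483647
  base <- as.numeric(base_seed) %% m
  as.integer((base * 48271 + seq_len(n) * 1234567) %% m)
}

#' @export
print.pp_run <- function(x, ...) {
  cat(sprintf("simulated run (seed %s): %d patches, median area %.2f um^2\n",
              ifelse(is.na(x$seed), "?", x$seed), x$patch_count,
              x$median_patch_area_um2))
  cat(sprintf("  %d cells entered, %d arrested, %d LTo differentiated\n",
              x$total_cells_in, x$n_arrested, x$n_lto_differentiated))
  invisible(x)
}

#' @export
print.pp_condition <- function(x, ...) {
  cat(sprintf("condition '%s': %d replicates (base seed %d)\n",
              attr(x, "label"), nrow(x), attr(x, "base_seed")))
  cat(sprintf("  patch count: median %g [%g, %g]\n",
              median(x$patch_count), min(x$patch_count), max(x$patch_count)))
  cat(sprintf("  median patch area: median %.1f um^2\n",
              median(x$median_patch_area_um2)))
  invisible(x)
}

#' @export
summary.pp_condition <- function(object, ...) {
  data.frame(
    label = attr(object, "label"),
    n = nrow(object),
    median_patch_count = median(object$patch_count),
    min_patch_count = min(object$patch_count),
    max_patch_count = max(object$patch_count),
    median_area_um2 = median(object$median_patch_area_um2))
}
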