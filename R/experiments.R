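#' Assumption experiment 1: perturb the E15.5 LTin cell count
#'
#' The model's first key assumption is that the LTin cell count at E15.5
#' should match the flow-cytometry estimate (0.45 % of gut surface area).
#' This driver re-runs the simulation with the count calculated from reduced
#' surface-area percentages (default 0.05-0.45 % in 0.05 % steps) and from
#' 2-5 fold increases, and compares each condition's distributions of
#' per-run patch count and median patch area against the baseline with the
#' A-Test. Conditions use disjoint deterministic seed streams (no
#' common-random-numbers pairing): distributions are compared as independent
#' samples. The baseline is compared against itself, so its rows carry
#' a = 0.5 exactly.
#'
#' @param base baseline `pp_config` (its `input$fraction_pct` is the
#'   baseline percentage; added to the grid if absent).
#' @param fractions surface-area percentages to explore.
#' @param folds fold increases of the baseline count to explore.
#' @param n_reps replicates per condition (`>= 2`); the 300 used for the
#'   published analyses is the default, desk-scale runs pass less.
#' @param base_seed base seed; per-condition seeds derive from it.
#' @return An object of class `pp_experiment`: a data frame with one row per
#'   (condition, response) -- columns `condition`, `response`, `a`,
#'   `magnitude`, `category`, `n_reps`, `base_seed` -- with the per-condition
#'   result distributions attached as the `"distributions"` attribute.
#' @seealso [migration_experiment()], [plot.pp_experiment()]
#' @export
cellcount_experiment <- function(base, fractions = seq(0.05, 0.45, by = 0.05),
                                 folds = 2:5, n_reps = 300, base_seed = 1) {
  base <- validate_config(base)
  if (!is.numeric(n_reps) || n_reps < 2)
    stop("domain error: n_reps must be >= 2", call. = FALSE)

  base_frac <- base$input$fraction_pct
  fr <- sort(unique(c(fractions, base_frac)), decreasing = TRUE)
  conditions <- list()
  for (f in fr) {
    cfg <- base
    cfg$input$fraction_pct <- f
    cfg$input$fold <- 1
    lab <- if (isTRUE(all.equal(f, base_frac))) "baseline"
           else sprintf("fraction_%.2fpct", f)
    conditions[[lab]] <- cfg
  }
  for (m in sort(folds)) {
    cfg <- base
    cfg$input$fold <- m
    conditions[[sprintf("fold_%gx", m)]] <- cfg
  }
  run_experiment(base, conditions, baseline_label = "baseline",
                 n_reps = n_reps, base_seed = base_seed,
                 varied_subtree = "input")
}

#' Assumption experiment 2: replace the LTin migration-rate function
#'
#' The model's second key assumption is that LTin cells migrate into the gut
#' at a constant (linear) rate, extrapolated from the single E15.5 estimate.
#' This driver swaps the LTin input schedule for the exponential
#' (slow-then-fast) and square-root (fast-then-slow) alternatives. All forms
#' deliver exactly the same cell count at E15.5 -- the one timepoint anchored
#' to data -- and run with their own shape to E17.5. Comparisons against the
#' linear baseline are as in [cellcount_experiment()].
#'
#' @param base baseline `pp_config` (the linear form is forced for the
#'   baseline condition).
#' @param forms schedule forms to run; must include `"linear"`.
#' @param n_reps replicates per condition (`>= 2`).
#' @param base_seed base seed.
#' @return A `pp_experiment` (see [cellcount_experiment()]); the shared
#'   E15.5 count is attached as attribute `"n_e155"`.
#' @export
migration_experiment <- function(base,
                                 forms = c("linear", "exponential", "sqrt"),
                                 n_reps = 300, base_seed = 1) {
  base <- validate_config(base)
  if (!is.numeric(n_reps) || n_reps < 2)
    stop("domain error: n_reps must be >= 2", call. = FALSE)
  if (!"linear" %in% forms)
    stop("configuration error: the linear form is the baseline and must be ",
         "included", call. = FALSE)
  bad <- setdiff(forms, c("linear", "exponential", "sqrt"))
  if (length(bad))
    stop("configuration error: unknown input form(s): ",
         paste(bad, collapse = ", "), call. = FALSE)

  conditions <- list()
  for (f in unique(forms)) {
    cfg <- base
    cfg$input$form <- f
    conditions[[f]] <- cfg
  }
  out <- run_experiment(base, conditions, baseline_label = "linear",
                        n_reps = n_reps, base_seed = base_seed,
                        varied_subtree = "input")
  attr(out, "n_e155") <- schedules_from_config(base)$ltin$n_e155
  out
}

run_experiment <- function(base, conditions, baseline_label, n_reps,
                           base_seed, varied_subtree) {
  for (lab in names(conditions))
    check_single_subtree_diff(base, conditions[[lab]], varied_subtree, lab)

  dists <- list()
  for (i in seq_along(conditions)) {
    lab <- names(conditions)[i]
    cond_seed <- derive_seeds(as.numeric(base_seed) + 1000003, 1000)[i]
    dists[[lab]] <- run_replicates(conditions[[lab]], n_reps, cond_seed,
                                   label = lab)
  }

  responses <- c("patch_count", "median_patch_area_um2")
  rows <- list()
  basedist <- dists[[baseline_label]]
  for (lab in names(conditions)) {
    for (resp in responses) {
      at <- a_test(dists[[lab]][[resp]], basedist[[resp]])
      rows[[length(rows) + 1]] <- data.frame(
        condition = lab, response = resp, a = at$a,
        magnitude = at$magnitude, category = at$category,
        n_reps = as.integer(n_reps), base_seed = as.integer(base_seed),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  structure(tab, class = c("pp_experiment", "data.frame"),
            distributions = dists, baseline = baseline_label,
            config = base)
}

# every condition must differ from the baseline config in exactly one
# configuration subtree -- checked mechanically before any run
check_single_subtree_diff <- function(base, cfg, subtree, label) {
  for (nm in names(base)) {
    if (nm == subtree) next
    if (!identical(base[[nm]], cfg[[nm]]))
      stop("configuration error: condition '", label, "' differs from the ",
           "baseline outside the '", subtree, "' subtree ('", nm, "')",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Write an experiment table to CSV
#'
#' @param table a `pp_experiment`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0)
    stop("nothing to write: empty experiment table", call. = FALSE)
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Write per-condition run results to CSV
#'
#' One row per run: `condition_label`, `replicate_index`, `seed`,
#' `patch_count`, `median_patch_area_um2`, `total_cells_in`.
#'
#' @param cond a `pp_condition`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_condition <- function(cond, path) {
  stopifnot(inherits(cond, "pp_condition"))
  df <- data.frame(condition_label = attr(cond, "label"),
                   replicate_index = cond$replicate, seed = cond$seed,
                   patch_count = cond$patch_count,
                   median_patch_area_um2 = cond$median_patch_area_um2,
                   total_cells_in = cond$total_cells_in)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.pp_experiment <- function(x, ...) {
  cat(sprintf("assumption experiment: %d conditions vs '%s' (%d reps each)\n",
              length(unique(x$condition)), attr(x, "baseline"),
              x$n_reps[1]))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
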