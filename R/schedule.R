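#' Cumulative cell-input schedule
#'
#' The number of cells that have entered the gut by time `t` (hours since
#' E14.5) is modelled by one of three functional forms, all anchored to the
#' same count `n_e155` at E15.5 (t = 24 h) -- the only timepoint at which a
#' cell count has been estimated from flow cytometry. The linear form is the
#' model's baseline assumption; the exponential (slow start, rapid late
#' increase) and square-root (rapid start, tailing off) forms are the two
#' alternatives explored by the migration-rate experiment. Each form runs with
#' its own shape through to `t_end`, so the total input differs between forms
#' by design.
#'
#' @param form `"linear"`, `"exponential"` or `"sqrt"`.
#' @param n_e155 cell count at E15.5 (t = 24 h).
#' @param k exponential growth constant (per hour; used only by the
#'   exponential form). The default, `log(2) / 24`, doubles the instantaneous
#'   rate every 24 hours, giving a visibly slow-then-fast input over the
#'   72-h window.
#' @param t_end end of the simulated window (hours, default 72 = E17.5).
#' @return An object of class `pp_schedule`.
#' @seealso [cumulative_input()], [cells_to_inject()], [e155_count()]
#' @export
input_schedule <- function(form = c("linear", "exponential", "sqrt"),
                           n_e155, k = log(2) / 24, t_end = 72) {
  form <- match.arg(form)
  stopifnot(is.numeric(n_e155), length(n_e155) == 1, n_e155 >= 0,
            is.numeric(k), k > 0, is.numeric(t_end), t_end >= 24)
  structure(list(form = form, n_e155 = as.numeric(n_e155), k = k,
                 t_end = t_end), class = "pp_schedule")
}

#' Expected cumulative cell input at time t
#'
#' Closed forms (t in hours since E14.5, anchor at 24 h):
#' \describe{
#'   \item{linear}{`n_e155 * t / 24`}
#'   \item{sqrt}{`n_e155 * sqrt(t / 24)`}
#'   \item{exponential}{`n_e155 * (exp(k t) - 1) / (exp(24 k) - 1)`}
#' }
#' All three are 0 at t = 0 and exactly `n_e155` at t = 24.
#'
#' @param t time in hours, within `[0, t_end]`. Vectorised.
#' @param s a `pp_schedule`.
#' @return Expected cumulative count (real-valued).
#' @export
cumulative_input <- function(t, s) {
  stopifnot(inherits(s, "pp_schedule"))
  if (any(!is.finite(t)) || any(t < 0) || any(t > s$t_end))
    stop("domain error: t must lie in [0, ", s$t_end, "]", call. = FALSE)
  switch(s$form,
         linear = s$n_e155 * t / 24,
         sqrt = s$n_e155 * sqrt(t / 24),
         exponential = s$n_e155 * (exp(s$k * t) - 1) / (exp(24 * s$k) - 1))
}

#' Integerised injection over a time interval
#'
#' Converts the continuous schedule into whole cells using a fractional-
#' remainder accumulator: the count injected over `(t_prev, t]` is
#' `floor(carry + cumulative(t) - cumulative(t_prev))` and the new carry is
#' the fractional part left over. Over any partition of `[0, t_end]` the
#' injected total is exactly `floor(cumulative(t_end))`, independent of step
#' size.
#'
#' @param t_prev,t interval endpoints (hours), `t_prev <= t`.
#' @param s a `pp_schedule`.
#' @param carry fractional remainder from the previous interval (in `[0, 1)`).
#' @return A list with integer `count` and the new `carry`.
#' @export
cells_to_inject <- function(t_prev, t, s, carry = 0) {
  if (t_prev > t)
    stop("domain error: t_prev must not exceed t", call. = FALSE)
  gain <- carry + cumulative_input(t, s) - cumulative_input(t_prev, s)
  count <- floor(gain)
  list(count = as.integer(count), carry = gain - count)
}

#' LTin cell count at E15.5 from the surface-area estimate
#'
#' Flow cytometry data anchor the model to the real system through a single
#' number: the fraction of the gut surface area occupied by LTin cells at
#' E15.5 (0.45 % at baseline). Dividing the occupied area by the footprint of
#' one cell gives the cell count:
#' `floor(fraction * gut_area / (pi * cell_radius^2))`.
#'
#' @param fraction proportion of gut surface area in `[0, 1]` (note:
#'   proportion, not percentage).
#' @param gut_area gut surface area (um^2).
#' @param cell_radius LTin cell radius (um).
#' @return Integer cell count.
#' @examples
#' e155_count(0.0045, 5e6, 5)  # baseline full profile: 286 cells
#' @export
e155_count <- function(fraction, gut_area, cell_radius) {
  stopifnot(is.numeric(fraction), fraction >= 0, fraction <= 1,
            is.numeric(gut_area), gut_area > 0,
            is.numeric(cell_radius), cell_radius > 0)
  as.integer(floor(fraction * gut_area / (pi * cell_radius^2)))
}

# Per-step injection counts over the whole run: diff(floor(cumulative)) at
# the step boundaries, which equals iterating cells_to_inject with its carry.
injection_counts <- function(s, dt_min, n_steps) {
  t_bounds <- (0:n_steps) * dt_min / 60
  t_bounds[n_steps + 1] <- s$t_end  # guard fp drift at the last boundary
  as.integer(diff(floor(cumulative_input(t_bounds, s))))
}

schedules_from_config <- function(config) {
  area <- config$environment$width_um * config$environment$height_um
  r <- config$cells$motile_radius_um
  n_ltin <- e155_count(config$input$fraction_pct / 100, area, r) *
    config$input$fold
  n_lti <- e155_count(config$input$lti_fraction_pct / 100, area, r)
  list(
    ltin = input_schedule(config$input$form, n_ltin,
                          k = config$input$k_per_hour,
                          t_end = config$input$t_end_hours),
    lti = input_schedule(config$input$lti_form, n_lti,
                         k = config$input$k_per_hour,
                         t_end = config$input$t_end_hours)
  )
}

#' @export
print.pp_schedule <- function(x, ...) {
  cat(sprintf("%s input schedule: %g cells at E15.5 (t = 24 h), t_end %g h",
              x$form, x$n_e155, x$t_end))
  if (x$form == "exponential") cat(sprintf(", k = %.4g /h", x$k))
  cat("\n")
  invisible(x)
}
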