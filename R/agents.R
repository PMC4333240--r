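#' Construct a motile cell
#'
#' @param kind `"LTin"` or `"LTi"`.
#' @param position numeric length-2 position in micrometres.
#' @param radius cell radius (um).
#' @param state `"migrating"` or `"arrested"`.
#' @param entry_time hours since E14.5 at which the cell entered the gut.
#' @return A list of class `pp_cell`.
#' @export
motile_cell <- function(kind = c("LTin", "LTi"), position, radius = 5,
                        state = c("migrating", "arrested"), entry_time = 0) {
  kind <- match.arg(kind)
  state <- match.arg(state)
  stopifnot(is.numeric(position), length(position) == 2)
  structure(list(kind = kind, position = as.numeric(position),
                 radius = radius, state = state, entry_time = entry_time),
            class = "pp_cell")
}

#' Per-step arrest probability near a differentiated LTo
#'
#' Differentiated LTo cells express factors that promote adhesion of motile
#' cells in their vicinity. The per-step probability that a migrating cell
#' arrests, evaluated against the nearest differentiated LTo, is
#' `expression * max(0, 1 - d / r_adh)`: proportional to the LTo's expression
#' level and decaying linearly to zero at the adhesion radius.
#'
#' @param expression LTo expression level in `[0, 1]`.
#' @param d distance to the LTo centre (um), `>= 0`.
#' @param r_adh adhesion radius (um), `> 0`.
#' @return Probability in `[0, 1]`. Vectorised over its arguments.
#' @examples
#' adhesion_arrest_probability(0.5, 25, 50)  # 0.25
#' @export
adhesion_arrest_probability <- function(expression, d, r_adh) {
  if (any(!is.finite(expression)) || any(expression < 0) ||
      any(expression > 1))
    stop("domain error: expression must lie in [0, 1]", call. = FALSE)
  if (any(d < 0) || any(r_adh <= 0))
    stop("domain error: d must be >= 0 and r_adh > 0", call. = FALSE)
  expression * pmax(0, 1 - d / r_adh)
}

#' Apply a contact event to an LTo cell
#'
#' Encodes the contact rules of the model: an LTin contact differentiates an
#' undifferentiated LTo (expression jumps to `l0`); an LTi contact matures an
#' already-differentiated LTo (one more recorded contact, expression raised by
#' `dl`, capped at 1). LTi contact with an undifferentiated LTo has no effect
#' (only LTin initiate), and repeated LTin contact with a differentiated LTo
#' has no further effect.
#'
#' @param lto a one-row list or data frame row with fields `differentiated`,
#'   `expression`, `lti_contacts`.
#' @param cell a `pp_cell` (only its `kind` is used) or a kind string.
#' @param l0 expression level at differentiation.
#' @param dl expression increment per LTi contact.
#' @return The updated LTo (same shape as the input).
#' @export
handle_contact <- function(lto, cell, l0 = 0.2, dl = 0.005) {
  kind <- if (is.character(cell)) cell else cell$kind
  if (!kind %in% c("LTin", "LTi"))
    stop("domain error: unknown cell kind '", kind, "'", call. = FALSE)
  if (kind == "LTin") {
    if (!lto$differentiated) {
      lto$differentiated <- TRUE
      lto$expression <- l0
    }
  } else if (lto$differentiated) {
    lto$lti_contacts <- lto$lti_contacts + 1L
    lto$expression <- min(1, lto$expression + dl)
  }
  lto
}

#' Advance an LTin cell by one step
#'
#' LTin cells perform an unbiased random walk: a migrating cell moves exactly
#' `speed * dt` in a uniformly random direction (positions wrapped by the
#' domain topology). Any LTo whose centre lies within the sum of the two radii
#' receives a contact event, and the cell then arrests with probability
#' [adhesion_arrest_probability()] evaluated against the nearest
#' differentiated LTo. Arrest is absorbing: an arrested cell never moves or
#' emits events again.
#'
#' Contact events are returned rather than applied; the caller applies them
#' via [handle_contact()] (the engine does so synchronously at the end of each
#' step).
#'
#' @param cell a `pp_cell` with `kind == "LTin"`.
#' @param env a `pp_environment`.
#' @return A list with the updated `cell` and `events`, a data frame with one
#'   row per contacted LTo (`lto` index and `kind`).
#' @export
step_ltin <- function(cell, env) {
  stopifnot(inherits(cell, "pp_cell"), cell$kind == "LTin")
  step_motile(cell, env, direction = random_unit_vector())
}

#' Advance an LTi cell by one step
#'
#' LTi cells perform a chemokine-biased random walk. With local concentration
#' `c` (see [chemokine_level()]) the bias is `b = min(1, c)` and the step
#' direction is `normalise((1 - b) * u + b * g_hat)`, where `u` is a uniformly
#' random unit vector and `g_hat` the unit chemokine gradient: an unbiased
#' walk in a flat field, a deterministic gradient ascent in a saturated one.
#' Contact and arrest behave as for [step_ltin()].
#'
#' @param cell a `pp_cell` with `kind == "LTi"`.
#' @param env a `pp_environment`.
#' @return As [step_ltin()].
#' @export
step_lti <- function(cell, env) {
  stopifnot(inherits(cell, "pp_cell"), cell$kind == "LTi")
  u <- random_unit_vector()
  b <- min(1, chemokine_level(env, cell$position))
  dir <- u
  if (b > 0) {
    g <- chemokine_gradient(env, cell$position)
    gn <- sqrt(sum(g^2))
    ghat <- if (gn > 0) g / gn else c(0, 0)
    v <- (1 - b) * u + b * ghat
    vn <- sqrt(sum(v^2))
    if (vn > 0) dir <- v / vn
  }
  step_motile(cell, env, direction = dir)
}

random_unit_vector <- function() {
  theta <- runif(1, 0, 2 * pi)
  c(cos(theta), sin(theta))
}

step_motile <- function(cell, env, direction) {
  no_events <- data.frame(lto = integer(0), kind = character(0),
                          stringsAsFactors = FALSE)
  if (cell$state == "arrested")
    return(list(cell = cell, events = no_events))

  cfg <- env$config
  step_len <- cfg$cells$speed_um_per_min * cfg$dt_min
  cell$position <- wrap_position(cell$position + step_len * direction, env)

  events <- no_events
  if (nrow(env$lto)) {
    d <- wrapped_distance(matrix(cell$position, ncol = 2, nrow = nrow(env$lto),
                                 byrow = TRUE),
                          cbind(env$lto$x, env$lto$y), env)
    touched <- which(d <= cell$radius + env$lto$radius)
    if (length(touched))
      events <- data.frame(lto = touched,
                           kind = rep(cell$kind, length(touched)),
                           stringsAsFactors = FALSE)
    diffed <- which(env$lto$differentiated)
    if (length(diffed)) {
      j <- diffed[which.min(d[diffed])]
      p <- adhesion_arrest_probability(env$lto$expression[j], d[j],
                                       cfg$adhesion$r_adh_um)
      if (p > 0 && runif(1) < p) cell$state <- "arrested"
    }
  }
  list(cell = cell, events = events)
}
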