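#' Create the simulation environment
#'
#' Builds the 2-D gut-surface domain and places the requested number of
#' stationary LTo (stromal organiser) cells uniformly at random without
#' pairwise overlap, by rejection sampling against the wrapped distance.
#' Placement consumes the current R random-number stream, so with a fixed
#' seed it is reproducible bit-for-bit. The motile-cell collection starts
#' empty; cells enter during the run according to the input schedules.
#'
#' The domain is periodic on the long (x) axis and reflective on the short
#' (y) axis.
#'
#' @param config a `pp_config` object (see [sim_config()]).
#' @return An object of class `pp_environment`: a list with `width`, `height`,
#'   an `lto` data frame (`x`, `y`, `radius`, `differentiated`, `expression`,
#'   `lti_contacts`), an empty `motile` data frame, and the configuration.
#' @export
create_environment <- function(config) {
  config <- validate_config(config)
  w <- config$environment$width_um
  h <- config$environment$height_um
  n <- config$environment$lto_count
  r <- config$environment$lto_radius_um

  if (n * pi * r^2 > 0.9 * w * h)
    stop("placement error: ", n, " LTo cells of radius ", r,
         " um cannot be packed into a ", w, " x ", h, " um domain ",
         "(required area exceeds 90% of the domain)", call. = FALSE)

  x <- numeric(n)
  y <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 1000L + 200L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("placement error: failed to place ", n, " non-overlapping LTo ",
           "cells after ", attempts - 1L, " attempts", call. = FALSE)
    cx <- runif(1, 0, w)
    cy <- runif(1, 0, h)
    if (placed > 0L) {
      d <- cpp_wrapped_distance(rep(cx, placed), rep(cy, placed),
                                x[seq_len(placed)], y[seq_len(placed)], w)
      if (any(d <= 2 * r)) next
    }
    placed <- placed + 1L
    x[placed] <- cx
    y[placed] <- cy
  }

  structure(list(
    width = w, height = h,
    lto = data.frame(x = x, y = y, radius = rep(r, n),
                     differentiated = rep(FALSE, n),
                     expression = rep(0, n),
                     lti_contacts = rep(0L, n)),
    motile = empty_motile(),
    config = config
  ), class = "pp_environment")
}

empty_motile <- function() {
  data.frame(x = numeric(0), y = numeric(0), kind = character(0),
             radius = numeric(0), state = character(0),
             entry_time = numeric(0), stringsAsFactors = FALSE)
}

#' Wrap a point into the domain
#'
#' Applies the domain's boundary convention: x is wrapped modulo the width
#' (periodic long axis, the gut tube seam) and y is reflected at 0 and the
#' height (mirror short axis).
#'
#' @param p numeric length-2 point `(x, y)` in micrometres.
#' @param env a `pp_environment`, or any list with `width` and `height`.
#' @return The wrapped point, satisfying `0 <= x < width`, `0 <= y <= height`.
#' @examples
#' env <- list(width = 5000, height = 1000)
#' wrap_position(c(5010, 500), env)  # periodic: (10, 500)
#' wrap_position(c(2500, 1010), env) # reflected: (2500, 990)
#' @export
wrap_position <- function(p, env) {
  stopifnot(is.numeric(p), length(p) == 2)
  cpp_wrap_point(p[1], p[2], env$width, env$height)
}

#' Wrapped distance between points
#'
#' Distance respecting the periodic/reflective topology: the x separation is
#' the shorter way around the periodic axis, the y separation is plain.
#' Vectorised over point pairs.
#'
#' @param p,q numeric length-2 points, or 2-column matrices of points.
#' @param env a `pp_environment`, or any list with `width` and `height`.
#' @return Numeric vector of distances in micrometres.
#' @export
wrapped_distance <- function(p, q, env) {
  p <- matrix(p, ncol = 2)
  q <- matrix(q, ncol = 2)
  cpp_wrapped_distance(p[, 1], p[, 2], q[, 1], q[, 2], env$width)
}

#' Chemokine concentration at a point
#'
#' The chemokine field is static and instantaneous: each differentiated LTo
#' cell whose expression level has reached the chemokine threshold contributes
#' a radial linear-decay kernel `expression * max(0, 1 - d / r_chem)`, where
#' `d` is the wrapped distance to the LTo centre, and contributions add.
#'
#' @param env a `pp_environment`.
#' @param p numeric length-2 point.
#' @return Non-negative concentration (dimensionless).
#' @export
chemokine_level <- function(env, p) {
  stopifnot(is.numeric(p), length(p) == 2)
  ch <- env$config$chemokine
  cpp_chem_level(p[1], p[2], env$lto$x, env$lto$y, env$lto$differentiated,
                 env$lto$expression, ch$threshold, ch$r_chem_um,
                 env$width, env$height)
}

#' Chemokine gradient at a point
#'
#' Central finite-difference gradient of [chemokine_level()] with step
#' `chemokine.fd_step_um`; the zero vector where the field is locally flat.
#' Used as the bias direction of the LTi chemokine-biased walk.
#'
#' @inheritParams chemokine_level
#' @return Numeric length-2 gradient vector (concentration per micrometre).
#' @export
chemokine_gradient <- function(env, p) {
  stopifnot(is.numeric(p), length(p) == 2)
  ch <- env$config$chemokine
  cpp_chem_gradient(p[1], p[2], env$lto$x, env$lto$y, env$lto$differentiated,
                    env$lto$expression, ch$threshold, ch$r_chem_um,
                    ch$fd_step_um, env$width, env$height)
}

#' @export
print.pp_environment <- function(x, ...) {
  cat(sprintf("gut-surface domain %g x %g um: %d LTo (%d differentiated), %d motile cells\n",
              x$width, x$height, nrow(x$lto), sum(x$lto$differentiated),
              nrow(x$motile)))
  invisible(x)
}
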