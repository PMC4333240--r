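#' Detect patches among arrested cells
#'
#' A patch (immature Peyer's patch) is a single-linkage cluster of arrested
#' cells: connected components of the graph joining every pair of cells whose
#' wrapped distance is at most `linking_distance`. Components smaller than
#' `min_size` are discarded. Every cell belongs to at most one patch.
#'
#' @param cells a data frame with columns `x` and `y` (positions in um),
#'   typically the arrested subset of the motile-cell table.
#' @param linking_distance maximum neighbour distance (um), `> 0`.
#' @param min_size minimum component size retained, `>= 1`.
#' @param env a `pp_environment`, or any list with `width` and `height`
#'   (the domain topology for wrapped distances).
#' @return A list of class `pp_patches`; each element is a `pp_patch` list
#'   with `members` (row indices into `cells`), `size`, and `centroid` (the
#'   x coordinate is a circular mean respecting the periodic axis).
#' @examples
#' env <- list(width = 5000, height = 1000)
#' cells <- data.frame(x = c(0, 10, 100), y = 0)
#' length(detect_patches(cells, 20, 1, env))  # 2 patches
#' @export
detect_patches <- function(cells, linking_distance, min_size, env) {
  if (!is.numeric(linking_distance) || linking_distance <= 0)
    stop("domain error: linking_distance must be > 0", call. = FALSE)
  if (!is.numeric(min_size) || min_size < 1)
    stop("domain error: min_size must be >= 1", call. = FALSE)
  n <- nrow(cells)
  if (is.null(n) || n == 0)
    return(structure(list(), class = "pp_patches"))

  lab <- cpp_single_linkage(cells$x, cells$y, env$width, linking_distance)
  out <- list()
  for (g in unique(lab)) {
    members <- which(lab == g)
    if (length(members) < min_size) next
    out[[length(out) + 1]] <- structure(
      list(members = members, size = length(members),
           centroid = wrapped_centroid(cells$x[members], cells$y[members],
                                       env$width)),
      class = "pp_patch")
  }
  structure(out, class = "pp_patches")
}

# Circular mean on the periodic axis, plain mean on the reflective one.
wrapped_centroid <- function(x, y, width) {
  theta <- 2 * pi * x / width
  cx <- atan2(mean(sin(theta)), mean(cos(theta))) * width / (2 * pi)
  if (cx < 0) cx <- cx + width
  c(x = cx, y = mean(y))
}

#' Patch area
#'
#' The area proxy is the summed footprint of the member cells,
#' `size * pi * cell_radius^2`: monotone in membership and robust for small
#' or elongated clusters (unlike a convex hull).
#'
#' @param p a `pp_patch`.
#' @param cell_radius radius of the member cells (um).
#' @return Area in um^2.
#' @export
patch_area <- function(p, cell_radius) {
  if (is.null(p$size) || p$size < 1)
    stop("domain error: patch must be non-empty", call. = FALSE)
  p$size * pi * cell_radius^2
}

#' @export
print.pp_patches <- function(x, ...) {
  cat(length(x), "patch(es)")
  if (length(x))
    cat(": sizes", paste(vapply(x, `[[`, integer(1), "size"),
                         collapse = ", "))
  cat("\n")
  invisible(x)
}
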