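#' Plot an experiment table
#'
#' Renders, per response, a boxplot of the per-condition result distributions
#' and a chart of the A-Test scores against the baseline with horizontal
#' guides at 0.29, 0.44, 0.56 and 0.71 (the large- and small-effect
#' boundaries). With `dir` given, writes one PNG per panel and returns the
#' file paths; otherwise draws on the current device.
#'
#' @param x a `pp_experiment`.
#' @param dir optional output directory for PNG files.
#' @param width,height device size in pixels when writing files.
#' @param ... ignored.
#' @return Invisibly, the written file paths (or `NULL` when drawing on the
#'   current device).
#' @export
plot.pp_experiment <- function(x, dir = NULL, width = 900, height = 500,
                               ...) {
  dists <- attr(x, "distributions")
  if (is.null(dists) || !length(dists))
    stop("nothing to plot: experiment carries no distributions",
         call. = FALSE)
  responses <- unique(x$response)
  labels <- c(patch_count = "patch count",
              median_patch_area_um2 = "median patch area (um^2)")
  paths <- character(0)

  for (resp in responses) {
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      f <- file.path(dir, paste0("boxplot_", resp, ".png"))
      grDevices::png(f, width = width, height = height)
      paths <- c(paths, f)
    }
    vals <- lapply(dists, `[[`, resp)
    graphics::boxplot(vals, las = 2, ylab = labels[[resp]],
                      main = paste("per-run", labels[[resp]],
                                   "by condition"),
                      cex.axis = 0.8)
    if (!is.null(dir)) grDevices::dev.off()
  }

  for (resp in responses) {
    if (!is.null(dir)) {
      f <- file.path(dir, paste0("atest_", resp, ".png"))
      grDevices::png(f, width = width, height = height)
      paths <- c(paths, f)
    }
    sub <- x[x$response == resp, ]
    graphics::plot(seq_len(nrow(sub)), sub$a, ylim = c(0, 1), xaxt = "n",
                   xlab = "", ylab = "A statistic vs baseline", pch = 19,
                   main = paste("A-Test scores:", labels[[resp]]))
    graphics::axis(1, at = seq_len(nrow(sub)), labels = sub$condition,
                   las = 2, cex.axis = 0.8)
    graphics::abline(h = c(0.29, 0.44, 0.56, 0.71), lty = 2,
                     col = "grey40")
    graphics::abline(h = 0.5, lty = 1, col = "grey70")
    if (!is.null(dir)) grDevices::dev.off()
  }
  invisible(if (length(paths)) paths else NULL)
}

#' Plot the final state of a run
#'
#' Spatial snapshot at E17.5: LTo cells as open (undifferentiated) or filled
#' (differentiated) circles scaled by expression, motile cells as points
#' coloured by kind, arrested cells emphasised. Requires a run executed with
#' `keep_state = TRUE`.
#'
#' @param x a `pp_run` carrying its final state.
#' @param ... ignored.
#' @export
plot.pp_run <- function(x, ...) {
  if (is.null(x$state))
    stop("run was not executed with keep_state = TRUE", call. = FALSE)
  env <- x$state$env
  graphics::plot(NA, xlim = c(0, env$width), ylim = c(0, env$height),
                 xlab = "x (um)", ylab = "y (um)", asp = 1,
                 main = sprintf("E17.5 state: %d patches", x$patch_count))
  mig <- env$motile[env$motile$state == "migrating", ]
  arr <- env$motile[env$motile$state == "arrested", ]
  graphics::points(mig$x, mig$y, pch = ".", col = "grey60")
  graphics::points(arr$x, arr$y, pch = 19, cex = 0.35,
                   col = ifelse(arr$kind == "LTin", "firebrick",
                                "dodgerblue3"))
  graphics::symbols(env$lto$x, env$lto$y,
                    circles = env$lto$radius + 40 * env$lto$expression,
                    inches = FALSE, add = TRUE,
                    fg = ifelse(env$lto$differentiated, "black", "grey70"))
  invisible(x)
}

#' Boxplot of a condition's replicate distribution
#'
#' @param x a `pp_condition`.
#' @param ... ignored.
#' @export
plot.pp_condition <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::boxplot(x$patch_count, ylab = "patch count",
                    main = attr(x, "label"))
  graphics::boxplot(x$median_patch_area_um2,
                    ylab = "median patch area (um^2)",
                    main = attr(x, "label"))
  invisible(x)
}
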