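#' Vargha-Delaney A-Test
#'
#' Non-parametric effect-magnitude statistic comparing two result
#' distributions: the probability that a randomly selected value from the
#' first sample exceeds a randomly selected value from the second, with ties
#' counted at half weight:
#' `A = (#\{x_i > y_j\} + 0.5 * #\{x_i = y_j\}) / (n1 * n2)`.
#' A value of 0.5 indicates no difference; values at or above 0.71 or at or
#' below 0.29 indicate a scientifically significant (large) difference.
#'
#' Computed via the midrank formula `A = (R1 - n1 (n1 + 1) / 2) / (n1 n2)`
#' (with `R1` the rank sum of the first sample in the pooled ranking), which
#' equals the pairwise definition exactly: rank sums involve only integers
#' and halves, so no float-order nondeterminism enters before the single
#' final division.
#'
#' @param x,y non-empty numeric samples (e.g. per-run patch counts for two
#'   conditions).
#' @return An object of class `pp_atest`: `a`, `magnitude` (`|a - 0.5|`),
#'   `category` (see [classify_effect()]), and the sample sizes `n1`, `n2`.
#' @examples
#' a_test(c(10, 11), c(1, 2))$a        # 1: complete separation
#' a_test(1:3, 1:3)$a                  # 0.5: identical samples
#' @export
a_test <- function(x, y) {
  if (length(x) < 1 || length(y) < 1)
    stop("domain error: both samples must be non-empty", call. = FALSE)
  if (!is.numeric(x) || !is.numeric(y) || anyNA(x) || anyNA(y))
    stop("domain error: samples must be numeric without missing values",
         call. = FALSE)
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))  # midranks for ties
  r1 <- sum(r[seq_len(n1)])
  a <- (r1 - n1 * (n1 + 1) / 2) / (n1 * n2)
  structure(list(a = a, magnitude = abs(a - 0.5),
                 category = classify_effect(a), n1 = n1, n2 = n2),
            class = "pp_atest")
}

#' Classify an A statistic into an effect-magnitude category
#'
#' With `m = |a - 0.5|`: `m < 0.06` is no effect, `0.06 <= m < 0.14` small,
#' `0.14 <= m < 0.21` medium, and `m >= 0.21` large -- so "large" corresponds
#' exactly to the significance boundaries `a >= 0.71` or `a <= 0.29`. The
#' table is symmetric about 0.5, and thresholds are inclusive on the
#' larger-effect side (a = 0.71 classifies as large) for determinism at
#' boundaries; a small guard tolerance keeps decimal inputs such as 0.71 on
#' the intended side of binary-float thresholds.
#'
#' @param a A statistic(s) in `[0, 1]`. Vectorised.
#' @return Character vector: `"none"`, `"small"`, `"medium"` or `"large"`.
#' @examples
#' classify_effect(c(0.5, 0.6, 0.36, 0.71, 0.29))
#' @export
classify_effect <- function(a) {
  if (!is.numeric(a) || anyNA(a) || any(a < 0) || any(a > 1))
    stop("domain error: a must lie in [0, 1]", call. = FALSE)
  m <- abs(a - 0.5)
  eps <- 1e-9
  ifelse(m >= 0.21 - eps, "large",
         ifelse(m >= 0.14 - eps, "medium",
                ifelse(m >= 0.06 - eps, "small", "none")))
}

#' Replicate-consistency analysis
#'
#' Determines the minimum number of replicate runs needed to mitigate the
#' simulator's inherent stochasticity. For each candidate replicate count
#' `n`, `n_subsets` independent result distributions of size `n` are
#' generated at the unperturbed configuration; each subset's `patch_count`
#' and `median_patch_area_um2` distributions are compared against the first
#' subset with [a_test()]. A candidate is sufficient when the maximum A-Test
#' magnitude across subsets and both responses falls in the no-effect band
#' (`< 0.06`): at that replicate count, re-running the same condition no
#' longer looks like a changed condition.
#'
#' @param config a `pp_config` (passed to `sim_fun`).
#' @param candidate_ns increasing vector of candidate replicate counts.
#' @param n_subsets number of independent subsets per candidate (`>= 2`).
#' @param base_seed base seed; each subset's seed is derived from it.
#' @param sim_fun function `(config, n, seed)` returning a data frame with
#'   columns `patch_count` and `median_patch_area_um2`; defaults to
#'   [run_replicates()]. Injectable so the analysis can be exercised (and
#'   verified) against cheap stub simulators.
#' @return An object of class `pp_consistency`: `sufficient` (logical), `n`
#'   (the smallest sufficient candidate, or `NA` if none -- an "insufficient"
#'   outcome, not an error), `max_magnitude` per candidate, and the full
#'   score `table` (candidate_n, subset, response, a, magnitude) with the
#'   subset seeds used.
#' @export
consistency_analysis <- function(config, candidate_ns, n_subsets = 20,
                                 base_seed = 1, sim_fun = run_replicates) {
  if (length(candidate_ns) < 1)
    stop("domain error: candidate_ns must be non-empty", call. = FALSE)
  if (is.unsorted(candidate_ns, strictly = TRUE))
    stop("domain error: candidate_ns must be increasing", call. = FALSE)
  if (n_subsets < 2)
    stop("domain error: n_subsets must be >= 2", call. = FALSE)

  responses <- c("patch_count", "median_patch_area_um2")
  rows <- list()
  max_mag <- numeric(length(candidate_ns))
  subset_seeds <- vector("list", length(candidate_ns))
  names(subset_seeds) <- as.character(candidate_ns)
  for (ci in seq_along(candidate_ns)) {
    n <- candidate_ns[ci]
    seeds <- derive_seeds(as.numeric(base_seed) + ci * 1000003, n_subsets)
    subset_seeds[[ci]] <- seeds
    subsets <- lapply(seeds, function(s) sim_fun(config, n, s))
    for (si in 2:n_subsets) {
      for (resp in responses) {
        at <- a_test(subsets[[si]][[resp]], subsets[[1]][[resp]])
        rows[[length(rows) + 1]] <- data.frame(
          candidate_n = n, subset = si, seed = seeds[si], response = resp,
          a = at$a, magnitude = at$magnitude)
      }
    }
    tab_ci <- do.call(rbind, rows[(length(rows) - 2 * (n_subsets - 1) + 1):
                                    length(rows)])
    max_mag[ci] <- max(tab_ci$magnitude)
  }
  sufficient_idx <- which(max_mag < 0.06)
  structure(list(
    sufficient = length(sufficient_idx) > 0,
    n = if (length(sufficient_idx)) candidate_ns[min(sufficient_idx)]
        else NA_integer_,
    candidate_ns = candidate_ns,
    max_magnitude = max_mag,
    subset_seeds = subset_seeds,
    table = do.call(rbind, rows)
  ), class = "pp_consistency")
}

#' @export
print.pp_atest <- function(x, ...) {
  cat(sprintf("A-Test: a = %.4f (magnitude %.4f, %s effect; n1 = %d, n2 = %d)\n",
              x$a, x$magnitude, x$category, x$n1, x$n2))
  invisible(x)
}

#' @export
print.pp_consistency <- function(x, ...) {
  cat("replicate-consistency analysis\n")
  for (i in seq_along(x$candidate_ns))
    cat(sprintf("  n = %4d: max |A - 0.5| = %.4f%s\n", x$candidate_ns[i],
                x$max_magnitude[i],
                if (x$max_magnitude[i] < 0.06) "  (sufficient)" else ""))
  if (x$sufficient)
    cat("minimum sufficient replicate count:", x$n, "\n")
  else
    cat("no candidate was sufficient\n")
  invisible(x)
}
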