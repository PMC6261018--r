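#' Covariate-window reference class
#'
#' The reference class of test i with half-width `delta` is the set of tests j
#' whose covariates satisfy `|x_j - x_i| <= delta` (closed boundary). The
#' center always belongs to its own class, so the class is never empty.
#'
#' @param data A [stat_table()] (or coercible data frame).
#' @param center_index Row index of the focal test.
#' @param delta Nonnegative window half-width.
#' @return A list of class `reference_class` with `center_index`, `delta`,
#'   and `member_indices` (in the original row order).
#' @examples
#' d <- stat_table(z = rnorm(4), x = c(0.1, 0.2, 0.3, 0.5))
#' build_reference_class(d, center_index = 2, delta = 0.1)$member_indices
#' @export
build_reference_class <- function(data, center_index, delta) {
  data <- as_stat_table(data)
  center_index <- as.integer(center_index)
  if (center_index < 1L || center_index > nrow(data)) {
    stop_invalid_input("`center_index` out of range.")
  }
  if (!is.finite(delta) || delta < 0) stop_invalid_input("`delta` must be >= 0.")
  members <- which(abs(data$x - data$x[center_index]) <= delta)
  structure(
    list(center_index = center_index, delta = delta, member_indices = members),
    class = "reference_class"
  )
}

#' Expected dimension of a reference class
#'
#' The expected number of tests falling in the window of half-width `delta`
#' around `x_center`: `N * P(|X - x_center| <= delta)`. Under the
#' `"uniform01"` covariate model the probability is the length of the overlap
#' of `[x_center - delta, x_center + delta]` with `[0, 1]`; under
#' `"empirical"` it is the observed fraction in the supplied data.
#'
#' @param N Number of tests.
#' @param delta Window half-width.
#' @param x_center Window center.
#' @param covariate_model `"uniform01"` or `"empirical"`.
#' @param data Required for `"empirical"`: a [stat_table()].
#' @return Expected class size (a nonnegative real, not necessarily integer).
#' @examples
#' expected_dimension(1000, 0.1, 0.5) # 200 for an interior point
#' expected_dimension(1000, 0.1, 0)   # 100, window truncated at the boundary
#' @export
expected_dimension <- function(N, delta, x_center,
                               covariate_model = c("uniform01", "empirical"),
                               data = NULL) {
  covariate_model <- match.arg(covariate_model)
  if (delta < 0) stop_invalid_input("`delta` must be >= 0.")
  if (covariate_model == "uniform01") {
    if (x_center < 0 || x_center > 1) {
      stop_invalid_input("`x_center` must lie in [0, 1] for the uniform01 model.")
    }
    p <- min(x_center + delta, 1) - max(x_center - delta, 0)
    p <- max(p, 0)
  } else {
    if (is.null(data)) stop_invalid_input("`data` is required for the empirical model.")
    data <- as_stat_table(data)
    p <- mean(abs(data$x - x_center) <= delta)
  }
  N * p
}

#' Partition covariates into the three step-prior regions
#'
#' Relative to a step location `x0` and a minimum half-width `delta0`,
#' covariates split into `R1` (`x <= x0 - delta0`), the open band `R2`
#' (`x0 - delta0 < x < x0 + delta0`), and `R3` (`x >= x0 + delta0`). In `R1`
#' and `R3` a window of half-width `delta0` never straddles the step, so the
#' smallest-window estimator is anchored on one prior value; in `R2` it mixes
#' both.
#'
#' @param x_values Numeric vector of covariates.
#' @param x0 Step location.
#' @param delta0 Positive minimum half-width.
#' @return A factor with levels `R1`, `R2`, `R3`, one label per covariate.
#' @examples
#' partition_regions(c(0.10, 0.18, 0.30), x0 = 0.2, delta0 = 0.05)
#' @export
partition_regions <- function(x_values, x0, delta0) {
  if (!is.finite(delta0) || delta0 <= 0) stop_invalid_input("`delta0` must be > 0.")
  lab <- ifelse(x_values <= x0 - delta0, "R1",
                ifelse(x_values >= x0 + delta0, "R3", "R2"))
  factor(lab, levels = c("R1", "R2", "R3"))
}
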