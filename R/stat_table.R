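#' Per-test summary-statistic table
#'
#' The package's central data structure: one row per hypothesis test, with a
#' z-value (standard normal under the theoretical null), a scalar covariate
#' (e.g. minor allele frequency, voxel location) and optionally the raw
#' 1-df chi-square statistic `w` the z-value was derived from.
#'
#' @param data A data frame with columns `test_id`, `z`, `x`, and optionally
#'   `w`. Alternatively pass `z` and `x` vectors directly.
#' @param z,x,w Used when `data` is missing: numeric vectors of statistics and
#'   covariates (and optionally chi-square values).
#' @param test_id Optional identifiers; defaults to `t1 ... tN`.
#' @return A tibble of class `stat_table` with columns `test_id` (character,
#'   unique), `z`, `x` (finite numeric) and `w` if supplied (nonnegative).
#' @examples
#' stat_table(z = rnorm(5), x = runif(5))
#' @export
stat_table <- function(data = NULL, z = NULL, x = NULL, w = NULL,
                       test_id = NULL) {
  if (is.null(data)) {
    if (is.null(z) || is.null(x)) {
      stop_invalid_input("supply either `data` or both `z` and `x`.")
    }
    data <- tibble::tibble(z = as.numeric(z), x = as.numeric(x))
    if (!is.null(w)) data$w <- as.numeric(w)
    if (!is.null(test_id)) data$test_id <- as.character(test_id)
  }
  data <- tibble::as_tibble(data)
  if (!all(c("z", "x") %in% names(data))) {
    stop_invalid_input("`data` must have columns `z` and `x`.")
  }
  if (!"test_id" %in% names(data)) {
    data$test_id <- paste0("t", seq_len(nrow(data)))
  }
  data$test_id <- as.character(data$test_id)
  keep <- intersect(c("test_id", "z", "x", "w"), names(data))
  data <- data[keep]
  if (nrow(data) < 1L) stop_invalid_input("need at least one test.")
  if (anyDuplicated(data$test_id)) stop_invalid_input("`test_id` values must be unique.")
  if (!all(is.finite(data$z))) stop_invalid_input("`z` must be finite.")
  if (!all(is.finite(data$x))) stop_invalid_input("`x` must be finite.")
  if ("w" %in% names(data) && any(data$w < 0, na.rm = TRUE)) {
    stop_invalid_input("`w` must be nonnegative.")
  }
  class(data) <- c("stat_table", class(data))
  data
}

as_stat_table <- function(data) {
  if (inherits(data, "stat_table")) data else stat_table(data)
}
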