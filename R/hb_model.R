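#' Histogram of z-values for mixture-density fitting
#'
#' Bins z-values into equal-width bins, the first step of the histogram-based
#' (HB) two-groups fit. The default range is `[min(z), max(z)]` padded by half
#' a bin width on each side so no observation sits exactly on an outer edge.
#'
#' @param z_values Numeric vector of z-values (finite).
#' @param n_bins Number of equal-width bins (at least 10).
#' @param range Optional length-2 numeric giving the histogram range. Values
#'   outside it are dropped from the counts.
#' @return An object of class `hb_histogram`: a list with `bin_edges`
#'   (length `n_bins + 1`, strictly increasing), integer `counts`,
#'   `bin_width`, and `n_in_range`.
#' @examples
#' h <- histogram_counts(rnorm(500), n_bins = 20)
#' sum(h$counts)
#' @export
histogram_counts <- function(z_values, n_bins, range = NULL) {
  if (!is.numeric(z_values) || !all(is.finite(z_values))) {
    stop_invalid_input("`z_values` must be a numeric vector of finite values.")
  }
  n_bins <- as.integer(n_bins)
  if (length(n_bins) != 1L || is.na(n_bins) || n_bins < 10L) {
    stop_invalid_input("`n_bins` must be a single integer >= 10.")
  }
  if (length(z_values) < n_bins) {
    stop_invalid_input("fewer z-values than bins: need length(z_values) >= n_bins.")
  }
  if (is.null(range)) {
    r <- base::range(z_values)
    if (r[2] - r[1] < sqrt(.Machine$double.eps)) {
      stop_invalid_input("z-values are (numerically) constant; histogram is degenerate.")
    }
    pad <- (r[2] - r[1]) / n_bins / 2
    range <- c(r[1] - pad, r[2] + pad)
  } else {
    range <- as.numeric(range)
    if (length(range) != 2L || !all(is.finite(range)) || range[2] <= range[1]) {
      stop_invalid_input("`range` must be two finite increasing values.")
    }
  }
  inside <- z_values >= range[1] & z_values <= range[2]
  make_histogram(z_values[inside], range[1], range[2], n_bins)
}

# equal-width binning by direct arithmetic (values must lie in [lo, hi])
make_histogram <- function(z, lo, hi, n_bins) {
  width <- (hi - lo) / n_bins
  idx <- floor((z - lo) / width) + 1
  idx[idx > n_bins] <- n_bins # right-closed outermost bin
  structure(
    list(bin_edges = seq(lo, hi, length.out = n_bins + 1L),
         counts = tabulate(idx, nbins = n_bins), bin_width = width,
         n_in_range = length(z)),
    class = "hb_histogram"
  )
}

#' Fit the marginal z-density by Poisson regression on histogram counts
#'
#' Fits `E(count in bin c) = exp(eta(c))` with `eta` a polynomial of the given
#' degree in the bin center, by Poisson GLM. The implied density is
#' `f(z) = exp(eta(z)) / (n * bin_width)`, renormalized to integrate to one
#' over the fitted range.
#'
#' @param hist An `hb_histogram` from [histogram_counts()].
#' @param degree Polynomial degree of the log-intensity (must be < n_bins - 1).
#' @return An object of class `hb_density`: coefficients on the internally
#'   rescaled z-axis plus everything needed to evaluate `f(z)`.
#' @export
fit_mixture_density <- function(hist, degree) {
  if (!inherits(hist, "hb_histogram")) {
    stop_invalid_input("`hist` must come from histogram_counts().")
  }
  degree <- as.integer(degree)
  n_bins <- length(hist$counts)
  if (degree < 1L || degree >= n_bins - 1L) {
    stop_invalid_input("`degree` must satisfy 1 <= degree < n_bins - 1.")
  }
  if (!all(is.finite(hist$counts))) stop_invalid_input("histogram counts must be finite.")
  if (sum(hist$counts > 0L) <= 1L) {
    stop_invalid_input("degenerate histogram: at most one nonzero bin.")
  }
  centers <- (hist$bin_edges[-1] + hist$bin_edges[-(n_bins + 1L)]) / 2
  # map the fitted range to [-1, 1] so raw powers stay well conditioned
  mid <- (hist$bin_edges[1] + hist$bin_edges[n_bins + 1L]) / 2
  half <- (hist$bin_edges[n_bins + 1L] - hist$bin_edges[1]) / 2
  u <- (centers - mid) / half
  X <- cbind(1, stats::poly(u, degree = degree, raw = TRUE))
  fit <- poisson_irls(X, hist$counts)
  if (!fit$converged || anyNA(fit$coefficients)) {
    # slower but step-halving glm.fit as a safety net
    fit <- suppressWarnings(
      stats::glm.fit(X, hist$counts, family = stats::poisson())
    )
    if (!fit$converged || anyNA(fit$coefficients)) {
      stop_fit_failure(sprintf(
        "Poisson regression did not converge (iter = %d, deviance = %g, NA coefs = %d).",
        fit$iter, fit$deviance, sum(is.na(fit$coefficients))
      ))
    }
  }
  out <- structure(
    list(coefficients = unname(fit$coefficients), degree = degree,
         mid = mid, half = half, bin_edges = hist$bin_edges,
         bin_width = hist$bin_width, n_fit = hist$n_in_range,
         deviance = fit$deviance, log_norm = 0),
    class = "hb_density"
  )
  # renormalize so the density integrates to 1 over the fitted range
  grid <- seq(hist$bin_edges[1], hist$bin_edges[n_bins + 1L], length.out = 513L)
  fg <- eval_density(out, grid)
  integral <- sum((fg[-1] + fg[-length(fg)]) / 2) * (grid[2] - grid[1])
  out$log_norm <- log(integral)
  out
}

# Plain IRLS for the log-linear Poisson model (canonical link, no offsets,
# no weights). Same fixed point as stats::glm.fit but without its
# per-call family dispatch; the caller falls back to glm.fit when the
# unguarded iteration fails to converge.
poisson_irls <- function(X, y, max_iter = 50L, tol = 1e-10) {
  mu <- y + 0.5
  eta <- log(mu)
  dev_old <- Inf
  beta <- NULL
  for (it in seq_len(max_iter)) {
    sw <- sqrt(mu)
    fit <- .lm.fit(X * sw, (eta + (y - mu) / mu) * sw)
    if (fit$rank < ncol(X)) {
      return(list(coefficients = beta, deviance = dev_old, converged = FALSE, iter = it))
    }
    beta <- numeric(ncol(X))
    beta[fit$pivot] <- fit$coefficients # undo QR column pivoting
    eta <- pmin(drop(X %*% beta), 30)
    mu <- exp(eta)
    dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
    if (!is.finite(dev)) {
      return(list(coefficients = beta, deviance = dev, converged = FALSE, iter = it))
    }
    if (abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
      return(list(coefficients = beta, deviance = dev, converged = TRUE, iter = it))
    }
    dev_old <- dev
  }
  list(coefficients = beta, deviance = dev_old, converged = FALSE, iter = max_iter)
}

# log f-hat(z): polynomial log-intensity minus log(n * width) and the
# renormalization constant
eval_log_density <- function(fit, z) {
  u <- (z - fit$mid) / fit$half
  eta <- fit$coefficients[1]
  up <- u
  for (k in seq_len(fit$degree)) {
    eta <- eta + fit$coefficients[k + 1L] * up
    up <- up * u
  }
  eta - log(fit$n_fit * fit$bin_width) - fit$log_norm
}

eval_density <- function(fit, z) exp(eval_log_density(fit, z))

#' Null-proportion estimate from a fitted mixture density
#'
#' Central matching at z = 0 under the theoretical N(0,1) null:
#' `pi0_hat = min(1, f_hat(0) / dnorm(0))`. The standard normal density is
#' maximal at zero, so tests concentrated away from zero leave the ratio
#' below one.
#'
#' @param fit An `hb_density` from [fit_mixture_density()].
#' @return Estimated null proportion in `[0, 1]`.
#' @export
estimate_pi0 <- function(fit) {
  if (!inherits(fit, "hb_density")) stop_invalid_input("`fit` must be an hb_density.")
  min(1, eval_density(fit, 0) / stats::dnorm(0))
}

#' Control parameters for the histogram-based fit
#'
#' Defaults scale with the reference-class size n: `n_bins =
#' max(10, min(120, round(sqrt(n))))` and polynomial degree 7 for
#' n >= 5000, 4 below (small covariate windows need fewer parameters).
#'
#' @param n_bins Number of histogram bins, or `NULL` for the size-adaptive
#'   default.
#' @param degree Polynomial degree of the log-density, or `NULL` for the
#'   size-adaptive default.
#' @param min_size Smallest reference class the fit accepts (default 200);
#'   smaller inputs raise a `refclass_too_small` error.
#' @return A list of class `hb_control`.
#' @export
hb_control <- function(n_bins = NULL, degree = NULL, min_size = 200L) {
  structure(list(n_bins = n_bins, degree = degree,
                 min_size = as.integer(min_size)),
            class = "hb_control")
}

default_n_bins <- function(n) max(10L, min(120L, as.integer(round(sqrt(n)))))
default_degree <- function(n) if (n >= 5000L) 7L else 4L

# One-stop HB fit used by both CRC and ARC paths. Returns class "hb_fit".
# Skips per-call input validation (inputs come from a validated stat_table);
# this is the ARC bootstrap's hot path.
hb_fit_impl <- function(z_values, control = hb_control()) {
  n <- length(z_values)
  if (n < control$min_size) {
    stop_refclass_too_small(sprintf(
      "reference class has %d statistics; minimum is %d.", n, control$min_size))
  }
  n_bins <- if (is.null(control$n_bins)) default_n_bins(n) else as.integer(control$n_bins)
  degree <- if (is.null(control$degree)) default_degree(n) else as.integer(control$degree)
  r <- base::range(z_values)
  if (r[2] - r[1] < sqrt(.Machine$double.eps)) {
    stop_invalid_input("z-values are (numerically) constant; histogram is degenerate.")
  }
  pad <- (r[2] - r[1]) / n_bins / 2
  h <- make_histogram(z_values, r[1] - pad, r[2] + pad, n_bins)
  dens <- fit_mixture_density(h, degree)
  structure(
    list(pi0_hat = estimate_pi0(dens), density = dens,
         bin_edges = h$bin_edges, n_fit = dens$n_fit,
         n_bins = n_bins, degree = degree),
    class = "hb_fit"
  )
}

#' Fit the histogram-based two-groups model
#'
#' Convenience wrapper combining [histogram_counts()], [fit_mixture_density()]
#' and [estimate_pi0()] into one fitted object that can evaluate the LFDR at
#' any z.
#'
#' @param z_values Numeric vector of z-values (standard normal under the null).
#' @param control An [hb_control()] list.
#' @return An object of class `hb_fit` with elements `pi0_hat`, `density`,
#'   `n_fit`, `n_bins`, `degree`.
#' @examples
#' z <- c(rnorm(9000), rnorm(1000, mean = 3))
#' fit <- hb_fit(z)
#' fit$pi0_hat
#' @export
hb_fit <- function(z_values, control = hb_control()) {
  hb_fit_impl(as.numeric(z_values), control)
}

# log LFDR at query points; vectorized, no warnings (hot path)
hb_lfdr_impl <- function(fit, query_z) {
  log_psi <- log(fit$pi0_hat) + stats::dnorm(query_z, log = TRUE) -
    eval_log_density(fit$density, query_z)
  pmin(1, exp(pmin(log_psi, 0)))
}

#' Histogram-based LFDR (combined reference class)
#'
#' Fits the two-groups model to `z_values` and evaluates
#' `Psi_hat(z) = min(1, pi0_hat * dnorm(z) / f_hat(z))` at each query point.
#' Queries outside the fitted range are evaluated by polynomial extrapolation
#' of the log-density (a warning is emitted) and clamped to `[0, 1]`.
#'
#' @param z_values Numeric vector used to fit the mixture density.
#' @param query_z Numeric vector of z-values at which to evaluate the LFDR.
#' @param n_bins,degree Optional overrides of the [hb_control()] defaults.
#' @param control An [hb_control()] list (ignored for fields overridden above).
#' @return Numeric vector of LFDR values in `[0, 1]`, one per query.
#' @examples
#' z <- c(rnorm(20000), rnorm(5000, mean = 3))
#' hb_lfdr(z, query_z = c(0, 2, 4))
#' @export
hb_lfdr <- function(z_values, query_z, n_bins = NULL, degree = NULL,
                    control = hb_control()) {
  if (!is.null(n_bins)) control$n_bins <- n_bins
  if (!is.null(degree)) control$degree <- degree
  fit <- hb_fit_impl(as.numeric(z_values), control)
  rng <- range(fit$bin_edges)
  if (any(query_z < rng[1] | query_z > rng[2])) {
    warning("some query z-values lie outside the fitted range; ",
            "the log-density is extrapolated there.", call. = FALSE)
  }
  hb_lfdr_impl(fit, query_z)
}

#' Combined-reference-class LFDR for a test table
#'
#' Data-frame-first interface: fits one histogram-based model to all z-values
#' (the combined reference class, CRC) and returns the per-test LFDR.
#'
#' @param data A data frame with columns `test_id`, `z`, `x` (see
#'   [stat_table()]).
#' @param control An [hb_control()] list.
#' @return A tibble with columns `test_id`, `z`, `x`, `lfdr`, `method`
#'   (`"CRC"`).
#' @examples
#' d <- simulate_dataset(sim_config(N = 20000, seed = 7))
#' head(lfdr_crc(d))
#' @export
lfdr_crc <- function(data, control = hb_control()) {
  data <- as_stat_table(data)
  fit <- hb_fit_impl(data$z, control)
  tibble::tibble(
    test_id = data$test_id, z = data$z, x = data$x,
    lfdr = hb_lfdr_impl(fit, data$z), method = "CRC"
  )
}
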