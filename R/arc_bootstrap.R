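#' Configuration for the adaptive-reference-class bootstrap
#'
#' Bundles the tuning constants of the ARC procedure: the number of bootstrap
#' samples `B`, the smallest window half-width `delta0` (the bias anchor), the
#' grid of candidate half-widths, and the root seed from which every
#' per-(focal, replicate) substream is derived.
#'
#' @param delta0 Smallest candidate half-width; the bootstrap mean at `delta0`
#'   anchors the prediction-bias estimate.
#' @param B Number of bootstrap samples per candidate (default 100).
#' @param delta_grid Increasing numeric vector of candidate half-widths with
#'   minimum `delta0`, or `NULL` to build `grid_points` log-spaced values from
#'   `delta0` to half the empirical covariate range at fit time.
#' @param grid_points Size of the default grid (default 15).
#' @param seed Integer root seed; every bootstrap draw is a deterministic
#'   function of (seed, focal index, replicate), so results do not depend on
#'   evaluation order.
#' @param max_rejection_tries Cap on redraws when rejection sampling for the
#'   focal pair (default 1000).
#' @param force_include If `TRUE`, skip rejection sampling and instead
#'   overwrite one uniformly chosen slot of each resample with the focal index.
#'   Faster but not the literal conditioned bootstrap; off by default.
#' @return A list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(delta0, B = 100L, delta_grid = NULL,
                             grid_points = 15L, seed = 1L,
                             max_rejection_tries = 1000L,
                             force_include = FALSE) {
  if (!is.finite(delta0) || delta0 <= 0) stop_invalid_input("`delta0` must be > 0.")
  B <- as.integer(B)
  if (B < 2L) stop_invalid_input("`B` must be at least 2.")
  if (!is.null(delta_grid)) {
    delta_grid <- as.numeric(delta_grid)
    if (length(delta_grid) < 1L || is.unsorted(delta_grid, strictly = TRUE) ||
        abs(delta_grid[1] - delta0) > 1e-12 || any(delta_grid < delta0)) {
      stop_invalid_input(
        "`delta_grid` must be strictly increasing with minimum exactly `delta0`.")
    }
  }
  structure(
    list(B = B, delta0 = delta0, delta_grid = delta_grid,
         grid_points = as.integer(grid_points), seed = as.integer(seed),
         max_rejection_tries = as.integer(max_rejection_tries),
         force_include = isTRUE(force_include)),
    class = "bootstrap_config"
  )
}

# deterministic substream seed for (root seed, focal test, replicate);
# constants keep the intermediate products well inside 2^53
substream_seed <- function(seed, focal, b) {
  h <- (abs(as.numeric(seed)) %% 2147483647) * 31 +
    as.numeric(focal) * 131071 + as.numeric(b) * 8191 + 17
  as.integer(h %% 2147483647)
}

resolve_delta_grid <- function(config, x) {
  if (!is.null(config$delta_grid)) return(config$delta_grid)
  delta_max <- (max(x) - min(x)) / 2
  if (delta_max <= config$delta0) return(config$delta0)
  exp(seq(log(config$delta0), log(delta_max), length.out = config$grid_points))
}

# single conditioned resample (indices 1..N containing `focal`)
draw_one_sample <- function(N, focal, max_tries, force_include) {
  if (force_include) {
    idx <- sample.int(N, N, replace = TRUE)
    idx[sample.int(N, 1L)] <- focal
    return(idx)
  }
  for (try in seq_len(max_tries)) {
    idx <- sample.int(N, N, replace = TRUE)
    if (any(idx == focal)) return(idx)
  }
  stop_resampling_failure(sprintf(
    "no resample contained the focal pair after %d tries.", max_tries))
}

#' Bootstrap resamples conditioned on the focal pair
#'
#' Draws `B` resamples of size N (with replacement) from the rows of `data`,
#' keeping only resamples that contain the focal test — the conditioned
#' bootstrap behind the ARC err estimate. Rejection sampling accepts a raw
#' resample with probability `1 - (1 - 1/N)^N` (about 0.632 for large N).
#'
#' @param data A [stat_table()].
#' @param focal_index Row index of the focal test.
#' @param B Number of resamples.
#' @param seed Root seed (see [bootstrap_config()]).
#' @param max_rejection_tries,force_include See [bootstrap_config()].
#' @return A list of `B` integer vectors of length `nrow(data)`, each
#'   containing `focal_index` at least once.
#' @export
draw_bootstrap_samples <- function(data, focal_index, B, seed,
                                   max_rejection_tries = 1000L,
                                   force_include = FALSE) {
  data <- as_stat_table(data)
  N <- nrow(data)
  if (N < 2L) stop_invalid_input("need at least two tests to bootstrap.")
  B <- as.integer(B)
  if (B < 2L) stop_invalid_input("`B` must be at least 2.")
  focal_index <- as.integer(focal_index)
  if (focal_index < 1L || focal_index > N) stop_invalid_input("`focal_index` out of range.")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old_seed), add = TRUE)
  lapply(seq_len(B), function(b) {
    set.seed(substream_seed(seed, focal_index, b))
    draw_one_sample(N, focal_index, max_rejection_tries, force_include)
  })
}

restore_rng <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Bootstrap mean and variance of replicate LFDR estimates
#'
#' Sample mean and unbiased (B - 1 denominator) sample variance of the
#' per-replicate LFDR values at one candidate half-width.
#'
#' @param lfdr_boot Numeric vector of bootstrap LFDR estimates in `[0, 1]`.
#' @return Named numeric vector `c(mu_hat, sigma2_hat)`.
#' @examples
#' bootstrap_moments(c(0.2, 0.3, 0.4)) # mean 0.3, variance 0.01
#' @export
bootstrap_moments <- function(lfdr_boot) {
  if (length(lfdr_boot) < 2L) stop_invalid_input("need at least two bootstrap values.")
  if (any(!is.finite(lfdr_boot)) || any(lfdr_boot < 0 | lfdr_boot > 1)) {
    stop_invalid_input("bootstrap LFDR values must lie in [0, 1].")
  }
  c(mu_hat = mean(lfdr_boot), sigma2_hat = stats::var(lfdr_boot))
}

#' Bootstrap prediction-bias estimate
#'
#' The difference between the bootstrap mean at half-width delta and the
#' bootstrap mean at the smallest half-width delta0, which serves as the
#' pseudo-truth. Exactly zero at delta = delta0; may be negative (err uses
#' its square).
#'
#' @param mu_delta Bootstrap mean at the candidate half-width.
#' @param mu_delta0 Bootstrap mean at `delta0`.
#' @return `mu_delta - mu_delta0`.
#' @export
prediction_bias <- function(mu_delta, mu_delta0) {
  if (any(c(mu_delta, mu_delta0) < 0 | c(mu_delta, mu_delta0) > 1)) {
    stop_invalid_input("bootstrap means must lie in [0, 1].")
  }
  mu_delta - mu_delta0
}

#' Bootstrap err profile over the half-width grid
#'
#' For each candidate half-width, evaluates the focal test's LFDR on every
#' bootstrap reference class (the resampled pairs whose covariates fall within
#' the window), then aggregates into the bootstrap mean, variance, prediction
#' bias against the `delta0` anchor, and `err = variance + bias^2` — the
#' delta-dependent part of the estimator's mean squared error.
#'
#' Replicates whose reference class is smaller than the histogram fit's
#' minimum (or whose fit degenerates) are dropped and counted; a half-width
#' retaining fewer than `B/2` valid replicates is flagged unusable and
#' excluded from the minimization. An unusable `delta0` aborts the procedure,
#' since the bias anchor would be missing.
#'
#' @param data A [stat_table()].
#' @param focal_index Row index of the focal test.
#' @param config A [bootstrap_config()].
#' @param control An [hb_control()] for the per-window histogram fits.
#' @return A tibble of class `err_profile` with one row per half-width:
#'   `delta`, `mu_hat`, `sigma2_hat`, `bias_hat`, `err_hat`, `n_valid_boot`,
#'   `usable`; attributes `focal_index`, `delta0`, `B`.
#' @export
estimate_err_profile <- function(data, focal_index, config,
                                 control = hb_control()) {
  data <- as_stat_table(data)
  focal_index <- as.integer(focal_index)
  if (focal_index < 1L || focal_index > nrow(data)) {
    stop_invalid_input("`focal_index` out of range.")
  }
  grid <- resolve_delta_grid(config, data$x)
  n_delta <- length(grid)
  xi <- data$x[focal_index]
  zi <- data$z[focal_index]
  N <- nrow(data)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old_seed), add = TRUE)

  lfdr_mat <- matrix(NA_real_, nrow = config$B, ncol = n_delta)
  for (b in seq_len(config$B)) {
    set.seed(substream_seed(config$seed, focal_index, b))
    idx <- draw_one_sample(N, focal_index, config$max_rejection_tries,
                           config$force_include)
    d <- abs(data$x[idx] - xi)
    o <- order(d)
    d_sorted <- d[o]
    z_sorted <- data$z[idx][o]
    for (g in seq_len(n_delta)) {
      k <- findInterval(grid[g], d_sorted)
      if (k < 1L) next
      lfdr_mat[b, g] <- tryCatch(
        hb_lfdr_impl(hb_fit_impl(z_sorted[seq_len(k)], control), zi),
        arclfdr_refclass_too_small = function(e) NA_real_,
        arclfdr_invalid_input = function(e) NA_real_,
        arclfdr_fit_failure = function(e) NA_real_
      )
    }
  }

  n_valid <- colSums(!is.na(lfdr_mat))
  usable <- n_valid >= config$B / 2
  if (!usable[1]) {
    stop_procedure_failure(sprintf(
      "bias anchor missing: only %d of %d bootstrap replicates usable at delta0 = %g.",
      n_valid[1], config$B, grid[1]))
  }
  if (any(!usable)) {
    warning(sprintf("%d of %d half-widths dropped: fewer than B/2 usable replicates.",
                    sum(!usable), n_delta), call. = FALSE)
  }
  mu <- sigma2 <- rep(NA_real_, n_delta)
  for (g in which(n_valid >= 2L)) {
    m <- bootstrap_moments(lfdr_mat[!is.na(lfdr_mat[, g]), g])
    mu[g] <- m[["mu_hat"]]
    sigma2[g] <- m[["sigma2_hat"]]
  }
  bias <- mu - mu[1]
  bias[1] <- 0
  err <- sigma2 + bias^2

  profile <- tibble::tibble(
    delta = grid, mu_hat = mu, sigma2_hat = sigma2, bias_hat = bias,
    err_hat = err, n_valid_boot = as.integer(n_valid), usable = usable
  )
  attr(profile, "focal_index") <- focal_index
  attr(profile, "delta0") <- config$delta0
  attr(profile, "B") <- config$B
  class(profile) <- c("err_profile", class(profile))
  profile
}

#' Select the optimal window half-width from an err profile
#'
#' Picks the usable half-width minimizing `err_hat`; ties break toward the
#' smallest (most local) half-width.
#'
#' @param profile An `err_profile` from [estimate_err_profile()].
#' @return A list of class `delta_star` with `delta_star`, `err_at_star`,
#'   and the `profile`.
#' @export
select_optimal_delta <- function(profile) {
  if (!inherits(profile, "err_profile")) {
    stop_invalid_input("`profile` must come from estimate_err_profile().")
  }
  ok <- which(profile$usable & is.finite(profile$err_hat))
  if (length(ok) == 0L) stop_procedure_failure("no usable half-width in the profile.")
  best <- ok[which.min(profile$err_hat[ok])]
  structure(
    list(delta_star = profile$delta[best],
         err_at_star = profile$err_hat[best],
         profile = profile),
    class = "delta_star"
  )
}

#' Adaptive-reference-class LFDR for one focal test
#'
#' Runs the full ARC procedure for one test: bootstrap err profile over the
#' half-width grid, argmin selection of the half-width, then a single
#' histogram-based fit on the original (non-bootstrap) reference class at the
#' selected half-width, evaluated at the focal z.
#'
#' @inheritParams estimate_err_profile
#' @return A one-row tibble with `test_id`, `z`, `x`, `lfdr`, `method`
#'   (`"ARC"`), `delta_star`, `refclass_size`.
#' @export
arc_lfdr <- function(data, focal_index, config, control = hb_control()) {
  data <- as_stat_table(data)
  profile <- estimate_err_profile(data, focal_index, config, control)
  star <- select_optimal_delta(profile)
  rc <- build_reference_class(data, focal_index, star$delta_star)
  fit <- hb_fit_impl(data$z[rc$member_indices], control)
  tibble::tibble(
    test_id = data$test_id[focal_index],
    z = data$z[focal_index], x = data$x[focal_index],
    lfdr = hb_lfdr_impl(fit, data$z[focal_index]),
    method = "ARC",
    delta_star = star$delta_star,
    refclass_size = length(rc$member_indices)
  )
}

#' Adaptive-reference-class LFDR for a set of tests
#'
#' Applies [arc_lfdr()] to each requested row. Each focal test draws its own
#' deterministic bootstrap substreams from the root seed, so the result does
#' not depend on the order of `focal_indices`.
#'
#' @param data A [stat_table()].
#' @param config A [bootstrap_config()].
#' @param focal_indices Row indices to estimate (default: all rows — expensive
#'   for large tables).
#' @param control An [hb_control()].
#' @return A tibble with one row per focal test (columns as [arc_lfdr()]).
#' @export
lfdr_arc <- function(data, config, focal_indices = NULL,
                     control = hb_control()) {
  data <- as_stat_table(data)
  if (is.null(focal_indices)) focal_indices <- seq_len(nrow(data))
  purrr::map_dfr(focal_indices, function(i) {
    arc_lfdr(data, i, config, control)
  })
}
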