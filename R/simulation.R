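#' Step-function prior on the null probability
#'
#' The null-probability prior `pi0(x)` equals `pi01` for covariates at or
#' below the step location `x0` and `pi02` above it, with `pi01 <= pi02`
#' (alternatives are enriched at low covariate values, as with low minor
#' allele frequencies). Setting `pi01 = pi02` gives a constant prior (no
#' covariate effect).
#'
#' @param x0 Step location.
#' @param pi01,pi02 Null probabilities below/above the step, in `[0, 1]`,
#'   with `pi01 <= pi02`.
#' @return A list of class `step_prior`.
#' @export
step_prior <- function(x0, pi01, pi02) {
  if (any(c(pi01, pi02) < 0 | c(pi01, pi02) > 1)) {
    stop_invalid_input("`pi01` and `pi02` must lie in [0, 1].")
  }
  if (pi01 > pi02) stop_invalid_input("`pi01` must be <= `pi02`.")
  structure(list(x0 = x0, pi01 = pi01, pi02 = pi02), class = "step_prior")
}

#' Evaluate a step prior
#'
#' @param x Numeric vector of covariates.
#' @param prior A [step_prior()].
#' @return `pi01` where `x <= x0` (the boundary belongs to the first branch),
#'   `pi02` where `x > x0`.
#' @examples
#' step_prior_at(c(0.1, 0.2, 0.5), step_prior(0.2, 0.6, 0.95))
#' @export
step_prior_at <- function(x, prior) {
  if (!inherits(prior, "step_prior")) stop_invalid_input("`prior` must be a step_prior.")
  ifelse(x <= prior$x0, prior$pi01, prior$pi02)
}

#' Probit z-transform of a 1-df chi-square statistic
#'
#' `z = qnorm(pchisq(w, 1))`, computed through the upper tail on the log
#' scale so extreme statistics keep full precision. The transform is strictly
#' increasing in `w` and yields exactly N(0, 1) when `w` is central
#' chi-square with 1 df. Values beyond the representable tail are clamped at
#' +/- 8.3 with a warning.
#'
#' @param w Nonnegative chi-square statistics.
#' @return z-values (standard normal under the null).
#' @examples
#' z_transform(qchisq(0.5, df = 1)) # the chi-square median maps to 0
#' @export
z_transform <- function(w) {
  if (any(w < 0)) stop_invalid_input("`w` must be nonnegative.")
  z <- stats::qnorm(stats::pchisq(w, df = 1, lower.tail = FALSE, log.p = TRUE),
                    lower.tail = FALSE, log.p = TRUE)
  out_of_range <- !is.finite(z) | abs(z) > 8.3
  if (any(out_of_range)) {
    warning(sum(out_of_range), " z-value(s) clamped at +/- 8.3.", call. = FALSE)
    z <- pmin(pmax(z, -8.3), 8.3)
  }
  z
}

#' Simulation configuration
#'
#' Study conditions for the synthetic-data generator: `N` tests with
#' Uniform(0, 1) covariates, a [step_prior()] on the null probability, and
#' alternative 1-df Wald chi-square statistics with noncentrality `delta`.
#'
#' @param N Number of tests (default 30000, the package's reduced-scale
#'   benchmark size; the full-scale study uses 300000).
#' @param prior A [step_prior()] (default `step_prior(0.2, 0.6, 0.95)`).
#' @param delta Noncentrality of the alternative chi-square (default 4, the
#'   midpoint of the 1.5–7 range the benchmark scenarios span).
#' @param seed Integer seed for the generator.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(N = 30000L, prior = step_prior(0.2, 0.6, 0.95),
                       delta = 4, seed = 1L) {
  N <- as.integer(N)
  if (N < 1L) stop_invalid_input("`N` must be >= 1.")
  if (!is.finite(delta) || delta <= 0) stop_invalid_input("`delta` must be > 0.")
  if (!inherits(prior, "step_prior")) stop_invalid_input("`prior` must be a step_prior.")
  structure(list(N = N, prior = prior, delta = delta, seed = as.integer(seed)),
            class = "sim_config")
}

# oracle posterior on the chi-square scale; identical to the z-scale
# posterior because the probit transform is monotone (densities pick up the
# same Jacobian in numerator and denominator)
oracle_lfdr <- function(w, pi0_x, delta) {
  log_g0 <- stats::dchisq(w, df = 1, log = TRUE)
  log_g1 <- stats::dchisq(w, df = 1, ncp = delta, log = TRUE)
  # 1 / (1 + (1-pi0)/pi0 * g1/g0), stable in the log ratio
  ratio <- (1 - pi0_x) / pi0_x * exp(pmin(log_g1 - log_g0, 700))
  out <- 1 / (1 + ratio)
  out[pi0_x == 0] <- 0
  out
}

#' Simulate a covariate-modulated two-groups dataset
#'
#' Generates the benchmark design: covariates `x ~ Uniform(0, 1)`, latent
#' alternative indicators `A | x ~ Bernoulli(1 - pi0(x))` under the step
#' prior, Wald statistics `w ~` central chi-square (1 df) for nulls and
#' noncentral chi-square (1 df, ncp `delta`) for alternatives, and
#' `z = z_transform(w)`. The returned table carries the generating truth:
#' the indicator `A`, the prior `pi0_x` at each covariate, and the oracle
#' LFDR `lfdr_true` (the exact posterior null probability given `z` and `x`,
#' computed from the closed-form densities).
#'
#' @param config A [sim_config()].
#' @return A [stat_table()] (class `sim_stat_table`) with extra columns `w`,
#'   `A`, `pi0_x`, `lfdr_true`.
#' @examples
#' d <- simulate_dataset(sim_config(N = 1000, seed = 42))
#' mean(d$A)
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) stop_invalid_input("`config` must be a sim_config.")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old_seed), add = TRUE)
  set.seed(config$seed)
  N <- config$N
  x <- stats::runif(N)
  pi0_x <- step_prior_at(x, config$prior)
  A <- stats::rbinom(N, 1L, 1 - pi0_x)
  w <- numeric(N)
  n_alt <- sum(A)
  w[A == 0L] <- stats::rchisq(N - n_alt, df = 1)
  if (n_alt > 0L) w[A == 1L] <- stats::rchisq(n_alt, df = 1, ncp = config$delta)
  z <- suppressWarnings(z_transform(w))
  out <- stat_table(z = z, x = x, w = w)
  out$A <- as.integer(A)
  out$pi0_x <- pi0_x
  out$lfdr_true <- oracle_lfdr(w, pi0_x, config$delta)
  class(out) <- c("sim_stat_table", class(out))
  attr(out, "config") <- config
  out
}

#' Mean squared error of LFDR estimates against the oracle
#'
#' Conditional MSE within each covariate region plus the marginal MSE over
#' all evaluated tests. Empty regions are reported with `n = 0` and `NA`
#' MSE rather than zero.
#'
#' @param estimates Numeric vector of estimated LFDR values.
#' @param truth Numeric vector of oracle LFDR values (same length).
#' @param regions Optional factor from [partition_regions()] (same length);
#'   omit for the marginal MSE only.
#' @return A tibble with columns `region` (`"R1"`, `"R2"`, `"R3"`,
#'   `"marginal"`), `n`, `mse`.
#' @examples
#' evaluate_mse(c(0.3, 0.6), c(0.2, 0.4)) # marginal MSE 0.025
#' @export
evaluate_mse <- function(estimates, truth, regions = NULL) {
  if (length(estimates) != length(truth)) {
    stop_invalid_input("`estimates` and `truth` must have equal length.")
  }
  sq <- (estimates - truth)^2
  rows <- list()
  if (!is.null(regions)) {
    if (length(regions) != length(truth)) {
      stop_invalid_input("`regions` must match the estimates in length.")
    }
    regions <- factor(regions, levels = c("R1", "R2", "R3"))
    for (r in levels(regions)) {
      in_r <- regions == r
      rows[[r]] <- tibble::tibble(
        region = r, n = sum(in_r),
        mse = if (any(in_r)) mean(sq[in_r]) else NA_real_
      )
    }
  }
  rows[["marginal"]] <- tibble::tibble(region = "marginal",
                                       n = length(sq), mse = mean(sq))
  dplyr::bind_rows(rows)
}

# paired delta-method standard error of log2(mean(a) / mean(c))
log2_ratio_se <- function(a, c) {
  n <- length(a)
  if (n < 2L) return(NA_real_)
  g <- a / mean(a) - c / mean(c)
  sqrt(stats::var(g) / n) / log(2)
}

#' Benchmark ARC against CRC on simulated data
#'
#' Runs the full comparison on one simulated dataset: draws `n_focal` focal
#' tests, estimates each focal LFDR under both the combined reference class
#' (one fit to all z-values) and the adaptive reference class (per-test
#' bootstrap half-width selection), and summarizes squared error against the
#' generator's oracle LFDR — conditionally on the covariate regions of
#' [partition_regions()] and marginally, as relative MSE (ARC / CRC) with its
#' base-2 logarithm and a paired delta-method Monte-Carlo standard error.
#'
#' @param config A [sim_config()] describing the dataset.
#' @param delta0 Smallest window half-width (bias anchor); also used to
#'   partition the regions around the prior's step.
#' @param B Bootstrap samples per candidate half-width (default 100).
#' @param n_focal Number of focal tests (default 50, at least 10).
#' @param grid_points Candidate half-widths (default 10, log-spaced).
#' @param seed Root seed for focal sampling and the bootstrap substreams
#'   (default: the simulation seed).
#' @param focal_regions Optional subset of `c("R1", "R2", "R3")` from which
#'   focal tests are drawn (e.g. `c("R1", "R3")` to stay clear of the step).
#' @param control An [hb_control()].
#' @return An object of class `arc_comparison`: a list with `focal` (one row
#'   per focal test: `test_id`, `z`, `x`, `region`, `lfdr_true`, `lfdr_crc`,
#'   `lfdr_arc`, `delta_star`, `refclass_size`) and `summary` (per region and
#'   marginal: `n`, `mse_crc`, `mse_arc`, `remse`, `log2_remse`,
#'   `se_log2_remse`).
#' @export
run_comparison <- function(config, delta0, B = 100L, n_focal = 50L,
                           grid_points = 10L, seed = NULL,
                           focal_regions = NULL, control = hb_control()) {
  n_focal <- as.integer(n_focal)
  if (n_focal < 10L) stop_invalid_input("`n_focal` must be at least 10.")
  if (is.null(seed)) seed <- config$seed
  sim <- simulate_dataset(config)
  regions_all <- partition_regions(sim$x, config$prior$x0, delta0)

  eligible <- seq_len(nrow(sim))
  if (!is.null(focal_regions)) {
    eligible <- which(regions_all %in% focal_regions)
    if (length(eligible) < n_focal) {
      stop_invalid_input("not enough tests in the requested focal regions.")
    }
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old_seed), add = TRUE)
  set.seed(substream_seed(seed, 0L, 1L))
  focal <- sort(sample(eligible, n_focal))

  crc_fit <- hb_fit_impl(sim$z, control)
  lfdr_crc_vals <- hb_lfdr_impl(crc_fit, sim$z[focal])

  bc <- bootstrap_config(delta0 = delta0, B = B, grid_points = grid_points,
                         seed = seed)
  arc <- lfdr_arc(sim, bc, focal_indices = focal, control = control)

  focal_tbl <- tibble::tibble(
    test_id = sim$test_id[focal], z = sim$z[focal], x = sim$x[focal],
    region = regions_all[focal],
    lfdr_true = sim$lfdr_true[focal],
    lfdr_crc = lfdr_crc_vals,
    lfdr_arc = arc$lfdr,
    delta_star = arc$delta_star,
    refclass_size = arc$refclass_size
  )

  mse_c <- evaluate_mse(focal_tbl$lfdr_crc, focal_tbl$lfdr_true, focal_tbl$region)
  mse_a <- evaluate_mse(focal_tbl$lfdr_arc, focal_tbl$lfdr_true, focal_tbl$region)
  summary <- dplyr::left_join(
    dplyr::rename(mse_c, mse_crc = "mse"),
    dplyr::select(dplyr::rename(mse_a, mse_arc = "mse"), -"n"),
    by = "region"
  )
  summary$remse <- summary$mse_arc / summary$mse_crc
  summary$log2_remse <- log2(summary$remse)
  summary$se_log2_remse <- vapply(summary$region, function(r) {
    in_r <- if (r == "marginal") rep(TRUE, nrow(focal_tbl)) else focal_tbl$region == r
    if (sum(in_r) < 2L) return(NA_real_)
    log2_ratio_se((focal_tbl$lfdr_arc[in_r] - focal_tbl$lfdr_true[in_r])^2,
                  (focal_tbl$lfdr_crc[in_r] - focal_tbl$lfdr_true[in_r])^2)
  }, numeric(1))

  structure(
    list(focal = focal_tbl, summary = summary, config = config,
         delta0 = delta0, B = as.integer(B), seed = as.integer(seed)),
    class = "arc_comparison"
  )
}
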