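test_that("histogram_counts conserves counts and honors explicit ranges", {
  set.seed(42)
  z <- rnorm(1000)
  h <- histogram_counts(z, n_bins = 20)
  expect_s3_class(h, "hb_histogram")
  expect_equal(sum(h$counts), 1000)
  expect_equal(length(h$bin_edges), 21)
  expect_true(all(diff(h$bin_edges) > 0))
  expect_equal(diff(range(h$bin_edges)) / 20, h$bin_width, tolerance = 1e-12)

  # point mass inside an explicit range lands in exactly one bin
  h2 <- histogram_counts(rep(0.5, 50), n_bins = 10, range = c(0, 1))
  expect_equal(sum(h2$counts > 0), 1)
  expect_equal(max(h2$counts), 50)

  # values outside an explicit range are dropped
  h3 <- histogram_counts(c(rep(0.5, 30), rep(5, 7)), n_bins = 10, range = c(0, 1))
  expect_equal(sum(h3$counts), 30)
  expect_equal(h3$n_in_range, 30)
})

test_that("histogram_counts matches brute-force bin assignment", {
  z <- seq(-3, 3, length.out = 121)
  h <- histogram_counts(z, n_bins = 12)
  edges <- h$bin_edges
  brute <- integer(12)
  for (v in z) {
    for (j in 1:12) {
      upper_ok <- if (j == 12) v <= edges[13] else v < edges[j + 1]
      if (v >= edges[j] && upper_ok) {
        brute[j] <- brute[j] + 1L
        break
      }
    }
  }
  expect_identical(h$counts, brute)
})

test_that("histogram_counts rejects invalid input", {
  expect_error(histogram_counts(rnorm(5), 10), class = "arclfdr_invalid_input")
  expect_error(histogram_counts(c(rnorm(20), NA), 10),
               class = "arclfdr_invalid_input")
  expect_error(histogram_counts(c(rnorm(20), Inf), 10),
               class = "arclfdr_invalid_input")
  expect_error(histogram_counts(rnorm(20), 5), class = "arclfdr_invalid_input")
  expect_error(histogram_counts(rep(1, 50), 10), class = "arclfdr_invalid_input")
})

test_that("a quadratic log-density is recovered exactly from exact counts", {
  h <- exact_density_hist(dnorm, lo = -4, hi = 4, n_bins = 40)
  fit <- fit_mixture_density(h, degree = 2)
  centers <- (h$bin_edges[-1] + h$bin_edges[-41]) / 2
  f_hat <- exp(arclfdr:::eval_log_density(fit, centers))
  expect_equal(f_hat, dnorm(centers), tolerance = 1e-3)
})

test_that("the fitted density integrates to one and estimates the mixture", {
  z <- two_groups_z(100000, pi0 = 0.8, mu1 = 3, seed = 7)
  h <- histogram_counts(z, n_bins = 100)
  fit <- fit_mixture_density(h, degree = 7)
  grid <- seq(min(h$bin_edges), max(h$bin_edges), length.out = 2001)
  fg <- arclfdr:::eval_density(fit, grid)
  integral <- sum((fg[-1] + fg[-2001]) / 2) * diff(grid[1:2])
  expect_equal(integral, 1, tolerance = 1e-2)
  expect_true(all(fg > 0))
  # true marginal density at 0: 0.8 phi(0) + 0.2 phi(-3)
  f0_true <- 0.8 * dnorm(0) + 0.2 * dnorm(-3)
  expect_equal(arclfdr:::eval_density(fit, 0), f0_true, tolerance = 0.1 * f0_true)
})

test_that("degenerate or misspecified density fits error out", {
  h <- exact_density_hist(dnorm, n_bins = 40)
  h$counts <- c(100L, rep(0L, 39))
  expect_error(fit_mixture_density(h, 7), class = "arclfdr_invalid_input")
  expect_error(fit_mixture_density(exact_density_hist(dnorm, n_bins = 12),
                                   degree = 11),
               class = "arclfdr_invalid_input")
})

test_that("estimate_pi0 implements capped central matching at zero", {
  # counts following phi exactly -> pi0 = 1
  fit_null <- fit_mixture_density(exact_density_hist(dnorm), degree = 2)
  expect_equal(estimate_pi0(fit_null), 1, tolerance = 1e-3)

  # closed-form mixture: pi0 = 0.8 + 0.2 * phi(3)/phi(0) ~ 0.8022
  # (a high-degree fit, since a two-component log-density is not polynomial)
  mix <- function(z) 0.8 * dnorm(z) + 0.2 * dnorm(z, mean = 3)
  fit_mix <- fit_mixture_density(
    exact_density_hist(mix, lo = -4.5, hi = 7, n_bins = 80), degree = 16)
  expect_lt(abs(estimate_pi0(fit_mix) - (0.8 + 0.2 * dnorm(3) / dnorm(0))),
            0.005)

  # overdispersed-at-zero fit caps at exactly 1
  narrow <- function(z) dnorm(z, sd = 0.5)
  fit_narrow <- fit_mixture_density(
    exact_density_hist(narrow, lo = -3, hi = 3, n_bins = 40), degree = 2)
  expect_identical(estimate_pi0(fit_narrow), 1)
})

test_that("hb_lfdr is calibrated on pure-null data and matches the oracle", {
  set.seed(5)
  z_null <- rnorm(100000)
  psi0 <- hb_lfdr(z_null, query_z = 0)
  expect_gte(psi0, 0.95)
  expect_lte(psi0, 1)

  z <- two_groups_z(100000, pi0 = 0.8, mu1 = 3, seed = 3)
  psi3 <- hb_lfdr(z, query_z = 3)
  expect_lt(abs(psi3 - two_groups_oracle(3)), 0.03)
})

test_that("hb_lfdr stays in [0,1], is deterministic, and tracks the oracle", {
  z <- two_groups_z(100000, pi0 = 0.8, mu1 = 3, seed = 9)
  queries <- seq(-4, 4, by = 0.25)
  psi <- hb_lfdr(z, queries)
  expect_true(all(psi >= 0 & psi <= 1))
  expect_identical(psi, hb_lfdr(z, queries))
  expect_lte(mean(abs(psi - two_groups_oracle(queries))), 0.05)
})

test_that("hb_lfdr enforces the minimum reference-class size", {
  expect_error(hb_lfdr(rnorm(150), 0), class = "arclfdr_refclass_too_small")
  expect_error(hb_fit(rnorm(199)), class = "arclfdr_refclass_too_small")
})

test_that("queries outside the fitted range are extrapolated with a warning", {
  z <- two_groups_z(20000, seed = 13)
  expect_warning(psi <- hb_lfdr(z, query_z = max(z) + 2), "outside the fitted range")
  expect_true(psi >= 0 && psi <= 1)
})

test_that("pi0_hat is near one on pure-null data across seeds", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    hb_fit(rnorm(100000))$pi0_hat >= 0.95
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("lfdr_crc returns a tidy per-test table", {
  d <- small_sim(N = 5000, seed = 21)
  out <- lfdr_crc(d)
  expect_s3_class(out, "tbl_df")
  expect_named(out, c("test_id", "z", "x", "lfdr", "method"))
  expect_equal(nrow(out), 5000)
  expect_true(all(out$lfdr >= 0 & out$lfdr <= 1))
  expect_identical(unique(out$method), "CRC")
})

test_that("hb_fit tidiers expose coefficients and fit summary", {
  fit <- hb_fit(two_groups_z(20000, seed = 2))
  td <- tidy(fit)
  expect_equal(nrow(td), fit$degree + 1)
  gl <- glance(fit)
  expect_equal(gl$n_fit, 20000)
  expect_true(gl$pi0_hat >= 0 && gl$pi0_hat <= 1)
})
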