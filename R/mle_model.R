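#' Log-likelihood of the central/noncentral chi-square mixture
#'
#' Marginal log-likelihood of 1-df Wald chi-square statistics under the
#' two-groups model `pi0 * g0(w) + (1 - pi0) * g1(w; delta)`, where `g0` is
#' the central chi-square density with one degree of freedom and `g1` the
#' noncentral chi-square density with noncentrality `delta`. At `delta = 0`
#' the mixture degenerates to `g0` regardless of `pi0`.
#'
#' @param w_values Nonnegative chi-square statistics. Exact zeros are floored
#'   at `1e-8` (the 1-df density diverges at zero).
#' @param pi0 Null proportion in `[0, 1]`.
#' @param delta Nonnegative noncentrality parameter.
#' @return The summed log mixture density.
#' @examples
#' chi2_mixture_loglik(1, pi0 = 1, delta = 3) # log g0(1)
#' @export
chi2_mixture_loglik <- function(w_values, pi0, delta) {
  if (any(w_values < 0)) stop_invalid_input("`w_values` must be nonnegative.")
  if (pi0 < 0 || pi0 > 1) stop_invalid_input("`pi0` must lie in [0, 1].")
  if (delta < 0) stop_invalid_input("`delta` must be nonnegative.")
  w <- pmax(w_values, 1e-8)
  dens <- pi0 * stats::dchisq(w, df = 1) +
    (1 - pi0) * stats::dchisq(w, df = 1, ncp = delta)
  ll <- sum(log(dens))
  if (!is.finite(ll)) {
    rlang::abort("non-finite chi-square mixture log-likelihood.",
                 class = "arclfdr_numeric_error")
  }
  ll
}

#' Type-II maximum-likelihood fit of the chi-square two-groups model
#'
#' Maximizes the marginal log-likelihood over `(pi0, delta)` on
#' `[0, 1] x (0, delta_max]`. A coarse grid search locates the basin (the
#' surface can be multimodal as `pi0` approaches 1), then `optim` (L-BFGS-B)
#' refines from the best cell. Deterministic given the data.
#'
#' @param w_values Nonnegative 1-df chi-square statistics (at least 100).
#' @param delta_max Upper bound for the noncentrality (default 50).
#' @return An object of class `chi2_mixture_fit` with `pi0_hat`, `delta_hat`,
#'   `loglik`, `converged`, and `n`.
#' @examples
#' w <- c(rchisq(9000, 1), rchisq(1000, 1, ncp = 4))
#' fit <- fit_type2_mle(w)
#' c(fit$pi0_hat, fit$delta_hat)
#' @export
fit_type2_mle <- function(w_values, delta_max = 50) {
  w_values <- as.numeric(w_values)
  if (length(w_values) < 100L) {
    stop_invalid_input("need at least 100 statistics for the type-II MLE fit.")
  }
  if (any(!is.finite(w_values)) || any(w_values < 0)) {
    stop_invalid_input("`w_values` must be finite and nonnegative.")
  }
  nll <- function(par) -chi2_mixture_loglik(w_values, par[1], par[2])

  pi0_grid <- c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.99, 0.999)
  delta_grid <- c(0.5, 1, 2, 3, 4, 6, 8, 12)
  cells <- expand.grid(pi0 = pi0_grid, delta = delta_grid)
  vals <- mapply(function(p, d) nll(c(p, d)), cells$pi0, cells$delta)
  best <- which.min(vals)

  opt <- stats::optim(
    par = c(cells$pi0[best], cells$delta[best]), fn = nll,
    method = "L-BFGS-B",
    lower = c(0, 1e-4), upper = c(1, delta_max),
    control = list(maxit = 500)
  )
  if (opt$convergence != 0 && opt$value > vals[best]) {
    stop_fit_failure(sprintf(
      "type-II MLE did not converge (code %d); best grid point: pi0 = %g, delta = %g.",
      opt$convergence, cells$pi0[best], cells$delta[best]))
  }
  structure(
    list(pi0_hat = opt$par[1], delta_hat = opt$par[2],
         loglik = -opt$value, converged = opt$convergence == 0,
         n = length(w_values)),
    class = "chi2_mixture_fit"
  )
}

#' LFDR from a fitted chi-square mixture
#'
#' Evaluates `Psi(w) = pi0 * g0(w) / (pi0 * g0(w) + (1 - pi0) * g1(w; delta))`
#' at each statistic, clamped to `[0, 1]`. For `delta > 0` the likelihood
#' ratio `g1/g0` is increasing in `w`, so the LFDR is nonincreasing.
#'
#' @param w_values Nonnegative chi-square statistics.
#' @param fit A `chi2_mixture_fit` from [fit_type2_mle()], or any list with
#'   `pi0_hat` and `delta_hat`.
#' @return Numeric vector of LFDR values in `[0, 1]`.
#' @export
mle_lfdr <- function(w_values, fit) {
  if (is.null(fit$pi0_hat) || is.null(fit$delta_hat)) {
    stop_invalid_input("`fit` must carry `pi0_hat` and `delta_hat`.")
  }
  if (any(w_values < 0)) stop_invalid_input("`w_values` must be nonnegative.")
  w <- pmax(w_values, 1e-8)
  pi0 <- fit$pi0_hat
  if (pi0 >= 1) return(rep(1, length(w)))
  if (pi0 <= 0) return(rep(0, length(w)))
  num <- pi0 * stats::dchisq(w, df = 1)
  den <- num + (1 - pi0) * stats::dchisq(w, df = 1, ncp = fit$delta_hat)
  pmin(1, pmax(0, num / den))
}

#' Type-II MLE LFDR for a test table
#'
#' Data-frame-first interface to the chi-square mixture model: fits
#' `(pi0, delta)` to the `w` column (computed as `z^2` when absent — the z
#' is the probit transform of the chi-square, but squaring the z of a
#' two-sided statistic is only valid when the table was built from
#' chi-squares; supply `w` directly when in doubt) and returns per-test LFDR.
#'
#' @param data A [stat_table()] with a `w` column of 1-df chi-square
#'   statistics (or a `z` column to invert).
#' @param delta_max Passed to [fit_type2_mle()].
#' @return A tibble with `test_id`, `w`, `x`, `lfdr`, `method` (`"MLE"`);
#'   the fit is attached as attribute `"fit"`.
#' @export
lfdr_mle <- function(data, delta_max = 50) {
  data <- as_stat_table(data)
  w <- if ("w" %in% names(data)) data$w else z_to_w(data$z)
  fit <- fit_type2_mle(w, delta_max = delta_max)
  out <- tibble::tibble(
    test_id = data$test_id, w = w, x = data$x,
    lfdr = mle_lfdr(w, fit), method = "MLE"
  )
  attr(out, "fit") <- fit
  out
}

# inverse of the probit z-transform: w with F_chisq1(w) = Phi(z)
z_to_w <- function(z) {
  stats::qchisq(stats::pnorm(z, lower.tail = FALSE, log.p = TRUE),
                df = 1, lower.tail = FALSE, log.p = TRUE)
}
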