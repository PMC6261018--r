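#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a histogram-based fit
#'
#' @param x An `hb_fit`.
#' @param ... Unused.
#' @return A tibble with one row per log-density polynomial coefficient
#'   (`term`, `estimate`); the coefficients apply to the fitted range
#'   rescaled to `[-1, 1]`.
#' @export
tidy.hb_fit <- function(x, ...) {
  k <- seq_along(x$density$coefficients) - 1L
  tibble::tibble(term = paste0("u^", k), estimate = x$density$coefficients)
}

#' Glance at a histogram-based fit
#'
#' @param x An `hb_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `pi0_hat`, `n_fit`, `n_bins`, `degree`,
#'   `deviance`.
#' @export
glance.hb_fit <- function(x, ...) {
  tibble::tibble(pi0_hat = x$pi0_hat, n_fit = x$n_fit, n_bins = x$n_bins,
                 degree = x$degree, deviance = x$density$deviance)
}

#' Tidy a chi-square mixture fit
#'
#' @param x A `chi2_mixture_fit`.
#' @param ... Unused.
#' @return A tibble with rows for `pi0` and `delta`.
#' @export
tidy.chi2_mixture_fit <- function(x, ...) {
  tibble::tibble(term = c("pi0", "delta"),
                 estimate = c(x$pi0_hat, x$delta_hat))
}

#' Glance at a chi-square mixture fit
#'
#' @param x A `chi2_mixture_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `pi0_hat`, `delta_hat`, `loglik`, `converged`,
#'   `n`.
#' @export
glance.chi2_mixture_fit <- function(x, ...) {
  tibble::tibble(pi0_hat = x$pi0_hat, delta_hat = x$delta_hat,
                 loglik = x$loglik, converged = x$converged, n = x$n)
}

#' Tidy an ARC/CRC comparison
#'
#' @param x An `arc_comparison` from [run_comparison()].
#' @param ... Unused.
#' @return The per-region summary tibble.
#' @export
tidy.arc_comparison <- function(x, ...) tibble::as_tibble(x$summary)

#' Glance at an ARC/CRC comparison
#'
#' @param x An `arc_comparison`.
#' @param ... Unused.
#' @return A one-row tibble with the marginal MSEs, relative MSE and its
#'   base-2 log.
#' @export
glance.arc_comparison <- function(x, ...) {
  marg <- x$summary[x$summary$region == "marginal", ]
  tibble::tibble(n_focal = marg$n, mse_crc = marg$mse_crc,
                 mse_arc = marg$mse_arc, remse_marg = marg$remse,
                 log2_remse_marg = marg$log2_remse)
}

#' Plot a bootstrap err profile
#'
#' Shows `err = variance + bias^2` and its two components against the
#' candidate half-width (log axis), with the selected minimum highlighted.
#'
#' @param object An `err_profile` from [estimate_err_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.err_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$bias2 <- df$bias_hat^2
  long <- tidyr::pivot_longer(
    df[c("delta", "sigma2_hat", "bias2", "err_hat")],
    cols = c("sigma2_hat", "bias2", "err_hat"),
    names_to = "component", values_to = "value")
  long$component <- factor(long$component,
                           levels = c("err_hat", "sigma2_hat", "bias2"),
                           labels = c("err", "variance", "bias²"))
  star <- df$delta[which.min(ifelse(df$usable, df$err_hat, Inf))]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$delta, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = star, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(Delta), y = "bootstrap estimate",
                  colour = NULL,
                  title = "Bootstrap err profile",
                  subtitle = sprintf("selected Δ* = %.4g", star)) +
    ggplot2::theme_minimal()
}

#' Plot an ARC/CRC comparison summary
#'
#' Bar chart of the base-2 log relative MSE (ARC / CRC) per covariate region
#' and marginally; bars below zero favor the adaptive reference class.
#'
#' @param object An `arc_comparison` from [run_comparison()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.arc_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object$summary)
  df <- df[is.finite(df$log2_remse), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$log2_remse)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$log2_remse - .data$se_log2_remse,
      ymax = .data$log2_remse + .data$se_log2_remse), width = 0.2) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = expression(log[2] ~ "relative MSE (ARC / CRC)"),
                  title = "ARC vs CRC mean squared error") +
    ggplot2::theme_minimal()
}

#' @export
print.hb_fit <- function(x, ...) {
  cat("Histogram-based two-groups fit\n")
  cat(sprintf("  n = %d, bins = %d, degree = %d\n", x$n_fit, x$n_bins, x$degree))
  cat(sprintf("  pi0_hat = %.4f\n", x$pi0_hat))
  invisible(x)
}

#' @export
print.chi2_mixture_fit <- function(x, ...) {
  cat("Type-II MLE chi-square mixture fit\n")
  cat(sprintf("  n = %d, pi0_hat = %.4f, delta_hat = %.3f, loglik = %.2f%s\n",
              x$n, x$pi0_hat, x$delta_hat, x$loglik,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
print.arc_comparison <- function(x, ...) {
  cat(sprintf("ARC vs CRC comparison (N = %d, delta0 = %g, B = %d, %d focal tests)\n",
              x$config$N, x$delta0, x$B, nrow(x$focal)))
  print(tibble::as_tibble(x$summary))
  invisible(x)
}

#' @export
print.step_prior <- function(x, ...) {
  cat(sprintf("Step prior: pi0(x) = %g for x <= %g, %g for x > %g\n",
              x$pi01, x$x0, x$pi02, x$x0))
  invisible(x)
}
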