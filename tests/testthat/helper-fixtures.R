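# Shared fixtures, all generated in code under fixed seeds.

# z-values from the two-groups model pi0 * N(0,1) + (1 - pi0) * N(mu1, 1)
two_groups_z <- function(n, pi0 = 0.8, mu1 = 3, seed = 1) {
  set.seed(seed)
  alt <- stats::rbinom(n, 1, 1 - pi0)
  stats::rnorm(n, mean = mu1 * alt)
}

# closed-form LFDR of the normal two-groups model above
two_groups_oracle <- function(z, pi0 = 0.8, mu1 = 3) {
  num <- pi0 * stats::dnorm(z)
  num / (num + (1 - pi0) * stats::dnorm(z, mean = mu1))
}

# a histogram whose counts follow a density exactly (up to integer rounding)
exact_density_hist <- function(density_fun, lo = -4, hi = 4, n_bins = 40,
                               scale = 1e8) {
  edges <- seq(lo, hi, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  width <- edges[2] - edges[1]
  counts <- as.integer(round(scale * density_fun(centers) * width))
  structure(
    list(bin_edges = edges, counts = counts, bin_width = width,
         n_in_range = sum(counts)),
    class = "hb_histogram"
  )
}

# small covariate-modulated dataset for ARC plumbing tests
small_sim <- function(N = 2000, seed = 11, delta = 6,
                      prior = step_prior(0.2, 0.6, 0.95)) {
  simulate_dataset(sim_config(N = N, prior = prior, delta = delta, seed = seed))
}
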