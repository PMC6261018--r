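# arclfdr

Covariate-adaptive local false discovery rate (LFDR) estimation for
large-scale hypothesis testing.

In a genome-wide association scan or an imaging study, each of N tests
yields a z-value (standard normal under the null) and a scalar covariate —
minor allele frequency, voxel location — that carries information about how
plausible each null hypothesis is. Under the empirical-Bayes two-groups
model the marginal density of a z-value is

    f(z) = π₀ f₀(z) + (1 − π₀) f₁(z),      f₀ = φ (theoretical null),

and the LFDR is the posterior null probability Ψ(z) = π₀ f₀(z) / f(z);
tests with Ψ̂ < 0.2 are reported as discoveries. When the prior π₀(x)
depends on the covariate, the question becomes the *reference class
problem*: which tests should be pooled to estimate one test's LFDR?

`arclfdr` implements both answers:

* **CRC** (combined reference class, `lfdr_crc()`): pool all N tests into
  one histogram-based fit — Poisson regression of histogram counts on a
  polynomial, null proportion by central matching at zero.
* **ARC** (adaptive reference class, `lfdr_arc()`): pool only tests with
  |xⱼ − xᵢ| ≤ Δ, choosing Δ per test by minimizing a conditioned-bootstrap
  estimate of err(Δ) = variance + prediction bias², with the smallest
  candidate half-width Δ₀ anchoring the bias estimate.

It also provides a type-II maximum-likelihood two-groups model for 1-df
chi-square statistics (`lfdr_mle()`), a synthetic-data generator with exact
oracle LFDR (`simulate_dataset()`), an MSE benchmarking harness
(`run_comparison()`), broom-style `tidy()`/`glance()` methods, `autoplot()`
figures, and a command-line front end (`inst/cli/arclfdr`).

## Worked example

Simulate a scan of 20,000 tests whose null prior steps from 0.6 (x ≤ 0.2)
to 0.95 (x > 0.2), with noncentrality 6 alternatives:

```r
library(arclfdr)

d <- simulate_dataset(sim_config(N = 20000,
                                 prior = step_prior(0.2, 0.6, 0.95),
                                 delta = 6, seed = 7))
crc <- lfdr_crc(d)
head(crc, 3)
#> # A tibble: 3 × 5
#>   test_id       z     x  lfdr method
#>   <chr>     <dbl> <dbl> <dbl> <chr>
#> 1 t1      -0.0120 0.989 1.000 CRC
#> 2 t2       0.455  0.398 1     CRC
#> 3 t3       1.05   0.116 0.939 CRC
sum(crc$lfdr < 0.2)
#> [1] 869
```

An LFDR near 1 says the test is almost surely null. Now take one promising
test in the alternative-rich low-covariate region (row 4: z = 3.22,
x = 0.070) and let ARC choose its reference class:

```r
cfg <- bootstrap_config(delta0 = 0.05, B = 100, grid_points = 10, seed = 42)
arc_lfdr(d, 4, cfg)
#> # A tibble: 1 × 7
#>   test_id     z      x   lfdr method delta_star refclass_size
#>   <chr>   <dbl>  <dbl>  <dbl> <chr>       <dbl>         <int>
#> 1 t4       3.22 0.0697 0.0152 ARC         0.139          4193
crc$lfdr[4]
#> [1] 0.0665
d$lfdr_true[4]
#> [1] 0.0138
```

ARC settles on a window of half-width 0.139 (4,193 tests, all on the
enriched side of the step) and estimates Ψ̂ = 0.0152, close to the
generator's oracle value 0.0138; the covariate-blind CRC estimate 0.0665
over-states the null probability more than fourfold because it averages the
two prior regimes. `estimate_err_profile()` exposes the per-Δ bootstrap
mean, variance, bias and err behind the selection, and `autoplot()` draws
the profile.

At the fit level, `glance(hb_fit(d$z))` reports the pooled null-proportion
estimate (here π̂₀ = 0.904, matching the design's E π₀(x) = 0.88 up to
estimation error, with 120 bins and a degree-7 log-density).

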