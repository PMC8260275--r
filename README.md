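# multinoise

Cascade models of neural spike-count variability with multiple noise
sources, and the machinery to fit and validate them.

## The problem

Binned spike counts of sensory neurons are commonly modelled as a
linear–nonlinear–Poisson (LNP) cascade: a filtered stimulus value
`x_t` drives a static nonlinearity `f`, and counts are Poisson with mean
`f(x_t)`. Poisson noise pins the variance to the mean, yet recorded
responses range from sub- to strongly super-Poisson and change character
with stimulus conditions. Worse, assuming the wrong noise structure
biases the *deterministic* part of the model: fitted nonlinearities come
out too linear, or acquire spurious offsets.

`multinoise` implements a cascade for users who want to model that
variability explicitly — systems/computational neuroscientists fitting
retinal ganglion cell or similar single-neuron recordings. Variability
enters at three stages, and spike generation is deterministic:

    r_t = R[ y_t + n_down,t ],   y_t | lambda_t ~ N(lambda_t, sigma_mult^2 * lambda_t),
    lambda_t = f(x_t + n_up,t),  n_up ~ N(0, sigma_up^2),
    f(x) = beta1 * log(1 + exp(beta2 * x + beta3)) + beta4,

with `n_down` Gaussian `N(0, sigma_down^2)` (or, in the *mixture*
variant, present only with probability `p_down` — an intermittent noise
source that produces an excess of zero counts), and `R[.]` rounding to
the nearest nonnegative integer. Upstream noise is shaped by the slope of
`f`, multiplicative noise scales with its output, downstream noise is
input-independent: three distinct, identifiable signatures.

The package provides:

* the exact count likelihood, by composing the stage densities through
  the nonlinearity (change of variables + adaptive quadrature in C++),
* multi-start bounded Nelder–Mead maximum-likelihood fitting of the
  nonlinearity and all noise strengths simultaneously, plus the LNP
  baseline under the same protocol,
* reverse-correlation preprocessing (whitened spike-triggered average,
  13 Hz zero-phase smoothing, 2×half-max binning, z-scoring) from raw
  stimulus/spike-count traces,
* metrics: Jensen–Shannon divergence between count distributions, SNR
  (`Var_s E[r|s] / E_s Var(r|s)`), input-weighted nonlinearity error,
  maximum curvature `beta1 * beta2^2 / 4`,
* a parameter-recovery harness that simulates suites of datasets from
  randomized models and measures how well fitting recovers them.

## Worked example

Simulate ~8 minutes of data (5000 bins) from a known model with all three
noise sources active, then fit it back:

```r
library(multinoise)

truth <- multistage_model(
  softplus_params(2, 3, -1, 0.1),          # sharply rectified nonlinearity
  noise_params(0.4, 0.9, 0.5))             # sigma_up, sigma_mult, sigma_down

set.seed(11)
x <- rnorm(5000)                           # z-scored generator signal
d <- binned_dataset(x, simulate_responses(truth, x, seed = 12))

fit <- fit_mle(d, variant = "gaussian", cfg = fit_config(n_starts = 3, seed = 99))
print(fit)
#> Multistage noise model fit (gaussian): log-likelihood -7609.5935 over 5000 bins, best of 3 starts
#> Multistage noise model
#>   softplus nonlinearity: f(x) = 2.026 * log(1 + exp(3.02 x + -1.07)) + 0.1688
#>   noise (gaussian variant): sigma_up = 0.3962, sigma_mult = 0.9604, sigma_down = 0.2638
```

The generating nonlinearity `(2, 3, -1, 0.1)` and the two noise sources
that matter here (`sigma_up = 0.4`, `sigma_mult = 0.9`; together ~92% of
the total noise) are recovered within a few percent. Compare against the
Poisson baseline and inspect a fitted count distribution:

```r
lnp <- fit_lnp(d, cfg = fit_config(n_starts = 3, seed = 99))
nonlinearity_error(truth$nonlinearity, fit$model$nonlinearity)  # 0.053 spikes
nonlinearity_error(truth$nonlinearity, lnp$model)               # 0.264 spikes
noise_contribution(truth)                  # 0.47 / 0.46 / 0.08 (up/mult/down)
response_pmf(fit$model, x = 1)$probs[1:5]  # 0.053 0.084 0.121 0.140 0.139
```

The weighted error of the multistage fit's nonlinearity (0.053 spikes) is
five times smaller than the LNP fit's (0.264 spikes), whose Poisson
assumption must absorb the non-Poisson variability. `sigma_down`
contributes only 8% of the noise here and is correspondingly weakly
identified — the recovery harness reports relative errors only for
sources contributing at least 20%.

A thin command-line wrapper over the same functions is installed as
`exec/multinoise` (subcommands `simulate`, `loglik`, `fit`, `metrics`,
`recover`).

## Documentation

The methods vignette (`vignettes/multistage-noise-model.Rmd`) describes
the model, the likelihood construction and its numerical strategy, the
fitting protocol, the synthetic study design, and known limitations.
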