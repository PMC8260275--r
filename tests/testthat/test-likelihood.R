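test_that("nonlinearity-output density is a valid change of variables", {
  m <- multistage_model(softplus_params(1, 2, 0, 0), noise_params(0.5, 0, 0))
  g <- p_lambda(m, 0)
  expect_false(is_point_mass(g))
  expect_equal(grid_mass(g), 1, tolerance = 1e-6)
  expect_true(all(g$values >= 0) && all(diff(g$points) > 0))
  # sigma_up -> 0: mass concentrates at f(x)
  m0 <- multistage_model(softplus_params(1, 2, 0, 0), noise_params(0, 1, 1))
  g0 <- p_lambda(m0, 0.7)
  expect_true(is_point_mass(g0))
  expect_equal(g0$point_mass, softplus_eval(m0$nonlinearity, 0.7))
  # linear regime: approximately Gaussian with mean f(x), SD b1 b2 sigma_up
  ml <- multistage_model(softplus_params(1.5, 2, 8, 0), noise_params(0.3, 0, 0))
  gl <- p_lambda(ml, 0)
  expect_equal(multinoise:::grid_mean(gl), softplus_eval(ml$nonlinearity, 0),
               tolerance = 1e-3)
  expect_equal(max(gl$values), dnorm(0) / (1.5 * 2 * 0.3), tolerance = 1e-3)
  # matches a large Monte-Carlo histogram (binned comparison)
  mx <- multistage_model(softplus_params(1, 2, 0, 0), noise_params(0.5, 0, 0))
  set.seed(5)
  lam <- softplus_eval(mx$nonlinearity, 0 + rnorm(1e6, 0, 0.5))
  br <- quantile(lam, seq(0, 1, length.out = 26))
  emp <- as.numeric(table(cut(lam, br, include.lowest = TRUE))) / 1e6
  gx <- p_lambda(mx, 0, n_grid = 8001)
  cdf <- cumsum(c(0, diff(gx$points) * (head(gx$values, -1) + gx$values[-1]) / 2))
  model_p <- diff(approx(gx$points, cdf / max(cdf), xout = br, rule = 2)$y)
  expect_lt(jsd(emp / sum(emp), model_p / sum(model_p)), 1e-3)
})

test_that("multiplicative and downstream stages reduce to identities when off", {
  m <- multistage_model(softplus_params(1, 2, 0, 0), noise_params(0.5, 0, 0))
  expect_identical(p_y(m, 0.3)$points, p_lambda(m, 0.3, n_grid = 4001)$points)
  expect_identical(p_z(m, 0.3)$points, p_y(m, 0.3)$points)
  # single-lambda Gaussian: sigma_up = 0, sigma_mult^2 = 1.5, f(x) = 4
  p <- softplus_params(1, 1, 0, 0)
  x4 <- softplus_inverse(p, 4)
  my <- multistage_model(p, noise_params(0, sqrt(1.5), 0))
  gy <- p_y(my, x4)
  expect_equal(grid_mass(gy), 1, tolerance = 1e-6)
  expect_equal(gy$values, dnorm(gy$points, 4, sqrt(6)), tolerance = 1e-6)
  # pure shift: f == c, only downstream Gaussian noise
  mz <- multistage_model(softplus_params(1, 1, -800, 2), noise_params(0, 0, 0.8))
  gz <- p_z(mz, 0)
  expect_equal(gz$values, dnorm(gz$points, 2, 0.8), tolerance = 1e-8)
})

test_that("densities at every stage integrate to one", {
  m <- multistage_model(softplus_params(1.5, 1.2, 0.3, 0.1),
                        noise_params(0.4, 0.8, 0.6))
  for (x in c(-1, 0.5, 2)) {
    expect_equal(grid_mass(p_lambda(m, x)), 1, tolerance = 1e-6)
    expect_equal(grid_mass(p_y(m, x)), 1, tolerance = 1e-6)
    expect_equal(grid_mass(p_z(m, x)), 1, tolerance = 1e-6)
  }
  mm <- multistage_model(softplus_params(1.5, 1.2, 0.3, 0.1),
                         noise_params(0.4, 0.8, 0.6, p_down = 0.5,
                                      variant = "mixture"))
  expect_equal(grid_mass(p_z(mm, 0.5)), 1, tolerance = 1e-6)
})

test_that("count pmf matches Gaussian closed forms and conserves mass", {
  # noiseless: point mass at quantize(f(x))
  m0 <- multistage_model(softplus_params(1, 1, 0, 0), noise_params(0, 0, 0))
  x24 <- softplus_inverse(m0$nonlinearity, 2.4)
  pmf0 <- response_pmf(m0, x24)
  expect_equal(pmf0$probs[3], 1)
  expect_equal(sum(pmf0$probs), 1)
  # f == 0 with unit downstream noise: rectified-Gaussian closed form
  mg <- multistage_model(softplus_params(1, 1, -800, 0), noise_params(0, 0, 1))
  pmfg <- response_pmf(mg, 0)
  expect_equal(pmfg$probs[1], pnorm(0.5), tolerance = 1e-9)
  expect_equal(pmfg$probs[2], pnorm(1.5) - pnorm(0.5), tolerance = 1e-9)
  expect_lt(pmfg$tail_mass, 1e-8)
  # tail auto-extension keeps total mass at one
  mb <- multistage_model(softplus_params(3, 2, 2, 0), noise_params(0.5, 1, 1))
  pmfb <- response_pmf(mb, 2)
  expect_equal(sum(pmfb$probs) + pmfb$tail_mass, 1, tolerance = 1e-6)
})

test_that("count probabilities agree with the lambda-space quadrature oracle", {
  m <- multistage_model(softplus_params(1, 2, 0, 0), noise_params(0.5, 1, 0.3))
  pmf <- response_pmf(m, 1)
  for (k in 0:5)
    expect_equal(pmf$probs[k + 1], oracle_count_prob(m, 1, k), tolerance = 1e-7)
  # mixture variant, different operating point
  mm <- multistage_model(softplus_params(2, 1, 0.5, 0.1),
                         noise_params(0.3, 0.8, 1.2, p_down = 0.4,
                                      variant = "mixture"))
  pmfm <- response_pmf(mm, 0.8)
  for (k in 0:5)
    expect_equal(pmfm$probs[k + 1], oracle_count_prob(mm, 0.8, k),
                 tolerance = 1e-7)
  # near-deterministic output stage under strong upstream noise (narrow
  # count windows in the integration variable)
  mh <- multistage_model(softplus_params(3, 4, 0, 0), noise_params(1, 0.05, 0.02))
  pmfh <- response_pmf(mh, 0.5)
  for (k in c(0:3, 8))
    expect_equal(pmfh$probs[k + 1], oracle_count_prob(mh, 0.5, k),
                 tolerance = 1e-6)
})

test_that("count pmf matches simulation histograms (generator/likelihood duality)", {
  m <- multistage_model(softplus_params(1, 2, 0, 0), noise_params(0.5, 1, 0.3))
  pmf <- response_pmf(m, 1)
  emp <- mc_pmf(m, 1, 1e6, pmf, seed = 21)
  expect_lt(jsd(emp, pmf$probs / sum(pmf$probs)), 1e-3)
})

test_that("log-likelihood is additive, floored, and variant-consistent", {
  m <- multistage_model(softplus_params(1, 2, 0, 0), noise_params(0.5, 1, 0.3))
  set.seed(3)
  x <- rnorm(80)
  d <- binned_dataset(x, simulate_responses(m, x, seed = 4))
  # single closed-form bin
  mg <- multistage_model(softplus_params(1, 1, -800, 0), noise_params(0, 0, 1))
  d1 <- binned_dataset(0, 0L)
  expect_equal(as.numeric(log_likelihood(mg, d1)), log(pnorm(0.5)),
               tolerance = 1e-9)
  # duplicating every bin doubles the log-likelihood exactly
  d2 <- binned_dataset(rep(d$inputs, 2), rep(d$counts, 2))
  expect_equal(as.numeric(log_likelihood(m, d2)),
               2 * as.numeric(log_likelihood(m, d)), tolerance = 1e-10)
  # gaussian variant == mixture variant at p_down = 1, exactly
  mm1 <- multistage_model(m$nonlinearity,
                          noise_params(0.5, 1, 0.3, p_down = 1,
                                       variant = "mixture"))
  expect_equal(as.numeric(log_likelihood(mm1, d)),
               as.numeric(log_likelihood(m, d)), tolerance = 1e-8)
  # impossible observation hits the floor with a warning, never -Inf
  m0 <- multistage_model(softplus_params(1, 1, 0, 0), noise_params(0, 0, 0))
  dbad <- binned_dataset(0, 5L)
  expect_warning(llb <- log_likelihood(m0, dbad), "floor")
  expect_true(is.finite(llb))
  expect_identical(attr(llb, "n_floored"), 1L)
})

test_that("log-likelihood agrees with per-bin oracle probabilities", {
  m <- multistage_model(softplus_params(1.8, 1.4, -0.5, 0.2),
                        noise_params(0.6, 0.7, 0.4))
  set.seed(13)
  x <- rnorm(12)
  d <- binned_dataset(x, simulate_responses(m, x, seed = 14))
  oracle_ll <- sum(log(mapply(function(xi, ri) oracle_count_prob(m, xi, ri),
                              d$inputs, d$counts)))
  expect_equal(as.numeric(log_likelihood(m, d, eps = 1e-10)), oracle_ll,
               tolerance = 1e-4)
})

test_that("history-augmented likelihood conditions on observed previous counts", {
  p <- softplus_params(1, 2, 0, 0)
  mh <- multistage_model(p, noise_params(0, 0, 0.5), history_weight = 0.4)
  d <- binned_dataset(c(0.2, -0.1, 0.5), c(1L, 2L, 0L))
  x_eff <- d$inputs + 0.4 * c(0, 1, 2)
  ll_manual <- sum(sapply(1:3, function(t) {
    lam <- softplus_eval(p, x_eff[t]); k <- d$counts[t]
    lo <- if (k > 0) pnorm((k - 0.5 - lam) / 0.5) else 0
    log(pnorm((k + 0.5 - lam) / 0.5) - lo)
  }))
  expect_equal(as.numeric(log_likelihood(mh, d)), ll_manual, tolerance = 1e-8)
})

test_that("LNP likelihood matches the Poisson pmf and its closed-form MLE", {
  p1 <- softplus_params(1, 1, 0, 0)
  x1 <- softplus_inverse(p1, 1)
  expect_equal(log_likelihood_lnp(p1, binned_dataset(x1, 0L)), -1)
  x2 <- softplus_inverse(p1, 2)
  expect_equal(log_likelihood_lnp(p1, binned_dataset(x2, 2L)),
               2 * log(2) - 2 - log(2))
  # constant-rate model: likelihood over the rate is maximized at the mean count
  set.seed(8)
  counts <- rpois(400, 3.2)
  d <- binned_dataset(numeric(400), counts)
  ll_at <- function(rate)
    log_likelihood_lnp(softplus_params(1, 1, -800, rate), d)
  mle <- optimize(ll_at, c(0.5, 10), maximum = TRUE)$maximum
  expect_equal(mle, mean(counts), tolerance = 1e-4)
})
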