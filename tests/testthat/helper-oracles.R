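# Independent oracles used across tests.
#
# The package computes count probabilities by marginalizing over the
# upstream noise variable u (lambda = f(x+u)) with adaptive quadrature in
# C++.  The oracle here goes the other route: the explicit change-of-
# variables density over lambda, composed stage by stage with stats::
# integrate at high precision.  Agreement between the two is a genuine
# dual-route check.

oracle_count_prob <- function(m, x, k) {
  p <- m$nonlinearity
  np <- m$noise
  if (np$sigma_up == 0) {
    lam <- softplus_eval(p, x)
    s1 <- sqrt(np$sigma_mult^2 * lam + np$sigma_down^2)
    s0 <- np$sigma_mult * sqrt(lam)
    bin <- function(s) {
      if (s > 0) {
        hi <- pnorm((k + 0.5 - lam) / s)
        lo <- if (k > 0) pnorm((k - 0.5 - lam) / s) else 0
        hi - lo
      } else as.numeric(spike_quantize(lam) == k)
    }
    return(np$p_down * bin(s1) + (1 - np$p_down) * bin(s0))
  }
  pz <- function(z) {
    sapply(z, function(zi) {
      f_lam <- function(lam) {
        u <- softplus_inverse(p, lam) - x
        plam <- dnorm(u, 0, np$sigma_up) / softplus_derivatives(p, u + x)$first
        s1 <- sqrt(np$sigma_mult^2 * lam + np$sigma_down^2)
        dens <- np$p_down * dnorm(zi, lam, s1)
        if (np$p_down < 1) {
          s0 <- np$sigma_mult * sqrt(lam)
          dens <- dens + (1 - np$p_down) * dnorm(zi, lam, s0)
        }
        plam * dens
      }
      lo_lam <- p$beta4 + 1e-12
      # split at the mixture-kernel centre so adaptive integration cannot
      # step over a narrow conditional density (small sigma_mult/sigma_down)
      if (zi > lo_lam) {
        integrate(f_lam, lo_lam, zi, rel.tol = 1e-10,
                  stop.on.error = FALSE)$value +
          integrate(f_lam, zi, Inf, rel.tol = 1e-10,
                    stop.on.error = FALSE)$value
      } else {
        integrate(f_lam, lo_lam, Inf, rel.tol = 1e-10,
                  stop.on.error = FALSE)$value
      }
    })
  }
  lo <- if (k == 0) -40 else k - 0.5
  integrate(pz, lo, k + 0.5, rel.tol = 1e-9, stop.on.error = FALSE)$value
}

# random valid model with all three sources active, scaled to moderate rates
rand_model <- function(variant = "gaussian") {
  p <- softplus_params(runif(1, 0.5, 4), runif(1, 0.5, 4),
                       runif(1, -2, 2), runif(1, 0, 0.5))
  np <- noise_params(runif(1, 0.05, 1), runif(1, 0.05, 1.5), runif(1, 0.05, 1.5),
                     p_down = if (variant == "mixture") runif(1, 0.3, 1) else 1,
                     variant = variant)
  multistage_model(p, np)
}

# empirical count distribution from n simulated draws at a fixed input,
# padded to the length of a reference pmf
mc_pmf <- function(m, x, n, pmf_ref, seed) {
  r <- simulate_responses(m, rep(x, n), seed = seed)
  emp <- tabulate(r + 1L, nbins = length(pmf_ref$probs))
  emp / sum(emp)
}
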