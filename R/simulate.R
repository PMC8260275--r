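#' Deterministic spike quantization
#'
#' The cascade generates spikes deterministically: the continuous noisy
#' output is mapped to the nearest nonnegative integer count. Ties at
#' half-integers round up (0.5 -> 1); any consistent tie rule affects only
#' measure-zero events under the continuous noise distributions.
#'
#' @param z Numeric vector of continuous model outputs.
#' @return Integer vector of spike counts, `>= 0`.
#' @export
spike_quantize <- function(z) {
  if (!all(is.finite(z))) stop("spike_quantize requires finite input")
  as.integer(pmax(0, floor(z + 0.5)))
}

#' Draw downstream noise values
#'
#' Samples the downstream additive noise: a zero-mean Gaussian of SD
#' `sigma_down` present with probability `p_down`, and exactly 0 otherwise
#' (the `"gaussian"` variant has `p_down = 1`).
#'
#' @param np A [noise_params()] object.
#' @param n Number of draws, >= 1.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of `n` downstream noise draws.
#' @export
sample_downstream <- function(np, n, seed = NULL) {
  validate_noise_params(np)
  n <- as.integer(n)
  if (n <= 0L) stop("n must be positive")
  if (!is.null(seed)) set.seed(seed)
  out <- numeric(n)
  present <- if (np$p_down >= 1) rep(TRUE, n) else runif(n) < np$p_down
  k <- sum(present)
  if (k > 0L && np$sigma_down > 0)
    out[present] <- rnorm(k, 0, np$sigma_down)
  out
}

# single-bin-at-a-time core shared by the vectorized and history paths;
# x_eff is the effective nonlinearity input (stimulus + history term)
simulate_stage <- function(m, x_eff, quantize = TRUE) {
  p <- m$nonlinearity; np <- m$noise
  n <- length(x_eff)
  lam <- softplus_eval(p, x_eff + if (np$sigma_up > 0) rnorm(n, 0, np$sigma_up) else 0)
  if (any(lam < 0)) {            # cannot occur for beta4 >= 0; defensive clamp
    warning("negative nonlinearity output clamped to 0")
    lam <- pmax(lam, 0)
  }
  y <- if (np$sigma_mult > 0) lam + rnorm(n, 0, 1) * np$sigma_mult * sqrt(lam) else lam
  z <- y + sample_downstream(np, n)
  if (quantize) spike_quantize(z) else z
}

#' Simulate spike-count responses from the multistage model
#'
#' Per bin: draw upstream noise `N(0, sigma_up^2)`, evaluate the softplus at
#' the noisy input (plus `history_weight * r_{t-1}` when the model has a
#' response-history term), draw the multiplicative stage so the result has
#' conditional mean `lambda` and conditional variance `sigma_mult^2 * lambda`,
#' add a downstream noise draw, and quantize to the nearest nonnegative
#' integer count.
#'
#' @param m A [multistage_model()].
#' @param inputs Numeric vector of filtered stimulus values.
#' @param seed Optional integer seed; runs are bit-reproducible given a seed.
#' @param prev_count Spike count preceding the first bin (history models
#'   only; default 0).
#' @param quantize Apply spike quantization (default `TRUE`). Setting
#'   `FALSE` returns the continuous pre-quantization output, used e.g. for
#'   signal-to-noise calculations on the continuous cascade.
#' @return Integer vector of spike counts (or numeric if `quantize = FALSE`).
#' @export
simulate_responses <- function(m, inputs, seed = NULL, prev_count = 0L,
                               quantize = TRUE) {
  stopifnot(inherits(m, "multistage_model"))
  if (!all(is.finite(inputs))) stop("inputs must be finite")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(m$history_weight))
    return(simulate_stage(m, inputs, quantize = quantize))
  # sequential path: each bin's input depends on the previous count
  n <- length(inputs)
  out <- if (quantize) integer(n) else numeric(n)
  r_prev <- as.numeric(prev_count)
  for (t in seq_len(n)) {
    out[t] <- simulate_stage(m, inputs[t] + m$history_weight * r_prev,
                             quantize = quantize)
    r_prev <- if (quantize) out[t] else spike_quantize(out[t])
  }
  out
}
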