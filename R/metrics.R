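#' Signal-to-noise ratio of a model's responses
#'
#' Monte-Carlo estimate of
#' \deqn{SNR = \frac{\mathrm{Var}_s\,[\,E[r \mid s]\,]}
#'                  {E_s\,[\,\mathrm{Var}(r \mid s)\,]}:}
#' stimuli are drawn from `input_sampler`, each is presented `n_reps` times,
#' and the variance over stimuli of the conditional mean response is divided
#' by the mean over stimuli of the conditional response variance.
#'
#' @param m A [multistage_model()].
#' @param input_sampler Function of `n` returning `n` stimulus draws;
#'   defaults to standard normal (inputs are z-scored).
#' @param n_stimuli,n_reps Monte-Carlo sample sizes (defaults 2000 x 200).
#' @param seed Optional integer seed.
#' @param quantize Apply spike quantization (default `TRUE`); `FALSE`
#'   computes the SNR of the continuous pre-quantization output.
#' @return Scalar SNR estimate; `Inf` (with a warning) for a noiseless
#'   model, whose conditional variance vanishes.
#' @export
snr <- function(m, input_sampler = NULL, n_stimuli = 2000, n_reps = 200,
                seed = NULL, quantize = TRUE) {
  stopifnot(inherits(m, "multistage_model"))
  if (is.null(input_sampler)) input_sampler <- function(n) rnorm(n)
  if (!is.null(seed)) set.seed(seed)
  x <- input_sampler(n_stimuli)
  r <- simulate_stage(m, rep(x, each = n_reps), quantize = quantize)
  rm <- matrix(as.numeric(r), nrow = n_reps)
  mu <- colMeans(rm)
  v <- colMeans(rm^2) - mu^2
  v <- v * n_reps / (n_reps - 1)
  den <- mean(v)
  if (den <= 0) {
    warning("conditional variance is zero: noiseless model, SNR is infinite")
    return(Inf)
  }
  var(mu) / den
}

#' Noise level giving a target single-source SNR
#'
#' Finds, by bisection, the level of one noise source (the others set to
#' zero, nonlinearity fixed) at which the model's SNR equals `target`
#' (default 0.5). SNR decreases monotonically in the level, and the
#' Monte-Carlo SNR uses a common seed at every bisection step so the
#' bracketed function is deterministic.
#'
#' @param m A [multistage_model()]; only its nonlinearity (and `p_down`,
#'   for the downstream source in the mixture variant) is used.
#' @param source One of `"up"`, `"mult"`, `"down"`.
#' @param target Target SNR, > 0.
#' @param input_sampler,n_stimuli,n_reps,seed Passed to [snr()].
#' @param tol Relative tolerance on `|snr - target|`.
#' @return The noise level (SD for `"up"`/`"down"`, scale for `"mult"`).
#' @export
noise_level_for_snr <- function(m, source = c("up", "mult", "down"),
                                target = 0.5, input_sampler = NULL,
                                n_stimuli = 2000, n_reps = 200, seed = 1L,
                                tol = 0.05) {
  source <- match.arg(source)
  stopifnot(target > 0)
  p <- m$nonlinearity
  p_down <- if (m$noise$variant == "mixture") m$noise$p_down else 1
  variant <- m$noise$variant
  model_at <- function(level) {
    s <- c(up = 0, mult = 0, down = 0)
    s[source] <- level
    multistage_model(p, noise_params(s[["up"]], s[["mult"]], s[["down"]],
                                     p_down = if (source == "down") p_down else 1,
                                     variant = if (source == "down") variant else "gaussian"))
  }
  snr_at <- function(level)
    snr(model_at(level), input_sampler = input_sampler,
        n_stimuli = n_stimuli, n_reps = n_reps, seed = seed)
  # bracket: snr decreases with level
  hi <- 1; n_try <- 0
  while (snr_at(hi) > target) {
    hi <- hi * 2; n_try <- n_try + 1
    if (n_try > 40) stop(sprintf("target SNR %.3g unreachable below level %.3g", target, hi))
  }
  lo <- hi / 2; n_try <- 0
  while (snr_at(lo) < target) {
    lo <- lo / 2; n_try <- n_try + 1
    if (n_try > 60) stop(sprintf("target SNR %.3g unreachable above level %.3g", target, lo))
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    s <- snr_at(mid)
    if (abs(s - target) < tol * target) return(mid)
    if (s > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Jensen-Shannon divergence between discrete distributions
#'
#' \deqn{JSD(P, Q) = \tfrac12[D_{KL}(P, R) + D_{KL}(Q, R)],\quad
#'       R = \tfrac12(P + Q),}
#' with Kullback-Leibler divergence
#' \eqn{D_{KL}(Q, R) = \sum_x Q(x) \log_2(Q(x)/R(x))} and the convention
#' that terms with `Q(x) = 0` vanish. Logarithms are base 2, so the JSD is
#' symmetric, always finite and bounded in `[0, 1]` bits (1 bit exactly for
#' distributions with disjoint support).
#'
#' @param p,q Probability vectors over a shared support (equal length), or
#'   two [response_pmf()] objects, which are padded to a common count range.
#' @return JSD in bits.
#' @export
jsd <- function(p, q) {
  if (inherits(p, "count_pmf") && inherits(q, "count_pmf")) {
    n <- max(length(p$probs), length(q$probs))
    pv <- c(p$probs, numeric(n - length(p$probs)))
    qv <- c(q$probs, numeric(n - length(q$probs)))
  } else {
    pv <- as.numeric(p); qv <- as.numeric(q)
    if (length(pv) != length(qv))
      stop("p and q must share a common support (equal length)")
  }
  if (any(pv < 0) || any(qv < 0)) stop("probabilities must be >= 0")
  sp <- sum(pv); sq <- sum(qv)
  if (abs(sp - 1) > 1e-6 || abs(sq - 1) > 1e-6)
    stop("p and q must each sum to 1 (within 1e-6)")
  pv <- pv / sp; qv <- qv / sq
  r <- (pv + qv) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log2(a[i] / r[i]))
  }
  (kl(pv) + kl(qv)) / 2
}

#' Input-weighted absolute error between two nonlinearities
#'
#' \deqn{\int |f_{true}(x) - f_{est}(x)|\, w(x)\, dx} over `[lower, upper]`,
#' with `w` defaulting to the standard normal density (inputs are z-scored,
#' so this weights errors by how often each input occurs). Computed by
#' composite Simpson quadrature on a dense uniform grid. Units: spikes per
#' bin.
#'
#' @param true_p,est_p [softplus_params()] objects to compare.
#' @param weight_fn Density function of the input distribution.
#' @param lower,upper Integration limits (default +/- 5 input SD).
#' @param n_grid Odd number of Simpson grid points.
#' @return Weighted mean absolute error in spikes per bin.
#' @export
nonlinearity_error <- function(true_p, est_p, weight_fn = dnorm,
                               lower = -5, upper = 5, n_grid = 4001) {
  stopifnot(inherits(true_p, "softplus_params"), inherits(est_p, "softplus_params"))
  if (n_grid %% 2L == 0L) n_grid <- n_grid + 1L
  x <- seq(lower, upper, length.out = n_grid)
  g <- abs(softplus_eval(true_p, x) - softplus_eval(est_p, x)) * weight_fn(x)
  h <- (upper - lower) / (n_grid - 1)
  w <- rep(c(2, 4), length.out = n_grid)
  w[c(1, n_grid)] <- 1
  sum(w * g) * h / 3
}
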