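# Synthetic recording generator for the preprocessing tests.
#
# Fast biphasic gamma-difference filter (RGC-like); the balanced lobes keep
# its support compact so the 2 x half-max binning rule decorrelates
# neighbouring bins.
true_filter_taps <- function(n_taps, dt) {
  tt <- (seq_len(n_taps) - 1) * dt
  k <- (tt / 0.025)^2 * exp(-tt / 0.025) - 0.8 * (tt / 0.04)^2 * exp(-tt / 0.04)
  k / sqrt(sum(k^2))
}

# white (or AR(1)) Gaussian stimulus -> known filter -> softplus -> Poisson
# spikes per frame
simulate_recording <- function(n_frames, dt, taps, seed, rho = 0) {
  set.seed(seed)
  s <- rnorm(n_frames)
  if (rho > 0) s <- as.numeric(stats::filter(s * sqrt(1 - rho^2), rho,
                                             method = "recursive"))
  g <- as.numeric(stats::filter(s, taps, method = "convolution", sides = 1))
  g[is.na(g)] <- 0
  rate <- softplus_eval(softplus_params(0.5, 2, -1, 0.02), g)
  list(stim = stimulus_trace(s, dt), counts = rpois(n_frames, rate))
}
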