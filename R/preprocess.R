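#' Stimulus trace
#'
#' Contrast value per stimulus frame, with the frame duration in seconds
#' (e.g. a Gaussian noise stimulus refreshed every 67 ms).
#'
#' @param values Numeric vector of contrast values per frame.
#' @param frame_dt Frame duration in seconds, > 0.
#' @return An object of class `stimulus_trace`.
#' @export
stimulus_trace <- function(values, frame_dt) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("stimulus values must be finite")
  if (!is.finite(frame_dt) || frame_dt <= 0) stop("frame_dt must be > 0")
  structure(list(values = values, frame_dt = as.numeric(frame_dt)),
            class = "stimulus_trace")
}

#' Linear temporal filter
#'
#' Weights over lags (lag 0 first), sampled at `dt` seconds. The width at
#' half-max, used to choose the response bin length, is measured on the
#' absolute filter around its global extremum, interpolating the half-max
#' crossings on each side; secondary lobes beyond the crossings are ignored.
#'
#' @param taps Numeric vector of filter weights over lag.
#' @param dt Sample interval in seconds.
#' @return An object of class `linear_filter`.
#' @export
linear_filter <- function(taps, dt) {
  taps <- as.numeric(taps)
  if (!all(is.finite(taps))) stop("filter taps must be finite")
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  structure(list(taps = taps, dt = as.numeric(dt)), class = "linear_filter")
}

#' @export
print.linear_filter <- function(x, ...) {
  cat(sprintf("linear filter: %d taps at %.4g s (half-max width %.4g s)\n",
              length(x$taps), x$dt, filter_half_max_width(x)))
  invisible(x)
}

#' @rdname linear_filter
#' @param f A `linear_filter`.
#' @return `filter_half_max_width`: the half-max width in seconds.
#' @export
filter_half_max_width <- function(f) {
  a <- abs(f$taps)
  i0 <- which.max(a)
  peak <- a[i0]
  if (peak <= 0) stop("degenerate (all-zero) filter has no half-max width")
  thr <- peak / 2
  # walk out from the extremum to the first crossing on each side
  cross <- function(idx_seq) {
    prev <- i0
    for (i in idx_seq) {
      if (a[i] <= thr) {
        # linear interpolation between prev (above) and i (below)
        frac <- (a[prev] - thr) / (a[prev] - a[i])
        return(prev + sign(i - prev) * frac)
      }
      prev <- i
    }
    idx_seq[length(idx_seq)]   # never crossed: clip at the boundary
  }
  left <- if (i0 > 1) cross((i0 - 1):1) else 1
  right <- if (i0 < length(a)) cross((i0 + 1):length(a)) else length(a)
  (right - left) * f$dt
}

#' Estimate a linear filter by reverse correlation
#'
#' Computes the spike-triggered average corrected for stimulus
#' autocorrelation: the whitened regression solution
#' `(X'X)^{-1} X'r` where `X` holds the stimulus at lags `0..n_lags-1`.
#' For white stimuli the correction reduces to a scalar; for temporally
#' correlated stimuli it removes the autocorrelation-induced bias of the
#' raw spike-triggered average. A near-singular lag covariance triggers a
#' ridge-regularized solve with a warning.
#'
#' @param stim A [stimulus_trace()].
#' @param spike_counts_per_frame Integer vector of spike counts per frame,
#'   same length as the stimulus.
#' @param n_lags Number of filter taps to estimate.
#' @return A [linear_filter()] at the stimulus frame rate.
#' @export
estimate_filter <- function(stim, spike_counts_per_frame, n_lags) {
  stopifnot(inherits(stim, "stimulus_trace"))
  s <- stim$values
  r <- as.numeric(spike_counts_per_frame)
  if (length(r) != length(s)) stop("stimulus and spike counts must align per frame")
  n <- length(s)
  if (n <= 10 * n_lags) stop("trace too short relative to n_lags")
  rows <- n_lags:n
  X <- sapply(0:(n_lags - 1), function(l) s[rows - l])
  y <- r[rows]
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  k <- tryCatch(solve(XtX, Xty), error = function(e) NULL)
  if (is.null(k) || rcond(XtX) < 1e-12) {
    warning("near-singular stimulus autocovariance; using ridge-regularized solve")
    ridge <- 1e-6 * mean(diag(XtX))
    k <- solve(XtX + diag(ridge, n_lags), Xty)
  }
  linear_filter(as.numeric(k), stim$frame_dt)
}

#' Low-pass smooth a linear filter
#'
#' Zero-phase low-pass smoothing of the filter taps with a Hamming-windowed
#' sinc kernel (default cutoff 13 Hz). The symmetric kernel is applied
#' centred (linear phase, zero delay) with zero padding, attenuating energy
#' above the cutoff by more than 20 dB while passing low frequencies nearly
#' unchanged.
#'
#' @param f A [linear_filter()].
#' @param cutoff_hz Cutoff frequency in Hz; must be below the Nyquist
#'   frequency `1 / (2 dt)`.
#' @return A smoothed [linear_filter()].
#' @export
smooth_filter <- function(f, cutoff_hz = 13) {
  fs <- 1 / f$dt
  if (cutoff_hz >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  if (cutoff_hz <= 0) stop("cutoff must be positive")
  fc <- cutoff_hz / fs                     # cycles per sample
  M <- ceiling(3.3 / (0.5 * fc))           # Hamming transition ~ half the cutoff
  mseq <- -M:M
  h <- 2 * fc * sinc(2 * fc * mseq) * (0.54 + 0.46 * cos(pi * mseq / M))
  h <- h / sum(h)
  padded <- c(numeric(M), f$taps, numeric(M))
  sm <- stats::filter(padded, h, method = "convolution", sides = 2)
  linear_filter(as.numeric(sm[(M + 1):(M + length(f$taps))]), f$dt)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Convert spike times to per-frame counts
#'
#' Frames are half-open intervals `[start, end)` in frame units; a spike
#' exactly on a boundary belongs to the later frame. Spikes outside the
#' recording are dropped with a warning.
#'
#' @param times Spike times in seconds.
#' @param n_frames Number of stimulus frames.
#' @param frame_dt Frame duration in seconds.
#' @return Integer vector of length `n_frames`.
#' @export
spike_times_to_counts <- function(times, n_frames, frame_dt) {
  stopifnot(frame_dt > 0, n_frames >= 1)
  idx <- floor(times / frame_dt) + 1L
  keep <- idx >= 1L & idx <= n_frames
  if (any(!keep))
    warning(sprintf("%d spike(s) outside the recording dropped", sum(!keep)))
  tabulate(idx[keep], nbins = n_frames)
}

#' Bin a recording into an input-response dataset
#'
#' Convolves the stimulus with the filter to obtain the generator signal,
#' partitions time into contiguous non-overlapping windows of length twice
#' the filter's half-max width (rounded down to whole frames), and stores
#' per window the mean filtered value and the summed spike count. This
#' window length keeps neighbouring filtered values nearly uncorrelated.
#' Filtered values are z-scored over the dataset. The first `n_lags - 1`
#' frames (incomplete filter support) and any incomplete trailing window are
#' dropped; their counts are reported in attributes `dropped_leading_frames`
#' and `dropped_trailing_frames`.
#'
#' @param f A [linear_filter()] (typically estimated then smoothed).
#' @param stim The [stimulus_trace()] used for the recording.
#' @param spike_counts_per_frame Integer vector of spike counts per frame.
#' @return A [binned_dataset()] with z-scored inputs; attributes record the
#'   window length in frames and the dropped frames.
#' @export
bin_dataset <- function(f, stim, spike_counts_per_frame) {
  stopifnot(inherits(f, "linear_filter"), inherits(stim, "stimulus_trace"))
  s <- stim$values
  r <- as.numeric(spike_counts_per_frame)
  if (length(r) != length(s)) stop("stimulus and spike counts must align per frame")
  wf <- floor(2 * filter_half_max_width(f) / stim$frame_dt)
  if (wf < 1) stop("binning window shorter than one frame")
  L <- length(f$taps)
  filt <- as.numeric(stats::filter(s, f$taps, method = "convolution", sides = 1))
  valid <- L:length(s)                      # frames with full filter support
  n_win <- floor(length(valid) / wf)
  if (n_win < 1) stop("recording too short for a single window")
  idx <- valid[seq_len(n_win * wf)]
  win <- rep(seq_len(n_win), each = wf)
  x <- as.numeric(tapply(filt[idx], win, mean))
  counts <- as.integer(tapply(r[idx], win, sum))
  x_mean <- mean(x); x_sd <- sd(x)
  if (x_sd <= 0) stop("filtered stimulus has zero variance; cannot z-score")
  d <- binned_dataset((x - x_mean) / x_sd, counts,
                      bin_width = wf * stim$frame_dt)
  attr(d, "window_frames") <- wf
  attr(d, "dropped_leading_frames") <- L - 1L
  attr(d, "dropped_trailing_frames") <- length(s) - (L - 1L) - n_win * wf
  attr(d, "x_center") <- c(mean = x_mean, sd = x_sd)
  d
}
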