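#' One-dimensional density grid
#'
#' Evaluable representation of the intermediate densities of the cascade:
#' the nonlinearity-output density `P_Lambda`, the post-multiplicative
#' density `P_Y` and the pre-quantization density `P_Z`. Holds strictly
#' increasing abscissae and nonnegative density values; for proper
#' (non-degenerate) stages the trapezoidal integral over the grid is 1 to
#' within a small tolerance. Degenerate stages (zero noise so far) are
#' represented as a point-mass descriptor.
#'
#' @param points Strictly increasing numeric abscissae.
#' @param values Nonnegative density values at `points`.
#' @param lo,hi Effective support bounds.
#' @return An object of class `density_grid`.
#' @export
density_grid <- function(points, values, lo = min(points), hi = max(points)) {
  if (any(diff(points) <= 0)) stop("density grid points must be strictly increasing")
  if (any(values < 0)) stop("density values must be >= 0")
  structure(list(points = points, values = values, lo = lo, hi = hi,
                 point_mass = NA_real_),
            class = "density_grid")
}

point_mass_grid <- function(at) {
  structure(list(points = at, values = Inf, lo = at, hi = at,
                 point_mass = at),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  if (is_point_mass(x)) {
    cat(sprintf("density grid: point mass at %.6g\n", x$point_mass))
  } else {
    cat(sprintf("density grid: %d points on [%.4g, %.4g], trapezoid mass %.8f\n",
                length(x$points), x$lo, x$hi, grid_mass(x)))
  }
  invisible(x)
}

#' @rdname density_grid
#' @param g A `density_grid`.
#' @export
is_point_mass <- function(g) !is.na(g$point_mass)

#' Trapezoidal integral of a density grid
#' @param g A [density_grid()].
#' @return The trapezoidal integral of `values` over `points` (1 for a
#'   point mass).
#' @export
grid_mass <- function(g) {
  if (is_point_mass(g)) return(1)
  sum(diff(g$points) * (head(g$values, -1) + g$values[-1]) / 2)
}

# mean of a density grid (used in tests / diagnostics)
grid_mean <- function(g) {
  if (is_point_mass(g)) return(g$point_mass)
  f <- g$points * g$values
  sum(diff(g$points) * (head(f, -1) + f[-1]) / 2)
}

# uniform grid over the upstream noise variable; +/- 6.5 SD leaves ~8e-11
# of mass outside, and uniform spacing keeps the trapezoid rule second-order
# (quantile spacing would put O(1/n) errors in the wide tail steps)
upstream_u_grid <- function(sigma_up, n, width = 6.5) {
  seq(-width, width, length.out = n) * sigma_up
}

#' Density of the nonlinearity output
#'
#' Change-of-variables density of `lambda = f(x + n_up)` with
#' `n_up ~ N(0, sigma_up^2)`:
#' \deqn{P_\Lambda(\lambda) = P_{up}(f^{-1}(\lambda) - x)\,
#'       \frac{df^{-1}(\lambda)}{d\lambda},}
#' supported on `(beta4, Inf)`. The density spreads out where the
#' nonlinearity is steep and compresses (piling up near `beta4`) where it is
#' flat. With `sigma_up = 0` the output is a point mass at `f(x)`.
#'
#' @param m A [multistage_model()].
#' @param x Scalar input (effective, i.e. including any history term).
#' @param n_grid Number of grid points.
#' @return A [density_grid()] over `lambda`.
#' @export
p_lambda <- function(m, x, n_grid = 4001) {
  p <- m$nonlinearity; np <- m$noise
  if (np$sigma_up <= 0) return(point_mass_grid(softplus_eval(p, x)))
  u <- upstream_u_grid(np$sigma_up, n_grid)
  lam <- softplus_eval(p, x + u)
  dens <- dnorm(u, 0, np$sigma_up) / softplus_derivatives(p, x + u)$first
  keep <- is.finite(dens) & diff(c(-Inf, lam)) > 0   # guard flat tails
  density_grid(lam[keep], dens[keep])
}

# P_Y / P_Z values at a vector of ordinates z, by trapezoid over the
# upstream variable; sd_fun(lambda) gives the conditional Gaussian SD.
mix_density_values <- function(m, x, z, sd_fun, n_u = 4001) {
  np <- m$noise
  if (np$sigma_up <= 0) {
    lam <- softplus_eval(m$nonlinearity, x)
    s <- sd_fun(lam)
    if (s <= 0) stop("degenerate stage has no density; use the point-mass path")
    return(dnorm(z, lam, s))
  }
  u <- upstream_u_grid(np$sigma_up, n_u)
  w <- dnorm(u, 0, np$sigma_up)
  lam <- softplus_eval(m$nonlinearity, x + u)
  s <- sd_fun(lam)
  du <- diff(u)
  vapply(z, function(zi) {
    f <- w * dnorm(zi, lam, s)
    sum(du * (head(f, -1) + f[-1]) / 2)
  }, numeric(1))
}

# shared grid construction for p_y / p_z
stage_grid <- function(m, x, sd_fun, n_grid, n_u) {
  p <- m$nonlinearity; np <- m$noise
  if (np$sigma_up > 0) {
    u_ex <- c(-8, 8) * np$sigma_up
    lam_rng <- softplus_eval(p, x + u_ex)
  } else lam_rng <- rep(softplus_eval(p, x), 2)
  s_max <- max(sd_fun(lam_rng), sd_fun(p$beta4))
  lo <- lam_rng[1] - 8 * s_max
  hi <- lam_rng[2] + 8 * s_max
  z <- seq(lo, hi, length.out = n_grid)
  vals <- mix_density_values(m, x, z, sd_fun, n_u = n_u)
  density_grid(z, vals, lo, hi)
}

#' Density after the multiplicative noise stage
#'
#' \deqn{P_Y(y) = \int P_\Lambda(\lambda)\,
#'   N(y;\, \lambda,\, \sigma_{mult}^2 \lambda)\, d\lambda,}
#' a smoothing of `P_Lambda` similar to a convolution except that the kernel
#' SD grows with `lambda`, spreading the density more at larger outputs.
#' With `sigma_mult = 0` this is `p_lambda()` unchanged.
#'
#' @inheritParams p_lambda
#' @param n_u Number of quadrature points over the upstream variable.
#' @return A [density_grid()] over `y`.
#' @export
p_y <- function(m, x, n_grid = 2001, n_u = 4001) {
  np <- m$noise
  if (np$sigma_mult <= 0) return(p_lambda(m, x, n_grid = max(n_grid, n_u)))
  if (np$sigma_up <= 0) {
    lam <- softplus_eval(m$nonlinearity, x)
    if (lam <= 1e-12) return(point_mass_grid(lam))   # vanishing conditional variance
  }
  sd_fun <- function(lam) np$sigma_mult * sqrt(pmax(lam, 0))
  stage_grid(m, x, sd_fun, n_grid, n_u)
}

#' Density before spike quantization
#'
#' Adds the downstream stage to [p_y()]. In the `"gaussian"` variant this is
#' the convolution of `P_Y` with `N(0, sigma_down^2)`; in the `"mixture"`
#' variant it is the blend
#' `p_down (P_Y * N(0, sigma_down^2)) + (1 - p_down) P_Y`, reflecting the
#' intermittent downstream source. With `sigma_down = 0` or `p_down = 0`
#' this is `p_y()` unchanged.
#'
#' @inheritParams p_y
#' @return A [density_grid()] over `z`.
#' @export
p_z <- function(m, x, n_grid = 2001, n_u = 4001) {
  np <- m$noise
  if (np$sigma_down <= 0 || np$p_down <= 0) return(p_y(m, x, n_grid, n_u))
  sd_on <- function(lam) sqrt(np$sigma_mult^2 * pmax(lam, 0) + np$sigma_down^2)
  g_on <- stage_grid(m, x, sd_on, n_grid, n_u)
  if (np$p_down >= 1) return(g_on)
  g_off <- p_y(m, x, n_grid, n_u)
  if (is_point_mass(g_off)) {
    # blend of a density and a point mass: keep the absolutely continuous
    # part on the grid and record the atom weight
    g <- density_grid(g_on$points, np$p_down * g_on$values, g_on$lo, g_on$hi)
    attr(g, "atom") <- c(at = g_off$point_mass, weight = 1 - np$p_down)
    return(g)
  }
  vals_off <- approx(g_off$points, g_off$values, xout = g_on$points,
                     yleft = 0, yright = 0)$y
  density_grid(g_on$points, np$p_down * g_on$values + (1 - np$p_down) * vals_off,
               g_on$lo, g_on$hi)
}

#' Spike-count probability mass function
#'
#' Integrates the pre-quantization density over count windows:
#' `P(r = 0)` is the mass below 0.5 and `P(r = k)` the mass in
#' `(k - 0.5, k + 0.5)` for `k >= 1`. `r_max` is extended automatically
#' until the tail mass beyond it falls below `tol_tail`.
#'
#' @param m A [multistage_model()].
#' @param x Scalar effective input.
#' @param r_max Initial truncation count; extended as needed (`NULL` to
#'   choose from the model's output scale).
#' @param tol_tail Maximum acceptable tail mass beyond `r_max`.
#' @param eps Absolute quadrature tolerance per count probability.
#' @return An object of class `count_pmf`: list with `probs` (counts
#'   `0..r_max`), `r_max` and `tail_mass`.
#' @export
response_pmf <- function(m, x, r_max = NULL, tol_tail = 1e-8, eps = 1e-9) {
  stopifnot(inherits(m, "multistage_model"), length(x) == 1L, is.finite(x))
  p <- m$nonlinearity; np <- m$noise
  lam_hi <- softplus_eval(p, x + 8 * np$sigma_up)
  sd_tot <- sqrt(np$sigma_mult^2 * lam_hi + np$sigma_down^2)
  if (is.null(r_max))
    r_max <- max(8, ceiling(lam_hi + 10 * sd_tot))
  par <- model_par_vec(m)
  repeat {
    probs <- cpp_count_pmf(x, as.integer(r_max), par, eps)
    tail_mass <- max(0, 1 - sum(probs))
    if (tail_mass <= tol_tail || r_max > 1e6) break
    r_max <- r_max * 2L
  }
  total <- sum(probs) + tail_mass
  if (abs(total - 1) > 1e-6)
    stop(sprintf("count pmf mass %.8f deviates from 1: upstream density stage inconsistent", total))
  structure(list(probs = probs, r_max = as.integer(r_max), tail_mass = tail_mass),
            class = "count_pmf")
}

#' @export
print.count_pmf <- function(x, ...) {
  k <- seq_along(x$probs) - 1L
  cat(sprintf("count pmf on 0..%d (tail mass %.2g): mean %.4g, sd %.4g\n",
              x$r_max, x$tail_mass, sum(k * x$probs),
              sqrt(max(0, sum(k^2 * x$probs) - sum(k * x$probs)^2))))
  invisible(x)
}

# effective nonlinearity inputs, including the response-history term
effective_inputs <- function(m, d, prev_count = 0L) {
  if (is.null(m$history_weight)) return(d$inputs)
  d$inputs + m$history_weight * c(prev_count, head(d$counts, -1))
}

#' Dataset log-likelihood under the multistage model
#'
#' Sum over bins of `log P(r_t | x_t)`, treating bins as independent. With
#' a response-history weight `w`, the nonlinearity input of bin `t` is
#' `x_t + w r_{t-1}` using the observed previous count (`r_0 = 0`). Bins
#' whose probability falls below 1e-300 contribute the floored logarithm;
#' their number is reported via the `"n_floored"` attribute (with a warning)
#' rather than producing `-Inf`.
#'
#' @param m A [multistage_model()].
#' @param d A [binned_dataset()].
#' @param eps Absolute quadrature tolerance per bin probability.
#' @return Scalar log-likelihood with attribute `n_floored`.
#' @export
log_likelihood <- function(m, d, eps = 1e-8) {
  stopifnot(inherits(m, "multistage_model"), inherits(d, "binned_dataset"))
  x <- effective_inputs(m, d)
  lp <- cpp_count_logprob(x, d$counts, model_par_vec(m), eps)
  n_floored <- sum(lp <= log(1e-300) + 1)
  if (n_floored > 0)
    warning(sprintf("%d bin(s) hit the 1e-300 probability floor", n_floored))
  structure(sum(lp), n_floored = n_floored)
}

#' Dataset log-likelihood under the LNP baseline
#'
#' Linear-nonlinear-Poisson model: counts are Poisson with rate `f(x_t)`,
#' giving `sum(r_t log f(x_t) - f(x_t) - log r_t!)`. Rates must be positive;
#' a nonpositive rate rejects the parameters with a large negative surrogate
#' value rather than `NaN`, so derivative-free optimizers can recover.
#'
#' @param p A [softplus_params()] object.
#' @param d A [binned_dataset()].
#' @return Scalar log-likelihood.
#' @export
log_likelihood_lnp <- function(p, d) {
  stopifnot(inherits(p, "softplus_params"), inherits(d, "binned_dataset"))
  rate <- softplus_eval(p, d$inputs)
  if (any(rate <= 0)) return(-1e12)
  sum(dpois(d$counts, rate, log = TRUE))
}
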