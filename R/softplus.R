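#' Softplus nonlinearity parameters
#'
#' The static nonlinearity of the cascade is a four-parameter softplus,
#' \deqn{f(x) = \beta_1 \log(1 + e^{\beta_2 x + \beta_3}) + \beta_4,}
#' which spans shapes from sharply rectified to effectively linear without
#' saturating. `beta1` sets the output scale (spikes per bin), `beta2` the
#' input gain (per z-scored input unit), `beta3` the input offset and
#' `beta4` the output offset (spikes per bin). `beta1` and `beta2` must be
#' positive so that `f` is strictly increasing and invertible; `beta4` must
#' be nonnegative so the nonlinearity output (a mean spike count) is never
#' negative.
#'
#' @param beta1,beta2,beta3,beta4 Numeric scalars; see Details.
#' @return An object of class `softplus_params`.
#' @examples
#' p <- softplus_params(1, 2, 0, 0.1)
#' softplus_eval(p, c(-1, 0, 1))
#' @export
softplus_params <- function(beta1, beta2, beta3, beta4 = 0) {
  p <- list(beta1 = as.numeric(beta1), beta2 = as.numeric(beta2),
            beta3 = as.numeric(beta3), beta4 = as.numeric(beta4))
  validate_softplus_params(p)
  structure(p, class = "softplus_params")
}

validate_softplus_params <- function(p) {
  v <- unlist(p[c("beta1", "beta2", "beta3", "beta4")])
  if (length(v) != 4L || !all(is.finite(v)))
    stop("softplus parameters must be four finite numbers", call. = FALSE)
  if (p$beta1 <= 0 || p$beta2 <= 0)
    stop("beta1 and beta2 must be > 0 (monotone increasing nonlinearity)",
         call. = FALSE)
  if (p$beta4 < 0)
    stop("beta4 must be >= 0 (nonnegative output offset)", call. = FALSE)
  invisible(p)
}

#' @export
print.softplus_params <- function(x, ...) {
  cat(sprintf(
    "softplus nonlinearity: f(x) = %.4g * log(1 + exp(%.4g x + %.4g)) + %.4g\n",
    x$beta1, x$beta2, x$beta3, x$beta4))
  invisible(x)
}

# log(1 + exp(eta)), overflow-safe
log1pexp <- function(eta) {
  out <- numeric(length(eta))
  pos <- eta > 0
  out[pos] <- eta[pos] + log1p(exp(-eta[pos]))
  out[!pos] <- log1p(exp(eta[!pos]))
  out
}

#' Evaluate the softplus nonlinearity
#'
#' @param p A [softplus_params()] object.
#' @param x Numeric vector of (z-scored) inputs.
#' @return `f(x)`, numeric vector of mean spike counts per bin.
#' @export
softplus_eval <- function(p, x) {
  if (!all(is.finite(x))) stop("inputs to softplus_eval must be finite")
  p$beta1 * log1pexp(p$beta2 * x + p$beta3) + p$beta4
}

#' Invert the softplus nonlinearity
#'
#' Returns the input `x` with `softplus_eval(p, x) == lam`. The softplus
#' range is the open interval `(beta4, Inf)`, so `lam` must exceed `beta4`;
#' density evaluation at or below `beta4` is the caller's responsibility
#' (the output density is zero there).
#'
#' @param p A [softplus_params()] object.
#' @param lam Numeric vector of nonlinearity outputs, all `> beta4`.
#' @return Numeric vector of inputs.
#' @export
softplus_inverse <- function(p, lam) {
  if (any(lam <= p$beta4))
    stop("softplus_inverse requires lam > beta4 (softplus range is (beta4, Inf))")
  v <- (lam - p$beta4) / p$beta1
  # log(expm1(v)): for large v, expm1 overflows; use v + log1p(-exp(-v))
  t <- ifelse(v > 30, v + log1p(-exp(-v)), log(expm1(v)))
  (t - p$beta3) / p$beta2
}

#' First and second derivatives of the softplus nonlinearity
#'
#' With \eqn{u = \beta_2 x + \beta_3} and \eqn{\sigma} the logistic
#' function, \eqn{f'(x) = \beta_1\beta_2\,\sigma(u)} and
#' \eqn{f''(x) = \beta_1\beta_2^2\,\sigma(u)(1-\sigma(u))}; both are
#' nonnegative everywhere (the softplus is increasing and convex).
#'
#' @inheritParams softplus_eval
#' @return A list with numeric vectors `first` and `second`.
#' @export
softplus_derivatives <- function(p, x) {
  if (!all(is.finite(x))) stop("inputs to softplus_derivatives must be finite")
  s <- stats::plogis(p$beta2 * x + p$beta3)
  list(first = p$beta1 * p$beta2 * s,
       second = p$beta1 * p$beta2^2 * s * (1 - s))
}

#' Maximum curvature of the softplus nonlinearity
#'
#' Rectification sharpness is quantified as the maximum of the second
#' derivative of the nonlinearity. For the softplus this is attained at
#' \eqn{\beta_2 x + \beta_3 = 0} where the logistic factor equals 1/4, giving
#' the closed form \eqn{\beta_1 \beta_2^2 / 4}. If `search_range` is supplied
#' and excludes that point, the maximum over the range (at an endpoint, by
#' monotonicity of \eqn{\sigma(1-\sigma)} away from its peak) is returned.
#'
#' @param p A [softplus_params()] object.
#' @param search_range Optional numeric length-2 interval of inputs.
#' @return Maximum of `f''` (spikes per bin per squared input unit).
#' @export
curvature_max <- function(p, search_range = NULL) {
  x_star <- -p$beta3 / p$beta2
  if (is.null(search_range) ||
      (x_star >= min(search_range) && x_star <= max(search_range)))
    return(p$beta1 * p$beta2^2 / 4)
  max(softplus_derivatives(p, range(search_range))$second)
}
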