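#' Configuration for maximum-likelihood fitting
#'
#' Controls the multi-start bounded Nelder-Mead optimization. Bounds are
#' enforced by parameter transforms (log for `beta1`, `beta2`, `beta4` and
#' the noise SDs; logit for `p_down`) so the simplex always stays inside the
#' feasible region; only impossible regions (negative SDs, probabilities
#' outside `[0, 1]`, non-monotone nonlinearities) are excluded.
#'
#' @param n_starts Number of randomized initial conditions (default 8).
#' @param seed Integer seed controlling start generation.
#' @param perturb_frac Multiplicative perturbation (+/- fraction) applied to
#'   the least-squares nonlinearity estimate to form starts (default 0.40).
#' @param max_evals Cap on function evaluations per start.
#' @param reltol Relative function-value convergence tolerance.
#' @param lik_eps Absolute quadrature tolerance per bin probability.
#' @param snr_n_stimuli,snr_n_reps Monte-Carlo sizes for the SNR-anchored
#'   noise start scales (see [noise_level_for_snr()]).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_starts = 8L, seed = 1L, perturb_frac = 0.40,
                       max_evals = 2000L, reltol = 1e-5, lik_eps = 1e-6,
                       snr_n_stimuli = 500L, snr_n_reps = 100L) {
  stopifnot(n_starts >= 1, perturb_frac >= 0, perturb_frac < 1,
            max_evals >= 1, reltol > 0)
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 perturb_frac = perturb_frac, max_evals = as.integer(max_evals),
                 reltol = reltol, lik_eps = lik_eps,
                 snr_n_stimuli = as.integer(snr_n_stimuli),
                 snr_n_reps = as.integer(snr_n_reps)),
            class = "fit_config")
}

# ---- parameter transforms (feasible-region bounds) -----------------------

clog <- function(v) log(pmax(v, 1e-8))
cexp <- function(t) exp(pmin(t, 50))

pack_ms <- function(m, variant) {
  p <- m$nonlinearity; np <- m$noise
  th <- c(clog(p$beta1), clog(p$beta2), p$beta3, clog(p$beta4),
          clog(np$sigma_up), clog(np$sigma_mult), clog(np$sigma_down))
  if (variant == "mixture")
    th <- c(th, qlogis(min(max(np$p_down, 1e-6), 1 - 1e-6)))
  th
}

unpack_ms <- function(th, variant) {
  p_down <- if (variant == "mixture") plogis(th[8]) else 1
  multistage_model(
    softplus_params(cexp(th[1]), cexp(th[2]), th[3], cexp(th[4])),
    noise_params(cexp(th[5]), cexp(th[6]), cexp(th[7]),
                 p_down = p_down, variant = variant))
}

pack_lnp <- function(p)
  c(clog(p$beta1), clog(p$beta2), p$beta3, clog(p$beta4))

unpack_lnp <- function(th)
  softplus_params(cexp(th[1]), cexp(th[2]), th[3], max(cexp(th[4]), 1e-9))

# ---- least-squares nonlinearity initializer ------------------------------

#' Least-squares softplus initializer
#'
#' Initial nonlinearity estimate for the optimization: inputs are grouped
#' into ~`n_bins` equal-count quantile bins, and the softplus is fit by
#' least squares to the per-bin mean counts (a coarse-grid search over gain
#' and offset with linear solves for scale and output offset, polished by
#' Nelder-Mead on all four parameters).
#'
#' @param d A [binned_dataset()] with at least 20 bins spanning more than
#'   one input SD.
#' @param n_bins Number of quantile bins (default 20).
#' @return A [softplus_params()] object.
#' @export
init_nonlinearity_ls <- function(d, n_bins = 20L) {
  stopifnot(inherits(d, "binned_dataset"))
  if (length(d) < 20L)
    stop("least-squares initializer needs at least 20 bins")
  if (diff(range(d$inputs)) <= sd(d$inputs))
    warning("inputs span less than one SD; initializer may be poorly constrained")
  if (length(unique(d$counts)) == 1L) {
    warning("all counts equal; returning a flat-softplus fallback")
    return(softplus_params(1e-2, 1, 0, max(mean(d$counts), 0)))
  }
  ord <- order(d$inputs)
  grp <- cut(seq_along(ord), breaks = min(n_bins, length(ord)), labels = FALSE)
  mx <- as.numeric(tapply(d$inputs[ord], grp, mean))
  mc <- as.numeric(tapply(d$counts[ord], grp, mean))
  # coarse grid over (gain, input offset); scale and output offset by lm
  best <- NULL; best_sse <- Inf
  for (b2 in c(0.25, 0.5, 1, 2, 4, 8)) {
    for (b3 in -3:3) {
      g <- log1pexp(b2 * mx + b3)
      fit <- lm(mc ~ g)
      b1 <- coef(fit)[[2]]; b4 <- coef(fit)[[1]]
      if (!is.finite(b1) || b1 <= 0) next
      b4 <- max(b4, 0)
      sse <- sum((mc - (b1 * g + b4))^2)
      if (sse < best_sse) { best_sse <- sse; best <- c(b1, b2, b3, b4) }
    }
  }
  if (is.null(best)) best <- c(max(mean(mc), 0.1), 1, 0, 0)
  sse_fn <- function(th) {
    p <- unpack_lnp(th)
    sum((mc - softplus_eval(p, mx))^2)
  }
  th0 <- c(clog(best[1]), clog(best[2]), best[3], clog(max(best[4], 1e-4)))
  opt <- optim(th0, sse_fn, method = "Nelder-Mead",
               control = list(maxit = 800, reltol = 1e-10))
  unpack_lnp(opt$par)
}

# ---- randomized starts ---------------------------------------------------

#' Randomized initial conditions for the multi-start optimization
#'
#' Nonlinearity parameters of each start are the least-squares estimate,
#' each parameter independently perturbed by a multiplicative
#' `Uniform(1 - perturb_frac, 1 + perturb_frac)` factor. Noise levels are
#' drawn `Uniform(0, scale)` where `scale` is the level at which that source
#' alone yields SNR 0.5 under the least-squares nonlinearity
#' ([noise_level_for_snr()]); `p_down` (mixture variant) is drawn
#' `Uniform(0.05, 1)`. Start lists are reproducible under `cfg$seed`.
#'
#' @param d A [binned_dataset()].
#' @param cfg A [fit_config()].
#' @param variant `"gaussian"` or `"mixture"`.
#' @return List of [multistage_model()] start points, with the SNR-anchored
#'   scales in attribute `"noise_scales"`.
#' @export
random_starts <- function(d, cfg = fit_config(), variant = c("gaussian", "mixture")) {
  variant <- match.arg(variant)
  ls <- init_nonlinearity_ls(d)
  base <- multistage_model(ls, noise_params(0, 0, 0))
  scales <- vapply(c("up", "mult", "down"), function(s)
    noise_level_for_snr(base, s, target = 0.5, seed = cfg$seed,
                        n_stimuli = cfg$snr_n_stimuli,
                        n_reps = cfg$snr_n_reps),
    numeric(1))
  set.seed(cfg$seed)
  starts <- lapply(seq_len(cfg$n_starts), function(j) {
    fac <- runif(4, 1 - cfg$perturb_frac, 1 + cfg$perturb_frac)
    p <- softplus_params(ls$beta1 * fac[1], ls$beta2 * fac[2],
                         ls$beta3 * fac[3], max(ls$beta4 * fac[4], 0))
    lev <- runif(3, 0, scales)
    pd <- if (variant == "mixture") runif(1, 0.05, 1) else 1
    multistage_model(p, noise_params(lev[1], lev[2], lev[3],
                                     p_down = pd, variant = variant))
  })
  attr(starts, "noise_scales") <- scales
  attr(starts, "ls_init") <- ls
  starts
}

# ---- fitting -------------------------------------------------------------

# Nelder-Mead with simplex restarts: rebuilding the simplex at the current
# optimum escapes the collapsed-simplex stalls NM is prone to in 7-8
# dimensions; we restart until the improvement falls below 0.05 log-units.
nm_with_restarts <- function(th0, objective, cfg, max_rounds = 3L) {
  total_evals <- 0L
  opt <- optim(th0, objective, method = "Nelder-Mead",
               control = list(maxit = cfg$max_evals, reltol = cfg$reltol))
  total_evals <- total_evals + opt$counts[1]
  for (round in seq_len(max_rounds - 1L)) {
    re <- optim(opt$par, objective, method = "Nelder-Mead",
                control = list(maxit = cfg$max_evals, reltol = cfg$reltol))
    total_evals <- total_evals + re$counts[1]
    improved <- opt$value - re$value
    if (re$value < opt$value) opt <- re
    if (improved < 0.05) break
  }
  opt$counts[1] <- total_evals
  opt
}

run_starts <- function(starts, pack, unpack, objective, cfg) {
  per_start <- vector("list", length(starts))
  for (j in seq_along(starts)) {
    th0 <- pack(starts[[j]])
    opt <- tryCatch(nm_with_restarts(th0, objective, cfg),
                    error = function(e) e)
    if (inherits(opt, "error")) {
      per_start[[j]] <- list(init = starts[[j]], params = NULL,
                             loglik = -Inf, converged = FALSE,
                             n_evals = NA_integer_, error = conditionMessage(opt))
    } else {
      per_start[[j]] <- list(init = starts[[j]], params = unpack(opt$par),
                             loglik = -opt$value,
                             converged = opt$convergence == 0L,
                             n_evals = unname(opt$counts[1]), error = NULL)
    }
  }
  per_start
}

start_table <- function(per_start) {
  data.frame(start = seq_along(per_start),
             loglik = vapply(per_start, `[[`, numeric(1), "loglik"),
             converged = vapply(per_start, `[[`, logical(1), "converged"),
             n_evals = vapply(per_start, function(s)
               as.integer(s$n_evals %||% NA_integer_), integer(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

finalize_fit <- function(per_start, type, variant, cfg, d) {
  ok <- which(is.finite(vapply(per_start, `[[`, numeric(1), "loglik")))
  if (length(ok) == 0L)
    stop("all optimization starts failed; diagnostics: ",
         paste(vapply(per_start, function(s) s$error %||% "divergent", ""),
               collapse = "; "))
  lls <- vapply(per_start, `[[`, numeric(1), "loglik")
  best <- which.max(lls)
  if (!per_start[[best]]$converged)
    warning("best start did not satisfy the convergence criterion; result flagged")
  structure(list(model = per_start[[best]]$params,
                 loglik = lls[best],
                 type = type, variant = variant,
                 best_start = best,
                 converged = per_start[[best]]$converged,
                 per_start = start_table(per_start),
                 starts = per_start,
                 config = cfg, n_bins = length(d), seed = cfg$seed),
            class = "multinoise_fit")
}

#' Multi-start maximum-likelihood fit of the multistage model
#'
#' Maximizes [log_likelihood()] by Nelder-Mead from each randomized start
#' ([random_starts()]), in transformed coordinates that keep the search
#' inside the feasible region; the solution with the highest likelihood is
#' reported, along with per-start diagnostics. The `"gaussian"` variant
#' fixes `p_down = 1`; the `"mixture"` variant fits it.
#'
#' @param d A [binned_dataset()]; at least 200 bins recommended.
#' @param variant `"gaussian"` or `"mixture"`.
#' @param cfg A [fit_config()].
#' @return An object of class `multinoise_fit` with elements `model` (the
#'   maximum-likelihood [multistage_model()]), `loglik`, `per_start`,
#'   `starts`, `config`.
#' @export
fit_mle <- function(d, variant = c("gaussian", "mixture"), cfg = fit_config()) {
  variant <- match.arg(variant)
  stopifnot(inherits(d, "binned_dataset"))
  starts <- random_starts(d, cfg, variant)
  objective <- function(th) {
    m <- unpack_ms(th, variant)
    -as.numeric(suppressWarnings(log_likelihood(m, d, eps = cfg$lik_eps)))
  }
  per_start <- run_starts(starts, function(m) pack_ms(m, variant),
                          function(th) unpack_ms(th, variant), objective, cfg)
  finalize_fit(per_start, "multistage", variant, cfg, d)
}

#' Multi-start maximum-likelihood fit of the LNP baseline
#'
#' Same multi-start Nelder-Mead procedure as [fit_mle()], applied to the
#' linear-nonlinear-Poisson likelihood [log_likelihood_lnp()] over the four
#' softplus parameters, for a fair comparison with the multistage model.
#'
#' @inheritParams fit_mle
#' @return A `multinoise_fit` whose `model` is a [softplus_params()].
#' @export
fit_lnp <- function(d, cfg = fit_config()) {
  stopifnot(inherits(d, "binned_dataset"))
  ls <- init_nonlinearity_ls(d)
  set.seed(cfg$seed)
  starts <- lapply(seq_len(cfg$n_starts), function(j) {
    fac <- runif(4, 1 - cfg$perturb_frac, 1 + cfg$perturb_frac)
    softplus_params(ls$beta1 * fac[1], ls$beta2 * fac[2],
                    ls$beta3 * fac[3], max(ls$beta4 * fac[4], 1e-6))
  })
  objective <- function(th) -log_likelihood_lnp(unpack_lnp(th), d)
  per_start <- run_starts(starts, pack_lnp, unpack_lnp, objective, cfg)
  finalize_fit(per_start, "lnp", "poisson", cfg, d)
}

#' @export
print.multinoise_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s): log-likelihood %.4f over %d bins, best of %d starts%s\n",
              if (x$type == "lnp") "LNP" else "Multistage noise model",
              x$variant, x$loglik, x$n_bins, nrow(x$per_start),
              if (x$converged) "" else " [not converged]"))
  print(x$model)
  invisible(x)
}

#' Write a fit result to JSON
#'
#' Serializes the fitted parameters, log-likelihood and per-start
#' diagnostics (initial and final parameters, log-likelihoods, convergence
#' flags, evaluation counts) together with the configuration echo and seed.
#'
#' @param fit A `multinoise_fit`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  par_list <- function(m) {
    if (is.null(m)) return(NULL)
    if (inherits(m, "softplus_params")) return(unclass(m))
    c(unclass(m$nonlinearity), unclass(m$noise))
  }
  x <- list(type = fit$type, variant = fit$variant,
            loglik = fit$loglik, n_bins = fit$n_bins,
            best_start = fit$best_start, converged = fit$converged,
            params = par_list(fit$model),
            per_start = lapply(fit$starts, function(s)
              list(init = par_list(s$init), final = par_list(s$params),
                   loglik = s$loglik, converged = s$converged,
                   n_evals = s$n_evals)),
            config = unclass(fit$config), seed = fit$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
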