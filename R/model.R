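#' Noise parameters of the multistage cascade
#'
#' Three noise sources enter the cascade at different stages:
#' \describe{
#'   \item{upstream}{additive Gaussian `N(0, sigma_up^2)` added to the
#'     (z-scored) input before the nonlinearity; its effect on the response
#'     is shaped by the local slope of the nonlinearity.}
#'   \item{multiplicative}{at the nonlinearity output: given a nonlinearity
#'     output `lambda`, the post-multiplicative value is Gaussian with mean
#'     `lambda` and variance `sigma_mult^2 * lambda`, i.e. output variance
#'     scales with the mean by the constant factor `sigma_mult^2`
#'     (Poisson-like, but with free scale).}
#'   \item{downstream}{additive noise after the nonlinearity. In the
#'     `"gaussian"` variant it is `N(0, sigma_down^2)`; in the `"mixture"`
#'     variant it is `N(0, sigma_down^2)` with probability `p_down` and
#'     exactly 0 otherwise, modelling an intermittent noise source.}
#' }
#'
#' @param sigma_up SD of upstream additive noise (z-scored input units), >= 0.
#' @param sigma_mult Multiplicative noise scale (dimensionless), >= 0.
#' @param sigma_down SD of downstream additive noise (spikes per bin), >= 0.
#' @param p_down Probability the downstream noise is present, in `[0, 1]`.
#'   Must be 1 for the `"gaussian"` variant.
#' @param variant `"gaussian"` or `"mixture"`.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(sigma_up, sigma_mult, sigma_down,
                         p_down = 1, variant = c("gaussian", "mixture")) {
  variant <- match.arg(variant)
  np <- list(sigma_up = as.numeric(sigma_up), sigma_mult = as.numeric(sigma_mult),
             sigma_down = as.numeric(sigma_down), p_down = as.numeric(p_down),
             variant = variant)
  validate_noise_params(np)
  structure(np, class = "noise_params")
}

validate_noise_params <- function(np) {
  v <- unlist(np[c("sigma_up", "sigma_mult", "sigma_down", "p_down")])
  if (!all(is.finite(v))) stop("noise parameters must be finite", call. = FALSE)
  if (np$sigma_up < 0 || np$sigma_mult < 0 || np$sigma_down < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  if (np$p_down < 0 || np$p_down > 1)
    stop("p_down must lie in [0, 1]", call. = FALSE)
  if (np$variant == "gaussian" && np$p_down != 1)
    stop("gaussian variant requires p_down == 1", call. = FALSE)
  invisible(np)
}

#' @export
print.noise_params <- function(x, ...) {
  cat(sprintf("noise (%s variant): sigma_up = %.4g, sigma_mult = %.4g, sigma_down = %.4g",
              x$variant, x$sigma_up, x$sigma_mult, x$sigma_down))
  if (x$variant == "mixture") cat(sprintf(", p_down = %.4g", x$p_down))
  cat("\n")
  invisible(x)
}

#' Multistage noise model
#'
#' Combines a softplus nonlinearity with the three-source noise description
#' into the full generative model for binned spike counts:
#' `r_t = R[ y_t + n_down,t ]` where `y_t` is the noisy multiplicative-stage
#' output of `f(x_t + n_up,t)` and `R` rounds to the nearest nonnegative
#' integer. An optional `history_weight` `w` adds the weighted spike count of
#' the previous bin to the nonlinearity input, `f(x_t + w r_{t-1} + n_up,t)`.
#'
#' @param nonlinearity A [softplus_params()] object.
#' @param noise A [noise_params()] object.
#' @param history_weight Optional scalar spike-to-input conversion weight;
#'   `NULL` (default) for no response-history term.
#' @return An object of class `multistage_model`.
#' @examples
#' m <- multistage_model(softplus_params(1, 2, 0, 0),
#'                       noise_params(0.5, 1, 0.3))
#' simulate_responses(m, rnorm(10), seed = 1)
#' @export
multistage_model <- function(nonlinearity, noise, history_weight = NULL) {
  stopifnot(inherits(nonlinearity, "softplus_params"),
            inherits(noise, "noise_params"))
  if (!is.null(history_weight)) {
    history_weight <- as.numeric(history_weight)
    if (length(history_weight) != 1L || !is.finite(history_weight))
      stop("history_weight must be a finite scalar or NULL")
  }
  structure(list(nonlinearity = nonlinearity, noise = noise,
                 history_weight = history_weight),
            class = "multistage_model")
}

#' @export
print.multistage_model <- function(x, ...) {
  cat("Multistage noise model\n  ")
  print(x$nonlinearity)
  cat("  ")
  print(x$noise)
  if (!is.null(x$history_weight))
    cat(sprintf("  response-history weight: %.4g\n", x$history_weight))
  invisible(x)
}

# flat parameter vector used by the C++ likelihood kernel
model_par_vec <- function(m) {
  p <- m$nonlinearity; np <- m$noise
  c(p$beta1, p$beta2, p$beta3, p$beta4,
    np$sigma_up, np$sigma_mult, np$sigma_down, np$p_down)
}

#' Binned input-response dataset
#'
#' Paired arrays of the per-bin average filtered stimulus `x_t` (usually
#' z-scored) and nonnegative integer spike count `r_t`, with the bin width
#' in seconds.
#'
#' @param inputs Numeric vector of filtered stimulus values.
#' @param counts Integer vector of spike counts, same length.
#' @param bin_width Bin duration in seconds, > 0.
#' @return An object of class `binned_dataset`.
#' @export
binned_dataset <- function(inputs, counts, bin_width = 0.1) {
  inputs <- as.numeric(inputs)
  counts <- as.integer(round(counts))
  if (length(inputs) != length(counts) || length(inputs) < 1L)
    stop("inputs and counts must have equal length >= 1")
  if (!all(is.finite(inputs))) stop("inputs must be finite")
  if (any(counts < 0L)) stop("counts must be nonnegative integers")
  if (!is.finite(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  structure(list(inputs = inputs, counts = counts,
                 bin_width = as.numeric(bin_width)),
            class = "binned_dataset")
}

#' @export
print.binned_dataset <- function(x, ...) {
  cat(sprintf("binned dataset: %d bins of %.3g s; mean count %.3g, input range [%.3g, %.3g]\n",
              length(x$inputs), x$bin_width, mean(x$counts),
              min(x$inputs), max(x$inputs)))
  invisible(x)
}

#' @export
length.binned_dataset <- function(x) length(x$inputs)

# ---- serialization -------------------------------------------------------

#' Read or write a model as flat JSON
#'
#' Models are serialized as a flat JSON object with fields
#' `beta1..beta4, sigma_up, sigma_mult, sigma_down, p_down, variant` and
#' optionally `history_weight`.
#'
#' @param m A [multistage_model()].
#' @param path File path.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   returns a [multistage_model()].
#' @export
write_model_json <- function(m, path) {
  p <- m$nonlinearity; np <- m$noise
  x <- list(beta1 = p$beta1, beta2 = p$beta2, beta3 = p$beta3, beta4 = p$beta4,
            sigma_up = np$sigma_up, sigma_mult = np$sigma_mult,
            sigma_down = np$sigma_down, p_down = np$p_down,
            variant = np$variant)
  if (!is.null(m$history_weight)) x$history_weight <- m$history_weight
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  multistage_model(
    softplus_params(x$beta1, x$beta2, x$beta3, x$beta4),
    noise_params(x$sigma_up, x$sigma_mult, x$sigma_down,
                 p_down = x$p_down, variant = x$variant),
    history_weight = x$history_weight)
}

#' Read or write a binned dataset as CSV
#'
#' The CSV dialect has header columns `bin_index, x, count`; the bin width is
#' carried in a leading comment line `# bin_width: <seconds>`.
#'
#' @param d A [binned_dataset()].
#' @param path File path.
#' @return `write_dataset_csv` returns `path` invisibly; `read_dataset_csv`
#'   returns a [binned_dataset()].
#' @export
write_dataset_csv <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_width: %.17g", d$bin_width), con)
  write.csv(data.frame(bin_index = seq_along(d$inputs) - 1L,
                       x = d$inputs, count = d$counts),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  first <- readLines(path, n = 1L)
  bw <- 0.1
  if (grepl("^#\\s*bin_width:", first))
    bw <- as.numeric(sub("^#\\s*bin_width:\\s*", "", first))
  df <- read.csv(path, comment.char = "#")
  binned_dataset(df$x, df$count, bin_width = bw)
}
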