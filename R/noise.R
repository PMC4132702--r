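#' Measurement-noise specification
#'
#' Describes the noise added by the synthetic-data generators: a proportional
#' Gaussian component (coefficient of variation `cv`) plus an additive
#' Gaussian floor (`floor_sd`, in signal units). A seed is mandatory whenever
#' either component is nonzero, so that identical parameters and seed give
#' bit-identical output.
#'
#' @param cv Proportional Gaussian coefficient of variation (unitless, >= 0).
#' @param floor_sd Additive Gaussian standard deviation in signal units (>= 0).
#' @param seed Integer seed; required if `cv > 0` or `floor_sd > 0`.
#'
#' @return An object of class `noise_spec`.
#' @export
#' @examples
#' noise_off()
#' noise_spec(cv = 0.05, seed = 1)
noise_spec <- function(cv = 0, floor_sd = 0, seed = NULL) {
  stopifnot(is.numeric(cv), length(cv) == 1, is.finite(cv), cv >= 0)
  stopifnot(is.numeric(floor_sd), length(floor_sd) == 1, is.finite(floor_sd), floor_sd >= 0)
  noisy <- cv > 0 || floor_sd > 0
  if (noisy && is.null(seed)) {
    rlang::abort("a `seed` is required when noise is on (cv > 0 or floor_sd > 0)")
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(cv = cv, floor_sd = floor_sd, seed = seed), class = "noise_spec")
}

#' @rdname noise_spec
#' @export
noise_off <- function() noise_spec(0, 0, NULL)

is_noise_off <- function(noise) noise$cv == 0 && noise$floor_sd == 0

#' Apply a noise specification to a signal vector
#'
#' Adds proportional plus additive Gaussian noise and clamps the result to
#' physical bounds. With noise off the input is returned exactly (no RNG is
#' touched). The global RNG state is restored afterwards.
#'
#' @param x Numeric signal vector.
#' @param noise A [noise_spec()].
#' @param lower,upper Clamping bounds (default `[0, Inf)`).
#' @return Numeric vector, same length as `x`.
#' @export
apply_noise <- function(x, noise = noise_off(), lower = 0, upper = Inf) {
  stopifnot(inherits(noise, "noise_spec"))
  if (is_noise_off(noise)) return(pmin(pmax(x, lower), upper))
  y <- withr::with_seed(noise$seed, {
    x * (1 + noise$cv * stats::rnorm(length(x))) +
      noise$floor_sd * stats::rnorm(length(x))
  })
  pmin(pmax(y, lower), upper)
}

# summary.lm warns on zero-residual regressions; noise-free round trips hit
# this constantly and the R^2/SE are still what we want
quiet_lm_summary <- function(fit) {
  withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}
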