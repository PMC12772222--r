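# Synthetic relaxation decay series with planted time constants.

#' Generate a monoexponential decay series with Gaussian noise
#'
#' \eqn{I(t_i) = I_0 e^{-t_i/T} + \epsilon_i},
#' \eqn{\epsilon_i \sim N(0, (noise\_sd \cdot I_0)^2)}.
#'
#' @param T planted time constant in seconds (> 0).
#' @param I0 amplitude (arbitrary units).
#' @param delays delay times in seconds (>= 0).
#' @param noise_sd Gaussian noise SD as a fraction of I0 (>= 0).
#' @param seed integer seed; identical inputs reproduce the series.
#' @return data.frame with columns `delay_s`, `intensity`, and attribute
#'   `"truth"` = list(T, I0, noise_sd, seed).
#' @examples
#' gen_decay(0.5, 100, c(0, 0.5), noise_sd = 0)
#' @export
gen_decay <- function(T, I0, delays, noise_sd = 0, seed = 1L) {
  if (T <= 0) stop("T must be > 0")
  if (any(delays < 0)) stop("delays must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  I <- I0 * exp(-delays / T)
  if (noise_sd > 0) I <- I + rnorm(length(delays), 0, noise_sd * I0)
  structure(data.frame(delay_s = delays, intensity = I),
            truth = list(T = T, I0 = I0, noise_sd = noise_sd,
                         seed = as.integer(seed)))
}
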