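# Reduced spectral-density mapping and its exact forward model.
#
# The reduced mapping lumps the three high-frequency dipolar terms into a
# single effective density J(0.87 wH), turning {R1, R2, NOE} into
# {J(0), J(wN), J(0.87 wH)} by a linear transformation:
#
#   sigma_NH  = R1 (NOE - 1) (gammaN/gammaH)
#   J(0.87wH) = 4 sigma_NH / (5 d^2)
#   J(wN)     = [R1 - (7 d^2/4) J(0.87wH)] / (3 d^2/4 + c^2)
#   J(0)      = [R2 - (13 d^2/8) J(0.87wH) - (3 d^2/8 + c^2/2) J(wN)]
#               / (d^2/2 + 2 c^2/3)

#' Relaxation rates from a spectral-density triple (forward model)
#'
#' Computes {R1, R2, NOE} from {J(0), J(wN), J(0.87wH)} with the same
#' linearised equations that [reduced_spectral_density()] inverts, so the
#' round trip is exact to numerical precision.  Used to generate synthetic
#' relaxation observables with planted spectral densities.
#'
#' NOE is defined as 1 when R1 = 0 (null spectral density), the limit of
#' no cross-relaxation.
#'
#' @param J0,JwN,JwH087 spectral densities in s/rad (vectorised,
#'   non-negative).
#' @param ctx an [acquisition_context()].
#' @return data.frame with columns `R1`, `R2` (s^-1) and `NOE`.
#' @examples
#' ctx <- acquisition_context(field_T = 14.1)
#' gen_rates_from_J(2e-9, 1e-9, 1e-11, ctx)
#' @export
gen_rates_from_J <- function(J0, JwN, JwH087, ctx) {
  stopifnot(inherits(ctx, "acquisition_context"))
  if (any(c(J0, JwN, JwH087) < 0)) stop("spectral densities must be >= 0")
  d2 <- ctx$d2; c2 <- ctx$c2
  sigma <- (5 * d2 / 4) * JwH087
  R1 <- (d2 / 4) * (3 * JwN + 7 * JwH087) + c2 * JwN
  R2 <- (d2 / 8) * (4 * J0 + 3 * JwN + 13 * JwH087) +
    (c2 / 6) * (4 * J0 + 3 * JwN)
  NOE <- ifelse(R1 > 0, 1 + (1 / ctx$gamma_ratio) * sigma / R1, 1)
  data.frame(R1 = R1, R2 = R2, NOE = NOE)
}

#' Reduced spectral-density mapping
#'
#' Transforms measured {R1, R2, NOE} into the motional power spectrum
#' sampled at three frequencies: J(0), J(wN) and J(0.87 wH).  A negative
#' J(0) is returned as-is but flagged `out_of_model`, the signature of a
#' chemical-exchange contribution to R2 (or inconsistent inputs); the
#' mapping itself cannot distinguish rigidification from exchange.
#'
#' @param R1,R2 longitudinal and transverse rates in s^-1 (vectorised).
#' @param NOE heteronuclear NOE ratio (I_sat/I_ref).
#' @param ctx an [acquisition_context()].
#' @return data.frame with columns `J0`, `JwN`, `JwH087` (s/rad),
#'   `J0_over_JwH` (NA when J(0.87wH) is 0) and logical `out_of_model`.
#' @examples
#' ctx <- acquisition_context(field_T = 14.1)
#' r <- gen_rates_from_J(2e-9, 1.5e-9, 2e-11, ctx)
#' reduced_spectral_density(r$R1, r$R2, r$NOE, ctx)
#' @export
reduced_spectral_density <- function(R1, R2, NOE, ctx) {
  stopifnot(inherits(ctx, "acquisition_context"))
  n <- max(length(R1), length(R2), length(NOE))
  R1 <- rep_len(R1, n); R2 <- rep_len(R2, n); NOE <- rep_len(NOE, n)
  d2 <- ctx$d2; c2 <- ctx$c2
  sigma <- R1 * (NOE - 1) * ctx$gamma_ratio
  JwH <- 4 * sigma / (5 * d2)
  JwN <- (R1 - (7 * d2 / 4) * JwH) / (3 * d2 / 4 + c2)
  J0 <- (R2 - (13 * d2 / 8) * JwH - (3 * d2 / 8 + c2 / 2) * JwN) /
    (d2 / 2 + 2 * c2 / 3)
  data.frame(
    J0 = J0, JwN = JwN, JwH087 = JwH,
    J0_over_JwH = ifelse(JwH > 0, J0 / JwH, NA_real_),
    out_of_model = J0 < 0 | JwN < 0 | JwH < 0
  )
}
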