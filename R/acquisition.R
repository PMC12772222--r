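# Physical constants (SI). Gyromagnetic ratios in rad s^-1 T^-1; gamma_N is
# kept with its negative sign so NOE formulas carry their conventional sign.
.const <- list(
  mu0     = 4 * pi * 1e-7,
  h       = 6.62607015e-34,
  gamma_H = 2.6752218744e8,
  gamma_N = -2.71261804e7
)

#' Acquisition context for spectral-density mapping
#'
#' Bundles the spectrometer field and the interaction constants of the
#' 15N-1H spin pair needed by [reduced_spectral_density()] and
#' [gen_rates_from_J()]: the dipolar constant
#' \eqn{d = \mu_0 h \gamma_H \gamma_N / (8 \pi^2 r_{NH}^3)} and the CSA
#' constant \eqn{c = \omega_N \Delta\sigma / \sqrt{3}}.
#'
#' Angular frequencies `omega_H` and `omega_N` are stored as magnitudes
#' (rad/s); the sign of the 15N gyromagnetic ratio is carried separately in
#' `gamma_ratio = gamma_N / gamma_H` (negative), which is what the NOE
#' conventions use.  No default field is assumed: supply either `field_T`
#' or `freq_MHz`.
#'
#' @param field_T static field B0 in tesla (e.g. 14.1).
#' @param freq_MHz alternatively, the 1H Larmor frequency in MHz
#'   (e.g. 600); exactly one of `field_T`/`freq_MHz` must be given.
#' @param r_NH N-H bond length in angstrom; default 1.02, the conventional
#'   amide value.
#' @param delta_sigma_N 15N chemical-shift anisotropy in ppm; default -160,
#'   the conventional amide value.
#' @return an object of class `acquisition_context`: a list with
#'   `field_T`, `omega_H`, `omega_N` (rad/s, magnitudes), `gamma_ratio`,
#'   `r_NH`, `delta_sigma_N`, and the derived squared constants `d2`, `c2`
#'   (s^-2).
#' @examples
#' ctx <- acquisition_context(field_T = 14.1)
#' ctx$omega_H / (2 * pi) / 1e6  # proton frequency, MHz
#' @export
acquisition_context <- function(field_T = NULL, freq_MHz = NULL,
                                r_NH = 1.02, delta_sigma_N = -160) {
  if (is.null(field_T) == is.null(freq_MHz))
    stop("supply exactly one of `field_T` or `freq_MHz`")
  if (is.null(field_T))
    field_T <- freq_MHz * 1e6 * 2 * pi / .const$gamma_H
  stopifnot(field_T > 0, r_NH > 0)
  omega_H <- .const$gamma_H * field_T
  omega_N <- abs(.const$gamma_N) * field_T
  r_m <- r_NH * 1e-10
  d <- .const$mu0 * .const$h * .const$gamma_H * abs(.const$gamma_N) /
    (8 * pi^2 * r_m^3)
  cc <- omega_N * abs(delta_sigma_N) * 1e-6 / sqrt(3)
  structure(list(
    field_T = field_T,
    omega_H = omega_H,
    omega_N = omega_N,
    gamma_ratio = .const$gamma_N / .const$gamma_H,
    r_NH = r_NH,
    delta_sigma_N = delta_sigma_N,
    d2 = d^2,
    c2 = cc^2
  ), class = "acquisition_context")
}

#' @export
print.acquisition_context <- function(x, ...) {
  cat(sprintf("Acquisition context: B0 = %.3f T (1H %.1f MHz)\n",
              x$field_T, x$omega_H / (2 * pi) / 1e6))
  cat(sprintf("  r_NH = %.3f A, delta_sigma_N = %.1f ppm\n",
              x$r_NH, x$delta_sigma_N))
  cat(sprintf("  d^2 = %.4g s^-2, c^2 = %.4g s^-2\n", x$d2, x$c2))
  invisible(x)
}

#' Single-Lorentzian spectral density
#'
#' Rigid isotropic rotor model \eqn{J(\omega) = (2/5)\,\tau_c /
#' (1 + (\omega\tau_c)^2)}, the closed-form limit used to benchmark the
#' reduced mapping.
#'
#' @param omega angular frequency (rad/s), vectorised.
#' @param tau_c rotational correlation time (s).
#' @return spectral density in s/rad.
#' @export
lorentzian_J <- function(omega, tau_c) {
  stopifnot(tau_c > 0)
  (2 / 5) * tau_c / (1 + (omega * tau_c)^2)
}

#' Rigid-rotor relaxation rates from the full dipolar/CSA expressions
#'
#' Forward model for an amide 15N relaxed by dipolar coupling to its proton
#' and by 15N CSA, with a single-Lorentzian spectral density.  Uses the
#' full five-frequency expressions (no high-frequency lumping), so it can
#' quantify the approximation error of the reduced mapping.
#'
#' @param tau_c correlation time (s).
#' @param ctx an [acquisition_context()].
#' @return list with `R1`, `R2` (s^-1), `NOE`, `sigma_NH` (s^-1), and the
#'   exact `J0`, `JwN`, `JwH087` values of the underlying Lorentzian.
#' @export
rates_from_lorentzian <- function(tau_c, ctx) {
  stopifnot(inherits(ctx, "acquisition_context"))
  J <- function(w) lorentzian_J(w, tau_c)
  wH <- ctx$omega_H; wN <- ctx$omega_N
  d2 <- ctx$d2; c2 <- ctx$c2
  # gamma_N < 0: the double-quantum transition sits at wH - |wN|, the
  # zero-quantum at wH + |wN| (this asymmetry is the origin of the 0.87
  # factor in the reduced mapping).
  wDQ <- wH - wN; wZQ <- wH + wN
  R1 <- (d2 / 4) * (J(wZQ) + 3 * J(wN) + 6 * J(wDQ)) + c2 * J(wN)
  R2 <- (d2 / 8) * (4 * J(0) + J(wZQ) + 3 * J(wN) + 6 * J(wH) +
                      6 * J(wDQ)) +
    (c2 / 6) * (4 * J(0) + 3 * J(wN))
  sigma <- (d2 / 4) * (6 * J(wDQ) - J(wZQ))
  noe <- 1 + (1 / ctx$gamma_ratio) * sigma / R1
  list(R1 = R1, R2 = R2, NOE = noe, sigma_NH = sigma,
       J0 = J(0), JwN = J(wN), JwH087 = J(0.87 * wH))
}
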