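#' Arrhenius damage kinetics parameters
#'
#' The extent of irreversible thermal injury is quantified by the Arrhenius
#' damage integral
#' \deqn{\Omega(t) = \ln\{C(0)/C(t)\} = A \int_0^t \exp\{-E_a/(R\,T(t'))\}\,dt',}
#' where `C` is the remaining concentration of undamaged tissue, `A` (1/s) a
#' frequency factor, `E_a` (J/mol) the activation energy and `T` the absolute
#' temperature. `Omega = 1` (i.e. 63 % of the tissue denatured) is the
#' conventional coagulation threshold.
#'
#' The shipped defaults (`A = 7.39e39` 1/s, `E_a = 2.577e5` J/mol) are
#' literature-style placeholder values for liver; they are configuration
#' inputs, not measured constants, and should be overridden when modelling a
#' specific tissue.
#'
#' @param A frequency factor (1/s), > 0.
#' @param E_a activation energy (J/mol), > 0.
#' @return An `arrhenius_params` object.
#' @export
arrhenius_params <- function(A = 7.39e39, E_a = 2.577e5) {
  if (!is.finite(A) || A <= 0) stop("A must be > 0")
  if (!is.finite(E_a) || E_a <= 0) stop("E_a must be > 0")
  structure(list(A = A, E_a = E_a, R = GAS_CONSTANT),
            class = "arrhenius_params")
}

#' Accumulate Arrhenius damage over one time step
#'
#' Advances the damage parameter by the rectangle rule,
#' `Omega <- Omega + dt * A * exp(-E_a / (R * (T + 273.15)))`, elementwise.
#' Temperatures are supplied in degrees Celsius and converted to kelvin inside
#' the exponent. With `mask` given, voxels outside the mask (air, vaporized)
#' are frozen.
#'
#' @param Omega current damage parameter (scalar or array), >= 0.
#' @param T_celsius temperature (degrees C), same shape as `Omega`.
#' @param dt time step (s), > 0.
#' @param params an [arrhenius_params()] object.
#' @param mask optional logical array; damage accumulates only where `TRUE`.
#' @return Updated `Omega`.
#' @export
arrhenius_increment <- function(Omega, T_celsius, dt, params = arrhenius_params(),
                                mask = NULL) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  T_K <- T_celsius + 273.15
  if (any(T_K <= 0)) stop("absolute temperature must be positive")
  rate <- params$A * exp(-params$E_a / (params$R * T_K))
  if (is.null(mask)) {
    Omega + dt * rate
  } else {
    Omega[mask] <- Omega[mask] + dt * rate[mask]
    Omega
  }
}

#' Damaged-tissue ratio from the damage parameter
#'
#' `alpha = 1 - exp(-Omega)`: the volume fraction of denatured tissue implied
#' by first-order decay of the undamaged concentration, `C(t)/C(0) = exp(-Omega)`.
#' `Omega = 1` gives alpha = 63 % (the irreversible-damage threshold) and
#' `Omega = 5` gives 99 % (operationally "completely coagulated").
#'
#' @param Omega damage parameter, >= 0 (scalar or array).
#' @return `alpha` in `[0, 1]`, same shape as `Omega`.
#' @export
alpha_from_omega <- function(Omega) {
  if (any(Omega < 0)) stop("Omega must be >= 0")
  1 - exp(-Omega)
}

#' Bath time needed to reach a target damage parameter
#'
#' For tissue held at a constant temperature the Arrhenius integral is linear
#' in time, so the holding time that produces `Omega_target` is the closed
#' form `t = Omega_target * exp(E_a / (R T_K)) / A` -- the exact inverse of
#' [arrhenius_increment()] at constant temperature. This is the design rule
#' for constant-temperature water-bath coagulation of calibration samples.
#'
#' @param T_const bath temperature (degrees C).
#' @param Omega_target target damage parameter, > 0.
#' @param params an [arrhenius_params()] object.
#' @return Required bath time (s).
#' @export
bath_time_for_omega <- function(T_const, Omega_target, params = arrhenius_params()) {
  if (!all(Omega_target > 0)) stop("Omega_target must be > 0")
  T_K <- T_const + 273.15
  if (any(T_K <= 0)) stop("absolute temperature must be positive")
  Omega_target * exp(params$E_a / (params$R * T_K)) / params$A
}

#' Optical penetration depth in the diffusion regime
#'
#' `delta = 1 / sqrt(3 mu_a (mu_a + mu_s'))` (mm): the 1/e depth of the
#' diffuse fluence in a scattering-dominated medium. Used to gauge how the
#' small coagulation-induced drop in `mu_a` deepens light penetration.
#'
#' @param mu_a absorption coefficient (1/mm), > 0.
#' @param mu_s_prime reduced scattering coefficient (1/mm), >= 0.
#' @return Penetration depth (mm).
#' @export
penetration_depth <- function(mu_a, mu_s_prime) {
  if (any(!is.finite(mu_a)) || any(mu_a <= 0)) {
    stop("mu_a must be > 0 (penetration depth undefined for a transparent medium)")
  }
  if (any(mu_s_prime < 0)) stop("mu_s_prime must be >= 0")
  1 / sqrt(3 * mu_a * (mu_a + mu_s_prime))
}
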