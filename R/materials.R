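#' Material optical and thermal properties
#'
#' Bundles the per-material constants used throughout the simulation. All
#' quantities are stored in one consistent internal unit system --
#' millimetre, gram, second, joule, degree Celsius -- so optical coefficients
#' are in 1/mm, thermal conductivity in W/(mm K), density in g/mm^3, specific
#' heat in J/(g K) and latent heat in J/g. Use [convert_property()] to bring
#' values quoted in the usual literature units (W/(cm K), g/cm^3, 1/cm, ...)
#' into this system.
#'
#' @param mu_a absorption coefficient (1/mm).
#' @param mu_s_prime_native reduced scattering coefficient of native tissue
#'   (1/mm).
#' @param mu_s_prime_coagulated reduced scattering coefficient of fully
#'   coagulated tissue (1/mm); must be >= the native value.
#' @param g scattering anisotropy factor (mean cosine of the single-scattering
#'   deflection angle), in `[0, 1)`.
#' @param n refractive index (>= 1).
#' @param k thermal conductivity (W/(mm K)).
#' @param rho density (g/mm^3).
#' @param c_p specific heat capacity (J/(g K)).
#' @param T_v vaporization temperature (degrees C).
#' @param L_v latent heat of vaporization (J/g).
#'
#' @return An object of class `material_properties`.
#' @seealso [liver_materials()] for liver-like defaults, [convert_property()].
#' @export
material_properties <- function(mu_a, mu_s_prime_native,
                                mu_s_prime_coagulated = mu_s_prime_native,
                                g = 0.9, n = 1.44,
                                k, rho, c_p, T_v = 100, L_v = 2257) {
  vals <- c(mu_a = mu_a, mu_s_prime_native = mu_s_prime_native,
            mu_s_prime_coagulated = mu_s_prime_coagulated,
            k = k, rho = rho, c_p = c_p, L_v = L_v)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all material coefficients must be finite and non-negative")
  }
  # T_v = Inf encodes a material that never vaporizes (air)
  if (is.na(T_v) || T_v <= 0) stop("T_v must be > 0")
  if (g < 0 || g >= 1) stop("anisotropy g must lie in [0, 1)")
  if (n < 1) stop("refractive index n must be >= 1")
  if (mu_s_prime_coagulated < mu_s_prime_native) {
    stop("mu_s_prime_coagulated must be >= mu_s_prime_native")
  }
  structure(
    list(mu_a = mu_a,
         mu_s_prime_native = mu_s_prime_native,
         mu_s_prime_coagulated = mu_s_prime_coagulated,
         g = g, n = n, k = k, rho = rho, c_p = c_p,
         T_v = T_v, L_v = L_v),
    class = "material_properties")
}

#' @export
print.material_properties <- function(x, ...) {
  cat("<material_properties>\n")
  cat(sprintf("  optics : mu_a %.4g /mm, mu_s' %.4g -> %.4g /mm, g %.2f, n %.3f\n",
              x$mu_a, x$mu_s_prime_native, x$mu_s_prime_coagulated, x$g, x$n))
  cat(sprintf("  thermal: k %.4g W/(mm K), rho %.4g g/mm^3, c_p %.4g J/(g K)\n",
              x$k, x$rho, x$c_p))
  cat(sprintf("  phase  : T_v %.4g C, L_v %.4g J/g\n", x$T_v, x$L_v))
  invisible(x)
}

#' Liver-like default material set
#'
#' Returns the air and tissue property tables used by the shipped scenarios.
#' The tissue optics are anchored at 980 nm: `mu_a = 0.07` /mm for native
#' tissue and a 2.65-fold increase in the reduced scattering coefficient upon
#' complete coagulation (native 1.0 /mm, coagulated 2.65 /mm), with `g = 0.9`
#' and `n = 1.44`. Thermal constants are water-like placeholders (liver is
#' ~70-80 % water): `k = 5.1e-4` W/(mm K), `rho = 1e-3` g/mm^3,
#' `c_p = 3.6` J/(g K), boiling at 100 C with `L_v = 2257` J/g. These are
#' literature-style defaults, not measurements; override them per scenario
#' when fitting a specific tissue.
#'
#' @return Named list with elements `air` and `tissue`, each a
#'   [material_properties()] object.
#' @export
liver_materials <- function() {
  list(
    air = material_properties(
      mu_a = 0, mu_s_prime_native = 0, mu_s_prime_coagulated = 0,
      g = 0, n = 1.0,
      k = 2.6e-5,      # 0.026 W/(m K)
      rho = 1.2e-6,    # 1.2 kg/m^3
      c_p = 1.005,
      T_v = Inf, L_v = 0),
    tissue = material_properties(
      mu_a = 0.07, mu_s_prime_native = 1.0, mu_s_prime_coagulated = 2.65,
      g = 0.9, n = 1.44,
      k = 5.1e-4,      # 0.51 W/(m K)
      rho = 1.0e-3,    # 1.0 g/cm^3
      c_p = 3.6,
      T_v = 100, L_v = 2257))
}

#' Convert a material property to internal units
#'
#' The internal unit system is mm / g / s / J / degrees C. Literature tables
#' commonly quote conductivity in W/(cm K) or W/(m K), density in g/cm^3 or
#' kg/m^3 and optical coefficients in 1/cm; this helper performs those
#' conversions so configuration files can state values in their source units.
#'
#' @param value numeric value in `unit`.
#' @param unit character unit label. Supported: `"W/(mm K)"`, `"W/(cm K)"`,
#'   `"W/(m K)"`, `"g/mm^3"`, `"g/cm^3"`, `"kg/m^3"`, `"1/mm"`, `"1/cm"`,
#'   `"J/(g K)"`, `"J/g"`, `"C"`, `"mm"`, `"1/s"`, `"J/mol"`.
#' @return Value converted to internal units.
#' @export
convert_property <- function(value, unit) {
  factor <- switch(unit,
    "W/(mm K)" = 1, "W/(cm K)" = 1 / 10, "W/(m K)" = 1 / 1000,
    "g/mm^3" = 1, "g/cm^3" = 1 / 1000, "kg/m^3" = 1e-6,
    "1/mm" = 1, "1/cm" = 1 / 10,
    "J/(g K)" = 1, "J/g" = 1, "C" = 1, "mm" = 1, "1/s" = 1, "J/mol" = 1,
    stop("unsupported unit: ", unit))
  value * factor
}

# universal gas constant, J/(mol K)
GAS_CONSTANT <- 8.314

# material id codes used in voxel lattices
MAT_AIR <- 0L
MAT_TISSUE <- 1L
MAT_VAPORIZED <- 2L
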