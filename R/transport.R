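#' Scanned Gaussian beam configuration
#'
#' A collimated beam at normal incidence (+z) whose axis moves at constant
#' speed along a straight segment on the tissue surface. The irradiation time
#' is the path length divided by the speed.
#'
#' @param power irradiation power (W), >= 0.
#' @param diameter_1e2 beam diameter at 1/e^2 intensity (mm), > 0.
#' @param start_xy,end_xy numeric `(x, y)` scan endpoints (mm).
#' @param speed scan speed (mm/s), > 0.
#' @return A `beam_config` with derived `t_on` (s) and `sigma` (per-axis
#'   Gaussian standard deviation, mm; the 1/e^2 radius equals `2 * sigma`).
#' @export
beam_config <- function(power, diameter_1e2 = 2.8,
                        start_xy = c(0, -10), end_xy = c(0, 10), speed = 1) {
  if (!is.finite(power) || power < 0) stop("power must be >= 0")
  if (!is.finite(diameter_1e2) || diameter_1e2 <= 0) stop("beam diameter must be > 0")
  if (!is.finite(speed) || speed <= 0) stop("speed must be > 0")
  len <- sqrt(sum((end_xy - start_xy)^2))
  structure(
    list(power = power, diameter_1e2 = diameter_1e2,
         start_xy = as.numeric(start_xy), end_xy = as.numeric(end_xy),
         speed = speed, path_length = len, t_on = len / speed,
         sigma = diameter_1e2 / 4),
    class = "beam_config")
}

#' @export
print.beam_config <- function(x, ...) {
  cat(sprintf(
    "<beam_config> %g W, 1/e^2 diameter %g mm, (%g,%g) -> (%g,%g) mm @ %g mm/s (t_on %g s)\n",
    x$power, x$diameter_1e2, x$start_xy[1], x$start_xy[2],
    x$end_xy[1], x$end_xy[2], x$speed, x$t_on))
  invisible(x)
}

#' Sample photon launch states for a Gaussian beam
#'
#' Draws launch positions from the beam's transverse intensity profile: an
#' axis-symmetric Gaussian whose 1/e^2 radius is twice the per-axis standard
#' deviation (`sigma = diameter_1e2 / 4`). All packets start at the top of the
#' lattice travelling along +z with unit weight.
#'
#' @param beam a [beam_config()].
#' @param center_xy `(x, y)` of the beam axis (mm).
#' @param n number of packets to draw.
#' @return List with `position` (n x 3 matrix, z = 0), `direction`
#'   (n x 3, all `(0, 0, 1)`) and `weight` (all 1).
#' @export
sample_beam_photon <- function(beam, center_xy = c(0, 0), n = 1L) {
  pos <- cbind(x = center_xy[1] + beam$sigma * stats::rnorm(n),
               y = center_xy[2] + beam$sigma * stats::rnorm(n),
               z = 0)
  list(position = pos,
       direction = matrix(rep(c(0, 0, 1), each = n), ncol = 3,
                          dimnames = list(NULL, c("ux", "uy", "uz"))),
       weight = rep(1, n))
}

#' Monte Carlo absorbed-power-density field
#'
#' Traces photon packets from the beam through the current voxel optics and
#' returns the volumetric absorbed power density `S` (W/mm^3), scaled so that
#' `sum(S) * voxel_volume = power * absorbed_fraction`. Specular reflection
#' at the air--tissue interface (and any other refractive-index mismatch,
#' e.g. crater walls) is applied through stochastic unpolarized Fresnel
#' events; scattering uses the Henyey--Greenstein phase function; low-weight
#' packets are terminated by Russian roulette.
#'
#' The run is deterministic for a fixed `seed`. The returned `tallies` are
#' fractions of the launched weight and close the energy balance exactly:
#' `absorbed + escaped + specular == launched + roulette_gain - roulette_loss`
#' to rounding; the roulette net term is zero in expectation.
#'
#' @param grid a [build_grid()] lattice.
#' @param optics an [update_optical_field()] result consistent with `grid`.
#' @param beam a [beam_config()].
#' @param center_xy beam-axis position (mm).
#' @param n_photons number of packets (>= 1).
#' @param seed integer RNG seed; when `NULL` the current RNG state is used.
#' @param roulette_threshold packet weight below which roulette is played.
#' @param roulette_p survival probability (survivors are reweighted by
#'   `1/roulette_p`).
#' @return An `absorbed_power_field`: list with `S` (3D array, W/mm^3) and
#'   `tallies`.
#' @export
compute_absorption <- function(grid, optics, beam, center_xy = c(0, 0),
                               n_photons = 1e5, seed = NULL,
                               roulette_threshold = 1e-4, roulette_p = 0.1) {
  if (prod(grid$shape) == 0) stop("zero-size grid")
  stopifnot(identical(dim(optics$mu_a), as.integer(grid$shape)) ||
              identical(dim(optics$mu_a), grid$shape))
  half_x <- grid$shape[1] * grid$voxel_size / 2
  half_y <- grid$shape[2] * grid$voxel_size / 2
  r_1e2 <- beam$diameter_1e2 / 2
  if (abs(center_xy[1]) - r_1e2 > half_x || abs(center_xy[2]) - r_1e2 > half_y) {
    warning("beam footprint entirely outside the grid; S = 0")
    return(structure(
      list(S = array(0, dim = grid$shape),
           tallies = list(launched = 1, absorbed = 0, escaped = 1,
                          specular = 0, roulette_gain = 0, roulette_loss = 0)),
      class = "absorbed_power_field"))
  }
  if (!is.null(seed)) {
    set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  }
  out <- mc_transport_cpp(optics$mu_a, optics$mu_s, optics$n, grid$shape,
                          grid$voxel_size, optics$g,
                          center_xy[1], center_xy[2], beam$sigma,
                          as.integer(n_photons), roulette_threshold, roulette_p)
  S <- out$absorbed_weight * (beam$power / (n_photons * grid$voxel_size^3))
  structure(list(S = S, tallies = out$tallies),
            class = "absorbed_power_field")
}

#' @export
print.absorbed_power_field <- function(x, ...) {
  t <- x$tallies
  cat(sprintf(
    "<absorbed_power_field> absorbed %.4f, escaped %.4f, specular %.4f (roulette net %+.2e)\n",
    t$absorbed, t$escaped, t$specular, t$roulette_gain - t$roulette_loss))
  invisible(x)
}
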