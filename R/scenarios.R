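#' Assemble a simulation scenario
#'
#' A scenario bundles everything one run needs: lattice geometry, material
#' tables, beam, schedule and damage kinetics, plus the qualitative outcome
#' the settings are designed to produce. Construction validates the schedule
#' against the FTCS stability limit and records the scenario's dimensionless
#' groups (tissue optical depth and the thermal diffusion number
#' `k t_heat / (rho c_p dx^2)`) in `groups` for comparison across scales.
#'
#' @param name scenario label.
#' @param shape,voxel_size,air_thickness,tissue_thickness lattice geometry,
#'   see [build_grid()].
#' @param materials material table, see [liver_materials()].
#' @param beam a [beam_config()].
#' @param schedule a [schedule_config()].
#' @param damage an [arrhenius_params()].
#' @param expected one of `"none"`, `"coagulation_only"`,
#'   `"coagulation_and_vaporization"`.
#' @return A `scenario` object.
#' @export
scenario <- function(name, shape, voxel_size, air_thickness, tissue_thickness,
                     materials = liver_materials(), beam, schedule,
                     damage = arrhenius_params(),
                     expected = c("none", "coagulation_only",
                                  "coagulation_and_vaporization")) {
  expected <- match.arg(expected)
  # construction-time consistency: geometry must build and dt must be stable
  grid <- build_grid(shape, voxel_size, air_thickness, tissue_thickness,
                     materials)
  dt_max <- min(stability_limit(materials$air, voxel_size),
                stability_limit(materials$tissue, voxel_size))
  if (schedule$dt > dt_max) {
    stop(sprintf("scenario '%s': dt = %g s exceeds stability limit %g s",
                 name, schedule$dt, dt_max))
  }
  tis <- materials$tissue
  groups <- list(
    optical_depth = (tis$mu_a + tis$mu_s_prime_native / (1 - tis$g)) *
      tissue_thickness,
    thermal_number = tis$k * schedule$t_heat / (tis$rho * tis$c_p * voxel_size^2),
    stability_ratio = schedule$dt / dt_max)
  structure(
    list(name = name, shape = as.integer(shape), voxel_size = voxel_size,
         air_thickness = air_thickness, tissue_thickness = tissue_thickness,
         materials = materials, beam = beam, schedule = schedule,
         damage = damage, expected = expected, groups = groups),
    class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: %g W @ %g mm/s, %dx%dx%d @ %g mm, expect %s\n",
              x$name, x$beam$power, x$beam$speed,
              x$shape[1], x$shape[2], x$shape[3], x$voxel_size, x$expected))
  invisible(x)
}

#' Build the voxel grid of a scenario
#' @param sc a [scenario()].
#' @return A [build_grid()] lattice.
#' @export
scenario_grid <- function(sc) {
  build_grid(sc$shape, sc$voxel_size, sc$air_thickness, sc$tissue_thickness,
             sc$materials)
}

#' Run a scenario
#'
#' @param sc a [scenario()].
#' @param seed optional seed overriding the schedule's.
#' @param dop use the dynamic optical properties update (`FALSE` gives the
#'   static-optics baseline).
#' @param n_photons optional override of packets per transport call.
#' @param ... passed to [run_simulation()].
#' @return An `ablation_result`.
#' @export
run_scenario <- function(sc, seed = NULL, dop = TRUE, n_photons = NULL, ...) {
  schedule <- sc$schedule
  if (!is.null(seed)) schedule$seed <- as.integer(seed)
  if (!is.null(n_photons)) schedule$n_photons <- as.integer(n_photons)
  run_simulation(scenario_grid(sc), sc$beam, schedule, sc$damage,
                 dop = dop, ...)
}

#' Reference irradiation scenarios
#'
#' Builds the six full-scale scanned-beam scenarios -- 50 W at 0.5, 0.75 and
#' 1.0 mm/s (coagulation and vaporization expected) and 10 W at 1.0, 1.25 and
#' 1.5 mm/s (coagulation only) -- on the 300 x 300 x 150 lattice of 0.1 mm
#' voxels with a 20 mm scan, dt = 1e-5 s, t_heat = 2e-3 s, cooling times of
#' 30 s (high power) and 10 s (low power) and 1e7 packets per transport call.
#' With `scaled = TRUE` each scenario also gets a desk-scale twin
#' (`*_scaled`): a 48 x 40 x 28 lattice of 0.25 mm voxels (1 mm air / 6 mm
#' tissue, 12 x 10 mm laterally), a 4 mm scan at the same power, speed and
#' beam diameter so the local fluence conditions are preserved, dt = 4e-4 s,
#' t_heat = 0.05 s, shortened cooling and 4000 packets per call. Twins
#' preserve the qualitative with/without-DOP contrast, not absolute lesion
#' sizes.
#'
#' @param scaled also emit the desk-scale twins.
#' @param materials material table.
#' @param damage Arrhenius parameters.
#' @return Named list of [scenario()] objects.
#' @export
make_reference_scenarios <- function(scaled = TRUE,
                                     materials = liver_materials(),
                                     damage = arrhenius_params()) {
  settings <- rbind(
    data.frame(power = 50, speed = c(0.5, 0.75, 1.0),
               t_off = 30, expected = "coagulation_and_vaporization"),
    data.frame(power = 10, speed = c(1.0, 1.25, 1.5),
               t_off = 10, expected = "coagulation_only"))
  out <- list()
  for (i in seq_len(nrow(settings))) {
    s <- settings[i, ]
    name <- sprintf("%s_%gW_%gmms",
                    if (s$power >= 50) "high" else "low", s$power, s$speed)
    out[[name]] <- scenario(
      name = name,
      shape = c(300L, 300L, 150L), voxel_size = 0.1,
      air_thickness = 5, tissue_thickness = 10,
      materials = materials,
      beam = beam_config(power = s$power, diameter_1e2 = 2.8,
                         start_xy = c(0, -10), end_xy = c(0, 10),
                         speed = s$speed),
      schedule = schedule_config(dt = 1e-5, t_heat = 2e-3,
                                 t_laser_off = s$t_off, n_photons = 1e7),
      damage = damage, expected = s$expected)
    if (scaled) {
      out[[paste0(name, "_scaled")]] <- scenario(
        name = paste0(name, "_scaled"),
        shape = c(48L, 40L, 28L), voxel_size = 0.25,
        air_thickness = 1, tissue_thickness = 6,
        materials = materials,
        beam = beam_config(power = s$power, diameter_1e2 = 2.8,
                           start_xy = c(0, -2), end_xy = c(0, 2),
                           speed = s$speed),
        schedule = schedule_config(dt = 4e-4, t_heat = 0.05,
                                   t_laser_off = if (s$power >= 50) 6 else 3,
                                   n_photons = 4000,
                                   roulette_threshold = 1e-3),
        damage = damage, expected = s$expected)
    }
  }
  out
}

#' Reference curve of reduced scattering versus damage parameter
#'
#' Evaluates the DOP model at given damage parameters:
#' `alpha = 1 - exp(-Omega)` and
#' `mu_s'(Omega) = (1 - alpha) native + alpha coagulated`. The curve rises
#' steeply up to `Omega = 1` and saturates towards the coagulated value
#' (within 1 % at `Omega = 5`), mirroring bath-coagulation calibration data.
#'
#' @param native,coagulated reduced scattering (1/mm); `coagulated >= native`.
#' @param omegas damage parameter values, default `0:5`.
#' @return Data frame with columns `Omega`, `alpha`, `mu_s_prime`.
#' @export
make_dop_reference_curve <- function(native = 1.0, coagulated = 2.65,
                                     omegas = 0:5) {
  if (coagulated < native) stop("coagulated must be >= native")
  alpha <- alpha_from_omega(omegas)
  data.frame(Omega = omegas, alpha = alpha,
             mu_s_prime = (1 - alpha) * native + alpha * coagulated)
}
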