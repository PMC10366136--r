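#' Two-timescale coupling schedule
#'
#' The simulation advances on two clocks: the thermal/damage step `dt`
#' (explicit FTCS, ~1e-5 s at 0.1 mm voxels) and the transport refresh
#' interval `t_heat` (~2e-3 s), during which the optics and structure are
#' frozen because the damage parameter barely changes within one interval.
#' Light transport is recomputed, the optics updated and vaporized voxels
#' removed once per `t_heat` window; after the laser switches off, thermal
#' diffusion and damage continue for `t_laser_off` while residual heat keeps
#' coagulating tissue.
#'
#' @param dt thermal step (s), > 0.
#' @param t_heat transport refresh interval (s); an integer multiple of `dt`,
#'   and `dt <= t_heat`.
#' @param t_laser_off post-irradiation cooling time (s), >= 0.
#' @param n_photons packets per transport call.
#' @param seed integer RNG seed for the whole run.
#' @param snapshot_interval interval (s) at which y = 0 plane snapshots of
#'   `T` and `Omega` are stored; `Inf` (default) disables plane snapshots
#'   (the scalar time series is always recorded).
#' @param roulette_threshold,roulette_p Russian roulette settings passed to
#'   [compute_absorption()].
#' @return A `schedule_config`.
#' @export
schedule_config <- function(dt = 1e-5, t_heat = 2e-3, t_laser_off = 30,
                            n_photons = 1e5, seed = 1L,
                            snapshot_interval = Inf,
                            roulette_threshold = 1e-4, roulette_p = 0.1) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (t_heat < dt) stop("t_heat must be >= dt")
  n_inner <- t_heat / dt
  if (abs(n_inner - round(n_inner)) > 1e-8) {
    stop("t_heat must be an integer multiple of dt")
  }
  if (t_laser_off < 0) stop("t_laser_off must be >= 0")
  structure(
    list(dt = dt, t_heat = t_heat, t_laser_off = t_laser_off,
         n_inner = as.integer(round(n_inner)),
         n_photons = as.integer(n_photons), seed = as.integer(seed),
         snapshot_interval = snapshot_interval,
         roulette_threshold = roulette_threshold, roulette_p = roulette_p),
    class = "schedule_config")
}

#' Beam-axis position during the scan
#'
#' Linear interpolation along the scan segment at the configured speed;
#' `t_on = path_length / speed`. Times outside `[0, t_on]` are clamped to the
#' endpoints.
#'
#' @param t time since irradiation start (s).
#' @param beam a [beam_config()].
#' @return Numeric `(x, y)` (mm).
#' @export
beam_position <- function(t, beam) {
  frac <- if (beam$path_length > 0) {
    pmin(pmax(t * beam$speed / beam$path_length, 0), 1)
  } else 0
  beam$start_xy + frac * (beam$end_xy - beam$start_xy)
}

seed_for_window <- function(seed, j) {
  as.integer((as.numeric(seed) + 10007 * j) %% 2147483647)
}

#' Run the coupled laser-ablation simulation
#'
#' Orchestrates the full coupling loop. For each transport window `j`
#' (continuing while `j * t_heat <= t_on`, as the coupling loop's non-strict
#' bound prescribes): (a) the damaged ratio `alpha = 1 - exp(-Omega)` updates
#' the per-voxel optics through the DOP rule and the lattice is rebuilt;
#' (b) Monte Carlo transport computes `S` with the beam at
#' `beam_position(j * t_heat)`; (c) the enthalpy and damage fields advance
#' `t_heat / dt` explicit steps; (d) voxels whose enthalpy reached
#' `H_th = rho (c_p T_v + L_v)` are vaporized: they become air, their enthalpy
#' leaves with the vapor (the new air voxel restarts at the pre-removal
#' temperature with air heat capacity) and their damage state is frozen.
#' After the laser switches off the same stepping continues with `S = 0` for
#' `t_laser_off`.
#'
#' With `dop = FALSE` the optics stay at their native values (`alpha` forced
#' to 0 in the mixing rule) -- the static-optics baseline; damage and
#' vaporization are still tracked.
#'
#' @param grid a [build_grid()] lattice.
#' @param beam a [beam_config()]; the irradiation time is its `t_on`.
#' @param schedule a [schedule_config()].
#' @param damage an [arrhenius_params()].
#' @param dop logical; update optics dynamically (default) or keep them
#'   native.
#' @param T0 initial temperature (degrees C).
#' @param verbose print one progress line per second of simulated time.
#' @return An `ablation_result`: final `state` and `grid`, logical `removed`
#'   and `coagulated` masks (disjoint), `timeseries` data frame, optional
#'   plane `snapshots`, per-window transport `tallies`, and `meta` (seed,
#'   config hash, settings) sufficient to reproduce the run.
#' @export
run_simulation <- function(grid, beam, schedule, damage = arrhenius_params(),
                           dop = TRUE, T0 = 22, verbose = FALSE) {
  tis <- grid$materials$tissue
  air <- grid$materials$air
  dt_max <- grid_stability_limit(grid)
  if (schedule$dt > dt_max * (1 + 1e-12)) {
    stop(sprintf("dt = %g s violates the stability limit %g s", schedule$dt, dt_max))
  }
  H_th <- threshold_enthalpy(tis)
  meta <- list(
    seed = schedule$seed,
    config_hash = rlang::hash(list(grid$shape, grid$voxel_size,
                                   grid$materials, beam, schedule, damage,
                                   dop, T0)),
    dop = dop, power = beam$power, speed = beam$speed, t_on = beam$t_on)

  state <- initial_state(grid, T0)
  tallies <- list()
  ts_rows <- list()
  snapshots <- list()
  next_snap <- 0
  j_mid <- max(1L, grid$shape[2] %/% 2L)  # y-plane nearest y = 0

  take_snapshot <- function(state, grid) {
    if (state$time + 1e-12 >= next_snap &&
        is.finite(schedule$snapshot_interval)) {
      snapshots[[length(snapshots) + 1L]] <<- list(
        time = state$time,
        T = state$T[, j_mid, ], Omega = state$Omega[, j_mid, ])
      next_snap <<- next_snap + schedule$snapshot_interval
    }
  }
  record <- function(state, grid) {
    ts_rows[[length(ts_rows) + 1L]] <<- data.frame(
      time = state$time, T_max = max(state$T),
      n_coagulated = sum(state$Omega >= 1 & grid$material_id == MAT_TISSUE),
      n_removed = sum(grid$material_id == MAT_VAPORIZED),
      total_enthalpy = sum(state$H) * grid$voxel_size^3)
  }

  advance_window <- function(state, grid, with_source) {
    state <- step_enthalpy(state, grid, schedule$dt, schedule$n_inner,
                           damage = damage)
    vap <- vaporize_voxels(grid, state$H, H_th)
    newly <- vap$grid$material_id == MAT_VAPORIZED &
      grid$material_id == MAT_TISSUE
    if (any(newly)) {
      # enthalpy leaves with the vapor; air restarts at the local temperature
      state$H[newly] <- air$rho * air$c_p * state$T[newly]
      state$T[newly] <- state$H[newly] / (air$rho * air$c_p)
      state$S[newly] <- 0
    }
    list(state = state, grid = vap$grid)
  }

  # irradiation phase
  j <- 0L
  last_report <- -1
  while (j * schedule$t_heat <= beam$t_on + 1e-12) {
    alpha <- if (dop) {
      a <- array(0, dim = grid$shape)
      in_tis <- grid$material_id == MAT_TISSUE
      a[in_tis] <- alpha_from_omega(state$Omega[in_tis])
      a
    } else 0
    optics <- update_optical_field(grid, alpha)
    pos <- beam_position(j * schedule$t_heat, beam)
    field <- compute_absorption(grid, optics, beam, pos,
                                n_photons = schedule$n_photons,
                                seed = seed_for_window(schedule$seed, j),
                                roulette_threshold = schedule$roulette_threshold,
                                roulette_p = schedule$roulette_p)
    state$S <- field$S
    tallies[[length(tallies) + 1L]] <-
      c(list(j_light = j, time = state$time, x = pos[1], y = pos[2]),
        field$tallies)
    step <- advance_window(state, grid, TRUE)
    state <- step$state
    grid <- step$grid
    take_snapshot(state, grid)
    record(state, grid)
    if (verbose && floor(state$time) > last_report) {
      last_report <- floor(state$time)
      message(sprintf("t = %.2f s  T_max = %.1f C  removed %d  coagulated %d",
                      state$time, max(state$T),
                      sum(grid$material_id == MAT_VAPORIZED),
                      sum(state$Omega >= 1 & grid$material_id == MAT_TISSUE)))
    }
    j <- j + 1L
  }

  # cooling phase: source off, damage and diffusion continue
  state$S <- array(0, dim = grid$shape)
  n_cool <- as.integer(round(schedule$t_laser_off / schedule$t_heat))
  for (i in seq_len(n_cool)) {
    step <- advance_window(state, grid, FALSE)
    state <- step$state
    grid <- step$grid
    take_snapshot(state, grid)
    record(state, grid)
  }

  removed <- grid$material_id == MAT_VAPORIZED
  coagulated <- state$Omega >= 1 & grid$material_id == MAT_TISSUE
  structure(
    list(state = state, grid = grid,
         removed = removed, coagulated = coagulated,
         timeseries = do.call(rbind, ts_rows),
         snapshots = snapshots,
         tallies = do.call(rbind, lapply(tallies, as.data.frame)),
         meta = meta),
    class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat(sprintf("<ablation_result> %g W @ %g mm/s%s, t = %.2f s\n",
              x$meta$power, x$meta$speed,
              if (x$meta$dop) " (DOP)" else " (static optics)",
              x$state$time))
  cat(sprintf("  removed %d voxels, coagulated %d voxels, T_max %.1f C\n",
              sum(x$removed), sum(x$coagulated), max(x$state$T)))
  invisible(x)
}
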