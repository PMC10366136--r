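#' Temperature from volumetric enthalpy
#'
#' The enthalpy method represents phase change by a plateau in the
#' enthalpy--temperature relation:
#' \deqn{T = H/(\rho c_p) \quad (H < \rho c_p T_v), \qquad
#'       T = T_v \quad (\rho c_p T_v \le H \le \rho(c_p T_v + L_v)).}
#' The zero reference is `H = 0` at 0 degrees C. At `H` exactly equal to
#' `rho c_p T_v` the two branches agree (continuity). Enthalpy above the
#' vaporization threshold `rho (c_p T_v + L_v)` on a still-present voxel means
#' a removal was missed and raises an error.
#'
#' @param H enthalpy density (J/mm^3), scalar or array, >= 0.
#' @param props [material_properties()] of the voxel's material.
#' @return Temperature (degrees C), same shape as `H`.
#' @export
enthalpy_to_temperature <- function(H, props) {
  if (any(H < 0)) stop("H must be >= 0 (zero reference is 0 C)")
  rcp <- props$rho * props$c_p
  H_th <- threshold_enthalpy(props)
  if (any(H > H_th + 1e-9 * max(1, H_th))) {
    stop("enthalpy above the vaporization threshold on a present voxel: missed removal")
  }
  T <- H / rcp
  if (is.finite(props$T_v)) {
    plateau <- H > rcp * props$T_v
    T[plateau] <- props$T_v
  }
  T
}

#' Vaporization threshold enthalpy
#'
#' `H_th = rho (c_p T_v + L_v)`: the volumetric enthalpy at which the voxel's
#' water content has fully vaporized and the voxel is removed from the tissue.
#'
#' @param props [material_properties()].
#' @return Threshold enthalpy (J/mm^3).
#' @export
threshold_enthalpy <- function(props) {
  props$rho * (props$c_p * props$T_v + props$L_v)
}

#' Explicit time-step stability bound
#'
#' The forward-time centred-space (FTCS) scheme for 3D heat conduction is
#' stable for `dt <= rho c_p dx^2 / (6 k)`. The solver refuses to step with a
#' larger `dt`.
#'
#' @param props [material_properties()].
#' @param voxel_size lattice spacing (mm).
#' @return Maximum stable time step (s); `Inf` when `k = 0`.
#' @export
stability_limit <- function(props, voxel_size) {
  if (props$k <= 0) return(Inf)
  props$rho * props$c_p * voxel_size^2 / (6 * props$k)
}

#' Stability limit over the materials actually present in a grid
#'
#' @param grid a [build_grid()] lattice.
#' @return Minimum [stability_limit()] over the materials occupying at least
#'   one voxel (vaporized voxels conduct as air).
#' @export
grid_stability_limit <- function(grid) {
  lim <- Inf
  if (any(grid$material_id != MAT_TISSUE)) {
    lim <- min(lim, stability_limit(grid$materials$air, grid$voxel_size))
  }
  if (any(grid$material_id == MAT_TISSUE)) {
    lim <- min(lim, stability_limit(grid$materials$tissue, grid$voxel_size))
  }
  lim
}

#' Initial field state at a uniform temperature
#'
#' @param grid a [build_grid()] lattice.
#' @param T0 initial temperature (degrees C), default 22 (room temperature).
#' @return A `field_state`: list of arrays `H`, `T`, `S`, `Omega` and scalar
#'   `time`.
#' @export
initial_state <- function(grid, T0 = 22) {
  rcp <- ifelse(grid$material_id == MAT_TISSUE,
                grid$materials$tissue$rho * grid$materials$tissue$c_p,
                grid$materials$air$rho * grid$materials$air$c_p)
  H <- array(rcp * T0, dim = grid$shape)
  structure(
    list(H = H, T = array(T0, dim = grid$shape),
         S = array(0, dim = grid$shape),
         Omega = array(0, dim = grid$shape), time = 0),
    class = "field_state")
}

#' Advance the enthalpy field by explicit finite differences
#'
#' Integrates `dH/dt = k lap(T) + S` with a 7-point Laplacian, harmonic-mean
#' face conductivity between dissimilar materials and adiabatic (zero-flux)
#' lattice boundaries, optionally accumulating the Arrhenius damage integral
#' on tissue voxels at the same cadence. Temperature is recovered from
#' enthalpy every step through the latent-heat plateau; voxels that overshoot
#' the plateau stay clamped at `T_v` until the caller removes them with
#' [vaporize_voxels()].
#'
#' @param state a `field_state` (see [initial_state()]).
#' @param grid the [build_grid()] lattice (vaporized voxels conduct as air).
#' @param dt time step (s); must satisfy [stability_limit()] for every
#'   material present.
#' @param n_steps number of consecutive steps to take.
#' @param damage optional [arrhenius_params()]; when supplied, `Omega` is
#'   accumulated each step on tissue voxels.
#' @param omega_T_min temperature (degrees C) below which the damage-rate
#'   exponential is skipped; the Arrhenius rate at the default 42 C is
#'   ~1e-3 1/s for liver-like parameters, orders of magnitude below what
#'   moves the `Omega = 1` contour over a simulation. Set to `-Inf` to
#'   evaluate everywhere.
#' @return Updated `field_state` with `time` advanced by `n_steps * dt`.
#' @export
step_enthalpy <- function(state, grid, dt, n_steps = 1L, damage = NULL,
                          omega_T_min = 42) {
  air <- grid$materials$air
  tis <- grid$materials$tissue
  dt_max <- grid_stability_limit(grid)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (dt > dt_max * (1 + 1e-12)) {
    stop(sprintf("dt = %g s violates the FTCS stability limit %g s", dt, dt_max))
  }
  acc <- !is.null(damage)
  if (!acc) damage <- arrhenius_params()  # values unused
  out <- thermal_damage_steps_cpp(
    state$H, state$S, state$Omega, grid$material_id, grid$shape,
    grid$voxel_size, dt, as.integer(n_steps),
    air$k, air$rho * air$c_p,
    tis$k, tis$rho * tis$c_p, tis$T_v,
    damage$A, damage$E_a / damage$R, omega_T_min, acc)
  if (anyNA(out$H)) stop("NaN in enthalpy field: diverged")
  state$H <- out$H
  state$T <- out$T
  state$Omega <- out$Omega
  state$time <- state$time + n_steps * dt
  state
}
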