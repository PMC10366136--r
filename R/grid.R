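#' Build the voxelized air/tissue model
#'
#' Constructs the rectangular voxel lattice on which light transport, heat
#' diffusion and damage kinetics operate: a layer of air on top of a layer of
#' tissue, with the beam incident along +z. The lateral origin `(x, y) = (0, 0)`
#' is at the centre of the tissue surface and depth is measured along +z, so
#' the air--tissue interface sits at `z = air_thickness` (5 mm by default).
#'
#' The default geometry is a 300 x 300 x 150 lattice of 0.1 mm cubic voxels
#' (30 x 30 x 15 mm) with 5 mm of air over 10 mm of tissue.
#'
#' @param shape integer vector `(nx, ny, nz)` of voxel counts.
#' @param voxel_size cubic voxel edge length (mm), > 0.
#' @param air_thickness thickness of the air layer (mm).
#' @param tissue_thickness thickness of the tissue layer (mm). Together with
#'   `air_thickness` this must equal `nz * voxel_size`, and both must be
#'   integer multiples of `voxel_size`.
#' @param materials named list with `air` and `tissue`
#'   [material_properties()] entries.
#'
#' @return A `voxel_grid` object: list with `shape`, `voxel_size`,
#'   `material_id` (3D integer array; 0 air, 1 tissue, 2 vaporized),
#'   `surface_z` (depth of the original air--tissue interface, mm),
#'   `surface_index` (first tissue z-slice, 1-based) and `materials`.
#' @export
build_grid <- function(shape = c(300L, 300L, 150L), voxel_size = 0.1,
                       air_thickness = 5, tissue_thickness = 10,
                       materials = liver_materials()) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape <= 0L)) {
    stop("shape must be three positive voxel counts")
  }
  if (!is.finite(voxel_size) || voxel_size <= 0) {
    stop("voxel_size must be > 0")
  }
  n_air <- air_thickness / voxel_size
  n_tis <- tissue_thickness / voxel_size
  if (abs(n_air - round(n_air)) > 1e-9 || abs(n_tis - round(n_tis)) > 1e-9) {
    stop("layer thicknesses must be integer multiples of voxel_size")
  }
  n_air <- as.integer(round(n_air))
  n_tis <- as.integer(round(n_tis))
  if (n_air + n_tis != shape[3L]) {
    stop(sprintf(
      "air (%g mm) + tissue (%g mm) layers do not fill nz * voxel_size = %g mm",
      air_thickness, tissue_thickness, shape[3L] * voxel_size))
  }
  if (n_tis < 1L) stop("grid must contain at least one tissue slice")
  material_id <- array(MAT_AIR, dim = shape)
  if (n_air < shape[3L]) {
    material_id[, , (n_air + 1L):shape[3L]] <- MAT_TISSUE
  }
  structure(
    list(shape = shape, voxel_size = voxel_size,
         material_id = material_id,
         surface_z = air_thickness,
         surface_index = n_air + 1L,
         air_thickness = air_thickness,
         tissue_thickness = tissue_thickness,
         materials = materials),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  n_vap <- sum(x$material_id == MAT_VAPORIZED)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels @ %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_size))
  cat(sprintf("  air %g mm / tissue %g mm, surface at z = %g mm",
              x$air_thickness, x$tissue_thickness, x$surface_z))
  if (n_vap > 0) cat(sprintf(", %d voxels vaporized", n_vap))
  cat("\n")
  invisible(x)
}

#' Voxel-centre coordinates of a grid
#'
#' @param grid a `voxel_grid`.
#' @return List with numeric vectors `x`, `y` (centred on 0) and `z` (from the
#'   top of the air layer), in mm.
#' @export
grid_coordinates <- function(grid) {
  h <- grid$voxel_size
  ax <- function(n) (seq_len(n) - 0.5 - n / 2) * h
  list(x = ax(grid$shape[1]), y = ax(grid$shape[2]),
       z = (seq_len(grid$shape[3]) - 0.5) * h)
}

#' Per-voxel optical fields under the dynamic optical properties model
#'
#' Applies the dynamic optical properties (DOP) rule: the reduced scattering
#' coefficient of each tissue voxel is the volume-fraction mixture of the
#' native and fully coagulated values, weighted by the thermally damaged
#' ratio `alpha`,
#' \deqn{\mu_s'(\alpha) = (1-\alpha)\,\mu_{s,native}' + \alpha\,\mu_{s,coagulated}',}
#' while the absorption coefficient is held at its native value (its change on
#' coagulation is negligible at near-infrared wavelengths). The Monte Carlo
#' kernel needs the scattering coefficient itself, obtained through the
#' similarity relation `mu_s = mu_s' / (1 - g)`. Air and vaporized voxels get
#' zero interaction coefficients and `n = 1`.
#'
#' @param grid a [build_grid()] lattice.
#' @param alpha damaged-tissue ratio, either a scalar or a 3D array matching
#'   the grid; values must lie in `[0, 1]`.
#' @return An `optical_field`: list of 3D arrays `mu_a`, `mu_s`, `n` and the
#'   scalar `g`.
#' @export
update_optical_field <- function(grid, alpha = 0) {
  tis <- grid$materials$tissue
  if (length(alpha) == 1L) {
    alpha <- array(alpha, dim = grid$shape)
  }
  if (!identical(dim(alpha), as.integer(grid$shape)) &&
      !identical(dim(alpha), grid$shape)) {
    stop("alpha must be a scalar or an array matching the grid shape")
  }
  if (anyNA(alpha) || min(alpha) < -1e-12 || max(alpha) > 1 + 1e-12) {
    stop("alpha must lie in [0, 1]")
  }
  alpha <- pmin(pmax(alpha, 0), 1)
  in_tissue <- grid$material_id == MAT_TISSUE
  mu_s_prime <- (1 - alpha) * tis$mu_s_prime_native +
    alpha * tis$mu_s_prime_coagulated
  mu_a <- array(0, dim = grid$shape)
  mu_s <- array(0, dim = grid$shape)
  n <- array(1, dim = grid$shape)
  mu_a[in_tissue] <- tis$mu_a
  mu_s[in_tissue] <- mu_s_prime[in_tissue] / (1 - tis$g)
  n[in_tissue] <- tis$n
  structure(list(mu_a = mu_a, mu_s = mu_s, n = n, g = tis$g),
            class = "optical_field")
}

#' Remove vaporized voxels from the lattice
#'
#' Tissue voxels whose volumetric enthalpy has reached the vaporization
#' threshold `H_th = rho (c_p T_v + L_v)` are removed: they become air-like
#' voxels (zero interaction coefficients, `n = 1`, air thermal properties) and
#' never revert. The comparison is inclusive (`H >= H_th`) so ties resolve
#' deterministically.
#'
#' @param grid a `voxel_grid`.
#' @param H enthalpy density array (J/mm^3) matching the grid.
#' @param H_th vaporization threshold enthalpy (J/mm^3), > 0; defaults to
#'   [threshold_enthalpy()] of the grid's tissue material.
#' @return List with `grid` (updated lattice) and `removed` (logical array,
#'   the cumulative removal mask over all calls).
#' @export
vaporize_voxels <- function(grid, H, H_th = threshold_enthalpy(grid$materials$tissue)) {
  if (!is.finite(H_th) || H_th <= 0) stop("H_th must be finite and > 0")
  if (!identical(dim(H), as.integer(grid$shape)) &&
      !identical(dim(H), grid$shape)) {
    stop("H must match the grid shape")
  }
  new_vap <- grid$material_id == MAT_TISSUE & H >= H_th
  grid$material_id[new_vap] <- MAT_VAPORIZED
  list(grid = grid, removed = grid$material_id == MAT_VAPORIZED)
}
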