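#' Lesion metrics on the central cross-section
#'
#' Quantifies the simulated lesion the way cross-sectioned samples are
#' measured: on the zx plane through `y = 0` (the centre of the scanned
#' range), the vaporization region is the removed-voxel mask and the
#' coagulation region is `Omega >= 1` on remaining tissue. Width is the
#' bounding extent along x, depth the bounding extent below the *original*
#' tissue surface (so the vaporization depth is the crater depth), and area
#' the in-plane voxel count times the voxel face area.
#'
#' @param result an [run_simulation()] result, or a list with elements
#'   `removed`, `coagulated` (3D logical arrays) and `grid`.
#' @return A one-row data frame: `vap_width`, `vap_depth`, `vap_area`,
#'   `coag_width`, `coag_depth`, `coag_area` (mm, mm, mm^2 respectively).
#' @export
lesion_metrics <- function(result) {
  grid <- result$grid
  if (is.null(grid) || is.null(result$removed) || is.null(result$coagulated)) {
    stop("result must carry removal and coagulation masks and the grid")
  }
  h <- grid$voxel_size
  j_mid <- max(1L, grid$shape[2] %/% 2L)
  measure <- function(mask3d) {
    plane <- mask3d[, j_mid, , drop = FALSE]
    plane <- array(plane, dim = dim(mask3d)[c(1, 3)])
    if (!any(plane)) return(c(width = 0, depth = 0, area = 0))
    idx <- which(plane, arr.ind = TRUE)
    width <- (max(idx[, 1]) - min(idx[, 1]) + 1L) * h
    depth <- (max(idx[, 2]) - grid$surface_index + 1L) * h
    c(width = width, depth = max(depth, 0), area = nrow(idx) * h^2)
  }
  v <- measure(result$removed)
  c <- measure(result$coagulated)
  data.frame(vap_width = v[["width"]], vap_depth = v[["depth"]],
             vap_area = v[["area"]],
             coag_width = c[["width"]], coag_depth = c[["depth"]],
             coag_area = c[["area"]])
}

#' Root mean square percentage error
#'
#' `100 * sqrt(mean(((sim - meas) / meas)^2))`: the validation statistic used
#' to compare simulated against measured series (e.g. the DOP-model reduced
#' scattering curve against bath-coagulated measurements).
#'
#' @param simulated,measured equal-length numeric vectors; `measured` must be
#'   nonzero everywhere.
#' @return RMSPE in percent.
#' @export
rmspe <- function(simulated, measured) {
  if (length(simulated) != length(measured)) stop("series lengths differ")
  if (any(measured == 0)) stop("measured values must be nonzero")
  100 * sqrt(mean(((simulated - measured) / measured)^2))
}

#' Relative difference in percent
#'
#' `100 * |sim - ref| / ref`, the per-quantity simulation-vs-experiment
#' comparison statistic.
#'
#' @param sim simulated value(s).
#' @param ref reference value(s), > 0.
#' @return Percent difference, same shape as the inputs.
#' @export
relative_difference <- function(sim, ref) {
  if (any(ref <= 0)) stop("reference values must be > 0")
  100 * abs(sim - ref) / ref
}

#' Axial absorption profile under the beam axis
#'
#' Samples the absorbed power density along the z column through
#' `(x, y) = (0, 0)`, reported against depth from the current surface -- the
#' first voxel on the column that is still present is depth 0, so after
#' vaporization the profile starts at the crater floor.
#'
#' @param field an [compute_absorption()] result or any list with a 3D `S`.
#' @param grid the matching [build_grid()] lattice.
#' @return Data frame with `depth` (mm, voxel centres from the current
#'   surface) and `S` (W/mm^3).
#' @export
axial_absorption_profile <- function(field, grid) {
  S <- if (is.list(field)) field$S else field
  i_mid <- max(1L, grid$shape[1] %/% 2L)
  j_mid <- max(1L, grid$shape[2] %/% 2L)
  column <- S[i_mid, j_mid, ]
  mat <- grid$material_id[i_mid, j_mid, ]
  first <- which(mat == MAT_TISSUE)
  start <- if (length(first)) min(first) else 1L
  nz <- grid$shape[3]
  data.frame(
    depth = (seq.int(start, nz) - start + 0.5) * grid$voxel_size,
    S = column[start:nz])
}
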