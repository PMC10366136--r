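#' Write a scenario to a YAML configuration file
#'
#' @param sc a [scenario()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(sc, path) {
  doc <- list(
    name = sc$name,
    grid = list(shape = as.integer(sc$shape), voxel_size = sc$voxel_size,
                air_thickness = sc$air_thickness,
                tissue_thickness = sc$tissue_thickness),
    materials = lapply(sc$materials, function(m) unclass(m)),
    beam = list(power = sc$beam$power, diameter_1e2 = sc$beam$diameter_1e2,
                start_xy = sc$beam$start_xy, end_xy = sc$beam$end_xy,
                speed = sc$beam$speed),
    schedule = list(dt = sc$schedule$dt, t_heat = sc$schedule$t_heat,
                    t_laser_off = sc$schedule$t_laser_off,
                    n_photons = sc$schedule$n_photons,
                    seed = sc$schedule$seed),
    damage = list(A = sc$damage$A, E_a = sc$damage$E_a),
    expected = sc$expected)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a scenario from a YAML configuration file
#'
#' Material blocks may carry an optional `units:` map (e.g.
#' `units: {k: "W/(cm K)", rho: "g/cm^3", mu: "1/cm"}`); listed fields are
#' converted to the internal mm/g/s/J/C system through [convert_property()].
#' The `mu` entry applies to all three optical coefficients.
#'
#' @param path YAML file written by [write_scenario()] or by hand.
#' @return A [scenario()].
#' @export
read_scenario <- function(path) {
  doc <- yaml::read_yaml(path)
  mats <- lapply(doc$materials, function(m) {
    units <- m$units
    m$units <- NULL
    if (!is.null(units)) {
      if (!is.null(units$k)) m$k <- convert_property(m$k, units$k)
      if (!is.null(units$rho)) m$rho <- convert_property(m$rho, units$rho)
      if (!is.null(units$mu)) {
        for (f in c("mu_a", "mu_s_prime_native", "mu_s_prime_coagulated")) {
          m[[f]] <- convert_property(m[[f]], units$mu)
        }
      }
    }
    do.call(material_properties, m)
  })
  scenario(
    name = doc$name,
    shape = doc$grid$shape, voxel_size = doc$grid$voxel_size,
    air_thickness = doc$grid$air_thickness,
    tissue_thickness = doc$grid$tissue_thickness,
    materials = mats,
    beam = beam_config(power = doc$beam$power,
                       diameter_1e2 = doc$beam$diameter_1e2,
                       start_xy = unlist(doc$beam$start_xy),
                       end_xy = unlist(doc$beam$end_xy),
                       speed = doc$beam$speed),
    schedule = schedule_config(dt = doc$schedule$dt,
                               t_heat = doc$schedule$t_heat,
                               t_laser_off = doc$schedule$t_laser_off,
                               n_photons = doc$schedule$n_photons,
                               seed = if (is.null(doc$schedule$seed)) 1L
                                      else doc$schedule$seed),
    damage = arrhenius_params(A = doc$damage$A, E_a = doc$damage$E_a),
    expected = if (is.null(doc$expected)) "none" else doc$expected)
}

#' Export a volumetric field as NIfTI
#'
#' Writes a 3D array with the voxel size recorded in the header pixdim (mm),
#' so lesion volumes overlay correctly in standard viewers.
#'
#' @param volume 3D numeric or logical array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size voxel edge length (mm).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, voxel_size) {
  img <- RNifti::asNifti(array(as.numeric(volume), dim = dim(volume)))
  RNifti::pixdim(img) <- rep(voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write lesion metrics rows as CSV
#'
#' One row per run: condition label, power, speed, then the six lesion
#' metrics from [lesion_metrics()].
#'
#' @param results named list of `ablation_result` objects.
#' @param path output CSV path.
#' @return The assembled data frame, invisibly.
#' @export
write_metrics_csv <- function(results, path) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    cbind(data.frame(condition = nm, power = r$meta$power,
                     speed = r$meta$speed, dop = r$meta$dop),
          lesion_metrics(r))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write per-window transport tallies as JSON
#'
#' @param result an `ablation_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_tallies_json <- function(result, path) {
  jsonlite::write_json(
    list(meta = result$meta, tallies = result$tallies),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
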