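# Shared fixture builders. Everything is generated in code; no data files.

# tissue that only absorbs: photons travel straight and deposit fully at the
# first interaction, so the axial profile is exactly Beer-Lambert
absorbing_materials <- function(mu_a = 1) {
  m <- liver_materials()
  m$tissue <- material_properties(
    mu_a = mu_a, mu_s_prime_native = 0, g = 0, n = 1,
    k = 5.1e-4, rho = 1e-3, c_p = 3.6)
  m
}

# scattering tissue with the refractive index matched to air, so a
# continuous-space slab oracle with no Fresnel events is comparable
matched_scatter_materials <- function(mu_a = 0.5, mu_s_prime = 2, g = 0.9) {
  m <- liver_materials()
  m$tissue <- material_properties(
    mu_a = mu_a, mu_s_prime_native = mu_s_prime, g = g, n = 1,
    k = 5.1e-4, rho = 1e-3, c_p = 3.6)
  m
}

# all-tissue block (no air) for pure conduction tests
tissue_block <- function(n = 21, h = 0.1) {
  build_grid(c(n, n, n), h, air_thickness = 0, tissue_thickness = n * h)
}

# very small but complete scenario for fast end-to-end runs (~1 s)
mini_scenario <- function(power = 30, speed = 2, t_laser_off = 0.2,
                          n_photons = 300, seed = 1L) {
  scenario(
    name = "mini",
    shape = c(16L, 16L, 12L), voxel_size = 0.25,
    air_thickness = 1, tissue_thickness = 2,
    beam = beam_config(power = power, diameter_1e2 = 1.4,
                       start_xy = c(0, -0.5), end_xy = c(0, 0.5),
                       speed = speed),
    schedule = schedule_config(dt = 4e-4, t_heat = 0.05,
                               t_laser_off = t_laser_off,
                               n_photons = n_photons, seed = seed,
                               roulette_threshold = 1e-3),
    expected = "none")
}
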