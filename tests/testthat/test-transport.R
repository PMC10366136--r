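test_that("beam sampling reproduces the 1/e^2 Gaussian convention", {
  b <- beam_config(power = 10, diameter_1e2 = 2.8,
                   start_xy = c(0, -10), end_xy = c(0, 10), speed = 1)
  expect_equal(b$sigma, 0.7)          # 1/e^2 radius = 2 sigma
  expect_equal(b$t_on, 20)            # 20 mm path at 1 mm/s
  set.seed(5)
  s <- sample_beam_photon(b, center_xy = c(0.3, -1.2), n = 1e5)
  expect_equal(sd(s$position[, "x"]), b$diameter_1e2 / 4, tolerance = 0.01)
  expect_equal(sd(s$position[, "y"]), b$diameter_1e2 / 4, tolerance = 0.01)
  # mean launch position is the beam axis (3 standard errors)
  se <- b$sigma / sqrt(1e5)
  expect_lt(abs(mean(s$position[, "x"]) - 0.3), 3 * se)
  expect_lt(abs(mean(s$position[, "y"]) + 1.2), 3 * se)
  expect_true(all(s$direction[, "uz"] == 1))
  expect_true(all(s$weight == 1))
  # degenerate beam collapses onto the axis
  b0 <- beam_config(power = 1, diameter_1e2 = 1e-12,
                    start_xy = c(0, 0), end_xy = c(0, 1), speed = 1)
  s0 <- sample_beam_photon(b0, c(1, 2), n = 100)
  expect_equal(max(abs(s0$position[, "x"] - 1)), 0, tolerance = 1e-9)
})

test_that("specular reflectance at the air-tissue interface matches Fresnel", {
  g <- build_grid(c(40, 40, 40), 0.1, 1, 3)
  opt <- update_optical_field(g, 0)
  b <- beam_config(power = 1, diameter_1e2 = 1,
                   start_xy = c(0, 0), end_xy = c(0, 0.001), speed = 1)
  f <- compute_absorption(g, opt, b, c(0, 0), n_photons = 2e4, seed = 7)
  R_expected <- ((1.44 - 1) / (1.44 + 1))^2   # 0.0325 at normal incidence
  se <- sqrt(R_expected * (1 - R_expected) / 2e4)
  expect_lt(abs(f$tallies$specular - R_expected), 3 * se + 1e-3)
})

test_that("energy balance closes exactly and the field is deterministic", {
  g <- build_grid(c(30, 30, 30), 0.1, 1, 2)
  opt <- update_optical_field(g, 0.5)
  b <- beam_config(power = 2, diameter_1e2 = 1.4,
                   start_xy = c(0, 0), end_xy = c(0, 1), speed = 1)
  f1 <- compute_absorption(g, opt, b, c(0, 0.2), n_photons = 5e3, seed = 42)
  t <- f1$tallies
  closure <- t$absorbed + t$escaped + t$specular -
    (t$launched + t$roulette_gain - t$roulette_loss)
  expect_lt(abs(closure), 1e-9)
  expect_true(all(f1$S >= 0))
  expect_true(all(f1$S[g$material_id != 1L] == 0))
  # S integrates to power x absorbed fraction
  expect_equal(sum(f1$S) * g$voxel_size^3, b$power * t$absorbed,
               tolerance = 1e-9)
  # bit-identical under the same seed
  f2 <- compute_absorption(g, opt, b, c(0, 0.2), n_photons = 5e3, seed = 42)
  expect_identical(f1$S, f2$S)
  expect_identical(f1$tallies, f2$tallies)
})

test_that("a conservative medium absorbs nothing", {
  m <- liver_materials()
  m$tissue <- material_properties(mu_a = 0, mu_s_prime_native = 0.5,
                                  g = 0.9, n = 1.44,
                                  k = 5.1e-4, rho = 1e-3, c_p = 3.6)
  g <- build_grid(c(20, 20, 20), 0.1, 0.5, 1.5, materials = m)
  f <- compute_absorption(g, update_optical_field(g, 0),
                          beam_config(1, 1, c(0, 0), c(0, 0.001), 1),
                          n_photons = 2e3, seed = 3)
  expect_equal(f$tallies$absorbed, 0)
  expect_equal(sum(f$S), 0)
  expect_equal(f$tallies$escaped + f$tallies$specular, 1, tolerance = 1e-9)
})

test_that("pure absorber reproduces Beer-Lambert depth deposition", {
  mu_a <- 1
  g <- build_grid(c(20, 20, 60), 0.1, 1, 5,
                  materials = absorbing_materials(mu_a))
  opt <- update_optical_field(g, 0)
  b <- beam_config(power = 1, diameter_1e2 = 1e-9,
                   start_xy = c(0, 0), end_xy = c(0, 1e-6), speed = 1)
  n <- 5e4
  f <- compute_absorption(g, opt, b, c(0, 0), n_photons = n, seed = 1)
  # total absorbed fraction for a 5 mm slab at mu_a = 1/mm
  expect_equal(f$tallies$absorbed, 1 - exp(-5), tolerance = 3 * sqrt(exp(-5) / n) + 2e-3)
  # per-slice absorbed weight is multinomial around the closed form
  w_slice <- apply(f$S, 3, sum) * g$voxel_size^3 / b$power
  zi <- 11:40   # first 3 mm of tissue
  edges <- (zi - 11) * 0.1
  p <- exp(-mu_a * edges) - exp(-mu_a * (edges + 0.1))
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(w_slice[zi] - p) < 3 * se + 1e-4))
})

test_that("higher scattering pulls deposited energy toward the surface", {
  g <- build_grid(c(40, 40, 40), 0.1, 1, 3)
  b <- beam_config(power = 1, diameter_1e2 = 1.4,
                   start_xy = c(0, 0), end_xy = c(0, 0.001), speed = 1)
  depth_mean <- function(alpha) {
    f <- compute_absorption(g, update_optical_field(g, alpha), b, c(0, 0),
                            n_photons = 1e4, seed = 9)
    w <- apply(f$S, 3, sum)
    z <- seq_along(w)
    sum(w * z) / sum(w)
  }
  expect_gt(depth_mean(0), depth_mean(1))  # coagulated optics: shallower
})

test_that("independent slab oracle agrees with the voxel kernel in depth", {
  mu_a <- 0.5; mu_sp <- 2; g_hg <- 0.9
  L <- 3; bw <- 0.25; n <- 2e4
  m <- matched_scatter_materials(mu_a, mu_sp, g_hg)
  vox <- build_grid(c(60, 60, 34), 0.1, 0.4, 3, materials = m)
  opt <- update_optical_field(vox, 0)
  b <- beam_config(power = 1, diameter_1e2 = 1e-9,
                   start_xy = c(0, 0), end_xy = c(0, 1e-6), speed = 1)
  f <- compute_absorption(vox, opt, b, c(0, 0), n_photons = n, seed = 21,
                          roulette_threshold = 1e-3)
  w_slice <- apply(f$S, 3, sum) * vox$voxel_size^3 / b$power
  # regroup the 0.1 mm tissue slices (5..34) into 0.25 mm oracle bins:
  # use 0.5 mm super-bins so both discretizations nest
  w_tis <- w_slice[5:34]
  sim_bins <- colSums(matrix(w_tis, nrow = 5))            # 6 bins of 0.5 mm
  orc <- slab_mc_oracle(n, mu_a, mu_sp / (1 - g_hg), g_hg, L, bw, seed = 33)
  orc_bins <- colSums(matrix(orc$absorbed_per_bin, nrow = 2))
  se <- sqrt(pmax(orc_bins * (1 - orc_bins), 1e-6) * 2 / n)  # both stochastic
  expect_true(all(abs(sim_bins - orc_bins) < 3 * se + 0.01))
})

test_that("degenerate inputs are caught", {
  g <- build_grid(c(10, 10, 10), 0.1, 0.5, 0.5)
  opt <- update_optical_field(g, 0)
  b <- beam_config(power = 1, diameter_1e2 = 0.5,
                   start_xy = c(0, 0), end_xy = c(0, 0.001), speed = 1)
  expect_warning(
    f <- compute_absorption(g, opt, b, center_xy = c(50, 0), n_photons = 10),
    "outside")
  expect_equal(sum(f$S), 0)
  expect_error(compute_absorption(g, opt, b, n_photons = 0), "n_photons")
})
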