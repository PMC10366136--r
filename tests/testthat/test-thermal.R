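test_that("enthalpy-temperature map has the latent-heat plateau", {
  tis <- liver_materials()$tissue
  rcp <- tis$rho * tis$c_p
  expect_equal(enthalpy_to_temperature(0, tis), 0)
  expect_equal(enthalpy_to_temperature(rcp * 50, tis), 50)
  # halfway through vaporization the temperature is clamped at T_v
  expect_equal(enthalpy_to_temperature(tis$rho * (tis$c_p * tis$T_v + tis$L_v / 2), tis),
               tis$T_v)
  # continuity at the plateau onset
  expect_equal(enthalpy_to_temperature(rcp * tis$T_v, tis), tis$T_v)
  # enthalpy past the removal threshold flags a missed removal
  expect_error(enthalpy_to_temperature(threshold_enthalpy(tis) * 1.01, tis),
               "missed removal")
  expect_error(enthalpy_to_temperature(-1, tis), "H must be")
})

test_that("threshold enthalpy is rho (c_p T_v + L_v)", {
  w <- material_properties(mu_a = 0, mu_s_prime_native = 0, g = 0, n = 1,
                           k = 6e-4, rho = 0.001, c_p = 4.2,
                           T_v = 100, L_v = 2257)
  expect_equal(threshold_enthalpy(w), 2.677)
  w0 <- material_properties(mu_a = 0, mu_s_prime_native = 0, g = 0, n = 1,
                            k = 6e-4, rho = 0.001, c_p = 4.2,
                            T_v = 100, L_v = 0)
  expect_equal(threshold_enthalpy(w0), 0.001 * 4.2 * 100)
  w2 <- material_properties(mu_a = 0, mu_s_prime_native = 0, g = 0, n = 1,
                            k = 6e-4, rho = 0.002, c_p = 4.2,
                            T_v = 100, L_v = 2257)
  expect_equal(threshold_enthalpy(w2), 2 * threshold_enthalpy(w))
})

test_that("stability bound scales as the FTCS criterion", {
  tis <- liver_materials()$tissue
  expect_equal(stability_limit(tis, 0.1),
               tis$rho * tis$c_p * 0.01 / (6 * tis$k))
  expect_equal(stability_limit(tis, 0.2), 4 * stability_limit(tis, 0.1))
  k0 <- material_properties(mu_a = 0, mu_s_prime_native = 0, g = 0, n = 1,
                            k = 0, rho = 1, c_p = 1)
  expect_true(is.infinite(stability_limit(k0, 0.1)))
  # the reference settings are stable at dt = 1e-5 s on 0.1 mm voxels
  g <- build_grid(c(4, 4, 4), 0.1, 0.2, 0.2)
  expect_lt(1e-5, grid_stability_limit(g))
  # and the solver refuses an unstable step
  st <- initial_state(g)
  expect_error(step_enthalpy(st, g, dt = 1), "stability")
})

test_that("uniform temperature with no source is a fixed point", {
  g <- build_grid(c(6, 6, 6), 0.1, 0.2, 0.4)   # mixed air/tissue
  st <- initial_state(g, 22)
  st2 <- step_enthalpy(st, g, dt = 1e-5, n_steps = 50)
  expect_equal(st2$H, st$H, tolerance = 1e-14)
  expect_equal(max(abs(st2$T - 22)), 0, tolerance = 1e-12)
})

test_that("adiabatic stepping conserves total enthalpy to machine precision", {
  g <- build_grid(c(10, 10, 10), 0.1, 0.3, 0.7)  # dissimilar-material faces
  st <- initial_state(g, 22)
  st$H[5, 5, 7] <- st$H[5, 5, 7] * 10            # localized hot spot
  total0 <- sum(st$H)
  st2 <- step_enthalpy(st, g, dt = 5e-5, n_steps = 1000)
  drift <- abs(sum(st2$H) - total0) / total0
  expect_lt(drift / 1000, 1e-12)                 # per-step relative drift
})

test_that("conduction obeys the maximum principle", {
  g <- tissue_block(9, 0.1)
  st <- initial_state(g, 20)
  set.seed(7)
  st$H <- st$H * array(runif(prod(g$shape), 0.5, 1.5), dim = g$shape)
  lo <- min(st$T <- st$H / (g$materials$tissue$rho * g$materials$tissue$c_p))
  hi <- max(st$T)
  st2 <- step_enthalpy(st, g, dt = 0.005, n_steps = 200)
  expect_gte(min(st2$T), lo - 1e-12)
  expect_lte(max(st2$T), hi + 1e-12)
})

test_that("plateau clamps temperature at T_v during strong heating", {
  g <- tissue_block(5, 0.1)
  st <- initial_state(g, 22)
  st$S <- array(5, dim = g$shape)   # W/mm^3, uniform volumetric source
  clamped <- FALSE
  for (i in 1:30) {
    st <- step_enthalpy(st, g, dt = 0.01, n_steps = 10)
    expect_lte(max(st$T), g$materials$tissue$T_v + 1e-9)
    if (max(st$H) > g$materials$tissue$rho * g$materials$tissue$c_p *
          g$materials$tissue$T_v) clamped <- TRUE
  }
  expect_true(clamped)   # the run did enter the plateau regime
})
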