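test_that("reference scenario set covers both power regimes", {
  scs <- make_reference_scenarios(scaled = FALSE)
  expect_length(scs, 6)
  powers <- vapply(scs, function(s) s$beam$power, numeric(1))
  speeds <- vapply(scs, function(s) s$beam$speed, numeric(1))
  expect_equal(sort(unique(powers)), c(10, 50))
  expect_equal(unname(speeds[powers == 50]), c(0.5, 0.75, 1.0))
  expect_equal(unname(speeds[powers == 10]), c(1.0, 1.25, 1.5))
  for (s in scs) {
    expect_identical(s$shape, c(300L, 300L, 150L))
    expect_equal(s$beam$path_length, 20)
    expect_equal(s$schedule$dt, 1e-5)
    expect_equal(s$schedule$t_heat, 2e-3)
    expect_lt(s$groups$stability_ratio, 1)
    expect_equal(s$expected,
                 if (s$beam$power == 50) "coagulation_and_vaporization"
                 else "coagulation_only")
  }
  # cooling: 30 s after high power, 10 s after low power
  expect_equal(scs[["high_50W_0.5mms"]]$schedule$t_laser_off, 30)
  expect_equal(scs[["low_10W_1mms"]]$schedule$t_laser_off, 10)
})

test_that("scaled twins keep the irradiation conditions and stay stable", {
  scs <- make_reference_scenarios(scaled = TRUE)
  expect_length(scs, 12)
  for (nm in grep("_scaled$", names(scs), value = TRUE)) {
    tw <- scs[[nm]]
    full <- scs[[sub("_scaled$", "", nm)]]
    expect_equal(tw$beam$power, full$beam$power)
    expect_equal(tw$beam$speed, full$beam$speed)
    expect_equal(tw$beam$diameter_1e2, full$beam$diameter_1e2)
    expect_equal(tw$beam$path_length, 4)
    expect_lt(tw$groups$stability_ratio, 1)
    expect_equal(tw$expected, full$expected)
    # same tissue optics => same optical depth per unit thickness
    expect_equal(tw$groups$optical_depth / tw$tissue_thickness,
                 full$groups$optical_depth / full$tissue_thickness)
  }
  # an unstable schedule is rejected at construction
  expect_error(
    scenario("bad", c(10L, 10L, 10L), 0.1, 0.5, 0.5,
             beam = beam_config(1, 1, c(0, 0), c(0, 1), 1),
             schedule = schedule_config(dt = 1e-3, t_heat = 1e-2,
                                        t_laser_off = 0)),
    "stability")
})

test_that("DOP reference curve saturates toward the coagulated value", {
  tab <- make_dop_reference_curve(native = 1.0, coagulated = 2.65,
                                  omegas = 0:5)
  expect_equal(tab$mu_s_prime[tab$Omega == 0], 1.0)
  # Omega = 5 is within 1% of full coagulation (alpha = 99.3%)
  expect_lt(abs(tab$mu_s_prime[tab$Omega == 5] - 2.65) / 2.65, 0.01)
  # increments shrink as Omega grows: fast rise to Omega = 1, then saturation
  inc <- diff(tab$mu_s_prime)
  expect_true(all(diff(inc) < 0))
  expect_true(all(inc > 0))
  expect_error(make_dop_reference_curve(2, 1), "coagulated")
})

test_that("scenario YAML round-trips, including unit conversion", {
  sc <- mini_scenario()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_equal(back$shape, sc$shape)
  expect_equal(back$materials$tissue$mu_a, sc$materials$tissue$mu_a)
  expect_equal(back$beam$power, sc$beam$power)
  expect_equal(back$schedule$dt, sc$schedule$dt)
  expect_equal(back$damage$A, sc$damage$A)

  # hand-written config quoting literature units
  doc <- yaml::read_yaml(path)
  doc$materials$tissue$k <- 5.1e-3            # W/(cm K)
  doc$materials$tissue$rho <- 1.0             # g/cm^3
  doc$materials$tissue$mu_a <- 0.7            # 1/cm
  doc$materials$tissue$mu_s_prime_native <- 10
  doc$materials$tissue$mu_s_prime_coagulated <- 26.5
  doc$materials$tissue$units <- list(k = "W/(cm K)", rho = "g/cm^3",
                                     mu = "1/cm")
  yaml::write_yaml(doc, path)
  conv <- read_scenario(path)
  expect_equal(conv$materials$tissue$k, 5.1e-4)
  expect_equal(conv$materials$tissue$rho, 1e-3)
  expect_equal(conv$materials$tissue$mu_a, 0.07)
  expect_equal(conv$materials$tissue$mu_s_prime_coagulated, 2.65)
})

test_that("volumes, metrics tables and tally logs round-trip to disk", {
  sc <- mini_scenario(power = 40)
  r <- run_scenario(sc, seed = 2)
  d <- withr::local_tempdir()

  nii <- file.path(d, "T.nii.gz")
  write_volume(r$state$T, nii, sc$voxel_size)
  back <- RNifti::readNifti(nii)
  expect_equal(dim(back), as.integer(sc$shape))
  expect_equal(max(abs(back - r$state$T)), 0, tolerance = 1e-6)
  expect_equal(RNifti::pixdim(back)[1], sc$voxel_size, tolerance = 1e-6)

  csv <- file.path(d, "metrics.csv")
  df <- write_metrics_csv(list(mini = r), csv)
  re <- utils::read.csv(csv)
  expect_equal(nrow(re), 1)
  expect_equal(re$vap_area, df$vap_area)
  expect_true(all(c("condition", "power", "speed", "coag_area") %in% names(re)))

  js <- file.path(d, "tallies.json")
  write_tallies_json(r, js)
  log <- jsonlite::read_json(js)
  expect_equal(length(log$tallies), nrow(r$tallies))
  expect_equal(log$meta$seed, 2)
})
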