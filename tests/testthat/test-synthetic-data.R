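test_that("enzyme dosing arithmetic matches the preparation activities", {
  d20 <- enzyme_dose(20)
  expect_equal(d20$bg_iu_per_g_glucan, 124.2, tolerance = 1e-4)
  expect_equal(d20$prep_g_per_g_glucan, 20 / 95)
  d10 <- enzyme_dose(10)
  expect_equal(d10$bg_iu_per_g_glucan, 62.1, tolerance = 1e-4)
  d0 <- enzyme_dose(0)
  expect_equal(unlist(d0), c(prep_g_per_g_glucan = 0, bg_iu_per_g_glucan = 0))
  expect_error(enzyme_dose(10, cellulase_activity = 0), "> 0")
})

test_that("dilution conserves mass and dilutes the dissolved glucose", {
  raw <- slurry_composition() # 13% WIS, 29.8 g/L glucose
  dil <- dilute_slurry(raw, 10)
  expect_equal(dil$water_added_kg_per_kg, 0.30)
  expect_equal(dil$diluted_glucose_g_L, 22.159, tolerance = 1e-4)
  expect_equal(dil$composition$wis0, 10)
  # mass balance: solids unchanged, glucose mass conserved (1 kg/L liquid)
  solids_before <- 0.13
  solids_after <- (1 + dil$water_added_kg_per_kg) * 0.10
  expect_equal(solids_before, solids_after, tolerance = 1e-12)
  glucose_before <- 29.8 * (1 - 0.13)
  glucose_after <- dil$diluted_glucose_g_L *
    ((1 - 0.13) + dil$water_added_kg_per_kg)
  expect_equal(glucose_before, glucose_after, tolerance = 1e-12)
  # identity dilution
  same <- dilute_slurry(raw, 13)
  expect_equal(same$water_added_kg_per_kg, 0)
  expect_equal(same$composition$initial_liquid_glucose, 29.8)
  expect_error(dilute_slurry(raw, 15), "exceeds")
})

test_that("conversion-model calibration reproduces the printed anchors", {
  m <- calibrate_conversion_model()
  # tau solves (1-u)/(1-u^2) = 57/72, u = exp(-48/tau) -> u = 15/57
  expect_equal(m$tau, -48 / log(15 / 57), tolerance = 1e-9)
  expect_equal(m$tau, 35.955, tolerance = 1e-4)
  expect_equal(m$p, log(0.54 / 0.72) / log(10 / 20), tolerance = 1e-9)
  expect_equal(m$p, 0.41504, tolerance = 1e-4)
  a <- default_anchors()
  pred <- predict_conversion(m, a$time, a$impeller_speed, a$enzyme_load)
  expect_equal(pred, a$conversion, tolerance = 1e-8)
})

test_that("conversion-model calibration rejects infeasible anchor sets", {
  a <- default_anchors()
  bad <- a
  bad$conversion[3] <- 0.50 # lower at 96 h than at 48 h: non-monotone
  expect_error(calibrate_conversion_model(bad), "calibration error")
  superlin <- a
  superlin$conversion[1] <- 0.30 # x(48)/x(96) < 48/96: super-linear growth
  expect_error(calibrate_conversion_model(superlin), "calibration error")
  expect_error(calibrate_conversion_model(a[1:3, ]), ">= 4 anchors")
  expect_error(calibrate_conversion_model(data.frame(x = 1)), "columns")
})

test_that("conversion curves start at zero and stay monotone on the calibrated box", {
  m <- fx_conv_model()
  expect_equal(predict_conversion(m, 0, 500, 20), 0)
  t <- seq(0, 96, by = 2)
  for (rpm in c(25, 150, 500)) {
    for (load in c(10, 20)) {
      x <- predict_conversion(m, t, rpm, load)
      expect_true(all(x >= 0 & x <= 1))
      expect_true(all(diff(x) > 0))
    }
  }
  # monotone in speed and load at fixed time
  for (tt in c(12, 48, 96)) {
    expect_true(all(diff(predict_conversion(m, tt, seq(25, 500, 25), 20)) > 0))
    expect_true(all(diff(predict_conversion(m, tt, 300, c(10, 15, 20))) > 0))
  }
  expect_warning(predict_conversion(m, 48, 700, 20), "extrapolating")
  expect_warning(predict_conversion(m, 48, 500, 5), "extrapolating")
})

test_that("conversion_curve respects the grid contract", {
  m <- fx_conv_model()
  cond <- hydrolysis_conditions(500, 20, duration = 96)
  cc <- conversion_curve(m, cond, grid = seq(0, 96, by = 4))
  expect_s3_class(cc, "conversion_curve")
  expect_equal(cc$conversion[1], 0)
  expect_equal(cc$conversion[cc$time_h == 48], 0.57, tolerance = 1e-8)
  expect_error(conversion_curve(m, cond, grid = c(0, 10, 5)), "sorted")
  expect_error(conversion_curve(m, cond, grid = c(0, 100)), "duration")
})

test_that("WIS declines linearly with conversion by glucan mass balance", {
  comp <- hydrolysis_composition() # 10% WIS, glucan 0.48
  expect_equal(wis_from_conversion(0, comp), 10)
  expect_equal(wis_from_conversion(0.72, comp), 6.544)
  expect_equal(wis_from_conversion(1, comp), 5.2)
  x <- seq(0, 1, by = 0.05)
  expect_true(all(diff(wis_from_conversion(x, comp)) < 0))
  expect_error(wis_from_conversion(1.2, comp), "\\[0, 1\\]")
  expect_error(wis_from_conversion(-0.1, comp), "\\[0, 1\\]")
})

test_that("glucose mapping uses the hydration factor and round-trips exactly", {
  comp <- hydrolysis_composition()
  expect_equal(glucose_from_conversion(0, comp), 22.159, tolerance = 1e-4)
  released <- glucose_from_conversion(1, comp) - glucose_from_conversion(0, comp)
  expect_equal(released, 48 * 180 / 162) # 53.33 g/L from 48 g/L glucan
  x <- seq(0, 1, by = 0.01)
  back <- conversion_from_glucose(glucose_from_conversion(x, comp), comp)
  expect_equal(back, x, tolerance = 1e-12)
})

test_that("noisy glucose sampling is seeded, scoped and calibrated", {
  m <- fx_conv_model()
  cc <- conversion_curve(m, hydrolysis_conditions(500, 20),
                         grid = seq(0, 96, by = 0.05))
  comp <- hydrolysis_composition()
  clean <- sample_noisy_glucose(cc, comp, cv = 0)
  expect_equal(clean$glucose_obs_g_L, clean$glucose_g_L)
  s1 <- sample_noisy_glucose(cc, comp, cv = 0.04, seed = 99)
  s2 <- sample_noisy_glucose(cc, comp, cv = 0.04, seed = 99)
  expect_identical(s1$glucose_obs_g_L, s2$glucose_obs_g_L)
  # seeding is scoped: caller RNG stream unaffected
  withr::with_seed(1, {
    before <- runif(1)
    sample_noisy_glucose(cc, comp, cv = 0.04, seed = 99)
  })
  withr::with_seed(1, after <- runif(1))
  expect_identical(before, after)
  # empirical CV of the multiplicative noise near nominal 4%
  ratio <- s1$glucose_obs_g_L / s1$glucose_g_L - 1
  expect_gt(sd(ratio), 0.035)
  expect_lt(sd(ratio), 0.045)
})

test_that("simulated power observations round-trip through the fit", {
  truth <- default_power_correlation()
  grid <- 10^seq(0, 4, length.out = 60)
  exact <- simulate_power_observations(truth, grid)
  expect_equal(exact$p0, power_number(grid, truth))
  fit <- fit_power_correlation(exact)
  expect_equal(fit$K1, truth$K1, tolerance = 1e-8)
  expect_equal(fit$K2, truth$K2, tolerance = 1e-8)
  n1 <- simulate_power_observations(truth, grid, noise_cv = 0.05, seed = 3)
  n2 <- simulate_power_observations(truth, grid, noise_cv = 0.05, seed = 3)
  expect_identical(n1, n2)
  expect_false(identical(
    n1$p0,
    simulate_power_observations(truth, grid, noise_cv = 0.05, seed = 4)$p0))
})

test_that("composition and condition constructors validate ranges", {
  expect_error(slurry_composition(wis0 = 0), "> 0")
  expect_error(slurry_composition(wis0 = 45), "<= 40")
  expect_error(slurry_composition(glucan_frac_of_wis = 1.4), "\\[0, 1\\]")
  expect_error(hydrolysis_conditions(1200, 20), "<= 1000")
  expect_error(hydrolysis_conditions(500, 0), "> 0")
  expect_error(hydrolysis_conditions(500, 20, wis_initial = 25), "<= 20")
})
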