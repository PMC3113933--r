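test_that("average shear rate is K_s * N", {
  m <- illustration_rheology()
  expect_equal(average_shear_rate(rpm_to_rps(500), m), 95.833, tolerance = 1e-4)
  expect_equal(average_shear_rate(rpm_to_rps(25), m), 4.7917, tolerance = 1e-4)
  expect_identical(average_shear_rate(0, m), 0)
  expect_error(average_shear_rate(-1, m), ">= 0")
})

test_that("consistency index follows a * WIS^b and its limits", {
  m <- illustration_rheology()
  expect_equal(consistency_index(12, m), 14.14214, tolerance = 1e-6)
  expect_equal(consistency_index(10, m), 14.14214 * (10 / 12)^5,
               tolerance = 1e-6)
  expect_equal(consistency_index(10, m), 5.683407, tolerance = 1e-6)
  flat <- rheology_model(a = 3.2, b = 0, n_pl = 0.7)
  expect_equal(consistency_index(c(1, 10, 40), flat), rep(3.2, 3))
  expect_error(consistency_index(0, m), "> 0")
  expect_error(consistency_index(50, m), "<= 40")
})

test_that("apparent viscosity reproduces the printed anchor and arithmetic", {
  m <- illustration_rheology()
  expect_equal(apparent_viscosity(50, 12, m), 2.0, tolerance = 1e-10)
  expect_equal(apparent_viscosity(95.83, 10, m), 0.581, tolerance = 1e-3)
  newt <- rheology_model(a = 0.5, b = 2, n_pl = 1)
  expect_equal(apparent_viscosity(c(1, 10, 1000), 10, newt),
               rep(consistency_index(10, newt), 3))
  expect_error(apparent_viscosity(0, 10, m), "> 0")
  expect_error(apparent_viscosity(-5, 10, m), "> 0")
})

test_that("viscosity is monotone in shear rate and WIS, with power-law scaling", {
  m <- illustration_rheology()
  gammas <- 10^seq(-1, 3, length.out = 41)
  mu <- apparent_viscosity(gammas, 10, m)
  expect_true(all(diff(mu) < 0)) # strictly shear-thinning for n < 1
  wis_grid <- seq(1, 15, by = 0.5)
  expect_true(all(diff(apparent_viscosity(50, wis_grid, m)) > 0))
  # scaling identity mu(c*gamma) = c^(n-1) mu(gamma)
  for (cc in c(0.3, 2, 17)) {
    expect_equal(apparent_viscosity(cc * gammas, 10, m),
                 cc^(m$n_pl - 1) * apparent_viscosity(gammas, 10, m),
                 tolerance = 1e-12)
  }
})

test_that("calibration pins the prefactor and round-trips the anchor", {
  m <- calibrate_rheology(2.0, 12, 50, b = 5, n_pl = 0.5)
  expect_equal(m$a, 2.0 * 50^0.5 / 12^5, tolerance = 1e-12)
  expect_equal(m$a, 5.683407e-5, tolerance = 1e-6)
  expect_equal(calibrate_rheology(1.0, 1, 1, b = 1, n_pl = 1)$a, 1.0)
  # property: round trip to 1e-10 relative over random anchors/exponents
  withr::with_seed(7, {
    for (i in 1:25) {
      anc <- list(mu = runif(1, 0.1, 20), wis = runif(1, 2, 20),
                  g = runif(1, 1, 200))
      b <- runif(1, 0.5, 12); n <- runif(1, 0.1, 1)
      mod <- calibrate_rheology(anc$mu, anc$wis, anc$g, b = b, n_pl = n)
      expect_equal(apparent_viscosity(anc$g, anc$wis, mod), anc$mu,
                   tolerance = 1e-10)
    }
  })
  expect_error(calibrate_rheology(-1, 12, 50, b = 5, n_pl = 0.5), "> 0")
  expect_error(calibrate_rheology(2, 0, 50, b = 5, n_pl = 0.5), "> 0")
})

test_that("model constructor enforces its invariants", {
  expect_error(rheology_model(a = -1, b = 5, n_pl = 0.5), "> 0")
  expect_error(rheology_model(a = 1, b = 5, n_pl = 0), "> 0")
  expect_error(rheology_model(a = 1, b = 5, n_pl = 1.2), "<= 1")
  expect_error(rheology_model(a = 1, b = 5, n_pl = 0.5, K_s = -2), "> 0")
  expect_s3_class(rheology_model(a = 1, b = 5, n_pl = 1), "rheology_model")
})
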