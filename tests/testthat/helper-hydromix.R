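# Shared fixtures, built in code.

# Illustration rheology of the worked examples: b = 5, n = 0.5, prefactor
# pinned to the 2 Pa.s @ (12% WIS, 50/s) anchor -> a = 5.683407e-5.
illustration_rheology <- function() {
  calibrate_rheology(2.0, 12, 50, b = 5, n_pl = 0.5)
}

# Default calibrated components, computed once per test run.
.fixtures <- new.env(parent = emptyenv())

fx_conv_model <- function() {
  if (is.null(.fixtures$conv)) .fixtures$conv <- calibrate_conversion_model()
  .fixtures$conv
}

fx_rheology <- function() {
  if (is.null(.fixtures$rheo)) {
    .fixtures$rheo <- default_rheology_model(conv_model = fx_conv_model())
  }
  .fixtures$rheo
}

fx_trajectory <- function(rpm, load, grid = seq(0, 96, by = 0.5)) {
  run_trajectory(hydrolysis_conditions(rpm, load),
                 geometry = reactor_geometry(),
                 rheology = fx_rheology(),
                 correlation = default_power_correlation(),
                 composition = hydrolysis_composition(),
                 conv_model = fx_conv_model(),
                 grid = grid)
}

# Hand-built trajectory with prescribed power, for identities that need a
# known integrand.
fake_trajectory <- function(time_h, power_W, geometry = reactor_geometry()) {
  e <- c(0, cumsum(diff(time_h) * (head(power_W, -1) + tail(power_W, -1)) / 2))
  structure(data.frame(time_h = time_h, power_W = power_W,
                       volumetric_power_W_m3 = power_W / geometry$working_volume,
                       energy_Wh = e,
                       energy_kWh_m3 = e / 1000 / geometry$working_volume),
            class = c("process_trajectory", "data.frame"),
            condition = hydrolysis_conditions(100, 20),
            geometry = geometry)
}
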