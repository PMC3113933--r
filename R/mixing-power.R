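#' Stirred-tank reactor geometry
#'
#' Dimensions and fluid properties of the bench-scale stirred tank. Defaults
#' describe the reference rig: a 2.5 L vessel of 130 mm diameter with a
#' three-blade 45-degree pitched-blade impeller (diameter 70 mm, blade width
#' 20 mm) and a 1.0 kg working weight occupying 980 mL.
#'
#' @param tank_diameter Tank diameter, m.
#' @param impeller_diameter Impeller diameter, m; must be smaller than the
#'   tank diameter.
#' @param blade_width Impeller blade width, m (carried as metadata; not used
#'   in the power formulas).
#' @param working_volume Working volume, m^3.
#' @param fluid_density Slurry density, kg/m^3. Default 1000 (the 1.0 kg /
#'   980 mL working basis implies about 1020; the round value is used and is
#'   configurable).
#' @return An object of class `reactor_geometry`.
#' @export
reactor_geometry <- function(tank_diameter = 0.130,
                             impeller_diameter = 0.070,
                             blade_width = 0.020,
                             working_volume = 9.8e-4,
                             fluid_density = 1000) {
  check_num(tank_diameter, "tank_diameter", positive = TRUE, scalar = TRUE)
  check_num(impeller_diameter, "impeller_diameter", positive = TRUE, scalar = TRUE)
  check_num(blade_width, "blade_width", positive = TRUE, scalar = TRUE)
  check_num(working_volume, "working_volume", positive = TRUE, scalar = TRUE)
  check_num(fluid_density, "fluid_density", positive = TRUE, scalar = TRUE)
  if (impeller_diameter >= tank_diameter) {
    stop("'impeller_diameter' must be smaller than 'tank_diameter'",
         call. = FALSE)
  }
  structure(list(tank_diameter = tank_diameter,
                 impeller_diameter = impeller_diameter,
                 blade_width = blade_width,
                 working_volume = working_volume,
                 fluid_density = fluid_density),
            class = "reactor_geometry")
}

#' @export
print.reactor_geometry <- function(x, ...) {
  cat("Stirred-tank geometry\n")
  cat(sprintf("  D_t = %.3f m, D_i = %.3f m, w_i = %.3f m\n",
              x$tank_diameter, x$impeller_diameter, x$blade_width))
  cat(sprintf("  working volume %.4g m^3, density %.4g kg/m^3\n",
              x$working_volume, x$fluid_density))
  invisible(x)
}

#' Power-number correlation P0 = K1/Re + K2
#'
#' Two-parameter relation between the impeller power number and the impeller
#' Reynolds number, valid across laminar, transition and (asymptotically)
#' turbulent regimes for non-Newtonian fluids: `K1/Re` dominates in the
#' laminar region and `K2` is the turbulent plateau.
#'
#' @param K1 Laminar coefficient, >= 0.
#' @param K2 Turbulent plateau, > 0.
#' @param n_points,rss Optional fit metadata attached by
#'   [fit_power_correlation()].
#' @return An object of class `power_correlation`.
#' @export
power_correlation <- function(K1, K2, n_points = NA_integer_, rss = NA_real_) {
  check_num(K1, "K1", nonneg = TRUE, scalar = TRUE)
  check_num(K2, "K2", positive = TRUE, scalar = TRUE)
  structure(list(K1 = K1, K2 = K2, n_points = n_points, rss = rss),
            class = "power_correlation")
}

#' @export
print.power_correlation <- function(x, ...) {
  cat(sprintf("Power-number correlation: P0 = %.4g/Re + %.4g\n", x$K1, x$K2))
  if (!is.na(x$n_points)) {
    cat(sprintf("  fitted to %d observations, RSS = %.4g\n", x$n_points, x$rss))
  }
  invisible(x)
}

#' Fitted power-number correlation of the reference rig
#'
#' The published least-squares fit for the pitched-blade rig mixing a 10%
#' WIS pretreated-spruce slurry: K1 = 346.7, K2 = 1.27.
#'
#' @return A [power_correlation()].
#' @export
default_power_correlation <- function() power_correlation(346.7, 1.27)

#' Impeller Reynolds number
#'
#' \eqn{Re_i = \rho N_i D_i^2 / \mu}. Below about 1e4 the flow is laminar to
#' transitional and the power number depends on viscosity; above, it is
#' turbulent and the power number plateaus.
#'
#' @param density Fluid density, kg/m^3.
#' @param impeller_speed Impeller speed, rev/s.
#' @param impeller_diameter Impeller diameter, m.
#' @param viscosity Apparent viscosity, Pa·s; must be > 0.
#' @return Dimensionless Reynolds number. Vectorised.
#' @export
reynolds_number <- function(density, impeller_speed, impeller_diameter,
                            viscosity) {
  check_num(density, "density", positive = TRUE)
  check_num(impeller_speed, "impeller_speed", positive = TRUE)
  check_num(impeller_diameter, "impeller_diameter", positive = TRUE)
  check_num(viscosity, "viscosity", positive = TRUE)
  density * impeller_speed * impeller_diameter^2 / viscosity
}

#' Power number from the correlation
#'
#' Evaluates \eqn{P_0 = K_1/Re + K_2}: strictly decreasing in Re, bounded
#' below by the turbulent plateau `K2`.
#'
#' @param re Impeller Reynolds number, > 0.
#' @param corr A [power_correlation()].
#' @return Dimensionless power number. Vectorised over `re`.
#' @export
power_number <- function(re, corr) {
  stopifnot(inherits(corr, "power_correlation"))
  check_num(re, "re", positive = TRUE)
  corr$K1 / re + corr$K2
}

#' Fit the power-number correlation by least squares
#'
#' Ordinary least squares of the observed power numbers on `1/Re`: the model
#' `P0 = K1/Re + K2` is linear in its parameters, so the fit is exact in the
#' transformed variable, unweighted, with no outlier exclusion.
#'
#' @param observations A data frame with numeric columns `re` and `p0`
#'   (e.g. from [simulate_power_observations()] or assembled from
#'   [net_fluid_power()] measurements).
#' @return A [power_correlation()] carrying `n_points` and `rss`.
#' @export
#' @examples
#' obs <- simulate_power_observations(default_power_correlation(),
#'                                    re_grid = c(1, 10, 100, 1000))
#' fit_power_correlation(obs)
fit_power_correlation <- function(observations) {
  if (!is.data.frame(observations) ||
      !all(c("re", "p0") %in% names(observations))) {
    stop("'observations' must be a data frame with columns 're' and 'p0'",
         call. = FALSE)
  }
  re <- observations$re
  p0 <- observations$p0
  check_num(re, "re", positive = TRUE)
  check_num(p0, "p0")
  if (length(re) < 2L || length(unique(re)) < 2L) {
    stop("degenerate fit: need >= 2 observations with distinct Re",
         call. = FALSE)
  }
  fit <- stats::lm(p0 ~ I(1 / re))
  cf <- stats::coef(fit)
  K1 <- unname(cf[2]); K2 <- unname(cf[1])
  if (K1 < 0 || K2 <= 0) {
    warning("fitted correlation parameters are nonphysical (K1 = ",
            format(K1, digits = 4), ", K2 = ", format(K2, digits = 4),
            "); noisy data?", call. = FALSE)
  }
  # bypass the constructor: a noisy fit may legitimately fall outside the
  # physical parameter range and the estimate must still be reportable
  structure(list(K1 = K1, K2 = K2, n_points = length(re),
                 rss = sum(stats::residuals(fit)^2)),
            class = "power_correlation")
}

#' Net power dissipated to the fluid from motor measurements
#'
#' Motor draw while agitating air approximates the motor's own losses
#' (friction etc.); the power delivered to the slurry is the loaded draw
#' minus that baseline.
#'
#' @param motor_power_loaded Motor power while mixing the slurry, W.
#' @param motor_power_air Motor power while agitating air, W.
#' @return Net fluid power, W. Vectorised. A loaded draw below the air
#'   baseline signals a measurement fault and errors.
#' @export
net_fluid_power <- function(motor_power_loaded, motor_power_air) {
  check_num(motor_power_loaded, "motor_power_loaded", nonneg = TRUE)
  check_num(motor_power_air, "motor_power_air", nonneg = TRUE)
  if (any(motor_power_loaded < motor_power_air)) {
    stop("measurement fault: loaded motor power below the air baseline",
         call. = FALSE)
  }
  motor_power_loaded - motor_power_air
}

#' Impeller power draw
#'
#' \eqn{P = P_0 \rho N_i^3 D_i^5}, the standard dimensionless-group form of
#' stirred-tank power consumption.
#'
#' @param p0 Power number, >= 0.
#' @param density Fluid density, kg/m^3, >= 0.
#' @param impeller_speed Impeller speed, rev/s, >= 0.
#' @param impeller_diameter Impeller diameter, m, >= 0.
#' @return Power, W. Vectorised.
#' @export
impeller_power <- function(p0, density, impeller_speed, impeller_diameter) {
  check_num(p0, "p0", nonneg = TRUE)
  check_num(density, "density", nonneg = TRUE)
  check_num(impeller_speed, "impeller_speed", nonneg = TRUE)
  check_num(impeller_diameter, "impeller_diameter", nonneg = TRUE)
  p0 * density * impeller_speed^3 * impeller_diameter^5
}

#' Volumetric power input
#'
#' Power per working volume, W/m^3 — the unit used to compare mixing energy
#' across scales.
#'
#' @param power Power, W.
#' @param geometry A [reactor_geometry()] (supplies the working volume).
#' @return W/m^3. Vectorised over `power`.
#' @export
volumetric_power <- function(power, geometry) {
  stopifnot(inherits(geometry, "reactor_geometry"))
  check_num(power, "power", nonneg = TRUE)
  power / geometry$working_volume
}

#' Cumulative mixing energy from a power time series
#'
#' Trapezoidal integration of power over time. Energy is reported in both
#' Wh and MJ; the series starts at 0 and is non-decreasing for non-negative
#' power.
#'
#' @param times Time points, h, strictly increasing.
#' @param powers Power at each time point, W, >= 0.
#' @return A data frame with columns `time_h`, `energy_Wh`, `energy_MJ`.
#' @export
#' @examples
#' cumulative_energy(c(0, 48, 96), c(1, 1, 1)) # 96 Wh = 0.3456 MJ at 96 h
cumulative_energy <- function(times, powers) {
  check_num(times, "times", nonneg = TRUE)
  check_num(powers, "powers", nonneg = TRUE)
  if (length(times) != length(powers)) {
    stop("'times' and 'powers' must have the same length", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  wh <- trapz_cum(times, powers)
  data.frame(time_h = times, energy_Wh = wh, energy_MJ = wh * 3600 / 1e6)
}
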