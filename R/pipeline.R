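#' Default rheology model calibrated to the printed anchors
#'
#' The rheology exponents are not printed for this material, so the defaults
#' are pinned to the two quantitative constraints that are: (i) an apparent
#' viscosity of 2 Pa·s at 12% WIS and a shear rate of 50/s, which fixes the
#' prefactor `a` for any exponent pair via [calibrate_rheology()]; and (ii)
#' a 96-h time-averaged volumetric power of 1.5 kW/m^3 at 500 rpm and 20
#' FPU/g glucan under the fitted power correlation, which pins the WIS
#' exponent `b` by a 1-D root find once the flow-behaviour index is chosen.
#' `n_pl` itself is not identifiable from these two constraints (the anchor
#' absorbs any choice into `a`) and is fixed at 0.5, mid-range for
#' shear-thinning pretreated-softwood slurries; downstream energy figures
#' are insensitive to this choice.
#'
#' @param n_pl Flow-behaviour index, default 0.5.
#' @param K_s Metzner-Otto constant, default 11.5.
#' @param anchor_viscosity,anchor_wis,anchor_shear Viscosity anchor
#'   (Pa·s, % WIS, 1/s); defaults 2.0, 12, 50.
#' @param mean_power_target Mean volumetric power target, W/m^3; default
#'   1500.
#' @param at_speed,at_load Operating point of the power target, rpm and
#'   FPU/g glucan; defaults 500 and 20.
#' @param correlation,geometry,conv_model,composition Pipeline components
#'   used to evaluate the power target; package defaults when omitted. The
#'   composition is diluted to 10% WIS before use.
#' @return A calibrated [rheology_model()].
#' @export
#' @examples
#' default_rheology_model()
default_rheology_model <- function(n_pl = 0.5, K_s = 11.5,
                                   anchor_viscosity = 2.0, anchor_wis = 12,
                                   anchor_shear = 50,
                                   mean_power_target = 1500,
                                   at_speed = 500, at_load = 20,
                                   correlation = default_power_correlation(),
                                   geometry = reactor_geometry(),
                                   conv_model = calibrate_conversion_model(),
                                   composition = hydrolysis_composition()) {
  cond <- hydrolysis_conditions(at_speed, at_load)
  objective <- function(b) {
    rheo <- calibrate_rheology(anchor_viscosity, anchor_wis, anchor_shear,
                               b = b, n_pl = n_pl, K_s = K_s)
    traj <- run_trajectory(cond, geometry, rheo, correlation, composition,
                           conv_model)
    mean_volumetric_power(traj) - mean_power_target
  }
  b <- stats::uniroot(objective, c(0.5, 40), tol = 1e-10)$root
  calibrate_rheology(anchor_viscosity, anchor_wis, anchor_shear,
                     b = b, n_pl = n_pl, K_s = K_s)
}

#' Composition of the diluted hydrolysis slurry
#'
#' Convenience wrapper: the whole pretreatment slurry ([slurry_composition()]
#' defaults, 13% WIS) diluted with water to the hydrolysis WIS content.
#'
#' @param target_wis Target WIS, % wt/wt, default 10.
#' @return A [slurry_composition()] at the target WIS with diluted dissolved
#'   glucose.
#' @export
hydrolysis_composition <- function(target_wis = 10) {
  dilute_slurry(slurry_composition(), target_wis)$composition
}

#' Run the rheology-coupled power trajectory for one condition
#'
#' The end-to-end composition the package exists for: conversion X(t) from
#' the calibrated generator, WIS(t) by glucan mass balance, apparent
#' viscosity at the Metzner-Otto shear rate, impeller Reynolds number, power
#' number from the correlation, power draw P = P0 rho N^3 D^5, volumetric
#' power and trapezoidal cumulative energy.
#'
#' @param cond A [hydrolysis_conditions()].
#' @param geometry A [reactor_geometry()].
#' @param rheology A [rheology_model()].
#' @param correlation A [power_correlation()].
#' @param composition A [slurry_composition()] of the hydrolysis slurry;
#'   its `wis0` is overridden by `cond$wis_initial`.
#' @param conv_model A `conversion_model`.
#' @param grid Time grid, h; default 0 to `cond$duration` in 0.5 h steps.
#' @return A data frame of class `process_trajectory` with one row per time
#'   point and columns `time_h`, `conversion`, `wis_percent`,
#'   `shear_rate_per_s`, `viscosity_Pa_s`, `reynolds`, `power_number`,
#'   `power_W`, `volumetric_power_W_m3`, `energy_Wh`, `energy_kWh_m3`.
#'   A zero impeller speed yields all-zero power and energy columns with
#'   `NA` viscosity/Reynolds/power-number (undefined at zero shear).
#' @export
run_trajectory <- function(cond, geometry = reactor_geometry(),
                           rheology = default_rheology_model(),
                           correlation = default_power_correlation(),
                           composition = hydrolysis_composition(),
                           conv_model = calibrate_conversion_model(),
                           grid = seq(0, cond$duration, by = 0.5)) {
  stopifnot(inherits(cond, "hydrolysis_conditions"),
            inherits(geometry, "reactor_geometry"),
            inherits(rheology, "rheology_model"),
            inherits(correlation, "power_correlation"),
            inherits(composition, "slurry_composition"))
  if (is.unsorted(grid)) stop("'grid' must be sorted", call. = FALSE)

  comp <- composition
  comp$wis0 <- cond$wis_initial
  n_rps <- rpm_to_rps(cond$impeller_speed)

  x <- predict_conversion(conv_model, grid, cond$impeller_speed,
                          cond$enzyme_load)
  wis <- wis_from_conversion(x, comp)

  if (n_rps == 0) {
    gamma <- rep(0, length(grid))
    mu <- re <- p0 <- rep(NA_real_, length(grid))
    p <- rep(0, length(grid))
  } else {
    gamma <- average_shear_rate(n_rps, rheology)
    mu <- apparent_viscosity(gamma, wis, rheology)
    re <- reynolds_number(geometry$fluid_density, n_rps,
                          geometry$impeller_diameter, mu)
    p0 <- power_number(re, correlation)
    p <- impeller_power(p0, geometry$fluid_density, n_rps,
                        geometry$impeller_diameter)
    gamma <- rep(gamma, length(grid))
  }
  pv <- p / geometry$working_volume
  e_wh <- trapz_cum(grid, p)

  structure(data.frame(time_h = grid,
                       conversion = x,
                       wis_percent = wis,
                       shear_rate_per_s = gamma,
                       viscosity_Pa_s = mu,
                       reynolds = re,
                       power_number = p0,
                       power_W = p,
                       volumetric_power_W_m3 = pv,
                       energy_Wh = e_wh,
                       energy_kWh_m3 = e_wh / 1000 / geometry$working_volume),
            class = c("process_trajectory", "data.frame"),
            condition = cond, geometry = geometry)
}

#' Run trajectories over a speed-by-load grid
#'
#' @param speeds Impeller speeds, rpm.
#' @param loads Enzyme loads, FPU/g glucan.
#' @param ... Passed to [run_trajectory()] (components and grid).
#' @return A list of `process_trajectory` objects named
#'   `"<rpm>rpm_<load>FPU"`.
#' @export
run_sweep <- function(speeds = c(25, 75, 150, 300, 500), loads = c(10, 20),
                      ...) {
  grid <- expand.grid(speed = speeds, load = loads)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    run_trajectory(hydrolysis_conditions(grid$speed[i], grid$load[i]), ...)
  })
  names(out) <- sprintf("%grpm_%gFPU", grid$speed, grid$load)
  out
}

#' Time-averaged volumetric power of a trajectory
#'
#' Identically `cumulative energy / (duration * working volume)`.
#'
#' @param traj A `process_trajectory`.
#' @return Mean volumetric power, W/m^3.
#' @export
mean_volumetric_power <- function(traj) {
  stopifnot(inherits(traj, "process_trajectory"))
  n <- nrow(traj)
  duration <- traj$time_h[n] - traj$time_h[1]
  if (duration <= 0) stop("trajectory has zero duration", call. = FALSE)
  geom <- attr(traj, "geometry")
  (traj$energy_Wh[n] - traj$energy_Wh[1]) / duration / geom$working_volume
}

#' Energy reduction from doubling the enzyme load
#'
#' Percent reduction of the final cumulative energy of the high-load
#' trajectory relative to the low-load one, at the same impeller speed and
#' time grid. A higher enzyme load thins the slurry faster, so the reduction
#' is positive.
#'
#' @param traj_low,traj_high Trajectories at low and high enzyme load, same
#'   speed and grid.
#' @return Percent reduction, `100 * (E_low - E_high) / E_low`.
#' @export
energy_reduction_from_enzyme <- function(traj_low, traj_high) {
  stopifnot(inherits(traj_low, "process_trajectory"),
            inherits(traj_high, "process_trajectory"))
  cl <- attr(traj_low, "condition"); ch <- attr(traj_high, "condition")
  if (cl$impeller_speed != ch$impeller_speed) {
    stop("trajectories must share the impeller speed", call. = FALSE)
  }
  if (nrow(traj_low) != nrow(traj_high) ||
      any(traj_low$time_h != traj_high$time_h)) {
    stop("trajectories must share the time grid", call. = FALSE)
  }
  e_low <- traj_low$energy_Wh[nrow(traj_low)]
  e_high <- traj_high$energy_Wh[nrow(traj_high)]
  if (e_low == 0) return(0)
  100 * (e_low - e_high) / e_low
}

#' Second-order response surface of conversion vs. energy and time
#'
#' Ordinary least squares of conversion on the full second-order polynomial
#' in total energy input `E` and hydrolysis time `t`:
#' \deqn{X = \beta_0 + \beta_1 E + \beta_2 t + \beta_3 E^2 + \beta_4 t^2 +
#'   \beta_5 E t.}
#' Fit one surface per enzyme load, as the reference analysis does.
#'
#' @param points Data frame with numeric columns `energy`, `time`,
#'   `conversion`; at least 6 rows and a full-rank design.
#' @return An object of class `response_surface`: coefficients (named
#'   intercept, energy, time, energy2, time2, energy_time), `r_squared`
#'   and `n_points`. `r_squared` is defined as 0 when the response is
#'   constant (zero total sum of squares).
#' @export
fit_response_surface <- function(points) {
  req <- c("energy", "time", "conversion")
  if (!is.data.frame(points) || !all(req %in% names(points))) {
    stop("'points' must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(points) < 6L) stop("need >= 6 points", call. = FALSE)
  X <- cbind(intercept = 1, energy = points$energy, time = points$time,
             energy2 = points$energy^2, time2 = points$time^2,
             energy_time = points$energy * points$time)
  qrX <- qr(X)
  if (qrX$rank < 6L) {
    stop("degenerate fit: rank-deficient second-order design", call. = FALSE)
  }
  beta <- qr.coef(qrX, points$conversion)
  fitted <- drop(X %*% beta)
  rss <- sum((points$conversion - fitted)^2)
  tss <- sum((points$conversion - mean(points$conversion))^2)
  r2 <- if (tss == 0) 0 else 1 - rss / tss
  structure(list(coefficients = beta, r_squared = r2,
                 n_points = nrow(points)),
            class = "response_surface")
}

#' @export
print.response_surface <- function(x, ...) {
  cat("Second-order response surface: conversion ~ energy + time\n")
  print(round(x$coefficients, 6))
  cat(sprintf("  R^2 = %.4f on %d points\n", x$r_squared, x$n_points))
  invisible(x)
}

#' @export
predict.response_surface <- function(object, newdata, ...) {
  X <- cbind(1, newdata$energy, newdata$time, newdata$energy^2,
             newdata$time^2, newdata$energy * newdata$time)
  drop(X %*% object$coefficients)
}

#' Conversion-vs-energy frontier at selected times
#'
#' Tabulates, for each trajectory and each selected time, the conversion
#' reached and the cumulative energy spent — the trade-off view of mixing
#' intensity, enzyme load and residence time. Times off the grid are
#' linearly interpolated (a note is emitted).
#'
#' @param trajectories List of `process_trajectory` objects sharing a grid.
#' @param times Selected times, h. Default `c(24, 48, 96)`.
#' @return A tidy data frame with columns `condition`, `impeller_speed`,
#'   `enzyme_load`, `time_h`, `conversion`, `energy_Wh`, `energy_kWh_m3`;
#'   one row per (trajectory, time).
#' @export
conversion_energy_frontier <- function(trajectories, times = c(24, 48, 96)) {
  stopifnot(is.list(trajectories), length(trajectories) > 0)
  grids <- lapply(trajectories, `[[`, "time_h")
  if (!all(vapply(grids, identical, logical(1), grids[[1]]))) {
    stop("trajectories must share the time grid", call. = FALSE)
  }
  if (!all(times %in% grids[[1]])) {
    message("note: some selected times are off the grid; interpolating linearly")
  }
  labs <- names(trajectories) %||% as.character(seq_along(trajectories))
  rows <- lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    cond <- attr(tr, "condition")
    data.frame(condition = labs[i],
               impeller_speed = cond$impeller_speed,
               enzyme_load = cond$enzyme_load,
               time_h = times,
               conversion = stats::approx(tr$time_h, tr$conversion, times)$y,
               energy_Wh = stats::approx(tr$time_h, tr$energy_Wh, times)$y,
               energy_kWh_m3 = stats::approx(tr$time_h, tr$energy_kWh_m3,
                                             times)$y)
  })
  do.call(rbind, rows)
}
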