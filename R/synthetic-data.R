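#' Composition of the pretreated slurry
#'
#' Carries the mass-balance quantities the pipeline needs: the WIS content,
#' the glucan fraction of the solids and the dissolved glucose already
#' present in the pretreatment liquor. Defaults are the whole-slurry analysis
#' of SO2-catalysed steam-pretreated spruce: 13% WIS of which 48.0% is
#' glucan, with 29.8 g/L glucose in the liquid fraction. Remaining solid and
#' liquid fractions may be attached as metadata via `other`.
#'
#' @param wis0 WIS content, % wt/wt, in (0, 40].
#' @param glucan_frac_of_wis Glucan mass fraction of the solids, in \[0, 1\].
#' @param initial_liquid_glucose Dissolved glucose in the slurry liquid, g/L.
#' @param other Named list of additional composition metadata (fractions of
#'   mannan, lignin, liquor sugars, ...); not used in computations.
#' @return An object of class `slurry_composition`.
#' @export
slurry_composition <- function(wis0 = 13,
                               glucan_frac_of_wis = 0.48,
                               initial_liquid_glucose = 29.8,
                               other = list()) {
  check_num(wis0, "wis0", positive = TRUE, scalar = TRUE)
  if (wis0 > 40) stop("'wis0' must be <= 40 %", call. = FALSE)
  check_num(glucan_frac_of_wis, "glucan_frac_of_wis", nonneg = TRUE, scalar = TRUE)
  if (glucan_frac_of_wis > 1) {
    stop("'glucan_frac_of_wis' must be in [0, 1]", call. = FALSE)
  }
  check_num(initial_liquid_glucose, "initial_liquid_glucose", nonneg = TRUE,
            scalar = TRUE)
  structure(list(wis0 = wis0,
                 glucan_frac_of_wis = glucan_frac_of_wis,
                 initial_liquid_glucose = initial_liquid_glucose,
                 other = other),
            class = "slurry_composition")
}

#' @export
print.slurry_composition <- function(x, ...) {
  cat(sprintf("Slurry composition: %.3g%% WIS (glucan %.1f%% of WIS), %.3g g/L dissolved glucose\n",
              x$wis0, 100 * x$glucan_frac_of_wis, x$initial_liquid_glucose))
  invisible(x)
}

#' Hydrolysis operating condition
#'
#' @param impeller_speed Impeller speed, rpm, in (0, 1000].
#' @param enzyme_load Cellulase loading, FPU per g glucan, > 0.
#' @param wis_initial Initial WIS content of the (diluted) hydrolysis slurry,
#'   % wt/wt, in (0, 20]. Default 10.
#' @param duration Hydrolysis duration, h. Default 96.
#' @return An object of class `hydrolysis_conditions`.
#' @export
hydrolysis_conditions <- function(impeller_speed, enzyme_load,
                                  wis_initial = 10, duration = 96) {
  check_num(impeller_speed, "impeller_speed", nonneg = TRUE, scalar = TRUE)
  if (impeller_speed > 1000) stop("'impeller_speed' must be <= 1000 rpm",
                                  call. = FALSE)
  check_num(enzyme_load, "enzyme_load", positive = TRUE, scalar = TRUE)
  check_num(wis_initial, "wis_initial", positive = TRUE, scalar = TRUE)
  if (wis_initial > 20) stop("'wis_initial' must be <= 20 %", call. = FALSE)
  check_num(duration, "duration", positive = TRUE, scalar = TRUE)
  structure(list(impeller_speed = impeller_speed,
                 enzyme_load = enzyme_load,
                 wis_initial = wis_initial,
                 duration = duration),
            class = "hydrolysis_conditions")
}

#' @export
print.hydrolysis_conditions <- function(x, ...) {
  cat(sprintf("Hydrolysis condition: %g rpm, %g FPU/g glucan, %g%% WIS, %g h\n",
              x$impeller_speed, x$enzyme_load, x$wis_initial, x$duration))
  invisible(x)
}

#' Enzyme dosing arithmetic
#'
#' Converts a cellulase loading (FPU per g glucan) into the mass of enzyme
#' preparation required and the beta-glucosidase activity it carries along.
#' Defaults are the activities of the preparation used in the reference
#' experiments: 95 FPU and 590 IU beta-glucosidase per g of enzyme solution,
#' under which 10 and 20 FPU/g glucan correspond to 62.1 and 124.2 IU/g
#' glucan.
#'
#' @param load Cellulase loading, FPU per g glucan, >= 0.
#' @param cellulase_activity Cellulase activity of the preparation, FPU per
#'   g, > 0.
#' @param bg_activity Beta-glucosidase activity of the preparation, IU per
#'   g, > 0.
#' @return A list with `prep_g_per_g_glucan` (g preparation per g glucan)
#'   and `bg_iu_per_g_glucan` (IU beta-glucosidase per g glucan).
#' @export
#' @examples
#' enzyme_dose(20) # 124.2 IU/g glucan
enzyme_dose <- function(load, cellulase_activity = 95, bg_activity = 590) {
  check_num(load, "load", nonneg = TRUE, scalar = TRUE)
  check_num(cellulase_activity, "cellulase_activity", positive = TRUE,
            scalar = TRUE)
  check_num(bg_activity, "bg_activity", positive = TRUE, scalar = TRUE)
  prep <- load / cellulase_activity
  list(prep_g_per_g_glucan = prep,
       bg_iu_per_g_glucan = prep * bg_activity)
}

#' Dilute the slurry to a target WIS content
#'
#' Mass balance for dilution with water: solids are conserved, the liquid
#' phase gains the added water, and the dissolved glucose is diluted
#' accordingly (liquid density taken as 1.0 kg/L). Per kg of slurry at WIS
#' fraction `w0`, reaching target fraction `w` requires `w0/w - 1` kg water.
#'
#' @param composition A [slurry_composition()].
#' @param target_wis Target WIS content, % wt/wt, in (0, `wis0`].
#' @return A list with `composition` (the diluted [slurry_composition()]),
#'   `water_added_kg_per_kg` (kg water per kg undiluted slurry) and
#'   `diluted_glucose_g_L`.
#' @export
#' @examples
#' dilute_slurry(slurry_composition(), 10) # 0.30 kg water/kg, ~22.2 g/L
dilute_slurry <- function(composition, target_wis) {
  stopifnot(inherits(composition, "slurry_composition"))
  check_num(target_wis, "target_wis", positive = TRUE, scalar = TRUE)
  if (target_wis > composition$wis0) {
    stop("'target_wis' exceeds the current WIS content; cannot concentrate by dilution",
         call. = FALSE)
  }
  w0 <- composition$wis0 / 100
  w <- target_wis / 100
  water <- w0 / w - 1
  liquid0 <- 1 - w0                     # kg liquid per kg slurry (~ L at 1 kg/L)
  glucose_mass <- composition$initial_liquid_glucose * liquid0
  diluted_glucose <- glucose_mass / (liquid0 + water)
  comp <- slurry_composition(wis0 = target_wis,
                             glucan_frac_of_wis = composition$glucan_frac_of_wis,
                             initial_liquid_glucose = diluted_glucose,
                             other = composition$other)
  list(composition = comp,
       water_added_kg_per_kg = water,
       diluted_glucose_g_L = diluted_glucose)
}

#' Anchor conversions of the reference experiments
#'
#' The four printed glucan-to-glucose conversions that identify the synthetic
#' generator: 57% at (500 rpm, 20 FPU/g glucan, 48 h), 26% at (25 rpm, 20
#' FPU, 48 h), 72% at (500 rpm, 20 FPU, 96 h) and 54% at (500 rpm, 10 FPU,
#' 96 h).
#'
#' @return A data frame with columns `impeller_speed` (rpm), `enzyme_load`
#'   (FPU/g glucan), `time` (h) and `conversion` (fraction).
#' @export
default_anchors <- function() {
  data.frame(impeller_speed = c(500, 25, 500, 500),
             enzyme_load = c(20, 20, 20, 10),
             time = c(48, 48, 96, 96),
             conversion = c(0.57, 0.26, 0.72, 0.54))
}

#' Calibrate the saturating conversion generator to printed anchors
#'
#' The synthetic generator is
#' \deqn{X(t; N, E) = \min\{1,\ (E/E_{ref})^p (c_0 + c_1 N)\}\,(1 - e^{-t/\tau})}
#' a saturating exponential in time with multiplicatively separable impeller
#' speed (linear response) and enzyme load (power response) effects — the
#' simplest form that passes through the four printed anchors, is monotone
#' in all three arguments, and reproduces the observed near-linear
#' conversion-vs-speed relationship at fixed time.
#'
#' Calibration: `tau` by a 1-D root find from an anchor pair sharing (N, E)
#' at two times; `c0`, `c1` by linear regression of the anchor amplitudes on
#' speed at the reference load; `p` from anchors at other loads. Every
#' anchor must be reproduced within 0.5 percentage points.
#'
#' @param anchors Data frame with columns `impeller_speed` (rpm),
#'   `enzyme_load` (FPU/g glucan), `time` (h), `conversion` (fraction);
#'   at least 4 rows spanning two speeds, two loads and two times. Default
#'   [default_anchors()].
#' @return An object of class `conversion_model` with fields `tau` (h),
#'   `c0`, `c1` (per rpm), `p`, `load_ref` (FPU/g glucan) and the calibrated
#'   speed/load ranges.
#' @export
#' @examples
#' m <- calibrate_conversion_model()
#' m$tau # ~35.96 h
calibrate_conversion_model <- function(anchors = default_anchors()) {
  req <- c("impeller_speed", "enzyme_load", "time", "conversion")
  if (!is.data.frame(anchors) || !all(req %in% names(anchors))) {
    stop("'anchors' must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(anchors) < 4L ||
      length(unique(anchors$impeller_speed)) < 2L ||
      length(unique(anchors$enzyme_load)) < 2L ||
      length(unique(anchors$time)) < 2L) {
    stop("need >= 4 anchors spanning >= 2 speeds, >= 2 loads and >= 2 times",
         call. = FALSE)
  }
  check_num(anchors$conversion, "conversion", positive = TRUE)
  if (any(anchors$conversion > 1)) {
    stop("anchor conversions must be fractions in (0, 1]", call. = FALSE)
  }

  # tau from the first (speed, load) pair observed at two times
  key <- paste(anchors$impeller_speed, anchors$enzyme_load)
  pair <- NULL
  for (k in unique(key)) {
    sub <- anchors[key == k, ]
    if (length(unique(sub$time)) >= 2L) {
      sub <- sub[order(sub$time), ]
      pair <- sub[1:2, ]
      break
    }
  }
  if (is.null(pair)) {
    stop("calibration error: no anchor pair shares (speed, load) at two times",
         call. = FALSE)
  }
  t1 <- pair$time[1]; t2 <- pair$time[2]
  x1 <- pair$conversion[1]; x2 <- pair$conversion[2]
  if (x2 <= x1) {
    stop("calibration error: anchors non-monotone in time at fixed (speed, load)",
         call. = FALSE)
  }
  ratio_fn <- function(tau) {
    (1 - exp(-t1 / tau)) / (1 - exp(-t2 / tau)) - x1 / x2
  }
  # ratio (1-e^{-t1/tau})/(1-e^{-t2/tau}) spans (t1/t2, 1) over tau in
  # (0, Inf); the anchor ratio must fall inside to identify tau
  if (x1 / x2 <= t1 / t2 * (1 + 1e-12)) {
    stop("calibration error: anchor pair implies super-linear growth (x1/x2 <= t1/t2)",
         call. = FALSE)
  }
  tau <- tryCatch(
    stats::uniroot(ratio_fn, c(1e-3, 1e5), tol = 1e-12)$root,
    error = function(e) stop("calibration error: no saturation time constant fits the two-time anchor pair",
                             call. = FALSE))

  sat <- function(t) 1 - exp(-t / tau)
  load_ref <- pair$enzyme_load[1]

  # speed response at the reference load
  at_ref <- anchors[anchors$enzyme_load == load_ref, ]
  if (length(unique(at_ref$impeller_speed)) < 2L) {
    stop("calibration error: need >= 2 speeds at the reference load",
         call. = FALSE)
  }
  amp <- at_ref$conversion / sat(at_ref$time)
  cf <- stats::coef(stats::lm(amp ~ at_ref$impeller_speed))
  c0 <- unname(cf[1]); c1 <- unname(cf[2])

  # load exponent from anchors off the reference load
  off <- anchors[anchors$enzyme_load != load_ref, ]
  amp_off <- off$conversion / sat(off$time)
  amp_pred <- c0 + c1 * off$impeller_speed
  p <- mean(log(amp_off / amp_pred) / log(off$enzyme_load / load_ref))
  if (!is.finite(p) || p < 0) {
    stop("calibration error: enzyme-load exponent is not identifiable or negative",
         call. = FALSE)
  }

  model <- structure(list(tau = tau, c0 = c0, c1 = c1, p = p,
                          load_ref = load_ref,
                          speed_range = range(anchors$impeller_speed),
                          load_range = range(anchors$enzyme_load)),
                     class = "conversion_model")
  # every anchor must be reproduced within 0.5 percentage points
  pred <- predict_conversion(model, anchors$time, anchors$impeller_speed,
                             anchors$enzyme_load, check_range = FALSE)
  if (any(abs(pred - anchors$conversion) > 0.005)) {
    stop("calibration error: anchors not reproduced within 0.5 percentage points",
         call. = FALSE)
  }
  model
}

#' @export
print.conversion_model <- function(x, ...) {
  cat("Anchor-calibrated conversion generator\n")
  cat(sprintf("  X(t; N, E) = min(1, (E/%g)^%.4g * (%.4g + %.4g N)) * (1 - exp(-t/%.4g h))\n",
              x$load_ref, x$p, x$c0, x$c1, x$tau))
  cat(sprintf("  calibrated over %g-%g rpm, %g-%g FPU/g glucan\n",
              x$speed_range[1], x$speed_range[2],
              x$load_range[1], x$load_range[2]))
  invisible(x)
}

#' Evaluate the calibrated conversion generator
#'
#' @param model A [calibrate_conversion_model()] result.
#' @param time Time, h, >= 0. Vectorised (recycled with the other arguments).
#' @param impeller_speed Impeller speed, rpm.
#' @param enzyme_load Enzyme loading, FPU/g glucan.
#' @param check_range If `TRUE` (default), warn when (speed, load) falls
#'   outside the calibrated box; evaluation proceeds (flagged extrapolation).
#' @return Conversion fraction(s) in \[0, 1\].
#' @export
predict_conversion <- function(model, time, impeller_speed, enzyme_load,
                               check_range = TRUE) {
  stopifnot(inherits(model, "conversion_model"))
  check_num(time, "time", nonneg = TRUE)
  check_num(impeller_speed, "impeller_speed", nonneg = TRUE)
  check_num(enzyme_load, "enzyme_load", positive = TRUE)
  if (check_range &&
      (any(impeller_speed < model$speed_range[1]) ||
       any(impeller_speed > model$speed_range[2]) ||
       any(enzyme_load < model$load_range[1]) ||
       any(enzyme_load > model$load_range[2]))) {
    warning("conditions outside the calibrated (speed, load) box; extrapolating",
            call. = FALSE)
  }
  amp <- pmin(1, (enzyme_load / model$load_ref)^model$p *
                (model$c0 + model$c1 * impeller_speed))
  pmin(1, pmax(0, amp * (1 - exp(-time / model$tau))))
}

#' Conversion trajectory for one operating condition
#'
#' @param model A `conversion_model`.
#' @param cond A [hydrolysis_conditions()].
#' @param grid Time grid, h, sorted, within \[0, `cond$duration`\].
#' @return A data frame of class `conversion_curve` with columns `time_h`
#'   and `conversion`, carrying the condition as an attribute.
#' @export
conversion_curve <- function(model, cond,
                             grid = seq(0, cond$duration, by = 0.5)) {
  stopifnot(inherits(model, "conversion_model"),
            inherits(cond, "hydrolysis_conditions"))
  check_num(grid, "grid", nonneg = TRUE)
  if (is.unsorted(grid)) stop("'grid' must be sorted", call. = FALSE)
  if (any(grid > cond$duration)) {
    stop("'grid' must lie within [0, duration]", call. = FALSE)
  }
  x <- predict_conversion(model, grid, cond$impeller_speed, cond$enzyme_load)
  structure(data.frame(time_h = grid, conversion = x),
            class = c("conversion_curve", "data.frame"),
            condition = cond)
}

#' WIS content at a given conversion
#'
#' As glucan hydrolyses, its anhydroglucose mass leaves the solids for the
#' liquid phase; on a constant-total-mass basis the WIS content declines
#' linearly, \eqn{\mathrm{WIS}(x) = \mathrm{WIS}_0 (1 - f_{glucan} x)}.
#' Hydration water is drawn from the liquid and does not change the total.
#'
#' @param x Conversion fraction(s), in \[0, 1\].
#' @param composition A [slurry_composition()] (supplies `wis0` and the
#'   glucan fraction).
#' @return WIS content, % wt/wt. Strictly decreasing in `x`.
#' @export
wis_from_conversion <- function(x, composition) {
  stopifnot(inherits(composition, "slurry_composition"))
  check_num(x, "x")
  if (any(x < 0 | x > 1)) stop("'x' must be in [0, 1]", call. = FALSE)
  composition$wis0 * (1 - composition$glucan_frac_of_wis * x)
}

# Internal: glucan load of the slurry, g per L (slurry density ~ 1 kg/L).
glucan_load_g_L <- function(composition) {
  composition$wis0 * 10 * composition$glucan_frac_of_wis
}

#' Glucose concentration at a given conversion
#'
#' \eqn{c(x) = c_0 + x\,G\,(180/162)} where `G` is the initial glucan load
#' (g/L, slurry density taken as 1.0 kg/L) and 180/162 the glucose /
#' anhydroglucose hydration factor. `c_0` is the dissolved glucose carried
#' over from pretreatment — a baseline offset, not part of the conversion.
#' Exact inverse: [conversion_from_glucose()].
#'
#' @param x Conversion fraction(s) in \[0, 1\].
#' @param composition A [slurry_composition()] describing the hydrolysis
#'   slurry (i.e. after any dilution).
#' @return Glucose concentration, g/L.
#' @export
glucose_from_conversion <- function(x, composition) {
  stopifnot(inherits(composition, "slurry_composition"))
  check_num(x, "x")
  if (any(x < 0 | x > 1)) stop("'x' must be in [0, 1]", call. = FALSE)
  composition$initial_liquid_glucose +
    x * glucan_load_g_L(composition) * 180 / 162
}

#' @rdname glucose_from_conversion
#' @param glucose Glucose concentration(s), g/L.
#' @export
conversion_from_glucose <- function(glucose, composition) {
  stopifnot(inherits(composition, "slurry_composition"))
  check_num(glucose, "glucose", nonneg = TRUE)
  (glucose - composition$initial_liquid_glucose) /
    (glucan_load_g_L(composition) * 180 / 162)
}

#' Sample a noisy glucose measurement series from a conversion curve
#'
#' Converts the curve to glucose concentrations and applies multiplicative
#' Gaussian noise, emulating HPLC measurement scatter. The default CV of 4%
#' reflects the reference experiments' stated reproducibility (SD of
#' concentrations below 4.2%).
#'
#' @param curve A [conversion_curve()].
#' @param composition A [slurry_composition()] for the glucose mapping.
#' @param cv Coefficient of variation of the multiplicative noise, >= 0.
#'   Default 0.04.
#' @param seed Optional integer seed; fixing it makes the series
#'   bitwise-reproducible without disturbing the caller's RNG state.
#' @return The curve data frame with added columns `glucose_g_L` (noiseless)
#'   and `glucose_obs_g_L` (noisy).
#' @export
sample_noisy_glucose <- function(curve, composition, cv = 0.04, seed = NULL) {
  stopifnot(inherits(curve, "conversion_curve"))
  check_num(cv, "cv", nonneg = TRUE, scalar = TRUE)
  clean <- glucose_from_conversion(curve$conversion, composition)
  noisy <- if (cv == 0) clean else {
    eps <- if (is.null(seed)) stats::rnorm(length(clean), 0, cv) else
      withr::with_seed(seed, stats::rnorm(length(clean), 0, cv))
    clean * (1 + eps)
  }
  out <- curve
  out$glucose_g_L <- clean
  out$glucose_obs_g_L <- noisy
  out
}

#' Simulate noisy power-number observations around a correlation
#'
#' Stand-in for the motor-power measurement campaign: power numbers on a
#' Reynolds-number grid with multiplicative Gaussian noise, for exercising
#' [fit_power_correlation()].
#'
#' @param corr A [power_correlation()] (the generating truth).
#' @param re_grid Reynolds numbers, > 0.
#' @param noise_cv Coefficient of variation of the multiplicative noise,
#'   >= 0. Default 0 (exact correlation values).
#' @param seed Optional integer seed (scoped; caller RNG untouched).
#' @return Data frame with columns `re` and `p0`.
#' @export
simulate_power_observations <- function(corr, re_grid, noise_cv = 0,
                                        seed = NULL) {
  stopifnot(inherits(corr, "power_correlation"))
  check_num(re_grid, "re_grid", positive = TRUE)
  check_num(noise_cv, "noise_cv", nonneg = TRUE, scalar = TRUE)
  p0 <- power_number(re_grid, corr)
  if (noise_cv > 0) {
    eps <- if (is.null(seed)) stats::rnorm(length(p0), 0, noise_cv) else
      withr::with_seed(seed, stats::rnorm(length(p0), 0, noise_cv))
    p0 <- p0 * (1 + eps)
  }
  data.frame(re = re_grid, p0 = p0)
}
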