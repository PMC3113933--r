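# Configuration schema: every known key with its required-ness. Unknown keys
# are rejected with a field-path message so typos cannot silently fall back
# to defaults.

config_schema <- function() {
  list(
    geometry = c("tank_diameter_m", "impeller_diameter_m", "blade_width_m",
                 "working_volume_m3", "fluid_density_kg_m3"),
    rheology = c("a", "b", "n_pl", "K_s", "anchor", "calibration"),
    rheology.anchor = c("viscosity_Pa_s", "wis_percent", "shear_rate_per_s"),
    rheology.calibration = c("mean_power_target_W_m3", "speed_rpm",
                             "load_fpu_per_g_glucan"),
    correlation = c("K1", "K2"),
    composition = c("wis0_percent", "glucan_frac_of_wis",
                    "initial_liquid_glucose_g_L", "dilute_to_wis_percent"),
    conditions = c("impeller_speed_rpm", "enzyme_load_fpu_per_g_glucan",
                   "duration_h"),
    grid = c("start_h", "end_h", "step_h"),
    noise = c("glucose_cv", "power_cv")
  )
}

check_keys <- function(block, allowed, path) {
  extra <- setdiff(names(block), allowed)
  if (length(extra)) {
    stop(sprintf("config: unknown key '%s.%s'", path, extra[1]), call. = FALSE)
  }
  invisible(block)
}

req_field <- function(block, field, path) {
  if (is.null(block[[field]])) {
    stop(sprintf("config: missing required field '%s.%s'", path, field),
         call. = FALSE)
  }
  block[[field]]
}

#' Default run configuration
#'
#' The packaged defaults: the bench rig geometry, the fitted power
#' correlation, the whole-slurry composition diluted to 10% WIS, the
#' anchor-calibrated rheology specification, the five studied impeller
#' speeds at both enzyme loads on a 0-96 h half-hour grid, and the stated
#' measurement noise levels. Matches `inst/extdata/default_config.json`.
#'
#' @return A `run_config` list.
#' @export
default_config <- function() {
  cfg <- list(
    geometry = list(tank_diameter_m = 0.130, impeller_diameter_m = 0.070,
                    blade_width_m = 0.020, working_volume_m3 = 9.8e-4,
                    fluid_density_kg_m3 = 1000),
    rheology = list(n_pl = 0.5, K_s = 11.5,
                    anchor = list(viscosity_Pa_s = 2.0, wis_percent = 12,
                                  shear_rate_per_s = 50),
                    calibration = list(mean_power_target_W_m3 = 1500,
                                       speed_rpm = 500,
                                       load_fpu_per_g_glucan = 20)),
    correlation = list(K1 = 346.7, K2 = 1.27),
    composition = list(wis0_percent = 13, glucan_frac_of_wis = 0.48,
                       initial_liquid_glucose_g_L = 29.8,
                       dilute_to_wis_percent = 10),
    conditions = data.frame(
      impeller_speed_rpm = rep(c(25, 75, 150, 300, 500), 2),
      enzyme_load_fpu_per_g_glucan = rep(c(10, 20), each = 5),
      duration_h = 96),
    grid = list(start_h = 0, end_h = 96, step_h = 0.5),
    noise = list(glucose_cv = 0.04, power_cv = 0.05),
    seed = 1
  )
  structure(validate_config(cfg), class = "run_config")
}

validate_config <- function(cfg) {
  sch <- config_schema()
  top <- c(names(sch)[!grepl("\\.", names(sch))], "seed")
  check_keys(cfg, top, "config")
  for (blk in c("geometry", "correlation", "composition", "grid")) {
    if (is.null(cfg[[blk]])) {
      stop(sprintf("config: missing required block '%s'", blk), call. = FALSE)
    }
  }
  check_keys(cfg$geometry, sch$geometry, "geometry")
  check_keys(cfg$correlation, sch$correlation, "correlation")
  check_keys(cfg$composition, sch$composition, "composition")
  check_keys(cfg$grid, sch$grid, "grid")
  if (!is.null(cfg$rheology)) {
    check_keys(cfg$rheology, sch$rheology, "rheology")
    if (!is.null(cfg$rheology$anchor)) {
      check_keys(cfg$rheology$anchor, sch$rheology.anchor, "rheology.anchor")
    }
    if (!is.null(cfg$rheology$calibration)) {
      check_keys(cfg$rheology$calibration, sch$rheology.calibration,
                 "rheology.calibration")
    }
  }
  if (!is.null(cfg$noise)) check_keys(cfg$noise, sch$noise, "noise")
  if (!is.null(cfg$conditions)) {
    conds <- cfg$conditions
    if (!is.data.frame(conds)) conds <- do.call(rbind.data.frame, conds)
    check_keys(conds, sch$conditions, "conditions")
    for (f in c("impeller_speed_rpm", "enzyme_load_fpu_per_g_glucan")) {
      req_field(conds, f, "conditions")
    }
    cfg$conditions <- conds
  }
  # range checks run through the constructors so messages name the field
  geometry_from_config(cfg)
  correlation_from_config(cfg)
  composition_from_config(cfg)
  grid_from_config(cfg)
  cfg
}

#' Load and validate a run configuration from JSON
#'
#' Unknown keys are rejected; missing blocks and out-of-range values error
#' with the offending field path. The packaged example lives at
#' `system.file("extdata", "default_config.json", package = "hydromix")`.
#'
#' @param path Path to a JSON configuration file.
#' @param quiet Suppress the effective-config echo message.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path, quiet = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(cfg) == 0) {
    stop("config: empty file; missing required block 'geometry'",
         call. = FALSE)
  }
  cfg <- validate_config(cfg)
  if (!quiet) {
    message("effective config (hash ", config_hash(cfg), "):\n",
            jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, pretty = TRUE,
                             digits = NA))
  }
  structure(cfg, class = "run_config")
}

#' Hash of a configuration
#'
#' MD5 of the canonical JSON serialisation; recorded in every output file so
#' mismatched provenance is detectable.
#'
#' @param cfg A `run_config`.
#' @return Character MD5 digest.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}

geometry_from_config <- function(cfg) {
  g <- cfg$geometry
  reactor_geometry(tank_diameter = req_field(g, "tank_diameter_m", "geometry"),
                   impeller_diameter = req_field(g, "impeller_diameter_m", "geometry"),
                   blade_width = g$blade_width_m %||% 0.020,
                   working_volume = req_field(g, "working_volume_m3", "geometry"),
                   fluid_density = g$fluid_density_kg_m3 %||% 1000)
}

correlation_from_config <- function(cfg) {
  power_correlation(K1 = req_field(cfg$correlation, "K1", "correlation"),
                    K2 = req_field(cfg$correlation, "K2", "correlation"))
}

composition_from_config <- function(cfg) {
  cmp <- cfg$composition
  raw <- slurry_composition(
    wis0 = req_field(cmp, "wis0_percent", "composition"),
    glucan_frac_of_wis = req_field(cmp, "glucan_frac_of_wis", "composition"),
    initial_liquid_glucose = cmp$initial_liquid_glucose_g_L %||% 29.8)
  target <- cmp$dilute_to_wis_percent
  if (is.null(target)) raw else dilute_slurry(raw, target)$composition
}

grid_from_config <- function(cfg) {
  g <- cfg$grid
  seq(req_field(g, "start_h", "grid"), req_field(g, "end_h", "grid"),
      by = req_field(g, "step_h", "grid"))
}

rheology_from_config <- function(cfg, geometry = geometry_from_config(cfg),
                                 correlation = correlation_from_config(cfg),
                                 composition = composition_from_config(cfg),
                                 conv_model = calibrate_conversion_model()) {
  r <- cfg$rheology
  if (is.null(r)) return(default_rheology_model())
  if (!is.null(r$a) && !is.null(r$b)) {
    return(rheology_model(a = r$a, b = r$b, n_pl = r$n_pl %||% 0.5,
                          K_s = r$K_s %||% 11.5))
  }
  anchor <- r$anchor %||% list(viscosity_Pa_s = 2.0, wis_percent = 12,
                               shear_rate_per_s = 50)
  cal <- r$calibration %||% list(mean_power_target_W_m3 = 1500,
                                 speed_rpm = 500, load_fpu_per_g_glucan = 20)
  default_rheology_model(
    n_pl = r$n_pl %||% 0.5, K_s = r$K_s %||% 11.5,
    anchor_viscosity = anchor$viscosity_Pa_s,
    anchor_wis = anchor$wis_percent,
    anchor_shear = anchor$shear_rate_per_s,
    mean_power_target = cal$mean_power_target_W_m3,
    at_speed = cal$speed_rpm, at_load = cal$load_fpu_per_g_glucan,
    correlation = correlation, geometry = geometry,
    conv_model = conv_model, composition = composition)
}

#' Instantiate all pipeline components from a configuration
#'
#' @param cfg A `run_config`.
#' @return A list: `geometry`, `rheology`, `correlation`, `composition`
#'   (diluted), `conv_model`, `conditions` (list of
#'   [hydrolysis_conditions()]), `grid`, `noise`, `seed`.
#' @export
build_components <- function(cfg) {
  geometry <- geometry_from_config(cfg)
  correlation <- correlation_from_config(cfg)
  composition <- composition_from_config(cfg)
  conv_model <- calibrate_conversion_model()
  rheology <- rheology_from_config(cfg, geometry, correlation, composition,
                                   conv_model)
  grid <- grid_from_config(cfg)
  conds <- cfg$conditions
  conditions <- if (is.null(conds)) list() else
    lapply(seq_len(nrow(conds)), function(i) {
      hydrolysis_conditions(conds$impeller_speed_rpm[i],
                            conds$enzyme_load_fpu_per_g_glucan[i],
                            wis_initial = composition$wis0,
                            duration = conds$duration_h[i] %||% max(grid))
    })
  list(geometry = geometry, rheology = rheology, correlation = correlation,
       composition = composition, conv_model = conv_model,
       conditions = conditions, grid = grid,
       noise = cfg$noise %||% list(glucose_cv = 0.04, power_cv = 0.05),
       seed = cfg$seed %||% 1L)
}

#' Read a time-series or power-measurement CSV
#'
#' Tolerant CSV reader for the package's file surfaces: comma-separated,
#' '.' decimal, UTF-8, `#` comment lines for metadata. Conversion series
#' require columns `time_h`, `conversion`; power tables require `rpm`,
#' `motor_power_loaded_W`, `motor_power_air_W`. Rows are sorted by time;
#' duplicate times are rejected.
#'
#' @param path CSV file path.
#' @param kind `"conversion"` or `"power"`.
#' @return A data frame.
#' @export
read_timeseries_csv <- function(path, kind = c("conversion", "power")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", blank.lines.skip = TRUE,
                        fileEncoding = "UTF-8")
  required <- switch(kind,
                     conversion = c("time_h", "conversion"),
                     power = c("rpm", "motor_power_loaded_W",
                               "motor_power_air_W"))
  missing_col <- setdiff(required, names(df))
  if (length(missing_col)) {
    stop(sprintf("missing column '%s' in %s", missing_col[1], path),
         call. = FALSE)
  }
  for (cn in required) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1]
      stop(sprintf("non-numeric value in column '%s', row %d of %s",
                   cn, bad, path), call. = FALSE)
    }
  }
  if (kind == "conversion") {
    if (anyDuplicated(df$time_h)) {
      stop(sprintf("duplicate time %g h in %s", df$time_h[duplicated(df$time_h)][1],
                   path), call. = FALSE)
    }
    df <- df[order(df$time_h), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write a data frame to CSV with a provenance header
#'
#' Comma-separated, '.' decimal, UTF-8, with `#`-prefixed metadata lines
#' (tool version plus any supplied key-value pairs). Numeric columns keep
#' 15 significant digits, so write-read round trips are lossless at 12.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param meta Named character vector of extra metadata lines.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(df, path, meta = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# hydromix %s", utils::packageVersion("hydromix")), con)
  for (k in names(meta)) writeLines(sprintf("# %s %s", k, meta[[k]]), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis described by a configuration
#'
#' Executes every trajectory in the configuration, fits the power
#' correlation to seeded synthetic power observations, fits the per-load
#' response surfaces, and tabulates the conversion-energy frontier.
#'
#' @param cfg A `run_config` (default [default_config()]).
#' @return A list of class `hydromix_results`: `config`, `components`,
#'   `trajectories`, `correlation_fit`, `surfaces` (per enzyme load),
#'   `frontier`, `mean_power` (named vector, W/m^3).
#' @export
run_analysis <- function(cfg = default_config()) {
  comp <- build_components(cfg)
  trajectories <- lapply(comp$conditions, function(cond) {
    run_trajectory(cond, comp$geometry, comp$rheology, comp$correlation,
                   comp$composition, comp$conv_model, grid = comp$grid)
  })
  names(trajectories) <- vapply(comp$conditions, function(cd) {
    sprintf("%grpm_%gFPU", cd$impeller_speed, cd$enzyme_load)
  }, character(1))

  obs <- simulate_power_observations(
    comp$correlation,
    re_grid = 10^seq(log10(0.5), log10(5000), length.out = 200),
    noise_cv = comp$noise$power_cv %||% 0.05,
    seed = comp$seed)
  correlation_fit <- fit_power_correlation(obs)

  loads <- unique(vapply(comp$conditions, `[[`, numeric(1), "enzyme_load"))
  surf_times <- seq(8, max(comp$grid), by = 8)
  surfaces <- lapply(loads, function(ld) {
    idx <- vapply(comp$conditions, function(cd) cd$enzyme_load == ld,
                  logical(1))
    pts <- do.call(rbind, lapply(trajectories[idx], function(tr) {
      data.frame(
        energy = stats::approx(tr$time_h, tr$energy_Wh, surf_times)$y,
        time = surf_times,
        conversion = stats::approx(tr$time_h, tr$conversion, surf_times)$y)
    }))
    fit_response_surface(pts)
  })
  names(surfaces) <- sprintf("%gFPU", loads)

  mean_power <- vapply(trajectories, mean_volumetric_power, numeric(1))

  structure(list(config = cfg, components = comp,
                 trajectories = trajectories,
                 correlation_fit = correlation_fit,
                 surfaces = surfaces,
                 frontier = conversion_energy_frontier(trajectories),
                 mean_power = mean_power),
            class = "hydromix_results")
}

#' Write the analysis report to a directory
#'
#' Deterministic file set: one trajectory CSV per condition, `frontier.csv`,
#' and `summary.json` (fitted correlation, per-load surface fits, mean
#' volumetric powers, seed, config hash). Identical configuration and seed
#' produce byte-identical files.
#'
#' @param results A `hydromix_results` from [run_analysis()].
#' @param out_dir Output directory; created if absent.
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(results, out_dir) {
  stopifnot(inherits(results, "hydromix_results"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(results$config)
  meta <- c(config_hash = hash, seed = as.character(results$components$seed))
  paths <- character()
  for (nm in names(results$trajectories)) {
    p <- file.path(out_dir, sprintf("trajectory_%s.csv", nm))
    write_timeseries_csv(as.data.frame(results$trajectories[[nm]]), p, meta)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "frontier.csv")
  write_timeseries_csv(results$frontier, p, meta)
  paths <- c(paths, p)

  cf <- results$correlation_fit
  summary <- list(
    tool = "hydromix",
    version = as.character(utils::packageVersion("hydromix")),
    config_hash = hash,
    seed = results$components$seed,
    correlation = list(K1 = cf$K1, K2 = cf$K2, n_points = cf$n_points,
                       rss = cf$rss),
    surfaces = lapply(results$surfaces, function(s) {
      list(coefficients = as.list(s$coefficients), r_squared = s$r_squared,
           n_points = s$n_points)
    }),
    mean_volumetric_power_W_m3 = as.list(results$mean_power))
  p <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
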