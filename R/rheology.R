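#' Power-law rheology model of a pretreated-lignocellulose slurry
#'
#' Apparent viscosity of the fibre suspension follows the Ostwald-de Waele
#' power law, \eqn{\mu = K_{PL}\,\gamma^{n_{PL}-1}}, with the consistency
#' index depending on the water-insoluble-solids (WIS) content only,
#' \eqn{K_{PL} = a\,\mathrm{WIS}^b}. The flow-behaviour index \eqn{n_{PL}}
#' is held constant over a hydrolysis run; the WIS dependence carries the
#' viscosity decline as glucan is solubilised. The average shear rate in the
#' stirred vessel is taken as \eqn{\gamma_{avg} = K_s N_i} (Metzner-Otto).
#'
#' @param a Consistency-index prefactor, Pa·s^n per (WIS %)^b. Must be > 0.
#' @param b WIS exponent (dimensionless), >= 0 (0 gives a WIS-independent
#'   consistency index).
#' @param n_pl Flow-behaviour index, in (0, 1]: shear-thinning up to the
#'   Newtonian limit 1.
#' @param K_s Metzner-Otto constant (dimensionless), > 0. Default 11.5, the
#'   standard Rushton-turbine value, used here for a pitched-blade impeller
#'   for lack of a published value.
#' @return An object of class `rheology_model`.
#' @seealso [apparent_viscosity()], [calibrate_rheology()],
#'   [default_rheology_model()]
#' @export
#' @examples
#' m <- rheology_model(a = 5.683e-5, b = 5, n_pl = 0.5)
#' apparent_viscosity(95.83, wis = 10, m)
rheology_model <- function(a, b, n_pl, K_s = 11.5) {
  check_num(a, "a", positive = TRUE, scalar = TRUE)
  check_num(b, "b", nonneg = TRUE, scalar = TRUE)
  check_num(n_pl, "n_pl", positive = TRUE, scalar = TRUE)
  check_num(K_s, "K_s", positive = TRUE, scalar = TRUE)
  if (n_pl > 1) stop("'n_pl' must be <= 1 (shear-thinning or Newtonian)",
                     call. = FALSE)
  structure(list(a = a, b = b, n_pl = n_pl, K_s = K_s),
            class = "rheology_model")
}

#' @export
print.rheology_model <- function(x, ...) {
  cat("Power-law slurry rheology model\n")
  cat(sprintf("  K_PL = a * WIS^b with a = %.4g, b = %.4g\n", x$a, x$b))
  cat(sprintf("  flow-behaviour index n_PL = %.4g%s\n", x$n_pl,
              if (x$n_pl == 1) " (Newtonian)" else " (shear-thinning)"))
  cat(sprintf("  Metzner-Otto constant K_s = %.4g\n", x$K_s))
  invisible(x)
}

#' Metzner-Otto average shear rate in a stirred vessel
#'
#' \eqn{\gamma_{avg} = K_s N_i}, the standard proxy shear rate that lets a
#' single apparent viscosity stand in for the non-Newtonian field around the
#' impeller.
#'
#' @param impeller_speed Impeller speed in rev/s (use [rpm_to_rps()] for rpm
#'   inputs).
#' @param model A [rheology_model()] (supplies `K_s`).
#' @return Average shear rate, 1/s. Vectorised over `impeller_speed`.
#' @export
average_shear_rate <- function(impeller_speed, model) {
  stopifnot(inherits(model, "rheology_model"))
  check_num(impeller_speed, "impeller_speed", nonneg = TRUE)
  model$K_s * impeller_speed
}

#' Consistency index at a given WIS content
#'
#' \eqn{K_{PL}(\mathrm{WIS}) = a\,\mathrm{WIS}^b}, strictly increasing in WIS
#' for `b > 0`. WIS is entered as the raw percentage (e.g. 10, 12).
#'
#' @param wis Water-insoluble-solids content, % wt/wt, in (0, 40].
#' @inheritParams average_shear_rate
#' @return Consistency index, Pa·s^n. Vectorised over `wis`.
#' @export
consistency_index <- function(wis, model) {
  stopifnot(inherits(model, "rheology_model"))
  check_num(wis, "wis", positive = TRUE)
  if (any(wis > 40)) stop("'wis' must be <= 40 %", call. = FALSE)
  model$a * wis^model$b
}

#' Apparent viscosity of the slurry
#'
#' \eqn{\mu = K_{PL}(\mathrm{WIS})\,\gamma^{n_{PL}-1}}. Non-increasing in the
#' shear rate for \eqn{n_{PL} \le 1}. A shear rate of exactly zero is
#' rejected (the power law diverges there for \eqn{n_{PL} < 1}); obtain a
#' positive rate from [average_shear_rate()] of a positive speed.
#'
#' @param shear_rate Shear rate, 1/s, > 0.
#' @param wis WIS content, % wt/wt, > 0.
#' @inheritParams average_shear_rate
#' @return Apparent viscosity, Pa·s. Vectorised over `shear_rate` and `wis`.
#' @export
apparent_viscosity <- function(shear_rate, wis, model) {
  stopifnot(inherits(model, "rheology_model"))
  check_num(shear_rate, "shear_rate", positive = TRUE)
  consistency_index(wis, model) * shear_rate^(model$n_pl - 1)
}

#' Pin the consistency prefactor to a measured viscosity anchor
#'
#' Given exponents `b` and `n_pl`, solves
#' \eqn{a = \mu^\ast \gamma^{\ast\,(1-n_{PL})} / \mathrm{WIS}^{\ast\,b}} so
#' that the returned model reproduces the anchor viscosity exactly. The only
#' printed viscosity measurement for this material — about 2 Pa·s at 12% WIS
#' and a shear rate of 50/s — is the default anchor used throughout the
#' package.
#'
#' @param anchor_viscosity Measured apparent viscosity, Pa·s, > 0.
#' @param anchor_wis WIS content of the measurement, % wt/wt, > 0.
#' @param anchor_shear Shear rate of the measurement, 1/s, > 0.
#' @param b,n_pl Exponents to carry into the model (see [rheology_model()]).
#' @param K_s Metzner-Otto constant, passed through.
#' @return A calibrated [rheology_model()]; `apparent_viscosity()` at the
#'   anchor point reproduces `anchor_viscosity` to 1e-10 relative.
#' @export
#' @examples
#' m <- calibrate_rheology(2.0, 12, 50, b = 5, n_pl = 0.5)
#' m$a # 5.683e-5
calibrate_rheology <- function(anchor_viscosity, anchor_wis, anchor_shear,
                               b, n_pl, K_s = 11.5) {
  check_num(anchor_viscosity, "anchor_viscosity", positive = TRUE, scalar = TRUE)
  check_num(anchor_wis, "anchor_wis", positive = TRUE, scalar = TRUE)
  check_num(anchor_shear, "anchor_shear", positive = TRUE, scalar = TRUE)
  a <- anchor_viscosity * anchor_shear^(1 - n_pl) / anchor_wis^b
  rheology_model(a = a, b = b, n_pl = n_pl, K_s = K_s)
}
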