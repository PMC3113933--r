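#' Convert impeller speed from rpm to revolutions per second
#'
#' User-facing surfaces (configuration files, CSV columns, condition objects)
#' carry impeller speed in rpm; all internal formulas (shear rate, Reynolds
#' number, power draw) use rev/s. This is the single conversion point.
#'
#' @param rpm Impeller speed in revolutions per minute.
#' @return Speed in revolutions per second.
#' @export
#' @examples
#' rpm_to_rps(500) # 8.333...
rpm_to_rps <- function(rpm) {
  stopifnot(is.numeric(rpm))
  rpm / 60
}

# Internal: scalar/vector numeric validation with a field-path style message.
check_num <- function(x, name, positive = FALSE, nonneg = FALSE,
                      finite = TRUE, scalar = FALSE) {
  if (!is.numeric(x) || length(x) == 0L) {
    stop(sprintf("'%s' must be numeric", name), call. = FALSE)
  }
  if (scalar && length(x) != 1L) {
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  }
  if (anyNA(x)) stop(sprintf("'%s' contains NA", name), call. = FALSE)
  if (finite && any(!is.finite(x))) {
    stop(sprintf("'%s' must be finite", name), call. = FALSE)
  }
  if (positive && any(x <= 0)) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  if (nonneg && any(x < 0)) {
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}

# Internal: cumulative trapezoidal integral of y over x; element 1 is 0.
trapz_cum <- function(x, y) {
  n <- length(x)
  if (n == 1L) return(0)
  c(0, cumsum(diff(x) * (y[-n] + y[-1]) / 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
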