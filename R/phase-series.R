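#' Phase series
#'
#' A sequence of wrapped phase angles, the common currency between the
#' modules of this package. Values must already lie in \eqn{[0, 2\pi)}; use
#' [wrap()] (or [as_phase_series()]) for raw angles.
#'
#' @param values numeric vector of angles in \eqn{[0, 2\pi)}, length >= 1.
#' @param dt optional sampling interval in seconds (> 0).
#' @param t0 start time in seconds, default 0.
#' @return numeric vector of class `"phase_series"` with attributes `dt`
#'   and `t0`.
#' @seealso [as_phase_series()]
#' @export
phase_series <- function(values, dt = NULL, t0 = 0) {
  if (length(values) < 1L) stop("phase_series() needs at least one value")
  if (any(!is.finite(values))) stop("phase values must be finite")
  if (any(values < 0 | values >= TWO_PI))
    stop("phase values must lie in [0, 2*pi); use wrap() first")
  if (!is.null(dt) && (!is.finite(dt) || dt <= 0)) stop("dt must be > 0")
  structure(as.numeric(values), dt = dt, t0 = t0, class = "phase_series")
}

#' Coerce angles to a phase series
#'
#' Wraps arbitrary finite angles onto \eqn{[0, 2\pi)} and builds a
#' [phase_series()].
#'
#' @inheritParams phase_series
#' @return a `"phase_series"` object.
#' @export
as_phase_series <- function(values, dt = NULL, t0 = 0) {
  if (inherits(values, "phase_series")) return(values)
  phase_series(wrap(as.numeric(values)), dt = dt, t0 = t0)
}

#' @export
print.phase_series <- function(x, ...) {
  dt <- attr(x, "dt")
  cat(sprintf("Phase series: %d samples%s\n", length(x),
              if (!is.null(dt)) sprintf(", dt = %g s", dt) else ""))
  print(utils::head(as.numeric(x), 10))
  if (length(x) > 10) cat("...\n")
  invisible(x)
}

# strip class/attributes for arithmetic-heavy internals
phase_values <- function(x) as.numeric(x)
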