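#' Wrap angles onto the circle
#'
#' Reduces real angles modulo \eqn{2\pi} onto \eqn{[0, 2\pi)}. This is the
#' wrapping step applied after every Euler-Maruyama update and whenever raw
#' phases enter the package.
#'
#' @param x numeric vector of angles in radians; must be finite.
#' @return numeric vector of the same length with all values in
#'   \eqn{[0, 2\pi)}; `x - wrap(x)` is an integer multiple of \eqn{2\pi}.
#' @examples
#' wrap(c(2 * pi, -pi / 2, 7.5))
#' @export
wrap <- function(x) {
  if (length(x) == 0L) return(numeric(0))
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("wrap() requires finite numeric angles")
  y <- x %% TWO_PI
  # guard against y == 2*pi from floating-point representation of x %% 2pi
  y[y >= TWO_PI] <- 0
  y
}

#' Signed minimal angular difference
#'
#' Maps `a - b` to the signed difference in \eqn{(-\pi, \pi]} along the
#' shorter arc. Internal workhorse for distances, unwrapping and truncation.
#'
#' @param a,b numeric angle vectors (recycled).
#' @return signed differences in \eqn{[-\pi, \pi)} (exact antipodes map to
#'   \eqn{-\pi}).
#' @keywords internal
angle_diff <- function(a, b) {
  ((a - b + pi) %% TWO_PI) - pi
}

#' Geodesic distance on the circle
#'
#' @param a,b numeric angle vectors in radians (recycled).
#' @return nonnegative distances in \eqn{[0, \pi]}; symmetric in its
#'   arguments.
#' @examples
#' circ_dist(0.1, 2 * pi - 0.1) # 0.2, shorter arc crosses 0
#' @export
circ_dist <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("circ_dist() requires finite angles")
  abs(angle_diff(a, b))
}

#' Mean resultant vector of a circular sample
#'
#' Computes the first trigonometric moment of a sample of angles: the mean
#' cosine C, mean sine S, mean resultant length \eqn{R = \sqrt{C^2 + S^2}}
#' and circular mean direction \eqn{\hat\mu = \mathrm{atan2}(S, C)}. When the
#' resultant is numerically zero (antipodal cancellation) the mean direction
#' is undefined and `defined` is `FALSE`.
#'
#' @param values numeric vector of angles in radians, length >= 1.
#' @return an object of class `"resultant_summary"`: a list with elements
#'   `C`, `S`, `R`, `mu_hat` (in \eqn{[0, 2\pi)}) and `defined`.
#' @examples
#' circ_mean_resultant(c(0, pi / 2))
#' @export
circ_mean_resultant <- function(values) {
  if (length(values) < 1L) stop("circ_mean_resultant() needs at least one angle")
  if (any(!is.finite(values))) stop("circ_mean_resultant() requires finite angles")
  C <- mean(cos(values))
  S <- mean(sin(values))
  R <- min(sqrt(C^2 + S^2), 1)
  defined <- R >= 1e-12
  mu_hat <- if (defined) wrap(atan2(S, C)) else NA_real_
  structure(list(C = C, S = S, R = R, mu_hat = mu_hat, defined = defined),
            class = "resultant_summary")
}

#' @export
print.resultant_summary <- function(x, ...) {
  cat("Circular resultant summary\n")
  cat(sprintf("  R = %.6f, C = %.6f, S = %.6f\n", x$R, x$C, x$S))
  if (x$defined) cat(sprintf("  mean direction = %.6f rad\n", x$mu_hat))
  else cat("  mean direction undefined (zero resultant)\n")
  invisible(x)
}

#' Circular mean direction
#'
#' Convenience wrapper returning just the mean direction of
#' [circ_mean_resultant()] (or `NA` when undefined).
#'
#' @param values numeric vector of angles in radians.
#' @return mean direction in \eqn{[0, 2\pi)}, or `NA_real_`.
#' @export
circ_mean <- function(values) circ_mean_resultant(values)$mu_hat

#' Concentration estimate from the mean resultant length
#'
#' Inverts the von Mises mean resultant length \eqn{R = A(\kappa) =
#' I_1(\kappa)/I_0(\kappa)} using the standard Mardia-Jupp piecewise
#' approximation:
#' \eqn{2R + R^3 + 5R^5/6} for \eqn{R < 0.53},
#' \eqn{-0.4 + 1.39R + 0.43/(1-R)} for \eqn{0.53 \le R < 0.85},
#' and \eqn{1/(R^3 - 4R^2 + 3R)} otherwise, capped at `1e6` as
#' \eqn{R \to 1}.
#'
#' @param R mean resultant length(s) in \eqn{[0, 1]}.
#' @return nonnegative concentration estimate(s); monotone nondecreasing in
#'   `R`, 0 at `R = 0`.
#' @examples
#' estimate_kappa(circ_mean_resultant(rvonmises(1000, pi / 4, 5, seed = 1))$R)
#' @export
estimate_kappa <- function(R) {
  if (any(!is.finite(R)) || any(R < 0) || any(R > 1))
    stop("estimate_kappa() requires R in [0, 1]")
  k <- ifelse(R < 0.53,
              2 * R + R^3 + 5 * R^5 / 6,
              ifelse(R < 0.85,
                     -0.4 + 1.39 * R + 0.43 / (1 - R),
                     1 / (R^3 - 4 * R^2 + 3 * R)))
  k[R == 0] <- 0
  pmin(pmax(k, 0), 1e6)
}
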