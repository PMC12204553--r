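check_pair <- function(theta1, theta2, min_len = 2L) {
  t1 <- phase_values(theta1); t2 <- phase_values(theta2)
  if (length(t1) != length(t2)) stop("phase series must have equal length")
  if (length(t1) < min_len) stop("phase series too short")
  list(t1 = t1, t2 = t2)
}

#' Phase-locking value
#'
#' \deqn{\mathrm{PLV} = \left| \frac{1}{N} \sum_n e^{i(\theta_1(t_n) -
#'   \theta_2(t_n))} \right|,} ranging from 0 (no synchronization) to 1
#' (perfect locking). Invariant to a constant offset between the series.
#'
#' @param theta1,theta2 equal-length angle vectors (or [phase_series()]).
#' @return PLV in `[0, 1]`.
#' @export
plv <- function(theta1, theta2) {
  p <- check_pair(theta1, theta2)
  min(Mod(mean(exp(1i * (p$t1 - p$t2)))), 1)
}

#' Directional phase synchronization index
#'
#' The argument of the mean complex phase-difference vector,
#' \deqn{\mathrm{DPSI} = \arg \frac{1}{N} \sum_n e^{i(\theta_1(t_n) -
#'   \theta_2(t_n))} \in (-\pi, \pi],}
#' i.e. the consistent phase offset between two rhythms. When the resultant
#' of the difference vector is numerically zero the index is undefined and
#' `NA` is returned with a warning.
#'
#' @inheritParams plv
#' @return DPSI in \eqn{(-\pi, \pi]}, or `NA_real_` when undefined.
#' @export
dpsi <- function(theta1, theta2) {
  p <- check_pair(theta1, theta2)
  z <- mean(exp(1i * (p$t1 - p$t2)))
  if (Mod(z) < 1e-12) {
    warning("DPSI undefined: zero resultant of the phase-difference vector")
    return(NA_real_)
  }
  Arg(z)
}

bin_index <- function(theta, bins) {
  idx <- floor(wrap(theta) / TWO_PI * bins) + 1L
  pmin(idx, bins)
}

#' Binned circular mutual information
#'
#' Plug-in mutual information between two phase series from their
#' `bins x bins` joint histogram on \eqn{[0, 2\pi)^2}, in nats. Zero-count
#' cells contribute nothing. The optional Miller-Madow correction adds
#' \eqn{(B_{xy} - B_x - B_y + 1)/(2n)} (counts of nonzero joint/marginal
#' bins) to offset plug-in bias.
#'
#' @inheritParams plv
#' @param bins number of equal-width bins per axis, >= 2; default 16.
#' @param correction `"none"` (default, the plain plug-in) or
#'   `"miller-madow"`.
#' @return mutual information in nats, >= 0.
#' @examples
#' th <- wrap(seq(0, 2 * pi, length.out = 161)[-161])
#' circ_mi(th, th, bins = 16) # log(16): perfectly dependent
#' @export
circ_mi <- function(theta1, theta2, bins = 16,
                    correction = c("none", "miller-madow")) {
  correction <- match.arg(correction)
  if (bins < 2) stop("bins must be >= 2")
  p <- check_pair(theta1, theta2)
  n <- length(p$t1)
  i1 <- bin_index(p$t1, bins); i2 <- bin_index(p$t2, bins)
  joint <- matrix(tabulate((i1 - 1L) * bins + i2, nbins = bins * bins),
                  nrow = bins) / n
  px <- colSums(joint); py <- rowSums(joint)
  nz <- joint > 0
  outer_p <- outer(py, px)
  mi <- sum(joint[nz] * log(joint[nz] / outer_p[nz]))
  if (correction == "miller-madow")
    mi <- mi + (sum(nz) - sum(px > 0) - sum(py > 0) + 1) / (2 * n)
  max(mi, 0)
}

#' Pairwise synchronization report
#'
#' Bundles the three pairwise synchrony metrics computed on two wrapped
#' phase series: [plv()], [circ_mi()] and [dpsi()].
#'
#' @inheritParams circ_mi
#' @return an object of class `"sync_report"`: list with `plv`, `mi`,
#'   `dpsi`, `n` and `bins`.
#' @export
sync_report <- function(theta1, theta2, bins = 16,
                        correction = c("none", "miller-madow")) {
  p <- check_pair(theta1, theta2)
  structure(list(plv = plv(p$t1, p$t2),
                 mi = circ_mi(p$t1, p$t2, bins = bins, correction = correction),
                 dpsi = dpsi(p$t1, p$t2),
                 n = length(p$t1), bins = bins),
            class = "sync_report")
}

#' @export
print.sync_report <- function(x, ...) {
  cat(sprintf("Synchronization report (n = %d, %d bins)\n", x$n, x$bins))
  cat(sprintf("  PLV  = %.4f\n  MI   = %.4f nats\n  DPSI = %.4f rad\n",
              x$plv, x$mi, x$dpsi))
  invisible(x)
}

#' Joint phase histogram
#'
#' The `bins x bins` count matrix underlying [circ_mi()], exportable as
#' delimited text for heatmap rendering.
#'
#' @inheritParams circ_mi
#' @return integer matrix of joint counts; rows index `theta2` bins,
#'   columns `theta1` bins.
#' @export
joint_phase_histogram <- function(theta1, theta2, bins = 16) {
  p <- check_pair(theta1, theta2)
  i1 <- bin_index(p$t1, bins); i2 <- bin_index(p$t2, bins)
  matrix(tabulate((i1 - 1L) * bins + i2, nbins = bins * bins), nrow = bins)
}
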