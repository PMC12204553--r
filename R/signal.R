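#' Raw sampled signal
#'
#' A one-dimensional real-valued signal with a sampling rate and an optional
#' mask of missing samples.
#'
#' @param samples numeric vector (arbitrary units). Positions flagged in
#'   `gap_mask` may be `NA`.
#' @param fs sampling rate in Hz (> 0).
#' @param gap_mask optional logical vector marking missing samples; same
#'   length as `samples`.
#' @return an object of class `"raw_signal"`.
#' @export
raw_signal <- function(samples, fs, gap_mask = NULL) {
  if (!is.finite(fs) || fs <= 0) stop("fs must be > 0")
  samples <- as.numeric(samples)
  if (!is.null(gap_mask)) {
    gap_mask <- as.logical(gap_mask)
    if (length(gap_mask) != length(samples))
      stop("gap_mask length must equal samples length")
  }
  observed <- if (is.null(gap_mask)) samples else samples[!gap_mask]
  if (any(!is.finite(observed))) stop("observed samples must be finite")
  structure(list(samples = samples, fs = fs, gap_mask = gap_mask),
            class = "raw_signal")
}

#' @export
print.raw_signal <- function(x, ...) {
  gaps <- if (is.null(x$gap_mask)) 0L else sum(x$gap_mask)
  cat(sprintf("Raw signal: %d samples at %g Hz (%d missing)\n",
              length(x$samples), x$fs, gaps))
  invisible(x)
}

has_gaps <- function(x) !is.null(x$gap_mask) && any(x$gap_mask)

#' Z-score normalization
#'
#' Centers and scales a signal to zero mean and unit variance. The Hilbert
#' phase is invariant to positive affine rescaling, so this step only guards
#' numerics downstream.
#'
#' @param x a [raw_signal()] without unfilled gaps.
#' @return a normalized `"raw_signal"`.
#' @export
normalize_signal <- function(x) {
  stopifnot(inherits(x, "raw_signal"))
  if (has_gaps(x)) stop("impute gaps before normalization")
  s <- sd(x$samples)
  if (!is.finite(s) || s == 0) stop("cannot normalize a constant signal")
  raw_signal((x$samples - mean(x$samples)) / s, x$fs)
}

# analytic signal via the FFT construction (one-sided spectrum doubling)
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1L) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Hilbert-transform phase extraction
#'
#' Builds the analytic signal \eqn{\hat x(t) = x(t) + i\,\mathcal{H}[x](t)}
#' via the FFT one-sided-spectrum construction and returns its instantaneous
#' phase \eqn{\theta(t) = \arg \hat x(t)} wrapped to \eqn{[0, 2\pi)} together
#' with the amplitude envelope \eqn{|\hat x(t)|}. The finite-length
#' transform distorts the first and last few percent of samples; interior
#' samples of a pure unit cosine have envelope \eqn{\approx 1} and phase
#' advancing at the cosine's angular frequency.
#'
#' @param x a [raw_signal()] with at least 8 samples and no unfilled gaps.
#' @return an object of class `"analytic_phase"`: list with `phase` (a
#'   [phase_series()] with `dt = 1/fs`) and `envelope`.
#' @examples
#' t <- seq(0, 10, by = 1 / 360)[-3601]
#' ap <- extract_phase(raw_signal(cos(2 * pi * t), fs = 360))
#' head(ap$envelope)
#' @export
extract_phase <- function(x) {
  stopifnot(inherits(x, "raw_signal"))
  if (has_gaps(x)) stop("impute gaps before phase extraction")
  if (length(x$samples) < 8L) stop("phase extraction needs >= 8 samples")
  z <- analytic_signal(x$samples)
  structure(list(phase = phase_series(wrap(Arg(z)), dt = 1 / x$fs),
                 envelope = Mod(z)),
            class = "analytic_phase")
}

#' @export
print.analytic_phase <- function(x, ...) {
  cat(sprintf("Analytic phase: %d samples, dt = %g s\n", length(x$phase),
              attr(x$phase, "dt")))
  invisible(x)
}

#' Circular outlier treatment
#'
#' Computes each observation's geodesic deviation \eqn{d_i =
#' \mathrm{circ\_dist}(\theta_i, \hat\mu)} from the sample circular mean and
#' treats extremes (\eqn{d_i > \pi/2}, i.e. more than 90 degrees away):
#' \describe{
#'   \item{`"weight"`}{returns Gaussian circular-kernel weights
#'     \eqn{w_i = \exp(-d_i^2 / 2\tau^2)} for downweighted estimation;}
#'   \item{`"truncate"`}{maps each flagged angle to the nearer of
#'     \eqn{\hat\mu \pm \pi/2} along the shorter arc (exact antipodes go to
#'     \eqn{\hat\mu + \pi/2});}
#'   \item{`"none"`}{reports distances and flags only.}
#' }
#'
#' @param theta numeric angle vector (or [phase_series()]), nonempty, with a
#'   defined circular mean.
#' @param mode `"weight"`, `"truncate"` or `"none"`.
#' @param tau kernel scale in radians (> 0); default `pi/4`.
#' @param mu optional reference direction; by default the sample circular
#'   mean is estimated from the data.
#' @return an object of class `"outlier_treatment"`: list with `values`
#'   (treated angles; unchanged except under `"truncate"`), `weights`
#'   (`NULL` unless `mode = "weight"`), `dist`, `flagged` and `mu_hat`.
#' @export
treat_outliers <- function(theta, mode = c("weight", "truncate", "none"),
                           tau = pi / 4, mu = NULL) {
  mode <- match.arg(mode)
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0")
  th <- wrap(phase_values(theta))
  if (is.null(mu)) {
    res <- circ_mean_resultant(th)
    if (!res$defined) stop("circular mean undefined: cannot score outliers")
    mu <- res$mu_hat
  } else {
    mu <- wrap(mu)
  }
  dev <- angle_diff(th, mu) # signed, in [-pi, pi)
  d <- abs(dev)
  flagged <- d > pi / 2
  values <- th
  weights <- NULL
  if (mode == "weight") {
    weights <- exp(-d^2 / (2 * tau^2))
  } else if (mode == "truncate") {
    side <- ifelse(dev > 0, 1, -1)
    side[dev <= -pi + 1e-12] <- 1 # antipodal tie goes to mu + pi/2
    values[flagged] <- wrap(mu + side[flagged] * pi / 2)
  }
  structure(list(values = values, weights = weights, dist = d,
                 flagged = flagged, mu_hat = mu, mode = mode,
                 tau = tau),
            class = "outlier_treatment")
}

#' Geodesic phase bridging
#'
#' Linear interpolation on the unit circle between two known phases across a
#' gap of `k` steps, along the shorter arc:
#' \eqn{\theta_{j+\ell} = \arg\{e^{i\theta_a(1 - \ell/k)} e^{i\theta_b
#' \ell/k}\}} evaluated as \eqn{\theta_a + (\ell/k)\,\delta} with
#' \eqn{\delta} the signed minimal difference. Antipodal endpoints have no
#' unique geodesic and raise an error.
#'
#' @param theta_a,theta_b endpoint angles in radians.
#' @param k gap length in steps (>= 2); the endpoints sit `k` steps apart.
#' @return the `k - 1` interior angles in \eqn{[0, 2\pi)}.
#' @examples
#' bridge_phase_gap(7 * pi / 4, pi / 4, k = 2) # midpoint 0, through zero
#' @export
bridge_phase_gap <- function(theta_a, theta_b, k) {
  if (k < 2) stop("bridge_phase_gap() needs k >= 2")
  a <- wrap(theta_a); b <- wrap(theta_b)
  delta <- angle_diff(b, a)
  if (abs(abs(delta) - pi) < 1e-12)
    stop("antipodal endpoints: geodesic interpolation is not unique")
  ell <- seq_len(k - 1)
  wrap(a + delta * ell / k)
}

#' Cubic-spline gap imputation
#'
#' Fills interior gaps of a sampled signal with a cubic spline fitted
#' through the observed samples, leaving observed samples untouched. Spline
#' interpolation is exact for signals that are (piecewise-global) cubic
#' polynomials. Gaps at the sequence boundary, or longer than `max_gap`
#' seconds, cannot be bridged reliably and raise an error naming the gap.
#'
#' @param x a [raw_signal()] whose `gap_mask` marks the missing samples.
#' @param max_gap maximum gap length in seconds; default 0.25.
#' @return a `"raw_signal"` with all gaps filled and no `gap_mask`.
#' @export
spline_impute <- function(x, max_gap = 0.25) {
  stopifnot(inherits(x, "raw_signal"))
  if (!has_gaps(x)) return(raw_signal(x$samples, x$fs))
  mask <- x$gap_mask
  n <- length(x$samples)
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  max_len <- max_gap * x$fs
  for (r in which(runs$values)) {
    if (starts[r] == 1L || ends[r] == n)
      stop(sprintf("gap at samples %d-%d touches the sequence boundary",
                   starts[r], ends[r]))
    if (runs$lengths[r] > max_len)
      stop(sprintf("gap at samples %d-%d exceeds max_gap = %g s (%g samples)",
                   starts[r], ends[r], max_gap, max_len))
  }
  obs <- which(!mask)
  f <- splinefun(obs, x$samples[obs], method = "fmm")
  out <- x$samples
  out[mask] <- f(which(mask))
  raw_signal(out, x$fs)
}
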