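#' Moving circular mean filter
#'
#' Smooths a wrapped phase series by replacing each sample with the circular
#' mean (resultant direction) of its centered window; the window shrinks at
#' the series edges. A window whose resultant is numerically zero leaves the
#' central sample unchanged.
#'
#' @param theta numeric angle vector (or [phase_series()]).
#' @param window odd window length >= 1.
#' @return smoothed angles in \eqn{[0, 2\pi)} (a [phase_series()] when the
#'   input was one, otherwise a plain numeric vector).
#' @export
moving_circ_mean <- function(theta, window) {
  if (length(window) != 1L || window < 1 || window %% 2 == 0)
    stop("window must be an odd count >= 1")
  th <- wrap(phase_values(theta))
  if (window == 1L) return(if (inherits(theta, "phase_series")) theta else th)
  n <- length(th)
  half <- (window - 1) / 2
  cc <- cumsum(cos(th)); ss <- cumsum(sin(th))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  C <- cc[hi] - c(0, cc)[lo]
  S <- ss[hi] - c(0, ss)[lo]
  out <- wrap(atan2(S, C))
  undef <- sqrt(C^2 + S^2) < 1e-12
  out[undef] <- th[undef]
  if (inherits(theta, "phase_series"))
    phase_series(out, dt = attr(theta, "dt"), t0 = attr(theta, "t0"))
  else out
}

detection_result <- function(predictions, scores, method, config) {
  structure(list(predictions = as.integer(predictions), scores = scores,
                 method = method, config = config),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("Detection result (%s): %d / %d samples flagged\n", x$method,
              sum(x$predictions), length(x$predictions)))
  invisible(x)
}

# inverse-ECDF percentile with strict ">" exceedance; ties excluded
percentile_threshold <- function(scores, percentile) {
  quantile(scores, percentile / 100, type = 1, names = FALSE)
}

#' Circular-SDE phase-deviation detector
#'
#' The phase-anomaly detector: extract the Hilbert phase of the signal,
#' smooth it with a moving circular mean, and flag samples whose geodesic
#' deviation \eqn{D(t) = \mathrm{circ\_dist}(\theta(t), \bar\theta)} from
#' the global circular mean \eqn{\bar\theta} (computed on the smoothed
#' series) exceeds `threshold_rad`. When the phase sweeps the cycle nearly
#' uniformly the flag rate is approximately \eqn{(\pi -
#' \mathrm{threshold})/\pi}.
#'
#' @param x a [raw_signal()].
#' @param threshold_rad deviation threshold in radians, in \eqn{(0, \pi]};
#'   default 3.
#' @param smooth_window odd moving-circular-mean window in samples;
#'   default 5.
#' @return a `"detection_result"`: per-sample binary `predictions` and
#'   deviation `scores` \eqn{D(t) \in [0, \pi]}.
#' @export
detect_sde_phase <- function(x, threshold_rad = 3, smooth_window = 5) {
  stopifnot(inherits(x, "raw_signal"))
  if (!is.finite(threshold_rad) || threshold_rad <= 0 || threshold_rad > pi)
    stop("threshold_rad must be in (0, pi]")
  theta <- extract_phase(x)$phase
  sm <- moving_circ_mean(theta, smooth_window)
  res <- circ_mean_resultant(phase_values(sm))
  if (!res$defined) stop("global circular mean undefined")
  D <- circ_dist(phase_values(sm), res$mu_hat)
  detection_result(D > threshold_rad, D, "sde",
                   list(threshold_rad = threshold_rad,
                        smooth_window = smooth_window))
}

#' Autoregressive residual detector
#'
#' Baseline amplitude-domain detector: fit an AR(`order`) model to the raw
#' signal by ordinary least squares on lagged samples (with intercept) over
#' the full record, score each sample by its absolute one-step-ahead
#' residual, and flag scores strictly above the `percentile`-th percentile
#' of the scored samples. The first `order` samples cannot be scored and are
#' reported as 0 / not flagged.
#'
#' @param x a [raw_signal()] with more than `order` samples.
#' @param order AR order; default 5.
#' @param percentile residual percentile threshold in (0, 100); default 75.
#' @return a `"detection_result"` with per-sample scores and flags.
#' @export
detect_ar <- function(x, order = 5, percentile = 75) {
  stopifnot(inherits(x, "raw_signal"))
  s <- x$samples
  n <- length(s)
  if (n <= order + 1L) stop("signal too short for the AR order")
  if (percentile <= 0 || percentile >= 100) stop("percentile must be in (0, 100)")
  if (sd(s) == 0) stop("constant signal: AR design is singular")
  lagged <- stats::embed(s, order + 1L)
  y <- lagged[, 1L]
  X <- cbind(1, lagged[, -1L, drop = FALSE])
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) stop("singular AR design matrix")
  resid <- abs(y - X %*% qr.coef(qr_X, y))
  scores <- c(rep(0, order), resid)
  thr <- percentile_threshold(resid, percentile)
  pred <- scores > thr
  pred[seq_len(order)] <- FALSE
  detection_result(pred, scores, "ar",
                   list(order = order, percentile = percentile))
}

#' Windowed Fourier power detector
#'
#' Baseline frequency-domain detector: segment the signal into
#' `window_sec`-second windows with fractional `overlap`, compute each
#' window's total spectral power \eqn{\sum_k |X_k|^2 / L} (Parseval: the
#' window's sum of squares), flag windows strictly above the
#' `percentile`-th percentile across windows, and mark every sample covered
#' by at least one flagged window as positive. A sample's score is the
#' maximum power among the windows covering it.
#'
#' @param x a [raw_signal()].
#' @param window_sec window length in seconds; default 1.
#' @param overlap fractional window overlap in `[0, 1)`; default 0.5.
#' @param percentile power percentile threshold in (0, 100); default 90.
#' @return a `"detection_result"` with per-sample scores and flags.
#' @export
detect_fourier <- function(x, window_sec = 1, overlap = 0.5,
                           percentile = 90) {
  stopifnot(inherits(x, "raw_signal"))
  s <- x$samples
  n <- length(s)
  wlen <- round(window_sec * x$fs)
  if (wlen < 2 || wlen > n) stop("window does not fit the signal")
  step <- max(1L, round(wlen * (1 - overlap)))
  starts <- seq.int(1L, n - wlen + 1L, by = step)
  if (length(starts) < 3L) stop("fewer than 3 windows: shorten window_sec")
  power <- vapply(starts, function(s0) {
    seg <- s[s0:(s0 + wlen - 1L)]
    sum(Mod(fft(seg))^2) / wlen
  }, numeric(1L))
  thr <- percentile_threshold(power, percentile)
  flagged_w <- power > thr
  scores <- numeric(n)
  pred <- logical(n)
  for (w in seq_along(starts)) {
    idx <- starts[w]:(starts[w] + wlen - 1L)
    scores[idx] <- pmax(scores[idx], power[w])
    if (flagged_w[w]) pred[idx] <- TRUE
  }
  detection_result(pred, scores, "fourier",
                   list(window_sec = window_sec, overlap = overlap,
                        percentile = percentile, n_windows = length(starts),
                        flagged_windows = sum(flagged_w)))
}

#' Run a detector by name
#'
#' Dispatcher over the three per-sample anomaly detectors.
#'
#' @param x a [raw_signal()].
#' @param method `"sde"`, `"ar"` or `"fourier"`.
#' @param ... passed to the selected detector.
#' @return a `"detection_result"`.
#' @export
detect_anomalies <- function(x, method = c("sde", "ar", "fourier"), ...) {
  method <- match.arg(method)
  switch(method,
         sde = detect_sde_phase(x, ...),
         ar = detect_ar(x, ...),
         fourier = detect_fourier(x, ...))
}

#' Binary classification metrics
#'
#' Confusion counts and accuracy/precision/recall/F1 for per-sample
#' detector evaluation. Zero-denominator conventions: precision, recall and
#' F1 are 0 when undefined.
#'
#' @param y_true,y_pred equal-length binary (0/1 or logical) vectors.
#' @return an object of class `"metrics_report"`: list with `tp`, `fp`,
#'   `tn`, `fn`, `accuracy`, `precision`, `recall`, `f1` and `n`.
#' @export
classification_metrics <- function(y_true, y_pred) {
  y_true <- as.integer(as.logical(y_true))
  y_pred <- as.integer(as.logical(y_pred))
  if (length(y_true) != length(y_pred)) stop("label length mismatch")
  if (any(is.na(y_true)) || any(is.na(y_pred))) stop("labels must be binary")
  tp <- sum(y_true == 1L & y_pred == 1L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  n <- length(y_true)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, n = n,
                 accuracy = (tp + tn) / n, precision = precision,
                 recall = recall, f1 = f1),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Classification metrics (n = %d)\n", x$n))
  cat(sprintf("  tp %d  fp %d  tn %d  fn %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}
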