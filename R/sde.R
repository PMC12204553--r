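#' Circular SDE model
#'
#' Specifies a system of `p` phase diffusions on the circle
#' \deqn{d\theta_i = \left[\omega_i + \sum_{j \ne i} K_{ij}
#'   \sin(\theta_j - \theta_i)\right] dt + \sigma_i \, dB_i(t),}
#' i.e. constant angular drift, Brownian diffusion, and optional
#' Kuramoto-type sinusoidal coupling.
#'
#' @param omega drift vector in rad/s (length `p`).
#' @param sigma diffusion vector in rad/\eqn{\sqrt{s}}, elementwise >= 0.
#' @param coupling optional `p x p` coupling matrix \eqn{K_{ij}} in 1/s with
#'   zero diagonal; `NULL` (default) means uncoupled.
#' @return an object of class `"sde_model"`.
#' @examples
#' sde_model(omega = c(1.0, 1.2, 1.5), sigma = c(0.5, 0.4, 0.3))
#' @export
sde_model <- function(omega, sigma, coupling = NULL) {
  p <- length(omega)
  if (length(sigma) != p) stop("omega and sigma must share length")
  if (any(!is.finite(omega)) || any(!is.finite(sigma)) || any(sigma < 0))
    stop("omega must be finite and sigma finite, >= 0")
  if (!is.null(coupling)) {
    coupling <- as.matrix(coupling)
    if (!all(dim(coupling) == c(p, p)))
      stop("coupling must be a p x p matrix matching omega")
    if (any(diag(coupling) != 0)) stop("coupling must have zero diagonal")
  }
  structure(list(omega = as.numeric(omega), sigma = as.numeric(sigma),
                 coupling = coupling, p = p), class = "sde_model")
}

#' @export
print.sde_model <- function(x, ...) {
  cat(sprintf("Circular SDE model, p = %d\n", x$p))
  cat("  omega:", format(x$omega), "rad/s\n")
  cat("  sigma:", format(x$sigma), "rad/sqrt(s)\n")
  cat("  coupling:", if (is.null(x$coupling) || all(x$coupling == 0))
    "none" else "Kuramoto-type", "\n")
  invisible(x)
}

# explicit Euler-Maruyama step loop; noise drawn per step, component-major
simulate_sde_loop <- function(model, theta0, n_steps, dt) {
  p <- model$p
  K <- model$coupling
  sig_sqdt <- model$sigma * sqrt(dt)
  phases <- matrix(NA_real_, nrow = p, ncol = n_steps)
  phases[, 1L] <- wrap(theta0)
  th <- phases[, 1L]
  for (n in seq_len(n_steps - 1L)) {
    drift <- model$omega
    if (!is.null(K)) {
      # coupling evaluated at the previous step's phases (explicit scheme)
      drift <- drift + rowSums(K * sin(outer(th, th, function(a, b) b - a)))
    }
    th <- wrap(th + drift * dt + sig_sqdt * rnorm(p))
    phases[, n + 1L] <- th
  }
  phases
}

# vectorised uncoupled path; identical RNG stream to simulate_sde_loop
simulate_sde_fast <- function(model, theta0, n_steps, dt) {
  p <- model$p
  xi <- matrix(rnorm(p * (n_steps - 1L)), nrow = p)
  inc <- model$omega * dt + model$sigma * sqrt(dt) * xi
  raw <- cbind(theta0, theta0 + rowCumsum(inc))
  dimnames(raw) <- NULL
  wrap_matrix(raw)
}

rowCumsum <- function(m) {
  if (ncol(m) == 1L) return(m)
  t(apply(m, 1L, cumsum))
}

wrap_matrix <- function(m) {
  out <- m %% TWO_PI
  out[out >= TWO_PI] <- 0
  matrix(out, nrow = nrow(m), dimnames = dimnames(m))
}

#' Simulate a circular SDE path
#'
#' Euler-Maruyama integration on the circle: each step adds the drift (plus
#' any Kuramoto coupling term evaluated at the previous step's phases) and a
#' Gaussian increment \eqn{\sigma\sqrt{\Delta t}\,\xi}, then wraps modulo
#' \eqn{2\pi}. Noise is drawn per step in component-major order from one
#' seeded generator, so coupled and uncoupled code paths share the same
#' stream and runs are reproducible by seed.
#'
#' @param model an [sde_model()].
#' @param theta0 initial phase vector (length `p`), any finite angles.
#' @param n_steps number of stored time points `N` (>= 2); the path contains
#'   `theta0` followed by `N - 1` update steps.
#' @param dt time step in seconds (> 0).
#' @param seed optional integer seed.
#' @return an object of class `"sde_path"`: list with `phases` (`p x N`
#'   matrix of wrapped angles), `dt`, `seed` and `model`.
#' @examples
#' m <- sde_model(1.0, 0.5)
#' path <- simulate_sde(m, theta0 = 0, n_steps = 1000, dt = 0.01, seed = 1)
#' estimate_drift_diffusion(path)
#' @export
simulate_sde <- function(model, theta0, n_steps, dt, seed = NULL) {
  stopifnot(inherits(model, "sde_model"))
  if (length(theta0) != model$p)
    stop("theta0 length must match the model dimension")
  if (any(!is.finite(theta0))) stop("theta0 must be finite")
  if (length(n_steps) != 1L || n_steps < 2) stop("n_steps must be >= 2")
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n_steps <- as.integer(n_steps)
  uncoupled <- is.null(model$coupling) || all(model$coupling == 0)
  theta0 <- wrap(theta0)
  phases <- if (uncoupled) simulate_sde_fast(model, theta0, n_steps, dt)
            else simulate_sde_loop(model, theta0, n_steps, dt)
  structure(list(phases = phases, dt = dt, seed = seed, model = model),
            class = "sde_path")
}

#' @export
print.sde_path <- function(x, ...) {
  cat(sprintf("Circular SDE path: p = %d, N = %d, dt = %g s\n",
              nrow(x$phases), ncol(x$phases), x$dt))
  invisible(x)
}

#' Unwrap a phase sequence
#'
#' Reconstructs a continuous real-valued phase path from wrapped angles by
#' the minimal-jump rule: each successive increment is mapped to
#' \eqn{(-\pi, \pi]}, so `wrap(unwrap_phase(theta))` reproduces `theta`
#' elementwise.
#'
#' @param theta numeric vector of wrapped angles (or a [phase_series()]),
#'   length >= 2.
#' @return numeric vector of unwrapped (cumulative) phases.
#' @examples
#' unwrap_phase(c(0.05, 2 * pi - 0.05)) # increment is -0.1, not +2*pi-0.1
#' @export
unwrap_phase <- function(theta) {
  theta <- phase_values(theta)
  if (length(theta) < 2L) stop("unwrap_phase() needs at least 2 values")
  d <- angle_diff(theta[-1L], theta[-length(theta)])
  theta[1L] + cumsum(c(0, d))
}

#' Estimate drift and diffusion from a wrapped phase path
#'
#' For each rhythm, the wrapped path is unwrapped (minimal-jump rule) and the
#' increments \eqn{\Delta\tilde\theta} give method-of-moments estimates
#' \deqn{\hat\omega = \mathrm{mean}(\Delta\tilde\theta)/\Delta t, \qquad
#'   \hat\sigma = \mathrm{sd}(\Delta\tilde\theta)/\sqrt{\Delta t}.}
#'
#' @param path an [simulate_sde()] result, or a numeric matrix/vector of
#'   wrapped phases (rows = rhythms) together with `dt`.
#' @param dt time step in seconds; taken from `path` when it is an
#'   `"sde_path"`.
#' @return an object of class `"drift_diffusion_estimate"`: list with
#'   `omega_hat` and `sigma_hat` (one entry per rhythm) and `dt`.
#' @export
estimate_drift_diffusion <- function(path, dt = NULL) {
  if (inherits(path, "sde_path")) {
    phases <- path$phases
    dt <- path$dt
  } else {
    phases <- if (is.matrix(path)) path else matrix(phase_values(path), nrow = 1L)
    if (is.null(dt)) dt <- attr(path, "dt")
    if (is.null(dt)) stop("dt must be supplied for raw phase input")
  }
  if (ncol(phases) < 3L) stop("drift/diffusion estimation needs N >= 3")
  est <- apply(phases, 1L, function(th) {
    d <- diff(unwrap_phase(th))
    c(mean(d) / dt, sd(d) / sqrt(dt))
  })
  structure(list(omega_hat = unname(est[1L, ]), sigma_hat = unname(est[2L, ]),
                 dt = dt), class = "drift_diffusion_estimate")
}

#' @export
print.drift_diffusion_estimate <- function(x, ...) {
  cat("Drift/diffusion estimates (per rhythm)\n")
  cat("  omega_hat:", format(x$omega_hat, digits = 5), "rad/s\n")
  cat("  sigma_hat:", format(x$sigma_hat, digits = 5), "rad/sqrt(s)\n")
  invisible(x)
}
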