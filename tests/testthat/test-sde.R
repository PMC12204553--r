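test_that("noise-free simulation is the exact closed-form rotation", {
  m <- sde_model(omega = 2, sigma = 0)
  path <- simulate_sde(m, theta0 = 0, n_steps = 500, dt = 0.01, seed = 1)
  expect_equal(as.numeric(path$phases[1, ]), wrap(0.02 * (0:499)),
               tolerance = 1e-12)
})

test_that("strong Kuramoto coupling synchronizes identical oscillators", {
  K <- matrix(5, 3, 3); diag(K) <- 0
  m <- sde_model(omega = rep(1, 3), sigma = rep(0, 3), coupling = K)
  path <- simulate_sde(m, theta0 = c(0.2, 1.0, 1.6), n_steps = 2000,
                       dt = 0.01, seed = 1)
  last <- path$phases[, 2000]
  pairs <- combn(3, 2)
  gaps <- apply(pairs, 2, function(ij) circ_dist(last[ij[1]], last[ij[2]]))
  expect_lt(max(gaps), 1e-3)
})

test_that("simulation is seed-reproducible and dimension-checked", {
  m <- sde_model(c(1, 1.2), c(0.5, 0.4))
  p1 <- simulate_sde(m, c(0, 0), 100, 0.01, seed = 5)
  p2 <- simulate_sde(m, c(0, 0), 100, 0.01, seed = 5)
  expect_identical(p1$phases, p2$phases)
  expect_true(all(p1$phases >= 0 & p1$phases < 2 * pi))
  expect_error(simulate_sde(m, 0, 100, 0.01), "theta0")
  expect_error(sde_model(c(1, 2), 0.5), "length")
  expect_error(sde_model(1, 0.5, coupling = matrix(1, 1, 1)), "diagonal")
})

test_that("vectorised uncoupled path equals the step loop on one RNG stream", {
  m <- sde_model(c(1, 1.5, 0.7), c(0.5, 0.2, 0.9))
  set.seed(42)
  fast <- circsde:::simulate_sde_fast(m, c(0, 1, 2), 200, 0.05)
  set.seed(42)
  loop <- circsde:::simulate_sde_loop(m, c(0, 1, 2), 200, 0.05)
  expect_equal(fast, loop, tolerance = 1e-12)
})

test_that("unwrapping follows the minimal-jump rule and inverts wrapping", {
  # observed jump from 0.05 to 2*pi - 0.05 unwraps to a -0.1 step
  u <- unwrap_phase(c(0.05, 2 * pi - 0.05))
  expect_equal(diff(u), -0.1, tolerance = 1e-12)

  set.seed(8)
  th <- wrap(cumsum(runif(300, -2, 2)) * 0.4)
  u <- unwrap_phase(th)
  expect_equal(wrap(u), th, tolerance = 1e-9)
  expect_true(all(abs(diff(u)) <= pi + 1e-12))

  # drifting path with sub-pi steps unwraps to a strictly increasing path
  mono <- wrap(0.3 * (0:100))
  expect_true(all(diff(unwrap_phase(mono)) > 0))
})

test_that("drift/diffusion estimators are exact on noise-free paths", {
  m <- sde_model(2, 0)
  path <- simulate_sde(m, 0, 1000, 0.01, seed = 1)
  est <- estimate_drift_diffusion(path)
  expect_equal(est$omega_hat, 2, tolerance = 1e-9)
  expect_equal(est$sigma_hat, 0, tolerance = 1e-9)
  expect_error(estimate_drift_diffusion(matrix(c(0, 1), 1), dt = 0.1), "N >= 3")
})

test_that("a single stochastic run lands within sampling error of the truth", {
  # omega = 1, sigma = 0.5, N = 1000, dt = 0.01: |omega_hat - 1| < 3*0.5/sqrt(10)
  m <- sde_model(1.0, 0.5)
  est <- estimate_drift_diffusion(simulate_sde(m, 0, 1000, 0.01, seed = 33))
  expect_lt(abs(est$omega_hat - 1.0), 0.47)
  expect_lt(abs(est$sigma_hat - 0.5), 0.1)
})

test_that("drift estimator is unbiased over replicates", {
  m <- sde_model(1.0, 0.5)
  set.seed(99)
  oh <- replicate(200, estimate_drift_diffusion(
    simulate_sde(m, 0, 1000, 0.01))$omega_hat)
  se <- sd(oh) / sqrt(length(oh))
  expect_lt(abs(mean(oh) - 1.0), 3 * se)
})

test_that("squared diffusion estimates center on sigma^2", {
  m <- sde_model(1.0, 0.5)
  set.seed(100)
  sh2 <- replicate(300, estimate_drift_diffusion(
    simulate_sde(m, 0, 1000, 0.01))$sigma_hat^2)
  expect_lt(abs(mean(sh2) - 0.25) / 0.25, 0.05)
})

test_that("uncoupled marginal increments match their theoretical moments", {
  # with K = 0 each component diffuses independently of p
  m3 <- sde_model(c(1, 5, -2), c(0.5, 0.1, 1.0))
  path <- simulate_sde(m3, c(0, 0, 0), 5000, 0.01, seed = 17)
  for (i in 1:3) {
    d <- diff(unwrap_phase(path$phases[i, ]))
    expect_lt(abs(mean(d) - m3$omega[i] * 0.01), 4 * m3$sigma[i] * 0.1 / sqrt(4999))
    expect_lt(abs(sd(d) / 0.1 - m3$sigma[i]) / m3$sigma[i], 0.05)
  }
})
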