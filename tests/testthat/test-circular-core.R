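test_that("wrap maps angles onto [0, 2*pi) and is idempotent", {
  expect_equal(wrap(2 * pi), 0)
  expect_equal(wrap(-pi / 2), 3 * pi / 2)
  expect_equal(wrap(7.5), 7.5 - 2 * pi, tolerance = 1e-12)

  x <- c(random_angles(200, 1) * 10 - 30, -2 * pi, 4 * pi, 0)
  w <- wrap(x)
  expect_true(all(w >= 0 & w < 2 * pi))
  expect_equal(wrap(w), w)
  # x - wrap(x) is an integer multiple of 2*pi
  k <- (x - w) / (2 * pi)
  expect_equal(k, round(k), tolerance = 1e-9)

  expect_error(wrap(NA_real_), "finite")
  expect_error(wrap(Inf), "finite")
})

test_that("circ_dist is the geodesic distance: symmetric, bounded, triangular", {
  expect_equal(circ_dist(0.7, 0.7), 0)
  expect_equal(circ_dist(0, pi), pi)
  expect_equal(circ_dist(0.1, 2 * pi - 0.1), 0.2, tolerance = 1e-12)

  a <- random_angles(100, 2); b <- random_angles(100, 3)
  c_ <- random_angles(100, 4)
  expect_equal(circ_dist(a, b), circ_dist(b, a))
  expect_true(all(circ_dist(a, b) >= 0 & circ_dist(a, b) <= pi))
  expect_true(all(circ_dist(a, c_) <= circ_dist(a, b) + circ_dist(b, c_) + 1e-12))
})

test_that("circ_mean_resultant matches hand-computed trigonometric moments", {
  r <- circ_mean_resultant(rep(1.3, 5))
  expect_equal(r$R, 1, tolerance = 1e-12)
  expect_equal(r$mu_hat, 1.3, tolerance = 1e-12)
  expect_true(r$defined)

  antipodal <- circ_mean_resultant(c(0, pi))
  expect_lt(antipodal$R, 1e-12)
  expect_false(antipodal$defined)
  expect_true(is.na(antipodal$mu_hat))

  r2 <- circ_mean_resultant(c(0, pi / 2))
  expect_equal(r2$C, 0.5)
  expect_equal(r2$S, 0.5)
  expect_equal(r2$R, sqrt(0.5), tolerance = 1e-12)
  expect_equal(r2$mu_hat, pi / 4, tolerance = 1e-12)
  # internal consistency R = sqrt(C^2 + S^2)
  x <- random_angles(57, 5)
  rx <- circ_mean_resultant(x)
  expect_equal(rx$R, sqrt(rx$C^2 + rx$S^2), tolerance = 1e-12)

  expect_error(circ_mean_resultant(numeric(0)))
})

test_that("von Mises density has the uniform limit and integrates to one", {
  th <- random_angles(20, 6)
  expect_equal(dvonmises(th, 1, 0), rep(1 / (2 * pi), 20))
  # series evaluation of I0(5) gives density ~0.8671 at the mode
  expect_equal(dvonmises(2, mu = 2, kappa = 5), 0.8671, tolerance = 1e-3)
  # trapezoid quadrature over [0, 2*pi)
  grid <- seq(0, 2 * pi, length.out = 10001)
  for (kappa in c(0, 0.5, 5, 50)) {
    f <- dvonmises(grid, mu = 1.1, kappa = kappa)
    integral <- sum((f[-1] + f[-length(f)]) / 2 * diff(grid))
    expect_equal(integral, 1, tolerance = 1e-6)
  }
  # large kappa must not overflow
  expect_true(is.finite(dvonmises(1, 1, 1e4)))
  expect_error(dvonmises(1, 1, -0.1), "kappa")
})

test_that("von Mises sampler is seeded, wrapped and concentrated correctly", {
  expect_identical(rvonmises(500, pi / 4, 5, seed = 11),
                   rvonmises(500, pi / 4, 5, seed = 11))
  s <- rvonmises(1e4, pi / 4, 5, seed = 12)
  expect_true(all(s >= 0 & s < 2 * pi))
  expect_lt(circ_dist(circ_mean(s), pi / 4), 0.05)
  # kappa = 0 is uniform: null resultant scales like n^{-1/2}
  u <- rvonmises(1e4, 0, 0, seed = 13)
  expect_lt(circ_mean_resultant(u)$R, 0.05)
  expect_error(rvonmises(0, 0, 1), "n >= 1")
})

test_that("kappa inverse is monotone, anchored at zero, and consistent", {
  expect_equal(estimate_kappa(0), 0)
  expect_gt(estimate_kappa(0.95), estimate_kappa(0.5))
  Rs <- seq(0, 0.999, length.out = 200)
  expect_true(all(diff(estimate_kappa(Rs)) >= 0))
  expect_lte(estimate_kappa(1), 1e6)
  expect_error(estimate_kappa(-0.01))
  expect_error(estimate_kappa(1.01))

  # n = 1000 draws at kappa = 5 recover roughly the true concentration
  k_hat <- estimate_kappa(circ_mean_resultant(
    rvonmises(1000, 0, 5, seed = 14))$R)
  expect_lt(abs(k_hat - 5), 0.6)
})

test_that("sampler/estimator round trip recovers kappa within 10%", {
  for (kappa in c(1, 5, 15)) {
    k_hats <- vapply(1:20, function(r) {
      estimate_kappa(circ_mean_resultant(
        rvonmises(2000, 1, kappa, seed = 1000 * kappa + r))$R)
    }, numeric(1))
    expect_lt(abs(mean(k_hats) - kappa) / kappa, 0.1)
  }
})

test_that("phase_series validates wrapped values and sampling metadata", {
  ps <- phase_series(c(0, 1, 6), dt = 0.5)
  expect_s3_class(ps, "phase_series")
  expect_equal(attr(ps, "dt"), 0.5)
  expect_error(phase_series(c(0, 7)), "2\\*pi")
  expect_error(phase_series(numeric(0)))
  expect_error(phase_series(1, dt = -1), "dt")
  expect_equal(as.numeric(as_phase_series(c(-pi / 2, 2 * pi))),
               c(3 * pi / 2, 0))
})
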