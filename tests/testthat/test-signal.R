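test_that("normalization gives zero mean, unit variance, affine invariance", {
  set.seed(1)
  x <- raw_signal(rnorm(500, 3, 7), fs = 100)
  z <- normalize_signal(x)
  expect_equal(mean(z$samples), 0, tolerance = 1e-12)
  expect_equal(var(z$samples), 1, tolerance = 1e-12)
  shifted <- raw_signal(2.5 * x$samples - 4, fs = 100)
  expect_equal(normalize_signal(shifted)$samples, z$samples, tolerance = 1e-9)
  expect_error(normalize_signal(raw_signal(rep(1, 10), 1)), "constant")
})

test_that("Hilbert phase of a pure cosine advances at its angular frequency", {
  x <- cosine_signal(f = 1, fs = 360, duration = 10)
  ap <- extract_phase(x)
  expect_true(all(ap$phase >= 0 & ap$phase < 2 * pi))
  idx <- interior(3600)
  u <- unwrap_phase(phase_values(ap$phase))[idx]
  t <- (idx - 1) / 360
  slope <- coef(lm(u ~ t))[2]
  expect_lt(abs(slope - 2 * pi) / (2 * pi), 0.02)
  expect_true(all(abs(ap$envelope[idx] - 1) < 0.05))
  expect_error(extract_phase(raw_signal(1:4, 1)), "8 samples")
})

test_that("phase extraction commutes with positive rescaling", {
  set.seed(2)
  t <- (0:999) / 100
  x <- cos(2 * pi * 0.5 * t) + rnorm(1000, 0, 0.05)
  p1 <- extract_phase(raw_signal(x, 100))$phase
  p2 <- extract_phase(raw_signal(3.7 * x, 100))$phase
  expect_equal(phase_values(p1), phase_values(p2), tolerance = 1e-9)
})

test_that("gapped signals are rejected until imputed", {
  mask <- rep(FALSE, 100); mask[40:42] <- TRUE
  x <- raw_signal(c(sin(1:100 / 5)), fs = 10, gap_mask = mask)
  expect_error(extract_phase(x), "gaps")
  expect_error(normalize_signal(x), "gaps")
  expect_silent(extract_phase(spline_impute(x, max_gap = 0.5)))
})

test_that("circular kernel weights follow exp(-d^2 / 2 tau^2)", {
  mu <- 1.0; tau <- pi / 4
  th <- wrap(mu + c(0, tau, -tau, 1.2, 2.5))
  tr <- treat_outliers(th, mode = "weight", tau = tau, mu = mu)
  expect_equal(tr$weights[1], 1)
  expect_equal(tr$weights[2], exp(-0.5), tolerance = 1e-6)
  expect_equal(tr$weights[2], tr$weights[3], tolerance = 1e-6)
  # strictly decreasing in distance
  d <- seq(0.01, pi, length.out = 50)
  w <- exp(-d^2 / (2 * tau^2))
  expect_true(all(diff(w) < 0))
  expect_error(treat_outliers(c(0, pi)), "undefined")
})

test_that("truncation maps extremes to the pi/2 boundary on the near side", {
  # concentrated cluster at mu ~ 1 plus one extreme at distance 2.5
  th <- c(rep(1, 50), wrap(1 + 2.5))
  tr <- treat_outliers(th, mode = "truncate")
  expect_true(tr$flagged[51])
  expect_equal(circ_dist(tr$values[51], tr$mu_hat), pi / 2, tolerance = 1e-6)
  # boundary approached from the correct side (the +pi/2 arc here)
  expect_equal(tr$values[51], wrap(tr$mu_hat + pi / 2), tolerance = 1e-6)
  expect_equal(tr$values[1:50], th[1:50]) # non-outliers untouched
})

test_that("phase bridging interpolates along the shorter arc", {
  expect_equal(bridge_phase_gap(0, pi / 2, k = 2), pi / 4, tolerance = 1e-12)
  # wrap-crossing case: the shorter arc passes through 0, not pi
  expect_equal(bridge_phase_gap(7 * pi / 4, pi / 4, k = 2), 0,
               tolerance = 1e-12)
  expect_error(bridge_phase_gap(0, pi, k = 4), "antipodal")
  expect_error(bridge_phase_gap(0, 1, k = 1), "k >= 2")

  # interior points partition the geodesic: distances to the endpoints sum
  # to the endpoint distance
  set.seed(3)
  for (r in 1:20) {
    a <- runif(1, 0, 2 * pi); b <- runif(1, 0, 2 * pi)
    if (abs(circ_dist(a, b) - pi) < 1e-6) next
    k <- sample(3:8, 1)
    mid <- bridge_phase_gap(a, b, k)
    expect_equal(circ_dist(mid, a) + circ_dist(mid, b),
                 rep(circ_dist(a, b), k - 1), tolerance = 1e-9)
  }
})

test_that("spline imputation recovers cubics exactly and never edits data", {
  t <- seq(0, 5, by = 0.05)
  cubic <- 2 + 0.5 * t - 0.3 * t^2 + 0.07 * t^3
  mask <- rep(FALSE, length(t)); mask[45:54] <- TRUE
  x <- raw_signal(replace(cubic, mask, NA), fs = 20, gap_mask = mask)
  filled <- spline_impute(x, max_gap = 1)
  expect_equal(filled$samples[mask], cubic[mask], tolerance = 1e-8)
  expect_identical(filled$samples[!mask], cubic[!mask])

  clean <- raw_signal(cubic, fs = 20)
  expect_identical(spline_impute(clean)$samples, cubic)

  edge_mask <- rep(FALSE, length(t)); edge_mask[1:3] <- TRUE
  edge <- raw_signal(replace(cubic, edge_mask, NA), 20, gap_mask = edge_mask)
  expect_error(spline_impute(edge), "boundary")
  long_mask <- rep(FALSE, length(t)); long_mask[30:60] <- TRUE
  long_gap <- raw_signal(replace(cubic, long_mask, NA), 20,
                         gap_mask = long_mask)
  expect_error(spline_impute(long_gap, max_gap = 0.25), "max_gap")
})
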