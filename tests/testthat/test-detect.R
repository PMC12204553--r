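test_that("moving circular mean matches the brute-force window resultant", {
  th <- random_angles(200, 1)
  for (window in c(5, 7)) {
    sm <- moving_circ_mean(th, window)
    half <- (window - 1) / 2
    ref <- vapply(seq_along(th), function(i) ref_window_mean(th, i, half),
                  numeric(1))
    expect_equal(sm, ref, tolerance = 1e-10)
  }
  expect_identical(moving_circ_mean(th, 1), th)
  expect_equal(moving_circ_mean(rep(2.2, 50), 5), rep(2.2, 50),
               tolerance = 1e-12)
  expect_error(moving_circ_mean(th, 4), "odd")
})

test_that("classification metrics follow the confusion-matrix arithmetic", {
  y <- c(1, 1, 0, 0, 1)
  m <- classification_metrics(y, y)
  expect_equal(c(m$accuracy, m$precision, m$recall, m$f1), rep(1, 4))

  set.seed(2)
  truth <- as.integer(seq_len(3600) %in% sample(3600, 180))
  m0 <- classification_metrics(truth, rep(0, 3600))
  expect_equal(m0$accuracy, 0.95)
  expect_equal(m0$recall, 0)
  expect_equal(m0$f1, 0)
  expect_equal(m0$tp + m0$fp + m0$tn + m0$fn, 3600)
  expect_error(classification_metrics(c(0, 1), 1), "mismatch")
})

test_that("AR detector flags a quarter of scored samples and scales invariantly", {
  sim <- sim_ecg_phase_anomalies(seed = 3)
  x <- as_raw_signal(sim)
  res <- detect_ar(x)
  scored <- (5 + 1):3600
  expect_equal(sum(res$predictions[scored]) / length(scored), 0.25,
               tolerance = 0.005)
  expect_equal(res$predictions[1:5], rep(0L, 5))
  # affine rescaling leaves the flags unchanged
  res2 <- detect_ar(raw_signal(10 * x$samples - 3, x$fs))
  expect_identical(res$predictions, res2$predictions)
  expect_error(detect_ar(raw_signal(rep(1, 100), 10)), "constant")
})

test_that("AR flags on white noise show no positional bias", {
  set.seed(4)
  x <- raw_signal(rnorm(5000), fs = 100)
  pos <- which(detect_ar(x)$predictions == 1)
  counts <- table(cut(pos, breaks = seq(0, 5000, by = 500)))
  p <- chisq.test(counts)$p.value
  expect_gt(p, 1e-4)
})

test_that("Fourier detector flags the top-power windows by construction", {
  sim <- sim_ecg_phase_anomalies(seed = 5)
  res <- detect_fourier(as_raw_signal(sim))
  expect_equal(res$config$n_windows, 19)
  frac <- res$config$flagged_windows / res$config$n_windows
  expect_gt(frac, 0)
  expect_lte(frac, 0.15)

  # a high-amplitude burst dominates the window power ranking
  set.seed(6)
  burst <- rnorm(2000, 0, 0.1)
  burst[1001:1100] <- burst[1001:1100] + 8
  resb <- detect_fourier(raw_signal(burst, fs = 200), window_sec = 1)
  expect_true(all(resb$predictions[1050] == 1))
  expect_equal(which.max(resb$scores) %in% 901:1100, TRUE)
})

test_that("SDE phase detector scores are geodesic deviations", {
  sim <- sim_ecg_phase_anomalies(seed = 7)
  x <- as_raw_signal(sim)
  res <- detect_sde_phase(x, threshold_rad = 3)
  expect_true(all(res$scores >= 0 & res$scores <= pi))
  expect_equal(length(res$predictions), 3600)

  # raising the threshold never increases the flagged count
  counts <- vapply(c(1, 1.5, 2, 2.5, 3), function(thr)
    sum(detect_sde_phase(x, threshold_rad = thr)$predictions), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(detect_sde_phase(x, threshold_rad = 4), "pi")
})

test_that("with near-uniform phases the SDE flag rate is (pi - thr)/pi", {
  # the benchmark signal sweeps one cycle per second, so phases cover the
  # circle almost uniformly and the deviation threshold acts as an arc cut
  rates <- vapply(1:5, function(s) {
    x <- as_raw_signal(sim_ecg_phase_anomalies(seed = 30 + s))
    mean(detect_sde_phase(x, threshold_rad = 3)$predictions)
  }, numeric(1))
  expected <- (pi - 3) / pi
  expect_lt(abs(mean(rates) - expected), 3 * sd(rates) / sqrt(5) + 0.01)
})

test_that("detect_anomalies dispatches on the method name", {
  x <- as_raw_signal(sim_ecg_phase_anomalies(seed = 8))
  expect_identical(detect_anomalies(x, "ar")$predictions,
                   detect_ar(x)$predictions)
  expect_identical(detect_anomalies(x, "sde", threshold_rad = 2)$predictions,
                   detect_sde_phase(x, threshold_rad = 2)$predictions)
})
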