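# shared fixtures built in code

random_angles <- function(n, seed) {
  set.seed(seed)
  runif(n, 0, 2 * pi)
}

# brute-force circular mean of one window (independent of moving_circ_mean)
ref_window_mean <- function(theta, i, half) {
  idx <- max(1, i - half):min(length(theta), i + half)
  atan2(mean(sin(theta[idx])), mean(cos(theta[idx]))) %% (2 * pi)
}

# pure-cosine test signal sampled like the ECG benchmark
cosine_signal <- function(f = 1, fs = 360, duration = 10) {
  t <- (seq_len(fs * duration) - 1) / fs
  raw_signal(cos(2 * pi * f * t), fs = fs)
}

interior <- function(n, frac = 0.05) {
  lo <- ceiling(n * frac) + 1
  hi <- floor(n * (1 - frac))
  lo:hi
}

# write a tiny synthetic two-channel WFDB record (format 212) for io tests
write_synthetic_wfdb <- function(dir, record = "synth01", n_samp = 64,
                                 fs = 360, gain = 200, baseline = 1024) {
  ch1 <- round(baseline + gain * sin(2 * pi * seq_len(n_samp) / 16) * 0.8)
  ch2 <- round(baseline + gain * cos(2 * pi * seq_len(n_samp) / 16) * 0.5)
  hea <- c(sprintf("%s 2 %d %d", record, fs, n_samp),
           sprintf("%s.dat 212 %d(%d) 11 %d 0 0 0 ch1", record, gain,
                   baseline, baseline),
           sprintf("%s.dat 212 %d(%d) 11 %d 0 0 0 ch2", record, gain,
                   baseline, baseline))
  writeLines(hea, file.path(dir, paste0(record, ".hea")))
  pairs <- rbind(ch1, ch2) # interleaved ch1[1], ch2[1], ch1[2], ...
  flat <- as.vector(pairs)
  stopifnot(length(flat) %% 2 == 0)
  s1 <- flat[seq(1, length(flat), by = 2)]
  s2 <- flat[seq(2, length(flat), by = 2)]
  s1u <- ifelse(s1 < 0, s1 + 4096L, s1)
  s2u <- ifelse(s2 < 0, s2 + 4096L, s2)
  b1 <- s1u %% 256L
  b2 <- (s1u %/% 256L) + 16L * (s2u %/% 256L)
  b3 <- s2u %% 256L
  con <- file(file.path(dir, paste0(record, ".dat")), "wb")
  writeBin(as.raw(as.vector(rbind(b1, b2, b3))), con)
  close(con)
  list(ch1 = ch1, ch2 = ch2, fs = fs, gain = gain, baseline = baseline,
       record = file.path(dir, record))
}
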