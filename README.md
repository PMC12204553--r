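# circsde

Physiological rhythms — the cardiac cycle, circadian oscillations, respiration
— are intrinsically *circular*: their state at any instant is a phase angle on
\[0, 2π), and treating that angle as an ordinary real number breaks down at
the wrap-around. `circsde` models such rhythms as **diffusions on the
circle**,

> dθᵢ(t) = \[ωᵢ + Σⱼ Kᵢⱼ sin(θⱼ − θᵢ)\] dt + σᵢ dBᵢ(t),  θᵢ ∈ \[0, 2π),

with angular drift ω (rad/s), Brownian diffusion σ (rad/√s) and optional
Kuramoto-type coupling K, and pairs that stochastic model with the circular
statistics needed to fit, test and exploit it:

* **Circular core** — wrapping, geodesic distance, mean resultant vector
  (C, S, R, μ̂ = atan2(S, C)), von Mises density/sampling (Best–Fisher), and
  the Mardia–Jupp inverse κ̂(R).
* **SDE engine** — Euler–Maruyama simulation with mod-2π wrapping, minimal-jump
  phase unwrapping, and moment estimators ω̂ = mean(Δθ̃)/Δt,
  σ̂ = sd(Δθ̃)/√Δt.
* **Bayesian inference** — random-walk Metropolis–Hastings for von Mises
  (μ, κ) under a uniform prior on μ and a Gamma(a, b) prior on κ, with
  circular posterior summaries.
* **Hypothesis tests** — Watson's U² (one-sample uniformity and two-sample)
  with label-permutation inference.
* **Synchronization** — phase-locking value, binned circular mutual
  information (nats), and the directional phase synchronization index.
* **Signal front end** — Hilbert-transform phase extraction, z-scoring,
  circular-kernel outlier weighting/truncation, cubic-spline gap imputation
  and geodesic phase bridging; a minimal read-only WFDB reader (formats
  212/16) for locally stored PhysioNet records.
* **Anomaly detection** — a circular phase-deviation detector for ECG-like
  signals (Hilbert phase → moving circular mean → geodesic deviation from
  the global circular mean → threshold), benchmarked against AR-residual
  and windowed-Fourier-power baselines on a synthetic phase-anomaly ECG
  generator with per-sample ground truth.

The intended audience is biostatisticians and biomedical-signal researchers
who need phase-domain (rather than amplitude-domain) analysis of rhythmic
signals.

## Worked example

Fit a von Mises model to simulated phase data by Metropolis–Hastings, then
run the phase-anomaly detector on a synthetic ECG benchmark:

```r
library(circsde)

th  <- rvonmises(100, pi / 4, 5, seed = 42)   # "observed" phases
fit <- fit_vonmises_mh(th, n_iter = 5000, seed = 43)
summary(fit)
#> Posterior summary (von Mises)
#>   mu:    0.7206 rad  [0.6373, 0.8088]
#>   kappa: 5.7539      [4.3562, 7.3708]
#>   (4000 retained samples after 20% burn-in)

sim <- sim_ecg_phase_anomalies(seed = 1)      # 3600 samples, 180 anomalies
res <- detect_sde_phase(as_raw_signal(sim), threshold_rad = 3)
classification_metrics(sim$labels, res$predictions)
#> Classification metrics (n = 3600)
#>   tp 10  fp 148  tn 3272  fn 170
#>   accuracy 0.9117  precision 0.0633  recall 0.0556  F1 0.0592
```

The posterior means sit close to the simulation truth (μ = π/4 ≈ 0.785,
κ = 5) with a credible interval that honestly reflects n = 100 angles. On
the benchmark, the phase detector attains high accuracy because anomalies
are rare (5%) and its flags are sparse; its precision/recall profile differs
sharply from the high-recall AR baseline (`detect_ar`) — compare them with
`run_detector_benchmark(seeds = 1:20)`.

A thin command-line front end over the same functions lives at
`inst/cli/circsde.R` (subcommands `gen-ecg`, `extract-phase`,
`fit-vonmises`, `circ-test`, `sync`, `simulate-sde`, `estimate-sde`,
`detect`, `benchmark`, `robustness`); every run writes a JSON provenance
block with its configuration and seed.

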