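---
title: "Circular SDE phase dynamics: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circular SDE phase dynamics: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circsde)
```

`circsde` treats the state of a physiological rhythm as a phase angle on the
circle and provides, around that single idea, a simulation model, Bayesian
and moment estimators, hypothesis tests, synchronization metrics and an
anomaly detector. This vignette explains the science behind each component,
the assumptions it makes, and the design decisions taken where several
defensible conventions exist.

## 1. The phase diffusion model

The temporal evolution of `p` interacting rhythms is modelled as a system of
stochastic differential equations on the torus:

$$d\theta_i(t) = \Big[\omega_i + \sum_{j \ne i} K_{ij}
\sin(\theta_j - \theta_i)\Big]\,dt + \sigma_i\,dB_i(t),
\qquad \theta_i \in [0, 2\pi),$$

with angular drift $\omega_i$ (rad/s), diffusion $\sigma_i$
(rad/$\sqrt{s}$) capturing biological noise, and an optional Kuramoto-type
coupling matrix $K$ (1/s, zero diagonal) that pulls oscillators toward
synchrony. Sample paths come from the explicit Euler--Maruyama scheme with a
mod-$2\pi$ wrap after every step; the coupling term is evaluated at the
previous step's phases, consistent with the explicit scheme. The scheme is
first-order; no Milstein or higher-order corrections are attempted (for
constant $\sigma$ the Milstein correction vanishes anyway).

**Reproducibility convention.** Noise increments are drawn per step in
component-major order from one seeded generator. The uncoupled special case
is computed by a vectorised cumulative sum that consumes the *same* RNG
stream as the step loop, so switching code paths can never change a seeded
result; the identity of the two paths is itself under test.

**Estimation.** Because the wrapped path hides the winding number,
estimation goes through *unwrapping*: successive increments are mapped to
$(-\pi, \pi]$ (the minimal-jump rule, threshold $\pi$ — the standard phase
unwrapping convention). The estimators are then the first two moments of
the increments, $\hat\omega = \overline{\Delta\tilde\theta}/\Delta t$ and
$\hat\sigma = \mathrm{sd}(\Delta\tilde\theta)/\sqrt{\Delta t}$. They are
consistent as long as the true per-step displacement rarely exceeds $\pi$,
i.e. $|\omega|\Delta t + 3\sigma\sqrt{\Delta t} < \pi$; all defaults in the
package respect that regime. Under it, $\hat\omega$ is unbiased with
standard deviation $\sigma/\sqrt{N\Delta t}$, which the test suite checks
by Monte Carlo (500 replicates at $\omega = 1$, $\sigma = 0.5$,
$N = 1000$, $\Delta t = 0.01$).

## 2. Circular descriptive statistics and the von Mises family

All estimators are built on the mean resultant vector
$C = \overline{\cos\theta}$, $S = \overline{\sin\theta}$,
$R = \sqrt{C^2 + S^2}$, $\hat\mu = \mathrm{atan2}(S, C)$. When $R$ is
numerically zero (antipodal cancellation) the mean direction is reported as
*undefined* rather than an arbitrary angle; downstream code treats that case
explicitly.

The von Mises distribution
$f(\theta \mid \mu, \kappa) = e^{\kappa\cos(\theta-\mu)}/(2\pi I_0(\kappa))$
is the package's parametric workhorse. The density is evaluated on the log
scale through the exponentially scaled Bessel function, so concentrations in
the hundreds do not overflow. Sampling uses the Best--Fisher (1979)
rejection algorithm with a wrapped-Cauchy envelope; it is exact, and the
seeded-stream contract makes repeated draws identical. The concentration is
recovered from $R$ by the standard Mardia--Jupp piecewise inverse
($2R + R^3 + 5R^5/6$ below $R = 0.53$; $-0.4 + 1.39R + 0.43/(1-R)$ up to
$0.85$; $1/(R^3 - 4R^2 + 3R)$ above), capped at $10^6$ so $R \to 1$ cannot
produce an infinite estimate.

## 3. Bayesian inference for (μ, κ)

The posterior under a von Mises likelihood, uniform prior on $\mu$ and
Gamma prior on $\kappa$ has no closed form, so the package uses a
componentwise Gaussian random-walk Metropolis--Hastings sampler:
$\mu$-proposals are wrapped back onto the circle (a symmetric proposal on
the circle, so no Jacobian correction), and $\kappa$-proposals at or below
zero are rejected through a $-\infty$ log posterior.

Choices that the model statement leaves open, and how they are fixed:

* **Gamma parameterization** — shape--rate, mean $a/b$. Defaults $a = 2$,
  $b = 1$ (prior mean 2, weakly informative); a flatter Gamma(2, 0.5) is
  appropriate for weakly concentrated real phase data. Both are exposed via
  `vm_prior()`.
* **Proposal scales** — defaults $sd_\mu = 0.1$, $sd_\kappa = 0.5$, which
  give mid-range acceptance (roughly 0.4--0.8) on samples of ~100
  concentrated angles; both configurable.
* **Initialization** — $\mu_0 = \pi/2$, $\kappa_0 = 1$.
* **Burn-in and summaries** — 20% of iterations discarded by default;
  $\mu$ is summarized *circularly* (resultant direction of the retained
  samples, credible interval formed from wrapped deviations around it),
  $\kappa$ arithmetically. Averaging $\mu$ samples linearly would fail for
  posteriors straddling $0 \equiv 2\pi$.

Correctness is checked two independent ways: a simulation study (n = 100
from VM($\pi/4$, 5), 5000 iterations) must recover the truth within
Monte-Carlo tolerance, and on a tiny 3-point dataset the chain's long-run
$\mu$ histogram is compared in total variation against a dense-grid
normalization of the same posterior — a detailed-balance smoke test that
does not reuse any sampler code.

## 4. Watson's U² and permutation inference

One-sample uniformity uses the classical statistic on rescaled sorted
angles; its closed-form minimum $1/(12n)$ on the regular grid is kept as an
exact oracle in the tests. The two-sample statistic compares pooled ECDFs
at the pooled order statistics, with ties collapsed to a single evaluation
point at which both ECDFs step.

The printed form of the two-sample statistic in the circular-statistics
literature is ambiguous about its centering term, so three variants are
exposed: `"classical"` ($\frac{n_1 n_2}{n^2}\sum_k (d_k - \bar d)^2$,
rotation-invariant and symmetric — the default and the recommended choice),
`"scaled"` (the $\frac{n_1 n_2}{n}$-prefactor reading with scalar mean
centering, i.e. the classical statistic scaled by $n$), and
`"scaled-literal"` (a per-observation centering $D_k = \frac{n_1}{n}F_1 +
\frac{n_2}{n}F_2$, retained for auditability only). Because permutation
inference is invariant to monotone rescaling of the statistic, the variant
choice barely affects p-values.

Inference is by label permutation with the add-one convention
$p = (1 + \#\{U^2_{perm} \ge U^2_{obs}\})/(n_{perm} + 1)$, so $p = 0$ is
impossible and the p-value is uniform on its attainable grid under the
null. The test suite calibrates the size empirically (500 null replicates
against the binomial 99% interval at $\alpha = 0.05$) and verifies power
growth with mean separation. Asymptotic critical values are deliberately
not tabulated — permutation is the primary inferential device.

## 5. Synchronization metrics

For two wrapped series the package reports the phase-locking value
$|\overline{e^{i(\theta_1 - \theta_2)}}|$, the directional phase
synchronization index $\arg \overline{e^{i(\theta_1 - \theta_2)}}$ (the
consistent phase offset; undefined, with a warning, when the resultant of
the difference vector vanishes), and circular mutual information estimated
by the plug-in rule on a $B \times B$ joint histogram of $[0, 2\pi)^2$, in
nats. The bin count is not canonical; the default is $B = 16$, a common
compromise between resolution and occupancy at $n$ in the thousands. The
plug-in estimator is biased upward by roughly $(B-1)^2/2n$ nats for
independent series — visible in the tests as the `< 0.01` bound at
$n = 10^5$ — and an optional Miller--Madow correction is available, but the
default stays uncorrected because the plain plug-in is the convention the
rest of the pipeline assumes.

## 6. Signal preprocessing and phase extraction

Phases of a real signal come from the analytic signal
$\hat x = x + i\mathcal{H}[x]$, built by the standard FFT one-sided-spectrum
construction, $\theta(t) = \arg\hat x(t)$. The Hilbert phase is invariant
to positive affine rescaling, so the z-scoring step (`normalize_signal`)
only guards numerics. Finite-length end effects distort the first and last
few percent of samples; invariant checks in the tests therefore exclude a
5% margin at each end, and users should do the same when estimating
frequencies from short records.

Robust preprocessing follows the circular geometry throughout:

* **Outliers** are scored by geodesic deviation $d_i$ from the (estimated
  or supplied) mean direction; observations beyond $\pi/2$ are either
  truncated to the nearer boundary $\hat\mu \pm \pi/2$ (exact antipodes go
  to $+\pi/2$ by convention) or downweighted by the circular kernel
  $w_i = e^{-d_i^2/2\tau^2}$. The kernel scale has no canonical value; the
  default $\tau = \pi/4$ places weight $e^{-2}$ at the flag boundary
  $d = \pi/2$, a package choice rather than a literature constant.
* **Amplitude gaps** are filled by a cubic spline through the observed
  samples before phase extraction (exact for cubic signals; observed
  samples are never modified), refusing boundary gaps and gaps longer than
  a configurable 0.25 s.
* **Phase gaps** are bridged geodesically along the shorter arc; antipodal
  endpoints are rejected because the geodesic is not unique.

## 7. The phase-anomaly detector and its baselines

The benchmark problem is a cosine rhythm whose anomalies live purely in the
phase: $x(t) = \cos(2\pi f t + \phi(t)) + \epsilon(t)$ with $\phi = \pi/2$
at a random 5% of samples and Gaussian noise of sd 0.05. Amplitude carries
essentially no class signal, which is exactly what defeats amplitude-domain
detectors. Generator defaults are the study conditions: $f = 1$ Hz,
$f_s = 360$ Hz, 10 s, so 3600 samples and exactly 180 anomalies.

Three per-sample detectors are implemented:

* **Circular SDE detector** — Hilbert phase, moving circular mean (window
  5; the window shrinks at the edges, and a window with zero resultant
  leaves its centre sample unchanged), global circular mean $\bar\theta$
  computed on the smoothed series, deviation
  $D(t) = \mathrm{circ\_dist}(\theta(t), \bar\theta)$, flag where
  $D(t) >$ `threshold_rad` (default 3 rad). Because the benchmark phase
  sweeps the circle almost uniformly, $D$ is nearly uniform on $[0, \pi]$
  and the flag rate is $\approx (\pi - \text{threshold})/\pi$: ~4.5% at
  3 rad (accuracy dominated by the 95% negatives) and ~36% at 2 rad. That
  one relation explains the sharp accuracy drop between the two thresholds.
* **AR baseline** — AR(5) fitted by ordinary least squares on lagged raw
  samples with intercept over the full record; scores are absolute
  one-step residuals; flags above the 75th percentile. The first 5 samples
  are unscored. The fit is affine-invariant by construction.
* **Fourier baseline** — 1 s windows at 50% overlap (19 windows over
  10 s), per-window total spectral power (Parseval), windows above the
  90th percentile flagged, flags broadcast to member samples.

**Percentile convention.** All percentile thresholds use the inverse-ECDF
(type-1) empirical quantile with a strict `>` rule, ties excluded. With 19
windows this flags exactly the single top-power window — 360 samples — which
is the reading consistent with the Fourier row of the reference metrics
(precision ≈ 0.053 at recall ≈ 0.106 implies 360 flagged samples). With
3595 scored AR samples the same convention flags 24.98% ≈ 25%.

`run_detector_benchmark()` regenerates the signal per seed, runs all three
detectors and averages the confusion-matrix metrics; 20 seeds give means
stable to well within the tolerances asserted in the acceptance tests.

## 8. Synthetic generators as study definitions

The generators are first-class, tested code, and their defaults *are* the
study conditions — they are not tuning knobs.

* `sim_ecg_phase_anomalies()` — as above; anomaly indices drawn without
  replacement, isolated samples, no refractory constraint.
* `sim_coupled_rhythms()` — three von Mises rhythms at 0°/120°/240° with
  $\kappa = (5, 10, 15)$; rhythms 2 and 3 share one latent Gaussian phase
  shift per observation. The latent mechanism is not fully specified in
  the source material; a shared $N(0, \sigma_Z^2)$ shift with
  $\sigma_Z = 0.35$ is the simplest mechanism that induces correlation
  between rhythms 2 and 3 and attenuates their apparent concentration
  (the resultant-based $\hat\kappa$ then systematically underestimates
  $\kappa_2, \kappa_3$ while mean directions survive within a few
  degrees). Only that qualitative signature is asserted; exact attenuated
  values depend on the unknown mechanism.
* `run_robustness_grid()` — crosses $N \in \{100, 500, 1000\}$ with
  $\sigma \in \{0.1, 0.5, 1.0\}$ at drifts $(1.0, 1.2, 1.5)$, 50
  replicates per cell. The grid's time step is not dictated by theory;
  $\Delta t = 0.1$ is the package default because it reconciles the
  expected error magnitude $\sigma\sqrt{2/\pi}/\sqrt{N\Delta t}$ with the
  reference error table, and it is recorded in every output row. At
  $\sigma = 0.1$ the drift error stops shrinking with $N$ (a wrapping/
  discretization floor of ~0.01); the $1/\sqrt{N}$ scaling is asserted at
  $\sigma = 1.0$ only.

What the generators deliberately do **not** emulate: realistic ECG
morphology (P-QRS-T waveshapes), beat-to-beat heart-rate variability,
baseline wander, or measurement artifacts. Passing benchmarks on these
signals demonstrates that the pipeline detects *phase* anomalies under
controlled conditions, not that it is a validated clinical arrhythmia
detector.

## 9. Problem sizes, tolerances and degenerate inputs

The test and acceptance workloads use the study sizes directly (they run in
seconds): 5 chains × 5000 MCMC iterations; 100 power and 500 size
replicates of the permutation test at 99–199 permutations; 20 benchmark
seeds × 3600 samples; 50 replicates per robustness cell; 500 replicates
for the drift-recovery check. Stochastic assertions use explicit
Monte-Carlo bounds (3 standard errors, binomial 99% intervals, or the
stated tolerance for reference values).

Degenerate inputs are rejected loudly rather than silently repaired:
non-finite angles, out-of-range phases in files (reported with their line
number), empty samples, zero-variance signals for AR/normalization,
antipodal endpoints for bridging, boundary or over-length gaps for
imputation, even smoothing windows, $\kappa_0 \le 0$ initializations, and
undefined circular means all raise errors. The single silent convention:
`dpsi()` returns `NA` with a warning when the phase-difference resultant is
zero, because that case legitimately arises in data.

## 10. Known limitations

* Drift/diffusion estimation assumes constant $\omega, \sigma$;
  time-varying coefficients are out of scope.
* The moment estimator for $\sigma$ absorbs discretization error at large
  $|\omega|\Delta t$; keep per-step displacements well below $\pi$.
* Plug-in MI depends on the bin count; values are comparable only at a
  fixed `bins`.
* The WFDB reader covers formats 212 and 16 read-only, without
  annotations, and never downloads anything: records must be on disk.
* The MH sampler is single-chain; multimodal posteriors (possible for
  near-uniform data) deserve multiple seeds, which `scripts/acceptance.R`
  demonstrates.
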