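---
title: "Models and methods behind bisectlab"
author: "bisectlab authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bisectlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bisectlab)
```

# The task and the design

In temporal bisection an observer sees (or hears) a stimulus lasting one of
several durations and classifies it as "short" or "long" relative to an
internal standard. bisectlab works with the canonical sub-second layout:
seven durations log-spaced between 300 and 900 ms, whose geometric mean
(520 ms) is the natural categorical anchor of a log-spaced set, since
$\sqrt{t_{\min} t_{\max}}$ equals the geometric mean of the whole set.

Because trial-history ("carryover") analyses condition on the previous
trial, the trial order must be first-order counterbalanced: every ordered
pair of labels should occur equally often. `generate_sequence()` constructs
such orders as random Eulerian circuits of the complete transition
multigraph over the 7 duration labels plus a NULL (blank) label, with each
arc duplicated `reps_per_transition` times. Hierholzer's algorithm with
seeded random edge choice yields a uniform-transition-count circuit; the
cyclic circuit is cut at a random position for presentation. With 8 labels
and 8 repetitions this gives the standard session: 512 trials, 448 of them
stimulus trials, 64 presentations of each duration, and all 64 ordered
trial types exactly 8 times (cyclically; the linear cut loses at most one
transition). Any uniform-count circuit has the property the analyses need,
so no attempt is made to reproduce a specific published sequence-generation
algorithm. NULL trials exist precisely to create transitions on which no
stimulus was presented; trials following a NULL are kept for direct
analyses but excluded from carryover conditioning. An optional lead-in of
three presentations at the geometric mean (used to seed the observer's
standard) is prepended with non-positive trial indices and ignored by all
analysis functions.

# The two-stage generative model

The synthetic-data generator implements a two-stage diffusion account of
bisection choices and reaction times.

**Stage 1 (clock).** Elapsed time is measured by a noisy accumulator
obeying $dx = A\,dt + m\sqrt{A}\,dB$. The rate is normalized to the
criterion duration: $A = 1/0.52\ \mathrm{s}^{-1}$ by default, so the
expected endpoint after timing the criterion is exactly 1. The endpoint at
stimulus offset is Gaussian with mean $AT$ and variance $m^2AT$; the noise
coefficient $m$ is therefore also the coefficient of variation of the clock
reading at the criterion, and the default $m = 0.15$ corresponds to typical
sub-second timing precision (Weber fractions of 0.1–0.2). A delta-rule
update of $A$ toward the normalization ($A \leftarrow A + \eta\,(1 -
x(T_{\rm ref}))$) is exposed but off by default, because no concrete
learning rule is established for this stage; the normalization itself is
what downstream stages rely on.

**Stage 2 (decision).** At offset, a two-boundary decision diffusion with
unit diffusion coefficient starts at $z \cdot a$ and drifts at rate $v$
toward the "long" boundary $a$ or the "short" boundary 0. The linkage
between stages is the substantive modelling choice:

- Starting point: $z = \mathrm{clip}(0.5 + \kappa\,(x - 1),\ 0.05,\ 0.95)$.
  An affine map with clipping is the minimal monotone choice; the clipping
  produces the rise-then-saturate profile of fitted $z$ across durations
  that bisection data show. The default gain $\kappa = 0.8$ was chosen (and
  then frozen) so that per-duration maximum-likelihood fits of simulated
  sessions recover the qualitative parameter profiles cleanly; larger gains
  drive $z$ deep into the clip region at both extremes and degrade the
  recovery of the other parameters.
- Drift: $v = v_{\rm gain}\,(x - b/0.52)$, the signed distance of the clock
  reading from the current categorical boundary $b$ (seconds), with
  $v_{\rm gain} = 8$ giving realistic choice consistency and RT spread.
- Boundary separation and non-decision time are duration-indexed:
  $a(d) = 1.1 + 0.5\,u(d)^2$ with $u$ the log-distance from the geometric
  mean normalized to $\pm 1$ at the extremes (separation lowest near the
  categorical boundary), and $t_0(d)$ decreasing linearly from 300 to
  200 ms across the duration range. These implement the expected
  qualitative profiles of fitted bisection parameters.
- Carryover: before each trial with a known predecessor duration,
  $b \leftarrow (1-g)\,b + g\cdot\textrm{prior duration}$. The gain $g$
  (default 0 — null model; 0.3 for the implanted-effect conditions) drifts
  the categorical boundary toward the previous duration, which is the
  mechanism behind the BP-versus-prior-duration slope. The generator has
  no response-history term, so decisional carryover is zero in expectation
  under $g = 0$.

The decision stage is simulated by Euler–Maruyama with a 1 ms step and a
Brownian-bridge crossing correction per step (the probability that the
path crossed a boundary inside a step although both endpoints are
interior). Without the correction, absorption probabilities carry an
$O(\sqrt{dt})$ bias that is visible against the closed-form absorption
formula $P(\text{long}) = (1 - e^{-2vza})/(1 - e^{-2va})$; with it, the
simulator matches the formula and the first-passage density (chi-square
comparisons across a parameter grid are part of the test suite).

# Psychometric fitting

The proportion of "long" responses per duration is fit by a cumulative
Gumbel on log duration, $P(\text{long}\mid d) = 1 - \exp(-\exp((\log d -
\alpha)/\beta))$, which is the natural family for a log-spaced set. This is
a binomial GLM with a complementary log-log link in $\log d$, so the fit is
the exact maximum-likelihood estimate computed by iteratively reweighted
least squares — fast enough for bootstrap and sliding-window use. The fit
reports the bisection point (50% quantile), the 25%/75% thresholds, the
difference limen $DL = (\theta_{75} - \theta_{25})/2$ and $CV = DL/BP$ (the
two identities hold exactly by construction and are asserted on every fit).
Lapse and guess asymptotes are fixed at 0 by default. Degenerate data —
all responses identical, or proportions pinned at 0.5 — are flagged
non-converged with a missing BP. Perfectly separated (step) data drive the
GLM slope to infinity, but the 50% crossing remains pinned between the
bracketing levels, so such fits are kept. Trials are first filtered to RTs
in [100, 1000] ms with inclusive bounds (the conservative reading of
"between").

Threshold intervals use a bias-corrected (BC, not BCa) parametric
bootstrap: per-level binomial responses are resampled from the fitted
curve, the model refit, and percentile endpoints shifted through the
normal quantile of the observed value's bootstrap rank; 1999 simulations
by default. Coverage of the BP interval measures ~95% at the nominal 95%
level over 200 synthetic datasets (the acceptance script recomputes this).

One systematic effect deserves note: the generative clock noise is additive
Gaussian in linear time, so the true psychometric curve is probit-like in
linear duration, while the fitted family is a Gumbel in log duration. The
family mismatch leaves a small (~2–3%) systematic offset between the fitted
BP and the generative boundary even with thousands of trials; the test
suite asserts 3% in the strong-evidence limit and 6% for the default chain
rather than pretending to exact consistency.

# Sequential analyses

`carryover_bp()` fits one psychometric function per prior-trial duration
(trials following NULLs excluded) and summarizes the profile by the OLS
slope of BP on prior duration; the implanted gain of 0.3 produces slopes
around 0.21 at 448 trials. Detection is the one-sided $t$ test on that
slope (df = bins − 2), one-sided because the carryover prediction is
directional; this detects the 0.3-gain effect in ≥ 90% of sessions while
the zero-gain null keeps its two-sided interval covering 0 in ≥ 90%.
Decisional carryover is the BP difference between trials following "short"
versus "long" responses. Note that with a nonzero perceptual gain the
decisional delta is not expected to vanish: the previous response
correlates with the previous duration.

`sliding_bp()` tracks the BP in a window advancing one trial at a time,
smoothed by a centered, edge-truncated moving average (default 10 points);
windows in which any duration falls below the per-level minimum (8 trials)
are flagged rather than silently fit. `minimum_window()` computes, for a
concrete realized sequence, the smallest window length such that every
contiguous window contains at least the minimum of every duration — the
number is a property of the realized sequence (typically 105–135 for this
design), not of the design family. With a zero minimum the requirement is
vacuous and the function returns 1.

# Diffusion-model inversion

The likelihood kernel is the Wiener first-passage density between two
absorbing boundaries, evaluated through the standard small-time and
large-time series with truncation chosen from the requested error bound;
the upper-boundary density is obtained by reflection ($v \to -v$, $w \to
1-w$). Starting-point variability (a uniform range of width `sz`)
is integrated by 11-point Gauss–Legendre quadrature, which is exact enough
that total mass deviates from 1 by less than $10^{-4}$ across the tested
grid. The density, simulator, and closed-form absorption probabilities form
a three-way oracle: each pair is checked against the others in the tests.

`fit_hddm()` performs hierarchical Bayesian estimation: subject-level
parameters $(a, v, t_0, z[, sz])$ — each optionally varying over a design
column such as duration or condition — are drawn from group-level normals
whose mean and SD are inferred. Sampling is random-walk Metropolis per
scalar parameter with step sizes adapted during burn-in (target acceptance
0.25–0.5), and conjugate Gibbs updates for the group mean (flat prior) and
variance (weakly informative inverse-gamma, shape 2, scale 0.02). Bounds on
the admissible region are enforced by proposal rejection. Chains start
overdispersed (log-normal jitter around a common heuristic start).
Defaults are 4 chains of 5000 samples after 2000 burn-in; the test suite
and acceptance script run 4 × 800/600, which already yields $\hat R <
1.01$ and group-mean recovery within a few percent at 19 subjects × 448
trials. Convergence is summarized by the Gelman–Rubin potential scale
reduction factor $\hat R = \sqrt{((n-1)/n\,W + B/n)/W}$; identical chains
give $\sqrt{(n-1)/n}$, i.e. 1 up to $O(1/n)$. Model fit is compared by
DIC ($\bar D + p_D$, $p_D = \bar D - D(\bar\theta)$) for hierarchical fits
and by summed AIC over per-subject maximum-likelihood fits
(`fit_ddm_mle()`, L-BFGS-B) for fast fixed-effects comparisons — the
latter is how the package answers "which parameter carries a condition
effect": candidate models letting $z$, $a$ or $v$ vary by condition are
fit and the lowest summed AIC wins. A +0.05 shift of $z$ in one condition
is credited to $z$ in ≥ 80% of replicate experiments at 6 subjects × 600
trials.

`posterior_predictive()` simulates datasets (500 by default) at the
per-subject posterior means over the observed design and compares
per-duration choice proportions and RT deciles with the simulated
2.5–97.5% envelope.

Per-duration ML fits of full simulated sessions recover the qualitative
parameter profiles the generator implants: drift negative below and
positive above the boundary and monotone in duration; non-decision time
decreasing; starting point rising toward the middle and saturating;
boundary separation larger at the extremes than at the middle. The
starting-point-variability profile (endpoint SD grows with $\sqrt{T}$) is
implanted but its per-duration ML recovery is too noisy to assert, because
clipping truncates the $z$ range at both extremes; it is left untested.

# EEG time/frequency statistics

`morlet_tf()` convolves single-channel epochs with complex Morlet wavelets
at log-spaced frequencies (defaults: 100 frequencies from 10 to 40 Hz).
The cycle count grows with frequency by the two-parameter convention
$c(f) = c_0 + s\,(c_0 f/f_{\min} - c_0)$ with $c_0 = 3$ and $s = 0.5$: at
the lowest frequency the wavelet has 3 cycles, and $s$ interpolates between
constant cycles ($s=0$) and cycles proportional to frequency ($s=1$).
Wavelets are unit-energy normalized — any fixed linear normalization works
because every downstream statistic is invariant to per-frequency scaling,
and power is quadratic in signal amplitude (asserted in tests). Samples
whose wavelet support (±3 temporal SDs) extends past the epoch edge are
flagged in a validity mask; epochs too short for the widest wavelet raise
an error naming the limiting frequency.

Baseline handling has two modes matching the two analysis styles the
package supports: none (raw power into the regression) and single-trial
division, in which each trial's power is divided per frequency by its own
mean power in the −200–0 ms window. Single-trial division is preferred
when trial counts are low because one extreme-power trial otherwise
dominates the shared baseline; the test suite constructs exactly this
fixture and shows the average-baseline estimator collapsing while the
single-trial estimator stays at its true level.

The "direct" and "carryover" effects are per-pixel OLS slopes of
single-trial power on the present or the prior trial's duration (trials
without a usable prior excluded). Group inference is a cluster-based
permutation test: pixelwise one-sample $t$ statistics against zero,
thresholded two-tailed at $p < 0.05$, grouped into 8-connected clusters in
the frequency × time plane, with the maximum cluster size (pixel count;
summed |t| mass available as an option) compared to a sign-flipping null.
Positive and negative clusters are pooled into one maximum-statistic null,
and cluster $p$ values use the add-one exceedance proportion. A paired
contrast (e.g. two stimulation conditions) is run by sign-flipping
per-subject difference maps, which is exactly the condition-label swap.
The test controls family-wise error at or below the nominal level; on
unsmooth null maps it is conservative (measured rates 0.01–0.05 at nominal
0.05 over 100 runs) because the integer cluster-size statistic is heavily
tied — a known property of cluster-size inference, not a defect.

`simulate_eeg_epochs()` builds epochs as independent $1/f$-shaped Gaussian
noise per channel plus a Hann-windowed sinusoid at the centre of the
effect band (default 17–23 Hz, window 0.3–0.9 s) whose squared amplitude
grows linearly with the chosen regressor; a fixed decreasing topography
projects the oscillation across channels. At the frozen conditions
(slope 2 per second, oscillation-to-noise amplitude ratio 0.8, 8 subjects,
30 trials per prior level), the full chain — simulate, decompose, regress
on prior duration, cluster-test — recovers the implanted beta-band effect
in ≥ 80% of runs. What this shows about real data is deliberately limited:
the generator emulates band-limited power covarying with a regressor on a
$1/f$ background, but not volume conduction, artifacts, non-stationary
background rhythms, or channel covariance, so passing tests validate the
statistics, not any preprocessing.

# Orchestration and reproducibility

`run_pipeline()` executes design → simulate → filter → psychometrics →
sequential (→ optional DDM and EEG stages) from a single configuration
list (YAML-serializable), writing CSV/JSON outputs plus a manifest. Every
stochastic stage derives its seed deterministically from the global seed,
so identical configurations produce byte-identical outputs; this is
asserted for the pipeline, the MCMC sampler and the permutation test. The
package is driven from R; there is no shell executable, and
`scripts/acceptance.R` is a thin Rscript over the exported functions.

## Problem sizes used by the tests and the acceptance script

Simulation-based checks run at deliberately chosen sizes: first-stage
moments at 20,000 replicates; absorption-probability grids at 6,000–20,000
trials per point; hierarchical recovery at 19 subjects × 448 trials with
4 chains × 800 samples after 600 burn-in; model-comparison experiments at
6 subjects × 600 trials × 20 replicates; bootstrap coverage at 200
datasets × 499 resamples; carryover calibration at 100 sessions per
condition; EEG calibration at 100 null runs × 500 permutations and 20
implanted-effect runs at 30 analysis frequencies. These sizes put Monte
Carlo error comfortably below the asserted margins while keeping the whole
suite to a few minutes.

## Known limitations

- Only the second-stage decision process is fit; first-stage parameters
  exist in the generator alone, and the learning rule for the clock rate is
  an exposed stub rather than an estimable component.
- The hierarchical sampler treats group means/SDs with conjugate updates
  that ignore the truncation of subject parameters to the admissible
  region; with the weak priors and realistic parameter ranges used here the
  effect is negligible, but extreme settings (e.g. $z$ near a bound) would
  bias the group SD.
- Inter-trial drift variability (`sv`) and non-decision-time variability
  (`st`) are not modelled.
- The EEG module analyzes one channel at a time; there is no channel
  adjacency in the cluster statistic and no source or topography-level
  inference.
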