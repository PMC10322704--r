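---
title: "Methods: pupil-linked arousal coding in hypothalamic neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pupil-linked arousal coding in hypothalamic neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`pupilcoding` implements the analysis chain that links single orexin
(hypocretin) cell activity in the lateral hypothalamus to pupil-indexed
arousal in head-fixed mice: pupil extraction from tracked landmark points,
calcium and photometry preprocessing, a per-cell linear encoding model with
leave-one-predictor-out variance partitioning, coherence and lagged
cross-correlation between neural activity and pupil size, and
locomotion-bout-matched group comparisons for loss-of-function experiments.
Because the recorded datasets are not required to develop or test the
methods, the package ships a synthetic-session generator with analytic
ground truth; every stage is validated by parameter recovery on those
sessions.

# Pupil extraction

Pupil videos are reduced upstream (by a DeepLabCut-style tracker, which we
do not reimplement) to eight landmark points per frame on the pupil edge,
each with a likelihood. Per frame we fit a circle to the eight points with
the Kasa algebraic least-squares method: minimising
$\sum_i (x_i^2 + y_i^2 + D x_i + E y_i + F)^2$ is a linear problem with a
closed-form solution, so the fit is deterministic, order-invariant and fast
enough for hours of 20 Hz video. An iterative geometric fit would differ by
$O(\sigma^2/r)$ at our jitter levels — negligible against the landmark
noise, which is why the closed-form algebraic fit was chosen; the test
suite checks it against a brute-force geometric grid search.

Points whose likelihood falls below a threshold (default 0.9; the choice is
a configuration knob, as no canonical value exists) are replaced by linear
interpolation of that point's coordinates between the nearest flanking
confident frames before fitting; frames where the geometry itself is
degenerate have their radius interpolated instead. Leading and trailing gaps
take the nearest valid value — interpolation never extrapolates. The
interpolation scheme is linear by choice; downstream analyses are not
sensitive to the interpolant because blinks are short (hundreds of
milliseconds) relative to pupil dynamics.

Event-aligned responses (`align_to_events`) cut fixed peri-event windows,
with per-event baselines and responses averaged over stated sub-windows
(e.g. baseline at $-2$ s and response at $+6$ s from running-bout onset, or
the mean over the last 10 s of a 30 s stimulation train). Events whose
windows do not fit in the trace are dropped and counted.

# Trace preprocessing

Imaging traces follow a fixed order: **neuropil correction** (plain
subtraction of the halo ROI trace — no scaling coefficient), **duplicate
merging** (cells appearing in several Z-planes are averaged), **3-sample
moving average** (edges shrink the window rather than padding with zeros,
preserving length), and **z-scoring**. The dF/F baseline $F_0$ is the 10th
percentile of the neuropil-corrected trace; a percentile baseline is
standard practice, the percentile is configurable, and the degenerate case
($|F_0|$ below $10^{-6}\times$ the trace scale) raises an explicit error
rather than producing unbounded ratios.

Photometry traces are detrended with a **convex-hull template**: the lower
convex hull of (index, value) is scanned forward in time, keeping only
vertices whose values strictly decrease; the kept vertices are linearly
interpolated to full length (holding the last value to the end), subtracted,
and the residual z-scored. This removes slow monotone bleaching without
assuming a parametric decay. We implement the literal lower-hull reading; a
running-minimum envelope would differ only when the trace dips below the
hull between vertices, and the pure-trend degenerate case (residual variance
zero) is an error by contract. The template is non-increasing by
construction.

# Encoding model

Each cell's processed trace is regressed (ordinary least squares with
intercept, in-sample) on three z-scored predictors on the imaging clock:
pupil radius, running speed, and the lick square wave convolved with a
reward spline. Pupil and behaviour are moved onto the imaging clock by
linear interpolation — camera frames are hardware-synchronised to plane
captures, but the resampling rule onto the imaging clock is a documented
choice of this package.

The reward spline is selected from a candidate basis by refitting the full
model for every cell under every candidate and keeping the kernel that wins
the per-cell argmax vote (ties to the earlier kernel); maximising the mean
$r^2$ is available as an alternative rule. No canonical spline set exists
for this regressor, so the package
ships a documented default: eight raised-cosine bumps with log-spaced
supports from 0.5 to 8 s, non-negative and unit-area. Kernel identity is
recoverable on synthetic sessions only when the indicator kernel is fast;
with a slow indicator the vote legitimately shifts toward longer supports
(the regressor then absorbs indicator dynamics), which the tests account
for.

Cells with full-model $r^2 < 0.05$ are removed (the boundary value is
kept). For the remaining cells, each predictor $v$ is dropped and the model
refit; the **contribution** of $v$ is
$100\,(1 - r^2_{-v} / r^2_{\text{full}})$. Dividing the full by the reduced $r^2$ directly would give a ratio
$\ge 1$; the standard unique-contribution form above is what "percentage
contribution to explained variance" means on a 0–100 scale. With correlated predictors contributions need not sum to 100 and raw
values can be negative (shared variance); raw values are reported alongside
a zero-floored version. Nested-model monotonicity
($r^2_{-v} \le r^2_{\text{full}}$) is asserted on every run. Cells are
labelled `pupil` / `reward` / `both` / `other` at a 20% contribution
cutoff; per-variable histograms above a 10% minor cutoff are also emitted.
No regularisation or train/test split is used — the quantity of interest is
in-sample explained variance.

# Time-series measures

**ON/OFF classification** is the sign of the Pearson correlation with pupil
size, applied to cells that survive the $r^2$ filter.

**Cross-correlation** is the biased estimator (covariances divided by $n$,
normalised by the two standard deviations), stable at large lags. The sign
convention — a positive peak lag means the first argument leads — is stated
in the output. One caveat the tests make explicit: on signals whose
autocorrelation is nearly flat over a few samples, the $1 - |k|/n$ envelope
of the biased estimator pulls the peak slightly toward zero; lag-recovery
checks therefore use sessions whose drive decorrelates over seconds.

**Multitaper coherence** uses DPSS (Slepian) tapers computed in-package
from the tridiagonal form of the concentration problem (Sturm-sequence
bisection plus inverse iteration, $O(n)$ per taper), verified against an
independent reference implementation to $10^{-9}$. Defaults: the first
seven tapers with Thomson adaptive eigenvalue
weighting, a single epoch spanning the whole trace, and pointwise averaging
of per-subject spectra after clipping all subjects to the shortest length.
The time-bandwidth product is a free parameter; we use
$NW = 4$, the smallest standard value for which seven tapers are well
concentrated ($\lambda_7 \approx 0.94$). Magnitude-squared coherence is
reported; it is bounded in $[0,1]$ by Cauchy–Schwarz, symmetric, and
scale-invariant, and its null floor for $K$ equally weighted tapers is
$1/K$ in expectation — the Monte-Carlo check in the acceptance suite uses
uniform weights for exactly that closed form, and observes the adaptive
floor nearby.

# Running bouts and group matching

Running is partitioned at the binary 1 cm/s threshold. Bouts are contiguous
supra-threshold epochs, with sub-0.5 s gaps merged and sub-1 s epochs
dropped (documented defaults). Bout profiles are
raw speed over a fixed $-2$ to $+8$ s peri-onset window, chosen to contain
both the $-2$ s baseline and $+6$ s response probes used in the group
comparisons.

Equivalent bouts across groups are found by k-means (Lloyd's algorithm,
k-means++ seeding under a fixed seed, at most 1000 iterations, within-SS
asserted non-increasing per iteration) on z-scored profiles, pooling both
groups. A cluster qualifies when both groups are represented and their mean
raw-speed profiles differ by at most 0.5 cm/s at every time point; the
number of clusters defaults to 4; both knobs are configurable because no
canonical equivalence criterion exists. Group tests are thin
wrappers over `t.test` and `wilcox.test` (Mann–Whitney U), reporting n,
statistic, and p.

# The synthetic-session generator

The generator emulates the recorded study conditions: a 20 Hz pupil camera
reduced to eight landmarks with likelihoods and blink episodes; cells at
the 5.15 Hz volume rate with raw plus neuropil-halo fluorescence; wheel
speed; 50 milkshake rewards at uniform 60–90 s intervals with Bernoulli
lick bursts; and optional 30 s optogenetic trains at 1/5/10/20 Hz every
120–150 s. Design choices, each made once:

* **Latent arousal** is an Ornstein–Uhlenbeck process (30 s correlation
  time, unit stationary sd): the simplest stationary Gaussian process with
  realistic slow arousal drift, and its closed-form autocovariance is used
  in tests.
* **Pupil** is a first-order low-pass (1.5 s time constant) of a net drive
  (arousal + locomotion + reward transients + stimulation), then a pure
  0.3 s conduction delay. Cells encode the *undelayed* command, so neural
  activity genuinely precedes dilation by a generator-known lag — with a
  slow indicator the fluorescence lag can mask this lead, so lead-recovery
  tests use the fast-indicator configuration.
* **Cells** are weighted sums of the z-scored predictors convolved with a
  unit-sum exponential calcium kernel (1.6 s, GCaMP6s-like) plus white
  noise. Coding is distributed, as in the recorded population: dominant
  class weights (pupil-ON, pupil-OFF, reward, locomotion, mixed, null) plus
  small graded background weights on all predictors for positively-coded
  cells. A purely categorical design would leave most true shares exactly
  zero, making rank-based recovery degenerate regardless of estimator
  quality. True variance shares use the covariance decomposition
  $s_j = w_j\,\mathrm{cov}(cp_j, s)/(\mathrm{var}(s)+\sigma^2)$ on the
  realised convolved predictors, which sums to one with the noise share
  exactly; pupil-OFF cells stay pure so all shares are non-negative.
* **Bouts** are stereotyped archetypes (4 s/4 cm/s, 8 s/7 cm/s,
  14 s/10 cm/s, small amplitude jitter) with rectangular on/off edges,
  exact zero speed at rest and at least 10 s between bouts. Stereotypy is
  what makes k-means matching across groups meaningful, the rectangular
  edges make switch times exact ground truth for detection, and the 10 s
  rest keeps peri-onset windows single-bout. Real running is messier in all
  three respects; the bout tests validate the machinery, not mouse gait.
* **Blinks** are confidence drops only — the extraction path sees nothing
  else — and raw fluorescence adds a shared slow contamination trace with a
  5% leak of the cell signal into the halo, so neuropil correction is
  exercised realistically.
* The **ablation scenario** (`simulate_dtr_scenario`) gives both groups
  identical bout statistics and shifts the ablated group's baseline radius
  by 4 px, about 1.8 times the per-mouse baseline sd once between-mouse
  spread and bout-sampled arousal noise are accounted for; this puts the
  one-tailed two-sample t-test (8 vs 7 mice) near 95% power by design.

What passing these tests does **not** show: robustness to non-circular
pupils, eyelid occlusion geometry, tracker failure modes other than low
confidence, motion artefacts, nonlinear calcium dynamics, or non-stationary
arousal statistics — none of which the generator emulates.

# Numerical choices and problem sizes

Determinism: every random draw descends from a single session seed with
fixed per-stage offsets, so any stage is individually bit-reproducible.
Degenerate inputs fail loudly with classed conditions (zero-variance
z-scores, pathological dF/F baselines, collinear designs named by column,
pure-trend photometry). Ties in the kernel vote go to the earlier kernel;
k-means ties go to the lower cluster index.

The recovery analyses run on a 60-cell, 30-minute session at the recorded
rates (9270 cell samples) with 20 rewards — the session length and reward
count are scaled to hold the generative structure of the full protocol while
keeping the whole suite comfortably reproducible on a laptop; the null
calibration uses 1000 pure-noise cells at $n = 2000$, and the group-power
check runs 100 seeded scenarios of 15 mice each. `scripts/acceptance.R`
recomputes all headline quantities from scratch at these sizes.
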