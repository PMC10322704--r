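# pupilcoding

Analysis pipeline linking hypothalamic **orexin (hypocretin) cell activity**
to **pupil-indexed arousal** in head-fixed mice, for systems-neuroscience
users who record pupil video alongside two-photon calcium imaging or fiber
photometry. The package turns landmark-tracker output into a pupil size
trace, produces analysis-ready neural traces, quantifies what each neuron
encodes, and runs the locomotion-controlled group comparisons used in
loss-of-function experiments — all validated end-to-end on synthetic
sessions with known ground truth.

## What it computes

* **Pupil extraction** — per-frame Kasa algebraic circle fit to 8 tracked
  pupil-edge landmarks, with confidence-gated linear interpolation across
  blinks, plus event-aligned pupil responses (`fit_circle`,
  `extract_pupil_trace`, `align_to_events`).
* **Preprocessing** — neuropil-corrected dF/F (halo subtraction, percentile
  F0), duplicate-plane ROI merging, 3-sample smoothing, z-scoring;
  convex-hull detrending for photometry (`preprocess_cells`,
  `convex_hull_detrend`).
* **Encoding model** — per-cell OLS of activity on z-scored pupil,
  locomotion, and spline-convolved reward predictors. Cells with
  $r^2 < 0.05$ are removed; for the rest, each predictor's **contribution**
  is the drop in explained variance when it is left out,

  $$\mathrm{contribution}(v) = 100\left(1 - \frac{r^2_{-v}}{r^2_{\mathrm{full}}}\right),$$

  and cells are classified pupil / reward / both / other at a 20% cutoff
  (`build_reward_regressor`, `encode_cells`).
* **Time series** — pupil ON/OFF classification by correlation sign, lagged
  cross-correlation (positive lag = first argument leads), and multitaper
  coherence with 7 DPSS tapers and Thomson adaptive weighting
  (`cross_correlation`, `multitaper_coherence`).
* **Running bouts** — 1 cm/s run/rest partition, bout detection, k-means
  (Lloyd + k-means++) matching of equivalent bouts across groups, and the
  group tests (`detect_bouts`, `match_equivalent_bouts`, `compare_groups`).
* **Synthetic sessions** — a generator reproducing the study conditions
  (20 Hz pupil video, 5.15 Hz volume rate, 50 rewards at 60–90 s intervals,
  30 s optogenetic trains at 1/5/10/20 Hz) with analytic per-cell variance
  shares for recovery testing (`simulate_session`, `simulation_config`).

## Worked example

The numbered drivers under `analysis/` run the whole pipeline on a stored
synthetic session (`Rscript analysis/01_simulate_session.R 1`, then the
rest in order). Driver 04 fits the encoding model and checks recovery
against the generator's ground truth; with seed 1 it prints:

```
Reward spline: kernel 6 (support 3.62 s) won 33/60 cell votes
Kept 53/60 cells (r2 >= 0.05); median r2 = 0.90

  both  other  pupil reward
    11      7     23     12
  pupil: Spearman(true share, contribution) = 0.928
  locomotion: Spearman(true share, contribution) = 0.962
  reward: Spearman(true share, contribution) = 0.983
  label accuracy vs ground truth: 98.1%
```

All seven noise-only cells land in `other` or below the r² filter; the
Spearman values say the estimated percentage contributions rank the cells
almost exactly as their true generative variance shares do. Driver 06 runs
the ablation-style comparison on locomotion-matched bouts:

```
Matched 60 + 62 bouts in 3 qualifying cluster(s); max mean-speed difference 0.29 cm/s
Baseline pupil at -2 s: control 30.1 px vs ablated 26.1 px; one-tailed t = 3.05, p = 0.00559 (n = 8 vs 7 mice)
```

i.e. the two groups run identically (mean bout speeds within 0.29 cm/s)
while the injected baseline-pupil deficit of the ablated group is detected.

## Layout

```
R/                  package code (generator, extraction, preprocessing,
                    encoding, time-series, bouts, session I/O + report)
analysis/           numbered narrative drivers writing under results/
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R
vignettes/pupilcoding-methods.Rmd   model, assumptions, design choices
```
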