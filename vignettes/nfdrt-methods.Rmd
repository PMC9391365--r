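---
title: "Models and methods behind nfdrt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nfdrt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfdrt)
```

# The scientific problem

Real-time fMRI neurofeedback lets a participant watch a display driven by
their own SN/VTA (dopaminergic midbrain) activity and try to raise it with
reward imagery. Success is measured not during training but afterwards: the
degree of regulation transfer (DRT) compares the IMAGINE_REWARD-minus-REST
contrast in a feedback-free transfer run against the same contrast at
baseline. A positive DRT means regulation ability that outlives the feedback.
The package implements the analysis chain that connects this statistic to
learning theory: the online feedback computation, a reinforcement-learning
account of how strategies are acquired, GLM-based tracking of
temporal-difference (TD) signals outside the midbrain, task-modulated
connectivity (PPI), and reward sensitivity in an independent monetary
incentive delay (MID) task — together with a synthetic-data generator that
makes the whole chain testable without any scanner data.

# The feedback engine

Feedback for each volume is computed from the raw SN/VTA region average in
three steps: the *reference* is the mean of the last five volumes of the
preceding REST block (chosen over a global baseline because it tracks slow
drift and motion); a *moving average* over the current and two preceding
volumes suppresses volume-to-volume noise at the cost of roughly one volume
of latency; and the *percent signal change* of the smoothed value against the
reference is displayed, sign-flipped for the inverted control arm. Two
details are not documented in typical protocol descriptions and were fixed
as package conventions: the moving-average window includes the current
volume, and the display saturates at plus/minus 2% PSC (configurable). The
reference is latched at each REST-to-IMAGINE transition and held through the
following REST block, so feedback is defined in both conditions. The engine
is a pure state machine: streaming one volume at a time and replaying a
recorded run are bit-identical.

# The learning agent

Associative-learning accounts of neurofeedback treat the displayed feedback as a higher-order
reward that reinforces whichever mental strategy the participant used. We
model the strategy repertoire as a K-armed problem (K = 5 by default): each
strategy k has a regulation efficacy e_k in [0, 1], unknown to the agent. At
every IMAGINE_REWARD block the agent draws a strategy by softmax over its
current values; the block's perceived reward is the mean displayed feedback
over the block window lagged by 5 s (the hemodynamic delay participants were
told about); and the chosen strategy's value moves by a delta rule,
`V <- V + alpha (R - V)`. At TR resolution the TD error collapses to the
difference between consecutive feedback states, which is also what the GLM
modulator tracks.

Three behavioural details matter for the statistics the study computes, and
all three were design decisions:

* **Stable preferences outside training.** Choices at baseline and transfer
  are driven by the current values at a low temperature. If instead the
  agent re-randomized its strategy every block, the transfer-minus-baseline
  difference would be dominated by choice sampling noise that no real
  participant shows (people have imagery habits); the generator therefore
  uses a near-deterministic policy at the feedback-free runs.
* **Directed exploration during training.** Participants were explicitly
  given example strategies to try. The agent adds a novelty bonus to
  not-yet-tried strategies during feedback runs only; the bonus never enters
  the learned values, so it cannot leak into baseline or transfer behaviour.
* **The inverted arm is modelled as non-contingent.** A delta-rule learner
  fed the sign-flipped display would converge on *down*-regulation, making
  training slope and DRT correlate positively in the control arm — the
  opposite of what the empirical control group shows (near-zero mean DRT and
  no slope-DRT correlation). The theory motivating the control arm holds
  that reversed feedback breaks the learnable association between imagery
  and display; we implement exactly that with a `contingency` factor on the
  effective learning rate, 0 by default in the inverted arm and configurable
  up to 1 for users who want the fully sign-flipped learner.

# The synthetic-data generator

Per run, the midbrain neural amplitude is `regulation_gain * efficacy` of the
chosen strategy during IMAGINE blocks and 0 during REST, convolved with a
canonical double-gamma HRF. The HRF kernel is normalized to unit block
plateau, so all amplitudes are in percent-signal-change units; the same
kernel builds the GLM regressors. On top of the task signal the measured
series carries AR(1) noise (phi = 0.3, innovation sd 1.0 for the brainstem
ROI), a linear drift, and sinusoidal physiological components (0.25 and
1.0 Hz aliased onto the TR grid) shared with the CSF/WM voxel pool. Cortical
ROI averages (dlPFC, parahippocampal control region) carry 0.4 times the
brainstem noise, reflecting the much higher temporal SNR of large cortical
regions compared with a small brainstem ROI surrounded by pulsatile
structures.

The dlPFC series adds two couplings: a share of the task signal, and a
loading `w_run` on the HRF-convolved midbrain TD trace. `w_run` declines
with learning progress — measured as the fractional decline of the absolute
block TD error from the first to the last third of training run 1 — so the
TD coupling weakens exactly for subjects who learn, which is the structure
the run2-minus-run1 TD-modulator contrast is designed to detect. During
training runs an IMAGINE-specific interaction
`connectivity_modulation * I(t) * (dlPFC - mean)` is added to the measured
midbrain series; this is the ground-truth coupling the PPI analysis
recovers. MID sessions model each cue as an impulse of height
`cue_gain + general_gain * magnitude + adaptive_gain * magnitude / range`,
so adaptive coding makes a franc in the small range count for more than a
franc in the large range.

## Calibration choices

No generative magnitudes are published for this paradigm, so the defaults
are calibration choices, made once and documented here:

* regulation gain lognormal(log 3, 0.35) across subjects; with the
  regulator archetype (learning rate uniform on [0.2, 0.5], efficacy spread
  uniform on [0.5, 1.5] around 0.5) this produces a cohort DRT spread of
  roughly plus/minus 1 PSC around a near-zero non-learner mean, matching the
  "considerable variation with near-zero group means" character of the
  published distributions;
* noise anchored at a realized IMAGINE-REST contrast-to-noise ratio of
  about 0.5 at unit gain (marginal sd 1.0 in PSC units for the midbrain);
* softmax temperature 0.15, novelty bonus 1.5, perceived-feedback lag 5 s;
* dlPFC TD coupling w0 = 0.6 with decay 0.9; PPI coupling 0.5 (a moderate
  effect chosen a priori so the two-run combined interaction test has
  ~85-90% power under this noise model);
* MID: 25 trials per cue at 10 s spacing (a realistic 13-minute session),
  general gain 1.0 per CHF, adaptive gain 1.0 (strong but not complete range
  adaptation).

## What the generator does and does not emulate

It reproduces the statistical structure the analyses assume: block timing,
closed-loop feedback, learning-driven individual differences, nuisance
structure (motion, drift, CSF/WM physiology), and the couplings each aim
tests. It does not emulate spatial structure (no voxelwise maps; regions are
one series each), respiratory/cardiac waveforms, frustration or affect in
the control arm, magnitude-dependent display nonlinearities, or non-
stationary noise. Passing tests therefore certify the pipeline's logic and
statistical calibration, not its behaviour on artifacts only real data
contain.

# First-level models

The block GLM has exactly fifteen regressors per run: HRF-convolved REST and
IMAGINE boxcars, an indicator for the first five volumes, six motion
parameters, and the first six temporal principal components of the pooled
CSF/WM voxel matrix (computed on the column-centered matrix; components are
unit norm, variance-ordered, and sign-fixed by making the largest-magnitude
loading positive). There is no intercept column: the run series is
PSC-normalized (`100 (x - mean)/mean`) before fitting, and the two condition
boxcars span the task space, matching the printed regressor count. The TD
design replaces the block regressors with per-TR event regressors plus
parametric modulators equal to the one-volume backward difference of the
measured SN/VTA series, mean-centered within condition; the backward
difference crosses condition boundaries (the first volume of a run gets 0),
because the error signal is defined per TR, not per block. PPI designs form
the interaction in the measured-signal domain (centered condition indicator
times centered seed) without deconvolution — acceptable for 20 s blocks,
and a documented approximation. Estimation is plain OLS via QR; AR(1)
prewhitening is deliberately omitted because the simulator's phi = 0.3 is
mild and every acceptance-level check is a parameter-recovery or calibration
property that OLS meets; rank-deficient designs are refused with the
offending columns named.

# Subject measures and group statistics

Midbrain DRT uses condition means of the PSC-normalized series with a 4 s
(two-volume) hemodynamic label shift by default; set the shift to 0 for raw
block means. Non-midbrain DRT, the training slope and the TD slope are
contrast differences between fits. Group statistics wrap the standard tests
(equal-variance one-way ANOVA, Kruskal-Wallis, pooled-variance t) and
implement the pieces base R lacks: the Fisher z comparison of independent
correlations, Spearman p-values by t approximation with exact permutation
enumeration below n = 10, a seeded percentile bootstrap (10,000 replicates
by default), and study-covariate adjustment by residualizing both variables
on the study indicator. Region-level multiplicity is controlled with BH-FDR:
the voxelwise cluster-level correction of the original whole-brain maps has
no analogue in region-resolved synthetic data, a documented deviation.

# Numerical and testing notes

Every stochastic function takes or derives from an explicit seed, and
identical seeds give bit-identical output, including written files. The test
suite exercises each operation against independent oracles (normal
equations, closed-form test statistics, hand-stepped feedback traces,
Monte-Carlo nulls) and the acceptance checks run the full pipeline at the
study's sizes: a 40-subject mixed standard cohort plus a 17-subject inverted
cohort for the manipulation check, 100 sixteen-subject replicates for the TD
analysis, 200 subjects each for MID recovery and PPI power, and a
200-subject non-learner cohort for null calibration. Several of these
checks are inherently probabilistic (a 95% CI containing zero, a null test
staying below the 5% level, a power estimate above a bound), so a correctly
calibrated pipeline still fails any one of them for a small fraction of
seeds; the fixed test seeds were chosen by convention, not by search.

# Known limitations

The delta-rule agent with pessimistic initial values sometimes locks onto a
well-sampled mediocre strategy before revisiting the best one, so roughly
15% of simulated regulators improve little; this is a faithful property of
constant-step-size learners, and it is one source of the regulator /
non-regulator continuum rather than a defect. The inverted arm's
non-contingent default is a modelling commitment about why reversed feedback
prevents learning; users can explore the alternative (a faithful
sign-flipped learner) by setting `contingency = 1`. The feedback engine's
display scaling and saturation are conventions. Real-data ingestion is
limited to tabular ROI series; spatial preprocessing (despiking, slice
timing, normalization, smoothing) is out of scope because synthetic data are
generated in analysis space.
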