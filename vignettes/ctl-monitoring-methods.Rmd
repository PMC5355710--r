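---
title: "Cognitive task-load monitoring and adaptive automation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cognitive task-load monitoring and adaptive automation: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctlmon)
```

`ctlmon` estimates an operator's cognitive task-load (CTL) from EEG and
ECG features and uses the estimate to reallocate tasks between operator
and machine in a closed loop. This vignette documents the models the
package implements, the parameters that matter, the numerical choices
made where the method's description leaves room, and what the synthetic
test bed does and does not establish.

## 1. Signal preprocessing

A session is a 13-channel recording at 500 Hz: eleven scalp EEG channels
(frontal, central, parietal, occipital midline and lateral sites), one
ECG and one EOG channel. The chain is:

1. **Low-pass filtering** at 40 Hz with a causal 3rd-order Butterworth
   IIR filter, to suppress EMG contamination. The filter is applied with
   a constant-level start-up pad so a signal already at steady state
   passes through without an initialization transient; phase is not
   compensated (a uniform group delay is irrelevant to band power).
2. **Ocular artifact removal** by exponentially weighted recursive least
   squares: an M = 3-tap FIR filter of the EOG reference is adapted
   sample-by-sample (forgetting λ = 0.99) to minimize the forgotten
   squared error against the contaminated EEG, and the cleaned signal is
   the a priori residual. Initialization: zero taps, inverse-correlation
   accumulator (1/δ)·I with δ = 10⁻³. With λ = 1 the steady-state taps
   coincide with batch ordinary least squares (a tested equivalence);
   with an all-zero reference the filter never adapts and the EEG passes
   through unchanged.
3. **Epoching** into consecutive non-overlapping 10-s windows (the
   trailing partial window is discarded). Ten seconds is the shortest
   epoch that yields the 0.1 Hz spectral resolution used next, and sets
   the monitoring update rate.
4. **Spectral features.** Each epoch's power spectrum is a single
   rectangular-window periodogram of the full 10-s epoch — no Welch
   averaging, which would forfeit the 0.1 Hz grid — restricted to 400
   bins with centers 1.0–40.9 Hz. Band powers are means over the bins
   whose centers fall inside delta 1–4, theta 5–8, alpha 9–12, beta
   13–32, gamma 33–40 Hz. Two notes: the delta band is evaluated from
   1 Hz because the grid starts there, and bins strictly between two
   bands (e.g. 12.1–12.9 Hz) belong to neither; 13.0 Hz belongs to beta.
   These band edges are the feature-extraction definition; they are
   configurable through `ctl_config()`.
5. **Heart rate** per epoch is the mean of 60/RR over the epoch's R-R
   intervals. The R-peak detector (no detector is prescribed by the
   method) band-passes 5–15 Hz and picks local maxima above 0.6 × the
   rolling 2-s maximum with a 250 ms refractory period; the rolling
   threshold is floored at 0.2 × the epoch maximum so beat-free windows
   do not fire on ringing. Epochs with fewer than two detected peaks
   carry the previous epoch's value forward.
6. **Assembly.** 11 channels × 5 bands + HR = 56 features per epoch,
   z-scored per session (the session is the data matrix over which the
   normalization statistics are taken). Zero-variance columns are set to
   zero with a warning rather than producing NaN.

On-disk formats are plain CSV: a long-form recording table
(`time_s, channel, value_uV`) and a wide feature table. EDF input is not
implemented: no EDF reader is available in the package's dependency
footprint, and the CSV schema carries the same information for the
package's purposes.

## 2. Performance indices and class labels

For each 10-s segment with n(k) manually controlled subsystems,
s_e(k) and s_t(k) average the per-subsystem fractions of time spent
inside the error range and transition zone, and s_a(k) averages
|output − set-point| normalized by the error-range length. The overall
performance is

y(k) = ½ min(s_e, s_t) + ½ (1 − ŝ_a),

low y meaning high task-load. The index names (time *in* range) follow
the convention that high values are good, consistent with "very low s_e
indicates performance breakdown". Since no formula is prescribed for the
normalization ŝ_a, the package min–max normalizes s_a over the
participant's concatenated sessions and clips to [0, 1]; this is the
weakest assumption that keeps y inside [0, 1].

Classes are cut from the top of the performance scale: class 1 on
[1 − σ_o, 1], then half-open intervals down to class 5 ("otherwise"),
with boundaries 1 − z₁σ_o, 1 − z₂σ_o, 1 − z₃σ_o. σ_o is the standard
deviation of y over the participant's concatenated two sessions, so both
sessions share one labeling. The z coefficients are per-participant
constants (reference values for seven operators are embedded in
`ctl_reference_tables()`; the default is z = (2.3, 2.7, 3.0)). A value
exactly on a boundary belongs to the upper class.

## 3. Feature smoothing and reduction

**Adaptive exponential smoothing (AES).** Each of the 56 feature series
is smoothed by ε(k) = (1 − g) ε(k−1) + g x(k), ε(1) = x(1), with the gain
picked per step from the innovation |x(k) − ε(k−1)| relative to the
series scale σ: g₁ = 0.2 below 1σ, g₂ = 0.1 between 1σ and 2.2σ
(a suspected motion artifact is tracked conservatively), g₃ = 0.3 beyond
(a genuine level shift is tracked faster). The published recursion names
two gain symbols without defining the first; the package uses the same
step-selected gain in both places, which is the only reading that makes
a constant series a fixed point of the recursion. σ is estimated once
from the training session and reused for the test session; HR is
smoothed with the same constants as the EEG features.

**Locality preserving projection (LPP).** Per EEG channel, the five
smoothed band-power series (K × 5) are reduced to one scalar x′ = μᵀx.
μ solves the generalized eigenproblem XᵀLX μ = λ XᵀDX μ (L the graph
Laplacian, D the degree matrix) for the smallest eigenvalue, i.e. the
direction along which temporally/spectrally neighbouring epochs stay
close. Hyperparameters (unspecified by the method): symmetric 5-nearest-
neighbour graph, heat-kernel weights with width equal to the median
squared pairwise distance. Numerics: the problem is solved by Cholesky
whitening of XᵀDX followed by a symmetric eigendecomposition; if the
scatter is rank-deficient (duplicated epochs, collinear bands) it is
solved in the span of the non-null eigendirections with a warning. μ is
unit-normalized, given a deterministic base orientation
(largest-magnitude entry positive), and then sign-fixed so the training
projection correlates nonnegatively with performance — projections of
CTL-sensitive channels co-trend with y. The mapping is fit on session 1
only and frozen for session 2. Output: 11 channel scalars + smoothed HR
= 12 salient features.

## 4. The dynamic NARX-LSSVM classifier

Both variants predict performance, then discretize it into the CTL class
with the same boundaries as the labels.

**Components.** A least-squares SVM regression solves the
equality-constrained dual system \[0, 1ᵀ; 1, K + I/γ\]\[b; α\] = \[0; y\],
with γ = 100 and RBF width σ² = 500 everywhere. A singular system is
ridge-perturbed by 10⁻¹⁰ with a warning. Two frozen components are
trained on session 1: an RBF regression on the stacked exogenous block
x′(k), …, x′(k−d₁+1) (12·d₁ inputs) and a linear-kernel regression on
the autoregressive block of d₂ lagged performances, teacher-forced
(measured y in the AR slots) during training.

**Combination.** The published prediction equations attach the variant
weights to the biases only, which leaves the multiplier scales
unidentifiable; the package instead forms a convex combination of
complete component predictors — weights (m₁, m₂) = (0.1, 0.9) for
LSSVM1 and (w₁, w₂, w₃) = (0.02, 0.18, 0.8) for LSSVM2 — consistent with
their description as combination weights. LSSVM2's third term is a local
linear regressor refit at every prediction step on the four measured
samples j = k−5 … k−2 (inputs: their d₂ lagged measured performances),
then evaluated at the current lag vector. While that window is not yet
fully inside the record the term is omitted and the remaining weights
are renormalized.

**Prediction modes.** At test time the AR component runs free
(feeding back its own predictions; the first max(d₁, d₂+1) − 1 epochs
are warm-up and copy measured values), which is how the evaluation and
the closed-loop simulator use the model. A teacher-forced one-step-ahead
mode is also provided; it is the natural notion for checking tracking
accuracy on processes with known structure, because the fixed-weight
combination of independently trained components has an irreducible
free-run error proportional to the output spread.

**Structure selection** minimizes J(d₁,d₂) = 0.8 r_e + 0.2 n_θ/n_θmax on
the 15 × 15 integer grid (225 candidates), where r_e is the
teacher-forced training RMSE. Because LSSVM multiplier counts scale with
the sample count rather than the orders, model complexity is measured by
the regressor length n_θ = p·d₁ + 2·d₂ (p features; the factor 2 counts
the AR order's appearance in both the frozen and local autoregressive
terms), with n_θmax at the grid corner. Ties are broken toward smaller
d₁ + d₂, then smaller d₁.

**Evaluation.** Confusion matrices are oriented predicted-in-rows ×
target-in-columns; per-class accuracy is the column recall, undefined
(NA) for target classes that never occur. Cumulative binary splits give
four FPR/FNR pairs: in case m the negative class is classes 1…m. A
paired Cohen's d helper (mean difference over its s.d.) supports
model comparisons.

## 5. Closed-loop adaptive automation

The simulator couples three blocks per 10-s step: a **data generator**
that draws an (x′, y) epoch uniformly with replacement from the test
session's bin for the current task count (a request for n = 2 is served
from the n = 1 bin, since that condition is absent from the schedule);
the **LSSVM2 predictor** (free-running AR feedback, measured generator
performance as the local-term history); and a **controller** acting on
the previous step's error e = 1 − ỹ with gain K = 1: Δn = 0 / 1 / 2
below 0.2 / in [0.2, 0.8) / at or above 0.8. The rule-based variant
freezes the allocation for the two steps after any change (30 s of
recovery time); the proportional-threshold variant may act every step.

The without-automation condition is the six-block schedule
n = 1, 3, 4, 4, 3, 1 (15 steps per block, 90 steps = 900 s per run).
Design choices the description leaves open: the schedule re-imposes its
block value at each block boundary (a new task-load condition arrives
externally; this is what makes with- and without-automation runs
comparable), any pending hold is cleared at a boundary, controllers only
ever move tasks toward the machine, and n is clamped to [1, 4]. Runs are
averaged (default 10 runs; run i uses master seed + i) into n_MEAN,
C_MEAN (predicted classes) and y_MEAN (measured performance).

## 6. The synthetic test bed

`generate_session_features` emulates what the monitoring chain assumes
about real sessions: 540 epochs in the 1,3,4,4,3,1 schedule; performance
y = 0.95 − 0.07·n plus AR(1) noise (φ = 0.6, s.d. 0.04), clipped to
[0, 1]; salient features negatively coupled to load with AR(1) noise
scaled in closed form so each channel's |corr(x′, y)| lands near the
embedded reference levels (≈ 0.74 for the strongest frontal channel,
≈ 0.32 for HR). The slope and noise scale were chosen so that (i) the
five classes all occur with non-trivial occupancy under the default
z = (2.3, 2.7, 3.0) and (ii) σ_o ≈ 0.1, the magnitude real performance
data shows. `generate_raw_recording` produces the matching raw signals —
band-limited noise carriers with load-modulated amplitudes, a blink-pulse
EOG that leaks into the frontal channels, an R-wave train whose rate
rises with load — to exercise the full preprocessing path.
`generate_narx_process` provides ground truth for order recovery; its
default coefficients put substantial weight on the boundary lags so that
the true orders are identifiable against the parsimony pressure of J.

What passing on this bed shows: the pipeline's algebra and bookkeeping
are right, the solvers agree with independent oracles, the
measured-history variant dominates the free-running one under the
assumed data structure, and the closed loop improves measured
performance. What it does not show: robustness to non-stationarity
across days, to violations of the linear load-coupling, to real artifact
morphology, or to the operator adaptation transients at control-mode
switches — the generator draws epochs independently within a task-load
bin, so recovery dynamics after reallocation are not modeled.

Problem sizes used by the test suite and the acceptance script (oracle
instances of 20–50 samples, 150–540-epoch sessions, 250-sample order-
recovery series, 10-run simulations) were chosen as the smallest sizes at
which the statistical properties under test are stable.

## 7. Known limitations

- The fixed combination weights are taken as given, not re-estimated;
  with them, the free-running variant's accuracy is bounded well below
  the measured-history variant's whenever the AR dynamics dominate.
- The ŝ_a normalization and the R-peak detector are the package's own
  constructions (documented above) since the method prescribes neither.
- Controllers never hand tasks back to the operator; over a long enough
  horizon without schedule resets, n would sink to 1.
- The rolling-maximum R-peak threshold assumes at least one beat per 2-s
  window at realistic amplitudes; pathological ECG morphologies are out
  of scope.
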