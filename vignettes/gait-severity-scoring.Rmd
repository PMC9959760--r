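---
title: "Methods: severity scoring of parkinsonian gait from shank IMUs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: severity scoring of parkinsonian gait from shank IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitscore)
```

## The problem

The gait task of the Unified Parkinson's Disease Rating Scale (UPDRS) asks a
neurologist to watch a patient walk and assign a severity level from 0
(normal) to 4 (cannot walk). The rating is ordinal, coarse, and
rater-dependent. `gaitscore` implements an instrumented alternative: two
inertial measurement units (IMUs) strapped to the shanks just above the
ankles record 100 Hz gyroscope and accelerometer streams during a straight
12 m walk; twelve gait features are extracted per subject; and a small
nonlinear model maps the feature vector to a *continuous* score on
(-0.5, 4.5) whose rounding reproduces the ordinal level while its
fractional part ranks severity within a level.

## Signal processing pipeline

**Sensor conventions.** Sensor X is along the shank (inferior-superior), Y
anterior-posterior, Z mediolateral; gyroscope range ±1000 °/s,
accelerometer ±8 g, 100 Hz. Files store °/s and g; internally the package
works in rad/s and m/s². A global frame per stride uses P (progression:
the horizontal line joining two successive landing points of the same
foot), V (up, opposite gravity) and L (lateral, completing the
right-handed frame).

**Frame correction.** Mounting misalignment is estimated from a
quasi-static standing window at the start of the recording (gyro magnitude
below 5 °/s and specific-force magnitude within 10% of 1 g for at least
0.5 s): the measured gravity reaction is rotated onto the shank axis
(-X), and the same rotation is applied to both sensors. Any rotation
component about gravity is unobservable from a static window; it is also
irrelevant, because the per-stride P axis is defined from the data (the
trajectory tests verify this frame covariance to 1e-6).

**Event detection.** The mediolateral angular velocity of a walking shank
is cyclic: a large positive mid-swing peak flanked by negative troughs
near toe-off (TO, before the peak) and heel-strike (HS, after it). The
trace is low-passed with a zero-phase Butterworth filter (order 2 applied
forward and backward, 10 Hz cutoff), mid-swing peaks are found (height
≥ 50 °/s above baseline, ≥ 0.4 s apart), and TO/HS are read off as the
flanking local minima. A mirrored mounting (left vs right shank) flips the
sign of Z; the detector auto-flips when the median of the three largest
extrema is negative. All thresholds are exposed in
`gaitscore_config()$segmentation`. HS events delimit gait cycles; the TO
inside each cycle splits stance from swing. The first four steps of a
trial are treated as the accelerating phase and discarded; the following
ten steady cycles (per leg) are analysed.

**Trajectory reconstruction.** Each cycle is integrated independently. The
zero-velocity instant is the stance sample minimizing the 0.1 s-smoothed
gyro magnitude (foot-flat mid-stance). The attitude there is anchored from
the accelerometer (the specific force at a stationary instant is the
gravity reaction), propagated forward and backward across the cycle by
integrating the gyro (per-sample rotation vectors), and used to rotate the
specific force into the global frame, where gravity is subtracted.
Velocity is the cumulative trapezoidal integral, reset to zero at the
zero-velocity instant; the residual velocity at the terminal heel-strike —
itself a landing, hence stationary — is treated as accumulated drift and
removed linearly over the ZUPT-to-landing span. Position is the second
integral, zeroed at cycle start. The sensor sits at the ankle, so no
lever-arm correction is applied. The heading left free by the gravity
anchor cancels when positions are expressed in the per-cycle P/V/L frame.

**The twelve features.** Per cycle: stride length SL (horizontal
landing-to-landing displacement), cycle duration GD, percent swing phase
PSP, maximum ankle height MH (V excursion above the cycle-start
heel-strike), lateral range RL, shank rotation ranges RSZ/RSY/RSX
(ranges of the integrated gyro axes, degrees), maximum progression and
vertical ankle velocities MPV and MVV, maximum swing-phase mediolateral
angular velocity MSV, and the progression displacement at the MH instant,
MHD. SL, MH, RL, MPV, MVV and MHD are divided by subject height; a
subject's feature vector is the flat mean over all steady cycles of both
legs and all trials. "Two adjacent landing points" is read as consecutive
heel-strikes of the *same* leg (a stride), since each IMU is processed
independently. MH is measured from the ankle height at the cycle-start
heel-strike, the natural datum of a per-cycle integration.

## The scoring model

Four parallel hyperplanes in feature space separate the five levels. With
weights $w$ and offset $c$ (the $1/\lVert W\rVert$ normalization absorbed
into $w$), a subject's signed distance is $x_{hp} = w^\top x + c$. A
sigmoid bounds it into $(b_l, b_u) = (-0.5, 4.5)$:

$$y_{rd} = \frac{b_u - b_l}{1 + e^{-(x_{hp} - (b_u+b_l)/2)}} + b_l
        = \frac{5}{1 + e^{-x_{hp}+2}} - 0.5 ,$$

and a continuous piecewise-linear map sends the demarcation values
$p_1 < p_2 < p_3 < p_4$ (the $y_{rd}$ values at the four hyperplanes) to
0.5, 1.5, 2.5 and 3.5: with boundaries $(b_l, p_1, \dots, p_4, b_u)$ and
$j$ the segment index,

$$y = \frac{y_{rd} - \text{lower}_j}{\text{upper}_j - \text{lower}_j}
      + b_l + j .$$

The map is continuous, strictly increasing, and reduces to the identity
for the evenly spaced default $p = (0.5, 1.5, 2.5, 3.5)$. Rounding $y$
(half-up: 2.5 becomes 3, a fixed tie rule the scale itself leaves
ambiguous) recovers the level; the demarcations must satisfy
$p_1 - b_l \ge 0$, $p_{i+1} > p_i$, $b_u - p_4 \ge 0$.

## Training

The loss averages per-level mean absolute errors of the *continuous*
score, so every level present weighs equally regardless of its count:

$$L = \frac{1}{N}\sum_{j} E_j + \lambda R_1 + \beta R_2, \qquad
  E_j = \frac{1}{n_j}\sum_{i} |y_{j,i} - Y_{j,i}|,$$

with $R_1 = \sum_k (w_k\,\mathrm{sd}(x_k))^2$ a scale-aware L2 penalty
(sample sd of the raw training features, denominator $n-1$) and
$R_2 = \sum \text{(reciprocal demarcation gaps)}$ a barrier keeping
hyperplanes apart. $\lambda = 0.1$ and $\beta = 0.005$; $N$ counts the
levels present in the training set. The model consumes raw features —
$R_1$ already adapts to their scales — while healthy-reference z-scoring
(`standardize_features()`) is provided for presentation and the ANOVA
screen.

Fitting starts from the deterministic initialization $w = 0$, $c = 0$,
$p = (0.5, 1.5, 2.5, 3.5)$ and minimizes $L$ under the linear demarcation
constraints with a logarithmic-barrier method (`stats::constrOptim`,
BFGS inner iterations, central-difference gradients; strict gaps enforced
as $p_{i+1} - p_i \ge 10^{-3}$ so the feasible set is closed). The
absolute error is kept exact by default — the finite-difference gradients
tolerate the kink — with an optional Huber smoothing behind
`huber_delta`. The fit is deterministic (no multi-start), never returns a
loss above the initialization, and always satisfies the constraints.

Evaluation is leave-one-subject-out (LOSO): for each subject the model is
refit on all others (per-fold `std_x`), then scores the held-out subject.
The error statistic is $e = |s_e - s_n|$ between rounded and clinician
levels, with its cumulative distribution $c_i$ in percent. The SVM
(linear kernel, $C = 1$ — unstated in the source method, chosen for the
small-sample setting, RBF available via config), Gaussian naive Bayes
(variance floor $10^{-9}$ for singleton classes) and linear regression
(predictions clamped to $[-0.5, 4.5]$ before rounding) baselines consume
identical folds, so comparisons are paired.

Feature selection is a one-way ANOVA screen across level groups (healthy
subjects count as level 0; retain $p < 0.01$), followed by a greedy
wrapper: although the source literature labels it "recursive feature
elimination", its description is forward addition, and the description
wins — starting empty, each step adds the feature minimizing LOSO mean
error; the whole error-vs-size curve is recorded and the optimum breaks
ties toward smaller sets, then canonical feature order. The inner error is
LOSO-based (consistent with every reported error being LOSO); a true
backward mode exists behind `direction = "backward"`.

## The synthetic-data generator

No clinical recordings ship with the package, so its tests rest on two
generator tiers whose ground truth is known exactly.

**Feature tier** (`generate_features()`). A true $(w^*, c^*, p^*)$ defines
signed-distance bands per level (outer levels extend by one neighbouring
band width). Each subject's distance is drawn from a normal centred
mid-band and truncated to the band's central half (sd = a quarter of the
occupied region), then embedded in feature space along $\hat w^*$ with
isotropic Gaussian noise on top. The central-half margin is structural: a
rating scale assigns a level only where the rater is confident, so
noiseless data contain no boundary-hugging cases — and a noiseless table
must remain exactly recoverable by a refit model, which no generator that
places points arbitrarily close to a decision boundary can satisfy. The
per-level clusters are unimodal and ordered along $\hat w^*$, emulating
the qualitative structure of clinical feature distributions; they do not
emulate feature-specific units, inter-feature correlations, or outliers,
so passing tests certify the estimation machinery, not clinical validity.

**Signal tier** (`generate_imu_trial()`). An analytic ankle trajectory is
built per cycle: stationary through stance, and through swing a quintic
smoothstep covering the stride length with a C² bump (peak = max ankle
height) in the vertical and lateral axes; zero velocity and acceleration
at the stance boundaries make the arcs ZUPT-consistent. The shank pitch
rate is a mid-swing positive bump peaking at the MSV target plus narrow
negative dips at TO and HS — the landmark pattern the detector keys on.
Accelerometer samples are the trajectory's acceleration plus gravity
rotated into the pitching sensor frame; acceleration samples are chosen so
trapezoidal re-integration reproduces the analytic velocity exactly at the
sample instants, keeping discrete emission and analytic truth consistent
to well under a millimetre per cycle. Free targets are SL, GD, PSP, MH,
RL and MSV; the rotation ranges follow from the pitch-rate shape and are
recorded as derived truths. Net pitch per cycle is not forced to zero —
the per-cycle, gravity-anchored reconstruction is invariant to a secular
pitch term — which is a deliberate simplification, not a gait model.
Default targets (stride 1.20 m, cycle 1.10 s, swing 40%, peak ankle
height 0.25 m, peak swing pitch rate 400 °/s, height 1.60 m) describe an
unimpaired adult; 16 cycles are emitted so that ten steady cycles remain
after discarding the accelerating steps and the boundary-truncated first
cycle.

## Numerical choices and degenerate inputs

Integration is cumulative trapezoidal throughout; drift compensation is
linear between zero-velocity anchors (`drift_model = "none"` disables
it). Readers reject, never clip, out-of-range samples (error above 1%
violating rows) and refuse non-monotonic timestamps. A cycle plausibility
window of 0.4-4 s drops implausible HS pairs. Zero healthy variance stops
standardization with the offending feature named; a constant feature gets
$F = 0$, $p = 1$ in the ANOVA screen rather than NaN. Model JSON is
written with 17 significant digits so parameters round-trip bit-exactly.
Scoring ties at exact half-points round toward higher severity;
`findInterval` assigns demarcation values to the lower segment, where the
map is continuous anyway.

## Test scale and what the suite shows

The heavy recovery checks run at desk scale, chosen to finish in minutes
while keeping the Monte-Carlo estimates stable: label recovery uses 20
subjects per level noiseless and 50 per level at noise 0.3 band widths
over ten seeds (mirroring the qualitative exact/within-one structure of
clinical reports without claiming any dataset); the linear-baseline
comparison uses 12 subjects per level over four levels and ten seeds. A
three-level comparison would be vacuous — rounding a scalar linear
prediction yields equally spaced decision thresholds with a free offset
and spacing, which can realize *any* two-boundary layout — so the
comparison generates four levels with strongly uneven demarcation gaps
(0.83/0.60/3.42), a layout the linear model provably cannot match and the
adaptive demarcations can.

## Known limitations

The kinematics assume straight, level walking: no turning, freezing,
stair or treadmill gait, and no magnetometer (the hardware has none).
Levels 3-4 are modelled but untrainable from walking data, since such
patients cannot perform the task. Stride-to-stride variability features
are deliberately out of scope. The synthetic tiers validate internal
consistency and estimator behaviour; clinical performance claims require
clinical data.
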