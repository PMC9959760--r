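# gaitscore

Automatic severity scoring of parkinsonian gait from two shank-mounted
inertial measurement units (IMUs).

The gait task of the Unified Parkinson's Disease Rating Scale (UPDRS) rates
walking impairment on an ordinal 0–4 scale. Clinician ratings are coarse and
rater-dependent; `gaitscore` provides an instrumented alternative for
movement-analysis researchers and digital-biomarker developers. From raw
100 Hz gyroscope + accelerometer streams recorded at the ankles during a
straight walk it:

1. detects heel-strike and toe-off from the cyclic mediolateral shank
   angular velocity and windows the trial into steady gait cycles (the
   first four accelerating steps are discarded, ten steady cycles kept);
2. reconstructs the per-cycle ankle trajectory by strapdown integration
   with zero-velocity updates (ZUPT) and linear drift compensation, in a
   per-stride progression/vertical/lateral frame;
3. computes twelve gait features (`SL, GD, PSP, MH, RL, RSZ, RSY, RSX,
   MPV, MVV, MSV, MHD`), height-normalizing the spatial ones; and
4. maps the feature vector to a **continuous** severity score with a
   bounded parallel-hyperplane model.

## The model

Four parallel hyperplanes separate the five levels. A subject's signed
distance `xhp = w'x + c` is squashed into the score range by a sigmoid,

    yrd = 5 / (1 + exp(-xhp + 2)) - 0.5            # bounds (-0.5, 4.5)

and a continuous piecewise-linear map sends the demarcation values
`p1 < p2 < p3 < p4` (the `yrd` values at the hyperplanes) to 0.5, 1.5, 2.5
and 3.5, so rounding the final score `y` recovers the ordinal level while
its fractional part ranks severity *within* a level. Training minimizes
the level-balanced absolute error of the continuous score plus a
scale-aware L2 penalty (weight 0.1) and a reciprocal-gap barrier between
hyperplanes (weight 0.005), under the constraints
`p1 >= -0.5`, `p(i+1) > p(i)`, `p4 <= 4.5`, from the deterministic
initialization `w = 0, c = 0, p = (0.5, 1.5, 2.5, 3.5)`. Evaluation is
leave-one-subject-out (LOSO), with paired SVM, Gaussian naive Bayes and
linear-regression baselines, an ANOVA feature screen and a greedy wrapper
search.

## Worked example

No clinical recordings are distributed; the package ships a two-tier
synthetic generator (raw IMU signals with known gait parameters, and
feature tables with a known scoring structure).

```r
library(gaitscore)

## raw-signal tier: a trial with stride 1.20 m, cycle 1.10 s, 40% swing
trial <- generate_imu_trial(signal_gen_spec())
feats <- extract_trial_features(trial$left, height = 1.60)
round(colMeans(feats), 3)
#>      SL      GD     PSP      MH      RL     RSZ     RSY     RSX     MPV
#>   0.750   1.100  40.000   0.155   0.019  47.543   0.000   0.000   3.195
#>     MVV     MSV     MHD
#>   1.215 400.000   0.375
```

The extracted means recover the generator's targets: height-normalized
stride 1.20/1.60 = 0.750, cycle duration 1.100 s, swing 40%, peak swing
angular velocity 400 °/s.

```r
## feature tier: 45 subjects over levels 0-2, then fit and cross-validate
sim <- generate_features(feature_gen_spec(n_per_level = c(15, 15, 15),
                                          noise = 0.25), seed = 1)
fit <- gait_scorer(rated_level ~ F1 + F2 + F3, sim$table)
summary(fit)
#> In-sample: 91.1% exact, 100.0% within one level, mean error 0.089 (n = 45)

loso_cv(rated_level ~ F1 + F2 + F3, sim$table)
#> <loso_cv> model nonlinear: 45 folds, 88.9% exact, 100.0% within one,
#>           mean error 0.111
```

`predict()`, `coef()`, `plot()` (the score transfer curve with the
hyperplanes marked), `residuals()` and `simulate()` work as on any fitted
model object. `evaluate_models()` runs all four models on shared LOSO
folds; `anova_filter()` and `greedy_feature_search()` perform feature
selection. A thin command-line wrapper for extract/fit/evaluate/simulate
lives in `inst/cli/gaitscore.R`.

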