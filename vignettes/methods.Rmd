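---
title: "Recognizing therapy progress from tablet-game telemetry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing therapy progress from tablet-game telemetry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(playprogress)
```

## The problem

Children with autism spectrum disorder attend monthly therapy sessions in
which they play five specially designed tablet games (*Boxes*, *Sharing*,
*Pinwheel*, *Creativity*, *Cat and Dog*). Each session leaves three raw data
streams per game — touch-screen samples, inertial (accelerometer/gyroscope)
samples and game-flow events — plus a 74-item therapist questionnaire over
ten developmental areas. The question the package addresses: can the
*change* in behavioural telemetry between two sessions predict whether the
therapist's evaluation of a given area improved?

The pipeline is: per-game feature extraction → questionnaire scoring and
binary progress labelling → session-difference dataset construction →
classification with repeated stratified cross-validation → feature-relevance
ranking. Because the original cohort was never deposited, the package also
contains a first-class synthetic cohort generator, and the statistical
claims the test suite makes are *recovery properties on simulated data*,
not reproductions of the clinical results.

## Data model

Coordinates are normalized to $[0,1]$ with origin at the top-left; time is
seconds from game start; all rates are per second. Attitude sign
convention (the source material never states one): positive pitch = top
edge lifted (tilt backward), negative pitch = tilt forward; positive roll =
right edge lifted (tilt left). Direction-specific tilt features are only
well-defined once this is fixed; it is applied consistently by the
simulator and the extractors.

Sessions are stored as JSON Lines: a header object, then one object per
touch/motion/event sample with a `stream` discriminator. Numbers are
written with 17 significant digits so a write/read cycle is bit-exact.

## Kinematic operators

* **Path efficiency** — straight-line endpoint distance over traversed
  length; 1 for a perfectly direct drag. Defined as 1 for a zero-length
  path (a stationary touch is maximally direct).
* **Tilt episodes** — maximal contiguous runs where the direction-signed
  roll or pitch exceeds `tilt_threshold` (default 0.175 rad ≈ 10°; the
  source never publishes the threshold, so it lives in
  `extraction_config()` and results must cite the configuration used).
  Episode boundaries are at sample resolution — no sub-sample
  interpolation — which keeps the operator exactly checkable against a
  brute-force per-sample scan. The per-episode "maximum tilt" is the peak
  signed angle within the episode; summary statistics are over per-episode
  peaks (the prose is ambiguous between per-episode and global maxima; the
  per-episode reading yields a distribution, which is what the
  mean/sd/median tuple requires).
* **Oscillation count** — interior strict local extrema after collapsing
  equal-value plateaus; a proxy for unsteady control, invariant under
  monotone transforms of the angle.
* **Sign-change rate** — acceleration sign flips per second; zeros neither
  flip nor reset the last sign, so a resting sensor contributes nothing.
* **Exceedance fraction** — fraction of time $|a|$ exceeds
  `accel_threshold` (default 0.15 g), time-weighted by midpoint interval
  attribution. Absolute value is used because the source speaks of
  "exceeding a threshold" without sign.
* **Reaction-time matching** — greedy: each stimulus takes the earliest
  unconsumed tap within `response_window` (default 2 s) after onset.

## The feature registry

The registry is normative: 29 (Boxes) + 44 (Sharing) + 41 (Pinwheel) + 41
(Creativity) + 27 (Cat and Dog) = **182** named features, each tagged with
its information source (flow / touch / inertial). The published per-game
counts sum to 182 while the accompanying text claims a grand total of 181;
the registry follows the per-game counts and documents the discrepancy
rather than silently dropping a feature.

Choices made where the prose enumeration is not uniquely summable:

* *Sharing*: food moves are counted from the table only; other-object
  moves split into table→plate and plate→plate; drag statistics cover the
  four characters individually (the all-characters aggregate is derivable
  and excluded). 12 flow + 32 drag = 44.
* *Creativity*: drawing-speed statistics include the median (the published
  indicator table cites a "minimum speed of path drawing", implying the
  full five-number family), giving 15 speed features; with 4 flow, 16
  further touch features and 6 inertial features the total is 41.
* *Cat and Dog*: the restrain percentage is one feature; 7 flow + 20
  reaction-time features = 27.
* "Short" Boxes paths: traversed length below `short_path_threshold`
  (default 0.25) of the screen diagonal — the source gives no definition.
* A path is *horizontal* when its x-extent is at least its y-extent
  (Creativity sign-change features); also undefined in the source.

Statistics over empty sets (e.g. reaction times when nothing was answered)
are explicit `NA` markers, never silent zeros; imputation happens
downstream and is fitted on training folds only. Percentages are stored as
fractions in $[0,1]$; dataset-level min-max scaling makes the convention
immaterial.

## Labels

Item ratings on a $k$-point scale are rescaled to $[0,100]$ by
$100(r - r_{\min})/(r_{\max} - r_{\min})$; an area's evaluation is the
unweighted mean of its items; *progress* requires a strict increase
between the two sessions of a pair — a tie is *no progress*. The original
item-level scales are unpublished ("a few point scale"); the default
instrument uses 1–5 for all 74 items, which are distributed over the ten
areas exactly as the listed example elements (14, 8, 9, 2, 6, 9, 5, 6, 5,
10 — these happen to sum to 74).

## Datasets and preprocessing

A sample is the feature-wise difference between two sessions of one child,
in one of two pairing modes: `first_last` (at most one sample per child)
or `consecutive` (one per adjacent pair). Children with fewer than two
usable sessions are excluded. Pairing uses session order, not calendar
dates; absences therefore create unequal gaps, as in the original cohort.

Four preprocessing variants are supported: raw, raw + PCA, normalized
(min-max to $[0,1]$; constant features map to 0), normalized + PCA. PCA
retains the smallest leading component set reaching a cumulative
explained-variance ratio of 0.95 by default (no threshold is published;
the published post-PCA feature counts depend on the real data's variance
and are out of scope). During cross-validation the entire preprocessing
pipeline — imputation medians, normalization bounds, PCA rotation — is
re-fit inside every training fold; the source is silent on this and
fitting per fold is the conservative, leakage-free choice.

## Models and evaluation

Eight classifiers are implemented in the package (the environment provides
no tree or neural-network packages, and the model suite is central enough
to own):

* `decision_tree` — CART with weighted Gini, maxdepth 10, minsplit 5;
* `naive_bayes` — Gaussian class-conditionals (sd floored at $10^{-6}$);
* `bayes_net` — tree-augmented naive Bayes over equal-frequency
  5-bin discretized features, Chow–Liu structure on conditional mutual
  information, Laplace-smoothed CPTs (the source names Bayesian networks
  without structural detail; TAN is the standard strengthening of naive
  Bayes);
* `neural_net` — one hidden layer of 10 logistic units (WEKA-era
  defaults), standardized inputs, cross-entropy with decay $10^{-3}$,
  BFGS with analytic gradients, seeded initialization;
* `bagging_trees` — 25 bootstrap trees; `random_forest` — 50 bootstrap
  trees with a $\sqrt{p}$ random feature subspace per tree (subspace at
  tree rather than split granularity, a documented simplification);
* `adaboost_trees` — discrete AdaBoost with depth-2 weighted trees, 30
  rounds; `rotation_forest` — 10 trees, random feature partitions of
  size 3, per-partition PCA rotation fitted on a 75% bootstrap, majority
  vote.

Hyperparameters are fixed defaults, not tuned: the original work reports
no per-model settings, and a search would not be comparable anyway.

Evaluation is stratified 10-fold cross-validation repeated 10 times.
Accuracy is pooled over folds within a repetition (not averaged over
folds), giving one accuracy per repetition; the 95% confidence interval
halfwidth is $t_{0.975,\,R-1}\, s/\sqrt{R}$ over the $R$ repetition
accuracies — so constant accuracies print as ±0.00. Precision, recall and
F-measure are computed per class from the confusion counts pooled over all
folds and repetitions; 0/0 ratios are reported as NA. All randomness flows
from a master seed: partition seeds are `seed*1000 + r`, per-fold model
seeds `spec_seed + 7919*r + f` (keep the master seed modest so products
stay below $2^{31}$).

## Feature relevance

Per (game, area), every feature's consecutive-session delta is correlated
(Pearson and Spearman with mid-ranks) with the area-score delta, and its
information gain about the progress label is computed over equal-frequency
bins (default 5; duplicated quantiles collapse bins). Indicator ranking
takes the union of the top-$k$ (default 5) features per criterion and
orders by the best criterion rank. The admission threshold used for the
published indicator table is unstated, so the report is parameterized
rather than fixed.

## The synthetic cohort

The generator states a world matching the study design: 40 children aged
37–83 months, 2–7 monthly sessions (at least two sessions are required
downstream, so singleton children are not generated), ten latent skills on
a 0–100 scale evolving as $s_{t+1} = s_t + \text{drift} +
\mathcal N(0, \sigma_\ell)$ with drift 2 points/month and $\sigma_\ell = 3$
— modest but real therapy progress against session-to-session noise.
Therapist item ratings are rounded, clipped linear readouts of the area's
skill plus $\mathcal N(0, 0.4)$ rating points on the 1–5 scale: skill 50
maps to mid-scale exactly, so zero-noise simulations are exactly
reproducible in tests.

Gameplay is driven by behavioural *abilities* in $(0,1)$, logistic in
strength-weighted skill deviations: $(\text{skill}-50)/15$ inside a
logistic keeps controls bounded, monotone and differentiable, and an empty
effect map makes every ability exactly 0.5 — a null cohort whose gameplay
carries no skill signal. The default effect map links fine motor skill to
drag efficiency/speed (Boxes, Sharing, Creativity), instruction following
to rule compliance, attention to distractor susceptibility and
go/no-go accuracy, gross motor skill to tilt control, reaction-to-
stimulation to response latency, social-emotional skill to tap restraint,
and challenging behaviour to device-shake amplitude. Sampling rates
default to 60 Hz touch and 100 Hz motion (the study hardware's rates are
unpublished; these are typical tablet rates and the schema is
rate-agnostic). Game durations other than Sharing's stated five minutes
are unpublished and set once to plausible values (90–300 s).

What the simulator does **not** claim: quantitative realism of autism
motor signatures, realistic effect sizes (the study reports none — the
simulator's strengths are free parameters swept in tests), or calendar
irregularity beyond uniform session counts. A green recovery test
establishes that the pipeline can detect structure of the stated form at
the stated strength — not that the clinical accuracies are reproducible.

## Acceptance properties

Because the real data are unavailable, the headline accuracies are
replaced by properties: (a) *null calibration* — on permuted-label noise
datasets the grand mean CV accuracy over 20 seeds lies within its t-based
95% CI of 0.5; (b) *signal recovery* — with a class-mean separation of
1.5 pooled sd injected into 5 of 12 features at $n = 60$, every ensemble
model's mean 10×10 CV accuracy is at least 0.75; (c) *oracle
equivalence* — tilt detection, oscillation counts, speed statistics,
correlations and PCA match independent brute-force implementations on
1,000 random instances. Registry counts, the scripted perfect-play Boxes
fixture (each of five ball colours placed successfully exactly 4 times)
and the closed-form CI / metric / rescaling checks are exact.

## Numerical and degenerate-input choices

* Constant features normalize to 0; held-out rows clip to $[0,1]$.
* Sample sd of a single value is NA; tilt summary sd over one episode is
  reported as 0 (a degenerate but defined spread).
* Single-class training folds (possible after extreme stratification)
  predict that class rather than erroring mid-CV.
* Equal-frequency binning drops duplicated quantile breaks instead of
  erroring on heavily tied features.
* CART splits at midpoints between distinct sorted values; ties in gain
  keep the first (lowest feature index, lowest cut) for determinism.

## Known limitations

* The CV budget of the ensemble models is the dominant cost; the pure-R
  CART is vectorized over candidate cuts but still slower than compiled
  implementations.
* `random_forest` randomizes the feature subspace per tree, not per
  split.
* The simulator's games are structural analogues, not behavioural clones;
  in particular Cat and Dog's missed-touch channel is rarely exercised by
  the default generator, leaving that feature near-constant in simulated
  cohorts (it is then neutralized by normalization).
* Correlation-based rankings are descriptive; no multiple-testing
  correction is applied, matching the original analysis.
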