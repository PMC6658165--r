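---
title: "Variance risk from reward experience: models, generator and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance risk from reward experience: models, generator and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements: the
task model, the decision-variable construction, the choice models, the
synthetic spiking generator, and the single-neuron and population analyses —
together with the numerical and design choices that were genuinely open, and
what the synthetic benchmarks do and do not establish about real data.

## The task and its objective quantities

`simulateSession()` implements a two-alternative free-choice task with
*baited* rewards. Each of two objects (A, B) carries a block-wise base
probability `P0`; on every trial each unbaited object becomes baited with
probability `P0`, and a bait persists until the object is chosen. Choosing a
baited object delivers a fixed 0.7-ml reward and clears the bait. This
bait-and-persist state machine makes the *instantaneous* reward probability
grow with the number `n` of consecutive unchosen trials,

> P = 1 − (1 − P0)^(n+1),

which `scheduledProbability()` evaluates in closed form; the simulator's
marginal bait availability reproduces it (a Monte-Carlo test in the
acceptance suite). The schedule is what makes reward harvesting follow the
matching law: staying with one object lets the other accumulate reward.

Objective ("true") risk is the variance of the binary reward lottery,
`objectiveRisk(p, m) = p(1−p)m²` — the inverted-U over probability with
maximum `m²/4 = 0.1225 ml²` at `p = 0.5`. A printed form of this definition
that multiplies probability *and* magnitude inside the sum is dimensionally
inconsistent with that maximum; the standard Bernoulli variance, which
reproduces it, is implemented. The task's nominal probability floor is the
minimum base setting 0.05 (at `n = 0`). We make no attempt to reproduce a
risk lower bound below `objectiveRisk(0.05) ≈ 0.0167`, which no variance
reading of the definition yields.

Task parameters and defaults (`taskConfig()`):

* `probSum = 0.6` — the two base probabilities always sum to a constant so
  only relative probability varies; the constant itself is never printed in
  the source material, and 0.6 is the value consistent with the stated base
  range 0.05–0.55 at its endpoints. Configurable.
* `blockLengthRange = c(50, 150)`, drawn uniformly per block; consecutive
  blocks never repeat the same base pair.
* Cue positions are counterbalanced pseudorandomly (shuffled blocks of
  four), so left/right frequencies agree to well under 2%.
* Event times per trial are drawn from the task's stated intervals
  (fixation 1.0–2.0 s to alert; alert 0.7–1.0 s; 1.4–2.0 s to cue onset;
  saccade 0.25–0.75 s; target fixation 1.0–2.0 s). The outcome follows cue
  offset by 0.7–1.2 s, a realistic value chosen once where no interval is
  stated. Eleven fixed 500-ms epochs (`epochTable()`) anchor to these
  events; the pre-fixation epoch is the control period.

## Subjective decision variables

The recency weights are estimated by `fitHistoryWeights()` from a logistic
regression of the object choice on the last `N = 10` reward differences and
choice differences (`buildHistoryMatrix()`); both histories enter to avoid
omitted-variable bias. A reward indicator is 1 only when the object was
chosen *and* rewarded. From a fitted `WeightSet`,

* `objectValue()` computes per-object value as the weighted mean of the last
  ten reward deliveries, optionally plus the weighted choice history, with a
  single denominator `N` over both sums (the printed form; whether the
  original normalized each sum separately is unknowable);
* `subjectiveRisk()` computes per-object risk as the weighted sum of squared
  deviations of the reward indicators from the *unweighted* window mean,
  divided by `N − 1`. Weighted-mean variants exist in the literature but are
  not the default here. Negative fitted weights are used as-is; the rare
  negative risk values they can produce are retained.

Action-domain values and risks are estimated by refitting the history model
on action choices (left/right), not by relabelling object weights. The first
`N` trials of a session are burn-in and carry `NA` in every history-derived
column; all fits exclude them.

Degenerate inputs: history columns with zero variance are dropped with a
warning (weight 0); perfect separation or non-convergence of the logistic
fit triggers a ridge-penalized IRLS refit (`lambda = 0.01` on the
non-intercept terms), flagged in the diagnostics.

## Choice models and model comparison

`fitChoiceModel()` fits the side choice on the left–right value difference
and risk difference plus a side-bias intercept; a positive risk coefficient
is risk seeking. The minimal-value-difference control refits on the lowest
decile of `|ΔValue|` (the "10% of trials" subset is interpreted as the
lowest decile). `compareChoiceModels()` fits eleven models out-of-sample:
history weights come from the first half of the session, all models are
evaluated on the second half, and AIC/BIC are normalized to per-trial mean
deviance (values of order 2). The three reinforcement-learning variants
(`fitRLModel()`, likelihood in C++) are: standard Rescorla–Wagner updating
the chosen option; a *stack* variant in which the unchosen option's value
additionally accumulates toward the reward ceiling at a fitted rate,
capturing baited-reward persistence; and a *reversal* variant updating the
unchosen option toward the opposite outcome. No equations are printed for
the two modified variants; these forms are the package's reconstruction of
"choice-dependency" and "updating chosen and unchosen option".

### Generator calibration

The default generative agent (`logisticAgent()`) chooses by the same
value/risk logistic model, computing value and risk online from fixed
exponentially decaying weights (`1.5·e^(−j/2)` reward, `0.8·e^(−j/2)`
choice). Two sensitivities were calibrated once, against the source
behavior, and are not free parameters of the tests:

* `betaValue = 20`, so that simulated sessions reproduce the near-unity
  log-log matching slope the task elicits (lower sensitivities produce
  severe undermatching, slope ≈ 0.25 at `betaValue = 5`);
* `betaRisk = 6`, so that the fitted risk coefficient carries the
  statistical strength reported for the behavioral risk effect (z ≈ 3 at
  ten thousand trials). Under a matching-calibrated agent the value and risk
  regressors share R² ≈ 0.85, so a small generative risk weight would be
  statistically invisible at realistic session lengths — an identifiability
  property of the task, worth knowing when interpreting fitted risk
  coefficients on real sessions.

Parameter-recovery benchmarks are run conditional on the generative
weighting function (the true weights are supplied to
`decisionVariables()`). The full pipeline — weights re-estimated from the
simulated choices — recovers the weight *shape* up to the scale coupling
between the history fit and the choice model, so end-to-end checks assert
sign and significance rather than equality.

## The synthetic spiking generator

`makePopulation()` + `simulateSpikes()` produce Poisson neurons whose
per-epoch rate is `baseline × drift + Σ gain · z(variable)`, floored at
zero, counts Poisson over the 500-ms epoch. Design choices:

* Regressors are z-scored inside the rate model so gains (impulses/s per z
  unit) are comparable across variables; tuning signs are drawn ±1 per
  neuron by default, reflecting that risk is encoded with positive and
  negative slopes.
* Tuning can be restricted to named epochs or to an explicit event-anchored
  window (for latency designs); an `evoked` term adds a task-evoked rate
  bump in the tuned epochs so that tuned neurons are also *task-related* in
  the screening sense (real neurons are phasically active; purely tonic
  synthetic neurons would never pass a control-period contrast).
* Optional slow drift is a multiplicative AR(1) on the log baseline,
  for exercising the non-stationarity controls.
* With `spikeTimes = TRUE`, a piecewise-homogeneous Poisson stream is
  generated over the whole trial and epoch counts are re-binned from that
  stream, so counts and spike times are mutually consistent.

What the generator does *not* emulate: cross-neuron noise correlations (the
decoding deliberately ignores them, as a pseudo-population analysis must),
bursting or refractory spike statistics, eye-movement artifacts, and
reaction-time structure. Passing benchmarks therefore establish that the
analysis chain recovers known ground truth under Poisson variability — not
that real recordings satisfy the analyses' assumptions.

## Single-neuron battery

`taskRelatedness()` screens each (neuron, epoch) response against the
pre-fixation control by paired two-sided Wilcoxon test at `p < 0.005`,
Bonferroni-corrected over the ten non-control epochs; the control period
itself is always admitted. On count data this test is slightly conservative
(discrete ties), which the calibration suite makes visible.

`fitResponseRegression()` is OLS on trial-by-trial impulse rates with
two-sided t tests per coefficient (`p < 0.05`), standardized slopes
(`b·s_x/s_y`, an exact identity tested to machine precision), per-regressor
partial R² (`(SSE_reduced − SSE_full)/SSE_reduced`) and the overall F test.
Model ids `eq3`/`eq10`/`eq11`/`eq12`/`eq13`/`eq14`/`eq15`/`utility` select
the regressor sets (objective, subjective, history-augmented, two-back,
subjective-vs-objective competition, action-domain, object-vs-action
competition, and utility-substituted). Rank-deficient designs flag aliased
coefficients rather than silently dropping them.

`angleClassification()` fits the reduced two-risk-regressor model, requires
a significant overall F, and classifies by the polar angle of the two
coefficients into eight 45° segments (object-A risk toward 0°/180°, object-B
toward 90°/270°, risk sum 45°/225°, risk difference 135°/315°). Segments are
half-open `[centre − 22.5°, centre + 22.5°)`, so a boundary angle of 22.5°
belongs to the 45° segment — an explicit tie rule where the source is
silent. A zero coefficient vector is unclassifiable.

`stepwiseRegression()` uses forward entry at `p ≤ 0.05` and backward removal
at `p ≥ 0.10` from an empty model (thresholds unstated in the source; these
are the conventional defaults). `partialFTest()` tests a single added
regressor; `zTestDependentProportions()` is the McNemar-style normal
approximation for proportions measured on the same units.
`nonstationarityControls()` re-runs a model with a previous-trial-rate
autoregressive term and, separately, on control-period-subtracted responses.

`populationValueCurve()` z-scores activity against the control period,
sign-corrects by each neuron's slope on a reference variable, and averages
in equal-population bins (rank-based, stable under the heavy ties of the
value distributions). Risk-tuned populations are single-peaked over *reward
probability* — the inverted-U — while they are monotone over the subjective
value scale itself, because weighted value and weighted risk are strongly
positively correlated in the sampled regime (per-object reward rates rarely
exceed one half, so only the rising limb of risk-versus-reward-rate is
sampled). `riskUpdatingAnalysis()` contrasts cue-period activity on trial N
against N−1 after rewarded trials, split by the sign of the risk change.

## Sliding-window analysis and its calibration

`slidingWindowRegression()` counts spikes in 200-ms windows stepped by
25 ms along one alignment stream (default: fixation onset, −500 to
+1000 ms, so every window lies inside the guaranteed 1.0-s fixation span),
and solves the OLS for all windows jointly against the fixed design. A
variable is *coded* when more than six consecutive windows are individually
significant at `p < 0.05`.

The familywise rate of that run criterion is governed by the overlap
correlation of adjacent windows (7/8 for 200/25) and the number of windows
in the stream: an independent Gaussian-process oracle puts it at ≈ 5.9% for
73 windows and ≈ 4.25% for 53. `slidingShuffleCalibration()` measures it
directly on trial-shuffled data; on fully untuned populations with the
default 53-window stream it is ≈ 4.3%, below the 5% benchmark. Two
properties are worth knowing: the criterion's false-positive rate grows
with stream length (a criterion of six is only calibrated for streams of
this order), and trial-shuffling does *not* remove trial-level rate
variance in tuned neurons, which lengthens significance runs — on shuffled
*tuned* data the rate is nearer 5.5%. `codingLatency()` reads latencies as
the start of the first qualifying run; `jointCodingStats()` tests pairwise
coding co-occurrence against independence (chi-squared, exact fallback when
expected cells fall below 5) and regresses signed coefficients across
jointly coding neurons.

## Decoding

`buildPseudoPopulation()` splits trials into low vs high terciles of a
grouping variable (rank-based, stable under ties; a median split is
available and behaves similarly), z-scores counts against the control
period, and enforces a minimum of eight trials per group per neuron.
`decodePopulation()` classifies with a linear maximum-margin classifier
(cost 1, unscaled) or a single nearest neighbour, averaged over random
within-group trial matchings that permute each neuron's trials
independently — the pseudo-population construction for non-simultaneous
recordings. Cross-validation is leave-one-*pair*-out (one trial per group
per fold): plain leave-one-out with balanced groups biases the shuffle null
below 50% because the held-out trial's own class is in the training
minority, and the balanced variant removes that bias, centring the null on
chance. Groups are balanced by down-sampling, capped per group for
tractability.

`decodeShuffleNull()` permutes group labels; `decodingCurves()` maps
accuracy over population size; `subsetControlDecoding()` implements the
subset-sensitivity regression (accuracy of small random subsets on their
mean absolute risk coefficient), cross-decoding (e.g. object-risk neurons
decoding action risk), and decoding within trial subsets holding a control
variable constant. Because subjective object risk and action risk share
reward history, they are correlated at the trial level, so an object-risk
population decodes action risk somewhat *above* chance; the separation
property is that its action-risk excess stays well below its object-risk
excess — "little information", not none.

## Benchmark problem sizes

The test suite exercises: Monte-Carlo schedule emergence at 1.2×10⁵ trials;
behavioral parameter recovery at 10⁴ trials; model-family recovery on 20
replicates of 5×10³ trials; neuronal power and calibration on populations
of 80 tuned plus 600 untuned responses at 500 trials; shuffle calibration
on 100 neurons × 300 trials × 40 shuffles; and decoding on populations up
to 40 neurons with reduced matching iterations (6–10) and 200 label
shuffles. These sizes are the package's chosen benchmark conditions; the
functions themselves accept arbitrary sizes.

## Known limitations

* Session-level (not hierarchical) fitting; pooling across sessions is the
  caller's responsibility.
* The weighted value and risk constructions are strongly collinear in this
  task; risk coefficients from the choice model carry wide confidence
  intervals at realistic session lengths, and the package reports the
  shared-variance diagnostic alongside the fit.
* The run-length criterion of the sliding-window analysis is calibrated
  for ~50-window streams; users changing `range`, `width` or `step` should
  re-run `slidingShuffleCalibration()` before interpreting coded fractions.
* RL variant equations for the stack and reversal models are
  reconstructions; alternative parameterizations of "choice dependency"
  exist and would alter Table-style comparisons in detail, though not the
  family-level contrast tested here.
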