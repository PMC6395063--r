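---
title: "Belief entropy in a restless bandit: model, readouts, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Belief entropy in a restless bandit: model, readouts, and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
ideal-observer model and its assumptions, the behavioural segmentation, the
multivoxel and pupillometric readouts, what the synthetic generators emulate
(and deliberately do not), the numerical and design choices made where the
design was genuinely open, and the known limitations of what passing tests
demonstrate.

## The task and the ideal observer

The environment is a restless four-armed bandit: eight options exist, four
are selectable in a given run (each option is available in exactly two of the
four runs, which is what later allows cross-run decoding folds that cover all
eight options). One available option pays reward with probability 0.7 or 0.9;
the other three pay with probability 0.2. The identity of the high option
moves to one of the other three available options after a number of trials
drawn as `round(Normal(20, 5))`, truncated below at one trial, independently
of behaviour; the high payout rate is re-drawn uniformly from {0.7, 0.9} at
every switch. Runs are 200 trials; cohorts default to 19 subjects with four
runs each (800 trials per subject).

The observer maintains a joint posterior over four hypotheses `H`
(which available option is high) crossed with a payout-rate grid
`p = 0.30, 0.31, ..., 1.00` (71 values; the lower bound keeps the
hypothesized high rate above the fixed low rate of 0.2). The likelihood of an
outcome is read from the payout matrix `M[h, L, p]`, equal to `p` when the
chosen option `L` matches `h` and 0.2 otherwise. After each outcome the grid
is multiplied by the likelihood and renormalized; between trials it is mixed
with the uniform distribution with weight `s`:

```
prior_t = (1 - s) * posterior_{t-1} + s * uniform
```

with `s = 1/20`, the true mean switch frequency. Two readings of this
transition were possible — a leak over the full 4 x 71 grid, or over the four
hypotheses only — and the package uses the full-grid reading ("a uniform leak
over the parameter space"); at the uniform payout margins the two differ only
in how the rate dimension forgets. No leak is applied before a run's first
trial (the prior is uniform there anyway). All reported per-trial quantities
(marginals, entropy, relative uncertainty, expected values) are computed from
the posterior *after* that trial's outcome — the belief state at the point of
feedback — while choice policies act on the post-leak prior *entering* the
trial, since a choice cannot depend on the not-yet-seen outcome.

Entropy is reported in nats by default (base-2 available via
`observer_config(log_base = 2)`); the uniform belief gives `log(4) = 1.386`.
Relative uncertainty has no canonical closed form in this setting; the
package defines it as `1 - max_i p(H_i)` (the mass off the modal hypothesis),
a monotone companion to entropy, and exposes the definition as a replaceable
function (`ru_fun`) because it is an assumption, not a derived quantity.

Two hand-checkable anchors, frozen into the tests: starting uniform, a
rewarded choice yields marginals (0.52, 0.16, 0.16, 0.16) with entropy
1.21968 nats; an unrewarded one yields (0.1273, 0.2909, 0.2909, 0.2909). The
uniform belief assigns every option the expected value
`0.25 * 0.65 + 0.75 * 0.2 = 0.3125`.

## Behavioural segmentation and choice policies

An exploitation block starts at the first trial on which the agent selects
the current true high option *and* is rewarded, and ends at the last trial
before the choice switches; every other trial is exploration. The end rule is
purely choice-based: if the environment switches mid-block while the agent
keeps choosing the old option, those trials remain exploitation. *Core*
exploitation trials lie at least `k = 5` trials after the previous choice
switch and at least 5 before the next (run boundaries count as switches);
under this "at least five" reading a 10-trial block retains exactly one core
trial. The trial-wise analyses are restricted to this subset so that belief
dynamics are dissociated from changes in overt action.

Choice policies are softmax on the option beliefs,
`P(choose i) ∝ exp(beta * p(H_i))`, fitted by maximum likelihood separately
for explore and exploit trials with `beta` bounded to [0, 100]; estimates at
the bound are flagged non-identified (perfectly greedy data have an unbounded
likelihood). Ties in the policy's modal option break toward the lowest option
id. The simulated agent uses the same form with two temperatures; since an
online agent has no phase labels, it uses the exploit temperature when the
modal prior belief points at its previous choice and the explore temperature
otherwise — a deliberately simple proxy documented here because the phase
labels are only defined post hoc.

The switch analysis asks, on exploit trials with reward omission, whether
higher uncertainty makes the next-trial switch to exploration more likely:
a per-subject logistic regression of "next trial switches" on entropy (or
relative uncertainty), with the per-subject slopes tested against zero.
Complete separation falls back to a ridge-penalized fit; subjects with no
omission trials or constant outcomes are excluded with a warning.

## Multivoxel readout: representation strength

The decoder input stands in for per-trial beta maps: a trials x voxels
matrix per region. The pipeline mirrors the standard construction:

1. **Cross-run pairing.** The four runs are split into two pairs such that
   each pair covers all eight options; the model is trained on one pair and
   tested on the other, both ways, so each trial is tested exactly once.
2. **Dimensionality reduction.** PCA on the voxel-voxel covariance across
   *all* trials (training and test together), keeping the top 20 components;
   trial loadings are least-squares projections. Because the PCA sees test
   trials, `shuffle_bias_check()` is provided as the guard: it shuffles voxel
   identities within every trial and reruns the entire pipeline, and an
   unbiased pipeline yields a null statistic distribution symmetric about
   zero.
3. **Class balancing.** The training set is oversampled by deterministic
   cycling until all eight classes match the maximum count — no resampling
   randomness, so results are reproducible given the classifier seed.
4. **Classification.** An 8-way multinomial logistic regression (all eight
   options, even though only four are available per run; accuracy chance is
   therefore 1/8). The regularization is a weak L2 penalty (nnet weight
   decay, default 1) chosen for convergence on oversampled data — a
   documented knob, since no canonical value exists. Optimizer start values
   are seeded, making probabilities bit-reproducible.
5. **Representation strength.** For each test trial,
   `RS = log[ odds(chosen) / odds(unchosen) ]`, where the unchosen odds use
   the *mean* probability of the available-but-unchosen options (the sum is
   available behind `aggregate = "sum"`); probabilities are clipped to
   `[1e-6, 1 - 1e-6]` so RS is always finite. With uniform probabilities
   RS = 0; with `p_chosen = 0.5` and the rest spread over seven options,
   RS = log 13.

`searchlight_map()` runs the full pipeline in a sphere around every in-mask
voxel (default radius 7 voxels; desk-scale tests use radius 2 on small
volumes and may subsample centers via the `centers` argument); spheres never
include out-of-mask voxels. `residualize_voxelwise()` replaces each voxel's
trial series by OLS residuals against nuisance regressors (trial value,
recent reward history) for the control analyses.

## Pupil preprocessing

Blinks are interior gaps of missing samples, filled linearly between the
nearest valid samples on each side; edge gaps are never extrapolated, and
trials whose entire baseline window is lost are flagged and removed. Each
run is normalized independently as percent change from its mean over
retained samples. The per-trial baseline is the mean of the half-open window
`[feedback - 20 ms, feedback)` — 20 samples at 1000 Hz, 2 at the synthetic
default of 100 Hz (chosen for test speed; 1000 Hz is available). The first
25 trials of each run are excluded (start-of-run luminance transients), as
are lost trials and, when requested, non-core-exploit trials.

## What the synthetic generators emulate

The generators plant exactly the statistical structure the analyses assume,
so that every downstream stage is testable by effect recovery:

* **State-coding region** (`state_mixture`): each trial's pattern is a
  belief-weighted mixture of fixed random option prototypes
  (`gain * sum_i p(H_i) * proto_i + noise`); decoding the chosen option is
  easy when the belief is concentrated, so representation strength falls
  with entropy. Prototypes are standard normal and deliberately not
  orthogonalized (realistic overlap); a flag orthogonalizes them for
  worst-case tests.
* **Action-coding region** (`action_code`): the pattern is the chosen
  option's prototype plus an optional bleed toward the adjacent option on
  the id ring (emulating somatotopic confusions); beliefs never enter, so
  the entropy regression is null by construction.
* **Pupil traces**: each unrewarded trial emits a latent arousal pulse with
  iid lognormal gain; pulses accumulate into a tonic level with slow decay
  (0.9/trial) that sets the next trial's baseline (plus independent
  trial-level and sample-level noise, and blink gaps). The same latent level,
  through a smooth saturating map, flattens the state-region mixture weights
  on the next trial — the planted causal chain by which pupil *change*
  negatively predicts representation-strength *change*, specifically on
  unrewarded trials (rewarded trials emit no pulse) and specifically at lag
  0.
* **Univariate signal**: `b * dENT_t + noise` with
  `dENT_t = ENT_t - ENT_{t-1}`, the activity of a region tracking entropy
  increase.

Two generator choices deserve emphasis because they were made to keep the
planted effect identifiable, and they bound what passing tests show:

* Pulse amplitudes are, by default, *omission-gated but not entropy-scaled*
  (`pulse_entropy_weight = 0`). Scaling amplitudes by the trial's entropy
  increment ties the pupil to the observer's own mean-reverting entropy
  dynamics, which smears the planted lag-0 coupling into the adjacent lags
  and into the rewarded split through belief re-sharpening — a genuine
  confound of the differenced-series design, not an artifact of the code.
  The scaling is available as a knob for studying exactly that confound.
* Effect sizes (pupil gain 40 units/pulse against baseline noise SD 20,
  flattening gain 0.35, voxel noise SD 1.2 at 200 voxels) were fixed once so
  that a 19-subject cohort recovers the planted couplings with conventional
  significance while the null splits stay null; they are study conditions,
  not fitted quantities.

What the generators do **not** emulate: hemodynamics (patterns are per-trial
beta-map stand-ins; no HRF convolution or scanner timing), physiological
noise, drift, motion, spatial autocorrelation beyond the planted prototypes,
gaze position, or luminance effects on the pupil. Passing recovery tests
therefore shows the *analysis chain* is correct and calibrated — not that
these effects would be detectable in any particular real dataset.

## Regression suite and group inference

`build_design()` implements the trial-wise recipes (GLM1–GLM8 analogs):
phase indicators; entropy/reward/transition regressors; entropy (GLM4) or
belief-in-chosen-option (GLM5) against representation strength on
core-exploit trials; pupil-change plus entropy-change against
representation-strength change, split by reward (GLM6); entropy change
against univariate activity (GLM7); and regional signal + entropy change +
whole-brain mean against pupil change (GLM8). Delta series follow the
current-to-next convention `dx(t) = x_{t+1} - x_t` for the coupling analyses
and current-minus-previous for the entropy-change regressors, matching each
recipe's wording. When runs are concatenated, one bias column per run is
used. Designs are checked for full rank, with collinear columns named.

Group inference is the summary-statistics approach: per-subject OLS
coefficients tested against zero with a one-sample t-test. This deliberately
replaces mixed-effects group estimation — a simplification appropriate for
synthetic cohorts with exchangeable subjects. The cluster-mass permutation
correction thresholds the group t map voxelwise at one-tailed p = 0.001,
forms 6-connected clusters, scores them by the sum of t values, and compares
against the maximum-cluster-mass null from random subject sign flips;
positive and negative directions are corrected separately. The median-split
contrast assigns median-valued trials to the lower half.

`sample_size_t()` searches the smallest integer per-group n at which an
independent two-sample t-test reaches the target power, using the exact
noncentral-t power function. The two-sample family is used because it is the
family under which the printed anchor values (17 at d = 0.89, 6 at d = 1.58,
5 at d = 1.77; 80% power, alpha = 0.05 one-tailed) are all reproduced
exactly; note that d = 0.94 gives 15 under this computation.

## Numerical choices, degenerate inputs, problem sizes

* Belief normalization is enforced by renormalization at every update; drift
  over 800 sequential trials stays below 1e-12.
* Probability clipping at 1e-6 before odds; PCA rank tolerance 1e-10 of the
  top eigenvalue; `k` capped at the covariance rank.
* Entropy uses the `0 * log 0 = 0` convention.
* Empty trial lists give empty series; traces that never recover a valid
  sample flag every trial lost; an all-identical pupil-change vector is an
  error for the median split; fewer than two subjects is an error for any
  group test; zero between-subject variance is flagged.
* Option ids are 0-based (0–7), runs and trial indices 0-based; hypothesis
  positions 1–4 are the rank of the chosen option within the sorted
  available set of its run.
* All randomness flows from integer seeds; per-subject and per-stage
  substreams derive deterministically from the master seed, and the global
  RNG state is always restored.

The validation suite runs at deliberately chosen sizes: the double
dissociation on five 19-subject cohorts of 800 trials and 200-voxel regions;
the coupling analyses on the canonical 19-subject cohort; type-I calibration
of the coupling test on 500 zero-coupling cohorts (fresh structureless
representation series against a fixed cohort's pupil data); the bias check
at 200 voxel-shuffle permutations on a 40-voxel region; family-wise error of
the cluster correction on 200 pure-noise 12-cubed cohorts at 60 sign-flip
permutations each; searchlight recovery on 10-cubed volumes at radius 2 with
lattice-subsampled centers. These sizes make the suite complete in minutes
on one CPU while keeping every assertion a property of the method rather
than of a particular seed.

## Known limitations

* The residual coupling between the pupil's tonic decay and the observer's
  belief re-sharpening leaves a small negative tendency in the
  rewarded-split regression (typically |t| < 2 at n = 19). It is a property
  of differencing two series that share one latent input, and the reason the
  generator's default pulse amplitude is not entropy-scaled.
* The leak interpretation (full-grid versus hypotheses-only) and the
  relative-uncertainty formula are assumptions; both are isolated behind
  configuration so alternatives can be swapped in.
* The two-temperature simulated agent is a convenience policy; it produces
  realistic exploit shares (~70–80%) but is not a fitted model of any
  participant population.
* Pattern stores and exports are plain tab-separated text; volumes map to
  arrays indexed by integer coordinates rather than any neuroimaging file
  geometry.
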