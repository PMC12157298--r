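---
title: "Dynamic sitting: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic sitting: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynsit)
```

`dynsit` implements the software side of a posture-monitoring smart garment:
four textile capacitive strain sensors on the wearer's back produce a
4-channel signal sampled at 2 Hz, a classifier maps each sample to one of
seven posture classes, and a feedback engine converts the per-second
classification stream into haptic reminders that promote *dynamic sitting* —
frequent changes of seated position rather than any single "correct" posture.
This vignette documents the models, the tunable parameters, and the design
decisions taken where the underlying system description left the choice open.

## The synthetic signal model

No public recording of the garment's raw capacitance exists, so the package
ships a generator (`sim_config()`, `generate_dataset()`) that reproduces the
*statistical structure* of the acquisition study rather than its physics.
A frame from participant $p$ holding acquired posture type $a$ is

$$ c_{pa} = s_p \, \mu_a + \varepsilon, \qquad
   s_p \sim \mathcal N(1, \sigma_s^2), \quad
   \varepsilon \sim \mathcal N(0, \sigma_n^2 I_4), $$

where $\mu_a \in \mathbb R^4$ is a fixed per-type channel baseline,
$s_p$ is one multiplicative amplitude factor per participant (taller or
heavier wearers stretch the garment more, scaling all channels together —
the simplest model that min–max normalization removes exactly), and
$\varepsilon$ is i.i.d. additive sensor noise.

The baseline table `default_class_means()` is **synthetic**: its values are
constraint-driven, not measured. The constraints are that channel C1 has the
strictly largest between-class spread (it sits at the centre of the dorsal
width line, where skin deformation differs most across postures); that every
class pair is at least 4 noise SDs apart on some channel *except* (a) the
left/right leg-crossed pair, whose baselines differ by at most `crossed_gap`
(default 0.5 pF) on every channel — below the noise floor, which is exactly
why the two sub-variants are merged into one `leg_crossed` class — and
(b) the catch-all `other` posture, kept only 2 noise SDs from its nearest
neighbour because a grab-bag of miscellaneous postures cannot be far from
everything.

Defaults, chosen once: 20 participants, 2 Hz, 30 s per posture type
(hence 60 frames per type, 480 per participant, 9600 in total),
$\sigma_n = 1$ pF, $\sigma_s = 0.05$ (±5 % amplitude between wearers,
a plausible garment-fit spread), baselines spanning 30–90 pF. Participant
$i$ uses sub-seed `seed + i`, so sessions are independent but the dataset is
reproducible from one integer. Standing is assumed to follow the same 30 s
protocol as the sitting postures.

What the generator deliberately does **not** emulate: capacitance physics,
garment slippage, signal drift within a 30 s hold, Bluetooth dropouts, or
heavy-tailed artifacts. Passing tests on this data therefore demonstrate
protocol arithmetic, pipeline correctness and engine timing — not
field-grade classification difficulty (see *Limitations*).

## Preprocessing

`validate_samples()` drops frames with non-finite channels or values outside
per-channel plausibility bounds. What counts as "invalid" is configuration:
the default bounds are the simulator's physical range widened by 50 % in
value on each side (`[0.5 min, 1.5 max]` per channel), generous enough that
only genuine artifacts are removed.

`minmax_normalize()` rescales each channel to $[0,1]$ with extrema fitted on
the **training partition only** and applied unchanged elsewhere — fitting on
the full dataset would leak test information into the scaler. Held-out
values outside the training range are *not* clipped, preserving affine
invertibility; a constant channel maps to 0. Normalization granularity was
an open choice: the stated motive (removing individual amplitude
differences) argues for per-participant scaling, while the described
processing order (normalize, then split) argues for one global scaler. Both
are implemented — `normalize_per_participant()` removes the multiplicative
factor $s_p$ exactly, as the test suite verifies at zero noise — and the
global scaler is the default because it requires no per-wearer calibration
at deployment.

`split_dataset()` makes a stratified, seeded 80/20 split (each class within
one sample of the target fraction).

## The classifier benchmark

`compare_models()` reproduces the four-family comparison protocol:
k-nearest neighbours, RBF-kernel SVM, a single decision tree, and a random
forest, each tuned by exhaustive grid search (5-fold CV on the training
split, ties broken to the first point in lexicographic parameter order),
evaluated on the held-out 20 %, and then re-assessed by stratified 10-fold
cross-validation on the full dataset. The selection rule is: highest CV mean
accuracy, ties broken by the smallest CV standard deviation (accuracy first,
stability second). The reported SD is the population SD over the 10 fold
accuracies.

Since only the winning hyperparameters of the original study are published,
the default grids (`default_specs()`) bracket them with standard
alternatives (`k ∈ {1,3,5,7}`, `C ∈ {0.1,1,10}`, `gamma ∈ {0.01,0.1,1}`,
`max_depth ∈ {5,10,20,∞}`); `reference_specs()` pins each family to its
published optimum. The forest's tree count is unpublished; the default is
100 with a fixed seed. Folds are stratified even though the original
protocol does not say so: unstratified folds can starve a 7-class problem.
Two library-mapping notes: the forest expresses a depth limit through a leaf
cap (`maxnodes = 2^depth`, unrestricted once `2^depth ≥ n`), and
`min_samples_split` has no equivalent in the forest backend (its published
value, 2, is the unrestricted default anyway). kNN vote ties are broken
from a fixed internal RNG stream so predictions are a pure function of
their inputs.

## The reminder engine

The engine consumes one posture code per second. Sitting postures are graded
into three hazard tiers, each with its own reminder interval: leg crossed is
*serious* (5 min), back bent / forward / backward / other are *medium*
(10 min), upright is *low* (15 min). Standing belongs to no tier.

For each tier the engine keeps a **trailing window** of the tier's length.
Once a full window of records exists since the tier's last reset, the tier
fires a posture-change reminder if any single posture of the tier accounts
for *strictly more than* 70 % of the window's ticks; firing clears the
tier's records, so the countdown restarts. Counting is per posture within
the tier, not pooled across the tier's postures. Three semantic choices were
genuinely open:

* *Trailing vs tumbling windows.* The description supports both readings;
  trailing-with-reset-after-fire reproduces every documented first-fire time
  (300 s, 600 s, 900 s on constant streams) and cannot re-fire every second,
  so it is the implemented semantics.
* *Scope of the 70 % rule.* The threshold is stated for the 5-min
  leg-crossed case; it is generalized to all tiers as one configurable
  constant (`trigger_fraction`), because its stated purpose — buffering
  classifier noise and brief fidgeting — applies identically everywhere.
* *Strictness.* "More than 70 %" is implemented as a strict comparison;
  `recover_trigger_threshold()` bisects constructed windows on the
  fire/no-fire boundary and recovers 0.70 as the infimum, an executable
  check that the configured constant actually governs behaviour.

Independently, a sitting run of any non-stance labels reaching 45 min
(2700 s) fires a *sedentary* reminder telling the wearer to stand; one
stance tick resets the run, and the timer restarts after firing, so the
reminder repeats every 45 min of continued sitting (repetition policy was
unspecified; repeating is the health-purposeful reading). At most one
posture-change event is emitted per tick, the serious tier checked first.

Vibration constants come from a user comfort study: posture-change
reminders vibrate at 800 Hz for 3 s; the sedentary reminder keeps 800 Hz
(its frequency is not documented; reusing the comfortable one is the
conservative default) but lasts 7 s so the two cues are distinguishable.

The incremental ring-buffer engine is checked, in the test suite, against an
independent brute-force replay that recomputes every window count from
prefix sums over the raw sequence; the two must emit identical event lists
on randomized 2 h streams.

## Session reports and the intervention comparison

`summarize_session()` reproduces the companion interface's daily aggregates:
total sitting seconds (non-stance ticks), reminder counts by kind, and the
number of posture changes. "A change" is not well defined at 1 s
granularity, so runs shorter than a debounce window (default 3 s, matching
the vibration duration) are discarded before counting transitions —
otherwise classifier jitter would dominate the count. `persist_history()` /
`load_history()` keep an append-only JSON-lines history; corrupt lines are
skipped with a warning rather than poisoning the store.

`compare_phases()` is the before/after intervention test: a paired-sample
two-sided t-test on per-subject counts, computed closed-form on the
differences `before − after` (so more posture changes *with* feedback gives
a negative t, matching the original sign convention) and cross-checked
against `stats::t.test` to 1e-9 in the tests. Zero-variance differences are
flagged degenerate instead of producing a p-value.

## Numerical choices and problem sizes

Bisection in `recover_trigger_threshold()` builds windows with
`ceiling(f · w)` target ticks, which places the fire/no-fire infimum exactly
at the configured fraction; tolerance 1e-4. Stream time is integer seconds
starting at 1 (frame time is real-valued starting at 0); gapped or repeated
timestamps are rejected rather than repaired. The test suite runs the full
default dataset (9600 samples) for the benchmark checks, 2 h streams for
100 randomized engine-vs-oracle replays, and smaller constructed fixtures
everywhere else.

## Limitations

* The signal model is intentionally minimal. On data this clean all four
  classifier families land near ceiling (the package's own benchmark run
  puts every family above 97 %), so the *ordering* among the top families is
  decided by fold noise, and the clear real-data advantage of the random
  forest over the RBF-SVM does not reproduce here. The benchmark
  demonstrates the protocol; it does not re-establish the published ranking,
  whose dataset is unavailable.
* A single multiplicative amplitude factor is a first-order account of
  inter-wearer variation; real garment fit also shifts channels additively
  and drifts over a session.
* The engine trusts its input clock; it is a state machine over an ideal
  1 Hz stream, with transport loss out of scope.
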