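---
title: "Models and methods for carbohydrate and bolus recommendation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for carbohydrate and bolus recommendation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bolusrec)
```

## The recommendation problem

A person with type 1 diabetes asks, at time *t*: "how much should I eat (or
bolus) 10 minutes from now so that my blood glucose reaches a target value τ
minutes after that?" `bolusrec` learns this mapping retrospectively from
pump/CGM records: every historical meal or bolus whose outcome was observed
becomes a supervised example whose *label* is the event magnitude (grams of
carbohydrate or units of insulin) and whose *features* are the 6-hour history
of glucose/carb/insulin data before the event, the glucose value actually
reached at `t + 10 + τ` (standing in for the user's target), the horizon τ,
and a time-of-day consumption average. Models are scored by RMSE and MAE, in
physical units, against the magnitudes actually recorded.

The 10-minute offset between action time and the present encodes the clinical
instruction to bolus 10 minutes before eating, and the horizon grid
τ ∈ {30, 35, …, 90} min covers the window in which fast-acting insulin is
most active; beyond ~90 min too many unlogged factors intervene for the
label to remain attributable to the queried event.

Two example classes are built. *Inertial* examples have no meal or bolus in
the prediction window `(t, t+10+τ]` other than the queried event (plus, for
bolus-given-carbs, its paired meal at `t + 20`) — this matches how a
recommender would actually be used. *Unrestricted* examples allow other
events, trading realism for a larger sample. Inertial examples are by
construction a subset of unrestricted ones, and the admissibility filters
(below) apply to both.

## Pre-processing

**Meal anchoring.** Self-reported smartphone meal timestamps are unreliable
relative to the pump clock, often preceding the very bolus that covered the
meal. Each bolus with a positive bolus-wizard carbohydrate entry therefore
claims, in chronological order, the nearest unclaimed smartphone meal within
±60 minutes, moves it to exactly `bolus + 10` minutes, and replaces its
carbohydrates with the bolus-wizard grams (which the subject entered with the
pump in hand, and which are the more trustworthy estimate). Distance ties
break toward the meal whose logged carbs are closest to the bolus-wizard
entry, then toward the earlier meal — both tie-breaks are our deterministic
resolution of cases the anchoring rule leaves open. If no meal is within the
window, the subject is assumed to have forgotten to log it and a meal is
created from the bolus-wizard entry. Each smartphone meal can be claimed at
most once (chronological first-claim), correction boluses (no carb entry)
claim nothing, and a meal already sitting at `bolus + 10` with matching carbs
is left untouched, which makes the operation idempotent. The original
timestamp and carb estimate of a shifted meal are kept as provenance columns
but are not used by any model.

**Gap interpolation and admissibility.** CGM gaps are filled linearly on the
5-minute grid, interior to the measured range only, and flagged. An example
anchored at *t* with horizon τ is discarded when the glucose at the target
time or at *t* is itself interpolated, when more than 2 samples in the hour
before *t* are interpolated, or when more than 12 samples in the 6 hours
before *t* are. We count over half-open windows `(t-60, t]` and
`(t-360, t]`: "prior to *t*" is ambiguous about the endpoint, and including
*t* merely double-covers the separate present-time filter. The filter is
monotone: adding interpolation can only remove examples.

**Scaling.** All channels (glucose, carbs, bolus, basal, labels) are mapped
to `[0, 1]` by per-subject min–max scalers fitted on the training split only.
Values outside the training range scale linearly outside `[0, 1]` — no
clipping — so an unusually large test meal remains distinguishable from the
largest training meal. A constant channel is an error rather than a silent
divide-by-zero. Predictions are unscaled before scoring. The extra features
are scaled consistently: the glucose target with the glucose scaler, the
time-of-day average with the label scaler, planned carbs with the carb
channel scaler, and τ mapped linearly from `[30, 90]` to `[0, 1]`.

## Event binning and time conventions

Event streams are binned to the 5-minute CGM grid by rounding each timestamp
to the nearest grid point, ties rounding down; amounts falling in one bin are
summed and basal insulin enters as rate × 5/60 per bin, so channel totals are
conserved exactly. Rounding (rather than flooring) keeps the 10-minute
meal/bolus offsets exact multiples of the grid. Internally time is integer
minutes from the subject's record start; the wall-clock start is kept
separately and only used to derive the five time-of-day windows
(12am–6am, 6am–10am, 10am–2pm, 2pm–6pm, 6pm–12am, left-closed), which drive
both the time-of-day baseline and the μ feature.

## The two architectures

**LSTM chain.** Encoder 1 (state size 32) consumes the 72-step history of
(glucose, carbs, bolus, basal). The history length is a resolved ambiguity:
"the previous 6 h up to and including the present" can be read as 72 or 73
steps; we fix 72 steps covering `(t-355, t]` inclusive. Basal delivery is
included as a fourth per-step channel — whether "insulin dosages" includes
basal is unstated, and a separate channel lets the model use or ignore it.
Encoder 2 consumes only (carbs, bolus, basal) over the prediction window: the
glucose channel is omitted there rather than zero-filled, because glucose is
unobservable in the future and a zero would assert a measurement. Its initial
hidden state is a learned linear projection of encoder 1's final hidden
state (the cell state starts at zero). Encoder 2 runs for inertial examples
too, over all-zero event channels: a single architecture serves both classes,
and the unroll length itself encodes τ. The concatenation
`[s1, s2, G_target, τ, μ_ToD, (C_planned)]` feeds 2–5 hidden ReLU layers of
width 64 and one linear output. Dropout (inverted, rate per scenario) is
applied after each hidden fully connected layer only — placement elsewhere is
unstated and recurrent dropout would complicate the gradient derivation for
no demonstrated benefit. The queried event itself is masked out of the window
channels (and the `t+20` meal of bolus-given-carbs is carried only as the
planned-carbs feature), so no example contains its own label.

**Residual stack.** Up to 5 chain blocks are stacked. Block *b* receives the
glucose history minus the accumulated backcasts of blocks 1..b−1; event
channels and extra features pass to every block unchanged. Each block's head
is one *joint* linear layer of width 73 emitting `[backcast(72), forecast(1)]`;
the estimate is the sum of forecasts. Exact telescoping
(Σ backcasts + final residual = input) holds by construction and is asserted
to 1e-6 in the tests. With one block the stack reduces exactly to the chain
with a joint head.

**Training loss.** In scaled units,

    L = MSE(estimate, label)
      + (α/B) Σ_b MSE(forecast_1 + … + forecast_b, label)
      + (β/B) Σ_b MSE(backcast_b, glucose input of block b)

with α = β = 1 by default and B the number of blocks. The per-block terms add
supervision; their exact form (cumulative-forecast target, backcast toward
the block's own input, 1/B weights) is our resolution of a design left open,
exposed through `alpha`/`beta` in the configuration — setting both to zero
recovers the plain MSE, which is also the whole loss for the plain chain.
Gradients of every parameter are derived by hand (reverse-mode through the
head, both encoders, the projection, and the backcast-subtraction chain —
gradients reach a block both through its backcast and through the
auxiliary-loss targets of later blocks) and verified against central finite
differences to 1e-4 relative error on small configurations.

**No weight sharing.** Blocks always have independent parameters. A
parameter-count the original work reports suggests sharing may have been used
there, but that count is explicitly non-binding, and independent blocks keep
the optimizer's flat-parameter view simple; `count_parameters()` reports the
exact count for any configuration.

**Default hyper-parameters** follow the tuned per-scenario settings: LSTM
models use 2–3 FC layers with dropout 0–0.5; residual models 3–5 blocks, 2–5
FC layers, dropout 0.2–0.5; state 32 and width 64 everywhere except the
carbs-without-bolus scenario, whose much smaller example population halves
both (16/32) while inheriting the other settings from the all-carbs scenario.

## Training protocol

Subjects are split chronologically: last 10 days test, previous 10 days
validation, remainder (≈30 days and required to be nonempty) training.
Examples are built on the full continuous record and assigned to splits by
their event time. Optimisation uses Adam with a fixed learning rate of 0.001
and mini-batches of 64 grouped by horizon (so one batch's prediction windows
share a length; batch order and within-group assignment are reshuffled each
epoch). Early stopping halts training exactly 10 epochs after the last strict
improvement of validation MSE and restores the best-epoch weights. A generic
model is pretrained on all subjects' pooled (per-subject-scaled) training
examples, then fine-tuned per subject. Ten seeds (defaults 1–10) yield a
`mean` score (average over seeds, then subjects) and a `best` score (per
subject, the seed with the lowest *validation* MAE — the selection function
takes only validation metrics, so test data cannot leak into it). Model
comparisons use a one-tailed two-sample t-test, Welch's variant by default
since equal variances are not defensible across models; the pooled-variance
variant is exposed. The per-horizon transfer experiment contrasts, for
τ ∈ {30, 45, 60, 75, 90}, a model trained on all horizons with one trained
only on that horizon, both scored on that horizon's test examples; horizons
with too few examples are reported as missing rather than silently dropped.

## The synthetic benchmark

The simulator emulates the *structure* of pump/CGM study data, not human
physiology. Glucose is an equilibrium-reverting AR(1) noise process (default
equilibrium 120 mg/dL, stationary sd 5 mg/dL) plus superimposed linear event
responses: a meal of C grams contributes `C × 3.5 mg/dL` spread over a
triangular kernel peaking 45 min after the meal with 180 min support; a bolus
of D units subtracts `D × ISF` over a triangular kernel peaking at 75 min
with 300 min support. Kernels are normalised to sum to one over their
support, so the total excursion area equals amount × potency, and the model
is linear in event magnitudes — which yields the closed-form oracle
`dose = (no-action BG − target) / (ISF × g_i(τ))` (and the carb analogue),
verified by forward simulation to 1e-6 mg/dL. Carb ratios and insulin
sensitivities vary over the five time-of-day windows and across subjects, so
the time-of-day baseline is a meaningful competitor.

Three meals a day (with jittered times and carb amounts), bedtime snacks and
hypo-correction snacks (both un-bolused, guaranteeing a carbs-without-bolus
population), and stand-alone correction boluses (populating the all-boluses
scenario with inertial examples) are generated. The simulated bolus wizard
doses `carbs/CR + max(0, BG − target)/ISF`; about a fifth of its
recommendations are overridden by a factor U(0.8, 1.2), 5% of boluses are
dual (excluded as labels), the smartphone log jitters meal timestamps by
U(−30, +20) min, perturbs carb estimates by ~10%, and omits 15% of meals
entirely, and CGM gaps of 15–120 min occur on ~30% of days. These defaults
are fixed as the package's study conditions; they were chosen once to mirror
the logging pathologies described for the real cohort.

What the simulator does *not* capture: insulin-on-board interactions,
nonlinear and state-dependent glucose dynamics, exercise, stress, sensor
drift, or realistic hypoglycemia excursions. Passing tests on this benchmark
therefore demonstrate that the pipeline, models and protocol are implemented
correctly and that the architectures can learn a recoverable dose–response
structure under realistic logging noise — not that they reach any particular
accuracy on real patients.

## Problem sizes and numerical choices

The test suite and the acceptance script run desk-scale configurations chosen
as the package's reference conditions: benchmarks of 2–3 subjects × 30 days
(≈1000 inertial bolus-given-carbs examples per split-set), reduced models
(state 16, width 32, 2 blocks) and ≈10-epoch budgets for protocol-level
checks, and tiny configurations (state 4–8, 12-step histories) for algebraic
and gradient checks. Gradient agreement is asserted at 1e-4 relative error,
stack algebra at 1e-6, conservation at 1e-9, and the oracle round-trip at
1e-6 mg/dL. Weight matrices initialise as N(0, 1/fan-in) with zero biases
except the LSTM forget gates, which start at 1 so early training retains
memory. Degenerate inputs fail loudly: empty glucose streams, constant scaler
channels, spans too short to split, records built on un-anchored meals
(unless the raw-data ablation is requested explicitly), and infeasible oracle
targets all raise errors naming the cause.

## Known limitations

Training is single-threaded R; at the paper-scale configuration (12 subjects,
8 weeks, 10 seeds, 500-epoch cap) a full run is hours, not minutes — the
protocol functions accept reduced budgets and the defaults in the scripts use
them. The XML writer is event-at-a-time and slow for multi-month records (the
CSV dialect is the fast path). Bolus timestamps are trusted as recorded;
only meal timestamps are corrected. No clinical safety logic of any kind is
included: recommendations are retrospective model outputs for research use.
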