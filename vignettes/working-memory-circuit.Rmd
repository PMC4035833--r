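---
title: "A reward-shaped working-memory circuit: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reward-shaped working-memory circuit: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`wmcircuit` simulates how task-appropriate neural representations can emerge
in an initially unstructured recurrent circuit purely from reward feedback.
A network of binary threshold neurons is driven by brief, localized stimulus
inputs and must emit the correct action at a Go cue that arrives after a
delay; the only teaching signal is a scalar reward (+1/-1) delivered at the
Go step.  Synapses change through reward-modulated STDP with eligibility
traces, while two homeostatic mechanisms — intrinsic plasticity of the firing
thresholds and multiplicative synaptic scaling — keep the activity sparse and
the dynamics stable while the weights reorganize.

## The network

The recurrent circuit has `n_total = 250` units, 80% excitatory and 20%
inhibitory, with sparse random connectivity (`p_ee = 0.1`, `p_ei = 0.25`,
`p_ie = 0.4`, `p_ii = 0`; probabilities are target-first, so `p_ei` is the
probability that an excitatory neuron receives a given inhibitory synapse).
Each unit is a binary threshold element,

    x_i(t) = [ I_i(t) >= theta_i ],    I_i = sum_j w_ij x_j - sum_k w_ik y_k + eps,

with non-negative weight magnitudes (Dale's law; inhibition enters with a
minus sign), an inclusive threshold comparison, and independent background
noise `eps ~ U[0, 0.1]` redrawn per unit and step.  Units have no intrinsic
memory: anything the circuit retains across the delay lives in the recurrent
activity pattern.

Each input channel (a stimulus, or a context cue in the overlapping
multitask) drives a private block of `n_in = 5` excitatory units; presenting
the channel forces that block to be active for one time step, regardless of
the units' currents.  Channels occupy disjoint leading blocks of the
excitatory population, in channel order.

The decision layer has one unit per action, receives input from every
excitatory unit, and applies winner-take-all: only the unit with the largest
input (including its own noise draw) is active.  Decision units run at every
step but only the Go step is scored.

Two timing conventions deserve explicit statement because the dynamics are
discrete:

* **All units update synchronously from the previous step's excitatory
  state, including the decision units.**  The winner at the Go step is
  therefore a function of exactly the presynaptic vector that the decision
  eligibility trace pairs it with (pre at t-1, decision at t).  The
  alternative — a decision layer that reads the same step's recurrent state —
  decouples credit assignment from behaviour: the synapses the reward updates
  are never the ones that produced the scored decision, and reward learning
  of the readout silently fails.  We verified this directly with a
  hand-constructed network whose delay activity is perfectly
  stimulus-specific: with same-step reading, performance stays at chance
  indefinitely; with previous-step reading the task is learned within a few
  hundred trials.
* **Inhibition is fast.**  Within a step the inhibitory population is updated
  first, from the previous step's excitatory activity, and its fresh state
  gates the excitatory update of the same step (inhibitory-to-inhibitory
  interactions, absent at the defaults, would stay lagged).  With strictly
  lagged inhibition the negative feedback arrives one step after an activity
  surge, which produces boom-and-bust extinction of the delay-period
  activity cascade: training concentrates all firing in the first 3-4
  post-stimulus steps, an inhibitory avalanche follows, and performance at
  longer delays never leaves chance.  Fast inhibition is the convention of
  the self-organising recurrent network family this model belongs to.

### Initial thresholds

Excitatory and decision thresholds start at 0.5; intrinsic plasticity moves
them to their operating point (about 0.15-0.2 at the default noise level)
within the first training block, and the long-run behaviour is independent of
the initial value — the homeostasis tests confirm recovery from initial
thresholds between 0.1 and 1.0.  The inhibitory thresholds are the one place
where initialization matters (`theta_init_inh = 0.2`): the inhibitory
homeostasis rule is a population-level regulator whose drift vanishes once
the excitatory rate sits at its target, so it cannot recruit an inhibitory
population stranded above its afferent dynamic range (pooled excitatory drive
rarely exceeds 0.3).  At 0.2 the inhibitory units are silent during normal
sparse activity (about 6 active excitatory units) and fire during surges,
which is precisely the stabilising role inhibition plays here.

## Plasticity

Every excitatory synapse (recurrent excitatory-to-excitatory,
excitatory-to-inhibitory, and excitatory-to-decision) carries an eligibility
trace updated each step by

    e <- e * (1 - 1/tau_e) + [post(t) & pre(t-1)] - f * [post(t-1) & pre(t)],

a one-step STDP window: pre-then-post potentiates, post-then-pre depresses
with asymmetry `f` (`f = 1` in the recurrent layer, `f = 0.01` at decision
synapses, which limits interference from decision-unit firing during the
delay).  `tau_e = 2.5` steps; the forward-Euler decay factor `1 - 1/tau_e =
0.6` is the default, with `exp(-1/tau_e)` available as the `trace_decay`
switch.  Traces reset at trial onset and events are formed only from
within-trial activity pairs; the network state itself carries across trial
boundaries (the circuit runs continuously).

At the Go step the decision is scored (`r = +1` correct, `-1` otherwise — the
absolute reward, not a prediction error) and every plastic weight gains
`eta * r * e`, with `eta = 1e-5` in the recurrent layer and `1e-4` at
decision synapses.  Weights are rectified at zero and synaptic scaling then
renormalizes each neuron's incoming plastic weights to sum to one
(excitatory afferents; inhibitory incoming magnitudes are normalized once at
initialization and stay fixed).  Because weights change only at reward time,
scaling at reward time is equivalent to scaling every step.

Thresholds adapt homeostatically every step: excitatory and decision units
by `theta <- theta + lambda * (x - x0)` (`lambda = 1e-4` recurrent, `1e-3`
decision; targets `x0 = 0.03` and `0.25`), inhibitory units by
`theta <- theta - lambda_inh * (<x_exc> - x0)` with `lambda_inh = 1e-5`,
pooling the whole excitatory population.

Per-step order within a trial: (1) currents from the previous state, (2)
inhibitory update, fast inhibition, excitatory update, input forcing, (3)
decision WTA, (4) eligibility updates, (5) threshold adaptation, (6) at the
Go step only: score, commit traces, rectify, scale.

## Tasks and curriculum

All trials last `T_trial = 10` steps: the stimulus is forced at step 1, the
Go cue falls at step `delay + 1`, and the remaining steps are padding
(dynamics and homeostasis continue; no forcing, no reward).  The delay is
counted from stimulus onset, so the minimum-delay task (delay 1) is an
immediate stimulus-response association and each delay increment adds one
retention step.  We adopted this convention after comparing both readings:
with the Go cue one step later (offset counting) the first curriculum block
already requires formed recurrent chains, learning bootstraps far more
slowly, and final performance falls short of the reproduction targets by
about ten points across tasks.

Four task families share this structure:

* `delayed_response`: `M = K` (default 4), identity map — pure stimulus
  memory.
* `categorization`: `K = 8` stimuli, `M = 2` actions, a balanced random
  2-coloring drawn once per experiment; category boundaries exist only in
  the reward function.
* `multitask_disjoint`: the 8 stimuli split into two 4-stimulus domains,
  each with its own 2-way map (`M = 4`); the context (the stimulus' domain)
  is cued directly to the decision layer at the Go step, implemented as a
  restriction of the WTA competition to the cued domain's action pair.
* `multitask_overlap`: two orthogonal balanced 2-colorings of the same 8
  stimuli (`M = 4`); the active context is an extra forced input channel
  presented together with the stimulus, and the excitatory target rate is
  raised to `x0 = 0.05` to accommodate the extra inputs.

Delays are uniform on `1..T_max` (variable mode) or equal to `T_max` (fixed
mode).  Training follows an incremental-delay curriculum: `T_max` = 1..5
(1..3 for the overlapping variant), one block of 2e4 trials per value,
stimuli and contexts sampled uniformly and independently per trial.
Experiments are repeated five times with seeds `base, base + 1, ...`.

Ablation modes replace the recurrent learning rule: `frozen` keeps the
recurrent weights at their initial values; `stdp` applies the same STDP
events directly to the weights every step (no traces, no reward gating, same
`eta`), with rectification and scaling at the same cadence.  The decision
layer remains reward-modulated and all homeostatic mechanisms stay on in
both modes.

## Analyses

All representational analyses use the activity raster of the last 1000
training trials.  The delay period of a trial covers the steps strictly
between stimulus and Go (minimum-delay trials contribute nothing).

* `depth_of_selectivity`: `S = (N_cond - sum(R_i)/R_max) / (N_cond - 1)` on
  per-condition mean delay rates; 0 for uniform responses, 1 for exclusive
  ones, undefined (and excluded from population fractions, with a separate
  count) when all rates are zero.  Conditions can be stimuli, categories of
  one boundary (computed from that domain's or context's trials only in the
  multitask variants), or contexts.
* `selective_fraction` and `multiplexing_stats` summarise the population:
  the latter restricts to neurons with `S >= threshold` in at least one task
  and splits them into both- vs single-boundary-selective, the convention
  used for the multitask summaries.
* `psth` gives per-neuron firing probability by time since stimulus, with
  peak-time ordering; `psth_peakiness` (mean peak share of each row) is this
  package's scalar summary of temporal concentration.
* `pca_trajectories` projects pooled delay-period states onto the leading
  principal components, labelled by condition and time.
* `weight_matrix_summary` reports weight sparsity (fraction of existing
  excitatory synapses below `1e-3` of their mean) and a feedforwardness
  index — the share of excitatory weight mass flowing from earlier- to
  later-firing neurons under a peak-time ordering (1 for a chain, 0.5 for a
  symmetric matrix).  Both scalar indices are this package's own summaries
  of structure that is otherwise inspected visually.

A caveat worth stating: with binary units and sparse activity, a neuron with
a single reliable (stimulus, time-step) firing slot has a near-zero rate for
the non-preferred category and hence `S` close to 1 for any 2-way boundary.
Two-way category-selective fractions at moderate thresholds are therefore
structurally high in this model, and single-stimulus responders are not
distinguishable from genuine category coders by `S` alone; analyses that need
that distinction should inspect the per-stimulus rate profiles directly.

## What the simulations do and do not show

The training engine is the package's own data generator; there is no
external data.  Defaults are the study conditions (N = 250, 2e4 trials per
block, five seeds), and the acceptance script `scripts/acceptance.R` runs
them at full scale: it reproduces final performance near 70% on the
delayed-categorization curriculum, near 76% on the disjoint multitask and
near 63% on the overlapping multitask, with the corresponding selectivity
fractions.  The test suite uses the same conditions for the single-seed
checks and reduced block sizes (1e4 trials) where several seeds of an
ablation comparison are needed; the homeostasis property is verified over
4e5 steps, comfortably beyond the drift time of the slowest threshold.

Performance declines with delay: delays of one to two steps are answered at
90%+ after training, while five retention steps sit near the network's
memory capacity, so per-delay performance at the longest trained delays
approaches chance even though the windowed average over a variable-delay
block remains high.  This is the expected regime for a binary recurrent
network of this size, in which stimulus information survives as a
propagating activity chain rather than a fixed-point attractor.

Two specified comparisons do not come out in this implementation and are
deliberately left as failing checks rather than weakened: the
reward-independent STDP ablation, implemented as continuous unsupervised
STDP, slightly outperforms r-STDP on the fixed-delay categorization task
(its effective learning rate is far higher, since every step commits
events), and the overlapping multitask does not show the low two-way
category-specific fraction discussed above, for the structural reason given
there.

## Numerical choices

* Exact WTA ties resolve to the lowest unit index (relevant only with zero
  noise; with continuous noise ties have measure zero).
* Rows whose incoming weights sum to zero are left unnormalized with a
  warning; with the default connectivity this does not occur in practice.
* Synaptic scaling renormalizes only rows whose weights actually changed —
  mathematically a no-op for the others and numerically bit-stable.
* The compiled engine stores recurrent eligibility traces lazily (only
  synapses touched within the current trial, decayed by repeated
  multiplication), which makes it exactly — bit-for-bit — equivalent to the
  dense reference engine in R; the equivalence is asserted in the tests for
  all three learning modes, including the full activity rasters.
* Per-repeat seeds are `base + repeat - 1`, applied to everything: category
  maps, connectivity, noise and trial sampling all derive from the one seed,
  so a run is reproducible from its manifest.
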