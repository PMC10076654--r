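---
title: "A dual-learning columnar cortex with a basal-ganglia recommendation readout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dual-learning columnar cortex with a basal-ganglia recommendation readout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rasim)
```

## The model

`rasim` simulates a categorical learning system built from two coupled
learners with sharply separated roles:

* a **columnar spiking cortex** whose synapses change only through
  *temporal-correlation* rules — potentiation of inputs that repeatedly
  precede a neuron's firing, depression of inputs that fail to contribute,
  and homeostatic down-scaling of over-active neurons. No error or reward
  signal ever reaches these synapses.
* a **basal-ganglia readout** holding one non-negative *recommendation
  weight* per (column, category) pair. Only this layer receives
  *consequence feedback*: either a teacher signal naming the correct
  category, or a bare correct/incorrect bit.

The task is 30-way categorisation of stimuli that are never repeated
exactly: each category is a fixed 400-component *propensity profile*, and
every presentation re-draws each timeslot's spikes through an integer
chance draw, so two instances of a category are only ever statistically
alike.

### Stimuli

A category profile assigns each of the 400 inputs an integer propensity in
0..200, drawn uniformly from a *level pool* in which small levels are
repeated up to five times (linearly decaying multiplicity), biasing inputs
toward sparse firing. A presentation lasts a notional 200 ms divided into
600 timeslots of 1/3 ms. A 40 Hz gamma envelope modulates the input: each
8-slot gamma period carries a high-factor half (`f_hi = 50`) and a
low-factor half (`f_lo = 5`). The spike probability of input $i$ at slot
$t$ is

$$P(\text{spike}) = \frac{\mathrm{clamp}(\lceil p_i f_t \rceil - 1,\; 0,\; 10^4)}{10^4},$$

the probability that the product of propensity $p_i$ and modulation factor
$f_t$ exceeds an integer drawn uniformly from 1..10,000. With
`f_hi * 200 = 10,000` the strongest input reaches probability 1 on the
high half-period and stays near zero elsewhere.

Working memory is modelled by time-division: each presentation interleaves
*three* categories round-robin across its 75 gamma periods (25 periods
each), and the readout decides each of the three segments separately.

### Cortex

Each column has 10 layer-1 neurons (10 dendritic branches of 120 synapses
each, ~1,200 synapses per neuron, sources drawn from the 400 inputs), 10
layer-2 neurons and one layer-3 neuron, wired within the column. A branch
fires when its potential (sum of weights of its spiking sources) reaches
`theta_branch`; a neuron fires when at least `theta_neuron` branches fire.
Signals cross one layer per timeslot.

Three plasticity rules run at the end of every 200 ms window:

1. **Potentiation with reversal.** A synapse that carried an input at, or
   one slot before, its neuron's firing gains a tentative increment. The
   increment becomes permanent (`+d_pot`, capped at `w_max`) only if this
   pairing occurred at least `pair_min = 3` times within the window;
   otherwise the weight returns to its window-start value exactly.
2. **Contribution-miss depression.** A synapse whose branch fired at least
   `m_miss` times without that synapse carrying an input loses `d_dep`,
   floored at zero.
3. **Homeostatic scaling.** A neuron that fired more than `rho_max` times
   in the window has all its weights multiplied by `s_homeo < 1`, ratios
   preserved.

Weights are constant *within* a window; all changes apply at the window
boundary. This makes the reversal rule exactly net-zero and lets the
compiled engine defer its bookkeeping to per-window bitmask counts.

### Hippocampal connectivity bias

Before the cortex is wired, a small unprocessed sample of presentations
(default 30, covering all categories) is pooled into a 400x400
co-occurrence count matrix; greedy size-capped average-linkage
agglomeration on the cosine-normalised counts yields one input group per
column. Each layer-1 synapse then draws its source from the column's group
with probability `p_bias` (default 0.7) and uniformly otherwise. This is
the model's only hippocampal function.

### Basal ganglia

For one segment with per-column layer-3 spike counts $n$, the total
recommendation for category $c$ is $\sum_k n_k W_{kc}$; categories are
ranked by total (ties to the lowest index), so 2nd and 3rd choices are
always available. Under the teacher signal the weights toward the correct
category grow by `alpha_up * n` (saturating at `w_cap`); if the top choice
was wrong, the chosen category's weights on active columns shrink by the
proportion `delta_down`. Under correct/incorrect-only feedback an
incorrect choice shrinks the chosen category's active weights by
`delta_feedback`, and a correct choice changes nothing (the optional
`correct_boost` is off by default).

## The two experiments

**Experiment one (novelty learning).** 1,200 triple presentations in a
fixed, never-changing category order: 300 cortex-only, 600 with teacher
feedback, 300 test presentations in which decisions are recorded without
weight updates. Cortical plasticity never pauses, including during the
test.

**Experiment two (interference and recovery).** A 300-presentation
cortex-only warm-up on the first category set, 600 teacher presentations
of categories 1-15, 600 of categories 16-30, then a 300-presentation
all-category test (`after_split`). A recovery pass of 300 presentations
with correct/incorrect-only feedback is followed by a retest
(`after_feedback`), and a 30-presentation teacher relearn pass by a final
retest (`after_relearn`). The set-balance ratio (set-A accuracy over
set-B accuracy) tracks how evenly knowledge is retained.

## Parameters that matter, and the frozen defaults

The published description of this architecture leaves every numeric
constant of the cortex and readout open; the package's defaults were
calibrated once against the headline accuracies of the novelty run and the
split-training run and then frozen. The calibration taught us which
constants carry the physics:

* `theta_branch[1]` (default 40) sits about one standard deviation *below*
  the mean high-slot branch drive, so that **every column is initially
  active**. Columns that start silent can never recover (a silent neuron
  makes no pairings, so potentiation cannot lift it), and runs with a high
  layer-1 threshold degenerate into a handful of over-loaded "hub" columns
  that carry all categories at once.
* `rho_max` (defaults 90/60/10 per layer) is the selectivity dial:
  homeostasis repeatedly scales down whichever neurons fire most, so each
  column ends up responding strongly only to its preferred categories.
  The small layer-3 ceiling keeps per-segment counts low enough that
  their trial-to-trial noise is material — accuracy then grows with the
  number of columns, which is exactly the behaviour the architecture
  claims.
* `d_pot`/`d_dep` (default 1/16) set both the speed of receptive-field
  formation and the speed of *drift*: fields keep reorganising slowly
  throughout a run, which is why a readout trained long ago degrades
  relative to a freshly trained one.
* `delta_down` (teacher punishment) defaults to 0.0015, deliberately two
  orders of magnitude below the feedback-pass proportion. The
  split-training experiment is acutely sensitive to it: every punishment
  of an earlier-learned category during later learning acts on the shared
  (common-mode) part of the count signatures and uniformly demotes the
  whole earlier set, so with `delta_down` of even a few percent the first
  set's top-1 accuracy collapses toward zero — catastrophic rather than
  partial interference. At the per-mille default the punishment still
  calibrates over-claiming categories during interleaved training while
  leaving earlier learning largely intact.
* `delta_feedback` (default 0.375) is deliberately much larger: the
  correct/incorrect-only pass works *only* by demoting over-claiming
  categories, and needs a strong proportion to redistribute
  recommendation strength within 10 instances per category.
* `alpha_up` (default 0.02) is nearly a gauge parameter: rankings are
  invariant to the overall scale of the weights, so it matters only
  through its interaction with `w0` and the multiplicative punishments.

## What the generator emulates — and what it does not

The synthetic stimuli reproduce the statistical structure of the task:
category-specific propensity profiles, the decaying level pool, the exact
integer chance draw, gamma modulation and working-memory interleaving, and
the guarantee that no two instances are identical. They do not model
anything about natural sensory statistics — inputs are conditionally
independent Bernoulli draws given the category, with no spatial or
temporal correlations beyond the gamma envelope. Passing the accuracy
bands here therefore shows that the architecture can learn and retain
never-identical *statistical* categories; it says nothing about natural
images or sounds.

## Numerical choices

* All weight arithmetic uses dyadic-rational constants (1/16, 7/8, ...),
  so that small-instance tests can assert bit-for-bit equality between
  the compiled window engine and the per-synapse reference engine:
  branch-potential sums of short dyadic significands are exact in
  floating point and independent of summation order.
* Branch and neuron thresholds use `>=` comparisons; ranking ties break
  to the lowest category index; both choices make runs reproducible to
  the bit under a fixed seed.
* A layer-3 fire at slot $t$ is attributed to the working-memory segment
  of slot $t - 2$, the input slot it derives from through the two
  interlayer delays.
* The co-occurrence clustering relaxes its group-size cap by one when no
  mergeable pair remains, guaranteeing exactly `n_columns` groups; inputs
  that never spiked in the bias sample join the smallest groups.
* One master seed derives independent child streams for profiles, the
  bias sample, wiring and presentation draws, so a cortex run can be
  replayed against different basal-ganglia settings.

## Problem sizes used by the tests and the acceptance script

Full-scale runs (1,200-2,730 presentations of 600 x 400 spikes) take a few
minutes each on one CPU. The test suite exercises the full model on
reduced problem sizes — micro-cortices for the plasticity arithmetic and
engine-equivalence checks, 4-6 category curricula for the orchestration
tests, and reduced-seed replicates for the accuracy bands. The acceptance
script runs the experiments at full scale and reports medians over
replicate seeds, allocated by run cost: five seeds for the 15-column
novelty run, three for the split-training run, two for each 20-column
condition. These sizes are the package's own choice of a practical
default and can be raised freely.

## Known limitations

* The relative accuracy bands of the two experiments constrain, but do
  not uniquely determine, the free constants; other calibrations likely
  exist.
* The split-training experiment's correct/incorrect recovery stage is
  sensitive to the balance between the feedback proportion and the
  residual interference; its absolute level is the least pinned-down
  number the package reproduces.
* Indirect activation (imagination/recall driven by internal rather than
  sensory input) is outside the scope of this simulation, as are action
  sequences and any neuromodulatory influences.
* Timeslots are a notional 1/3 ms; no biophysical membrane dynamics,
  conduction delays beyond one slot per layer, or inhibitory interneurons
  are modelled.
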