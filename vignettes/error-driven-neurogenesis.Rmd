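---
title: "Error-driven neurogenesis: model, design choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-driven neurogenesis: model, design choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edn)
```

## The model

`edn` implements a one-shot, online learner built from kernel-memory
neurons. The network has a single hidden layer that starts empty and grows
in response to errors; nothing stored is ever modified, so previously
acquired knowledge cannot be overwritten (there is no catastrophic
forgetting by construction).

Every synapse carries a triangle kernel. An afferent synapse stores a
center $v$ (the value one input had when the neuron was created) and
responds to a new input $x$ with

$$k(x) = \max\!\left(0,\; 1 - \frac{|v - x|}{s}\right),$$

where the spread $s$ is a single half-width shared by the whole network.
A neuron's activation is the *mean* of its afferent synapse activations —
a 0–1 similarity between the current input and the stored pattern,
averaged over whichever inputs the neuron chose to watch. Each neuron
reaches the outputs through an efferent synapse with the same kernel and a
fixed center of 1, so any neuron whose activation is at or below $1-s$
contributes exactly zero: outputs only hear from neurons that closely
match their stored pattern. The output value is the weighted sum of these
thresholded contributions, with signed weights set once, at creation time,
from the error the network was making at that moment.

Learning is the same loop in every paradigm: run the forward pass, measure
an error, and if the error exceeds the error threshold $E_{th}$, store the
current input on a new neuron whose output weights encode the correction.
One presentation suffices — re-presenting a stored sample activates its
neuron fully and reproduces the stored association.

## Task-specific wiring

**Classification.** The error vector is the one-hot label minus the
softmax of the outputs; it always sums to zero. Only outputs whose error
magnitude exceeds $E_{th}$ receive a connection, with the signed error as
the weight. When all outputs are exactly zero (nothing in memory resembles
the input) the network *abstains* rather than guessing; abstention is a
real model state, returned as `NA` and rendered as the unclassified region
in decision grids.

**Input selection.** A new neuron need not watch every input. Surprise
selection maintains, per class, a running mean of previously stored input
values; the expectation for the current sample is the softmax-weighted
combination of class means, and only inputs whose actual value deviates
from that expectation by more than the surprise threshold $s_{th}$ are
stored (inputs with no recorded expectation are stored by default). This
shifts the representation from input–output mappings to feature–output
mappings and substantially reduces synapse counts at matched accuracy.
A random-subset selector is provided as a cheaper alternative.

**Regression.** A continuous target is coded by two non-negative output
magnitudes, real $r$ and inverse $i$; the decoded position on the task
scale is $r/(r+i)$, which is invariant to overall activity level —
activity becomes confidence, not value. A stored sample splits its error
magnitude $E$ into weights $w_r = E\,p$ and $w_i = E(1-p)$, where $p$ is
the target's position on the scale, so $w_r + w_i = E$ and the ratio
recovers $p$ exactly. Raw outputs are clamped below at zero before
decoding; an abstaining prediction (both outputs zero) is scored against
the scale midpoint so that early empty-network steps still generate enough
error to trigger growth. The error used for weighting is the absolute
error on the normalized 0–1 scale by default; a squared variant is
available behind `error_type = "squared"`, but absolute keeps
$w_r + w_i = E$ interpretable as a confidence and avoids collapsing
small-error weights.

**Reinforcement learning.** Actions are taken greedily on the outputs,
with a uniformly random action when all outputs are equal (including the
empty network). There are no labels, so errors are simulated at failures:
the last $m$ timesteps before a failure are inhibited, the most recent
with weight $-1$, fading linearly by $1/m$ per step of age. Each neuron
also accumulates a low-pass-filtered reward
$R \leftarrow \tau R + (1-\tau)\, r\, a_n$ at every timestep
($\tau = 0.9999$, $r = 1$ while the pole is balanced), and when a size cap
is configured the lowest-reward neuron is deleted whenever the cap is
exceeded. New neurons start at the current network-mean reward so they get
time to prove themselves before pruning can take them.

## Parameters that matter

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `spread` ($s$) | kernel half-width, dimensionless on normalized inputs | 0.4 (0.6 for cart-pole) | small = overfit to stored points, large = over-generalize; $s > 1$ makes every synapse respond to every input |
| `error_threshold` ($E_{th}$) | minimum error magnitude for growth and for output connections | 0.1 (0 for regression) | 0 stores one neuron per sample; large values stop growth entirely |
| `surprise_threshold` ($s_{th}$) | minimum expectation mismatch for an input to be stored | 0.05 (0.4 for glyph images) | higher values store fewer synapses per neuron until the representation fragments |
| `memory` ($m$) | failure window length in RL | 10 | each failure creates up to $m$ neurons |
| `max_size` | neuron cap with reward pruning | none | RL only; moderate caps also speed convergence |
| `tau` ($\tau$) | reward low-pass constant | 0.9999 | effective averaging horizon of $10^4$ timesteps |

## Normalization

All inputs are min–max normalized to $[0,1]$ — subtract the minimum,
divide by the range. For datasets the normalizer is fitted on the training
split only and unseen values clamp to $[0,1]$; constant features map to 0.

For the cart-pole task there is no dataset to fit, and the choice of
normalizing range turns out to be load-bearing. The package's default
applies the same min/range rule *online*: each state dimension is scaled
by the minimum and maximum observed so far across training (`normalization
= "running"`). This keeps kernel distances discriminative over the states
the agent actually visits. The alternative (`normalization = "fixed"`)
scales by static bounds tied to the failure thresholds (position
$\pm 2.4$ m, velocity $\pm 3$ m/s, angle $\pm 12^\circ$, angular velocity
$\pm 3$ rad/s, clamped). Under fixed bounds, the states visited while
balancing occupy a small central fraction of every dimension, so all
neurons are highly and nearly equally active everywhere; accumulated
rewards then barely differ across neurons and reward-based pruning
degenerates into near-random deletion, which inverts the expected benefit
of pruning. The running scheme restores the intended dynamic — pruned
networks converge faster than unpruned ones — which is why it is the
default. Its cost is mild non-stationarity: centers stored early are
expressed in a slightly different coordinate system than later ones, and
the observed range keeps the worst excursions ever seen.

## Numerical choices

* All arithmetic is double precision; no tolerance is applied inside the
  forward pass. The efferent cutoff is closed at zero: a neuron with
  activation exactly $1-s$ contributes exactly 0.
* Argmax ties (classification and greedy actions) break toward the lowest
  index; fully tied action outputs draw a seeded uniform action.
* Ties in pruning (equal minimal reward) remove the oldest neuron.
* The prediction logged during training is computed *before* the sample is
  stored, so learning curves honestly reflect one-shot behavior.
* The compiled cart-pole trainer and the pure-R reference engine consume
  R's RNG stream in the same order and are bit-identical run-for-run
  (floating-point contraction is disabled in the compiled code because the
  training dynamics are chaotic: a one-ulp difference in a reward changes
  a pruning choice and, from there, the whole learning curve).
* Model files are versioned JSON with 17 significant digits, which
  round-trips doubles losslessly.
* Degenerate inputs: an empty selection set creates no neuron (the model
  stagnates for that sample); zero-weight output connections are never
  stored; a regression scale must have positive width.

## What the synthetic generators emulate

The test suite and the acceptance script run entirely on programmatic
data:

* `make_blobs()` — three well-separated isotropic Gaussian classes in 2-D
  (centers (0.2, 0.25), (0.8, 0.25), (0.5, 0.8), sd 0.05, 20 points per
  class): the cleanly separable regime where one epoch should reach
  perfect held-out accuracy.
* `make_regression_surface()` — $y = \sin(2\pi x_1)\,x_2 + \varepsilon$,
  $\varepsilon \sim N(0, 0.05^2)$, $x$ uniform on the unit square: a
  smooth non-linear map with interacting inputs.
* `make_glyphs()` — 8×8 binary templates (bar, cross, box, diagonal) with
  optional pixel jitter and intensity noise: a small high-dimensional
  image task that exercises surprise-driven input selection and probes the
  method's known weakness to spatial shifts.

These fixtures reproduce the *statistical structure* each experiment
assumes — separability, smoothness, template-plus-noise — not the class
imbalance, feature correlations, or label noise of real datasets. Passing
on them shows the mechanics are correct and that the documented parameter
regimes behave as described; it does not certify accuracy figures on any
real benchmark.

Problem sizes were chosen to keep the full suite fast while leaving each
property statistically meaningful: 60-sample blob sets, 300-sample
regression surfaces, 60-sample glyph streams, 10 seeded repetitions of
each property run, and 10 seeded cart-pole runs per configuration.

## Known limitations

* The representation stores values per input index; a small spatial
  translation of an image changes every pixel's value and defeats the
  kernels. Glyph jitter makes this visible directly.
* Without a size cap the network grows for as long as errors exceed
  $E_{th}$; memory is linear in the number of stored samples.
* Cart-pole learning outcomes are strongly seed-dependent: most runs
  solve in low hundreds of trials, a minority stall for the full trial
  budget. Means over 10 seeds therefore carry large standard errors, and
  the acceptance script reports exactly such means.
* Uniform kernels cannot be refined after storage; there is no gradual
  fine-tuning of a nearly-correct model, only the addition of further
  corrections.
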