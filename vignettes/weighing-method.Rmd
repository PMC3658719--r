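---
title: "Estimating body weight from unstable scale patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating body weight from unstable scale patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An automatic scale in the entry corridor of a nest box reads 16 samples per
second, each tagged by the instrument as *stable* (consecutive readings
varying less than the device accuracy) or *unstable*. A small falcon of
100–190 g rarely stands still: only about 15% of weighing events contain
any stable readings at all. A traditional laboratory protocol that discards
unstable readings would throw away most of the data. `nestscale`
implements a pipeline that keeps them:

1. **Tare tracking** — while the pan is empty, the tare (empty-pan reading)
   is updated continuously with a robust location estimate, because dirt
   drifts it by the order of a gram per day.
2. **Segmentation** — an excursion of the calibrated weight above a
   threshold opens a *pattern* (the samples from arrival to departure);
   a run of below-threshold readings closes it.
3. **Estimation** — a pattern with stable readings is summarized by their
   arithmetic mean; an all-unstable pattern goes through a small
   multilayer perceptron (MLP) applied to nine cheap summaries of the
   pattern.
4. **Aggregation** — only the one estimate (plus its stable/unstable tag)
   is transmitted, instead of hundreds of raw samples.

## Tare and gain calibration

The tare is a running Huber M-estimate of location over the last 64
empty-pan readings (4 s at 16 samples/s), solved by iteratively reweighted
least squares at fixed robust scale (1.4826 × MAD), tuning constant 1.345,
at most 10 iterations, convergence tolerance 10⁻⁶ g, warm-started from the
previous tare. The Huber weights make the estimate insensitive to sporadic
wind spikes; a constant buffer (MAD = 0) falls back to the median. Tare
updating is suspended while a pattern is open, so an animal never biases
the empty-pan estimate.

Gain is calibrated separately (typically once a year) by ordinary least
squares of certified reference masses on mean raw readings; the calibrated
weight of a sample is `gain · raw + offset − tare`.

## Segmentation semantics

The boundary conventions, which the threshold description alone leaves
open, are fixed as follows (all configurable in `acquisition_config()`):

* a sample **strictly above** 50 g opens a pattern;
* readings at or below the threshold count toward closing; the **5th
  consecutive** one ("more than four") closes the pattern, and **all**
  trailing below-threshold samples are stripped, so a pattern never ends
  below threshold;
* a shorter below-threshold dip (the bird lifting its weight momentarily)
  stays in the pattern;
* readings above the 300 g upper bound of the plausible range are wind
  outliers: they are dropped, and while a pattern is open they neither
  extend nor reset the closing run;
* the valid range 50–300 g is inclusive at both ends;
* patterns still open at end of stream are flagged truncated and excluded
  from estimation by default;
* only patterns with **more than 16** samples (longer than a second) are
  valid.

The test suite checks these semantics sample-for-sample against an
independent two-pass reference implementation on 1,000 random streams.

## The nine features and the network

Repetition counts are undefined for continuous values, so weights are
quantized (default step 1 g, ties away from zero) before counting. The
nine summaries are: the most and second-most repeated weight with their
counts (`max_1`, `n_1`, `max_2`, `n_2`), the longest and second-longest
run with their values and lengths (`max_c1`, `nc_1`, `max_c2`, `nc_2`),
and the number of measurements (`n_el`). Every tie resolves to the larger
weight; if fewer than two distinct values (or runs) exist, the second
place is reported as 0/0 so the vector stays total.

The estimator network is a fully connected 9-H-1 sigmoid MLP (H = 3 in the
deployment). The output neuron's activation, in (0, 1), is multiplied by a
*resample factor* R to give grams, so estimates are bounded in (0, R).
Two pieces of the published description required decisions:

* **Sigmoid orientation.** The printed pseudocode computes
  `1/(1 + e^sum)`, a reversed sigmoid; the standard `1/(1 + e^(−sum))` is
  the default, with `sigmoid = "as_printed"` available for fidelity
  experiments.
* **Scaling.** Neither R nor the input scaling of the original deployment
  was published. The package fixes R = 300 g (the upper bound of the
  valid range) and scales weight-valued features by 1/R and count-valued
  features by 1/2048 (128 s of samples). **Consequently the published
  connection-weight table is kept as a verification fixture for the
  forward pass — its weights were trained under an unknown scaling and do
  not give gram-accurate estimates. Accurate estimation requires
  retraining under the declared scaling**, which the training module does.

The bias row of the published table is added to each neuron's weighted sum
before the sigmoid; the decimal commas in its last column are read as
decimal points, and its duplicated "from input 6" row label is read as
inputs 6 and 7 in table order (plain typographic errors).

## Training protocol

Patterns containing both stable and unstable readings provide supervised
examples: the target is the arithmetic mean of the stable readings
(trusting the scale's unbiasedness when it reports stability), and the
features are computed from the pattern with every stable reading removed.
Examples are split 50/50 at random; networks with 1–9 hidden neurons are
trained and the smallest one within 0.1 percentage points of the best
held-out mean accuracy is selected.

The optimizer is full-batch gradient descent on the mean squared error of
the scaled output (targets divided by R), weights initialized uniform on
(−0.5, 0.5). The learning rate is 5 with up to 10,000 epochs, early
stopping when the training MSE has not improved by 10⁻⁷ for 200 epochs;
much smaller rates (e.g. 0.05 for 2,000 epochs) demonstrably stall at a
plateau barely better than predicting the mean. Because the loss is
non-convex and a single initialization occasionally lands in a biased
local minimum, each fit runs 3 restarts (deterministic per seed) and keeps
the lowest final training MSE. Early stopping monitors the training loss
rather than a further held-out split: the full-batch loss is smooth, and
carving a validation set out of the modest example count costs more than
it protects.

Accuracy is reported as `100 · (1 − |manual − estimate| / manual)`,
averaged over pairs; per-pair values are rounded to two decimals when
printed.

## What the simulator emulates

`simulator_config()` defaults *are* the study conditions: 16 samples/s,
true weights uniform on 100–190 g, lognormal durations with mean 23.18 s
(log-sd 0.35), 15% of visits containing a still plateau, empty-pan tare
near 10 g drifting ~1 g/day, sporadic above-range wind spikes, and
exponential inter-visit gaps.

Movement is modelled as an AR(1) oscillation (coefficient 0.9) plus white
measurement noise (sd 0.1 g). The configured oscillation *amplitude*
(12 g) is interpreted as the typical peak excursion, so the AR(1)
stationary sd is amplitude/2 = 6 g — about 95% of excursions stay within
±12 g. The scale's internal stability rule is proprietary; the simulator's
stand-in tags a sample stable iff the max−min spread of the trailing 8
samples is at most 1 g, which the white-noise level satisfies only on
plateaus. A plateau (uniform 16–64 samples) suppresses the oscillation
entirely — a bird standing still.

What the simulator does **not** emulate: prey-delivery mass steps inside a
pattern, slow load shifts as the bird walks, temperature effects on the
load cell, or any correlation between movement style and body weight.
Passing tests therefore show that the pipeline recovers weights whose
unstable oscillation is zero-mean around the truth, not that the field
deployment's error statistics are reproduced on real birds.

## Scales used by the checks

The headline end-to-end property — held-out mean accuracy ≥ 98.5% and
pipeline mean absolute error ≤ 4 g — is computed on 7,856 simulated visits
(≈1,170 of which yield mixed-pattern training examples, split ≈585/585),
matching the size of the deployment's first-season archive. Seasonal trend
recovery uses 8 birds over 60 days at ~2 visits/day (≈950 visits) with a
−0.2 g/day trend, a compact inter-visit gap (5 s mean — idle hours teach
nothing), and recovers the slope within ±0.05 g/day from a per-bird
fixed-effect regression on the pipeline's estimates. Oracle-equivalence
checks run 10,000 random feature sequences and 1,000 random segmentation
streams.

## Known limitations

* The published connection weights cannot be used for estimation (scaling
  unrecoverable, above); they verify the forward pass only.
* The payload formula for raw forwarding is implemented verbatim although
  its leading 16 appears to double-count the per-byte factor; the
  reconciled per-pattern saving (`round(sps · duration)` bytes, 371 at the
  deployment's averages) is provided side by side, and neither is silently
  corrected.
* The accuracy metric is relative to each reference weight, not to a
  colony mean; the five recapture comparisons in the test suite pin the
  convention.
* The IRLS tare assumes the empty-pan level changes slowly; a sudden
  permanent step (e.g. debris landing on the pan) is absorbed only after
  the 64-sample window refills.
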