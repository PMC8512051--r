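---
title: "Class-imbalanced fall detection: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-imbalanced fall detection: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the method

A waist-worn tri-axial accelerometer sampled at 200 Hz sees falls as a
two-stage event: a free-fall interval in which the measured acceleration
magnitude drops toward zero, followed by a sharp impact peak of several g.
Activities of daily living (ADL) keep the signal magnitude vector
(SMV, `sqrt(ax^2 + ay^2 + az^2)`) oscillating about 1 g. A window
classifier can learn this distinction well — but realistic corpora are
heavily imbalanced (the reference accounting is 94,786 ADL windows against
8,439 fall windows, imbalance ratio ρ = 11.23), and a softmax classifier
trained on such data calibrates its posteriors against the prior: windows
with genuine but partial fall evidence receive fall posteriors well below
0.5 and are lost to the conventional cutoff.

`imbfall` implements the pipeline around the simplest repair, **output
threshold moving**. The trained network is untouched; the decision rule
"fall iff P(fall | window) ≥ λ" uses a moved cutoff:

* empirical rule: `λ̂ = argmin_λ |f − f_λ|`, where `f` is the minority
  frequency of the training split and `f_λ` the fraction of posteriors at
  or above `λ` — the cutoff that makes the prediction distribution match
  the training distribution;
* closed form: `λ* = k · exp(−ρ / (10 k)) + k / 10`, a fitted map from the
  imbalance ratio alone, with `k` the default threshold (0.5). It decays
  from ≈ `k` at balance toward `k/10` at extreme imbalance; at ρ = 11.23
  it gives 0.1029, i.e. the working threshold 0.1.

Because a threshold only relabels a fixed ranking, AUC is invariant under
threshold moving; what changes is the operating point — fall recall
(called *specificity* under the evaluation convention below) rises at the
cost of some false alarms.

## The classifier

`fall_resnet()` fits a small 1D residual network: four residual blocks,
each two 1×3 convolutions with batch normalization and ReLU plus a
shortcut addition (a 1×1 projection where shape changes), then global
average pooling and a two-way softmax head. Mini-batch Adam minimizes
cross-entropy (or a class-weighted / focal variant) for at most 30 epochs
at learning rate 0.001; the epoch with the lowest validation loss is
returned.

Published descriptions of this architecture class leave several details
open; the package fixes them as follows, as its own design choices:

* **Channel widths 16/32/64/128 with stride-2 downsampling at each block
  boundary.** The smallest standard residual layout consistent with "four
  residual blocks", and trainable on one CPU in minutes.
* **conv → BN → ReLU ordering** inside each block (the conventional
  order), with the second BN before the shortcut addition and a final
  ReLU after it; zero ("same") padding keeps block outputs aligned with
  the shortcut.
* **Global average pooling** before the fully connected layer: shape
  independence and parameter economy.
* **Optimizer Adam, batch size 64** (both unstated in the source
  literature for this setup; Adam is the de-facto default at learning
  rate 0.001).
* **Checkpoint selection by best validation loss**, no early stopping.
* Convolution biases are kept (the textbook convolution includes them)
  although batch normalization makes them redundant; their gradients are
  exactly zero through BN, which is harmless.

The whole network, including backpropagation, is implemented in base R
matrix algebra (convolutions as per-tap matrix products handed to BLAS).
The backward pass is verified against central-difference numerical
gradients in development and against a brute-force convolution oracle in
the test suite.

## The simulator: what it emulates, and what it does not

`sim_corpus()` states a world rather than fitting one — no generative
model of real fall signals is available, so the generator reproduces the
*phenomenology* the detectors rely on:

* ADL trials: gravity plus a rectified periodic activity component
  (standing/sitting sway at 0.3–0.4 Hz, walking at 2 Hz, jogging at
  2.8 Hz) scaled so the trial's SMV maximum lands in a kind-specific
  slice of `adl_peak_range` (default 10–25 m/s²), plus white sensor noise
  (`noise_sd` 0.3 m/s² per axis). The rectified waveform keeps the SMV
  floor at ~1 g: ADL data never dip toward free fall.
* Fall trials: pre-fall *walking drawn from the same amplitude law as ADL
  walking* (so windows before the fall carry no artificial fall cue — in
  real recordings the activity before a fall is just activity), a 0.35 s
  free-fall decay of all axes toward zero, a single half-sine impact
  (~80 ms) whose peak SMV lands in `impact_peak_range` (default
  30–50 m/s², disjoint from the ADL range by construction), and
  post-impact lying rest.

Defaults follow the reference recording setup where stated (200 Hz
sampling, 1 s windows, 3 s peak-centered fall segments, 6:2:2 split,
β = 0.5, k = 0.5) and field convention otherwise. The default pipeline
corpus (265 ADL / 92 fall trials) yields ~5,500 windows at ρ ≈ 11, a
desk-scale replica of the reference ratio 11.23.

What the simulator does **not** emulate: biomechanics (impact shape,
orientation dynamics and rotational components are stylized), subject
heterogeneity (age effects, sensor placement variation), gyroscope
channels (extra channels are zero-filled placeholders), near-fall
activities such as sudden sitting, and lying as an *ADL* (post-impact
rest is therefore a genuine fall cue in this world). Consequently a green
test establishes that the pipeline and the threshold-moving mechanism
behave correctly on data with the stated structure — not that any
particular accuracy transfers to real recordings. The published
real-data scores require the external corpus and GPU-scale training and
are deliberately out of scope.

## Preprocessing choices

* **Sliding-window stride is a free parameter** (default 0.5 s, 50%
  overlap — the common HAR convention). The reference corpus counts
  cannot be reconstructed without knowing the stride used there, so those
  counts are treated as reported inputs, not reproduced outputs.
* **ADL trials are windowed over their full length; fall trials are first
  reduced to the 3 s peak-centered segment.** This is the reading that
  reconciles "sampling 3 s around the peak in fall files" with windowing
  all data.
* Peak-centered segments are **edge-clipped to full length** (shifted
  inward, never shortened), so all windows are shape-uniform; argmax ties
  resolve to the first occurrence; windows use 0-based, half-open
  indexing.
* **Splitting is stratified by label** even though a plain random split
  would be the literal reading: at ρ ≈ 11 an unstratified split can leave
  a validation or test set with almost no falls, which makes checkpoint
  selection and evaluation meaningless. The run log records the split.

## Threshold and strategy details

* The empirical rule's candidate set is the sorted union of the observed
  posterior values and the grid 0.01–0.99 (step 0.01); the search is
  exhaustive and exact, ties go to the smallest candidate. It is
  evaluated on **validation** posteriors — using test posteriors would
  leak the evaluation set into the decision rule.
* Threshold moving is applied post hoc to the trained model's outputs.
  (Architecturally one can draw it as a final "layer"; mathematically it
  is the same function.)
* Class weights are `n_total / (2 n_c)` — inverse frequency, averaging 1
  over training samples, so the loss scale is comparable to the
  unweighted one.
* Focal loss uses `α_t = α` for the minority and `1 − α` for the majority
  class, defaults γ = 2, α = 0.75 (minority-favoring, the common choice
  for rare-event detection).
* SMOTE interpolates on raw flattened windows under Euclidean distance
  (the simplest faithful reading of the method); it is applied to the
  training split only. The `smote_threshold` strategy combines
  SMOTE-balanced training with the empirical threshold computed from
  validation posteriors against the *original* training frequency.

## Evaluation convention

Following the source convention of this method family, the **positive
class is ADL** and the negative class is the fall: TP = ADL correctly
classified, TN = fall correctly detected, FP = fall missed, FN = false
alarm. Hence *sensitivity* is ADL recall and *specificity* is fall
recall; β = 0.5 in the F-score weights specificity (fall recall) more
heavily. This is unusual — read `specificity` as "fraction of falls
detected" throughout.

Two caveats the package documents deliberately:

* Rates with zero denominators are reported as `NA` with a warning,
  never silently as 0 or 1.
* Applying the F-score formula to the literature's own printed
  sensitivity/specificity pair (99.33 / 91.86 at β = 0.5) yields 97.74,
  not the printed F-score; the formula as written is implemented and the
  printed value is not used as a reference anywhere.

AUC is computed from midranks (normalized Mann–Whitney statistic, ties
counting ½) with an independent trapezoid-over-ROC route exposed via
`roc_auc(method = "trapezoid")`; the two agree to 1e−9 and both are
tested against pairwise enumeration.

## Numerical and testing notes

* All randomness is explicit: per-trial seeds derive from a master seed
  by a fixed affine hash (every derived seed a valid 32-bit integer);
  generators and the fitter restore the caller's RNG state. Identical
  configurations reproduce corpora byte-identically and training
  histories to floating-point identity.
* Batch normalization uses the biased batch variance with ε = 1e−5 and
  momentum 0.1 running statistics; evaluation mode uses the running
  statistics saved with the best checkpoint.
* The full-scale mechanism test (~5,500 windows, ρ ≈ 11) trains for 10
  epochs rather than the 30-epoch maximum: on separable synthetic data
  validation loss converges within a few epochs, and the shorter run
  keeps the suite inside its CPU-time budget. The 30-epoch default
  remains the package default.
* Known limitations: training is single-threaded BLAS-bound; no
  resampling between sampling rates, no filtering/denoising, no streaming
  inference; `n_classes > 2` is accepted by the network but the
  thresholding layer is inherently binary.
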