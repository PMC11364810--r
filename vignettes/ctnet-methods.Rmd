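---
title: "Decoding motor imagery from EEG with a convolutional Transformer"
author: "ctnet package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor imagery from EEG with a convolutional Transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctnet)
```

## The problem

Motor imagery (MI) — the mental rehearsal of a movement without executing it
— modulates the sensorimotor rhythms of the EEG: imagining left- or
right-hand movement desynchronizes the mu (8–13 Hz) and beta (13–30 Hz)
bands over the contralateral motor cortex. A brain–computer interface
decodes these band-power patterns from short multi-channel EEG trials into
discrete commands. The canonical evaluation material is the BCI Competition
IV corpus: dataset 2a (22 EEG channels, four classes — left hand, right
hand, feet, tongue — 250 Hz, 1000-sample trial windows) and dataset 2b
(3 bipolar channels, two classes).

The decoding model implemented here, CTNet, is a compact hybrid: an
EEGNet-style convolutional front end learns local temporal filters and
spatial (cross-channel) patterns, a Transformer encoder with multi-head
self-attention integrates those local features over the whole trial, and a
single fully connected layer classifies the residual-fused features. The
whole network has only ~25 k trainable parameters, small enough to train
per subject on a few hundred trials.

## Architecture

An input trial is a standardized matrix $X' \in \mathbb{R}^{C \times T}$.
The convolutional module applies:

1. **Temporal convolution** — $F_1 = 8$ kernels of length $K_{c1} = 64$
   (one quarter of the 250 Hz sampling rate, so the filters resolve
   rhythms above ~4 Hz), applied along time with same-length zero padding,
   shared across channels; batch norm follows.
2. **Channel depth-wise convolution** — kernels of shape $(C, 1)$ with
   depth multiplier $D = 2$, collapsing the channel axis into
   $F_2 = F_1 D = 16$ spatial-filter maps; batch norm, ELU, average pooling
   of length $P_1 = 8$, dropout $p_1$.
3. **Temporal ("spatial") convolution** — $F_2$ kernels of length
   $K_{c2} = 16$ (about 500 ms at the post-pooling rate of ~31 Hz) with
   same padding over all $F_2$ maps; batch norm, ELU, average pooling of
   length $P_2 = 8$, dropout $p_1$.

Each pooling stage floors the length, so the token sequence fed to the
encoder has

$$T_c = \lfloor \lfloor T / P_1 \rfloor / P_2 \rfloor$$

steps of width $d = F_2$; `token_length(1000, 8, 8)` is 15, and the $P_2$
sweep {1, 6, 8, 10} yields token sizes {125, 20, 15, 12}.

The encoder stacks $L = 6$ identical post-norm layers. Each layer computes
$h = 2$ scaled dot-product attention heads
$Z_i = \mathrm{softmax}(Q_i K_i^\top / \sqrt{d_k}) V_i$ with per-head
projections $W^Q_i, W^K_i, W^V_i \in \mathbb{R}^{d \times d_k}$,
$d_k = d/h$, concatenates them through $W^O$, and applies the residual +
layer-norm arrangement $O = \mathrm{LN}(\mathrm{MHA}(X) + X)$, followed by a
position-wise feed-forward block (linear $d \to 4d$, exact GELU
$x\,\Phi(x)$ with $\Phi$ the standard-normal CDF, dropout, linear
$4d \to d$) and $E = \mathrm{LN}(\mathrm{FF}(O) + O)$. No positional
encoding is added: the token order information the classifier needs
survives in the flattened output, and the exact parameter accounting below
confirms this wiring.

The classifier adds the conv tokens and the encoder output elementwise
($S + E$ — a residual path that feeds the CNN features directly to the
classifier), flattens the $T_c \times d$ matrix, applies dropout
$p_2 = 0.5$, and maps through one fully connected layer to $N$ logits
trained with categorical cross-entropy.

### Parameter accounting as a design oracle

Several architectural details are under-determined by prose descriptions
alone (is there a positional embedding? how wide is the feed-forward
hidden layer? do convolutions carry biases?). We resolved them by exact
accounting against the published totals of 25.7 k / 24.9 k parameters:
bias-free convolutions (each is followed by an affine batch norm),
biased attention and feed-forward linears, feed-forward expansion 4
($16 \to 64$), no positional encoding, and a single-layer classifier give

* 22-channel, 4-class build: conv 5,040 + 6 × 3,280 encoder + 964
  classifier = **25,684**;
* 3-channel, 2-class build: conv 4,736 + 19,680 + 482 = **24,898**.

Any of the rejected alternatives (expansion 2 ≈ 19.3 k, a learnable
positional embedding +240, conv biases) breaks the match. A property test
checks `count_parameters()` against this closed form over randomized
configurations.

## Preprocessing and augmentation

The only preprocessing is per-trial Z-score standardization,
$(X - \mu)/\delta$ with scalar mean and standard deviation over all
$C \times T$ entries. We use the population standard deviation (divide by
$CT$); the definition is agnostic and the choice is covered by a unit
test. Standardization precedes everything else, including augmentation.

Segmentation-and-recombination (S&R) augmentation splits every training
trial into $K$ equal contiguous segments and builds artificial trials by
concatenating, in original temporal order, segment $k$ of a uniformly
drawn same-class trial for each position $k$. Defaults: $K = 8$ (125-sample
segments on the benchmark geometry) and one artificial trial per original
(training set doubled); both are configurable because no canonical values
exist. Augmentation is applied once per run, to the training portion only,
*after* the train/validation split — validation data is never synthetic, so
model selection cannot leak augmented copies of validation trials. The test
suite verifies by exhaustive block search that every artificial segment is
bit-identical to a same-class original block and never to another class's.

## Training protocols

Optimization is Adam with learning rate $10^{-3}$, $\beta_1 = 0.5$,
$\beta_2 = 0.999$, $\epsilon = 10^{-8}$, no weight decay. 30% of the
initial training set is reserved (stratified at random; the split is
seeded and reproducible) as a validation set, and the parameter snapshot
with minimum validation loss is kept — all epochs run, no early stopping.
The nominal batch sizes are 288 (subject-specific) and 512 (LOSO); when
they exceed the post-split training size the loop degrades to full-batch
training, which is what a batch of 288 means for a 288-trial benchmark
session. The subject-specific protocol trains and tests entirely within
one subject; LOSO pools all other subjects as training material, switches
the convolutional dropout from 0.5 to 0.25 (more data, less regularization
needed), and tests on the held-out subject. Both protocols attach
content fingerprints of everything that influenced training so tests can
audit that no test trial leaked into training or model selection.

One master seed fans out deterministically to the split, augmentation,
initialization and shuffling streams; a fixed seed makes a whole run
bit-reproducible, which the suite asserts.

## Evaluation statistics

* **Accuracy** is the confusion-matrix trace over the total.
* **Cohen's kappa** uses the balanced-chance convention $P_e = 1/N$, which
  matches the class-balanced benchmark sessions and reproduces the
  published mean kappa 0.7670 from the published mean accuracy 82.52%
  exactly; the marginal-product variant is available behind
  `kappa_from_cm(..., pe_method = "marginal")`.
* **Aggregation** reports mean ± sample standard deviation (n−1) of
  per-subject accuracy percentages and the mean kappa.
* **Hedges' g** is Cohen's d with pooled ($n_1 + n_2 - 2$) variance and the
  small-sample correction $1 - 3/(4(n_1+n_2) - 9)$.
* **The paired Wilcoxon signed-rank test** is exact: zeros dropped,
  midranks for tied magnitudes, and the p-value computed from the full
  $2^n$ sign-assignment distribution (evaluated via its generating
  function; a brute-force enumeration oracle confirms equivalence for
  $n \le 10$). The default alternative is one-sided (proposed minus
  baseline, `greater`), which reproduces the published 4-class p-values
  0.0020 (all nine differences positive, $1/512$) and 0.0059 (one negative
  difference tied in magnitude, $3/512$ with midranks). Published 2-class
  p-values such as 0.0078 are instead consistent with a two-sided reading;
  since the convention is not stated anywhere, both alternatives are
  exposed and none is guessed.

## The synthetic generator

Real benchmark recordings are large, subject to download terms, and far
too slow to train on in a test suite. The generator emulates the one
physiological feature the decoder exploits: class-conditional band-power
modulation. Every channel carries $1/f^{a}$ background noise (spectral
shaping of white noise, $a = 1$ by default — an EEG-like spectrum); the
channels mapped to a class additionally carry a narrow-band oscillation
(band-limited *filtered Gaussian noise*, not a sinusoid, so the fixture is
not trivially linearly separable and genuinely exercises the temporal
filters), whose variance is $(1 + \mathrm{effect})$ times baseline on
trials of that class. `effect = 0` makes classes exchangeable in
distribution — the null fixture. The default geometry (3 channels, 1000
samples, 250 Hz, 2 classes) mirrors the smaller benchmark so tests stay
fast.

What the generator does **not** emulate: real artifacts (EOG, EMG, line
noise), non-stationarity within a session, volume-conduction structure
across channels, or realistic inter-subject variability (synthetic
"subjects" are i.i.d. draws). Passing tests therefore demonstrate that the
pipeline recovers class-conditional band-power structure under controlled
conditions — not that it attains any particular accuracy on real
recordings, which remain an optional long-running workflow through the GDF
loader.

## Numerical choices

* Batch norm: momentum 0.1, $\epsilon = 10^{-5}$, biased batch variance in
  the normalization, unbiased in the running estimate (the framework
  convention); evaluation mode uses the stored running statistics, so a
  zero input still produces finite output.
* Layer norm: per-token over the $d$ features, $\epsilon = 10^{-5}$.
* Same padding with an even kernel pads one extra sample on the right.
* Pooling floors the sequence length; remainder samples are dropped.
* Initialization is Glorot-uniform for weights, zeros for biases, unit
  gains for normalization layers, seeded.
* Dropout is inverted (scaled at train time) and off at evaluation, so
  inference is deterministic — two forward passes agree bitwise.
* Cross-entropy clamps probabilities at $10^{-12}$ before the log.
* GELU uses the exact Gaussian-CDF form, not the tanh approximation.
* All forward/backward passes are hand-written dense linear algebra; the
  analytic gradients of every trainable parameter are pinned against
  central finite differences in the test suite.

## Problem sizes used by the test suite

The end-to-end checks train the full model on the default synthetic
geometry with 100 trials per class, a 70/30 stratified split, batch size
64 and 40 epochs — enough for the strong-effect fixture
($\mathrm{effect} = 3$) to exceed 90% held-out accuracy while the null
fixture stays inside the exact binomial 99% band around chance, with
held-out accuracy non-decreasing in effect size across
$\mathrm{effect} \in \{0, 1, 3\}$. Unit tests use miniature geometries
(64-sample trials, 2–4 layer-widths) so the whole suite runs on one CPU in
minutes.

## Known limitations

* Training runs on the CPU in R; desk-scale experiments are comfortable,
  but the full benchmark protocol (1000 epochs × 9 subjects) is a long
  batch job, not an interactive one.
* The GDF loader delegates parsing to the Python `mne` package through a
  subprocess; it requires a `python` with `mne` importable on the PATH and
  is exercised only for its error paths in the test suite, since GDF
  fixtures cannot be synthesized in a text-only repository.
* The exact Wilcoxon implementation enumerates up to $n = 25$ pairs —
  ample for nine-subject comparisons, not for large cohorts.
* `kappa()` assumes balanced test sets; for unbalanced sessions use the
  confusion-matrix form with the marginal convention.
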