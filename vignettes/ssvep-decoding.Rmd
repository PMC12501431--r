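---
title: "SSVEP decoding with background-EEG mixing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SSVEP decoding with background-EEG mixing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the scientific model behind `ssvepmix`, the
parameters that matter, the design choices made where the design was
genuinely open, and what the synthetic-data experiments do and do not
demonstrate about real EEG.

## Signal model

A steady-state visually evoked potential is the occipital response to a
stimulus flickering at frequency $f_m$: a periodic waveform containing
$f_m$ and its harmonics, phase-locked to the stimulus. We model an epoched
trial $x_h^m \in \mathbb{R}^{N_c \times N_s}$ (channel × time) of class
$m$ as

$$x_h^m = s^m + b_h,$$

where $s^m$ is a trial-invariant *task-related component* and $b_h$ is
trial-varying *background EEG*. Averaging trials estimates the task
component — the template $\bar x^m = \tfrac1n \sum_h x_h^m$ — because the
background, being uncorrelated across trials, shrinks under averaging
while the phase-locked component does not. The residual
$Bg_h = x_h^m - \bar x^m$ is the background estimate.

## BGMix

BGMix generates a new sample for target class $y$ by pairing a template of
$y$ with a background residual of a *different* class $y'$:
$\tilde x = \bar x^{y} + Bg'$. Operationally (per generated batch): draw
$n$ trials of class $y$ and average them into the template; draw a donor
class $y' \ne y$ uniformly and $n$ of its trials; subtract the donor
subset's own template to get $n$ residuals; emit template + residual for
each. A weight $\lambda \sim \mathrm{Beta}(\alpha,\beta)$ accompanies each
sample and enters **only the loss**,
$\lambda\,\mathrm{CE}(y) + (1-\lambda)\,\mathrm{CE}(y')$ — the waveform is
never $\lambda$-scaled. This differs deliberately from Mixup (provided in
`mixup_generate()` as the comparator), where $\lambda$ blends the signals
themselves.

Open choices, resolved as follows:

* **Template scope.** Templates can be built from all class trials or from
  the $n$ drawn trials. The subset convention is the default
  (`template_scope = "subset"`), since it is the operational description
  of the procedure and injects more template diversity; the all-trials
  convention is a config switch. Under the subset convention the expected
  background power of a generated sample is
  $\sigma^2/n + \sigma^2(1 - 1/n) = \sigma^2$ on white-noise input — the
  single-trial level — which the test suite verifies by Monte Carlo.
* **$\lambda$ distribution.** Only "a Beta distribution" is specified by
  the method; the default is $\mathrm{Beta}(1,1)$ (uniform), configurable.
* **Donor class.** Uniform over classes other than the target — the
  simplest unbiased choice.
* **Emission count.** Each draw yields all $n$ residual-swapped samples
  (not one sampled from them); draws repeat until the configured factor
  per original sample is reached, so per-class output counts are exactly
  `factor ×` the input counts and class balance is preserved.

## The AETF decoder

The network mirrors the classical SSVEP pipeline, learned end to end:

1. **Spatial filtering.** A fully connected layer across electrodes with
   tanh activation, applied independently at every time point:
   $N_c \to N_{sp}$ (default $2N_c$).
2. **Frequency filtering.** A 1-D convolution along time with $N_{fr}$
   kernels (default 8) of length $\lfloor f_s/2 \rfloor$ — long enough to
   resolve 2 Hz — with 'same' zero padding, ELU, and batch normalization
   per feature map.
3. **Temporal encoding.** The $N_s$ time points become tokens with
   embedding dimension $d_{model} = N_{sp} N_{fr}$. Sinusoidal positional
   encodings are added, then $N_{layer}$ (default 2) encoder layers apply
   multihead self-attention ($\mathrm{softmax}(QK^\top/\sqrt{d_k})V$,
   heads $= N_{fr}$, mimicking a filter bank) and a position-wise
   feed-forward block with leaky-ReLU, each wrapped in residual
   connections with layer normalization.
4. **Classification.** The full sequence is flattened (no pooling — the
   temporal structure is preserved) into a linear layer with $N_f$
   outputs.

Treating *time points* as tokens (sequence length $N_s$, embedding
$N_{sp}N_{fr}$) is a deliberate resolution of an ambiguity in the layer
table: it makes the attention matrices $N_s \times N_s$, i.e. maps of
which time points attend to which, which is the interpretable object the
architecture is designed around.

Choices the architecture description leaves open, with our defaults:
feed-forward width $2\,d_{model}$ (a modest width consistent with the
reported parameter budget, not the conventional $4\times$); dropout 0.1
inside encoder layers; leaky-ReLU slope 0.01; even convolution kernels pad
with the extra zero on the right; batch-norm uses batch statistics during
training (momentum 0.1) and running statistics at evaluation; kernels
longer than the window are clipped with a warning. Post-norm residual
blocks (normalization after the residual sum) follow the reference
Transformer-encoder implementation the architecture is based on.

The forward pass and its analytic backpropagation are implemented in
vectorized base R; a finite-difference gradient check (relative error
$< 10^{-4}$ on a small configuration) guards every layer's gradients.

### Training protocol

Adam (default lr $10^{-3}$, weight decay $10^{-2}$, batch 64) with early
stopping: training stops once the validation loss has not improved for
more than `patience` (default 20) epochs, and the best-validation
checkpoint is restored. The optimizer settings are not prescribed by the
method description; these defaults are ordinary practice and are logged
with every run. Two stages: an intersubject model is first trained on data
pooled from all subjects (no augmentation), then cloned and fine-tuned per
subject. BGMix runs only in stage 2; when it is active, the generated
samples from the subject's original train + validation trials form the new
training set, and the original train + validation trials concatenated form
the new validation set. Stage-1 pooling includes all subjects by default
(a leave-one-subject-out variant is a matter of passing different subject
lists).

Knowledge distillation compresses the 2-layer teacher into a 1-layer
student with halved hidden dimension (halving the frequency-filter count
halves $d_{model}$): the student trains on
$0.7\,\mathrm{CE}(\text{hard}) + 0.3\,T^2\,\mathrm{KL}(p^T_{teacher}\,\|\,p^T_{student})$
with temperature $T = 5$.

## Classical decoders

**eTRCA.** For each class, the TRCA filter $w$ maximizes the inter-trial
covariance of the filtered signal subject to a variance constraint — the
leading generalized eigenvector of $(S, Q)$, where $S$ sums
cross-covariances over ordered trial pairs $h_1 \ne h_2$ and $Q$ pools
within-trial covariance. Sums rather than means are used in both matrices;
the scale cancels in the Rayleigh quotient, a fact the test suite checks
against brute-force maximization rather than assumes. Per-class filters
form the ensemble $W \in \mathbb{R}^{N_c \times N_f}$. The filter bank
spans sub-bands $m\cdot 8$–$90$ Hz ($m = 1..3$ by default), combined with
the standard weights $a(m) = m^{-1.25} + 0.25$ (uniform weights are a
config alternative). The decision rule — correlation between the projected
trial and each projected class template, summed over sub-bands — follows
the original TRCA literature, since the method description leaves it
implicit. Degenerate (rank-deficient) covariances are ridge-regularized
with $\varepsilon = 10^{-8}\,\mathrm{tr}/d$ and a logged message.

**TDCA.** Trials are delay-embedded ($l = 5$ delays, zero-padded at the
trailing edge), augmented with their projection onto the class's
sinusoidal reference subspace ($P_i = QQ^\top$ from the QR decomposition
of the harmonic reference, $N_h = 5$), and discriminant directions are the
top $K$ (default 8) generalized eigenvectors of the between/within scatter
pair $(H_bH_b^\top, H_wH_w^\top)$. The filter bank is applied to TDCA as
in its original publication (switchable off). Because epoched trials carry
no post-window samples, training trials are zero-padded exactly like test
trials.

## Metrics

Balanced accuracy is the mean of per-class recalls. The information
transfer rate per selection of $T$ seconds with $N$ targets and accuracy
$P$ is
$\frac{60}{T}\left[\log_2 N + P\log_2 P + (1-P)\log_2\frac{1-P}{N-1}\right]$
bits/min, with $0\log 0 := 0$ and below-chance accuracies floored to zero
(the formula otherwise rewards adversarially wrong classifiers). $T$
defaults to the data window plus a 0.5 s gaze-shift overhead, recorded in
every report.

## The synthetic generator

`synth_dataset()` emulates the structure the decoders exploit: per-class
fundamentals plus harmonics with fixed phases (default: a 12-target grid,
9.25–14.75 Hz in 0.5 Hz steps with $0.5\pi$ phase steps, three harmonics
with $1/k$ amplitude decay), projected into channels by a fixed random
spatial pattern per class; 1/f background noise generated per channel and
spatially smeared by a random full-rank mixing matrix, so the background
is spatially correlated while the task components occupy a low-rank
subspace (this is what makes spatial filtering meaningful); and 10% white
sensor noise. The total noise is scaled per trial to the configured
task-to-background SNR, and the class signal is phase-locked across trials
by default (a latency-jitter option exists) because template averaging
presumes phase locking.

What it does **not** emulate: volume-conduction head geometry, eye-blink
and EMG artifacts, non-stationary alpha intrusions, inter-subject
variability of SNR, or electrode drift. Passing tests on this generator
therefore demonstrates the *algorithms compute what they claim* (and that
their relative ordering behaves sensibly with SNR and sample size), not
that the published accuracy levels transfer to any particular recording.

## Experiment sizes

The bundled experiments are sized for a single CPU. The end-to-end
classical benchmark uses the default 12-class set (6 trials per class,
0.5 s at 250 Hz, 10 dB SNR) where both eTRCA and TDCA reach ≥ 95%
held-out accuracy. The small-sample AETF experiment uses 6 classes at
100 Hz, 4 channels, −2 dB SNR, 3 training + 1 validation trials per class,
a 1-layer model with $d_{model} = 32$, a 10× BGMix pass ($n = 2$), and
40 epochs with patience 6, averaged over 5 seeds; at this size the mean
held-out balanced accuracy with BGMix exceeds the unaugmented mean by
roughly ten percentage points, reproducing the direction (not the
magnitude) of the augmentation benefit at full scale.

## File formats and containers

Epoched data live in a trials × channels × samples array with 0-based
integer labels, sampling rate and channel names (`epoched_eeg`). The
internal container uses R's native serialization (bit-exact round trips);
a plain-text CSV + JSON layout is provided for interchange, and
`epochs_from_array()` normalizes the channels × samples × classes × blocks
array convention common in public SSVEP distributions. MATLAB/EDF/HDF5
readers are out of scope for this implementation; convert such recordings
to one of the supported layouts first.

## Known limitations

* The AETF implementation is CPU-bound base R: suitable for the bundled
  desk-scale experiments and for studying the algorithms, not for
  full-scale benchmark replication with 80–120× augmentation on real
  datasets.
* Determinism is promised on a single machine (fixed seeds, serial BLAS
  paths); bit-equality across BLAS implementations is not.
* The Chebyshev band-pass (type I, order 4, 0.5 dB ripple, zero-phase) is
  a convention choice; the filter family/order used by reference
  preprocessing pipelines varies, and both order and ripple are exposed in
  `filter_spec()`.
* The default eTRCA/TDCA filter bank (sub-bands up to 90 Hz) requires
  sampling rates above 180 Hz; lower-rate data need a custom bank.
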