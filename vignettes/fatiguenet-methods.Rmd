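---
title: "Methods: synthetic physiology, the T2F convolutional classifier, and the evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic physiology, the T2F convolutional classifier, and the evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Driver fatigue develops gradually, and binary alert-versus-fatigued
classifiers discard exactly the graded information a warning system needs.
`fatiguenet` studies the harder multi-level problem: classify short EEG
epochs into five ordered states — normal, onset of fatigue, mid fatigue,
warning of fatigue, complete fatigue — or into the two- and three-level
reductions of that scale. The classifier is a seven-block one-dimensional
convolutional network whose activations are learnable interval type-2
fuzzy (T2F) units; a GAN can enlarge the training set, and an evaluation
suite measures accuracy, chance-corrected agreement, ROC behaviour and
robustness to additive white Gaussian noise.

Because multi-level fatigue recordings with trustworthy labels are scarce
and privacy-bound, the package ships a seeded synthetic generator so that
every stage is testable end to end.

## The synthetic signal model

`generate_recording()` builds each channel as a sum of band-limited
stochastic oscillators (white noise shaped in the frequency domain,
normalized to unit SD) plus deterministic event templates:

* **Occipital/parietal EEG (O1, O2, P4, C3).** An alpha-band (8–13 Hz) and
  a theta-band (4–8 Hz) oscillator whose amplitudes follow per-level
  schedules: alpha falls and theta rises with fatigue, so the theta/alpha
  band-power ratio increases monotonically with level. O1/O2 carry the
  full contrast, P4 80 % and C3 50 % of it, emulating the posterior
  dominance of the alpha rhythm.
* **Frontal EEG (Fp1, Fp2).** A weak alpha component plus smooth biphasic
  blink transients whose rate decreases with level. Blink onsets share a
  refractory gap of two template lengths, as real blinks do; the
  pre-blink ("clean") frontal signal is retained on the object so blink
  suppression can be validated against ground truth.
* **ECG.** A periodic QRS-like template at a heart rate that slows with
  level.
* **EMG.** A noise floor with high-variance movement bursts (steering
  corrections) whose rate decreases with level.
* **Respiration.** A slow sinusoid whose amplitude is clipped by a
  fraction that grows with level (shallow, flattened breathing).

EEG is sampled at 250 Hz and the auxiliary channels at 120 Hz. All
randomness passes through a single seed; identical `(config, seed)`
reproduce bit-identical arrays.

**Calibration.** The magnitudes of these signatures are not published
quantities; the defaults are calibration choices made once: adjacent
levels overlap in any single realization, extreme levels separate
cleanly, and the default schedules are strong enough that the reference
CNN reaches at least 0.80 held-out five-class accuracy at desk scale
(100 epochs per class). After min–max normalization the absolute
amplitude information is discarded, so classes are distinguished by
spectral shape alone — an intentionally conservative design.

**What the generator does not emulate:** volume conduction and channel
correlation, subject-level variability, non-stationarity within an epoch,
realistic artifact diversity (movement, electrode pops), or 1/f
background spectra. Passing tests therefore demonstrate that the
pipeline's machinery is correct and that it recovers a known spectral
class structure; they say nothing about accuracy on real recordings.

## Preprocessing

`preprocess_pipeline()` applies, in order:

1. **Middle window** — the centered `window_s` (default 15 s) of the
   recording, cut per channel at its own sampling rate; 0-based half-open
   sample windows, so a 300 s recording yields EEG indices
   `[35625, 39375)`.
2. **Mains notch** — second-order IIR notch at 50 Hz (quality factor 30,
   bandwidth ≈ 1.7 Hz), run forward–backward so event morphology is not
   phase-distorted. The mains frequency is a parameter for 60 Hz grids.
3. **Band-pass** — first-order Butterworth, 0.05–60 Hz, also zero-phase.
4. **Blink suppression** — on the frontal channels, supra-threshold
   transients (|robust z| > 6 on the MAD scale) are grouped into events;
   each event is aligned to the canonical blink template by maximizing the
   matched-filter response and a least-squares-scaled template is
   subtracted. A blink-free signal has no detections and passes through
   unchanged. This deterministic operator replaces toolbox-style blink
   removal so that its behaviour is fully testable against the paired
   clean signal.
5. **Min–max normalization** — each channel mapped linearly to [0, 1].
   A constant channel maps to all zeros (declared convention).
   Normalization is per channel per epoch; normalizing across channels
   instead would preserve inter-channel amplitude ratios, which the
   synthetic classes do not rely on.

The selected analysis channels default to P4, C3, O1, O2. The chain is
fully deterministic, and the filter stages are linear, both of which are
tested as properties.

## GAN augmentation

The generator maps a 100-dimensional uniform latent vector through fully
connected blocks of widths 128, 256, 512, 1024 and 3750 (leaky-rectifier
hidden units) to a signal of length 3750; the output unit is a logistic
sigmoid because augmentation runs after normalization, so real epochs
live in [0, 1]. The widths are treated as fully connected layer sizes: a
scalar width sequence does not define convolutional feature-map
arithmetic, and the fully connected reading reproduces the stated
input/output shapes exactly. The discriminator has five fully connected
layers (1024/512/256/128/1) with dropout (0.3) after layers 1 and 3 and a
sigmoid output clamped to `[1e-7, 1 - 1e-7]`.

Training is plain alternating SGD (learning rate 1e-5, batch 10, 200
epochs at full scale), with `k_disc` discriminator steps per generator
step. The generator loss defaults to the non-saturating form
`-mean log D(G(z))`, the standard remedy for vanishing early-training
gradients; the saturating minimax form is available by flag and both
closed forms are unit-tested. One GAN is trained per class;
`augment_dataset()` grows a dataset to a target size with proportional
class allocation, flags generated epochs as `synthetic`, and never
mutates real epochs. Whether an augmentation target refers to one class
or the whole dataset is left to the caller — both the per-class
generators and the target count are explicit arguments.

## The T2F activation

The activation literature for this architecture family specifies only
that an interval type-2 fuzzy unit with `3C` learnable parameters (`C` =
number of hidden channels) replaces the rectifier; the concrete form used
here is an interval type-2 fuzzy rectifying unit:

$$y = x \left[ \alpha\,\sigma(a(1+\delta)x) + (1-\alpha)\,\sigma(a(1-\delta)x) \right]$$

with one triple $(a_c, \delta_c, \alpha_c)$ per channel: $a_c > 0$ the
membership slope, $\delta_c \in [0,1)$ the half-width of the footprint of
uncertainty (the band between the upper membership $\sigma(a(1+\delta)x)$
and the lower membership $\sigma(a(1-\delta)x)$), and $\alpha_c \in
[0,1]$ the blend between them. The form was chosen because it (i) has
exactly three parameters per channel, (ii) collapses to the swish unit
$x\,\sigma(ax)$ at $\delta = 0$ and approaches the rectifier as
$a \to \infty$, so it interpolates linear, leaky and rectified behaviour
by adjusting its uncertainty traces, and (iii) is smooth everywhere.
Ranges are enforced by smooth reparameterization
($a = e^{\tilde a}$, $\delta = 0.99\,\sigma(\tilde d)$,
$\alpha = \sigma(\tilde b)$) so the optimizer works on unconstrained
scalars. Analytic gradients for the input and all three raw parameters
are verified against central finite differences.

With the default filter schedule (16, 32, 64 × 5) the network carries
3 × 368 = 1104 activation parameters.

## Architecture and input length

Each of the seven blocks is `conv1d (same padding) → activation →
maxpool(2, 2) → batch-norm`, with dropout 0.3 on the input and again
after the first block only, then a dense softmax head of width 2, 3 or 5.
The first convolution is wide (kernel 128, stride 20, 16 filters); the
remaining six use kernel 3, stride 1 (32 then 64 filters). Same-padding
convolution maps length `L` to `ceil(L/stride)` and pooling to
`floor(L/2)`.

The temporal input length is a free parameter. The canonical length
chain 2375 → 1187 → … → 18 (entering the softmax) corresponds to an
input of 47 500 samples, and the architecture-conformance tests anchor on
that chain; it is not reachable from a single 3750-sample epoch under
kernel 128/stride 20, an inconsistency in the source architecture table
that the package documents rather than hides. The default pipeline input
is the four selected channels concatenated into one vector (15 000
samples); a four-channel input of length 3750 is available via
`input_mode = "multichannel"`. The concatenated layout performed better
in pilot runs (its head sees five temporal positions rather than one) and
keeps per-channel spectral structure separated.

**First-layer initialization.** With plain random initialization the
network memorizes time-domain realizations of the training epochs (train
accuracy ≈ 0.9, held-out accuracy near chance): the discriminative
information is spectral, and nothing pushes randomly initialized wide
filters toward frequency selectivity on a few hundred examples. The
first convolution therefore defaults to a *filterbank initialization* —
Hann-windowed sinusoids log-spaced over 1.5–45 Hz, unit-normalized, with
small random perturbation — the standard learnable spectral prior of EEG
convolutional networks. The filters remain ordinary learnable weights;
`first_init = "he"` restores plain initialization.

## Training protocol

`train_config()` defaults to the tuned reference values: Adadelta,
cross-entropy loss, batch size 10, learning rate 0.001, dropout 0.3.
For the desk-scale study runs in the tests and the acceptance script the
package uses Adam at the same learning rate (Adam is inside the reference
hyperparameter search space): the learning-rate-scaled Adadelta variant
moves far too slowly to converge within a reduced-epoch budget.
Mini-batches are reshuffled each epoch, the best-validation epoch's
parameters are returned (ties broken toward the later epoch), and an
optional per-epoch learning-rate decay and early-stopping patience are
available. Fixed seeds make the whole training history bit-reproducible.

Batch-norm inference statistics deserve care in this setting: the
exponential running averages (momentum 0.9) of an early-selected best
epoch are still dominated by their initialization, which can collapse
inference-mode predictions while training-mode accuracy looks perfect.
After checkpoint selection the package therefore recalibrates every
batch-norm layer with one equal-weight pass over the training set
("precise BN"): shuffled minibatches are forwarded exactly as during
training — dropout active, batch-norm normalizing by minibatch
statistics, so the collected statistics describe the distribution the
scale/shift parameters were learned against — and the running statistics
are set to the average of those minibatch statistics. Shuffling matters:
chunking a class-grouped dataset would average nearly single-class batch
statistics, which misstate the within-batch variance of the mixed batches
seen in training.

Small-batch training with batch norm has a second failure mode: the
optimizer can settle in a basin whose features only discriminate
*relative to the minibatch statistics* — training-mode accuracy is
perfect while any fixed-statistics inference sits at chance, on the
training set too. Such runs are visible in their own validation trace
(chance level at every epoch), and `train_classifier()` responds with
automatic random restarts from a fresh derived seed (up to
`restarts = 2` by default), returning the best attempt.

Splitting is stratified 70/10/20 by default; `kfold_cv()` provides
stratified five-fold cross-validation with disjoint, exhaustive test
folds.

## Metrics and the robustness protocol

`confusion_and_metrics()` computes the confusion matrix, accuracy,
per-class one-vs-rest sensitivity/specificity/precision/F-score, their
unweighted (macro) means — the averaging scheme is a package choice —
and Cohen's kappa. `roc_ovr()` sweeps thresholds one-vs-rest and
integrates AUC by trapezoid, which equals pairwise concordance with ties
counted half; both are verified against brute-force oracles and pROC.
The "peak coefficient" among the engineered features is interpreted as
the crest factor `max(|x|)/RMS`; variance and kurtosis are population
moments (`m4/m2²`, not excess).

`add_awgn()` injects white Gaussian noise at a target SNR defined as
`10·log10(P_signal/P_noise)` with `P_signal = mean(x²)` — note that for
[0,1]-normalized epochs this includes the DC component, so a nominal SNR
overstates the ratio on the oscillatory part. Higher SNR means cleaner
signal. `robustness_curve()` corrupts every test epoch channel at each
grid SNR (multiple seeded replicates), re-applies min–max normalization
(the classifier's input contract), and reports mean ± SD accuracy per
(variant, SNR). The infinite-SNR entry bypasses the noise path entirely
and reproduces clean accuracy exactly. Degradation ordering between
activation variants under heavy noise is reported, never asserted as a
hard test.

## Problem sizes and numerical choices

The test suite and `scripts/acceptance.R` run the full study at desk
scale, chosen as the package's own working sizes: 100 recordings per
class for the five-level scenario (500 epochs of 15 s; 40 training
epochs), 50/class for two-level and 60/class for three-level; the
robustness protocol uses the two-level scenario at 50/class with an SNR
grid of ∞, 30, 25, 20, 15, 10 dB and four noise replicates. At these
sizes the five-level run reaches roughly 0.9 held-out accuracy (the test
suite requires at least 0.80), and the GAN distribution check trains a
reduced generator (latent 16) on a sinusoid family for 600 epochs and
compares band-power distributions by the two-sample KS statistic against
an untrained baseline.

Other numerical conventions: probabilities clamped at 1e-7 in the GAN;
softmax stabilized by max subtraction and cross-entropy clamped at 1e-12;
batch-norm epsilon 1e-5; constant signals min–max-normalize to zero;
EDF export quantizes to 16 bits with physical limits taken from the data
range (round trip is exact to within one quantization step); all stage
seeds derive deterministically from a single global seed so any stage can
be reproduced in isolation.

## Known limitations

* The synthetic generator's realism limits, listed above, bound what any
  green test implies about real EEG.
* The T2F functional form is the package's own concrete instantiation of
  an interval type-2 fuzzy activation; other three-parameter forms exist.
* The GAN is a plain fully connected, SGD-trained design; it matches
  coarse spectral statistics at small scale but is not a
  state-of-the-art time-series generator, and no Wasserstein or
  gradient-penalty variants are provided.
* The epoch-dataset container is an RDS file with a JSON manifest —
  portable across R sessions, not across languages.
* Training runs on a single CPU thread through BLAS matrix products;
  full-scale (thousands of epochs, hundreds of training epochs) runs are
  feasible but slow.
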