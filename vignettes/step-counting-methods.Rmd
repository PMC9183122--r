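---
title: "Counting steps by classifying left and right: models, training and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting steps by classifying left and right: models, training and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the approach

Wearable accelerometers are the one sensor available on essentially every
wrist device and phone, and the cheapest to run continuously — which is why
clinically deployable step counting should use the accelerometer alone.
The difficulty is that raw tri-axial acceleration is device- and
orientation-specific: the same walk recorded by a watch and by a phone in a
pocket produces signals with different axes, offsets and scales, and
manufacturer pedometers are opaque and uneven in quality.

`steplr` implements a two-stage approach. A classifier first labels every
instant of a walk as belonging to a *left* or a *right* step, using only a
short window of the preceding signal. Steps are then counted as
*transitions* between the two sides. The division of labor matters: the
per-instant classification can be mediocre (a systematic lag of a few
samples, or even flipping every label, leaves the transition count intact),
so the derived count is far more robust than the classification itself.
The test suite demonstrates this constructively: complementing every
predicted label drives classification accuracy to 0% while the step count
is unchanged.

Two accuracy metrics quantify the stages:

* step classification accuracy \(= 100 \cdot n_\text{correct} / N\) over
  per-window left/right labels;
* step-count accuracy
  \(= \left(1 - |c_\text{pred} - c_\text{true}| / c_\text{true}\right)
  \cdot 100\),
  symmetric in the error's direction and negative once the error exceeds
  the true count.

## Features and windowing

Recordings are uniformly sampled tri-axial acceleration in g, resampled to
the canonical 15 Hz model rate when they arrive faster (most modern
wearables record at 50 Hz). Two input representations are supported:

* **RAW3** — the three raw channels;
* **ENMO1** — the Euclidean norm minus one,
  \(\sqrt{a_x^2 + a_y^2 + a_z^2} - 1\),
  an orientation-robust scalar that removes the static gravity component no
  matter how the sensor is mounted. Negative values are kept (no clipping):
  a resting sensor reads exactly 0, and sub-1-g instants remain
  informative. ENMO is rotation invariant by construction, which is exactly
  what transferring across devices needs.

Training examples are *stride-1 sliding windows* labeled with the step side
of the window's **last** sample. Labeling by the last sample rather than the
window majority keeps the label well defined no matter how many steps a
window spans, and turns the task into "which side is stepping *now*, given
the recent past" — so windows can be long enough for the network to exploit
long-range rhythm. Defaults are 2 s (30 samples) for the recurrent model
and 4 s (60 samples) for the convolutional ones. No per-window
normalization or standardization is applied (a config flag exists, off by
default).

## The three classifiers

All three map a window to a two-class softmax and were deliberately kept
small:

* **CNN** — one convolution (256 filters, kernel 6, stride 1, ReLU, valid
  padding, no pooling), dropout 0.4, flatten, dense 128 (ReLU, dropout
  0.4), dense 2. Roughly 1.8 M parameters.
* **WaveNet-style** — two residual blocks of three dilated *causal*
  convolutions (32 filters, kernel 6, dilations 1, 2, 4), each layer with
  the gated activation \(\tanh(u) \odot \sigma(v)\) and a residual add
  (1×1 projection where channel counts differ); no skip connection from the
  input; dropout 0.4; flatten; dense 2. Dilation doubles each layer's
  receptive field at constant cost.
* **LSTM** — two LSTM layers of 256 and 128 cells (tanh output, sigmoid
  recurrent activations), both returning their *full output sequence*;
  the sequence is flattened into a dense-128 (ReLU) head and a dense-2
  output. Feeding the whole sequence rather than the last step improves
  gradient flow to early time steps.

Because no deep-learning framework is part of the package's dependency
footprint, the computational graph — forward passes and exact backward
passes for every layer, softmax cross-entropy, and Adam — is implemented in
the package itself as batched BLAS matrix algebra, with small C++ kernels
for the element-wise hot spots (bias+ReLU, dropout masks, in-place Adam
updates). Every layer's analytic gradient is verified against central
finite differences in the test suite, and the total parameter counts of all
default configurations are asserted against closed-form hand counts.

Design points that were genuinely open, and the choices made:

* *LSTM head over the output sequence*: flatten was chosen (a `"last"`
  head is available behind a flag). Flattening keeps one label per window
  while letting the head see every time step's output.
* *WaveNet dilation rates*: 1, 2, 4 within each block, consistent with
  each layer doubling its receptive field.
* *Padding*: causal for the WaveNet stack (its defining property —
  predicting the current step side from past signal), valid for the shallow
  CNN. The diagnostic `"last"` head makes the receptive-field claim
  testable: perturbing samples outside the final position's receptive field
  provably cannot change the output, and the suite checks exactly that.
* *Dropout placement*: rate 0.4 on convolutional and first dense layers,
  never on the 2-unit output (dropout on a softmax output is degenerate).
* *Residual projections*: a 1×1 linear projection on the residual path
  when channel counts differ, identity otherwise.
* *Initialization*: Glorot uniform everywhere, LSTM forget-gate bias 1,
  deterministic per seed.

## Training protocol

Adam (learning rate 0.001, \(\beta_1 = 0.9\), \(\beta_2 = 0.999\),
\(\epsilon = 10^{-7}\), no amsgrad), categorical cross-entropy, batch size
256 for the convolutional models and 512 for the LSTM, at most 50 epochs
with early stopping at patience 10 — monitoring *validation
step-classification accuracy* rather than loss, because accuracy is what
the downstream count cares about. The weights of the best validation epoch
are restored. These are the package defaults in `train_config()`.

Validation is always *subject-wise*: `split_subjects()` partitions people,
never windows, so no individual leaks across the split (asserted in every
cross-validation iteration). The canonical protocol holds out 2 of 30
subjects and repeats over shuffled splits (70 iterations by default);
iteration *i* derives every stochastic choice from `seed + i`, so a whole
cross-validation is reproducible from one master seed.

## Personalization (domain adaptation)

A general model can fail on subjects whose gait or device differs from
anything in training. `adapt_model()` fine-tunes *all* weights, starting
from the pretrained state, on windows drawn exclusively from a short
labeled span — by default the first 30 s, mirroring a calibration walk at
the start of a session. Adaptation uses the same Adam settings with at most
30 epochs and patience 5 monitored on the adaptation windows themselves
(30 s of data cannot spare a held-out set); full fine-tuning was chosen
over freezing early layers (a freeze flag exists). Evaluation uses only
the remainder of the recording; the adapted span is recorded on the model
handle and `evaluate_adapted()` refuses overlapping evaluation spans.

## The synthetic gait simulator

`simulate_subject()` generates labeled walking recordings so the entire
pipeline is testable offline: a constant 1 g gravity vector at an arbitrary
orientation, one raised-cosine acceleration burst per step (width
0.25/cadence seconds, directed along a fixed mix of the gravity axis and a
tangential axis; `"pocket"` placement uses a different mix than
`"wrist"`), alternating left/right with every second step's amplitude
scaled by the asymmetry ratio, per-step timing jitter, white sensor noise,
and an optional stand-still prefix. Labels alternate at step onsets and the
returned ground-truth count is by construction the transition count of the
emitted labels. Default study conditions: six-minute walks at 15 Hz,
cohort cadences drawn from 1.6–2.2 steps/s, asymmetry 0.6–0.8, noise
0.05 g, amplitude 0.8 g.

What the simulator emulates is the *structure* that makes left/right
classification possible in real wrist data — the instrumented arm swings
harder — plus the nuisances that make transfer hard (orientation,
cadence, timing jitter, noise). What it does **not** emulate: biomechanical
waveform detail, device-specific noise spectra and saturation, non-walking
activity, turns and pauses. Passing the synthetic end-to-end tests
therefore demonstrates that the machinery (windowing, optimization,
counting, adaptation) recovers known ground truth under realistic signal
structure; it does not certify accuracy on any particular real device, for
which labeled recordings remain necessary. Stand-still spans have no label
class of their own (the scheme is binary), so prefix samples carry the
first step's side and evaluation harnesses trim them.

## Numerical choices

* **Resampling**: when downsampling, a zero-phase fourth-order Butterworth
  low-pass at the target Nyquist is applied on a reflection-padded signal
  (no phase shift, no edge transients), then cubic-spline interpolation
  onto a uniform grid spanning the original duration. Spline rather than
  linear interpolation keeps the down/up round-trip error of walking-band
  sinusoids below 0.01 g at a 15 Hz grid, which linear interpolation cannot
  achieve (its error bound \(f''h^2/8\) is already ≈ 0.02 g for a 1 Hz
  sine at \(h = 1/15\) s).
* **Ties**: an exactly 50/50 softmax resolves to "L"; annotation events
  exactly on a sample timestamp label that sample.
* **Degenerate inputs**: empty or length-1 label sequences count 0 steps;
  step-count accuracy is undefined (error) for a true count of 0; windows
  longer than the recording, non-overlapping annotations, and non-finite
  training losses raise immediate errors.
* **Determinism**: weight init, shuffling and dropout all draw from R's
  RNG under seeds derived from one master seed; repeated runs reproduce
  histories, weights and counts bit-for-bit (single-threaded BLAS).

## Problem sizes used in the shipped experiments

The full-scale synthetic experiment used by the acceptance checks and by
`scripts/acceptance.R` — 12 simulated subjects, general CNN on ENMO with
4 s windows, 10/2 subject split — trains with `max_epochs = 3`
(patience 3) rather than the 50/10 default: the synthetic cohort is
separable enough that validation accuracy plateaus within the first epoch
(≈ 96%), and three epochs keep the whole experiment at desk scale. The
50/10 protocol remains the default for real cohorts. Cross-validation
tests run at reduced `n_iter` for the same reason; the API default stays
at 70 iterations.

## Known limitations

* The engine is CPU-bound R/BLAS: fine for these small architectures and
  cohort sizes, not intended for training large models.
* Binary labels mean non-walking spans produce arbitrary (possibly
  flickering) predictions; trimming rest periods is the caller's
  responsibility. An optional majority-vote smoother exists but is off by
  default because the canonical protocol describes none.
* The LSTM is the slowest and least robust of the three models on ENMO
  input — consistent with convolutional models being preferable for this
  task — and the simulator's idealized bursts likely understate that gap.
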