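---
title: "Grouped recurrent classification of multi-lead ECGs: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grouped recurrent classification of multi-lead ECGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A clinical electrocardiogram records the heart's electrical activity
simultaneously on several leads — voltage channels that view the cardiac
vector from different directions. Diagnoses depend both on the waveform of
individual leads (a widened P wave, a deepened Q, an elevated ST segment)
and on *which* leads carry the change: anterior infarction shows in the
precordial leads V1–V4, inferior infarction in II, III and aVF. A
classifier should therefore learn per-lead features, the relationships
between leads, and do so for any number of leads, since devices in the
field record 2, 3, 8 or 12 channels.

`leadwise` implements such a classifier end to end, together with a
synthetic data generator that stands in for clinical corpora, which cannot
be redistributed.

## The model

The architecture has four stages, all implemented in this package with
hand-written forward and backward passes (no external deep-learning
runtime is used):

1. **Per-lead residual convolutional encoder.** Each lead is one *group*
   processed by a 1-D convolutional encoder: a strided stem convolution,
   residual bottleneck blocks (1×1, 1×3, 1×1 convolutions), and a final
   block whose last layer fans out into four parallel branches — a 1×3
   convolution, two 1×3 dilated convolutions with rates 2 and 3, and an
   average-pool branch with a 1×1 projection — concatenated along the
   channel axis. Every convolution is followed by ReLU and then batch
   normalization, in that order. The group count always equals the input
   lead count; no code change is needed to move between 3, 8 and 12 leads.

2. **Grouped bidirectional LSTM.** One *global* Bi-LSTM consumes the
   elementwise sum of all per-lead feature sequences. Its hidden state at
   each time step is broadcast through a *global access* connection into
   n *intra-group* Bi-LSTMs, one per lead, which additionally read their
   own lead's features. The forget gate of every cell also reads the
   previous cell memory \(C_{t-1}\) (a peephole read, realised as a dense
   block of the forget weight matrix over the concatenated gate input);
   the input, candidate and output gates read only the hidden state, the
   global hidden state (intra cells) and the features. The state update is
   the standard \(C_t = f \odot C_{t-1} + i \odot \tilde C_t\),
   \(h_t = O_t \odot \tanh(C_t)\).

3. **Attention pooling.** Every Bi-LSTM (the global one and each of the n
   intra ones) owns its own attention instance. Per sequence,
   \(h_t\) is the sum of the two directions' hidden states at step *t* and
   *F* is the sum of the two directions' terminal states; scores
   \(h_t' = h_t^\top U F\) pass through a shift-invariant softmax to give
   the attention distribution \(a\), and the pooled feature is
   \(F_{nn} = \sum_t a_t h_t\) — a convex combination of the per-step
   states.

4. **Two task heads.** The n+1 pooled features are concatenated and fed to
   two affine softmax heads: a coarse head over {N, AR, MI, VH, AH} and a
   fine head over 15 subtypes. Both tasks train jointly on
   \(L = \lambda L^{(1)} + (1-\lambda) L^{(2)} + \lambda_{reg}\lVert W\rVert_2^2\)
   with \(\lambda = 0.2\) by default, so the fine-grained task dominates.

**Dynamic class weighting.** Clinical ECG corpora are heavily imbalanced
(normal rhythm alone is about 61% of records). Instead of resampling, each
mini-batch reweights its cross-entropy per class as
\(c_k = 1 - \text{count}_k/M + \xi\) with \(\xi = 0.01\): a class filling
the whole batch gets weight exactly \(\xi\), an absent class \(1 + \xi\),
and weights decrease strictly in the class's batch count. Weights are
computed independently per task from that task's labels, every batch. The
loss is the batch *sum* (not mean) of the weighted terms, as the weighting
rule is stated; the default learning rate (Adam, 1e-3 to 3e-3 at desk
scale) is calibrated to that convention.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `l_win` | 1900 samples | model input window; records are decimated (linear resampling) or centre-cropped to this length |
| `encoder$base_channels` | 32 | stem width; the encoder emits `4 * branch_channels` features per step |
| `encoder$block_strides` | (1, 1, 2) with stem stride 2 | total temporal reduction ×4, so `T' = ceiling(l_win / 4)` |
| `recurrent$hidden_size` | 64 | LSTM hidden/cell dimension \(D_h\) |
| `loss$xi` | 0.01 | additive constant keeping single-class batch weights positive |
| `loss$l2_lambda` | 0.01 | L2 coefficient over weight matrices (biases and normalization parameters excluded), applied once on the joint objective |
| `loss$task_lambda` | 0.2 | coarse-task share of the joint loss |
| `batch_size` | 32 | mini-batch size M used by the dynamic weights |

## Design choices where the design was open

* **Window length versus record length.** Ten seconds at 500 Hz is 5000
  samples, while the model's reference input window is 1900. How the gap
  is bridged is a genuine degree of freedom; we implement both
  `"decimate"` (uniform linear resampling, the default — cropping 3.8 s
  would discard beats the labels depend on) and `"crop-center"`
  (centred crop with symmetric zero padding), both deterministic, with
  0-based half-open window coordinates.
* **Candidate state.** The intra-cell equations reuse the symbol of the
  cell state for the pre-update candidate; we implement the standard
  candidate \(\tilde C_t\), the only reading under which the state update
  is well defined.
* **Peephole extent.** The equations place \(C_{t-1}\) in the forget gate
  only; we implement exactly that, with `full_peephole = TRUE` available
  to extend the read to the input and output gates. The peephole is a
  dense weight block, not a diagonal, matching the written matrix form.
* **Backward-direction wiring.** The backward global hidden state at time
  *t* feeds the backward intra cells at the same time *t* (mirror of the
  forward direction), and intra cells receive the global hidden state
  computed *at* the current step (the global cell updates first).
* **Attention pooling sum.** The pooled feature is a single sum over time
  steps; the "final" backward state is the backward pass's own terminal
  step, which sits at time index 1.
* **Parameter sharing.** Encoder and intra-LSTM parameters are shared
  across leads by default (`share_across_leads`, `share_intra`): sharing
  gives permutation-equivariance in the leads and fewer parameters; both
  are switchable.
* **Layer order.** Convolutions are followed by ReLU and then batch
  normalization — unusual, but implemented as specified, with
  `order = "bn_relu"` available for the conventional order.
* **Heads.** Each task head is a single affine layer before the softmax;
  hidden layers can be added by composing configs but are not the default.
* **L2 scope.** The penalty covers convolution, gate, attention and head
  weight matrices once, on the joint objective; biases and normalization
  scale/shift are excluded.

## Numerical choices

* Softmaxes (heads and attention) subtract the row maximum before
  exponentiation; attention distributions sum to 1 to 1e-12.
* Probabilities are clamped at 1e-12 before logs; the clamp is far below
  any reported loss.
* Batch normalization uses \(\epsilon = 10^{-5}\); zero-variance channels
  therefore pass through essentially unscaled. Evaluation mode uses
  running statistics (momentum 0.1), which makes inference deterministic
  and batch-size independent.
* All LSTM states start at zero; weights initialise small-uniform,
  seeded. The whole analytic backward pass is pinned against central
  finite differences in the test suite (relative error well under 1e-4 on
  every parameter family).
* Per-record seeds derive from the master seed by a fixed linear
  congruential mix modulo 2147483563, so datasets are reproducible
  record-by-record and independent of generation order.

## The synthetic generator

Each beat is a sum of five Gaussian bumps — P, Q, R, S, T — plus a flat
ST-segment shift, projected onto leads by a fixed per-lead amplitude
matrix that mimics coarse textbook morphology (dominant R in II and the
lateral precordials, deep S in V1/V2, inverted complexes in aVR). Classes
deform this template through rhythm statistics (RR mean/SD, ectopic and
dropped beats) and per-lead wave scalings following textbook lead
conventions: anterior/inferior/lateral infarction shift the ST segment in
V1–V4, II/III/aVF and I/aVL/V5/V6 respectively; ventricular hypertrophy
scales the R wave laterally (left) or in V1/V2 (right); atrial hypertrophy
widens (left), peaks (right) or does both to (biatrial) the P wave. Noise
is additive white Gaussian plus low-frequency sinusoidal baseline wander;
a powerline component exists but is off by default. The default class
prior matches a large clinical corpus: 61.10% normal, 18.14% sinus
arrhythmia, 7.72% atrial arrhythmia, and the remaining 13.04% spread over
12 classes.

What the generator does *not* emulate: realistic QRS microstructure,
inter-patient morphology variability, electrode artefacts, atrial
fibrillation's irregular baseline, or any pathophysiological dynamics. A
model that classifies these records well has demonstrated that the
architecture, gradients, weighting and multi-task plumbing work — not
that it reaches clinical performance; that requires a clinical corpus and
training at a scale (tens of thousands of iterations) outside this
package's test envelope.

## Scaled-down study sizes

The test suite exercises the full pipeline at desk scale, chosen so each
property is measured in seconds to minutes on one CPU core: records of
3–4 s at 50–100 Hz, input windows of 32–64 samples, hidden sizes 4–8,
encoders with 4–8 stem channels. The two training-based checks use (a)
200 records of a separable two-class task (normal versus anterior
infarction), 8 epochs, where training accuracy reaches ≥ 95%; and (b) the
imbalanced 15-class preset with 450 training records and 14 epochs,
evaluated on a fixed 300-record balanced set — balanced so that per-class
F1 on the 14 minority classes is estimated with usable precision — where
the median minority-class macro-F1 across three seeded runs is at least
that of the identical runs with uniform weights. Directional, stochastic
comparisons of this kind need the median across seeds because single runs
at this scale have high variance in both directions.

## Limitations

* Pure-R execution: roughly 0.3 s per 32-record batch at test scale;
  full-scale windows (1900 samples, 12 leads, hidden 64) train at minutes
  per epoch, fine for experimentation but not for large corpora.
* The dataset container is a plain-text directory (JSON metadata, CSV
  manifest and signals) plus minimal WFDB format-16 interoperability; no
  HDF5 binding is used.
* Single recurrent layer, single affine heads, no learning-rate
  schedules; the evaluation reports both macro and support-weighted
  aggregates and leaves the choice to the analyst.
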