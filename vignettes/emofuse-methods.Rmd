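---
title: "Multimodal emotion recognition from expression and EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal emotion recognition from expression and EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Dimensional affect recognition places an emotional state on two axes:
*arousal* (activation intensity) and *valence* (positivity). emofuse
implements a multimodal recognizer that reads both a facial-expression
feature stream and 32-channel EEG, discretising each axis into three
levels. The two modalities are complementary: facial features carry
valence strongly, while the EEG spectrum carries arousal — as activation
rises, beta-band (13–30 Hz) power grows and alpha-band (8–13 Hz) power
recedes, with the beta increase most visible over frontal electrodes.

The public affect corpora this class of model is usually evaluated on are
access-restricted, so the package ships a seeded synthetic generator that
reproduces exactly the statistical skeleton above. Every component is
testable end to end without any download.

# Pipeline overview

1. **EEG branch.** Raw trials are (optionally) denoised by wavelet
   soft-thresholding, cut into segments of `T` seconds (`1/T` matches the
   face frame rate), reduced to per-channel alpha/beta/theta band powers
   by Welch's method, and rendered as scalp topographies. Each topography
   is turned into an `M x N` feature matrix of local gradient-orientation
   descriptors on a fixed keypoint grid.
2. **BCN.** A bilinear convolution network maps each feature matrix to a
   feature vector: a *left* projection layer (learned `M' x M` matrices)
   recombines keypoint rows, a *right* projection layer (learned `N x N'`
   matrices) re-projects and shrinks the descriptor dimension, then a
   multichannel 1-D convolution with max-pooling and `tanh` activation,
   and two fully connected layers.
3. **Band attention.** The three per-band BCN features are combined as
   `f' = sum_i theta_i f_i` with `theta = softmax(W h_prev + b)` driven by
   the previous hidden state of the EEG-stream recurrence. A softmax is
   used here deliberately: the three bands compete for a unit budget of
   importance, and the weights are exported per segment for inspection.
4. **AM-LSTM streams.** Each stream feeds an attention-gated bidirectional
   LSTM: the input at every step is first reweighted elementwise by
   `a_t = sigmoid(W_x x_t + W_h h_prev + b)` (a sigmoid, not a softmax, so
   components are weighted independently), then passes through standard
   LSTM gate equations with inverted dropout on the emitted hidden state.
5. **Fusion.** Layer 2 merges the two hidden sequences per time step with
   `f_t = sigmoid(w [h_expr, h_eeg] + b)`; layer 3 runs another
   bidirectional LSTM over the fused sequence; its hidden states are
   mean-pooled over time.
6. **Objective.** Training minimises
   `Loss = loss_F + loss_SF + loss_DF` per head (arousal and valence):
   `loss_F` applies the additive-margin softmax (AM-Softmax) to each
   supervised feature (the two pooled stream features and the pooled
   fusion representation), `loss_SF` applies it to the subspace-fused
   feature, and `loss_DF` to the log of the averaged branch posteriors
   (decision fusion). Prediction takes the argmax of that averaged
   posterior.

## Subspace feature fusion

Features of dimension `df` are projected into `k` subspaces by learned
matrices `SW_j` (`df x dk`, `df = k * dk`). Each projected feature is
weighted by a Gaussian kernel of its distance to a learned center `M_j`,

`sw_ij = exp(-(1/df) ||f_i SW_j - M_j||^2)`,

the weighted projections are summed per subspace and the `k` subspace
vectors concatenated, conserving the input dimension. All mapping
matrices and centers are ordinary parameters trained by backpropagation
from random initialisation (scale 0.1). The subspace count `k` is a
hyperparameter; the package default is `k = 4`. The centers are one
`dk`-vector per subspace — the minimal reading consistent with the
weight formula.

## The AM-Softmax loss

For features `x` and per-class weights `w_j`, both unit-normalized,
logits are cosines; the true-class cosine is reduced by an additive
margin `m` and everything is scaled by `s`:

`L = -mean log( e^{s(cos th_y - m)} / (e^{s(cos th_y - m)} + sum_{j != y} e^{s cos th_j}) )`.

With `s = 1, m = 0` this is exactly the cosine-softmax loss, which the
test suite asserts. The exported defaults are the conventional
`s = 30, m = 0.35`. The *pipeline* configuration instead defaults to
`s = 10, m = 0.2`: with only three classes whose mean directions are
moderately separated, a margin of 0.35 cosine units at scale 30 is
frequently unsatisfiable, which flattens the loss landscape and stalls
optimisation — a well-known property of additive-margin losses on
few-class problems. Both values are plain config entries.

# Architectural readings and corrections

A few points of the underlying formulation are ambiguous or inconsistent;
the package adopts the following readings, chosen once and documented
here:

- The right projection layer multiplies on the *right* (`I_j h_{t,j}`):
  the printed form repeats the left-multiplication, but only right
  multiplication "projects each row" and reduces the feature dimension.
- The attention gate uses two distinct matrices for the input and the
  recurrent term; the printed equation reuses one symbol for both.
- The AM-Softmax denominator uses `e^{s(cos th_y - m)}` for the target
  term (the printed `+m` variant would make the loss inconsistent with
  its own numerator).
- The band-attention state `h_{n-1}` is the EEG-stream LSTM hidden state
  of the previous segment, per recurrence direction.
- The two fused streams are the facial-expression stream and the EEG
  stream (the formulation names them "RGB" and "BCN"/"depth" in places).
- The fusion network's classification layer is the cosine (AM-Softmax)
  classifier on the pooled layer-3 representation. An auxiliary
  fully-connected head trained only through the decision-fusion branch
  can acquire permuted class semantics (nothing ties its logit order to
  the labels), so the directly supervised classifier is the head.
- Decision fusion averages the posteriors of all supervised branches
  (expression, EEG, fused representation, subspace feature); `loss_DF`
  is the AM-Softmax applied to the log of that average.

# The synthetic generator

`generate_dataset()` emulates a dimensional-affect recording session:

- **EEG.** Each channel is a sum of three random-phase sinusoids per band
  (theta 4–8, alpha 8–13, beta 13–30 Hz) plus white Gaussian noise
  (`noise_sd = 0.5` uV). Band mean-square powers follow the arousal
  level: `(alpha, beta, theta) = (1.2, 0.3, 0.6)` uV^2 at level 0,
  `(0.8, 0.8, 0.6)` at level 1, `(0.4, 1.6, 0.6)` at level 2, and the
  beta amplitude is multiplied by 1.5 on the frontal group (Fp1, Fp2,
  F3, F4, F7, F8, Fz, AF3, AF4). The literature motivates the direction
  of these effects, not their size; the map is a package choice, exposed
  in `synth_config()`. Oscillator frequencies are drawn from the band
  interiors (1 Hz margin) so that finite-window spectral estimates keep
  their energy in-band.
- **Faces.** One `M x N` feature matrix per frame (defaults 12 x 16),
  equal to a valence-specific mean pattern scaled by
  `valence_effect_size = 1` plus unit-variance noise. This stands in for
  precomputed landmark descriptors; face detection itself is out of
  scope.
- **Labels and reproducibility.** Trials are assigned round-robin over
  the 3 x 3 arousal/valence grid, so cell counts never differ by more
  than one and class imbalance cannot confound the evaluation. Every
  draw derives from the root seed; the manifest records per-trial child
  seeds, and `replay_dataset()` regenerates a byte-identical dataset.

**What the generator does not model:** eye/muscle artifacts (only white
noise), non-stationarity within a trial, volume-conduction correlation
between channels, inter-subject variability, and photorealistic faces.
Passing the synthetic recovery tests therefore demonstrates that the
architecture and training machinery can extract exactly the documented
spectral/topographic structure — not that the method reaches any
particular accuracy on real recordings.

# Study conditions and numerical choices

- **Sampling/segmentation.** 128 Hz, 5 s trials, `T = 0.5` s: 64-sample
  windows give 2 Hz spectral bins, the coarsest resolution that still
  separates theta from alpha; shorter segments at this rate would not.
  10 segments per trial, matching a 2 fps face stream.
- **Spectral estimation.** Welch PSD, Hann window, 50 % overlap,
  one-sided density normalised so the band integrals sum to the signal's
  mean-square power (asserted against a direct-DFT Parseval oracle).
- **Denoising.** db4, level 4, periodized transform, universal threshold
  `lambda = sigma sqrt(2 log L)` with `sigma` from the median absolute
  deviation of the finest detail coefficients. The transform matches the
  standard periodization convention to machine precision and inverts
  exactly.
- **Topographies.** Azimuthal-equidistant electrode projection onto the
  unit disc, Shepard inverse-distance-weighted interpolation on a
  32 x 32 grid, zero outside the scalp mask, with each electrode's
  nearest pixel pinned to its exact value. IDW is constant-preserving
  and bounded by the electrode extrema, which the scalp-map tests
  assert.
- **Descriptors.** Gradient-orientation histograms (2 x 2 spatial cells,
  8 orientation bins, 8 x 8 support) on a fixed 3 x 3 keypoint grid in
  the study configuration; `build_feature_matrix()` defaults to the
  conventional 4 x 4 x 8 = 128-dimensional layout on a 5 x 5 grid.
  Descriptors are *not* contrast-normalized by default: for band-power
  maps the gradient magnitude is proportional to the band power and is
  precisely the discriminative signal; classic SIFT normalization would
  discard it. The rotation-equivariance test uses the single-cell
  descriptor where the property is exact.
- **Initialisation and conditioning.** Weights are drawn
  `N(0, 1/fan-in)`; LSTM forget biases start at 1. Inputs are
  standardized by one global mean/sd per modality computed on the
  training split and stored in the model — a shared affine shift that
  preserves every between-band and between-class contrast while removing
  the large common component that makes cosine losses ill-conditioned.
- **Optimisation.** Adam (`lr = 5e-3`, batch 30, 20 epochs, dropout 0.1)
  over all parameters jointly. Training is deterministic given the
  config seed; a non-finite loss aborts with the first non-finite stage
  named.
- **Problem sizes.** The bundled study uses n = 300 trials with a
  stratified 80/20 split, and n = 200 EEG-only trials for the
  attention-localization experiment — sizes chosen so the complete suite
  runs comfortably on a single desktop core while leaving the effects
  far from the decision boundaries of the tests.

# Evaluation

`evaluate_model()` reports, per head, recognition accuracy
`RA = N_TP / N_data`, the confusion-count F1
`2 N_TP / (2 N_TP + N_FP + N_FN)` (micro form; a macro variant is
available since the granularity used in published tables is often
unstated), and `R^2` over the ordinal levels. Attention-weight series
(`theta_alpha, theta_beta, theta_theta` per segment) are exported for any
trial via `export_attention()`.

Two properties tie the synthetic study back to the physiological
narrative, and both are asserted by the acceptance suite:

- trained on the full generator, the pipeline recovers arousal on
  held-out trials and multimodal fusion is at least as accurate as
  either stream trained identically;
- when only the beta band carries label information, the learned mean
  beta attention weight exceeds the alpha and theta weights across
  seeds.

# Known limitations

- The networks run on a small, dependency-free reverse-mode autodiff
  engine written for this package; it is single-threaded R and sized for
  desk-scale studies, not GPU workloads.
- Wavelet denoising requires the trial length to be divisible by
  `2^level` (periodized transform).
- The synthetic generator's band-power map is a stylised rendering of
  the alpha/beta narrative; absolute accuracies on it say nothing about
  restricted real corpora.
- Only soft attention is implemented; hard (sampling-based) attention is
  deliberately out of scope.
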