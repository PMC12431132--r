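---
title: "Methods: hybrid CNN-SVM drowsiness detection from EEG scalograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid CNN-SVM drowsiness detection from EEG scalograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Drowsiness at the wheel or at a control panel shows up in the
electroencephalogram (EEG) before it shows up in behaviour: as vigilance
drops, theta-band (4–7 Hz) power over central electrodes rises while the
posterior alpha rhythm (8–12 Hz) of relaxed wakefulness weakens and slows.
`drowsEEG` implements a complete detection pipeline built on that
physiology:

1. **Preprocess.** Each multichannel recording is band-pass filtered to
   0.1–30 Hz with a zero-phase linear-phase FIR filter, cut into
   non-overlapping 30-second windows on the central electrodes C3 and C4,
   and labelled by binarising the session's Karolinska Sleepiness Scale
   (KSS) rating: ratings 0–3 are *alert* (label 0), ratings 4–9 are
   *drowsy* (label 1).
2. **Time–frequency transform.** Every window is mapped to a scalogram with
   the Morlet continuous wavelet transform (CWT),

   $$W(a, b) = \frac{1}{\sqrt{a}} \sum_m x[m]\,
       \psi^*\!\left(\frac{m - b}{a}\right), \qquad
     \psi(t) = \pi^{-1/4} e^{i\omega_0 t} e^{-t^2/2},\; \omega_0 = 6,$$

   evaluated on 64 logarithmically spaced scales whose pseudo-frequencies
   $f = \frac{\omega_0}{2\pi} \cdot \frac{f_s}{a}$ span 0.5–30 Hz. The
   log-magnitude grid is rendered as an RGB image through a fixed
   perceptually uniform colormap, stored at 256×256 and fed to the network
   at 64×64 after bicubic resizing.
3. **Feature extractor.** A small 2D convolutional network:
   `[conv 3×3 (ReLU, 'same') → maxpool 2×2 → dropout 0.25] × 2` with 16 and
   64 filters, then `flatten (16·16·64 = 16384) → dense 128 (ReLU) →
   dropout 0.5 → dense 1`, trained end to end with a sigmoid/binary
   cross-entropy head (Adam, learning rate $10^{-3}$, batch 32, up to 50
   epochs, early stopping with patience 10 on a stratified 10 % validation
   split). The depth is a parameter: `cnn_config(n_conv_blocks = d)` builds
   the whole family, with filter widths doubling from 16 and capped at 128.
4. **Classifier head.** The 128-dimensional penultimate activations are
   standardised (training statistics only) and classified by a soft-margin
   SVM. The radial basis function kernel
   $K(x, x') = \exp(-\gamma \lVert x - x' \rVert^2)$ with $C = 1$,
   $\gamma = 0.4$ is the default; `grid_search_svm()` tunes $C$ and
   $\gamma$ by stratified 5-fold cross-validation on the training partition
   only. The drowsy class is positive throughout, and evaluation reports
   accuracy, sensitivity, specificity, precision, F1 (as percentages,
   displayed at two decimals with half-up rounding) plus ROC and
   precision–recall curves.

The hybrid split — network for representation, maximum-margin classifier
for the decision — is attractive on small EEG datasets because the SVM
head is convex, cheap to re-tune, and less prone to overfitting the last
layer than a softmax trained jointly.

```{r}
library(drowsEEG)
res <- run_drowsiness_pipeline(
  sim_config(sampling_rate = 128, session_duration = 60,
             n_subjects = 10, n_sessions_per_subject = 3),
  seed = 1, tc = train_config(epochs = 30))
res$metrics
```

## The synthetic cohort

No recordings ship with the package; `simulate_cohort()` generates them.
Each simulated session is a sum of band-limited oscillations plus a $1/f$
background:

* one oscillatory source per canonical band (delta 0.5–4, theta 4–7, alpha
  8–12, beta 13–30 Hz), built from six sinusoids at uniformly drawn
  frequencies with random phases and a slow (< 0.2 Hz) amplitude
  modulation, scaled to a state-dependent RMS amplitude in microvolts;
* pink ($1/f$) noise, independent per channel, while the oscillatory
  sources are shared across channels — homologous central electrodes are
  correlated in real recordings;
* log-normal per-subject band-gain multipliers (`subject_effect_sd`,
  default 0.2) so subjects differ reproducibly;
* a session schedule (default alert, alert, drowsy — mirroring protocols
  in which later sessions follow sleep deprivation) and a KSS rating per
  state (3 alert, 7 drowsy) that downstream code binarises like real
  annotations.

The drowsy state raises theta (5 → 15 µV) and lowers alpha (20 → 10 µV),
the signature the pipeline is supposed to detect. Everything is
deterministic given the configuration seed: per-entity seeds are derived
with an integer hash (`derive_seed`), so subject 3's session 2 is
bit-identical no matter what was simulated before it.

**Realism limits.** The generator produces stationary narrow-band
mixtures; it has no eye-blink or movement artefacts, no microsleep
transients, no non-stationary spectral drift, and its class separation is
controlled by the band-power configuration rather than by biology. It
validates the machinery (filters, transform, learning, evaluation
plumbing) and gives honest chance-level behaviour under shuffled labels,
but accuracy obtained on it says nothing about performance on clinical
recordings.

## Numerical choices

* **FIR design.** A single windowed-sinc band-pass with a sharp 0.1 Hz
  edge at 512 Hz would need tens of thousands of taps. The filter is
  instead the cascade of a Hamming high-pass whose transition spans from
  DC (cutoff 3·low) and a Hamming low-pass at 30 Hz, convolved into one
  symmetric (linear-phase) tap vector. The measured response is within
  1 dB of unity on 1–25 Hz, at least 40 dB down at 45 Hz and above, and
  rolls off monotonically below 0.1 Hz.
* **Zero-phase filtering.** Forward–backward filtering of a linear-phase
  FIR equals a single centred convolution with the autocorrelated taps;
  `apply_filter()` does exactly that via FFT with edge-reflection padding,
  so filtering is applied once per recording, before segmentation, and
  introduces no group delay.
* **CWT.** Direct evaluation of the inner-product sum is quadratic per
  scale. `cwt_morlet()` evaluates it as FFT convolution with sampled,
  scale-normalised Morlet kernels (support ±6 standard deviations),
  caching kernel FFTs per segment length and scale ladder.
  `cwt_morlet_direct()` keeps the brute-force sum as an oracle; the test
  suite requires agreement to a relative error of 1e-3 (measured ~1e-9).
* **Bicubic resizing** uses the standard cubic-convolution kernel
  (a = −0.5) with pixel-centre alignment and clamped edges, implemented as
  two cached interpolation matrices applied in the cheaper order.
* **The network engine is plain R.** No deep-learning framework is
  required: convolutions are im2col reshapes followed by BLAS matrix
  multiplication, max-pooling is a `pmax` over strided slices with
  single-argmax gradient routing, and Adam/binary cross-entropy are a few
  lines each. Gradients are verified against central finite differences in
  the tests. This keeps the package dependency-light at the cost of speed;
  the default problem sizes are chosen accordingly.
* **SVM.** The dual solver is libsvm via `e1071`, wrapped so that features
  are standardised with training statistics, the positive class is always
  drowsy regardless of class order, and boundary ties go to the alert
  class. The tests compare decision values against an independently
  implemented SMO solver on small problems.

## Problem sizes

The published-scale protocol (14 subjects × 3 sessions × 10 min at 512 Hz,
5040 scalograms balanced to 6720) is expressible — `sim_config()` defaults
to it — but training the pure-R CNN at that scale takes hours. The test
suite and the acceptance script therefore run a reduced cohort chosen as a
package default for CI-sized budgets: 10–14 subjects × 3 sessions × 60 s
at 128 Hz, 30 training epochs, which finishes in a few minutes and still
reaches > 90 % test accuracy with a chance-level shuffled control.

## Design decisions worth knowing

* **'Same' convolution padding** is used in every block so that two
  pool-by-2 stages map 64×64 inputs to the 16×16×64 = 16384-unit flatten
  stage of the canonical architecture.
* **Balancing order.** `balance_by_augmentation()` raises the minority
  (drowsy) class to parity *before* the pooled 70/30 split, matching the
  protocol the headline numbers come from. Augmented scalograms are
  near-duplicates of originals (half-overlap re-windowing of the source
  signal when available, small circular time shifts otherwise), so this
  order can leak information across partitions;
  `run_drowsiness_pipeline(augment_after_split = TRUE)` restricts
  augmentation to the training partition, and `split_spec(mode =
  "leave_subjects_out")` removes subject-level leakage entirely. Both
  alternatives are provided deliberately and reported honestly rather than
  silently substituted.
* **Metrics with empty denominators** (e.g. precision with no positive
  predictions) are `NA`, printed as `n/a`, never `NaN` or an error.
* **KSS binarisation** treats rating 4 and above as drowsy; ratings must
  be in 0–9 and missing ratings are an error rather than a silent drop.
* **Every stochastic stage is seeded** from one global seed through
  `derive_seed()`, so a pipeline run is reproducible from its argument
  list alone, and the CLI writes `run_config.yaml` next to every artifact.
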