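---
title: "Methods: camera-based vital-sign fusion with rppgtwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: camera-based vital-sign fusion with rppgtwin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rppgtwin)
```

## The problem and the pipeline

Remote photoplethysmography (rPPG) recovers cardiovascular signals from
ordinary camera video: each heartbeat changes facial blood volume, which
changes skin colour by an amount invisible to the eye but measurable in the
green channel of an RGB sensor. `rppgtwin` implements a complete
machine-learning pipeline on this principle — a "digital twin" of a
person's vital signs that estimates heart rate (HR, beats/min), breathing
rate (BR, breaths/min) and blood-oxygen saturation (SpO2, %) concurrently
from one facial video stream.

The pipeline has five stages, each a package module:

1. **Trace extraction** (`extract_traces()`): face detection and alignment,
   68-point landmarks, three regions of interest (both cheeks and the
   forehead — the skin patches where the haemoglobin absorption bands give
   the strongest pulse signal-to-noise), per-frame green-channel averaging,
   and buffering into 150-sample windows.
2. **Synthetic data** (`synth_ppg_trace()`, `synth_face_video()`,
   `synth_dataset()`): a generator with exact ground truth, so every later
   stage is testable without any proprietary video corpus.
3. **Data engineering** (`load_trace_files()`, `clean_traces()`,
   `split_subjectwise()`, `summarize_traces()`): aggregation, validity
   screening, and leak-free subject-disjoint splitting.
4. **Regression** (`xgb_spec()` / `mlp_spec()` / `lstm_spec()`,
   `train_model()`, `predict()`): three model families, each mapping one
   150-sample trace to one bio-signal value; one model per signal per
   family.
5. **Runtime** (`run_twin()`): the deployed loop emitting fused readings
   every 30 frames, with offline ground-truth comparison.

## Extraction design

**Windowing.** A window holds 150 samples; at the nominal 30 FPS it spans
exactly `buffer_fill_time(150, 30)` = 5 s, long enough for at least one
breathing cycle and typically five cardiac cycles. Batch extraction uses
0% overlap: adjacent windows share no samples, and the trailing partial
window is discarded. The sampling rate is the camera frame rate; with the
detection ceiling at 180 BPM (3 Hz), the Nyquist limit puts the minimum
usable frame rate at `nyquist_policy(180)$min_fps` = 6 FPS. Below that the
package warns and proceeds (frame rate is a property of the source, not a
hard precondition), but cardiac content above fps/2 is irrecoverable.

**AC component.** The pulsatile ("AC") part of a trace is defined as the
window minus its own mean. This is the simplest DC-removal consistent with
per-window processing; it is idempotent and makes every emitted trace sum
to zero, which the tests assert to float tolerance. No detrending or
band-pass filtering is applied — a deliberate minimalism that keeps the
extraction contract exactly checkable.

**ROI geometry.** The standard 68-point annotation does not prescribe
which landmarks bound the cheeks or forehead, so the package fixes its own
constants (`roi_constants()`): each cheek is the convex hull of five
jawline points, the nearest nose-flank point and the mouth corner on that
side; the forehead is the rectangle spanning the brows horizontally and
extending upward by 0.6 × the brow-to-eye distance. The constants are
configurable, deterministic, translation-equivariant, and exclude the eyes
and mouth by construction. The synthetic generator uses the same template,
so fixture tests have exact expected geometry.

**Detection gaps.** Frames with no detectable face contribute no samples.
Additionally, a partially filled window is flushed when the face is lost,
so no window ever stitches samples across a tracking gap — the
conservative reading of a tracker that "resets" on loss. A 300-frame clip
with one missing frame at position 100 therefore yields one window
(frames 101–250), not two.

**Alignment.** If the inter-ocular axis of a provisional landmark pass is
rotated beyond a threshold (default 5°), the face crop is rotated upright
about the box centre, the landmarker is re-run, and points are mapped back
through the exact inverse rotation. Pixel resampling is nearest-neighbour;
sidecar landmark metadata is transformed with the exact affine map so the
fixture path stays consistent with the pixels.

**Conventions.** All frames are RGB arrays on the 0–255 scale (BGR-native
decoders must swap at the boundary — this is where green/blue mix-ups are
prevented); coordinates are 0-based and pixel-centred; masks use even-odd
polygon rasterization with a 10⁻⁷ tie-break offset so edge-on-centre
pixels resolve deterministically.

## The synthetic world

The generator produces the raw green-channel intensity of a facial skin
patch as

$$ s_t = DC + A\,g(\mathrm{SpO2})\sin(2\pi f_{hr} t/\mathrm{fps})\,
   \bigl(1 + 0.1\,\sin(2\pi f_{br} t/\mathrm{fps})\bigr)
   + R\,\sin(2\pi f_{br} t/\mathrm{fps}) + \epsilon_t $$

with cardiac frequency $f_{hr}$ = HR/60, respiratory frequency $f_{br}$ =
BR/60, additive Gaussian sensor noise $\epsilon_t$, and a respiratory
influence entering twice: as baseline wander (amplitude $R$) and as a 10%
amplitude modulation of the pulse.

**Defaults and why.** DC = 120 counts (the green component of a mid-tone
skin colour), pulse amplitude 5 counts (small against DC, as real rPPG
pulsatility is), respiratory wander 2 counts, noise SD 1 count. The
profile sampler draws HR uniformly on [47, 180] BPM, BR on [10, 27]
breaths/min and SpO2 on [90, 100]% — the full validity intervals rather
than the narrow clinical mode, deliberately exercising the range where
errors grow. Ranges, seeds and amplitudes are fixed properties of this
stated world; they are not tuned against test outcomes.

**SpO2 coupling.** Green-channel video carries no physical SpO2 signal
(oximetry needs two wavelengths). To keep the SpO2 regression path
exercisable, the generator couples SpO2 to the effective pulse amplitude
through a documented monotone gain, $g = 0.4 + 0.06\,(\mathrm{SpO2}-90)$,
rising from 0.4 at 90% to 1.0 at 100%. This is a test scaffold, not a
physiological claim: a green SpO2 test proves the machinery recovers an
amplitude-coded parameter, nothing more.

**Waveform shape.** Sinusoids rather than realistic skewed PPG pulses:
the spectral ground truth is then exact and closed-form, so the
extraction-fidelity oracle ("dominant FFT frequency within one bin of
HR/60") is airtight. The phase is fixed at zero — all generated windows
are phase-aligned. What the generator does *not* emulate: realistic pulse
morphology, motion and illumination artifacts, compression noise,
photorealistic faces, multi-face scenes. A green test here establishes
that the pipeline's mechanics are correct on signals of known structure;
it says nothing about accuracy on real video.

**Face clips.** `synth_face_video()` renders a rectangular skin patch on a
static background; the whole patch's green channel follows $s_t$
uniformly, so the mean green over any region inside the face reproduces
the generating waveform exactly. Frames render lazily and
deterministically from the seed (byte-identical across calls). A JSON
sidecar carries the face box, the 68 template landmarks and the
per-window ground truth, which is what the fixture detector and
landmarker read.

## Data engineering

**Cleaning.** Validity intervals: HR ≤ 180 BPM (above is an outlier), BR
in [10, 27] breaths/min, SpO2 in [90, 100]%. "Rows with zero values" is
read as: any present ground-truth field equal to zero, or an all-zero
trace — both footprints of extraction failure. A rule only applies when
the relevant ground truth is present; a record that legitimately lacks BR
truth is not removed by the BR rule. Each removed record is attributed to
the first rule it violates (zero-row, HR, BR, SpO2), so removal counts
plus survivors always equal the input count, and cleaning is idempotent.

**Splitting.** The 60/20/20 split is by *samples* but the unit of
assignment is the *subject* (all of a person's records land in one
partition — identity leakage across partitions would inflate every
downstream score). Since subjects contribute unequal record counts, exact
fractions are a packing problem; the package assigns subjects
largest-first to the currently most-underfilled partition. This is
deterministic for a fixed seed (the seed only shuffles ties), and the
tests verify it stays within 0.05 of the exhaustively optimal maximum
deviation on small instances, and within 0.1 of the targets across 100
seeds at 20 subjects.

**Summaries.** The EDA profile (count, mean, SD, five-number summary per
signal) uses linear interpolation between order statistics
(`quantile` type 7), the convention of mainstream EDA tooling; a
single-observation group reports SD 0 with a warning.

## Regression models

The environment provides no gradient-boosting or deep-learning library,
so all three families are implemented in the package (the tree learner in
C++ via Rcpp, as boosting implementations universally are; the neural
models as hand-derived matrix code verified against numerical gradients).

**Boosted trees** (`xgb_spec()`): second-order gradient boosting with
squared-error loss — per round, gradient $g_i = \hat y_i - y_i$ and
hessian 1; exact-greedy splits maximize
$\tfrac12\bigl(G_L^2/(H_L+\lambda) + G_R^2/(H_R+\lambda) -
G^2/(H+\lambda)\bigr) - \gamma$ and leaves take $-G/(H+\lambda)$. The
learner is fully deterministic (ties resolve to the lowest feature index
and threshold); the recorded random state is metadata. Early stopping
monitors validation MAE and keeps the best round. Tuned per-signal
defaults: HR 0.05/350/depth 4/50 rounds; BR 0.05/300/5/200;
SpO2 0.01/100/6/5; random state 99.

**MLP** (`mlp_spec()`): input (150) → batch normalization (replacing
manual feature scaling) → dense layers [128, 64, 32] with ReLU and
dropout 0.2 → one linear output unit. **LSTM** (`lstm_spec()`): 64
recurrent units over the 150-step sequence (one scalar per step) → batch
normalization → dense cascade [64, 32] with LeakyReLU (negative slope
0.01, the conventional default) and dropout → linear output. Both train
with Adam (step 10⁻³) on MAE loss — matching the evaluation metric — with
batch 64, at most 500 epochs, and early stopping at patience 20 on
validation loss; the layer sizes are package defaults where only layer
types and order are prescribed.

Three numerical choices worth stating: (i) hidden layers use He
(variance-scaling) initialization, standard for ReLU-family activations,
but the **output head is zero-initialized**, so the first prediction is
exactly the training-target mean — this stabilizes early training and
makes degenerate constant-target problems exact; (ii) targets are
standardized internally (train mean/SD, restored at prediction), so Adam
step sizes are scale-free across HR/BR/SpO2; (iii) batch-norm inference
uses running statistics (momentum 0.99), making predictions
row-independent — batch and single-record prediction agree bit for bit.

**One model per signal.** Fusion means running the three per-signal
models on the shared trace, not a multi-output head. Each ROI trace is an
independent training record; ROI identity is not a feature.

**Serialization.** A trained model saves as a directory bundle —
`spec.json`, `params.json`, `meta.json` (seed, stopping point, dataset
fingerprint, MD5 checksum). Parameters are written as hexadecimal
floating-point strings because decimal JSON at the library's maximum
precision still perturbs the 16th significant digit; the hex encoding
makes save → load → predict bit-identical, which the round-trip tests
assert with `identical()`. A tampered bundle fails the checksum with an
integrity error.

## Evaluation

Four metrics over ground truth $y_g$ and predictions $y_p$: MAE, MAPE
(percent scale), RMSE, and Pearson correlation computed with the sample
(n−1) standard deviation. MAPE is undefined at zero ground truth and
Pearson at constant series; both report NA with a warning rather than
silently mutating inputs — cleaning, not evaluation, owns record removal.
Model selection ranks by lowest MAPE with ties broken by higher Pearson r
(the selection criterion is a documented package choice; MAPE is the
primary comparison metric throughout).

## Runtime

`run_twin()` reconciles two stated behaviours: training windows have 0%
overlap (5 s cadence), yet the deployed system updates every 30 frames
(1 s at 30 FPS). The runtime therefore keeps a **sliding** window of the
most recent 150 valid samples per ROI, advanced 30 frames per update,
while batch extraction for training remains non-overlapping. Before the
window first fills, events are flagged `warming_up`; afterwards each
event averages the three per-ROI predictions per signal. Event time is
media time (frame index / fps), so two offline runs of one clip are
bitwise identical — an invariant under test.

A consequence worth knowing: the generator emits phase-aligned training
windows, but a sliding runtime window starts at an arbitrary phase.
Models trained on raw phase-aligned traces degrade on phase-shifted
windows (visible in the runtime summary of the acceptance script, where
mid-stream HR readings are worse than window-boundary ones). This is a
property of raw-trace regression itself — phase-invariant features or
phase-augmented training data would remove it — and is left visible
rather than patched, since the package's contract is the pipeline, not a
new estimator.

## Known limitations

- No real-video decoding in this environment: sources are synthetic
  clips, frame directories (ASCII PPM + JSON sidecar) or frame lists.
- The shipped detector/landmarker stand-ins (background-contrast blob
  detection, geometric landmark template) are adequate for synthetic and
  simple scenes only; both interfaces accept user-supplied pretrained
  backends.
- The SpO2 path validates machinery, not physiology (see above).
- Single-subject assumption throughout: multiple faces resolve to the
  largest.
- Synthetic-world scores (the tests' recovery bars, the acceptance
  script's metrics) do not transfer to real datasets; the reference
  system's published numbers require its proprietary corpora and are out
  of scope here.
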