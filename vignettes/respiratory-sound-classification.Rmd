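---
title: "Classifying adventitious respiratory sounds with time-frequency images and a Vision Transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying adventitious respiratory sounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Auscultation of the lungs reveals two broad families of sound. Normal
(vesicular) breath sounds are broadband, with most of their energy between
100 and 2000 Hz. Adventitious sounds ride on top of them and indicate
pathology: *wheezes* are continuous, tonal events with a narrowband
fundamental between 100 and 1000 Hz lasting at least 80 ms, typical of
asthma and COPD; *crackles* are transients — coarse crackles last under
15 ms with a low pitch, fine crackles under 5 ms with a high pitch — and
point to secretions, fibrosis or pneumonia. The unit of analysis is the
*respiratory cycle* (one inspiration plus expiration), annotated with two
flags (crackle present, wheeze present), which also defines a four-class
taxonomy: normal / crackle / wheeze / both.

respsound implements the full pipeline for this task: audio and annotation
I/O, four time-frequency (TF) front-ends, conversion of TF matrices to
colour images, an encoder-only Vision Transformer (ViT) classifier written
in base R, patient-wise cross-validated evaluation, and a synthetic
respiratory-sound simulator so that every stage can be exercised and tested
without access to a clinical corpus.

## Signal conventions

Recordings are downsampled to 4 kHz (the sounds of interest do not exceed
2 kHz) and each annotated cycle is forced to a fixed 6 s duration:
segments are cut with `floor(start * rate)` half-open indexing, zero-padded
at the end when short, truncated at the end when long. Trailing (rather
than centred) padding preserves the onset timing of events; trailing
truncation of over-long cycles was chosen for the same reason. Resampling
uses polyphase FIR anti-aliasing so that energy above the target Nyquist
cannot fold back into the 100–2000 Hz band of interest.

## The four time-frequency front-ends

All four produce a `tfrep`: a K×L non-negative matrix with channel
frequencies and frame times.

**STFT.** Windowed DFT magnitudes, `N/2 + 1` non-redundant bins, phase
discarded. The analysis window is not prescribed by the task, so the
package defaults to a Hann window of 84 ms (336 samples at 4 kHz) with 50%
hop — matching the cochleogram frame so the four representations cover the
same time span (their frame-time ranges agree within one hop).

**MFCC.** The Mel scale `Mel(f) = 1127 ln(1 + f/700)` warps the frequency
axis; `M` triangular filters sit with their peaks equispaced on that scale
between `fmin` and `fmax` (edge filters are half-triangles so every
support stays inside the band). Log filterbank energies (floored at
`1e-10` before the log, so silent frames degrade gracefully rather than
produce `-Inf`) pass through the DCT
`Y_n = sqrt(2/M) * sum_m S_m cos(pi n (m + 1/2)/M)`; the first `n_mfcc`
coefficients are kept. Defaults `M = 64`, `n_mfcc = 20`. Both the
coefficient matrix and the log-Mel spectrogram are exposed
(`output = "logmel"`); the coefficient matrix is the default image input.

**CQT.** Centre frequencies `f_k = f1 * 2^((k-1)/b)` share one quality
factor `Q = 1/(2^(1/b) - 1)`; atom lengths shrink inversely with
frequency. `f_k` is computed by integer octave decomposition so that
`f_(k+b) = 2 f_k` holds *exactly* in floating point. Defaults `f1 = 100`
Hz, `b = 12` bins per octave, Hann atoms, direct (non-FFT) evaluation on a
42 ms hop grid — at 4 kHz and 6 s signals a fast CQT is unnecessary.

**Cochleogram.** A bank of `K = 64` gammatone filters of order 4,
impulse response `g(t) = t^(o-1) e^(-2 pi b(fc) t) cos(2 pi fc t)` with
`b(fc) = 1.019 ERB(fc)` and `ERB(fc) = 24.7 (4.37 fc/1000 + 1)`. Centre
frequencies are spaced uniformly on the ERB-rate scale between 100 Hz and
`fs/2` (linear spacing is available behind a flag). Each channel is
FIR-filtered by truncating the analytic impulse response where its gamma
envelope falls below 0.1% of peak — deterministic and testable, with no
recursive-approximation choices — and per-channel energy is summed over
84 ms Hann frames: `C(k,m) = sum_n Xhat(k,n)^2 w(n)`, which is
non-negative and quadratic in amplitude. Frequencies below 100 Hz are
deliberately unrepresented. Two notational wrinkles in the source material
were resolved on physical grounds: the printed impulse response carries a
*growing* exponential (meaningless for a filter; the standard decaying
form is implemented), and the frame sum is printed over amplitudes while
the text describes energy (energy is implemented).

## From matrices to images

Classifier inputs are RGB rasters: magnitude/energy matrices are mapped to
decibels relative to the matrix maximum (floor −80 dB), bilinearly resized,
min–max normalized per image, and passed through the published 256-entry
viridis gradient, low frequencies at the bottom. Normalizing *after* the
resize guarantees the matrix maximum maps to the viridis endpoint
(253, 231, 37) at any raster size. The dB + per-image min–max combination
makes `to_image` invariant to positive rescaling of the input, so absolute
recording gain cannot leak into the classifier. Cepstral (signed) matrices
skip the dB step. The default raster is 224×224 (the reference ViT input);
the desk-scale profile used in the tests and the acceptance script is
64×64.

## The classifier

An encoder-only ViT. The image is cut into non-overlapping 16 px patches
(row-major), each flattened and linearly projected to `d_model`; a
learnable class token is prepended and learnable position embeddings are
added. Each encoder layer applies multi-head scaled-dot-product
self-attention and a position-wise feed-forward network (ReLU), each
sub-layer wrapped in the *post-norm* residual form
`LayerNorm(x + Sublayer(x))` — the residual convention of the original
transformer, kept as written rather than swapped for the pre-norm variant
common in later ViT implementations. The class-token output feeds a linear
head with softmax. The reference geometry is `d_model = 512`, 6 layers;
heads and feed-forward width are not prescribed, so the conventional
pairing (8 heads, `d_ff = 2048`) is the default, both configurable. A
transformer *decoder* has no role in a fixed-label classifier and is not
implemented.

Training minimizes cross-entropy with Adam (learning rate 0.001, batch 16,
30 epochs — the study protocol), with early stopping after 10 epochs
without validation-loss improvement; the validation set is carved
patient-wise (10% of training patients) so no patient leaks across splits.
Weights are truncated-normal (sd 0.02), biases zero, everything seeded:
two runs with the same seed are bit-identical. Gradients are analytic
(verified against central finite differences to better than 1e-4 relative
error) and clipped to unit global norm — post-norm transformers under Adam
are prone to late-training divergence, and clipping removes it without
touching the study's optimizer settings. Class imbalance handling is off
by default; inverse-frequency weights sit behind
`train_config(class_weights = "balanced")`. Prediction is the probability
argmax with ties broken toward the lower class index.

The desk-scale profile (64×64 images, patch 16, `d_model` 64, 2 layers,
4 heads, `d_ff` 256) trains in seconds per epoch on one CPU and is the
configuration exercised by the test suite.

## The synthetic simulator

No generative model of auscultation audio is prescribed anywhere; the
simulator is this package's own construction, constrained only by the
spectro-temporal definitions above, and it is what the tests mean when
they say the pipeline "learns": passing shows the machinery is sound, not
that clinical performance transfers.

* **Normal sound**: Gaussian noise band-passed to 100–2000 Hz (zero-phase
  Butterworth), amplitude-modulated by a two-lobe breath envelope
  (raised-cosine inspiration, longer and weaker expiration). At least 90%
  of its spectral energy lies in 100–2000 Hz by construction.
* **Wheezes**: a fundamental plus two weaker harmonics (harmonics above
  Nyquist are dropped), slow sinusoidal frequency drift, raised-cosine
  ramps. The drift is capped at ±3% even though ±5% would be admissible:
  sinusoidal FM concentrates spectral mass at the deviation extremes, and
  a ±5% drift would park the periodogram peak exactly on the ±5% tonality
  bound the generator itself promises.
* **Crackles**: exponentially damped sinusoid bursts truncated at the
  event duration. The coarse/fine pitch split is placed at 600 Hz — the
  midpoint of the shared 100–2000 Hz range — with coarse f0 drawn from
  100–600 Hz and fine from 600–1800 Hz.
* **Mixing**: per event, the gain is set so event energy over the base
  sound's energy *within the event's support* equals the configured SNR
  (default 10 dB); this makes difficulty controllable per event and
  independent of cycle length. Class proportions default to the clinical
  corpus mix (normal 0.528, crackle 0.270, wheeze 0.128, both 0.074).

Everything derives from a single integer seed; identical configurations
give byte-identical datasets. What the simulator does *not* emulate:
stethoscope/device transfer functions, heart and friction artefacts,
airway physics, inter-patient acoustic variability beyond the RNG. Held-out
accuracy on synthetic patients therefore says nothing quantitative about
clinical recordings.

## Evaluation

Binary tasks count a cycle positive when the target sound is present. The
four-class task keeps the full 4×4 confusion matrix and reduces it with
the ICBHI challenge convention: true positives are adventitious cycles
classified *exactly* right (detecting only one of two co-occurring sounds
is an error), so the reduced accuracy equals the plain four-class
accuracy. Metrics are accuracy, sensitivity, specificity, precision, and
the score `Sco = (Sen + Spe)/2`; zero-denominator cells are reported as
`NA` with a warning rather than silently zero. `check_score_consistency()`
audits printed (Sen, Spe, Sco) triples at their printed precision —
applied to the published ViT results tables it confirms the wheeze and
four-class rows and flags one crackles cell whose printed score (71.7)
disagrees with the identity (72.7).

Cross-validation is patient-wise: seeded partitions of the patients into
`k = 10` folds whose sizes differ by at most one, repeated 5 times by
default (50 fold-level points). Because the protocol is described both as
"metrics from the aggregated confusion matrix" and as "averaging per-fold
values" — which differ in general — the report carries both, with the
aggregate as the headline. Model pairs are compared with the two-sided
Mann–Whitney U test and Wilcoxon signed-rank test at `alpha = 0.05`,
exact for small tie-free samples (n ≤ 12), normal approximation with
continuity and tie correction otherwise.

## Numerical choices, sizes, limitations

* The test suite and acceptance script run entirely at the desk-scale
  profile: 200–240 six-second cycles, 64×64 images, the tiny transformer,
  a handful of seeds. These sizes are the package's reproducibility
  contract, chosen so a complete run fits comfortably on one CPU core.
* Full-corpus training (thousands of cycles, `d_model` 512, 224×224
  images) is expressible with the same API but is not what the tests
  assert; the published headline accuracies require the real clinical
  corpus and GPU-scale training and are out of scope here.
* Gammatone kernels are cached per (bank, signal length), since corpus
  featurization applies one bank to thousands of equal-length cycles.
* The log floor (`1e-10`), dB floor (−80 dB), LayerNorm epsilon (`1e-5`),
  FIR truncation threshold (0.1% of envelope peak) and gradient clip
  (unit norm) are fixed numerical guards, not tuning knobs.
* `to_image` of an all-constant matrix returns the lowest viridis colour;
  degenerate inputs (silent cycles, empty annotation files, zero-length
  events) are either handled gracefully or rejected with a named error,
  as exercised in the tests.
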