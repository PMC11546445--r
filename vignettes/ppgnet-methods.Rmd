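---
title: "Classifying blood-pressure stages from PPG scalograms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying blood-pressure stages from PPG scalograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Photoplethysmography (PPG) measures microvascular blood-volume changes
optically; the pulse waveform carries information about vascular stiffness
and blood pressure. `ppgnet` implements a complete pipeline that classifies
short single-channel PPG segments into the four clinical blood-pressure
stages — normal (N), prehypertension (P), stage 1 (S1) and stage 2 (S2)
hypertension. The pipeline has three steps: signal preprocessing, a
time–frequency transform that turns each segment into a scalogram image,
and a compact depthwise-separable convolutional network (PPG-NET) trained
on those images. A seeded synthetic cohort generator stands in for clinical
recordings so that every stage is testable end to end on any machine.

The design target is an acquisition protocol in which each subject
contributes three 2.1-second segments sampled at 1000 Hz, each saved only
when its skewness signal-quality index is positive, with a cohort of 219
subjects yielding 657 segments split 240/255/102/60 across the four stages.

## The synthetic cohort generator

`generate_cohort()` emulates that design. Each subject draws a heart rate
from a class-specific range; each beat is a two-Gaussian waveform — a
systolic peak plus a delayed, scaled dicrotic bump — laid down with ±3%
beat-to-beat period jitter, under sinusoidal baseline wander (default
amplitude 0.15 of the systolic peak, 0.15–0.35 Hz) and white Gaussian
noise (default sd 0.03). The four default class morphologies form a
monotone gradient: dicrotic-notch amplitude 0.5/0.35/0.2/0.1, heart-rate
centers 65/72/80/88 bpm (each subject within ±1.5 bpm of its class
center), systolic width 0.095–0.065 s, reflection delay 0.30–0.21 s for
N/P/S1/S2. These are *fixtures*: they give the classifier a learnable,
physiologically flavored signal (stiffer arteries mean faster, sharper
pulses with weaker reflected waves), not calibrated hemodynamics. The
heart-rate ranges are deliberately narrower than the gaps between class
centers, so that even after the ±3% per-beat jitter the classes remain
separated in effective pulse rate: the default cohort is well separated
*by design*, which is the premise of the end-to-end learnability checks.
Every emitted segment must pass the skewness gate (sample skewness > 0);
segments that fail are regenerated with a fresh beat-phase offset, at most
100 times, mirroring the acquisition protocol's saving rule.

What the generator deliberately does *not* emulate: motion artifacts,
sensor decoupling, skin-tone and perfusion variability, arrhythmias, or
any real covariance between waveform shape and cuff blood pressure.
A passing end-to-end test therefore demonstrates that the pipeline's
machinery — preprocessing, transform, leakage-free evaluation, training —
works and can learn class structure from waveform morphology; it says
nothing about clinical accuracy on real patients.

With 219 subjects the default class proportions (0.365/0.388/0.155/0.092,
apportioned by largest remainder) give exactly 80/85/34/20 subjects, i.e.
240/255/102/60 segments — the reference cohort's bookkeeping.

## Preprocessing

Each segment passes through three stages, in order: adaptive wavelet
denoising, an equiripple FIR bandpass, and 0–1 min-max normalization, so
the output always lies in [0, 1].

**Denoising.** A 5-level periodized DWT with the sym8 wavelet (least
asymmetric, 8 vanishing moments; filters hard-coded because the R stack
carries no discrete-wavelet package). All detail bands are soft-thresholded
at the universal threshold λ = σ·√(2 ln n); the noise scale
σ = median(|d₁|)/0.6745 is estimated from the *finest* band only. The
per-level alternative (σ per band) fails on clean quasi-periodic signals:
coarse detail bands carry genuine pulse energy, their median inflates σ,
and real signal content is shrunk away (we measured ~48% peak distortion
on a clean sinusoid versus ~10⁻⁹ with the finest-band estimate, while the
noisy-signal MSE reduction is unchanged). The approximation band is never
touched.

**Bandpass.** The Parks–McClellan (Remez exchange) equiripple design is
implemented in `R/remez.R` (barycentric interpolation in the cos ω domain,
with log-scaled barycentric weights so ~1000-tap designs stay finite). The
installed `signal::remez` could not produce these designs (it crashes or
returns near-zero coefficients at high orders), which is why the algorithm
is authored here; the test suite validates every design against a direct
Fourier-sum evaluation of the response. The default specification is a
1001-tap filter at fs = 1000 Hz with passband 0.05–16 Hz and stopband from
18 Hz up. One honest limitation is built into the default: a 1-second FIR
cannot realize a stopband between DC and 0.05 Hz — those frequencies fall
inside a single resolution cell, and the minimax optimum for such a
specification degenerates to |H| ≈ 0.5 everywhere. The region below the
0.05 Hz pass edge is therefore left as a *don't-care* band by default;
a genuine DC stopband (`stop_lo`) is available for configurations whose
tap budget supports it. On 2.1-s segments this is immaterial — no filter
of any kind can resolve 0.05 Hz there.

**Zero-phase application.** The filter is exactly linear-phase (type I,
enforced symmetric), so `apply_filter()` compensates the constant group
delay (numtaps−1)/2 after a single convolution. Forward–backward filtering
would also be zero-phase but its padding transients span most of a
2100-sample segment when the filter itself is 1001 taps; group-delay
compensation preserves the pulse landmarks without that cost.

**Normalization.** (x − min)/(max − min); constant segments raise a
"degenerate segment" error so callers can drop them explicitly.

## The scalogram

`cwt_morlet()` computes the continuous wavelet transform with the analytic
Morlet (Gabor) wavelet ψ(t) = π^(−1/4)·e^(iω₀t)·e^(−t²/2), ω₀ = 6 (the
standard admissibility choice). Analysis frequencies sit on a log grid
(default 12 voices/octave); frequency f maps to scale a = ω₀/(2πf); each
coefficient row is the FFT convolution of the signal with the conjugated,
time-reversed, L2-normalized scaled wavelet, with zero-padded edges and no
cone-of-influence masking, so images are fully reproducible. The magnitude
matrix with descending frequency axis is the scalogram.

A property worth knowing: with L2 (1/√a) normalization the scale response
to a pure tone is √a·ψ̂(aω), whose maximum sits a factor ≈ 1/(2ω₀²) (~1.4%
for ω₀ = 6) *below* the tone frequency. That bias is smaller than one
voice, but for tones near a grid midpoint it decides which of the two
neighboring grid frequencies wins. The test suite therefore checks
localization against a direct numerical integration of the transform
definition (the independent oracle agrees with the implementation
including this bias) and separately checks exact nearest-grid localization
for a grid-aligned tone.

`render_scalogram()` min-max scales the magnitude per image, maps it
through the viridis colormap, and bilinearly resizes to the requested
size (default 224×224; the desk-scale pipeline uses 64×64). Rendering is
deterministic to the byte. Linear rather than log magnitude is the
default; both the band and the rendering are configuration, not baked in.

The default analysis band is 0.1–50 Hz with 12 voices per octave: it
brackets the 0.05–16 Hz physiologic band with margin on both sides, and
the network tolerates the class-irrelevant baseline-wander ridge it
includes below 0.5 Hz (restricting the band was tried and bought no
reliable accuracy).

## Balancing and the evaluation protocol

Class imbalance is handled by SMOTE oversampling plus majority
undersampling. SMOTE operates in *signal space* (the preprocessed
2100-sample vectors), not on images: a synthetic record is
x + λ(x_nn − x) with λ ~ U[0,1] and x_nn one of the k = 5 Euclidean
nearest same-class neighbors — a valid signal whose scalogram is then
recomputed. Interpolating pixels of rendered images instead would mix
colormap values with no physical meaning. Every synthetic record inherits
its parent's `source_subject_id`.

That provenance drives the leakage guard. `subject_aware_split()` groups
records by source subject, shuffles subjects, and assigns
round(0.2·n) of them to the held-out test side; synthetic records always
travel with their parent. `kfold_plan()` partitions the training subjects
into five folds with sizes differing by at most one. `assert_no_leakage()`
verifies — not assumes — that the source-subject sets of the two sides are
disjoint.

Two balancing modes exist because they answer different questions.
The pipeline default balances the *training side only, after* the split:
synthetic records can then never carry test-subject information into
training. The dataset-wide mode (`balance_classes()` on the full cohort,
target 250) reproduces the reference bookkeeping in which
240/255/102/60 becomes 250/250/250/250 — undersampling the 255-record
class, oversampling the rest.

## PPG-NET

The classifier is an Xception-style three-flow network built from
depthwise-separable convolutions: a stem of two standard 3×3 convolutions
(first stride 2); entry-flow residual blocks of two separable convolutions
plus 3×3 stride-2 max pooling, with 1×1 stride-2 convolution shortcuts;
a middle flow of identity-shortcut residual blocks of three separable
convolutions; an exit flow of separable convolutions; global average
pooling; and a dense softmax head over the four stages. A separable
convolution costs Dk²M + MN parameters against Dk²MN for the standard
convolution it replaces (2336 vs 18432 at Dk = 3, M = 32, N = 64).
Batch normalization follows every convolution by default and is
switchable; with it on, convolutions carry no bias and the parameter
count is exactly the closed-form sum, which the tests verify layer by
layer. Initialization is He-style random normals — there are no published
weights for this custom graph, so no transfer learning is attempted.

The engine (standard/depthwise/pointwise convolution, batch norm,
max pooling, global average pooling, dense, softmax cross-entropy,
forward and backward) is written in RcppArmadillo, single-threaded and
deterministic given the seed; no deep-learning framework exists in this
R stack. Backpropagation is verified against central finite differences
through both the plain and the batch-norm paths. One numerical note:
underflowing gradients are flushed below 10⁻³⁰ because subnormal doubles
make BLAS kernels orders of magnitude slower while carrying no
information.

Training follows the reference protocol: SGD (momentum 0.9 — the protocol
fixes optimizer SGD, learning rate 0.01, batch size 12, 100 epochs,
5 folds, but not momentum or patience), cross-entropy loss, shuffling only
the training indices each epoch, and early stopping when validation
performance plateaus. The monitored quantity is the validation
cross-entropy (with a 10⁻⁶ minimum improvement), not accuracy: the loss
keeps improving after accuracy saturates, so the kept weights — always
those of the best validation epoch, never a later one — are the
best-calibrated epoch rather than the first epoch that happened to top
the accuracy. `crossval_ppgnet()` runs the subject-aware five-fold
protocol; `run_pipeline()` additionally evaluates the final model on the
held-out 20% of subjects. Ties at the softmax argmax resolve to the
lowest class index.

### Desk scale

The default pipeline configuration is sized for a single CPU: 40 subjects
(10 per class), 64×64 images, a reduced PPG-NET (stem 16/32, entry 48/64,
three middle blocks at width 64, exit 96 — about 72k parameters), SMOTE
target 72 per class on the training side, and at most 20 epochs. On this
cohort the trained network reaches high held-out subject-aware accuracy
in a few CPU-minutes; the full-size 224×224 configuration is the same
code and is practical on GPU-class hardware but is not what the tests run.

## Metrics

`metrics_report()` computes one-vs-rest tallies per class — TP on the
diagonal, FP the column remainder, FN the row remainder, TN everything
else — and from them accuracy (TP+TN)/total, precision TP/(TP+FP),
sensitivity TP/(TP+FN), specificity TN/(TN+FP) and F1 (the harmonic mean
of precision and sensitivity), plus overall accuracy trace/total.
Per-class accuracy is deliberately the one-vs-rest form: it is the only
reading under which per-class and overall accuracy can differ, as they do
in published per-class tables. Any 0/0 denominator yields 0 and the class
is listed in the report's `zero_denominator` flag. The implementation is
tested for exact agreement with a brute-force counting oracle on random
label vectors.

## Numerical choices and degenerate inputs

- Remez exchange: grid of ~16 points per extremal allocated by band width
  (minimum 8 per band), convergence when the extremal set repeats or the
  ripple stabilizes within 10⁻⁶; final coefficients via inverse DFT of the
  sampled cosine polynomial, symmetrized exactly.
- DWT on odd lengths: the signal is padded by repeating its last sample;
  the pad is removed on reconstruction (round-trip is exact to 10⁻⁹).
- Constant signals: `normalize_minmax()` and `skewness_sqi()` raise
  errors rather than returning NaN; a constant scalogram renders as the
  uniform colormap floor.
- The SQI gate retries a bounded 100 times, then fails naming the class,
  rather than looping forever.
- Cohort class counts use largest-remainder apportionment so they always
  sum exactly to `n_subjects`.

## Known limitations

- The synthetic morphologies are fixtures; distinguishability of the four
  stages is built in by design, so end-to-end accuracy on this cohort is
  an upper bound of machinery quality, not a clinical claim.
- The default FIR leaves DC–0.05 Hz as a don't-care region (see above);
  users filtering long recordings at lower sampling rates should set
  `stop_lo` explicitly.
- The CWT uses zero-padding without cone-of-influence masking; the lowest
  analysis frequencies on a 2.1-s segment are dominated by edge effects.
- Training is CPU-bound and single-threaded; the full 224×224
  configuration is impractical without hours of CPU time.
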