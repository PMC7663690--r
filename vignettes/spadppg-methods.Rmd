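---
title: "Methods: vital-sign estimation from photon-count video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vital-sign estimation from photon-count video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`spadppg` estimates heart rate, the tachogram, the LF/HF sympathovagal
balance and the respiration rate from low-resolution photon-counting video
of a face, and ships a simulator that generates such video with exact
ground truth. This vignette documents the models, the tunable parameters,
the numerical choices, and what the simulator does and does not emulate.

## The acquisition and physiological model

A single-photon camera frame is a 32 × 64 grid of photon counts at 100 Hz.
Cardiac blood-volume changes modulate skin reflectance by a few percent, so
the expected count of a skin pixel at time $t$ is modelled as

$$\lambda_{skin}(t) = \mu_{skin}\,\bigl(1 - d\,p(t)\bigr)\,L(t),$$

where $p(t)$ is the unit-amplitude pulse waveform, $d$ the modulation depth
and $L(t)$ an optional illumination factor; background pixels have
$\lambda_{bg}(t) = \mu_{bg} L(t)$. Every pixel is an independent Poisson
draw — the appropriate noise model for photon counting; dark counts are
absorbed into $\mu_{bg}$.

Beat-to-beat variability is generated by a two-sinusoid instantaneous-RR
model,

$$RR(t) = \frac{60}{\mathrm{HR}} + a_{LF}\sin(2\pi f_{LF} t) +
          a_{HF}\sin(2\pi f_{HF} t),$$

with $f_{LF} \in [0.04, 0.15)$ Hz and $f_{HF} \in [0.15, 0.4]$ Hz. Beats
are placed iteratively ($t_{k+1} = t_k + RR(t_k)$), which gives the
tachogram an analytic ground truth: the LF/HF band-power ratio converges to
$(a_{LF}/a_{HF})^2$. Each beat contributes an asymmetric kernel (rise over
$0.15\,RR$, exponential decay, 30% dicrotic bump at $0.4\,RR$), mimicking
the sharp systolic upstroke of photoplethysmographic beats.

Simulator defaults are the study conditions used throughout the tests:
64 × 32 pixels at 100 Hz, 500 counts/pixel skin level, 50 counts
background, and 2% modulation depth. The modulation depth at the optimal
(green) wavelength is not established for this sensor class; 2% is a
realistic choice for green-light PPG and is a flagged configuration knob.
Head motion is a horizontal sinusoidal displacement of the skin ellipse;
pulsating light is a global sinusoidal gain.

**What the simulator does not emulate:** wavelength-dependent skin optics,
3D head shape and rotation (the skin region is a rigid ellipse),
non-periodic motion, sensor defects (hot pixels, crosstalk), and ambient
light outside the analysed band. Passing tests therefore demonstrate the
signal-processing chain under controlled, within-model conditions — not
performance on real recordings.

## Skin segmentation

The segmenter is a compact convolutional encoder–decoder: 8 encoder conv
stages (3 × 3, ReLU) with max-pools after stages 2, 4 and 6 (bottleneck at
1/8 resolution), and 6 decoder stages with 2× nearest-neighbour upsampling
before stages 1, 3 and 5 and a sigmoid head. There are no skip
connections. Default channel widths are 8-8-16-16-32-32-64-64 /
32-32-16-16-8-1 (≈110k parameters) — small enough to train in a few
minutes on one CPU core while easily exceeding 0.8 held-out IoU on
simulated faces.

Training minimizes the asymmetric squared loss with $\alpha = 0.4$; with
$\alpha < 0.5$ a false positive costs $1-\alpha$ versus $\alpha$ for a
false negative, which protects the pulse average from background
contamination. Binarization is inclusive at the threshold (default 0.5).

Three implementation choices matter for anyone retraining the network:

* **Per-image RMS normalization.** After every hidden conv stage the
  activations are divided by their per-image root-mean-square. Without any
  normalization, a 14-layer ReLU stack under a squared loss on a sigmoid
  head reliably collapses: coherent weight updates inflate decoder
  activations multiplicatively until the sigmoid saturates at exactly 0,
  where the squared loss has zero gradient and training freezes. The RMS
  norm is parameter-free, keeps predictions independent across images, and
  makes training converge for every seed we tried.
* **Optimizer.** Momentum SGD (0.9) with the global gradient norm clipped
  at 5, learning rate $10^{-3}$, 30 epochs, mini-batches of 10. Adaptive
  per-parameter methods step at full length even when the true gradient is
  vanishingly small but sign-consistent, which drives the same saturation
  collapse; clipped SGD steps shrink with the gradient and are stable here.
* **Input scaling.** Each frame is divided by its own maximum, making the
  segmenter invariant to exposure level.

The network runs on 10 Hz key frames (means of 10 raw frames), which both
reduces Poisson noise and matches the cadence at which masks are consumed
downstream. The `geometric_mask_provider()` bypasses the network entirely
(exact simulator masks, optionally eroded/dilated), so every downstream
stage is testable without training.

## Pulse extraction

Each raw frame uses the mask of its own key block (no mask interpolation —
masks are causal and piecewise constant over 10 frames). The frame value
is the mean of masked pixels after removing values strictly below the 10th
or above the 90th percentile (linear-interpolation percentile convention,
so an all-equal input is untouched). When the mask changes at a key-frame
boundary, the level step — first sample under the new mask minus last
sample under the old one — is subtracted from all subsequent samples; on
noise-free input the stitched signal is exactly continuous. A step
subtraction was chosen over a high-pass because a dedicated bandpass
follows anyway and the step model removes the artifact without touching
in-band content. Masks with fewer than 10 pixels are unusable: the last
value is held and flagged, and held stretches longer than a second should
be treated as invalidating the overlapping estimates.

The buffer holds 6000 samples (one minute at 100 Hz), FIFO. All standard
analyses run on this window; for records longer than a minute the batch
interface accepts a larger `capacity` so the full tachogram is used (the
one-minute cap exists for streaming latency, not as an analysis choice).

## Filtering and spectral heart rate

The bandpass is the fixed biquad
$H(z) = g\,(z-1)(z+1)\,/\,\bigl((z-0.824)(z-0.966)\bigr)$ at 100 Hz: exact
zeros at DC and Nyquist, real poles shaping a 0.4–4 Hz (24–240 bpm)
passband, gain normalized to unit peak in-band response. Filtering is
causal; the first 5 s of output are flagged as transient and excluded from
peak and FFT analysis. The realized response is gentle at the low edge:
$|H|$ at 0.05 Hz is about 0.11 of peak (amplitude ratio to 2 Hz ≈ 8.9,
power ratio ≈ 80). The pole/zero placement is treated as authoritative; no
attempt is made to sharpen it into a textbook Butterworth.

Heart rate is $60 \times$ the in-band argmax of the Hann-windowed,
mean-removed magnitude FFT at native length (no zero padding), so a full
buffer gives exactly 1 bpm resolution and on-bin tones are recovered
exactly.

## Beat detection and the tachogram

Beat candidates are local maxima of the filtered signal. Because blood
influx darkens the skin, the systolic event is a counts *dip*; `rppg()`
negates the filtered signal when its post-transient skewness is negative so
that beats point upward — detecting maxima of the un-oriented signal would
sit on the broad diastolic shoulder and triple the timing jitter.

Non-maximal suppression keeps the largest candidate within any window of
half the expected beat period ($0.5 \cdot 60/\mathrm{HR}_{FFT}$); survivors
below $0.3\times$ the 90th percentile of surviving amplitudes are dropped.
Both constants are configuration knobs; the defaults keep every true beat
of a clean train (including one at half amplitude) while rejecting
dicrotic bumps. Gaps longer than $1.5\times$ the mean RR trigger a search
for the local maximum in a window of half-width $0.5\times$ mean RR centred
one mean RR after the previous peak, iterated to a fixed point; the
operation is idempotent on clean trains.

RR intervals (timestamped at the later peak) are resampled to an even 4 Hz
grid by cubic spline — standard HRV practice for unevenly sampled RR
series. The tachogram PSD is a mean-removed Hann periodogram scaled so its
integral matches the RR variance (a sinusoidal modulation of amplitude $A$
seconds carries band power $A^2/2$). LF and HF are trapezoid areas over
0.04–0.15 and 0.15–0.4 Hz; respiration is the HF-band peak × 60. A span of
at least ~50 s is needed to resolve the LF edge; one-minute windows give
noisy LF/HF ratios and the analytic value is recovered within tens of
percent only on multi-minute records (the five-minute acceptance scenario
lands within 15–30%).

## Dependability scores

Both optical-artifact checks reduce a spectrum over the heart-rate band to
the *peak-area score*: the trapezoid area between the flanks where power
first falls to 25% of the dominant peak, as a fraction of total band area.
A flat spectrum degenerates to score 1 under the literal rule, so a
flatness guard additionally requires the peak to exceed 3× the band median
before flagging; the flag threshold is 0.5. With these defaults 20 seeded
null scenes produce no false flags while the two artifact scenarios (3 px
motion at 1 Hz; 30% light modulation at 1.1 Hz) score above 0.8.

Movement uses the per-key-frame mask centroid projected on its first
principal component (sign fixed so the first displacement is positive);
light uses the mean of out-of-mask pixels at 100 Hz, bandpassed like the
pulse (removing DC dominance) — both spectra are of the *filtered*
signals. The analysis band is 0.4–4 Hz for both checks, since their
purpose is detecting maskers of in-band HR content. Note the score
measures *periodicity*, not amplitude: with near-noiseless masks even a
0.2 px periodic wobble is correctly flagged, because nothing else competes
for spectral area. Streaming detection latency is bounded by the one-minute
buffer plus one 1 s update.

## Evaluation stack

The reference detector is a classic Pan–Tompkins chain (zero-phase 5–15 Hz
bandpass, five-point derivative, squaring, 150 ms moving-window
integration, adaptive dual thresholds with search-back, R times refined on
the raw trace); on clean synthetic ECG it reaches 100% recall and precision
at 50–100 bpm. Beat shapes are segmented between consecutive R times
shifted by a 200 ms pulse-transit lag (configurable to 0), linearly
resampled to 100 points, L2-normalized, and summarized by the mean
per-point sample ($n-1$) standard deviation. Tachogram RMSE compares both
tachograms spline-interpolated to a common 4 Hz grid over their overlap.

## Problem sizes and determinism

The test-suite and acceptance scenarios use 60–300 s recordings at the
default 64 × 32 / 100 Hz geometry, 200 training pairs / 30 epochs for the
segmenter, and 20-seed Monte-Carlo batches for false-positive checks —
sizes chosen so the full suite runs in minutes on a single core while every
spectral quantity is resolved at the precision asserted. All randomness
(beat jitter, Poisson rendering, ECG noise, weight initialization, batch
shuffling) is seeded; identical seeds give bit-identical frame stacks and
identical fits.

## Known limitations

* The skin region is a rigid ellipse; real faces deform, rotate, and have
  heterogeneous perfusion. IoU ≥ 0.8 on simulated masks says nothing about
  real-face segmentation.
* The biquad's low-edge rejection is modest (≈ 0.11 amplitude at 0.05 Hz),
  so strong very-low-frequency drifts attenuate but do not vanish.
* No ectopic-beat handling, no time-domain HRV indices, no motion
  compensation: detected artifacts invalidate estimates rather than being
  corrected.
* Light flicker outside 0.4–4 Hz (e.g. mains at 50/60 Hz, which aliases to
  40 Hz at a 100 Hz frame rate) is out of scope for the light check by
  design.
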