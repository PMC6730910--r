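---
title: "Decoding code-modulated VEPs: models, simulator and design choices"
author: "cvep authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding code-modulated VEPs: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decoding problem

In a code-modulated VEP (c-VEP) brain-computer interface every selectable
target flickers with its own pseudo-random binary code: one bit per 60 Hz
monitor frame, 0 = black, 1 = white. The flicker evokes visual evoked
potentials (VEPs) in the EEG, and a *backward model* — EEG2Code — inverts
the mapping: it predicts, for every frame, the probability that the bit
shown at that frame was 1, using the **following 250 ms** of EEG. The
window length reflects the duration of the prominent flash-VEP
components; its placement after the frame reflects causality of the
response. With EEG sampled at 600 Hz there are exactly 10 samples per
frame, the window is slid sample-wise (600 predictions per second), and
the 10 sample-wise predictions falling into one frame are averaged into
one per-bit probability. A threshold of 0.5 (ties mapped to 1 — the
printed description is silent on ties, and a fixed documented rule is
needed for bit-exact tests) yields the predicted pattern.

Because the prediction for bit $i$ uses samples $[10i, 10i + 150)$, the
prediction stream is delayed by 250 ms relative to stimulation, and a
recording of $10 n + 150$ samples yields predictions for all $n$ bits.
This also reproduces the characteristic trial arithmetic of online runs:
a 5 s run (300 frames, the last 250 ms being padding stimulation)
provides $3000 - 149 = 2851$ sample-wise predictions, i.e. 285 complete
bit predictions.

## The two backward models

**Ridge regression** (baseline). Each window is flattened to a
$150 \times 32 = 4800$-vector and mapped to its bit by closed-form ridge
regression with an unpenalised intercept. The penalty $\lambda$ defaults
to 1 (the source material does not state one; on the simulator the result
is insensitive over several orders of magnitude because the fit is
signal-dominated). Outputs are clipped to $[0, 1]$. A single
discriminative spatial filter (a CCA-style component regressing the label
on window-averaged channel activity) is available as an option but off by
default: the reference configuration feeds unfiltered windows.

**Convolutional network.** Five layers on the raw $150 \times 32$ window:

1. 16 convolutional kernels of size $1 \times 32$ — learned spatial
   filters (this is why no spatial filtering is applied beforehand);
2. 8 kernels of size $64 \times 1$ — temporal filters, zero-padded to
   preserve length;
3. temporal max-pooling;
4. dropout and a dense rectified layer;
5. a dense 2-way softmax giving $p_0$ and $p_1 = 1 - p_0$.

The published description fixes the kernel shapes and counts, the
learning rate (0.001), the batch size (256), the epoch count (25) and the
best-epoch selection rule (highest validation accuracy), but not the
pooling sizes, dropout rate, dense width, optimizer or padding. Those
were fixed here once, as the smallest conventional choices: max-pooling
size 2 / stride 2 applied twice (150 → 75 → 37 time steps), dropout 0.5
before a 128-unit rectified dense layer, batch normalisation after each
convolution (per-feature axis, scale and centre on), adaptive-moment
gradient descent (Adam) at the stated learning rate, and 2-class
cross-entropy — the loss form forced by the softmax output. The
implementation is written from first principles (forward and backward
passes in compiled code); its gradients are verified against finite
differences in the test suite, and training is bit-reproducible for a
fixed seed on one machine.

The validation split is the *contiguous tail* of the window sequence,
not a random subset. Neighbouring windows overlap by up to 149 of 150
samples; a random split would place near-duplicates of training windows
into the validation set and inflate validation accuracy. A contiguous
split leaks only at the single boundary.

## From bits to selections

*Synchronous* control correlates the real-valued per-bit predictions of a
fixed-length trial with every target's code and selects the highest
correlation (ties: lowest index). Real-valued probabilities rather than
binarised bits are used — binarisation discards confidence; the printed
description does not say which variant was used, and this choice is
documented here as the package's own.

*Asynchronous* (self-paced) control re-evaluates after every new bit, but
on the p-value of the one-sided test that the correlation is positive,
$t = r \sqrt{(n-2)/(1-r^2)}$ against a Student-t with $n - 2$ degrees of
freedom — the standard significance transform of a Pearson correlation,
which brings the trial length into the decision. The first candidate
whose p-value crosses the threshold is selected (ties: smallest p, then
lowest index). Evaluation starts at `min_bits = 12` (200 ms of code): the
t-transform is unstable on fewer points. If nothing crosses within
`max_trial_s` (default 10 s, several times the typical self-paced trial)
the non-control state is returned; the spelling protocol counts such
trials as abstentions (logged, excluded from the accuracy denominator) by
default, with a count-as-error mode as a flag.

*Massive candidate sets.* Since codes are random, candidates need no
recorded EEG: the prediction is ranked against the true code plus
hundreds of thousands of random distractor codes. The single-trial
operation draws its own seeded distractors; the protocol runner draws one
candidate set per run (streamed in fixed-size blocks to bound memory) and
ranks all trials against it, playing the role of a fixed 500,000-target
layout.

## Performance measures

For a selection accuracy $P$, $N$ classes and $T$ seconds per selection:

$$\mathrm{ITR} = \Big(\log_2 N + P \log_2 P + (1-P)\log_2 \tfrac{1-P}{N-1}\Big)\cdot\tfrac{60}{T}, \qquad
\mathrm{UTR} = (2P - 1)\log_2(N-1)\cdot\tfrac{60}{T},$$

$$\mathrm{CLM} = \begin{cases} 60\,(2P-1)/T & P \ge 0.5 \\ 0 & \text{otherwise.}\end{cases}$$

Conventions implemented: $x \log_2 x \equiv 0$ at $x = 0$ (ITR is then
continuous on $[0,1]$ and zero at chance); UTR is returned unclipped
(negative below chance, with a warning) because only CLM is defined with
a floor; UTR at $N = 2$ returns 0 since $\log_2(N-1)$ degenerates. For
per-bit rates both $T = 1/60$ s (one frame) and $T = 5/285$ s (285
complete predictions per 5 s run; the 250 ms window makes $1/60$ slightly
optimistic) are supported — the caller picks the convention. Result
tables aggregate by the arithmetic mean of per-unit metric values, which
by Jensen's inequality is at least the metric of the mean accuracy.

## What the simulator emulates — and what it does not

No public recordings exist for this paradigm, so the package ships a
forward simulator built on the same structural assumption the backward
models exploit: the EEG response to a code is a *linear superposition of
single-flash responses*. The code is upsampled by zero-order hold to
600 Hz, convolved with a 250 ms single-flash kernel, optionally passed
through a saturating nonlinearity, spatially mixed over 32 channels and
summed with coloured noise. After the pattern, 250 ms of random
stimulation is appended so the last bits keep a full window of EEG.

**Kernel.** The default is the classic triphasic flash-VEP morphology:
Gaussian components P1 (75 ms latency, 10 ms width), N1 (110 ms, 15 ms)
and P2 (180 ms, 30 ms), tapered to zero at the window end and normalised
to unit energy. The sharpness of the early components is not cosmetic:
the 60 Hz code occupies a band up to 30 Hz, and only a kernel with
spectral content in that band makes the code recoverable. An overly
smooth kernel (e.g. broad gamma-shaped bumps) annihilates the code band
and caps bit accuracy near 75% *regardless of noise level or training
size* — inconsistent with the real phenomenon, where sample-wise c-VEP
decoding demonstrably works. Any smooth 250 ms shape can be substituted
through `vep_kernel()`'s parameters.

**Noise.** A mixture of 1/f ("pink", synthesised by spectral shaping of
white noise) and white noise, default pink fraction 0.8, reflecting the
1/f-dominated EEG background. The SNR in dB is defined on total powers,
`10 log10(P_clean / P_noise)` across all channels and samples, and the
realised value is checked against the configured one in the tests.

**Spatial structure.** Gains default to an occipital-weighted profile:
0.15 on the 24 anterior channels, 0.70–1.00 on the last eight
(parieto-occipital/occipital) channels — VEPs are occipital, and this
gives spatial filters a topography to find.

**Nonlinearity.** An optional saturating compressor
$f(x) = \sigma \tanh(g x / \sigma)/g$ (linear as $g \to 0$; default gain
3) applied to the clean response before noise. It stands in for the
non-linear properties of the VEP that a superposition cannot express and
is what lets the tests demonstrate the CNN's advantage over the linear
baseline *in the direction* observed on real EEG.

Not emulated: biophysical head geometry, eye movements and other
artefacts, line noise, monitor raster latency, and any contamination
from non-attended flickering targets (an interference term the simulator
deliberately omits; whether it is measurable in practice is unknown).
Consequently, passing end-to-end tests shows the decoding stack is
correct and self-consistent under the model's own assumptions — it does
not certify performance on real recordings, whose accuracies are
reproduced here only at the level of the printed per-subject tables via
the metric formulas.

**"Subjects"** in protocol tables are simulated as distinct seed/SNR
combinations; no real EEG is involved anywhere.

## Numerical and degenerate-input choices

* Probability exactly at the 0.5 threshold → bit 1 (fixed tie rule).
* Sample-wise predictions not filling a 10-sample block are dropped with
  a warning (occurs only on malformed input lengths).
* Constant candidate codes have undefined correlation: reported as `NA`
  and excluded from every argmax; in the greedy decorrelation search they
  count as correlation 0.
* A noiseless recording has infinite SNR; `estimate_snr()` returns `Inf`.
* Ridge uses a Cholesky solve of the centred normal equations with the
  penalty added to the diagonal; on (numerically) singular systems it
  falls back to a QR solve.
* Batch normalisation uses $\epsilon = 10^{-5}$ and running statistics
  with momentum 0.1; training batches smaller than 8 windows are skipped
  (batch statistics would be meaningless).
* All stochastic operations take an explicit integer seed driving R's
  Mersenne-Twister generator; derived sub-seeds make every experiment
  stage independently reproducible.

## Problem sizes used by the test suite

The protocols scale linearly in recording length, so the suite exercises
them at sizes chosen to keep a full run in the tens of minutes on one
CPU while leaving each claim's statistics unambiguous: noiseless ridge
recovery uses the full 60 s training phase; the CNN end-to-end check
trains 5 epochs on 60 s at 0 dB SNR; the saturating-nonlinearity
comparison trains both models on 20 s at −6 dB over 5 paired seeds (4
epochs); the 500,000-candidate discrimination uses 100 two-second trials
against a ridge model trained on 20 s at 0 dB. Unit tests use 5–17 s
recordings. The full 384 s training phase and 7-run protocols are
available through `experiment_config()` defaults.

## Known limitations

* The CNN's unspecified hyperparameters (pooling, dropout, dense width,
  optimizer) are documented substitutes; no claim is made that they match
  the original figure's exact values.
* The greedy low-correlation pattern search is a documented proxy for
  optimised stimulation codes, with no claim of equivalence to any
  published construction.
* The asynchronous decoder evaluates per bit, not per sample; the source
  material does not state which was used.
* Ridge's historical spatial filtering pipeline is reduced to a single
  optional CCA-style component.
* The utility-rate and ITR values on simulated data characterise the
  simulator, not human performance.
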