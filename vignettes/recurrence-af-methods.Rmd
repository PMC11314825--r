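---
title: "Methods: recurrence-plot analysis of single-lead ECG for AF risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recurrence-plot analysis of single-lead ECG for AF risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Atrial fibrillation (AF) often announces itself: ECGs recorded days before a
documented episode already carry subtle dynamical signatures — increased
rhythm irregularity, altered atrial activity — that are hard to read by eye.
`rpaf` implements a screening pipeline for 10-second single-lead ECG
segments: denoise, reconstruct the phase-space trajectory, render it as a
recurrence plot, and classify the plot with a small residual convolutional
network into *pre-AF* (label 1) and *non-AF* (label 0) classes. Recurrence
quantification analysis (RQA) statistics are computed alongside as
interpretable summaries of the same structure the network sees.

Everything is exercised on synthetic ECG, so the full chain is testable
without clinical data; the same functions accept WFDB records and CSV
signals.

## Preprocessing

**Normalisation.** Each segment is mapped affinely to $[0,1]$:
$x_i' = (x_i - \min x)/(\max x - \min x)$. A constant segment maps to all
zeros rather than dividing by zero. Normalisation is applied per segment
(not per record), before denoising, so the threshold estimate below works
on a known scale.

**Wavelet denoising.** The segment is decomposed with the Daubechies-5
(db5) filter bank — whose shape resembles the QRS complex — for
$N = \lceil \log_2(f_s/f_L) \rceil$ levels, with $f_L = 0.5$ Hz the lower
edge of the diagnostic ECG band. At $f_s = 500$ Hz this gives $N = 10$,
clamped to $\lfloor \log_2 n \rfloor$ for short signals. The noise scale is
the median-absolute-deviation estimate from the finest detail level,
$\hat\sigma = \mathrm{median}(|d_1|)/0.6745$ (the absolute value matters: a
signed median of symmetric noise is near zero and useless). Every detail
level is then soft-thresholded with Donoho's universal threshold
$T = \hat\sigma\sqrt{2\ln n}$, where $n$ is the *signal length*: with the
decomposition depth in its place the threshold
($\sqrt{2\ln 10}\approx 2.1\,\hat\sigma$) would barely shrink anything.
Soft thresholding $W \mapsto \mathrm{sgn}(W)\max(|W|-T,0)$ is continuous
and non-expansive, which the test suite asserts as properties.

**Baseline removal.** The drift band is everything below $f_L$. After
$N$ levels the deepest approximation covers $[0, f_s/2^{N+1}]$; at 500 Hz
and $N=10$ that is only $[0, 0.244]$ Hz, while detail level 10 covers
$[0.244, 0.488]$ Hz — also entirely sub-$f_L$. Zeroing the approximation
alone therefore leaves a 0.25 Hz drift essentially untouched (its energy
sits in $D_{10}$, whose coefficients are far above the threshold). The
denoiser consequently zeroes the deepest approximation *plus every detail
band lying wholly below* $f_L$; with that rule more than 99% of a 0.25 Hz,
0.2 mV drift is removed while the beat morphology passes through. Note
that baseline removal also strips the clean signal's own sub-$f_L$ content
(its DC level in particular) — that is intended behaviour, not residual
drift, and the drift test compares against the clean signal passed through
the same operator.

Boundaries use half-point symmetric extension; the transform reconstructs
to machine precision (the suite demands $<10^{-8}$ on random
5000-sample signals, and observes $\sim 10^{-15}$).

## Recurrence analysis

**Embedding.** The trajectory is the classical delay embedding
$u_m(i) = (x(i), x(i+\tau), \dots, x(i+(m-1)\tau))$ with defaults
$m = 3$, $\tau = 3$ samples, giving $M = N - (m-1)\tau$ points.

**Recurrence matrix.** $R_{ij} = \Theta(\varepsilon - \lVert u_m(i) -
u_m(j)\rVert)$ with the Euclidean norm, $\varepsilon$ fixed at 10% of the
maximum pairwise distance, and $\Theta(0) = 0$ honoured exactly: a pair at
distance exactly $\varepsilon$ is non-recurrent. Because $\varepsilon$
scales with the trajectory's diameter, the matrix is invariant under any
affine amplitude rescaling $x \mapsto ax + b$ — asserted bit-for-bit in
the tests. A trajectory whose points are all identical has no scale to
work with and raises an error.

**Statistics.** From the histograms of maximal diagonal and vertical runs
of ones (minimum counted lengths $l_{\min} = v_{\min} = 2$):

* REC $= \sum_{ij} R_{ij}/M^2$ — recurrence rate;
* DET $= \sum_{l \ge l_{\min}} l\,p(l) \,/\, \sum_{ij} R_{ij}$ — determinism;
* ENTR $= -\sum_{l \ge l_{\min}} \hat p(l) \ln \hat p(l)$ — entropy of the
  normalised diagonal-length distribution (the conventional sign; the raw
  $\sum p \ln p$ form is negative for any non-degenerate distribution,
  at odds with entropies being reported positive);
* TT $= \sum_{v \ge v_{\min}} v\,p(v) / \sum_{v \ge v_{\min}} p(v)$ —
  trapping time; LAM analogous to DET over vertical lines;
* Lmean over diagonals $\ge l_{\min}$, and Lmax reported both raw and
  divided by $M$ (published values below 1 imply such a normalisation;
  no defining formula exists, so both are kept).

Conventions that were genuinely open and how they were fixed: the line of
identity is **included** by default (the defining sums run over all $i,j$),
with a Theiler-window argument to exclude it, since exclusion is common
practice; $v_{\min}$ mirrors $l_{\min} = 2$; REC is always defined while
the line-based statistics degrade to 0 with a `degenerate` flag when no
line reaches the minimum length. One consequence of reading the defining
sums literally deserves a note: for a fully recurrent matrix the two
corner cells lie on single-cell diagonals below $l_{\min}$, so DET equals
$(M^2-2)/M^2$, not exactly 1 — consistent with determinism values of
0.999 reported for near-periodic physiological signals.

The vectorised implementation (distance matrix via `dist()`, run scans via
a single `rle` over separator-joined diagonals) is checked for exact
equality against a deliberately naive double-loop oracle on hundreds of
random signals.

**Images.** A recurrence matrix is pooled to a fixed $S \times S$ image by
block averaging, so each pixel is a local recurrence density in $[0,1]$
and (for divisible sizes) the image mean equals REC. Matrices no larger
than $S$ are zero-padded instead. Default $S = 224$ for standalone use;
the classification benchmark uses $S = 64$. To bound the matrix size,
segments may be decimated before embedding (Fourier resampling to 500
samples by default in the pipeline).

## The classifier

A compact residual network: a stride-2 convolutional stem (3×3, 16
channels), three residual blocks (block 1 with 2×2 kernels, blocks 2–3
with 3×3; widths 16→32→64; stride-2 downsampling entering blocks 2 and 3),
global average pooling, and two fully connected layers (64→32→2). Each
block is conv–BN–ReLU–conv–BN with an additive skip and a final ReLU; a
1×1 projection (with BN) aligns shapes when channels or stride change.
Even 2×2 kernels use asymmetric (0,1) "same" padding. A `raw1d` variant
mirrors the topology with 1-D kernels of lengths 2/3/3 for classifying
the filtered segment directly.

Published descriptions of this architecture leave stem depth, widths and
pooling unspecified; the widths above are this package's declared
defaults, kept small enough that the whole parameter set is well under
11 MB at 32-bit (about 77k parameters, 0.3 MB).

The implementation is plain R: im2col patch matrices multiplied through
BLAS, hand-written backward passes for every layer, and Adam. A numeric
differentiation test validates the analytic gradients; training is exactly
reproducible from an integer seed. Weights use He initialisation except
the classification head, which starts near zero so an untrained model
predicts near-chance probabilities (and its cross-entropy sits at
$\ln 2$); hidden-layer He weights keep the gradient to the stem nonzero
at initialisation, which the suite asserts.

Training minimises cross-entropy with Adam (learning rate $10^{-5}$ by
default, matching the reference protocol) and early stopping on
validation loss: the weights returned are those of the best validation
epoch, and training halts after `patience` epochs without improvement.
Record-disjoint stratified 5-fold cross-validation is available via
`crossvalidate()`.

## Synthetic data: what it emulates, and what it does not

Each beat is a sum of five Gaussian deflections (P, Q, R, S, T) with
plausible lead-I amplitudes; RR intervals are drawn from a lognormal
distribution with prescribed mean rate and coefficient of variation (CV).
Both classes beat at 75 bpm: the non-AF-like class with CV 0.04 and full
P waves, the pre-AF-like class with CV 0.18 and P waves attenuated to
35%. Rate is deliberately held equal so that rhythm irregularity — not
heart rate — is the class discriminator; the irregular class's long RR
pauses lengthen its laminar diastolic segments, which is what gives it
the higher trapping time expected before AF onset. With unequal rates
that ordering washes out, because diastole length then competes with
irregularity.

Noise defaults: baseline drift 0.2 mV at 0.25 Hz, powerline 0.05 mV at
50 Hz, and muscle artifact of 0.05 mV standard deviation restricted to
above 45 Hz (white noise with its sub-corner FFT bins zeroed). All three
match what the denoiser targets.

This generator produces visually plausible, statistically separable ECG
classes. It does **not** model real AF physiology: no f-waves, no atrial
remodelling, no ectopy, no morphology drift, no electrode motion
artifacts, and a Gaussian-bump beat rather than a dynamical model.
Passing tests therefore demonstrate that the pipeline's machinery is
correct and that it can learn the kind of rhythm-irregularity signature
relevant to AF — not that it reaches any particular clinical accuracy.

## Data handling

WFDB records (formats 16 and 212) are read with gain/baseline conversion
to millivolt; CSV signals round-trip at full double precision with the
sampling rate inferred from the median time step (more than 1% jitter is
an error). Resampling is Fourier-method (spectrum truncation /
zero-padding with Nyquist-bin splitting), giving the exact
$\mathrm{round}(n \cdot f_{\text{out}}/f_{\text{in}})$ length rule and
clean tones staying on their frequency bin. Segmentation uses
non-overlapping windows, discarding the trailing remainder. Dataset
splitting apportions whole records (so no patient crosses a train/test
boundary) by largest remainder, ties resolved toward the training set.

## Problem sizes and numerical choices

The shipped benchmark — also what `scripts/acceptance.R` reruns — uses
200 synthetic signals per class (10 s at 500 Hz), denoised, decimated to
500 samples, embedded at $m = \tau = 3$, pooled to 64×64 images, split
7:2:1 by record, and trained for at most 20 epochs at learning rate
$10^{-3}$ with batch size 32 and patience 5. These sizes were chosen as a
desk-scale study a single core completes in a few minutes; held-out
accuracy and AUC on this benchmark are at or near 1.0 across seeds.
Tolerances: reconstruction is asserted below $10^{-8}$; oracle equality
is exact for the binary matrices and count-ratio statistics and within
$10^{-12}$ for the entropy (log summation order).

## Known limitations

* The synthetic classes are easier to separate than real pre-AF ECG;
  clinical performance claims require clinical data.
* The published architecture is under-specified, so the defaults here are
  declared rather than faithful; headline clinical accuracies are out of
  scope by construction.
* RQA on long segments is $O(M^2)$ in memory and time; decimation (or
  image pooling) is the intended mitigation.
* The 12-bit hospital XML dialect and WFDB annotation files are not
  parsed.
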