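---
title: "Recurrence-plot hybrid EEG-fNIRS workload classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrence-plot hybrid EEG-fNIRS workload classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neurorp)
```

## The problem

Hybrid brain-computer interfaces record electrical (EEG) and hemodynamic
(fNIRS) brain activity simultaneously. The two streams are grossly
incompatible as raw matrices: EEG arrives at 1,000 Hz over 30 channels,
fNIRS at 10.4 Hz over 16 source-detector sites and two wavelengths.
The usual workaround — decimating EEG to the fNIRS rate — discards most of
the electrical signal. This package takes a different route: each modality's
labeled signal windows are converted into *recurrence plots* (RPs), square
images indexed by time pairs rather than by time, so both modalities become
stacks of images on a shared window grid and no stream is ever resampled to
the other's rate. A time-distributed CNN-LSTM then classifies the image
sequences into four mental-workload states: 0-back, 2-back, 3-back and rest.

## Recurrence plots

A window of a multichannel signal is turned into a phase-space trajectory by
time-delay embedding: for embedding dimension $m$ and delay $d$, the state
at retained sample $i$ is
$\vec x(i) = (x_i, x_{i+d}, \dots, x_{i+(m-1)d})$
per channel, concatenated across channels. The binary recurrence matrix is

$$R(i,j) = \begin{cases} 1 & \lVert \vec x(i) - \vec x(j) \rVert_2 \le
\varepsilon \\ 0 & \text{otherwise,} \end{cases}$$

with unit main diagonal and symmetry by construction. When the dimension
$n$ of the underlying system is known, $m \ge 2n + 1$ suffices for the
embedding to recover the system's topology; `checkEmbedding()` warns (never
fails) below that bound. The defaults are $m = 1$, $d = 1$, the package's documented choice for
all shipped analyses.

Three decisions here were genuinely open:

* **Threshold interpretation.** $\varepsilon = 0.1$ is interpreted by
  default as a *fraction of the maximum phase-space distance in the window*
  (`epsilonMode = "fraction_of_max_distance"`). A literal absolute 0.1 on
  z-scored multichannel data yields near-empty plots (on z-scored windows
  pairwise distances scale like $\sqrt{2C}$ for $C$ channels), whereas the
  fraction reading preserves the printed value while remaining scale-free.
  The literal reading remains available as `epsilonMode = "absolute"`.
* **Multichannel handling.** One RP per modality per window, with the state
  vector stacking all channels after per-channel z-scoring, rather than one
  RP per channel. This yields exactly one image per modality per window,
  matching the two-branch network input.
* **Windowing.** 5 s windows with 20% overlap on both modalities; the
  within-window subsampling stride of 10 samples applies to EEG only
  (200 Hz $\times$ 5 s / 10 = 100, so EEG plots are 100$\times$100), while
  fNIRS uses stride 1 (10 Hz $\times$ 5 s = 50, so 50$\times$50 — a 5 s
  fNIRS window has no samples to spare). Consecutive non-overlapping runs
  of `tSeq = 4` windows sharing a label form one classifier sample; the
  sequence length is a free parameter of the design, and 4 windows span
  17 s of a 40 s task block.

## Pre-processing

EEG: anti-aliased downsampling from 1,000 Hz to 200 Hz, then a zero-phase
6th-order Butterworth bandpass, 1-40 Hz. fNIRS: two-wavelength optical
densities are converted to HbO/HbR concentration changes by the modified
Beer-Lambert law, downsampled to 10 Hz, then low-pass filtered at 0.2 Hz
(zero-phase, 6th-order) — the hemodynamic response would itself be damaged
by a 1 Hz high-pass, hence low-pass only.

Zero-phase filtering is realized as forward-backward application with
odd-reflection edge padding of three filter orders plus steady-state initial
conditions, so the net phase lag is exactly zero and the magnitude response
is the squared one-pass response. `butterMagnitudeTwoPass()` provides the
closed form (analog prototype evaluated at bilinear-prewarped frequencies)
used by the tests as an independent check on the time-domain path.

The resampler uses a Kaiser-window FIR low-pass (passband to 85% of the new
Nyquist, roughly 70 dB stopband from the new Nyquist upward) applied with
zero phase, followed by exact decimation for integer ratios or cubic-spline
evaluation on the new grid otherwise (10.4 Hz to 10 Hz is a 26:25 ratio).

The Beer-Lambert step solves, per site and sample,
$[\Delta \mathrm{HbO}; \Delta \mathrm{HbR}] =
(E \cdot d \cdot \mathrm{DPF})^{-1} [\Delta OD_{\lambda_1}; \Delta OD_{\lambda_2}]$
with optical densities referenced to the per-channel temporal mean. The
extinction table (760/850 nm defaults), DPF = 6.0 and source-detector
distance 3 cm are bundled documented constants, all overridable. Units: extinction in
umol$^{-1}$ L cm$^{-1}$, distance in cm, concentrations in umol/L.

For outlier rejection and normalization the package uses robust z-score window rejection (median/MAD pooled across
windows, threshold `zMax = 5`) and training-fold-only statistics for any
normalization, which is leakage-safe by construction. Image-level
standardization is available in `kfoldCV(normalize = TRUE)` but is off by
default: recurrence plots already live in $[0,1]$ and standardizing binary
images was not found to help training.

## The classifier

Each temporal slice (one RP per modality) passes through a shared-weight
block — two 3$\times$3 convolutions with 16 filters each and
rectified-linear activations, one 2$\times$2 max-pool, flatten, and a dense
projection to 64 units — wrapped time-distributed, so the same parameters
apply to every window and the block's parameter count is independent of the
sequence length. The hybrid network runs one such block per modality and
concatenates the two 64-vectors per time step (the minimal merge consistent
with a two-branch design). An LSTM with 64 units consumes the feature
sequence; its final hidden state passes through a 32-unit dense layer into
the 4-class softmax.

No deep-learning framework is involved: the network, backpropagation and
the Adam optimizer are implemented in the package itself, with the
convolution/pooling kernels in compiled code (single-precision GEMMs — the
dominant cost — with analytic gradients verified against numerical
differentiation in the test suite). Training is bit-reproducible given the
seed. Training hyperparameters are fixed, documented defaults: kernel 3$\times$3, pool 2$\times$2, Adam at $10^{-3}$,
categorical cross-entropy, 50 epochs / batch 32 / early-stopping patience
10 as library defaults, with the desk-scale study using 12 epochs and batch
4 (sized to its 27-sample folds).

## Evaluation

Stratified k-fold cross-validation (k = 10 by default; the fold unit is one
window sequence, so overlapping windows never straddle a fold boundary), a
model trained from scratch per fold, and four metrics per fold: accuracy
(trace over total), macro-averaged one-vs-rest precision and recall, and F1
as the harmonic mean of macro precision and macro recall — the standard
aggregation when a 4-class problem is summarized by single
precision/recall/F1 values. Classes with no predicted
(or actual) positives contribute 0 to their macro average, with a warning.

## The synthetic generator

Every downstream stage is testable without any external download via
`simulateSubject()`, which emulates the n-back protocol: 3 sessions, 3
series per condition per session, each series being 2 s instruction +
40 s task (20 stimuli of 2 s) + 20 s rest, hence 62 s per series and
$3 \times 3 \times 20 = 180$ stimulus trials per condition — three series
*per condition* per session is the reading under which that trial-count
arithmetic closes. Series order within a
session is a seeded permutation; whether the original experiment randomized
order is unknown, and no fidelity is claimed.

EEG is generated at 1,000 Hz over 30 channels as a mixture of shared source
time courses — a 6 Hz theta rhythm, a 9 Hz alpha rhythm, 50 Hz line noise,
cardiac (~1.1 Hz) and respiratory (~0.25 Hz) components, two shared
broadband (1/f) background sources — plus independent pink noise and a
linear drift per channel. fNIRS optical densities are generated at 10.4 Hz
for 16 sites by the *forward* Beer-Lambert model from latent HbO/HbR
traces: a class-amplitude-scaled boxcar convolved with a double-gamma
hemodynamic response (undershoot ~16 s), HbR = $-\tfrac13$ HbO, plus Mayer
waves, respiration, cardiac pulsation, drift and white measurement noise.

**What the class signatures are, and why.** The recurrence-plot transform
used here is deliberately scale-free: windows are z-scored per channel and
the binary threshold is a fraction of the window's maximum distance. A
consequence discovered in pilot analyses is that *purely amplitude-coded*
class differences are invisible to it — exactly the failure mode one should
expect from its invariances, and worth knowing about when interpreting real
data. The generator's class signatures are therefore waveform-coded:

* EEG: theta and alpha are both present in every channel and the
  *theta:alpha mixture ratio* shifts with n-back level (theta gain
  $1 + 0.5\,e\,\ell$, alpha gain $e^{-0.3\,e\,\ell}$ for effect size $e$
  and level $\ell \in \{1,2,3\}$, regional base amplitudes frontal /
  central / parietal), and the theta frequency rises mildly with load
  (5.5 Hz $+\,0.15\,e\,\ell$, capped at 7.5 Hz).
* fNIRS: the task-block neural drive carries a slow effort-fluctuation
  oscillation whose frequency grows with level ($0.05\,\ell$ Hz, jittered
  20% per block, inside the 0.2 Hz band), the response time-to-peak grows
  with level ($\approx 5/6/7$ s), and Mayer-wave amplitude is scaled up
  during task blocks with load ($1 + 0.15\,e\,\ell^2$). Site
  responsiveness gains are heterogeneous (uniform 0.3-1.2).

These signatures are modeling devices that make the labels recoverable, not
physiological measurements; their shapes (shared sources, load-dependent
rhythm ratios and latencies) are drawn from the n-back literature's
qualitative findings. Passing tests on this generator demonstrate that the
pipeline recovers waveform-coded class structure end-to-end; they do not
demonstrate performance on real recordings, whose class information may be
weaker, amplitude-coded (and thus attenuated by this transform), or
confounded by artifacts the generator does not model (motion, optode
decoupling, ocular and myogenic contamination).

With zero effect size all class dependence vanishes identically, which the
tests use as a null; separability is non-decreasing in `effectSize`.

## Desk-scale study conditions

`runWorkloadStudy()` evaluates the three classifiers on one synthetic
subject at desk scale: one session (27 samples — 6 sequences per n-back
condition, 9 rest), effect size 3, noise amplitudes at 0.3 of their
defaults, 5-fold stratified CV, 12 epochs, batch 4, and three evaluation
seeds on the one subject with the median reported. These sizes are the
package's chosen study conditions; the full result scale (26 subjects,
180 trials per condition, 10-fold CV per subject with long training runs)
is deliberately out of reach of a synthetic desk run, so no claim of
reproducing absolute real-data accuracies is made — the study checks that both
single-modality pipelines are clearly above 4-class chance and that fusing
the modalities does not lose information relative to the better branch.

## Numerical choices and degenerate inputs

* Constant windows: a zero-variance channel in a window is left at zero
  after centering (no division by zero); an all-constant trajectory has
  $\max D = 0$ and yields an all-ones plot in both binary and grayscale
  modes.
* `recurrenceMatrix` thresholds with $\le$, so the diagonal is always 1.
* EDF is written with a single-precision-like 16-bit quantization inherent
  to the format; round-trip tests budget one quantization step. Sampling
  rates that are not unit fractions are written on the smallest integer
  record duration that makes samples-per-record integral (10.4 Hz
  $\rightarrow$ 5 s records of 52 samples).
* The 26:25 fNIRS resampling (10.4 $\rightarrow$ 10 Hz) uses spline
  evaluation after anti-alias filtering; integer ratios decimate exactly.
* Filters refuse bands touching the Nyquist frequency; resampling refuses
  upsampling.
* `rejectOutliers` errors rather than silently returning an empty set when
  every window is rejected.
* Early stopping monitors training loss when no validation split is
  configured (the desk-scale folds are too small to spare one) and keeps
  the best-loss parameters.

## Known limitations

* The generator does not model volume conduction geometry, optode-specific
  photon paths, motion artifacts, or inter-subject variability; one
  synthetic subject differs from another only through the seed.
* Per-channel RPs (as opposed to channel-stacked ones) are available only
  through the configuration, not exercised by the shipped study.
* Recurrence *quantification* measures (determinism, laminarity, entropy)
  are out of scope; the plots feed a classifier, not RQA statistics.
* The absolute accuracies of the desk-scale study are specific to the
  synthetic signal model and its chosen effect size; they are not estimates
  of real-data performance.
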