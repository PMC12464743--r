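---
title: "Reconstructing respiration variation and heart rate from fMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing respiration variation and heart rate from fMRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physiorecon)
```

## The problem

Slow fluctuations in respiration depth (respiration variation, RV) and in
heart rate (HR) drive widespread, structured changes in the BOLD signal
measured by fMRI. They occupy the same 0.01–0.15 Hz band as the neurally
driven fluctuations that resting-state analyses target, so they act both as
a confound and as a physiological signal of interest. Many datasets lack
usable peripheral recordings; `physiorecon` reconstructs frame-aligned RV
and HR series directly from parcellated fMRI dynamics with a bidirectional
LSTM, and provides the surrounding pipeline: waveform feature extraction
with automated quality control, atlas-based dimensionality reduction,
response-function regression for percent-variance-explained maps, and
nuisance projection for connectivity analyses. A seeded forward simulator
generates coupled brain–body data with known ground truth so that every
stage is testable at desk scale.

## Physiological feature extraction

RV at a frame centered at time $t$ is the standard deviation of the raw
respiration-belt waveform in a 6 s window $[t-3, t+3]$; HR is
$60/\overline{\mathrm{IBI}}$, the inverse of the mean inter-beat interval
of pulse-oximetry beats whose interval midpoints fall in the same window,
in beats per minute. Both series are band-pass filtered to 0.01–0.15 Hz
with a 2nd-order Butterworth filter applied forward and backward (zero
phase, so physiology–BOLD timing is preserved) and resampled to the frame
grid of the downsampled fMRI data (1.44 s for a 0.72 s acquisition
decimated by 2).

Choices the definitions leave open, and what this package does:

* **Standard-deviation convention.** Population (divisor $n$) within the RV
  window. The distinction is a constant factor and vanishes under
  z-normalization; it is fixed here for reproducibility.
* **Edge windows** are truncated to the available samples rather than
  dropped, so every frame gets a value.
* **Frames with fewer than two beats** in the window are filled by linear
  interpolation from the nearest valid frames (nearest value at the ends),
  keeping series lengths intact for the model; interpolation happens before
  filtering because the filter needs a gap-free series.
* **Beat detection** is deliberately simple and deterministic: light
  moving-average smoothing (50 ms), local maxima above an adaptive
  threshold, and a 0.25 s refractory period in which the larger peak wins.
  The threshold is anchored at the 60th percentile of the smoothed signal
  and raised by 25 % of the remaining range above that anchor. The range
  term matters: with narrow pulses the 60th percentile sits just above the
  baseline, where smoothed measurement noise still produces local maxima;
  anchoring alone admits spurious beats at any realistic noise level, while
  the range-referenced threshold rejects them and still adapts to
  per-recording gain.
* **Quality control** follows scan-level criteria evaluated independently:
  waveform clipping at the digitizer saturation bounds (flagged when more
  than 1 % of samples saturate — single saturated samples are benign, and
  the fraction is configurable), mean HR below 30 or above 97 bpm, HR
  constant at 48 bpm (a known acquisition failure mode; "constant" means
  every frame within 0.5 bpm), and missing channels. The verdict fails
  exactly when any flag is set.

## Atlas composition and preprocessing

The parcellation is a composition of four published atlases — 400 cortical
regions, 72 white-matter bundle regions from a probabilistic atlas, 16
subcortical regions, and 9 brainstem arousal-network regions — for 497
ROIs. The probabilistic white-matter maps are thresholded at 0.95 before
labeling, excluding low-confidence voxels and limiting gray/white overlap.
Where atlases still claim the same voxel, precedence is gray-matter first
(cortical > subcortical > arousal network > white matter), configurable and
recorded in the bundle. Global ROI ids follow the concatenation order
cortical, white matter, subcortical, arousal network, because model input
channels are identified by position and the ordering must be frozen.

Per-ROI mean time series are preprocessed in the listed order: OLS removal
of linear + quadratic trends, zero-phase band-pass (0.01–0.15 Hz),
decimation by 2 keeping frames 1, 3, 5, … (a fixed, documented phase), and
z-normalization. Head-motion parameters are intentionally *not* regressed
out of model inputs: apparent motion carries respiratory information that
improves reconstruction; motion regressors enter only the connectivity
analyses.

## The reconstruction network

The model is a single bidirectional LSTM layer (hidden state $h$ per
direction) over the $R$ ROI channels, followed by dropout on the
concatenated $2h$ state and two independent linear heads that emit one RV
and one HR value per frame. Outputs have the same length as the input, and
any scan length is accepted. The bidirectional recurrence lets the network
use both past and future frames, so the hemodynamic lag between physiology
and BOLD needs no explicit modeling; the network performs the
deconvolution implicitly. Targets are intentionally the *unconvolved*
z-scored RV/HR series, avoiding commitment to a fixed response-function
shape during learning.

Reference configuration: hidden state 2000, batch 16, dropout 0.3, Adam
with initial learning rate $10^{-3}$, multiplied by 0.5 after 2 epochs
without validation improvement, keeping the weights of the epoch with the
lowest validation loss. Decisions the architecture description leaves
open:

* **Objective.** Equal-weighted sum of the two per-signal mean squared
  errors over valid frames. On z-scored targets the two terms are
  commensurate, and MSE is the standard choice for normalized sequence
  regression.
* **Variable-length batching.** Scans are padded to the batch maximum with
  a per-frame validity mask; padded frames contribute nothing to loss or
  gradients (the backward direction consumes each sequence reversed within
  its own length, so padding stays at the tail for both directions). A
  test verifies bit-level equality of a scan's predictions with and
  without batch padding.
* **Direction fusion.** The two directions' per-frame hidden states are
  concatenated (length $2h$) — the common bidirectional contract.
* **Stopping.** Epoch cap 100 with early stop after 6 epochs without
  validation improvement (three decay steps at patience 2); both are
  configurable and logged.
* **Initialization and reproducibility.** All weights are drawn uniformly
  from $\pm 1/\sqrt{h}$ (heads $\pm 1/\sqrt{2h}$); initialization, batch
  order and dropout all derive from the single configuration seed, and the
  training log (per-epoch train/validation loss and learning rate) is part
  of the returned model.

The LSTM forward pass, backpropagation through time, and Adam updates are
implemented in compiled code (RcppArmadillo) inside the package; gradients
are verified against central finite differences in the test suite.

Cross-validation is subject-wise: subjects are partitioned into five
disjoint test folds, and the remaining subjects of each fold are split into
training and validation so the overall fractions are 68/12/20. All scans of
a subject travel together; a property test asserts that no subject ever
straddles roles. Restricting `input_rois` in the configuration reproduces
single-ROI models, ranked percent-ROI models, and region-exclusion models
without code changes.

## Response functions and variance explained

For variance-explained and connectivity analyses the package assumes the
standard linear convolution model. The respiration response function is
the published difference-of-gammas form
$\mathrm{RRF}(t) = 0.6\,t^{2.1}e^{-t/1.6} - 0.0023\,t^{3.54}e^{-t/4.25}$
and the cardiac response function the published gamma-minus-Gaussian form
$\mathrm{CRF}(t) = 0.6\,t^{2.7}e^{-t/1.6} -
16/\sqrt{18\pi}\;e^{-(t-12)^2/18}$, both transcribed from their original
sources; tests pin their qualitative signatures (RRF(0) = 0, CRF's early
positive lobe and negative lobe near 12 s, decay below 5 % of peak past
50 s). Kernels are sampled at the frame spacing over a 60 s support —
both are negligible beyond ~50 s.

Each physiological signal contributes three regressors: the causal
convolution with its kernel, a temporal derivative (first difference,
leading zero), and a dispersion derivative (finite difference of the
convolution under a kernel time-axis stretch of $1+\varepsilon$, divided by
$\varepsilon$; $\varepsilon = 0.1$, configurable), absorbing small latency
and shape deviations. Percent variance explained for a series $y$ is
$100\,(1 - \mathrm{var}(r)/\mathrm{var}(y))$ where $r$ is the OLS residual
of $y$ on an intercept plus the six columns; values are clipped below at 0
(on held-out applications the raw quantity can be negative), and aliased
columns are dropped with a warning. Motion regressors never enter the
variance-explained model; they join the physiological basis only in the
connectivity nuisance set (six rigid-body parameters plus backward
first-difference derivatives).

## The forward simulator

The simulator is the package's testbed: it generates data *from* the model
the analyses assume, so recovery can be verified against known truth.

* **Latents.** RV and HR latents are correlated Gaussian noise band-passed
  by zeroing FFT coefficients outside 0.01–0.15 Hz — a zero-phase
  band-pass chosen over an IIR filter because it makes the spectral
  confinement invariant exact. Coupling uses shared-component mixing
  ($y = \rho x + \sqrt{1-\rho^2}\,\varepsilon$) before filtering, giving an
  analytic target correlation; the default $\rho = 0.275$ matches the
  population mean coupling between measured RV and HR.
* **Raw waveforms.** Respiration is a breathing-rate sinusoid (default
  1/3 Hz = 20 breaths/min, chosen so whole cycles fit the 6 s extraction
  window and windowed standard deviations are phase-stable) whose amplitude
  envelope follows the RV latent shifted by +3.5 standard deviations (the
  envelope must stay positive; 3.5 leaves the failure probability
  negligible at typical scan lengths). The pulse channel is a train of
  raised-cosine pulses whose instantaneous rate follows the HR latent
  rescaled to 70 ± 5 bpm. Because the extraction operators smooth over the
  6 s window (a boxcar with frequency response $\mathrm{sinc}(6f)$), the
  latents are pre-emphasized by the capped inverse of that response before
  synthesis: the simulator's contract is that *derived* RV/HR equal the
  latents, and without pre-emphasis the window attenuates the upper band
  enough to cap the round-trip correlation near 0.9. Waveforms are written
  on the 0–4095 ADC scale so clipping QC is exercisable on synthetic data.
* **ROI signals.** Each ROI row is
  $a_r\,\mathrm{z}(\mathrm{rv}\!*\!\mathrm{RRF}) +
  b_r\,\mathrm{z}(\mathrm{hr}\!*\!\mathrm{CRF}) + \eta_r$, z-scored, with
  loadings drawn from $U(0.5, 1.5)$ (a 10 % fraction of ROIs carries zero
  loading) and $\eta_r$ an AR(1) process (coefficient 0.3) capturing BOLD
  temporal autocorrelation with one parameter. The default marginal noise
  SD of 2.8 was fixed once so that the six true regressors explain roughly
  25 % of a loaded ROI's variance — the middle of the 20–30 % operating
  range the validation experiments target — and measured on the generator
  itself before any model training.
* **Datasets** group scans into synthetic subjects (default four scans per
  subject, echoing multi-run acquisitions); all randomness flows from one
  seed, and generation never touches the caller's RNG state.

What the simulator does **not** emulate: spatially structured noise and
motion artifacts, task-evoked activity, nonlinear or subject-specific
response functions, scanner drift beyond the linear/quadratic trends the
preprocessing removes, and realistic full-resolution 4D volumes (a small
4D writer exists for seed-map and extraction tests). Passing recovery
tests on simulated data therefore demonstrates the correctness of the
implementation and the identifiability of the model under its own
assumptions — not performance on real scans.

## Problem sizes used in validation

The shipped validation runs are sized for a desk-scale machine: the
end-to-end recovery experiment trains a reduced network (hidden state 64)
on 200 simulated scans of 50 ROIs × 300 frames at 1.44 s under a
subject-wise split, reaching median held-out correlations above 0.6 for
both signals in about two minutes on one CPU. The shuffled-pair baseline
(predictions correlated with unrelated latents) is consistent with zero.
Structural checks (497-ROI composition, 1.44 s resampling, 375 × 4 = 1500
manifest) and the OLS oracle comparisons run in seconds.

## Known limitations

* The training loop is CPU-bound R/C++; the reference configuration
  (hidden 2000 on 1500 scans) is expressed faithfully in the configuration
  defaults but is intended for GPU-scale reimplementation or patient batch
  runs, not interactive use.
* Beat detection targets clean or lightly noisy pulse waveforms; heavily
  corrupted PPG should be caught by QC rather than rescued.
* `percent_variance_explained` clips negatives, so tiny positive values on
  pure-noise inputs are expected (OLS always explains a little in-sample).
* Seed-based maps read the seed from the nearest voxel by default; a
  spherical-mean option exists but real analyses may prefer anatomically
  defined seeds.
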