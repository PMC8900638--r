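---
title: "Dynamic energy features for EEG emotion recognition: methods and design notes"
author: "dynergy authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic energy features: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynergy)
```

## The model

`dynergy` implements an EEG emotion-recognition pipeline built around a
single idea: instead of extracting features from each of the N electrode
channels separately (and concatenating N feature vectors, each carrying its
own noise), the multichannel signal s(t, i) is first projected onto one
scalar *energy sequence*

    ET(t) = sum_i w_i * s(t, i),      sum_i w_i = 1,

and all features are computed from that single series. For iid zero-mean
channel noise of variance σ², the noise contribution to the variance of the
energy sequence is σ²/N — cross-channel averaging smooths noise by a factor
N, while the class-relevant common activity survives. With uniform weights
w_i = 1/N this is the plain channel mean; the default *regional* weighting
divides the montage into four scalp regions (left/right anterior, left/right
posterior) carrying total coefficient mass 0.4/0.3/0.2/0.1, split equally
within a region, so that frontal areas with stronger emotional activation
contribute more. Both weightings are exposed because the source material
motivates the regional coefficients but prints the unweighted definition;
`weights = "uniform"` recovers the plain mean exactly.

The energy sequence of a trial is sliced by a moving window (defaults:
4 s width, 2 s step), giving 29 windows for a 60-s trial. Each window is
summarized by a 49-entry feature inventory:

* **Time domain (9):** mean, population SD, mean absolute first/second
  difference (raw and SD-normalized), instability index (SD of segment
  means), energy, Higuchi fractal dimension.
* **Frequency domain (25):** Hjorth activity/mobility/complexity of the
  DFT-band-limited signal and AR-spectrum peak frequency / in-band power
  sum, each over theta (4–7 Hz), alpha (8–13), beta (14–30), gamma (31–50)
  and the full band.
* **Dynamical (15):** approximate entropy; Shannon entropies of a six-level
  db4 wavelet decomposition (per component A6, D1–D6, plus the total
  wavelet entropy of the 7 relative component energies); differential
  entropy ½·ln(2πe·σ²_band) over delta–gamma and the full band.

The per-trial sequence of 29 window vectors is classified by a recurrent
network: a bidirectional LSTM (128 units per direction, outputs
concatenated), dropout 0.3, a second LSTM (64 units, final state), a dense
ReLU layer (128), and a softmax output, trained with RMSprop (learning rate
0.001, categorical cross-entropy, 46 epochs by default). Feature columns are
z-scored with training-fold statistics before entering the network.

Unsupervised dimensionality reduction is provided by **MIPCA**: the matrix
of pairwise mutual informations between feature columns is eigendecomposed,
components are ranked by contribution rate σ_k = μ_k / Σμ, and the smallest
l with cumulative contribution ≥ cutoff (default 0.95, conventionally
0.85–0.95) is retained; samples are projected as Z = X·B_l′.

## Tunable parameters

| parameter | default | notes |
|---|---|---|
| window width / step | 4 s / 2 s | yields 29 windows on 60-s trials (800 samples at 200 Hz, 512 at 128 Hz) |
| NSI segments M | 20 | left open at the source; 20 gives 40-sample segments in an 800-sample window; shorter windows fall back to 1-sample segments (flagged) |
| Higuchi k_max | 8 | left open at the source; the dimension is the negated LS slope of log L(k) on log k, exactly 1 for a line |
| ApEn m, r | 2, 0.2·SD(window) | standard practice; Chebyshev distance, strict d < r, self-matches included so both correlation sums are positive |
| AR order p | 10, Burg | the source gives the AR spectrum form but no order/estimator; Burg fits are always minimum-phase, with a flagged periodogram fallback |
| spectral grid | 512 points over [0, fs/2] | band power sums are sums of grid values, so they scale with grid size |
| band edges | theta 4–7, alpha 8–13, beta 14–30, gamma 31–50 Hz | as printed in the methods; delta (1–4 Hz) added for DE; "all" = no masking |
| MI bins | max(4, ⌈m^(1/3)⌉) | see numerical choices |
| MIPCA cutoff | 0.95 | configurable in (0, 1] |
| network | 128 / 0.3 / 64 / 128 | reference architecture; input 17 (`seed17`) or 19 (`deap19`) |
| training | RMSprop, lr 0.001, 46 epochs, batch 32 | batch size and loss are package choices (unspecified at the source) |

## Numerical and design choices

**The 49-entry inventory.** The feature *count* is stated at the source but
never enumerated. The default inventory (9 time + 15 Hjorth + 10 spectral +
15 dynamical) is one consistent reconstruction that both sums to 49 and
contains every feature named in the reported top-feature table. It is fully
configurable through the `inventory` argument.

**The 17-feature subset.** The reported top-feature table lists
"Hjorth-mobility/complexity" both as time-domain features and (for the beta
and full bands) as frequency features. Since the inventory computes Hjorth
parameters per band only, the two time-domain entries are mapped to the
gamma band — the only informative band (beta/gamma/all per the source's own
analysis) not already used — keeping the subset at 17 distinct columns,
matching the network's input size. The `deap19` subset adds the wavelet
entropy of the gamma-covering detail component (D2 at 200 Hz) and the
full-band spectral power sum.

**Histogram MI instead of value proportions.** The printed reduction steps
define per-feature "probabilities" as value proportions
p(x_i) = x_ij / Σ_i x_ij, which is ill-posed for negative-valued features
and never defines the joint p(x_i, y_j) needed for mutual information. The
package keeps the procedure's structure (MI matrix → eigendecomposition →
contribution cutoff) but estimates MI with equal-width histograms after a
min-shift. The literal value-proportion entropy of Steps 1–2 is available
for the diagonal via `fit_mipca(..., literal = TRUE)`.

**MI bin count.** A square-root rule (⌈√m⌉ bins) makes the histogram MI
estimator useless for this purpose: for *independent* columns its positive
bias is ≈ (B−1)²/(2m) nats, i.e. ~0.5 nats at m = 10⁴ — as large as real
dependencies. The default is therefore the cube-root rule
B = max(4, ⌈m^(1/3)⌉) (bias ≈ 0.02 nats at m = 10⁴), with `bins` exposed.
Estimation requires m ≥ 8·B samples.

**Hjorth after the DFT.** "Transform by DFT, then compute Hjorth" is read as
band-limiting by DFT masking (zeroing out-of-band bins, inverse transform)
followed by the classical time-domain Hjorth parameters, with derivatives as
first differences scaled by fs. Computing the three ratios directly on the
complex in-band DFT coefficients is available as `mode = "spectral"` for
fidelity comparisons. Variances use the population (1/N) form throughout,
matching the printed definitions.

**Degenerate inputs.** Zero-variance windows return flagged sentinels
rather than NaN: normalized differentials 0, fractal dimension 1, Hjorth
(0, 0, 0), DE = ½·ln(2πe·10⁻³⁰⁰). Band variances below 10⁻²⁴ are treated
as numerically zero because DFT masking of out-of-band signals leaves
O(10⁻¹⁶) roundoff residue. Eigenvector signs are fixed (largest-magnitude
entry positive) for reproducibility. The periodized db4 transform pads
odd-length levels by repeating the last sample (flagged; an 800-sample
window pads once at level 6); on dyadic lengths the transform is orthonormal
and conserves energy to ~10⁻¹⁰ relative.

**Montage presets.** The printed region tables contain obvious typos, which
the presets normalize: EP1→FP1, AP4→AF4, 01→O1, FC8→FT8, and the duplicated
FC5 in the 62-channel region 1 is read as FC1 — the only standard
62-channel montage label otherwise missing, and the only reading that gives
62 unique channels with 14 in region 1. "C8" is kept as printed although
the extended 10–20 system calls that position T8. Matching is
case-insensitive and whitespace-insensitive; a channel listed under two
regions is assigned to the first.

**Trial excerpting.** The 60-s analysis excerpt starts at 60 s for
240-s (SEED-like) trials and at second 4 for 63-s (DEAP-like) trials; both
are plain subsetting of the recording before projection and are left to the
caller, since the package operates on whatever excerpt it is given.

## What the synthetic generator does and does not emulate

Each synthetic trial is a sum over bands of band-limited Gaussian noise
*shared across channels* (the "common activity"), scaled per channel by a
region gain (proportional to the regional coefficients, mean 1) and a
per-subject channel gain ~ N(1, 0.1), plus iid N(0, 1) channel noise and a
per-subject DC offset. Class identity acts only through per-band component
amplitudes; the default two-class world doubles the gamma-band amplitude of
class 2 and keeps all other bands equal. Subject effects are constant
across a subject's trials, which makes leave-one-subject-out genuinely
harder than trial-level k-fold, mirroring the ordering seen on real
corpora. Everything is deterministic given the configuration seed.

This emulates: the corpus shapes (62 ch @ 200 Hz or 32 ch @ 128 Hz, 60-s
trials), band-structured common activity, channel noise obeying the σ²/N
smoothing law, and a recoverable class signal in a known band. It does
*not* emulate: non-stationarity, artifacts (blinks, EMG), 1/f spectral
shape, volume-conduction correlation structure, channel-specific spectra,
or label noise. A green end-to-end test therefore establishes that the
pipeline recovers a planted band-power class difference through the energy
sequence — not that it attains any particular accuracy on real EEG corpora,
which are access-restricted and out of scope.

## Evaluation protocols

`evaluate_loso()` holds each subject out in turn; `evaluate_kfold()` uses
label-stratified, seed-deterministic folds at trial level. All
fold-dependent fitting — feature standardization and (optionally) MIPCA —
happens strictly inside the training fold. The RBF C-SVC baseline
(`baseline_svm()`) summarizes each trial by window-mean features and scans
the penalty over 2⁻³…2⁸ with inner 5-fold selection; it exists as the
comparison path for the sequence classifier and is implemented in-package
(simplified SMO) because no SVM library is part of the supported
dependency set.

The network input defaults to the named 17/19-feature subsets (matching the
reference input sizes); projecting onto MIPCA components instead is
available via `use_mipca = TRUE`, since the source leaves ambiguous which
of the two feeds the network.

## Known limitations

* Headline accuracies of the motivating study are not reproducible here:
  both underlying corpora are registration-gated, so the package validates
  structure, closed forms, estimator-oracle agreement and parameter
  recovery on synthetic data instead.
* The EDF writer/reader supports the plain 16-bit format with a uniform
  sampling rate across signals — no EDF+ annotations.
* The SMO solver targets small-n baselines (kernel matrices are
  materialized); it is not a general-purpose SVM.
* Histogram MI is a biased estimator; the cube-root bin rule controls but
  does not remove the bias, and the MI matrix is only approximately PSD.

```{r example}
cfg <- synthetic_config(n_subjects = 2, trials_per_subject = 6,
                        duration_s = 12, seed = 5)
sf <- synthetic_features(cfg, spec = window_spec(4, 2))
sf$features
```
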