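---
title: "Methods: multimodal postural-control biomarkers in swaylab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal postural-control biomarkers in swaylab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

swaylab analyses a 320-second postural-control protocol: a 2-minute
quiet-stance baseline, a 40-s quiet-stance **PRE** phase, three 40-s
platform-perturbation segments at 25/50/75 % of maximal wave amplitude, and a
40-s quiet-stance **POST** phase performed identically to PRE. Because PRE and
POST differ only in what preceded them, the difference **POST − PRE** of any
feature isolates the adaptation of the postural-control system to the
perturbation. Four modalities are recorded simultaneously — centre-of-pressure
(CoP) displacement at 90 Hz, 64-channel EEG, six-muscle lower-limb surface
EMG at 1600 Hz, and heart rate at 1 Hz — alongside a 22-item concussion
symptom questionnaire (each item 0–6, severity = sum, range 0–132).

This vignette records the model choices, parameters, and numerical decisions
behind each stage, and what the synthetic cohort generator does and does not
emulate.

## Protocol conventions

Segments are half-open intervals `[start_s, end_s)` sliced by sample index
`[floor(start * fs), floor(end * fs))`, so contiguous segments never share a
sample. Time zero is the first sample of the baseline; all modalities are
assumed synchronized (the hardware performs the alignment; no cross-modal
drift correction is attempted). The narrative description of the protocol
gives PRE as 35 s while the protocol table gives 120–160 s; the package
follows the table (40 s), which all downstream windows (5-s trims, central
30 s) assume.

## CoP stabilogram battery

Raw AP/ML displacement in cm is smoothed with a Savitzky–Golay filter,
window 7 samples. The polynomial order is not dictated by the protocol; the
package defaults to 3, the standard choice below a 7-sample window (order ≥ 4
reproduces the data too faithfully to smooth; ≤ 2 distorts peaks). Both axes
are then mean-centered, so all distance features are measured from the mean
CoP position.

The feature set per phase (28 scalars): path lengths (TOTEX on the plane and
per axis), mean and RMS distances (MDIST, RDIST), per-axis SDs, extreme-point
magnitudes (anterior = max AP, posterior = |min AP|, analogous on ML, with
anterior positive by convention), mean velocities (TOTEX over duration), the
95 % confidence ellipse, mean absolute heading change, sample entropy and
multiscale complexity indices, and the spectral power-law exponent per axis.

**Ellipse.** The 2×2 AP/ML covariance is eigen-decomposed; axis half-lengths
are `sqrt(lambda_i * q)` with `q = qchisq(0.95, 2) ≈ 5.991`. The population
covariance (divisor *n*) is used without the small-sample F correction: with
2700–3600 samples per phase the correction is below 0.1 %. Identical points
give a zero-axes ellipse rather than an error; orientation is reported in
`(-pi/2, pi/2]` measured from the ML axis.

**Sample entropy.** SampEn(m, r) with m = 2 and r = 0.2 × series SD, the
community-standard parameterization for physiological series of this length
(the protocol leaves both unstated). Chebyshev distance, self-matches
excluded. Tolerance proportional to SD makes the measure invariant under
affine amplitude scaling. If no template pair matches at length m + 1 the
conditional probability is undefined; the value is returned as `NA`, excluded
from group statistics (with a count), and group-median imputed if it ever
reaches the classification table. The complexity index sums SampEn over
non-overlapping coarse-graining scales 1–6, holding r fixed at the scale-1
value (the usual multiscale-entropy convention, so the index reflects
structure, not the mechanical SD shrinkage of averaging).

**Multivariate entropy.** The AP/ML pair is embedded with composite delay
vectors (m samples from each channel); the (m+1)-level set extends each
vector by one sample in either channel. Extended-level pairs sharing a time
index are excluded: their level-m bases are identical, so counting them
inflates the numerator and can push the estimate negative — excluding them is
the natural generalization of self-match exclusion and keeps the estimate a
conditional probability. The tolerance is relative to the per-channel-averaged
SD.

**Spectral exponent.** One-sided periodogram (FFT magnitude squared, scaled
as power/Hz), ordinary least squares of log10 power on log10 frequency over
0.1–5 Hz. The band is a package default: below 0.1 Hz a 40-s record carries
at most 4 cycles (unstable estimates), above 5 Hz instrumentation noise
flattens real sway spectra. The fit requires at least 5 bins in band.

## EEG band powers and electrode statistics

Per segment, in order: trim 5 s from each end (guarding transition
artifacts), resample to 1024 Hz, 50 Hz notch, 1–45 Hz band-pass. Filters are
applied zero-phase (forward–backward): only band *powers* are consumed, so
phase distortion buys nothing and zero-phase keeps tone amplitudes exact. The
notch is a biquad with quality factor 30; the band-pass a 4th-order
Butterworth. Resampling is FFT-domain truncation, exact for content below the
new Nyquist (synthetic data contain nothing above 45 Hz). A 40-s segment
yields 30 s at 1024 Hz.

Welch PSD uses 2-s Hann windows at 50 % overlap — 0.5 Hz resolution, giving
the narrow delta band (1–4 Hz) six bins while still averaging 29
periodograms per 30-s segment. Band powers integrate the PSD over delta
(1–4), theta (4–8), alpha (8–13), beta (13–30), and low gamma (30–45 Hz) as
half-open intervals (the last closed); relative powers divide by the total
over 1–45 Hz and sum to one per channel.

The electrode-wise statistic is a paired two-tailed t-test of POST vs PRE
relative power across a group's subjects, per electrode, with
Benjamini–Hochberg FDR across the 64 electrodes. The correction family is
one band within one group, matching per-band reporting of electrode maps.
For the classification table the 64 channels are reduced by averaging the
relative powers across electrodes (5 bands × 2 phases = 10 features); the
electrode-to-feature reduction is not pinned down by the protocol and
averaging is the minimal choice consistent with a 10-feature EEG block.

The artifact pipeline of real recordings (ICA-based artifact removal,
bad-channel interpolation) is out of scope — synthetic inputs are
artifact-free — but `preprocess_eeg()` is the natural hook point where such
steps would be inserted.

## EMG and heart rate

EMG is filtered with a 50th-order (51-tap) windowed-sinc (Hamming) FIR
band-pass, 40–500 Hz, applied causally; the constant group delay is
irrelevant to areas and spectra, and the literal "order 50" design is kept.
The rectified-area feature integrates |signal| trapezoidally over the full
40-s phase; spectral features use the central 30 s of the phase (5 s dropped
each end) to exclude transition effects — the area uses the full phase
because cumulative activation is the quantity of interest, while spectra are
sensitive to the transition bursts.

From the one-sided FFT power spectrum restricted to 40–500 Hz: total power
(the sum, rising with contraction force), kurtosis and skewness computed as
*biased* sample moments of the vector of spectral values with the
normal-equals-3 convention (these describe the spectrum's shape: a more
symmetric, Gaussian-like spectrum lowers both), and the median frequency —
the smallest bin at which cumulative power reaches half the total (the
classic fatigue marker; the smallest-bin tie-break makes the value exact on
discrete spectra). An all-zero spectrum leaves the descriptors undefined
(`NA`), never fabricated.

Heart rate is summarized as mean and SD of bpm per phase; the five
non-baseline phase means are the heart-rate block of the feature table. The
recording hardware's nominal rate is reported inconsistently in the protocol
description (1 Hz vs 1000 Hz); the generator uses 1 Hz, which matches a
per-second bpm stream.

## Group statistics

PRE-vs-POST comparisons use the two-tailed Wilcoxon matched-pairs signed-rank
test (exact for ≤ 25 untied nonzero differences, tie-corrected normal
approximation otherwise; zero differences dropped with a logged count).
Between-subgroup comparisons (e.g. balance-problem vs not, in POST) use the
two-tailed Mann–Whitney test, exact for small untied samples. The
Shapiro–Wilk normality result is computed and reported but the nonparametric
outcome is always the one flagged — switching tests on the observed normality
p-value would make the reported test data-dependent.

Symptom subgroups are concussed subjects whose questionnaire item exceeds
zero; the threshold is a package decision (the scale has no published
cut-off) and item 5 encodes balance problems in the generator's layout.

The group-summary t-test (`two_sample_t_from_summary()`) is the
pooled-variance Student form: it reproduces printed t statistics computed
from (n, mean, SD) rows exactly — the Welch form does not — with df
n1 + n2 − 2.

## Classification stage

The 51-column biosignal table comprises 5 HR phase means, 12 EMG areas, 12
EMG median frequencies, 10 EEG band powers, and 12 CoP values (the six most
discriminative stabilogram features — TOTEX, MDIST_AP, MVELO, ellipse main
axis, SD_AP, posterior magnitude — each for PRE and POST). Three feature
selections feed the classifiers: the leading 9 principal components of the
z-scored biosignal table, the 22 raw questionnaire items, and their
31-column concatenation.

Five models are evaluated: random forest (300 trees), linear-kernel SVM
(C = 1, standardized in-fold), AdaBoost over depth-1 stumps (100 rounds,
SAMME), a single-hidden-layer perceptron (16 units, up to 1000 iterations,
standardized in-fold), and gradient boosting (100 rounds, learning rate 0.1,
depth 3). Hyperparameters are ordinary defaults, not tuned. Evaluation is
stratified 10-fold cross-validation repeated over ten seeds; per seed the
fold confusion matrices are pooled, and the reported accuracy, sensitivity
(recall of the concussion class — the positive class, since sensitivity
should track detection of the condition), and specificity are means over
seeds, in percent.

By default the PCA (and the z-scoring it needs) is refit inside each
training fold so the test fold never leaks into the projection;
`pca_before_cv = TRUE` reproduces the simpler fit-once-then-cross-validate
ordering. The difference matters at n = 54 and is worth a deliberate switch.

## The synthetic cohort generator

The generator exists so every stage is testable end to end without any data
download. Defaults emulate the study conditions: 26 concussed and 28
non-concussed athletes; questionnaire severity targets 36.47 vs 3.71 points
(items drawn independently binomial(6, p) with p calibrated so the expected
sum hits the target); a balance-problem subgroup of 14 of the 26 concussed
subjects, with the flag forced consistent with the balance item.

Signals per (modality, phase) segment:

* **CoP** — power-law (colored) Gaussian noise, synthesized by
  frequency-domain shaping (amplitude ∝ f^(−α/2)) and normalized to unit SD,
  scaled to a per-group, per-phase RMS amplitude, plus a small 0.08 Hz
  oscillatory drift (0.05 cm) placed *below* the power-law fit band so it
  does not bias exponent recovery. PRE exponent 1.2 everywhere; POST is
  steeper (1.4) and larger (0.75 vs 0.40 cm RMS) for concussed subjects,
  slightly larger (0.45 cm) for non-concussed. Because path-length features
  weight high frequencies (the mean step scales roughly like
  f_max^(3−α) × amplitude²), amplitude and exponent trade off; the defaults
  were calibrated once so the planted POST rise in TOTEX-type features is
  real rather than cancelled by the smoother spectrum.
* **EEG** — per channel, Gaussian noise with a piecewise-constant amplitude
  spectrum over the five bands (3/2/2/1/0.5 µV·Hz^(−1/2) for
  delta/theta/alpha/beta/low-gamma, a plausible 1/f-ish resting profile).
  Band amplitudes receive a lognormal per-phase jitter (SD 0.05, shared
  across channels) so POST−PRE differences carry subject-level variability
  rather than only estimator noise. For concussed subjects in POST, theta
  and delta amplitudes on ten frontal electrodes (Fp1, Fpz, Fp2, F3, Fz, F4,
  AF3, AF4, FC1, FC2) are multiplied by 1.3.
* **EMG** — per muscle, Gaussian noise with a Gaussian-shaped amplitude
  spectrum (centres 120/110/100 Hz for TA/GL/soleus, bandwidth 80 Hz)
  truncated to 40–500 Hz. Concussed POST soleus power is multiplied by 1.5;
  balance-problem subjects get a +15 Hz right-soleus centre shift in POST (a
  median-frequency shift).
* **HR** — baseline 75 bpm plus phase offsets (+5 PRE, −2 during platform
  motion while holding the bars, +8 POST) plus Gaussian noise, SD 3 bpm
  (concussion) vs 1.5 (non-concussion), clamped positive.

Noise synthesis draws complex Gaussian coefficients only at bins where the
amplitude profile is nonzero, without Hermitian symmetry, and uses the real
and imaginary parts of one inverse FFT as two independent real channels —
distributionally identical to shaping white noise, at a fraction of the
cost.

Reproducibility: each (subject, modality, phase) segment has its own seed
derived deterministically from the master seed, so regenerating any subset
of segments is bit-identical to slicing the full recording — feature
pipelines stream exactly the segments they need
(`stream_subject_features()`), keeping memory flat (a single full recording
is ~170 MB at the default EEG rate). EEG is generated directly at 1024 Hz —
the rate preprocessing resamples to — with `eeg_fs = 4096` available to
exercise the resampling step.

**What the generator does not emulate:** motion and ocular artifacts,
electrode noise and bad channels (hence the artifact pipeline is out of
scope), volume-conduction correlation between electrodes, biomechanics of
the platform segments beyond amplitude scaling, non-stationarity within a
phase, and any coupling between modalities. Passing tests therefore
demonstrate that the pipeline recovers what it measures under clean,
stationary, independent-channel conditions — not that the planted effect
sizes are physiologically calibrated.

## Numerical decisions and degenerate inputs

* A stabilogram whose smoothed axes have SD below 1e−12 is treated as static
  (smoothing a constant leaves ~1e−16 residue): distances, velocities,
  ellipse, entropies, heading, and exponents all return 0.
* Heading change skips zero-length steps; a path with no nonzero step is an
  error.
* Median frequency: smallest bin reaching half the cumulative power.
* Undefined entropies/descriptors are `NA` (a distinct marker), excluded
  from rank tests with a per-feature count, and group-median imputed only at
  classification-table assembly (none of the 51 table columns can be
  undefined on non-degenerate signals).
* The fused filter-plus-Welch path used by the band-power pipeline is
  asserted (in the test suite) to agree with the composable
  `preprocess_eeg()` + `welch_psd()` reference to ~1e−16.
* Wilcoxon zero differences are dropped (standard convention) and counted.

## Problem sizes used by the test suite

The suite exercises the study-scale conditions directly: the structural
criteria run the full 54-subject cohort with EEG at 1024 Hz; planted-effect
recovery uses 50 replicate cohorts of 20 concussed subjects for the
electrode maps, 20 draws per exponent for the power law, 10⁴ points for
ellipse coverage, and 60–100 draws for the EMG gains; null calibration uses
200 effect-free cohorts of 20 subjects (CoP features without the entropy
block, which has its own oracle tests). These sizes are the package's
choices, balancing statistical resolution of the Monte-Carlo checks against
a desk-scale run.

## Known limitations

* The multivariate entropy variant is one of several reasonable composite
  formulations; absolute values are not comparable across packages, though
  orderings are stable.
* Electrode-averaged EEG features discard topography; the electrode-wise
  statistics retain it, but the classifier never sees per-channel values.
* The generator's group effects are additive and independent across
  modalities; no attempt is made to model symptom-to-signal causal structure
  beyond the planted shifts.
* Classification metrics on synthetic cohorts reflect the planted effect
  sizes and are not estimates of real-cohort performance.
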