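---
title: "Oscillatory analysis of olfactory bulb-piriform cortex signals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oscillatory analysis of olfactory bulb-piriform cortex signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`olfosc` implements a family of analyses for two-region source-level
electrophysiological trial data — olfactory bulb (OB) and piriform cortex
(PC) time courses sampled around odor onset — aimed at one scientific
question: which aspects of the oscillatory OB–PC dialogue track the
*perceived intensity* of an odor, as opposed to its physical
concentration. This vignette documents the models, their assumptions, the
tunable parameters, and the design decisions behind the implementation.
It states no empirical result beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## The data model

A dataset is a list of per-participant `trial_set` objects (numeric arrays
of trials × regions × samples with a common time axis and sampling rate)
plus one behavioral table row per trial: the participant id, continuous
intensity and valence ratings on a 0–10 scale, the nominal concentration
label (Low/High), and two respiratory covariates (sniff amplitude and
sniff area-under-curve) that enter every model as nuisance fixed effects.
`median_split()` dichotomizes intensity within participant for the
classification analyses: ratings strictly above the participant's median
are "high", ties at the median fall to "low", and participants with a
rating range under 1.0 (too little variability to dichotomize) are
flagged.

## Superlet time–frequency maps

Wavelet spectrograms trade time against frequency resolution through the
cycle count of the analysis wavelet. The multiplicative superlet
estimator combines both regimes: at frequency $f$ the power estimate is
the geometric mean of the magnitude responses of Morlet wavelets with
$o \cdot c_1$ cycles, $o = 1 \dots O(f)$, so short wavelets contribute
temporal precision and long wavelets spectral precision.

Parameters and defaults:

* `base_cycles = 8` — the order-1 wavelet's cycle count. The wavelet's
  Gaussian SD is $s = c/(5f)$, i.e. its effective support spans roughly
  $c$ periods. We read the analysis convention "width 8" as the base cycle
  count; the alternative reading (maximum order) is available by setting
  `base_cycles` and `order` explicitly.
* `order = superlet_orders(freqs)` — a linear ramp from order 1 at the
  lowest analysis frequency to 8 at 100 Hz, rounded up. The literature
  specifies only that the order adapts with frequency band; a linear ramp
  is the simplest monotone schedule.
* Frequency grid and frame rate are caller-chosen. 1 Hz × 10 ms resolves
  100-ms-scale effects; the tests run coarser grids (2–3 Hz, 25–250 ms)
  purely for tractability, which is sufficient because every assertion is
  about band/window-level structure, not single cells.
* Edges: signals are reflection-padded by one longest-wavelet
  half-length; frames whose longest wavelet support crosses the padding
  are flagged in `meta$edge` rather than dropped, so the caller decides.
* No baseline correction is applied before the mixed models: the
  rank-inverse-normal transform absorbs any monotone rescaling of power.

Complex coefficients for coherence come from the order-1 (base) wavelet;
power from the full geometric mean. Amplitude normalization is such that a
unit-amplitude sinusoid at the analysis frequency yields power ≈ 1.

Coherence between regions is the trial-normalized cross-spectrum of those
coefficients, $|\sum_t x\bar y|^2 / (\sum_t |x|^2 \sum_t |y|^2)$, computed
over a trial subset (at least two; single-trial "coherence" is identically
one).

## Mass-univariate mixed models with weighted cluster-mass correction

Each time–frequency cell is modeled as

```
rank_inverse_normal(power) ~ predictor + valence + sniff_amplitude +
                             sniff_auc + (1 | participant)
```

with `predictor` either the continuous intensity rating or the
concentration label. The rank-inverse-normal (Blom) transform,
$\Phi^{-1}((r - 3/8)/(n + 1/4))$, enforces an approximately normal
response; a per-cell Shapiro–Wilk p-value on the conditional residuals can
be recorded as a QC layer (`shapiro = TRUE`).

Multiple comparisons are handled by a Monte-Carlo weighted cluster-mass
(WCM) test: cells with two-sided voxel $p <$ `forming_alpha` (default
.05) are joined by 8-connectivity within each t-sign, each cluster's mass
is $\sum |t|^w$ (default $w = 2$, i.e. a sum of squared t values), and the
observed masses are referred to the distribution of per-permutation
maximum masses. Permutations shuffle only the predictor of interest
*within participant*; covariates stay with their trial, preserving the
nuisance structure under the null. Corrected p-values are
$(1 + \#\{M_{null} \ge M\})/(B + 1)$ and can never undercut $1/(B+1)$.
Restricted-window analyses (e.g. a 0–500 ms early window) are the same
machinery under a frame mask.

Two fitting engines produce the per-cell t statistics:

* `engine = "lmer"` — lmerTest with Satterthwaite degrees of freedom, the
  reference implementation.
* `engine = "gls"` (default for maps) — a profiled-REML random-intercept
  fitter written for the permutation workload. The data are rotated into
  the eigenbasis of the grouping structure (per-participant mean vector
  plus orthonormal Helmert contrasts), where the covariance is diagonal
  for any variance ratio $\lambda = \sigma^2_b/\sigma^2_e$; the REML
  criterion is profiled on a 58-point log-spaced $\lambda$ grid, and all
  map cells are fitted simultaneously with matrix operations. A unit test
  holds its t values to within 2% of lmerTest across random-intercept
  strengths from 0 to 5× the residual SD. This is what makes
  1,000-permutation × thousands-of-cells refits tractable; the grid
  discretization affects observed and permuted maps identically, so the
  permutation p-values remain exact in distribution.

Cluster-level summaries report the mass, extent, corrected p, and the
peak-cell t. No claim is made to reproduce any particular convention for
"cluster t" values beyond the peak cell.

## Directed connectivity

The cross-spectral density over the stimulus window (default 0–2 s) is
estimated with DPSS multitapers at 3 Hz half-bandwidth smoothing
($K = 2TW - 1$ tapers; the tapers are computed from the standard
tridiagonal eigenproblem). The generator produces one signal per region;
this stands for hemisphere-averaged source time courses.

Spectral Granger causality is computed nonparametrically: Wilson's
iterative spectral matrix factorization decomposes $S(f) = H(f) \Sigma
H^*(f)$ (with a $10^{-8}\cdot\mathrm{tr}$ diagonal loading for numerical
positive-definiteness), and Geweke's formula gives the directional terms,
e.g. $gc_{y\to x}(f) = \ln S_{xx} / (S_{xx} - (\Sigma_{yy} -
\Sigma_{xy}^2/\Sigma_{xx}) |H_{xy}|^2)$. Every accepted factorization
reconstructs the input CSD to within $10^{-6}$ relative Frobenius error;
non-convergence is an error, never a silent fallback. A parametric
VAR-based Geweke spectrum (`var_granger_spectrum`) exists solely as the
independent oracle for tests and the acceptance script.

Group-level direction is the per-participant band-mean
$gc_{x \to y} - gc_{y \to x}$ — the subtraction removes variance common to
both directions — tested against zero with a two-tailed one-sample t test.
Band edges for the contrast default to beta 12–30 Hz and gamma 70–100 Hz
and are configurable. Trial spectra are averaged within participant (the
alternative, concatenating trials, changes the stationarity assumption,
not the estimator).

## Searchlight decoding

The trial-averaged OB–PC coherence spectrogram, one map per participant
per intensity class, is tiled with 12 Hz × 100 ms bins at 50% stride.
Bins with fewer than 10 neighboring bins within a two-bin Chebyshev
radius are excluded — an interior-only searchlight; because "neighbor"
could also mean cells within a bin, that reading is available as
`neighbor_rule = "cells"`. Each retained bin yields one example per
participant per class (the bin's coherence cells as features). A linear
SVM (C = 1; features z-scored with training-fold statistics only) is
evaluated leave-one-participant-out, holding out both of a participant's
class examples per fold. Significance: class labels are shuffled within
participant (preserving the pairing structure — with $P$ participants
there are only $2^P$ label patterns, which the implementation memoizes
exactly), bin accuracies are z-scored against the shuffle distribution,
and suprathreshold bin clusters are corrected with the same WCM machinery
on the bin grid. Per-class accuracies are retained for confusion
summaries.

## Phase–amplitude coupling

The Tort modulation index bins instantaneous amplitude by instantaneous
phase (18 bins of 20°), normalizes the binned means to a distribution
$P$, and reports $KL(P \| \mathrm{uniform}) / \log 18 \in [0, 1]$. Phase
and amplitude come from zero-phase FIR band-passes of the full epoch
followed by Hilbert transforms, then cropping to the analysis window —
filtering inside a 150 ms window would be all edge artifact. The default
window is 150 ms centered near 1 s post-onset, the period in which
coherence analyses indicate top-down PC→OB transfer; defaults are beta
12–16 Hz phase and gamma 70–90 Hz amplitude, both from the OB signal
(which region supplies the phase is configurable; the underlying
physiology motivates either choice and the methods literature does not
settle it). A 150 ms window holds only ~2 beta cycles, so single-trial MI
is noisy by construction; inference therefore runs across all trials with
the same mixed model as the power analyses, on rank-transformed MI.

One practical point the implementation surfaces: phase–amplitude
modulation of a carrier at $f_c$ by phase frequency $f_p$ lives in
sidebands at $f_c \pm f_p$. An amplitude band must contain those
sidebands for the modulation to survive filtering; the synthetic
generator therefore injects PAC on a *broadband* (band-passed noise)
carrier rather than a sinusoid.

## Burst analysis

Bursts are transient suprathreshold oscillatory events, detected per
trial on a time–frequency map: a cell is suprathreshold when its power
exceeds the mean plus one SD of its 10-trial block; the band-collapsed
suprathreshold frames form runs, and runs longer than three cycles of the
band's arithmetic mean frequency (beta 12–30 Hz: 143 ms; gamma
30–100 Hz: 46 ms) become events with onset, offset, peak frequency, peak
power, and duration in cycles.

Two deliberate design choices:

* **Block statistics exclude the scanned trial** (`exclude_self = TRUE`).
  If a trial's own burst enters its threshold, one strong event inflates
  the block SD at exactly its own cells, and the threshold tracks ~0.4×
  the burst's own power envelope: detected onsets then lag the true onset
  by a fixed fraction of the burst duration regardless of amplitude. A
  leave-one-trial-out block statistic is an unbiased reference for the
  scanned trial; the included-trial variant remains available.
* **Burst detection wants a fast TFR.** The superlet settings used for
  the power maps (8 base cycles with an order ramp) smear a 100 ms event
  over ~250 ms and destroy the 3-cycle duration discrimination; the
  pipeline's burst stage therefore uses an order-1, 2–3-cycle Morlet map.
  Band collapse defaults to the per-frame maximum across band cells
  (bursts are narrowband); `collapse = "mean"` suppresses single-cell
  noise crossings and is what the burst localization tests use.

Burst rates are event-onset counts per frame, spread over a 100 ms boxcar
(edge-clipped kernels are renormalized, so each event contributes exactly
one count and the series integral equals the event count exactly), scaled
to bursts/s. Rate time courses are analyzed per frame with the standard
mixed model after a Box–Cox transform of `rate + 1` (rates contain
zeros); the exponent is chosen per frame by profile likelihood over a
fixed grid, and the time axis is corrected with 1-D WCM clusters.

## The synthetic generator

`generate_dataset()` produces the study conditions the analyses assume:
by default 46 participants × 123 trials, 512 Hz, epochs −1 to +4 s with
odor on 0–2 s. Signals are Gaussian $1/f^\alpha$ noise ($\alpha = 1$,
generated in the frequency domain, matching broadband field-potential
spectra) plus additive injected effects:

* `power_effect` — Hann-windowed narrowband noise whose amplitude is
  $a(1 + \beta \Delta i)$, with $\Delta i$ the trial's mean-centered
  intensity: a within-participant slope for the LME to recover.
* `pac_effect` — a broadband amp-band carrier with envelope
  $1 + d\cos\phi$ of the background's phase-band component, $d$ optionally
  intensity-linked.
* `coupling_effect` — gain-scaled, lagged, band-passed activity of one
  region added to the other: a pure directed influence.
* `burst_effect` — Hann-tapered oscillations with Poisson counts whose
  rate is intensity-linked.

Ratings are drawn from a concentration-conditioned two-component Gaussian
model clipped to [0, 10]. The printed class statistics this emulates
(3.36 ± 2.14 and 6.80 ± 1.86) are *post-median-split* class means; with
overlapping components, mass crosses each participant's median, so the
component means must sit inside the targets. The generator uses component
means (4.196, 5.943), calibrated once by large-n simulation and frozen,
which reproduce post-split class means of 3.36/6.80 to within ±0.01 at
cohort scale — and the ~102% low-to-high difference. The component
overlap also reproduces the dissociation the analyses rely on: the
median-split intensity class disagrees with the concentration label on a
meaningful fraction of trials. Sniff AUC carries a weak positive
intensity dependence (mirroring the respiratory validation analysis);
sniff amplitude is independent.

Identical configurations (including the seed) generate bit-identical
datasets; effects superpose additively, so regenerating without an effect
returns the background exactly.

Effect magnitudes in physical units are not pinned down by the analyses
the generator serves; they are free parameters chosen once so that the
recovery experiments run at comfortable power at desk scale (e.g. the
beta power effect at `amplitude = 1.2`, `slope = 0.15` per rating unit —
roughly a 15% amplitude change per point — and burst SNRs of ~4–20× the
noise floor). What passing recovery tests show is that the pipeline
detects what was injected where it was injected and stays calibrated when
nothing is; they do not certify sensitivity at any particular real-world
effect size, nor do the Gaussian, stationary, artifact-free synthetic
signals exercise preprocessing robustness.

## Problem sizes and numerical choices

The test suite and acceptance script run everything at desk scale, chosen
as the package's own verification conditions: null calibrations use 100
datasets of 6 participants × 40 trials at 200 permutations (the
family-wise error rate is compared with the exact binomial 95% interval
around .05); effect recovery uses 20 seeded runs; decoding calibration
uses 50 replicates at 200 label shuffles; Granger and PAC calibrations
use 40 and 20 replicates at cohort sizes of 10 participants (very small
cohorts push the random-intercept variance to its boundary, where
Satterthwaite p-values are known to run slightly hot — a property of the
mixed-model approximation, not of the pipelines). Sampling rates in tests
(64–256 Hz) are set by the highest band analyzed, epochs span −0.5 to
+2.5 s, and analysis grids are 2–5 Hz × 30–250 ms.

Numerical details worth knowing: Wilson factorization iterates to a
$10^{-9}$ relative residual (machine precision is typically reached
within ~10 iterations; the self-paired lags — zero and Nyquist — take the
triangular split of the causal-part operator); Morlet wavelets are
truncated at ±3 Gaussian SDs; the λ-profile grid spans $10^{-3}$–$10^3$;
Box–Cox exponents are profiled over −1…2 in steps of 0.25; ties in ranks
take average ranks; cluster labeling is 8-connected flood fill; all
permutation schedules and the generator consume named child seeds derived
from one master seed, so every result in the package is reproducible from
a single integer.

## Known limitations

The package starts at source time courses: electrode recordings, source
reconstruction, and artifact preprocessing are out of scope. Granger
estimates are bivariate (no conditional/multivariate extension) and
time-averaged over the analysis window (no sliding-window variant).
Decoding is participant-level binary classification; no trial-level or
multiclass decoding. The synthetic generator makes no attempt at
biophysical realism — it encodes the statistical structure the analyses
assume, which is exactly what makes it a useful verification instrument
and nothing more.
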