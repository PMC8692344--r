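---
title: "Methods: sleep-EEG spectral analysis and data-driven insomnia subtyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep-EEG spectral analysis and data-driven insomnia subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnotype)
```

## Overview

`somnotype` turns overnight polysomnographic (PSG) EEG into quantitative
phenotypes of insomnia. The pipeline runs in five stages:

1. **Spectral analysis.** Six referenced EEG channels (F3-M2, F4-M1, C3-M2,
   C4-M1, O1-M2, O2-M1) are segmented into consecutive non-overlapping 5-s
   epochs, artifact-screened, Hann-windowed and Fourier-transformed; the
   one-sided power spectral density (PSD, uV²/Hz, 0.2 Hz resolution) is
   integrated over the five standard bands — delta [0.5, 4.5), theta
   [4.5, 8), alpha [8, 12), sigma [12, 15) and beta [15, 32] Hz — and
   averaged per sleep stage, per channel, and across channel groups
   (global, left and right hemispheres).
2. **Macroarchitecture.** Standard summary metrics from the 30-s hypnogram:
   time in bed (TIB), total sleep time (TST), sleep efficiency
   (SE = 100·TST/TIB), sleep-onset latency (SOL), wake after sleep onset
   (WASO), terminal wake, stage minutes and percentages, REM latency, and
   arousal indices with stage-time denominators.
3. **Indices.** The interhemispheric asymmetry index for delta power,
   `IAI = (ΣL − ΣR)/(ΣL + ΣR)` over the usable left/right channel
   stage-average delta powers (positive = left dominant), and the
   sleep-state misperception index
   `SSM = (objective TST − subjective TST)/objective TST`
   (positive = underestimation).
4. **Subtyping.** A 33-variable per-subject feature matrix is z-scored,
   reduced by PCA (10 retained components by default), clustered by Ward's
   minimum-variance agglomeration on Euclidean distances, and the number of
   clusters selected by a column-permutation test on the dendrogram.
5. **Characterization.** Descriptive per-subtype means ± SEM of all
   features, sleep quality and SSM, with optional paired night-1 versus
   acute bedtime-restriction (night-2) deltas. No inferential statistics
   are computed.

A synthetic cohort generator with planted subtype structure closes the
loop: every stage of the pipeline has a ground-truth recovery test.

## Spectral estimation

Each 5-s epoch (n samples at sampling rate fs) is multiplied by a periodic
Hann window `w` and transformed with an FFT. The one-sided PSD uses the
variance-preserving normalization `2|X|²/(fs·Σw²)` (DC and Nyquist bins not
doubled), which makes the discrete Parseval identity exact: the integral of
the PSD over frequency equals the windowed mean power `Σ(xw)²/Σw²`. A pure
sinusoid of amplitude A integrates to A²/2 (window-corrected), and white
noise of variance σ² to σ² in expectation; both are enforced by tests.

Band powers are integrals of the piecewise-linear PSD interpolant over each
band interval, with interpolated points inserted where band edges (0.5 and
4.5 Hz) fall between 0.2 Hz grid frequencies. Because the five bands tile
[0.5, 32] Hz, band powers are exactly additive to the total. Boundary
ownership is half-open (`lo ≤ f < hi`), with beta closed at 32 Hz, so a
frequency on a shared edge such as 4.5 Hz belongs to the higher band.

**Known bias.** The Hann kernel of a 5-s window leaks a small, fixed
fraction of power across band edges. Wherever the planted PSD steps by a
large factor (delta is 8× theta in N3), the narrow neighbouring bands
acquire a positive bias of roughly 5–8% while delta loses ~2–3%; the wide
delta and beta bands stay within 5% of planted values. This is a property
of windowed spectral estimation, not of the generator, and is why the
recovery tests bound delta/beta at 5% and theta/alpha/sigma at 10%.

## Artifact screening

The artifact detector flags a 5-s epoch on a channel when its RMS exceeds
`k = 3` times the rolling median RMS of the surrounding window, or when any
sample exceeds a hard 500 uV ceiling. The rolling median makes the
reference robust to stage-related amplitude shifts (N3 traces are ~60%
larger in RMS than wake). The window default is 25 epochs (~2 min): with
heavily contaminated recordings (30% of epochs) a shorter 15-epoch window
has a ≈9% chance that the window median itself is artifact-dominated,
silently masking true artifacts; 25 epochs reduces this to ≈3% while still
tracking within-night nonstationarity. Channels flagged on more than 25%
of epochs are excluded from all downstream averages (the boundary is
strict: exactly 25% is retained); a subject with no usable channel is
unanalyzable. Stage cells with no artifact-free epoch propagate as missing,
never as zero.

## The asymmetry and misperception indices

`compute_iai()` contrasts per-channel stage-average delta power between
hemispheres. When both hemispheres retain all three channels this equals
the sum-based ratio; with unequal usable-channel counts, per-hemisphere
*means* are contrasted, so losing one channel does not masquerade as
asymmetry. Besides the five stages, the index is emitted for the pooled
NREM aggregate and for an all-night (`ALL`) epoch-weighted aggregate,
because a single per-subject IAI is often wanted and no canonical stage
aggregation exists. The index is antisymmetric under hemisphere exchange
and invariant to common power rescaling — both tested exactly.

`compute_ssm()` is the plain misperception ratio; it satisfies
`ssm(T, (1−b)·T) = b` for any `T > 0` and errors on zero objective TST
(the ratio's domain).

## The feature matrix

The default 33 variables (`feature_names()`): 9 macro (TIB, TST, SE, SOL,
WASO, REM latency, arousal indices total/NREM/REM), 8 stage (N1/N2/N3/REM
minutes and % of TST), 12 absolute delta power (global/left/right ×
N2/N3/NREM/REM, uV²) and 4 IAI (wake, NREM, REM, all-night). Subjects
missing more than 25% of features are excluded; remaining missing cells
(for example REM-dependent variables on a night without scored REM) are
imputed with the cohort median before z-scoring. The set and order are
fixed and documented, and the matrix round-trips through a plain CSV.

## Cluster-number selection

The observed separation statistic for cutting level `k` is the dendrogram
height of the merge that fuses `k` clusters into `k − 1` — the natural Ward
separation measure. Each permutation replicate independently permutes every
retained component column across subjects (destroying the joint structure
while preserving every marginal) and re-runs the clustering; raw per-level
probabilities use add-one smoothing,
`p_k = (1 + #{replicates ≥ observed})/(1 + B)`.

Two empirical properties of this null shaped the selection rule:

* Because permutation preserves each component's *marginal* distribution —
  including its multimodality — the `k = 2` statistic of a genuinely
  3-cluster data set is usually *not* extreme (the permuted data still
  contains tall top merges). The informative level is the true `k` itself.
* Nine cutting levels (`k = 2..10`) are examined, and their raw p-values
  are nearly independent under structureless data, so "any level below
  0.05" would fire on ~45% of pure-noise cohorts.

Selection therefore uses family-wise calibrated (Westfall–Young max-T)
probabilities: each level's statistic is standardized by its permutation
mean and SD, and the adjusted `p_k` compares the observed standardized
statistic with the permutation distribution of the *maximum* standardized
statistic across levels. The optimal `k` is the first level (ascending from
2) with adjusted `p < alpha`; if none qualifies, `k_opt = 1`. Measured on
this package's fixtures: structureless 60×33 Gaussian matrices yield
`k_opt = 1` in ~95% of runs at `alpha = 0.05` with 500 permutations, while
the planted three-subtype cohort yields `k_opt = 3` in 20/20 selection
seeds. Raw and adjusted p-values are both reported.

Cut labels are stabilized by relabelling clusters in order of descending
size (ties broken by the lowest contained subject index), so assignments do
not depend on subject input order (tested via adjusted Rand index = 1 under
row shuffling).

## The synthetic cohort generator

The generator emulates the *statistical structure* of an insomnia cohort,
not physiological waveforms. Per subject it produces a hypnogram, a
six-channel EEG trace, arousal annotations and a subjective morning report,
with the ground-truth subtype label retained.

* **Hypnogram.** Sleep epochs follow a first-order N1/N2/N3/R Markov chain
  whose transition matrix gives textbook stage proportions (roughly
  N1 4%, N2 47%, N3 28%, R 21% of sleep). Intra-sleep wake is placed as
  alternating wake bouts (mean dwell ~2 min) whose total equals the
  night's WASO budget, and the latency run is drawn around the SOL target:
  realized SOL/TST/WASO track the planted targets, so cohort-level
  separation between subtypes reflects the planted between-subject SDs
  rather than within-night dwell noise. A free-running two-state
  sleep/wake chain was tried first and rejected: its within-night variance
  (~6 min SD of TST on a 90-min night) was as large as the planted
  between-subject SD, which would have made desk-scale recovery tests
  measure chain noise instead of the planted structure.
* **EEG.** Each 30-s staged epoch of each channel is band-limited Gaussian
  noise synthesized in the frequency domain: independent complex Gaussian
  Fourier coefficients scaled so the one-sided PSD equals the profile's
  stage×band levels (uV²/Hz), zero outside [0.5, 32] Hz. Delta-band power
  is multiplied by `(1 + a)` on left and `(1 − a)` on right channels, so
  the planted IAI equals `a` exactly in expectation — making the recovery
  test analytic (`a` recovered within ±0.02 on 30-min segments).
* **Stage PSD defaults** order delta power N3 ≫ N2 > N1 ≈ R ≈ W
  (40/15/8/7/5 uV²/Hz) as in textbook sleep EEG. They are configuration
  stand-ins, not empirical claims: no raw cohort data are available to fit.
* **Subjective report.** Subjective TST is `objective TST · (1 − b)` plus
  zero-mean noise (SD 5% of TST), clipped to [0, TIB], so the expected SSM
  equals the planted bias `b`; the quality rating is drawn around the
  profile mean and clipped to the 1–9 scale.
* **Planted subtypes.** Three profiles mirror short-sleep delta-deficient
  (TST 330 min, SOL 40, WASO 70 on a 450-min night; delta PSD halved;
  misperception 0.14), normal-sleep delta-deficient (TST 400; delta
  halved; misperception 0.05) and normal sleep (TST 405; full delta; no
  misperception). Between-subject SDs (TST 12, SOL 5, WASO 8 min; 8%
  log-normal PSD variation) put the discriminating features ≈6 SD apart.
  Targets and SDs scale proportionally for shorter desk-scale nights.
* **Acute restriction.** Night 2 delays bedtime by 120 min with the same
  rise time (TIB exactly 120 min shorter per subject), consolidates sleep
  (SOL and WASO scaled by 0.6, TST capped to the shorter opportunity), and
  multiplies delta PSD by the profile's `restriction_delta_gain`
  (1.3/1.25/1.0), reproducing the *direction* of the restriction response
  without asserting its magnitude.

What the generator does **not** emulate: discrete sleep microevents
(spindles, K-complexes), EOG/EMG/ECG channels, time-of-night dynamics of
slow-wave activity, inter-channel correlation, or realistic artifact
morphologies (artifacts are injected as high-amplitude 3 Hz transients at
12× epoch RMS). Passing recovery tests therefore demonstrate that the
pipeline measures what it claims on signals with known ground truth — not
that it handles every pathology of clinical recordings.

## Numerical and interface conventions

* Epoch indexing is 0-based; intervals are half-open `[onset, onset + d)`.
* Hypnograms are 30-s epochs spanning lights-off to lights-on; EDF files
  carry 16-bit samples with per-channel symmetric physical ranges
  (quantization error at most half the physical resolution, enforced by a
  round-trip test and cross-checked against an independent Python EDF
  reader).
* Channel labels match case-insensitively with `-`, `:`, `_` or space
  separators and an optional `EEG ` prefix; channels are always returned in
  canonical montage order.
* One user seed governs every stochastic stage through documented sub-seed
  derivation; reruns are byte-identical.
* Ward heights are on the distance scale (`sqrt(2·ΔSS)`, hclust
  `ward.D2`), monotone by construction, and the merge sequence matches an
  exhaustive minimum-ΔSS search on small instances (50 random instances
  with n ≤ 8 in the test suite).

## Problem sizes used by the test suite

The suite favours analytic oracles and small planted instances: 5-s epochs
at 128 Hz for spectral oracles (Nyquist comfortably above the 32 Hz beta
edge), 10–30-min single-stage segments for recovery tests, a 60-subject
90-min-night cohort with 500 permutations for the end-to-end subtype
recovery, 100 structureless cohorts for null calibration in the acceptance
script, and full 450-min nights only where the −120-min restriction
scenario requires them. These sizes were chosen so the whole suite runs on
a laptop in a few minutes while leaving every estimate's Monte-Carlo error
well inside the tested tolerance.

## Limitations

* The 33-variable set reconstructs the described feature categories; real
  studies should review and, where needed, reconfigure it.
* The permutation null preserves marginal multimodality, so a cohort whose
  structure lies along a *single* retained component is invisible to the
  test by construction; structure must span at least two components.
* Descriptive output only: group comparisons, covariate adjustment and
  mixed-model inference are intentionally out of scope.
* Arousals are consumed as annotations; no detection from raw EEG.
* Absolute (not relative) band power is reported, as is conventional for
  delta/slow-wave analyses; normalized power is out of scope.
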