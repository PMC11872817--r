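---
title: "Methods: paired pre/post resting-state EEG analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired pre/post resting-state EEG analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(resteeg)
```

# The analysis problem

A small cohort (ten patients) is recorded at rest, eyes predominantly
closed, once before and once after a neuromodulation session: 21 channels of
the 10/20 system at 200 Hz, at least ten minutes each. The question is
which features of the resting EEG changed. Because n is small and the
feature distributions are not credibly normal, every feature is reduced to
one scalar per subject and condition and compared with the paired Wilcoxon
signed-rank test; the study is exploratory, so no multiple-comparison
correction is applied by default and a trend band (0.05 ≤ p < 0.10) is
reported alongside significance at 5%.

This package implements that pipeline end to end, plus a synthetic cohort
generator that makes every stage testable without access to patient data.

# Preprocessing

Order is fixed: average reference, then filtering, then artifact segment
selection. Only this order is supported, because re-referencing after
filtering would mix channel-specific filter transients into every channel.

* **Average reference.** Each sample's cross-channel mean is subtracted;
  the operation is idempotent and makes the per-sample channel sum zero.
* **Filtering.** A 4th-order Butterworth high-pass at 0.1 Hz and a
  2nd-order notch at 50 Hz (quality factor 30), both applied
  forward-backward so the net phase is zero. Zero phase is not cosmetic:
  instantaneous phase extracted later for coupling analysis must not be
  biased by filter delay. The acquisition chain is assumed band-limited at
  80 Hz; no additional low-pass is applied offline because the gamma band
  extends to 80 Hz and the modulated coupling range to 85 Hz.
* **Artifact handling.** Manual expert artifact rejection is replaced by an
  automated stand-in: samples where any channel exceeds ±150 µV are
  rejected with 0.5 s padding on both sides, and the retained data is kept
  as a list of half-open segments (0-based sample indices). The threshold
  is a conventional gross-artifact bound, configurable, and deliberately
  documented as not taken from any publication. All downstream windowing
  and filtering respects segment boundaries, so rejection gaps never enter
  an estimate.

## Numerical choices in the filters

Two non-obvious choices matter here and were made after measuring the
alternatives:

* **Second-order sections.** The expanded 4th-order polynomial of a 0.1 Hz
  high-pass at 200 Hz has a 4-fold pole cluster at radius ≈ 0.997;
  coefficient rounding perturbs clustered roots by roughly the fourth root
  of machine epsilon, enough to push poles outside the unit circle and make
  the backward pass grow. All Butterworth designs are therefore applied as
  cascaded biquads. For band-pass designs every biquad receives one zero at
  DC and one at Nyquist — grouping like zeros produces sections with
  extreme gains whose edge transients dominate the cascade.
* **Even (mirror) edge padding.** The common odd-reflection rule for
  zero-phase filtering inserts, when an endpoint sits at an oscillation
  extremum, a DC plateau of twice the oscillation amplitude into the
  padding. A high-pass with a ~4 s time constant converts that plateau into
  a slow transient of noticeable amplitude well inside a 20 s record (the
  same behavior is reproducible with other standard implementations of
  odd-padding filtfilt). Mirror padding preserves the local mean;
  combined with steady-state filter-state initialisation and three time
  constants of padding, the residual edge error is about 1% of the signal.

# Spectral features

`power_spectrum()` is a Welch estimator: 512-sample Hanning windows, 50%
overlap, one-sided, window-power normalised so the integral over frequency
approximates the variance. At 200 Hz the grid spacing is 200/512 =
0.390625 Hz. Windows never straddle retained-segment boundaries; segments
shorter than one window are skipped. Region band power is the mean over the
region's channels of the mean power in the half-open band `[low, high)` —
half-open so that the shared edges of adjacent bands (4, 8, 14, 31 Hz) are
never double-counted.

Coherence uses the same windows: `|S_XY|² / (S_XX · S_YY)` with all three
spectra averaged over identical window sets. A single-window estimate is
identically 1, so at least two windows are required; the number of averaged
windows is carried in the result. Between regions, the inputs are the
region-average signals; within a region, the reported spectrum is the mean
coherence over all unordered channel pairs (for the two-channel regions
this is simply the coherence of the two channels). Region power averages
per-channel spectra while region coherence averages the signals first —
asymmetric by design, following the respective definitions of each
measure.

The 50 Hz notch trough lies inside the gamma and beta-gamma bands. Band
means include those bins by default; `exclude_notch_band = TRUE` drops
48–52 Hz from all band means. Since the trough affects pre and post
identically, the paired comparison is insensitive to this choice.

# Tsallis entropy

The estimator treats variance as the carrier of information: for interval
length L the first ⌊N/L⌋·L samples are cut into consecutive non-overlapping
intervals and

&nbsp;&nbsp;&nbsp;&nbsp;H(L) = 1 − Σ_j Var_j / (M·σ̂²),

with population variances throughout (divisor L within intervals, N for the
full series). The reported entropy is the mean of H(L) over 100 equally
spaced interval lengths between 1 and 500 samples: the arithmetic grid
1 + k·(499/99), k = 0..99, rounded to the nearest integer, duplicates kept
so the average is always over exactly 100 values. Conventions that the
estimator's definition leaves open were fixed as follows:

* Population (not sample) variance makes L = 1 well defined:
  single-sample intervals have zero variance, so H(1) = 1 exactly.
* Remainder samples beyond M·L are dropped from the interval sum for that
  L only; σ̂² always uses the full series, keeping the denominator common
  across the length grid.
* With exact tiling, the law of total variance gives H ∈ [0, 1]; the
  dropped remainder can move it by O(remainder/N).
* H is invariant to amplitude scaling (variances scale identically in
  numerator and denominator), which the tests assert.

Channel entropy is computed on the concatenated retained samples (segments
shorter than the largest interval length are excluded); region values are
means of member-channel entropies, and the `"all"` scope is the mean over
every channel. For stationary white noise E[H(L)] ≈ 1/L, so the grid
average is ≈ 0.02; strongly structured signals approach 1.

# Cross-frequency coupling

Canolty's modulation index is the magnitude of the time-averaged
envelope-weighted phasor, `|mean(A·exp(iφ))|`, with A the analytic-signal
envelope in the modulated band and φ the analytic-signal phase in the
modulating band. The comodulogram covers modulating centers 1–10 Hz (step
1 Hz, ±1 Hz bands, low edge clipped at 0.5 Hz) and modulated centers
20–85 Hz (step 5 Hz). Per segment, one cycle of the lowest modulating band
edge is trimmed from each end before averaging (analytic-signal edge
artifacts), and segments shorter than three modulating cycles are skipped.

The modulated band half-width deserves a note. A coupling at carrier f_a
modulated at f_p puts sidebands at f_a ± f_p; if the amplitude band is
narrower than the modulating frequency, the sidebands fall outside it, the
extracted envelope loses its modulation, and the comodulogram maximum lands
in the cells *adjacent* to the true carrier (this was measured, not
conjectured: with ±5 Hz bands a 6 Hz → 60 Hz injection peaks at 55/65 Hz).
The default half-width is therefore 10 Hz — wide enough to pass the
sidebands of any modulating frequency in the 1–10 Hz range, which is the
standard bandwidth rule for phase-amplitude coupling analysis.

Raw MI (no surrogate normalisation) is the reference quantity; a seeded
circular-time-shift surrogate z-score (`mi_surrogate_z()`) is available but
off by default. Note that time-shift surrogates only destroy coupling whose
modulating phase wanders; for strictly periodic modulation a circular shift
merely rotates the coupling phase, to which MI is invariant by
construction. For between-region pairs the phase is taken from the
first-named region and the amplitude from the second, and the reverse
direction is computed and reported as well rather than guessing a
directionality.

# Group statistics

Differences are post − pre. Zero differences are dropped, `|d|` is ranked
with midranks, and with m nonzero pairs

&nbsp;&nbsp;&nbsp;&nbsp;Z = (W⁻ − m(m+1)/4) / √( m(m+1)(2m+1)/24 − Σ(t³−t)/48 ),

where W⁻ is the negative-rank sum and t the tie-group sizes, so an overall
increase yields a negative Z and a decrease a positive one. No continuity
correction is applied — this is the convention under which the closed-form
worked examples reproduce exactly (m = 10, rank sum 3 gives |Z| =
24.5/√96.25 = 2.4973). The two-sided p is the normal tail; the effect size
is r = Z/√n with n the number of supplied pairs. Two conventions follow
from this and are worth stating:

* Against exhaustive sign enumeration, the uncorrected normal
  approximation estimates the *mid-p* (the attained statistic counted with
  half weight); compared to that oracle it is within 0.03 for every
  tie-free n = 8 dataset, while against the ordinary doubled-tail exact p
  the deviation reaches 0.068 at mid-range statistics. The test suite's
  enumeration oracle therefore uses mid-p.
* When all |differences| tie exactly (e.g. post = pre + 1 everywhere), the
  tie-corrected variance collapses the test to its sign-test limit, |Z| =
  √m — not the no-tie closed form. `stats::wilcox.test(correct = FALSE)`
  agrees and serves as the cross-check.

A one-sample Kolmogorov–Smirnov statistic of the standardized differences
against the standard normal is reported per feature as a normality screen;
it never gates the nonparametric test. `compare_all()` emits one row per
feature with W, Z, p, r, significance and trend flags; features with all
zero differences are reported as non-testable rather than silently dropped.
Benjamini–Hochberg adjustment is available behind a flag and off by
default, matching the exploratory framing. Comodulogram rows are
additionally pivoted into 0/1 significance masks per region pair.

# The synthetic cohort generator

`simulate_subject()` builds each channel as the sum of

1. pink (1/f) background noise, RMS 10 µV, independent per channel;
2. region-level oscillatory sources — band-limited Gaussian noise shared by
   all channels of a region (posterior alpha 10 ± 1 Hz at 8 µV RMS, frontal
   theta 6 ± 1 Hz at 5 µV, temporal alpha and beta, parietal beta, and
   40 ± 5 Hz gamma at occipital and frontal so the composite high bands
   carry oscillatory content) — sharing is what induces within-region
   coherence;
3. optional phase-amplitude coupling components,
   `sin(φ) + (1 + depth·sin(φ))·sin(θ + jitter)` with small (SD 0.1 rad)
   carrier phase jitter so coupling is strong but not the noiseless closed
   form;
4. white sensor noise, 2 µV RMS.

Subject-level amplitude gains are drawn log-normally (SD 0.15) from a
subject-specific stream shared by the pre and post recordings — the
"subject" is the same person twice — while noise realizations come from a
condition-specific stream. With no planted effects, pre and post are
therefore exchangeable and the pipeline's per-feature type-I error matches
the Wilcoxon level (the discrete exact level at n = 10 is 50/1024 ≈ 0.049).
All streams derive deterministically from one master seed, so a cohort is
byte-identical across runs.

Planted post-condition effects: `power` rescales the zero-phase band-passed
part of each region channel so band power is multiplied exactly (up to
filter roll-off); `coherence` mixes an extra shared band-limited source
into the region; `entropy` adds a slow (0.3 Hz) oscillation; `cfc` adds a
coupling component. Magnitudes are chosen for detectability at n = 10 and
are documented as synthetic settings, not published values. A planted
effect propagates to physically coupled features on purpose — a genuine
band-power increase also shifts, e.g., broadband entropy slightly — which
is exactly how a real effect would behave.

Defaults are 120 s per recording (test configurations use less; a
`paper_scale = TRUE` preset produces 757 s ≈ 12.6 min recordings matching
the average artifact-free length such studies report). Not emulated: volume
conduction and realistic head geometry, inter-channel correlation beyond
shared region sources, non-stationarity, and ocular/muscle artifact
morphology (artifact testing uses simple amplitude spikes). A green
pipeline test therefore establishes estimator and statistics correctness
under a plausible signal model, not robustness to real-world artifact
structure.

# What the tests establish

* Closed forms: MI = 1/2 for the cosine-envelope construction; entropy
  → c²/(c²+σ²) for a step-plus-noise series; H(1) = 1; white-noise entropy
  near zero; the printed effect sizes r = Z/√10 to four decimals.
* Oracles: exhaustive 2⁸ sign enumeration for the Wilcoxon approximation;
  `stats::wilcox.test` as an independent implementation; periodogram
  regression for 1/f slopes; analytic bias 1/K for independent-signal
  coherence (tested at zero overlap, where K is the window count).
* Calibration: 1000 seeded null cohorts through the full pipeline keep
  every feature's rejection rate in [0.03, 0.08] at α = 0.05; a planted
  ×1.5 occipital beta-gamma power increase is recovered in ≥ 80 of 100
  replicates while ≥ 90% of unplanted features stay non-significant; an
  injected 6 Hz → 60 Hz coupling localizes to the correct comodulogram
  cell in ≥ 95% of 50 replicates. Long-running suites use 6 s recordings —
  error rates do not depend on duration, and runtime does.

# Known limitations

* The Wilcoxon p is always the normal approximation; exact small-sample
  p-values are available in the test oracles but not in the pipeline.
* Within-region "coherence" for regions with more than two channels (the
  mean over channel pairs) is one of several defensible readings.
* EDF support covers the continuous 16-bit subset with equal sampling
  rates across signals — no annotations, no discontinuous records.
* The η²-style effect sizes some studies print alongside r have no agreed
  formula in this setting and are not computed.
* No source localization, no ICA-based artifact removal, no bad-channel
  interpolation, no resampling.
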