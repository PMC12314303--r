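---
title: "Methods: band power, phase locking and spectral Granger causality in task iEEG"
author: "streamsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band power, phase locking and spectral Granger causality in task iEEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`streamsync` analyses continuous intracranial EEG recorded during a
memory-guided action task: trials of fixation (jittered 1.9–2.1 s),
encoding (2 s), a jittered 3.9–4.1 s delay and an action/recall phase
(2 s), run in counterbalanced 10-trial blocks of two conditions
("same" / "different" objects).  Channels are grouped into three regions —
inferior parietal lobule (IPL, dorsal visual stream), ventral temporal
cortex (VTC, ventral stream) and hippocampus (HIP).  The pipeline
quantifies (i) task-period band-power changes, (ii) undirected phase
coupling between region pairs (phase-locking value, PLV) and (iii)
directed coupling (non-parametric spectral Granger causality, GC), and
models the period-by-condition structure of each quantity with linear
mixed-effects models.  A synthetic session generator with exact ground
truth makes every stage testable without patient data.

# Preprocessing

Line noise is removed with a zero-phase Butterworth band-stop of 1 Hz
width at 50 Hz and harmonics below 0.9 × Nyquist (prototype order 2, i.e.
a 4th-order band-stop transfer function; forward–backward filtering
squares the magnitude response and cancels the phase).  Bipolar
derivations between adjacent same-shaft contacts suppress common-mode
and far-field signals exactly — a property the test suite asserts to
machine precision.  Contacts flagged bad or inside the seizure-onset zone
are excluded before pairing; the derived channel inherits the deeper
contact's region label (overridable in the channel table, since a
functional criterion such as the larger unilateral response cannot be
evaluated before analysis).

Epochs run from −0.5 s to 7.8 s around encoding onset and are assembled
segment-wise: the last 0.5 s of fixation, the 2.0 s encoding phase, the
delay from 0.2 s to 4.0 s after delay onset (the jittered 0.0–0.2 s head
is dropped, the remainder split into two 1.9 s halves; any residual
jitter tail before recall is discarded), and the 2.0 s recall phase.
Sample counts per segment are fixed by the rate, so epochs are
index-exact across jitters.  Connectivity analyses use the same layout
with a 1.9 s baseline (the last 1.9 s of fixation).

Artifact handling: epochs are dropped per (trial, channel) when the
absolute robust z-score of the amplitude or of its first difference
exceeds 6 / 8 SD anywhere in the epoch.  This is a deliberately simple
stand-in for a clinical interictal-spike detector; z-scores use
median/MAD so the artifacts do not inflate their own normalisation, and
zero-variance channels are treated as bad channels rather than spikes.
Trials with incorrect behavioral responses (position, or identity in the
"different" condition) are excluded whole.

# Band power

Each 1 Hz band between 2 and 120 Hz (band *k* covers [*k*, *k*+1) Hz; the
analysis uses 2–13 Hz and the remainder is available but unanalysed) is
band-pass filtered (zero-phase Butterworth, prototype order 3) over the
*continuous* recording, the Hilbert envelope is extracted, decimated to
64 Hz with an anti-aliasing low-pass, divided by its session mean and
multiplied by 100.  This whitening flattens the 1/f spectral decay; every
band's session mean is exactly 100 by construction.  Theta (2–7 Hz,
bands 2–6) and alpha (8–13 Hz, bands 8–12) envelopes are the means of
their 1 Hz bands; the inclusive printed endpoints ("2–7", "8–13") make
the last bin ambiguous, so the bin sets are configurable.  Epoched band
envelopes are baseline-corrected by subtracting the per-trial mean over
[−0.5, 0) s.

A channel is *active* in a band and condition when any post-stimulus
envelope sample differs from baseline: per sample, a paired Wilcoxon
signed-rank test across trials compares the trial's baseline mean with
the envelope at that sample; each p-value is replaced by the maximum
within a centred six-sample (93.75 ms) window — a conservative smoothing
that can only remove significance, never add it (the test suite checks
this monotonicity) — and Benjamini–Hochberg FDR at q = 0.05 is applied
jointly across all time samples and channels.  All-zero difference
vectors return p = 1 rather than an error.  FDR is pooled across all
analysed channels (pooling per region would be the alternative; nothing
in the design forces either).

# Phase-locking value

Per task period, trial spectra are computed with two DPSS tapers
(time-bandwidth 1.5) on the period window (1.9 s baseline and delay
halves, 2.0 s encoding, the first 0.5 s of recall — the pre-response
part), zero-padded to 4 s so the 1 Hz grid 2–20 Hz is exact.  PLV is the
modulus of the trial- and taper-averaged unit cross-spectrum; tapers are
pooled at the coefficient level (per-taper PLV then averaging is the
configurable alternative; the choice is not dictated by the design).
PLV is invariant to per-channel fixed phase shifts and to coefficient
magnitudes, equals 1 for a constant phase offset, and under independent
phases has expectation ≈ √π/(2√N) — all asserted against independent
oracles.

Significance per pair and period uses a paired permutation null: each
trial contributes a baseline and a task-period segment, and permutations
swap the two labels within random subsets of trials (200 permutations).
The per-frequency point-wise threshold is the null's 95th percentile;
contiguous supra-threshold bins form clusters scored by mass (sum of
ΔPLV), tested against the permutation distribution of the maximal
cluster mass at P < 0.05.  Unequal window lengths (0.5 s recall vs 1.9 s
baseline) are inherited by the null, preserving frequency-dependent
smoothness bias.  Under a constructed exact null the pair-significance
rate stays in [0.02, 0.09], which the acceptance suite measures over 200
simulated pairs; the rate is measured per (pair, period) test, the
engine's type-I unit.

For each region pair the ratio of significant pairs per 1 Hz bin
(Sig.P.Ratio, pooled over patients and periods) is tested one-sided
against the chance level — the median ratio across bins — with an exact
binomial test, BH-FDR across the 19 bins; maximal runs of significant
bins are the selected frequency ranges.  With very few pairs a median
ratio of zero makes the binomial test permissive; the statistic is meant
for pooled cohorts (tens of pairs), which is how both the tests and the
acceptance script use it.  Period-averaged PLV over each selected range,
per condition, feeds the mixed-model stage.

# Spectral Granger causality

Signals are resampled to 40 Hz (zero-phase anti-alias low-pass at 0.95 ×
the target Nyquist, cubic-spline interpolation onto the new grid) and
re-epoched; a 1.9 s period window then holds 76 samples.  All GC windows
are 1.9 s: baseline, the first 1.9 s of encoding, and the two delay
halves; recall is refused as too short for reliable spectral estimation.
Per pair, period and condition the cross-spectral density is the
trial/taper average of outer products of Fourier coefficients with two
orthogonal sine tapers, zero-padded to 20 s (0.05 Hz grid, 0–20 Hz).
The phrase "two Hann tapers" from the lineage of this method is
ambiguous — two identical Hann tapers add no degrees of freedom — so the
2-taper sine family (the Hann-like orthogonal family) is used.

Wilson's spectral matrix factorization decomposes S(f) = H(f) Σ H*(f)
into a minimum-phase transfer function and innovation covariance:
initialization from the Cholesky factor of the zero-lag covariance,
iteration with the causal-part operator over the full frequency circle,
convergence at relative change < 1e−8 (maxIter 100; hitting it flags the
result instead of failing silently).  Near-singular spectra are
regularized with ε·I, ε = 1e−8 × mean diagonal power, and reported.  The
reconstruction residual ‖S − ΨΨ*‖/‖S‖ stays below 1e−6 on converged
output, verified on closed-form VAR spectra where the recovered Σ matches
the generating covariance.  Geweke's spectral GC follows:
GC_{Y→X}(f) = ln(S_xx / S̃_xx) with the intrinsic power
S̃_xx = S_xx − (Σ_yy − Σ_xy²/Σ_xx)|H_xy|²; values are non-negative up to
an explicit numerical clip, and swapping the channels swaps the two
directed spectra exactly.  The non-parametric estimate agrees with the
parametric GC of the generating VAR within 10 % at the coupling peak,
with reverse-direction leakage below 10 % of the peak.

Net GC (difference of the two directions; positive when the second
region leads) is averaged across pairs, periods and conditions; local
extrema of the mean spectrum define peak bands of extremum ± 1 Hz
(half-width configurable).  Selection keeps at most two extrema at least
2 Hz apart with magnitude ≥ 0.5 × the largest, above an absolute noise
floor of 1e−3 (spurious net GC between independent channels is an order
of magnitude smaller at realistic trial counts); a flat spectrum yields
an empty selection.  Period-averaged net GC over the selected ranges,
per condition, feeds the mixed-model stage.  GC is run only on pairs the
PLV stage found significant.

# Mixed-effects models

Each period-mean table (power, PLV, net GC) is fitted with
`value ~ taskPeriod * condition + (1 | patient) + (1 | patient:unit)`
(treatment coding; baseline period and the "same" condition as
references, matching how period effects are reported), REML via
`lmerTest` with Satterthwaite degrees of freedom (the df convention is
recorded in the output; changing it moves p-values, never estimates).
Per-model alpha follows the Bonferroni families: 0.05/6 for power (three
regions × two bands), 0.05/3 for PLV (one per selected range), 0.05 for
net GC.  Singular fits are refit without the nested unit term and
flagged; a zero-variance outcome short-circuits to an explicit degenerate
result.  Post-hoc pairwise period contrasts and within-period condition
contrasts come from `emmeans` on the fixed-effect covariance, Bonferroni
within family; estimated marginal means make them invariant to the
reference level, which the tests assert by refitting under a permuted
level order.

# The synthetic session generator

`simulateSession` emulates one session: the trial schedule above
(counterbalanced block pairs, uniform jitters — the design only states
ranges), 1/f^1.5 background (typical of intracranial field potentials;
exponent configurable), line noise at 50 Hz plus a 30 % 100 Hz harmonic
with a gradient along the shaft so bipolar derivation attenuates but does
not cancel it, and 70 ms interictal spike-and-wave transients at 5–10 ×
background SD with a genuinely sharp (~16 ms) component.  Effects are
specified per *bipolar* channel and realized exactly through a
cumulative-sum contact construction: contact *j* carries the sum of the
first *j*−1 channel signals plus its own background, so the bipolar
derivation returns precisely the configured channel signal plus a
background difference.

Band-power effects multiply a band-limited oscillator's amplitude within
the chosen periods (50 ms cosine ramps).  Phase coupling adds a shared
sinusoid with a fresh uniform phase per trial and Von Mises jitter of
concentration κ on the receiving channels, so the expected PLV is the
analytic resultant I₁(κ)/I₀(κ) (`vonMisesPLV`).  Directed coupling adds
band-limited noise to the source region and a lagged, scaled copy to the
target region, giving an unambiguous GC direction.  Three identifiability
constraints shape sensible lag choices: a lag near half a cycle of a
narrowband coupling is indistinguishable from an anti-phase advance (the
direction becomes ill-posed); a lag below one sample of the 40 Hz GC grid
(25 ms) carries no directed information after resampling; and a coupling
strength that drives coherence to 1 degenerates the partialization, so
moderate strengths give the cleanest directed spectra.  What the generator
does *not* emulate: realistic neural mass dynamics, volume-conduction
mixing beyond the common-mode term, non-stationary artifacts, eye
movements, or behaviourally driven signal changes — so passing tests
demonstrate correctness of the estimators on signals with known
structure, not clinical validity on patient recordings.

# Problem sizes and numerical choices

The test and acceptance runs use scaled problem sizes chosen to exercise
every code path at meaningful statistical power: null calibrations over
200 simulated pairs at 200 permutations and 80 trials; detector
sensitivity at the study's 80 trials per condition with six effect
channels, and false-positive calibration over 50 null sessions; the
end-to-end replication uses two simulated patients with 40 trials per
condition and 3/3/2 channels per region; mixed-model recovery uses 100
simulated cohorts of 10 patients × 20 channels.  FFTs are padded to
2-3-5-smooth lengths (R's mixed-radix FFT is pathological on large prime
lengths); the analytic-signal pad reflects the tail to avoid step edges.
DPSS tapers come from the classical tridiagonal eigenproblem and are
cached per window length.  EDF output quantizes to a symmetric 16-bit
digital range (±32767) so zero round-trips to zero and the worst-case
error is one quantization step.

# Known limitations

Single-shaft-per-region layout in the generator; bivariate (not
conditional) GC only, so indirect routes through a third region are not
partialized out; the spike stand-in is amplitude/derivative based and
will miss low-amplitude epileptiform patterns; Sig.P.Ratio's
median-as-chance convention is unstable for very small pair counts; and
PLV's known positive bias at small trial counts (≈ √π/(2√N)) is
inherited by any absolute PLV reading, though the task-vs-baseline
permutation contrast removes it from the inference.
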