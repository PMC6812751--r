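---
title: "Methods: Onset-Paradigm difference-ERP analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Onset-Paradigm difference-ERP analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis problem

During observation of an ambiguous figure such as the Necker lattice,
perception alternates spontaneously between two mutually exclusive 3D
interpretations while the stimulus itself never changes.  The
Onset-Paradigm makes these endogenous reversals accessible to ERP
averaging: the stimulus is presented discontinuously (about 800 ms on,
400 ms blank), the observer compares successive presentations and reports
either reversals or stability, and the reversal event becomes time-locked
to stimulus onset.  Because the identical stimuli appear in both
conditions, subtracting the stability-condition ERP from the
reversal-condition ERP (the *dERP*) cancels stimulus-driven activity and
isolates reversal-related components:

* **RP** — Reversal Positivity, occipital, ~140 ms, positive;
* **RN** — Reversal Negativity, occipito-parietal, ~260 ms, negative;
* **PP** — Parietal/Frontopolar Positivity, broad and late, ~540 ms at
  parietal and ~480 ms at frontal/frontopolar electrodes, positive;
* **FN** — Frontal Negativity, anterior, ~160 ms, negative — a signature
  reported in experienced meditators only.

`onseterp` implements the full chain from trial-level epochs to group
statistics, and a synthetic cohort generator that stands in for the
unreleased recordings so that every stage is testable offline.

## Pipeline and parameters

The stage order is fixed: **re-reference → reject → average → filter →
baseline → dERP → presence tests → peak measures → ANOVA → post-hocs.**

| Parameter | Default | Meaning |
|---|---|---|
| reference | TP9, TP10 | offline re-reference to the mastoid-adjacent pair (their per-trial mean is subtracted) |
| rejection threshold | 150 µV | a trial is removed iff any channel/sample has \|value\| **strictly** greater; "exceeding ±150 µV" is read as strictly beyond |
| low-pass cutoff | 25 Hz | zero-phase, applied to the averaged ERP, not single trials |
| baseline window | −60 … +40 ms | per-channel mean subtracted |
| minimum trials | 10 | averages below this are flagged excludable (the study excluded subjects with "too few" trials without stating a cutoff; its trial-count table bounds it at 12) |
| running-test alpha | 0.01 | per-sample, uncorrected |
| run criterion | 20 ms | = 10 successive samples at 500 Hz |

**Filter realization.**  The "latency-neutral low-pass at 25 Hz" is a
165-tap Hamming-windowed-sinc FIR (10 Hz transition band) applied centred
with reflection padding.  A symmetric odd-length kernel applied centred is
exactly zero-phase: a symmetric pulse keeps its peak sample, DC is
preserved, and the stopband is about −53 dB (|H(50 Hz)| ≈ 0.002, exposed
by `fir_response()` and asserted by test).

**Rejection scope.**  Whether the ±150 µV rule was applied to raw or
re-referenced data is not stated in the source analysis; this package
evaluates it on the re-referenced signal over the full epoch window, the
conservative reading.  This is an assumption, switchable only by
reordering the calls.

**Presence criteria.**  A component is *present* (confirmatory) when at
least one ROI electrode shows p < 0.01 in a one-sample t-test against
zero for at least 10 successive samples inside the temporal ROI.  The
exploratory variant requires two *neighbouring* electrodes (shipped
adjacency table) with qualifying runs; this package additionally requires
their runs to overlap in time by at least one sample — simultaneity is the
natural reading of a shared deflection, but it is an interpretation, since
the source text does not say whether the two electrodes' stretches had to
be simultaneous.  The running t-tests are two-tailed by default (the
source is silent; a one-tailed switch exists), and are computed per
group × experiment cell.

This criterion is deliberately liberal (no multiple-testing correction).
The test suite measures its family-wise false-detection rate on pure-noise
dERPs: near zero for white (sample-independent) noise, but well above the
per-test alpha once the noise is low-pass filtered, because 25 Hz
smoothing makes ~10-sample excursions the norm rather than the exception.
A "present" verdict therefore replicates the study's criterion; it is not
a calibrated error rate.

**Peak rule.**  The peak is the largest *strict interior* local extremum
of the ROI polarity; window endpoints are never peaks, and ties break to
the earliest latency.  Both choices make the stated fallback rule (window
mean when no local extremum exists) reachable and deterministic.  Fallback
rows keep their amplitude but have no latency, so they enter amplitude
ANOVAs and are excluded from latency ANOVAs.

## The synthetic cohort

`paper_fixture()` emits 12 meditators and 15 non-meditators.  Per-subject
trial counts are drawn per experiment from the study's trial bookkeeping
(mean ± SD, floored at the observed minima: passive 78.7 ± 26.2 / floor 34
and 65.8 ± 34.6 / floor 12; hold 61 ± 28.4 / 26 and 43.3 ± 25.4 / 13).
Components are Gaussian time-courses (the observed dERP deflections are
smooth and unimodal) with fixed topographies; reversal-only templates
survive the dERP, templates marked `both` (a P1- and an N1-like
stimulus-evoked pair) cancel in it exactly.  Between-subject variability
is an additive latency shift (SD 10 ms) and a multiplicative amplitude
scale (SD 0.2, truncated at 0.05) per subject × component — the simplest
model matching the individual peak scatter.  The spec sheet named the
amplitude jitter in µV but prescribed a multiplicative model; the
multiplicative form was kept.

The late positivity is planted as **two** templates (parietal, 540 ms,
+7 µV at Pz; frontal/frontopolar, 480 ms, +6 µV at Fpz, both σ = 60 ms),
because a single fixed-latency template cannot reproduce the printed
latency gradient across the scalp.

**Noise calibration.**  No noise magnitudes or single-trial SNR are
published, so the defaults are an explicit assumption, chosen once by a
calibration experiment *before* being frozen: per-trial white noise
(6 µV/sample) plus 1/f-shaped noise (3 µV/sample; spectrum ∝ 1/f, DC
removed, synthesized at a power-of-two FFT length and truncated).  At
these levels and the study's trial counts, grand-mean peak-latency
recovery stayed within ±10 ms for all five components over 25 independent
seeds, which is the recovery the acceptance criteria require.  Broad
components are the binding constraint: the peak of a σ = 80 ms template
under realistic low-frequency noise wanders by ±20 ms and more, which is
why the fixture's late positivity uses σ = 60 ms and amplitudes at the
upper end of the plausible range.  The generator does **not** emulate
spatially correlated noise, ocular or muscle artifact physiology, or
reversal-rate dynamics; large-amplitude artifacts are injected as single
random excursions (rate 0.1, ±300 µV), which reproduces the ~10% trial
attrition of the study's bookkeeping but nothing about real artifact
morphology.  A green recovery test therefore establishes that the
algorithms are correct and well-calibrated on data of this SNR and
structure — not that the study's effects are real.

## Group statistics

Peak measures feed a univariate mixed-model sums-of-squares decomposition
with between-subject factor GROUP and within-subject factors EXPERIMENT
and ELECTRODE; partial eta squared is SS_effect / (SS_effect + SS_error)
with each effect's own stratum error.  No sphericity correction is applied
by default, mirroring the integer dfs in the reported statistics;
Greenhouse-Geisser adjustment is available behind a flag (`gg = TRUE`).
Degrees of freedom are derived from the actual design.  Note the source
reports RN latency as F(8,200) (9 electrode levels) and PP as F(7,175)
(8 levels), which is inconsistent with its own 6- and 3-electrode ROIs;
this package follows the ROI table and flags the discrepancy rather than
guessing the electrode sets.

Post-hoc contrasts (occipital vs parietal, right vs left, central vs
peripheral, parietal vs central/frontopolar) are paired Wilcoxon
signed-rank tests on per-subject pools averaged over experiments, exact
null for n ≤ 25 (ties fall back to the normal approximation), with
Bonferroni-Holm step-down correction over the contrasts of one analysis;
corrected and uncorrected p-values are always reported side by side.  The
electrode pools behind the named contrasts are a package choice (shipped,
configurable) — the analysis names the contrasts but not the exact
pooling.

## Source clustering

The source-statistics stage is generic: it takes any 3D point cloud with
per-subject contrast values (a synthetic vertex field stands in for the
cortical mesh; no inverse solution is computed).  Per-vertex two-tailed
one-sample t-tests are thresholded at α = 0.05 and the surviving vertices
are grouped per hemisphere (split at x = 0, x ≤ 0 left) by k-means with
1000 restarts for k = 1…8.

**Elbow rule.**  The chosen k is the smallest whose explained-variance
ratio reaches 0.95, where the total sum of squares is **uncentred**
(about the coordinate origin, the head centre).  With the conventional
centred total, EV(k = 1) is identically zero and no rule with a 0.95
cutoff could ever return one cluster for a single compact blob; with the
uncentred total, a tight cloud far from the origin is almost fully
explained by its own centroid, two well-separated clouds need two, and
many clouds hit the k = 8 cap — exactly the qualitative behaviour the
elbow heuristic is meant to have.  The rule lives in one internal helper
so it can be swapped.  Because α = 0.05 thresholding passes ~5% of null
vertices, isolated straggler clusters beside the real blobs are expected
behaviour, as in the original cluster table.

## Degenerate inputs and numerical choices

* Zero across-subject variance in a t-test: p = 0 if the mean is nonzero,
  1 otherwise, with a degeneracy flag (running and vertex tests alike).
* All trials rejected: averaging refuses; the rejection report flags it.
* Epochs shorter than the filter half-width (82 samples): error, no
  silent truncation.
* `ms_to_sample` rounds to the nearest sample; 20 ms at 500 Hz is exactly
  10 samples.
* Holm adjustment: sort, multiply by (m−k+1), cumulative max, cap at 1.
* k-means uses a fixed seed parameter; all generator randomness flows from
  one cohort seed through deterministic per-subject seeds, so identical
  seeds give bit-identical cohorts regardless of whether subjects are
  generated singly or in bulk.

## Known limitations

* The study's raw EEG is not deposited, so its F statistics, p-values and
  group contrasts are not reproducible here; the package reproduces the
  *procedures* and recovers planted parameters from the synthetic world.
* Trial-level noise is spatially independent across channels; real EEG
  noise is correlated, which would make the two-neighbouring-electrodes
  exploratory criterion *more* liberal than our specificity estimate.
* Forward modelling, inverse solutions, anatomical labelling, behavioral
  reversal-rate analyses and frequency-domain analyses are out of scope.
* The type-I calibration of the GROUP test runs at the peak-measure level
  (1,000 simulated measure tables), not on 1,000 full EEG cohorts — the
  F-test only ever sees the measures table, and full cohorts at that count
  are outside a desk-scale budget.
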