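---
title: "Methods: vigilance staging, arousal stability scoring, and the synthetic world"
author: "vigistab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vigilance staging, arousal stability scoring, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigistab)
```

## The construct

During a 20-minute eyes-closed resting EEG most people drift from relaxed
wakefulness towards sleep onset. The trajectory of that drift — how fast,
how deep, whether at all — is a stable individual trait called *arousal
regulation*. People who remain in high-vigilance states for the whole
recording show *hyperstable* (hyperaroused) regulation, a pattern
repeatedly associated with depressive symptomatology; a fast decline is
typical of fatigue in chronic somatic illness. `vigistab` implements the
full measurement chain for this construct: per-second vigilance staging of
the EEG, condensation of the 1200-label sequence into a 1–14 **Arousal
Stability Score**, dichotomization at a cutoff of 13, and the group
statistics used to compare hyperaroused and non-hyperaroused participants
on questionnaire outcomes.

No clinical raw data ship with the package. Instead, a synthetic generator
produces ground-truth stage trajectories, stage-faithful EEG, and
participant cohorts whose questionnaire distributions match published
summary statistics. Every processing claim the package makes is therefore
testable against known ground truth.

## Vigilance stages and the classification cascade

Each non-artifact 1-second segment receives one of seven labels:

| stage | electrophysiological signature |
|-------|--------------------------------|
| 0     | low-voltage EEG, no slow eye movements |
| A1/A2/A3 | dominant alpha rhythm with an occipital / central / frontal centre of gravity |
| B1    | low-amplitude non-alpha EEG with slow horizontal eye movements (SEM) |
| B2/3  | high delta/theta power |
| C     | sleep onset: spindles or K-complexes |

Features come from the 1-second periodogram (1 Hz resolution at 100 Hz):
alpha power (8–12 Hz) per region of interest, delta+theta power (2–7 Hz),
total power (2–30 Hz), RMS amplitude, SEM presence (smoothed EOG excursion
within the second), and graphoelement presence. The decision cascade is
fixed and exhaustive — graphoelement → C; delta/theta dominant and alpha
not dominant → B2/3; alpha dominant → A-substage by the ROI with maximal
alpha power (ties towards occipital); otherwise B1 if SEM present, else 0.

**Design choices made where the design was open.** The original staging
tool localizes the alpha centre of gravity with a distributed source model
(LORETA); no parameters for that step are published. We replace it with a
channel-ROI argmax over occipital (O1, O2, Oz), central (C3, C4, Cz) and
frontal (F3, F4, Fz, Fp1, Fp2) mean alpha power, which captures the same
anteriorization construct at desk scale. All numeric thresholds
(`classifier_thresholds()`: alpha dominance fraction 0.4, low-voltage RMS
10 µV, delta/theta ratio 0.5, SEM band 0.1–1 Hz at 60 µV excursion) are
this package's defaults, tuned once against the synthetic generator and
exposed as configuration; they are not published constants. B2 and B3 are
merged ("B2/3") because the score never distinguishes them. Note that
under this cascade the low-voltage RMS bound is informational only: a
non-alpha, non-B2/3 segment resolves on SEM alone whether or not its
amplitude is below the bound.

## Preprocessing

The chain emulates standard staging preprocessing: 0.5–70 Hz band-pass
with 48 dB/oct roll-off (Butterworth magnitude of order 8), 50 Hz notch,
then resampling to 500 Hz and to 100 Hz before staging. Implementation
details that matter:

* Filters are realized in the frequency domain with a real transfer
  function — zero-phase by construction, so epoch-wise spectral features
  are not phase-distorted.
* Resampling is ideal (Fourier) interpolation. Because ideal resampling to
  500 Hz followed by ideal resampling to 100 Hz is identical to direct
  spectral truncation at 100 Hz, both stages are fused with the filter
  into one spectral pass; the 100 Hz output provably carries no energy
  above 50 Hz.
* **EOG channels are high-passed at 0.05 Hz**, not 0.5 Hz. An order-8
  high-pass at 0.5 Hz attenuates a 0.25 Hz slow eye movement by ~48 dB,
  which would erase the only feature staging reads from the EOG. Scalp
  channels use the standard 0.5 Hz edge.
* The low-pass edge is capped at 0.45× the sampling rate, which makes
  `preprocess()` effectively idempotent (second application changes
  passband RMS by < 1 %).

Artifact handling replaces the original ICA-plus-rater workflow with an
amplitude/variance flag (peak-to-peak > 200 µV on any non-EOG channel, or
cross-channel segment variance > 16× the recording median): the scoring
chain only needs contaminated segments *excluded* — they are labelled
`ARTIFACT`, never classified, and drop out of all scoring fractions.
Graphoelements are detected automatically (sigma-band 11–16 Hz moving RMS
elevated ≥ 0.5 s for spindles; a 0.3–2 Hz band-passed biphasic transient
large against the recording's own slow-wave background for K-complexes),
with an annotation-override path so human markings can replace or extend
the detector, preserving the original workflow's structure.

## The Arousal Stability Score

The recording is divided into twenty 1-minute epochs grouped into four
5-minute blocks. Fourteen rows are scanned, ordered by depth of arousal
decline:

* rows 1–4: at least one C segment; the block of its earliest occurrence
  gives score 1 (block 1) … 4 (block 4);
* rows 5–8: earliest epoch with ≥ 1/3 B2/3 segments, by block;
* rows 9–12: likewise for B1;
* row 13: every evaluable epoch has > 2/3 of its classified segments in
  {0, A1, A2, A3}; row 14: likewise for {0, A1}.

Two reading decisions were required. First, the rows are combined by
taking the **minimum fired row** (with 14 preferred over 13, which it
implies): the table orders rows by degree of decline and the score is a
single scalar, so the deepest, earliest decline wins. Second, fractions
are computed over non-artifact segments only, because artifact segments
are never classified; an epoch that is entirely artifact is unevaluable
and is skipped by the predominance rows. A sequence in which *no* row
fires is possible (diffuse sub-threshold B1 with enough non-A segments to
break row 13): it falls back to score 12 — the nearest non-hyperaroused
score — with `fallback_used = TRUE` for audit. The C rows require a single
segment, not a fraction, following the table's wording. Thresholds are
compared with a 10⁻⁹ tolerance so that exactly-2/3 never counts as "more
than 2/3" and exactly-1/3 always counts as "at least 1/3" regardless of
floating-point representation.

Group assignment is `hyperaroused` iff score ≥ 13. An independent
brute-force row scan (in the test helpers) replays all fourteen rows
explicitly; scorer and oracle agree on hundreds of randomized sequences,
including artifact-laden ones.

## What the synthetic world is — and is not

**Stage scripts.** Profile `"hyperaroused"` emits only stages 0 and A1
(scores 14 by construction); `"declining"` introduces B1, optionally
B2/3, then C at configurable emergence minutes, with the emergence minute
guaranteed to satisfy the scoring threshold (≥ 1/3 of the minute, or ≥ 1 C
segment). Emergence minutes left unspecified are drawn at random
(B1 in minutes 2–6, B2/3 3–6 minutes later, C 2–5 minutes after that,
each later stage present with fixed probability) — the source material
reports no per-stage dwell-time statistics, so trajectory shapes beyond
the scoring-relevant features are free choices, made once.

**EEG synthesis.** Each second carries its stage's signature on baseline
white noise (5 µV): 40 µV occipital-dominant alpha for A-stages with role
gains 1 / 0.35 / 0.1 across the dominant/adjacent/far ROI; extra broadband
noise for low-voltage stages; three coherent 2.2–6.8 Hz components
totalling 35 µV for B2/3; a 0.8 s, 45 µV, 13 Hz spindle or (p = 0.3) a
0.7 s biphasic 80 µV K-complex on central channels for C; a 250 µV,
0.25 Hz horizontal EOG sweep during B1. These amplitudes are the
generator's stated world: chosen once so that the default classifier
separates stages with margin while staying below the 200 µV artifact
bound and inside physiological ranges. The generator does **not** emulate
1/f background texture, volume conduction, alpha waxing/waning, or
pathology — so a green recovery test establishes that the classifier
reads the defined signatures correctly, not that it would reproduce a
human-rated staging of clinical data.

**Cohorts.** IDS-SR sum-scores are drawn from a truncated normal per
group. The published summaries (hyperaroused 20.6 ± 7.3, range 10–41;
non-hyperaroused 12.6 ± 6.2, range 1–24) are sample moments of bounded
data, so the parent mean/sd are *moment-calibrated*: we solve for the
parent parameters whose truncated distribution has exactly the target
mean and sd (closed-form truncated moments, Nelder–Mead), then
rejection-sample and round to integers. Using the printed values directly
as parent parameters would bias the hyperaroused group mean upward by
about +1.1 points. Gender counts (14/5 and 19/22) are matched exactly by
construction. MFI-20 (> 41, median ≈ 52), PSQI (8.4 ± 3.6 vs 5.6 ± 3.1)
and ESS (6.8 ± 3.0 vs 8.3 ± 3.6) are drawn from plausible truncated
normals at the published group summaries; the diagnosis class splits each
group about half cancer, half neuroinflammatory/autoimmune.

## Statistics layer

One-way ANOVA uses the classical decomposition (for two groups, F ≡ t²
of the pooled t test — verified to machine precision); partial η² is
SS_between/(SS_between+SS_within). The two-way ANOVA (group × gender)
uses Type III model-comparison sums of squares under sum-to-zero
contrasts, matching mainstream commercial defaults for unbalanced
designs, and requires ≥ 2 observations per crossed cell. Levene's test is
the mean-centred variant. The 2×2 chi-squared is uncorrected Pearson: the
uncorrected statistic reproduces the published 3.92 from the gender table,
the Yates-corrected one does not. The Mann–Whitney U reports the
tie-corrected normal-approximation Z without continuity correction (the
large-sample convention of the published item tests) and, for n₁+n₂ ≤ 16,
an exact tie-aware permutation p (`p_exact`) computed by a
count-distribution dynamic program — at those sizes the normal
approximation can be off by several hundredths, so the exact value is the
one an enumeration oracle can meaningfully check. Screening metrics of
the dichotomous score are sensitivity, specificity, Youden index, and the
binary AUC (sens+spec)/2, which reproduces the published 0.87 from the
published sensitivity/specificity; a trapezoidal (rank) AUC over the full
1–14 score is provided as `roc_auc()` but the underlying per-subject
scores were never published, so it is not an acceptance path. The main
group test is conventionally one-tailed (`tails = "one"` halves the F
p-value); item-level exploratory tests are two-tailed. No multiplicity
correction is applied to exploratory item tests, mirroring the analysis
the package emulates; this is a faithful reproduction, not an
endorsement.

## Reproducibility and numerical choices

One master seed fans out to per-participant child seeds through a fixed
affine map modulo 2³¹−1, so per-subject results are independent of cohort
size and processing order; the same seed yields byte-identical
`report.json`/`report.tsv` files. EDF output is 16-bit with per-channel
symmetric physical ranges (round-trip error ≤ max|x|/32767 per channel);
BrainVision output is 32-bit float and round-trips to single precision.
Tests and the acceptance script run the EEG chain on a reduced montage
(one channel triple per ROI plus HEOG) at 200–250 Hz and, where the score
itself is not needed, on shortened recordings — scaled down for runtime,
with the full 33-channel, 1000 Hz, 1200 s configuration remaining the
package default.

## Known limitations

* Classifier thresholds and synthesis amplitudes are co-designed; recovery
  rates quantify internal consistency, not agreement with human raters or
  with the original staging software's numeric output.
* The K-complex detector assumes the synthetic morphology (isolated
  biphasic transient); real K-complexes embedded in high-amplitude slow
  sleep EEG would need a tuned `kc_min_amp`.
* Stage B2 vs B3 and eyes-open data are out of scope.
* The published ROC confidence interval (resampling or parametric method
  unspecified) is not reproduced; only the point metrics are.
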