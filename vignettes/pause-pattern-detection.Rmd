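---
title: "Detecting cloned voices from speech pause patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cloned voices from speech pause patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The idea

Authentic speech is interrupted by pauses that biology forces on the
speaker: breathing, swallowing, and the cognitive work of reading and
planning the next phrase. A text-to-speech voice clone has none of these
constraints; it places pauses only where its training data suggests. The
hypothesis behind this package is that the *pattern* of pauses — not their
loudness, not the spectrum — carries enough signal to discriminate cloned
from authentic recordings, and keeps carrying it as cloning systems improve,
because it reflects what the machine does not need rather than what it
currently gets wrong.

Working on pause timing alone also buys robustness: features built from
amplitudes depend on the microphone and the speaker's distance to it, so the
package deliberately uses none.

## From audio to five numbers

A recording is first segmented by a voice activity detector (VAD) into
maximal voiced intervals. The spans between consecutive segments are
classified by length:

* gaps of at least 0.1 s and under 0.5 s are **micropauses**;
* gaps of 0.5 s or longer are **macropauses**;
* gaps under 0.1 s ("intra" gaps) are below the resolution at which we call
  something a pause. They still separate segments and still count in the
  recording length, but in neither pause rate. The flanking segments are not
  merged.

The recording is trimmed to start at the first segment's onset and end at
the last segment's offset, and five features are computed:

| feature | definition | units |
|---|---|---|
| `SpeechAV` | mean speech-segment length | s |
| `SpeechSD` | sample SD of segment lengths (0 for a single segment) | s |
| `SpeechProp` | total speech time / trimmed length | — |
| `MiRate` | micropauses per trimmed minute | 1/min |
| `MaRate` | macropauses per trimmed minute | 1/min |

Two conventions deserve a note. The denominator of `SpeechProp` is the
*trimmed* length: leading and trailing silence say more about when the
recording button was pressed than about the speaker, and the pause rates
already use the trimmed length explicitly. `SpeechSD` uses the n−1
denominator, the usual estimator when recordings are samples from a
speaker's behaviour.

## The voice activity detector

The default segmenter is a deterministic energy VAD: 25 ms frames with a
10 ms hop; a frame is voiced when its RMS exceeds the recording's noise
floor (the 10th percentile of frame RMS) times a factor of 4. Silent runs
shorter than 50 ms are absorbed into speech; voiced runs shorter than 50 ms
are dropped. Because the threshold is relative to the recording's own noise
floor, scaling all samples by a constant leaves the segmentation unchanged —
a property the amplitude-agnostic features inherit. The 50 ms
minimum-silence setting is deliberately below the 0.1 s micropause floor, so
the VAD cannot erase a pause that the feature definitions would count.

Two refinements handle cases a bare frame rule cannot:

* **No internal dynamic range.** If no frame clears the relative threshold
  (a noise burst spanning the whole file, or pure silence), the detector
  falls back to an absolute RMS floor of 0.01 to decide between "all
  speech" and "all silence". The relative rule resumes as soon as a
  recording contains both kinds of frame. The corollary is a known
  limitation: a recording with under ~10% silence has a noise-floor
  estimate contaminated by speech and degrades to the fallback.
* **Boundary refinement.** A 25 ms frame straddling a speech onset collects
  enough energy to trigger up to two frames early. After the frame-level
  pass, each boundary is refined to sample accuracy by scanning a 5 ms
  energy window within one frame of the coarse boundary for the first (or
  last) crossing of the same threshold. This is what makes segment
  boundaries reliable to within one hop (10 ms) on rendered timelines.

The segmenter is pluggable: any function from waveform to a sorted,
non-overlapping segment table can be registered with `set_segmenter()`, and
its output is validated against that contract before features are computed.
This is the seam through which a neural VAD (e.g. Silero) can replace the
energy detector without touching anything downstream; the default keeps the
package self-contained and exactly reproducible.

Audio enters the pipeline as mono WAV, averaged over channels and resampled
to a canonical 16 kHz by linear interpolation on load, so frame sizes have
fixed sample semantics regardless of the capture rate (which, for the
original cohort, is not documented).

## Comparing the classes

Each feature is compared between authentic and fake training recordings
with the two-sided Mann–Whitney U test at α = 0.05, reported feature by
feature without multiplicity correction (five pre-registered, strongly
correlated features). The p-value is exact — the full permutation
distribution — whenever `n1*n2 ≤ 400` and the pooled sample is tie-free,
and otherwise uses the normal approximation with tie and continuity
corrections. A pooled sample with no variation at all returns p = 1. Rank
tests keep the comparison invariant to any monotone rescaling of a feature.

## The detector

Five classical families are tuned by exhaustive grid search: AdaBoost on
decision stumps (ADA), an RBF support vector machine (SVM), random forest
(RF), L2-regularized logistic regression (LR), and a decision tree (DT).
Neural networks are deliberately out of scope: with ~130 training
recordings and 5 features they would mostly measure overfitting. The
default grids are small because the feature space is tiny: RF trees
{100, 300} × depth {3, 5, unlimited}; DT depth 2–8; LR penalty
{0.01, 0.1, 1, 10}; SVM cost {0.1, 1, 10} × kernel width {scale heuristic,
0.1, 1}; ADA rounds {25, 50, 100, 200} × learning rate {0.5, 1}. Tree
models see raw features; LR and SVM see features standardized by
training-fold mean and SD. AdaBoost is the package's own implementation of
the discrete two-class algorithm over depth-1 `rpart` stumps (no AdaBoost
implementation is among the package's dependencies); rounds stop early when
a stump cannot beat chance on the weighted sample.

Model selection uses **participant-grouped stratified 5-fold
cross-validation**: every recording of a participant — authentic and cloned
alike — shares a fold, because the clone of a training participant's voice
is not "unseen data" in any meaningful sense. Groups are assigned greedily,
largest first, each to the fold that keeps per-class counts most even
(ties: the emptier fold, then the lower index), which in practice holds
every fold's class ratio within ±2 recordings of the global ratio. The fold
assignment is computed once and shared by every family and every grid
point, so model comparisons are paired. The selection criterion is the
across-fold mean of balanced accuracy,
(sensitivity + specificity)/2 — the fold average, not the pooled-confusion
value — with grid order breaking exact ties. A validation fold that ends up
single-class (possible when a large group drags one class with it) is
skipped for the affected metric with a warning rather than silently
imputed.

The winner is refit on all training recordings and exposes both a hard
label and a continuous fake score (class probability, decision value, or
normalized vote margin, by family), from which ROC curves and the
rank-statistic AUC are computed.

## Evaluation on model-naive data

Test recordings are binned along three axes: participant (model-trained /
model-naive / pregenerated TTS), paragraph (trained P1–P2 / naive P3), and
generator (authentic / model-trained / model-naive). Every test recording
is naive on at least one axis by construction of the split rule. The report
is a confusion row per occupied cell, per-block overall accuracies, and a
compiled overall accuracy and AUC over the pooled test set. The package
also bundles, as a plain-CSV fixture, the confusion counts of a reference
evaluation of a pause-pattern detector on a 257-recording held-out set;
`reference_test_report()` rebuilds the full report from those counts, which
pins down the reporting arithmetic (e.g. compiled overall accuracy
204/257 ≈ 0.79) independently of any trained model. The AUC of a
counts-only report is `NA`; whether a pooled-score AUC and a per-subgroup
average would differ is exactly why the package always pools scores and
says so.

## The synthetic cohort

No recordings ship with the package, so validation rests on a generative
stand-in with the statistical structure the analysis assumes. A timeline
alternates speech segments and gaps:

* segment lengths are log-normal, moment-matched to a target mean and SD
  (log-normality is a modelling choice — positive, right-skewed, typical of
  speech-segment durations; the targets constrain only two moments);
* after each segment the gap is macro with probability
  `ma_rate/(mi_rate + ma_rate)`, drawn as 0.5 s plus an exponential excess
  (mean 0.3 s), otherwise micro, uniform on [0.1, 0.5);
* generation runs until the target duration (default 90 s, a typical read
  paragraph of ~200 words) is reached, always ending in a segment.

Class defaults are the observed class-level statistics of authentic
(segments 2.93 s ± 1.51, 11.72 micro- and 7.04 macropauses/min) and cloned
audio (3.49 s ± 1.22, 9.47 and 5.78). Note that only the *ratio* of the two
rates is a direct parameter: the realized pause frequency emerges from the
segment/gap alternation, and the four targets are not exactly jointly
attainable within this structure (mean segment length plus mean gap implies
slightly fewer gaps per minute than the rate targets state). The realized
rates land within ~7% of their targets and the tests hold the generator to
a 5% mean absolute relative error across the five features at large n —
`SpeechProp` and `SpeechSD` are emergent, and what the tests pin for them
is the *direction* of the class difference (clones: longer, steadier
segments, higher speech proportion, fewer pauses), not exact values.

Each participant carries one multiplicative log-normal random effect
(scale 0.15) on segment-length mean and pause rates, shared by their
authentic and cloned recordings, so recordings from one voice are
correlated — this is what makes participant-grouped cross-validation
consequential and is why naive-participant accuracy is the interesting
number. Pregenerated TTS voices draw from the cloned parameters without
participant effects. The default cohort reproduces the reference study
bookkeeping exactly: 49 participants, 384 recordings, 127 training / 257
testing under the default split; since the individual missingness pattern
behind those aggregates is not public, the package uses a fixed documented
incidence that reproduces every aggregate cell, gives each of the 30
training participants at least one training recording, and populates every
test subgroup.

What the simulator does *not* emulate: lexical and paragraph-specific
timing (its "paragraphs" differ only through sampling noise), accent and
language effects, channel/noise conditions, generator-specific pause
artifacts, and any amplitude or spectral structure beyond band-limited
noise. Passing tests therefore demonstrate that the pipeline recovers
class differences of the observed size and direction under grouped
sampling — not that any particular accuracy transfers to real recordings.

## Problem sizes and runtime choices

The test suite and the acceptance script run the full pipeline on the
384-recording cohort with 90 s timelines; the repeated-seed suites use 20
seeds for the class-comparison property (60 recordings per class) and 10
seeds for the full cross-validation pipeline. On one CPU the whole test
suite runs in about three minutes and the acceptance script in under one.
These sizes were chosen as the smallest at which the grouped CV behaves
like the study-scale problem (≈6 participants per fold).

## Known limitations

* The energy VAD is not a neural VAD; on real, noisy recordings its
  segment boundaries (hence absolute feature values) will differ from a
  Silero-style detector, which is why absolute feature statistics from
  other segmenters are not directly comparable. The pluggable contract
  exists precisely for that substitution.
* Short clips are out of scope by design: with fewer than a handful of
  pauses, rate features are dominated by quantization noise. The method
  presumes paragraph-length audio.
* The classifier learns pause statistics of *current* generators; the
  synthetic cohort inherits its class separation from fixed parameter
  targets and cannot discover a future generator that fakes pauses well.
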