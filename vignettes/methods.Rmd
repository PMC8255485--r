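---
title: "Occupancy-normalized vocalization scoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy-normalized vocalization scoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usvscore)
```

## The problem

Rats emit ultrasonic vocalizations (USVs) in two broad families: short
(~30-40 ms) 50-kHz calls associated with appetitive states, and long
(1-3 s) 22-kHz alarm calls. The 50-kHz family subdivides into fourteen
subtypes by spectrogram shape (Trill, Flat, Complex, Composite, Short,
Flat-Trill combination, Split, Trill-with-Jump, Step-Up/Down,
Multi-Step, Inverted-U, and the two Ramps), plus an "Unclear" bin for
calls that fit none of them.

When a rat chooses between a social reward (a caged juvenile
conspecific) and a non-social reward (sucrose solution) on the arms of
an X-shaped maze, the calls it emits near each reward carry information
about how it values them. Raw call counts are useless for this
comparison: animals differ enormously in overall "chattiness", and they
spend different amounts of time at each reward. This package implements
the scoring scheme that deals with both problems:

* Calls are rasterized onto a 25 Hz frame grid synchronized with video
  tracking; the unit of analysis is the **call frame** (one 40 ms bin
  carrying a subtype label), which weights long and short calls by
  their duration.
* Per zone, call frames are divided by the seconds the animal occupied
  that zone, giving the **combined vocalization score** (CVS, frames/s,
  over all 15 non-22-kHz subtypes) and per-subtype **SVS**.
* The within-subject contrast **dCVS/dSVS** (focal-zone score minus
  other-zone score; the focal zone is the higher sucrose in a sucrose
  discrimination trial, the juvenile in a social-sucrose trial) cancels
  chattiness differences between animals.

## Synchronization rules

Frame `k` spans `[k/25, (k+1)/25)` seconds; the trial starts at `t = 0`
and call intervals are half-open `[start, end)`. A frame carries a
subtype if a call of that subtype overlaps it by **any positive
amount**. This preserves 30-40 ms calls that straddle a frame boundary;
a call of duration `d` therefore occupies between `floor(25 d)` and
`floor(25 d) + 2` frames. The raster is one-hot: overlapping calls of
different subtypes are an input error, and when two non-overlapping
calls touch the same boundary frame the earlier call keeps it (making
the raster independent of input order).

Each frame takes the zone of the tracking sample nearest in time within
one frame interval. Frames with no usable sample are gaps and drop out
of both numerator and denominator of every score. Positions inside no
reward or sandpaper polygon belong to the neutral platform; neutral
time is excluded from preference scores, and calls emitted there are
tabulated but excluded from zone-normalized scores, mirroring the
exclusion of neutral time.

Channel selection (`select_channel()`) picks the microphone with the
largest recorded amplitude, ties to the lowest index — the rule used
when labels are taken from a four-channel recording.

## Scores and the subtype filter

`preference_score(t_focal, t_other)` is `100 t_f / (t_f + t_o)`; with
zero time in both reward zones it is flagged missing rather than scored
zero. CVS and SVS are plain ratios (frames per occupancy second), so
they are invariant to jointly rescaling counts and occupancy, and SVS
sums to CVS over the 15-subtype universe.

The log transform for the CVS ANOVA is `ln(cvs + 0.001)`. The offset —
one call frame per 1000 s of occupancy — keeps silent zones finite; no
base or zero-handling is canonical for this transform, so both the raw
and logged scores are reported, and the log is used only as the ANOVA
DV.

Rare subtypes are removed before subtype-level statistics with a
prevalence filter: a subtype is kept when it reaches the threshold
(default 2%) of pooled call frames. The denominator is all non-22-kHz
call frames with Unclear included — the same universe as the CVS — and
the filter is computed once on frames pooled across both tasks and
reward zones, then applied identically everywhere. Unclear never enters
subtype analyses regardless of prevalence, since it is a residual bin,
not a subtype.

## The statistical battery

* **t tests** (`usv_t_test()`): classical Student tests with Cohen's d;
  zero-variance inputs are flagged degenerate instead of producing an
  infinite statistic.
* **Repeated-measures ANOVA** (`rm_anova_within()`): fully
  within-subject designs with one or two factors via the classical
  `Error(subject/(A*B))` strata; no sphericity correction (only
  Bonferroni-corrected post hocs are offered, by design). Partial eta
  squared comes from each effect's own stratum,
  `SS_e / (SS_e + SS_err)`. An effect whose sums of squares are
  numerically zero (constant DV) reports `F = 0`, `p = 1` rather than a
  ratio of rounding noise.
* **Rank tests** (`rank_test()`): Kruskal-Wallis, Mann-Whitney U,
  Wilcoxon signed rank and Friedman with midrank ties. The default p
  is asymptotic (chi-square / normal with continuity correction), which
  is what mainstream GUI statistics packages report; exact null
  distributions by full enumeration (label permutations, sign flips,
  within-row rank permutations) are available below a configurable size
  cutoff and are verified against independent enumeration in the test
  suite.
* **Mixed model** (`fit_mixed_model()`): `lme4::lmer` REML fit of a
  delta score on sucrose concentration with a per-animal random
  intercept. The default slope CI is a cluster-robust Wald interval:
  a sandwich covariance over animals at the fitted GLS weights, with t
  quantiles on `n_animals - 1` df. The robust default matters because
  delta-score noise is heteroscedastic across conditions — the variance
  of an occupancy-normalized score grows as occupancy shrinks, and
  occupancy in the focal zone varies systematically with sucrose level —
  which makes the model-based interval slightly anticonservative
  (simulated coverage ~90% vs a calibrated ~95-97% for the robust one
  at the study's design size). The model-based Wald interval with
  `N - n_animals - 1` df stays available via `ci_method = "model"`.
  Marginal R² follows the Nakagawa decomposition,
  `var(fixed predictions) / (var fixed + var intercept + var resid)`.
  A singular random-intercept variance triggers a fall-back to pooled
  OLS with a warning (the balanced-design slope estimate is unchanged).
* **Cohen's kappa** (`cohen_kappa()`): `(p_o - p_e)/(1 - p_e)` for
  inter-rater agreement on label sequences.

## The synthetic cohort generator

No public recordings exist for this paradigm (part of the original
material was lost), so the package ships a generator whose output has
known ground truth at every pipeline stage.

**Occupancy.** A semi-Markov shuttle process over \{focal zone, other
zone, neutral platform\}: exponential dwell in the current zone, reward
to reward always via neutral, and the neutral-exit probability chosen
so the long-run focal share of reward time equals a target preference.
Default targets are calibrated to the study's group-mean zone times:
juvenile preference 0.62 / 0.55 / 0.19 against 2% / 5% / 10% sucrose,
and 0.65-0.70 for the higher sucrose in discrimination trials, with
neutral dwell set to reproduce the observed fraction of trial time on
the platform (16-30%).

**Emission.** Calls arrive as a Poisson process whose rate depends on
the occupied zone, with subtype drawn from a zone-specific mix and
duration from a truncated normal (50-kHz: 35 ms +/- 5; 22-kHz: 2 s +/-
0.5). The default mix follows the pooled subtype prevalences of the
study (Trill 27%, Flat 24%, Complex and Composite 11-12%, ..., six
rare subtypes ~1% each), with extra Trill weight (taken from Flat) in
the social zone. Generated calls are thinned so no two calls overlap or
share a frame; because thinning makes the kept calls a renewal process
with a known rate, requested rates are pre-compensated analytically and
the realized frame scores match their targets. Zone-level combined
scores default to the study's group means (sucrose zone ~0.31 frames/s
in social-sucrose trials; 0.13-0.41 in discrimination trials), and the
social-vs-sucrose score difference is planted as
`0.048 + 0.034 x sucrose% + animal offset` — the linear structure the
mixed model is designed to estimate. 22-kHz calls are emitted at a low
rate tuned so their long calls contribute roughly a quarter of all call
frames. Per-animal effects: a lognormal mean-1 chattiness multiplier
(log-sd 0.25) on all rates, and a Gaussian offset (sd 0.08 frames/s) on
the planted score difference, which becomes the random intercept the
mixed model should absorb.

**Microphones.** Four microphones near the arm ends;
`amp = A0 - 20 log10(1 + d/d0) + N(0, sd)` with `A0 = -20` dB,
`d0 = 10` cm, noise sd 2 dB — monotone in distance, so the nearest
microphone is loudest in expectation, which is all channel selection
needs.

**Determinism.** One master seed; every trial derives a substream seed
by hashing (animal, task, condition, day, stream), so cohorts are
reproducible trial by trial and byte-identical on disk across runs.

What the generator does **not** emulate: call bouts and serial
dependence between calls, caller identity (experimental vs juvenile
animal — deliberately, since the recordings could not separate them
either), acoustic waveforms, within-bout amplitude dynamics, tracking
jitter and dropouts beyond explicit gap rows, and day-to-day learning.
Passing tests therefore demonstrate that the pipeline arithmetic is
correct and the estimators are calibrated under the planted model; they
do not validate the behavioral assumptions against real recordings.

## Numerical and design choices

* Frame duration is 1/25 s = 40 ms throughout.
* Times are seconds; coordinates cm with origin at the maze center and
  y increasing toward group A's juvenile arm; reward-zone depth along
  the arm is a config parameter (default 20 cm), since only zone
  membership — not extent — is determined by the paradigm.
* Table dialects (delimiter, decimal mark, column names) are declared,
  never sniffed; European decimal-comma exports are handled by the
  dialect object. Error messages cite 1-based data rows.
* Score CSVs round to 6 significant digits; the pipeline's analyze
  stage consumes the written tables, so re-running it on a saved score
  bundle reproduces the stats tables bit-exactly.
* Simulation study sizes: the slope-recovery analysis script uses 100
  replicate cohorts of 8 animals x 3 conditions x 600 s; the acceptance
  checks use 500. A replicate is scored from the generator's zone
  timeline (the tracking-based zone assignment path is validated
  separately by exact round-trip tests), which keeps a 500-replicate
  study in the minutes range.

## Known limitations

* The pipeline ingests labels; it does not detect or classify calls
  from audio.
* With very short trials an animal may never visit one reward zone;
  affected animals are dropped from the within-subject ANOVAs (logged),
  and their delta scores are flagged missing rather than imputed.
* Exact rank tests enumerate the full null and are only intended for
  small samples (the default cutoff is 10 observations).
* The labeled-interval policy (e.g. annotating only alternate minutes)
  is handled implicitly: scores normalize by occupancy within whatever
  interval set was labeled, so no rescaling is applied or needed.
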