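---
title: "Scoring drum performances and testing training-related plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring drum performances and testing training-related plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drumscore)
```

## What the package computes

A drum performance on an electronic kit is a stream of time-stamped note
events. `drumscore` assesses such a stream against the metronomic ("perfect")
beat grid of a fixed assessment pattern and summarizes it with three numbers:

* **% bars completed** — a bar counts as completed when *every* expected
  strike of the pattern is present within half a beat of its nominal time;
* **flam error** — for slots where several limbs should strike simultaneously,
  the time from the first to the last matched event at that slot, evaluated in
  completed bars only;
* **HRS error** — the flam error pooled over the three-limb slots (beats 2
  and 4 of the quarter-note pattern: left foot on the pedal hi-hat, right hand
  on the ride, left hand on the snare), the package's coordination measure.

The second half of the package is the group-level statistical pipeline for a
two-group (training vs control) pre/post design with neuroimaging-derived
measures: TCV residualization of cerebellar lobule volumes, Mann-Whitney tests
on performance delta scores, per-measure ANCOVAs with covariates, and rank
correlations between corrected volumes and performance precision gains.

## The assessment patterns and the tolerance

Both patterns are one bar of 4/4 at a fixed tempo (no tempo fluctuation in the
backing track, so the grid is strictly periodic):

| pattern | slots/bar | expected strikes |
|---|---|---|
| quarter | 4 | beats 1, 3: ride (RH) + kick (RF); beats 2, 4: ride (RH) + snare (LH) + pedal hi-hat (LF) |
| eighth | 8 | closed hi-hat (RH) on all 8 slots; kick (RF) on beats 1, 3; snare (LH) on beats 2, 4 |

The completion tolerance is *half the pattern's subdivision interval*:
`0.5 * 60000 / tempo` ms for the quarter pattern and half that for the eighth
pattern. The assessment tempo is not itself a reported constant, so the
package fixes the default at 120 bpm, at which the tolerances take their
canonical printed values of 250 ms and 125 ms; both tempo and tolerance are
arguments (`make_template(pattern, tempo_bpm, tolerance_override)`). For the
eighth pattern we read "half a beat" as half the *eighth-note* interval
(125 ms), following the printed constant rather than the literal phrase. By
default the eighth pattern requires all twelve listed strikes (eight hi-hats
plus kick/snare backbone) for completion; a relaxed criterion can be obtained
by passing a template whose `expected` table is edited accordingly.

Bars are anchored at `song_offset_ms` (default 0) and a bar is scored when its
bar-start nominal time falls in the half-open capture window
`[start_s, end_s)` (default 60–180 s, i.e. minutes 1–3 of the song). The
half-open convention avoids double counting at the boundaries; anchoring by
bar start is a deterministic rule chosen where no convention is dictated.

## Matching events to the grid

Completion must tolerate extra hits, dropped strikes and large displacements,
so matching cannot be a naive per-slot nearest neighbour: an event must not be
consumed twice, and a displaced event must not steal a neighbour's slot when a
better global assignment exists. Per instrument, `match_events()` finds the
one-to-one assignment of events to expected strikes that

1. maximizes the number of strikes matched within the tolerance, and
2. among those, minimizes the total absolute deviation,
3. breaking remaining distance ties toward the earlier event.

Both point sets live on a line and are sorted, so an optimal assignment can
always be taken non-crossing (uncrossing two matched pairs never increases
either objective); the package therefore computes it exactly with a monotone
dynamic program over (events x slots). Because an event can only be matched
within `tolerance_ms`, the bipartite graph decomposes into small independent
components (rarely more than a couple of events wide when the tolerance is at
most half the slot spacing), and the DP runs per component — exact matching at
a cost that is effectively linear in performance length. The test suite checks
the DP against an exhaustive assignment oracle on random small streams.

Deviations are signed (`event - nominal`). Unmatched expected strikes are
recorded as missing; unmatched events are ignored for completion (presence
within tolerance is the criterion, extra hits are not penalized beyond their
ability to confuse the matcher — which the one-to-one rule prevents).

## The synthetic drummer

`simulate_performance()` emits, for every expected strike, an event at
`nominal + lag[limb] + N(0, sigma[limb])` with probability `1 - miss_prob`,
plus Poisson extra events uniform in time and instrument (uniform so they
carry no information about the grid and genuinely stress the one-to-one
matcher). Jitter is i.i.d. per strike by default — the simplest model with a
closed-form oracle:

```
P(bar completed) = [ (1 - m) * (2 * pnorm(tol / sigma) - 1) ]^k
```

for `k` expected strikes per bar (`closed_form_completion_prob()`). An AR(1)
drift option (`ar1_phi`) adds slow within-limb autocorrelation for robustness
checks, but is off by default precisely because it breaks this closed form.
A `learning_gain` in (0, 1] scales jitter and miss probability
multiplicatively to model training (`after_training()`).

Defaults (jitter 60 ms, miss 5%, 0.2 extra hits/bar) are *plausible-novice
placeholders*: true novice jitter magnitudes are not well established, and
nothing downstream depends on them — tests and the acceptance script always
set explicit parameters. What the simulator does **not** model: tempo drift,
expressive micro-timing, velocity dynamics, biomechanical coupling between
limbs. Passing tests therefore show the scoring machinery is correct under a
known generative model, not that real novice data look Gaussian.

## The cohort generator and the statistical pipeline

`simulate_cohort()` draws, per subject and measure,
`baseline + subject_level + time_noise + effect * [drum group at T2]` with
`subject_level ~ N(0, between_sd)` and `time_noise ~ N(0, within_sd)`.
Lobular volumes are additionally scaled by a latent per-subject total-volume
factor (CV 7%), so TCV correction has genuine shared variance to remove.
Group sizes default to 15 + 16 with sex counts 7/8 and 8/8 and ages uniform on
16–19 years — the matched two-group design shape. Baseline means use published
before-training values where available and typical atlas proportions
elsewhere; group-by-time **effects are always user-set and default to zero**
(a null cohort), so calibration properties are testable out of the box and no
"expected result" is baked into the generator. Drum-score rows get larger SDs
(novice performance is highly variable) and are clamped to their natural
ranges.

`run_table2_pipeline()` chains the analysis:

1. subjects missing a timepoint are excluded with a warning;
2. `tcv_correct()`: TCV = row sum of the 20 hemispheric lobule columns; each
   volume column (vermis included, though outside the sum) is replaced by its
   pooled-OLS residual plus grand mean. Residuals are orthogonal to TCV by
   construction (checked to 1e-10). If TCV is constant the slope is
   unidentifiable and volumes pass through unchanged with a warning;
3. per brain measure, an ANCOVA of the per-subject delta (T2 − T1) on group +
   covariates. The default covariate is sex only (coded male = 0, female = 1,
   so coefficients are interpretable); age can be added via `covariates =
   c("sex", "age")`. The alternative `on_post_adjusting_pre` design regresses
   the T2 value on group + covariates + T1. The *delta* design is the default
   because the per-subject change is the quantity of scientific interest and
   it keeps one row per subject — published F degrees of freedom of the form
   F(2, 59) are not reproducible from 31 subjects under any per-subject model,
   and the package reports honest df rather than imitating that shape;
4. drum scores: Shapiro-Wilk screens each group's deltas; nonparametric
   Mann-Whitney is used when either group deviates from normality (the typical
   case for novice performance data), Welch's t otherwise. The HRS delta is
   reported both as raw ms (post − pre) and as percent precision change
   (`100 * (pre - post) / pre`); the Mann-Whitney consumes the raw ms delta by
   default (`hrs_delta = "pct"` switches) — both conventions are emitted
   because published methods and results differ on which is quoted;
5. demographics: chi-squared (Yates off by default, the uncorrected Pearson
   statistic being the common default of desktop statistics packages; a flag
   enables it) for sex, Mann-Whitney for age;
6. rank correlation between TCV-corrected left VIIIa volume at T2 and HRS
   precision gain within the training group, emitted as **both** Spearman's
   rho and Kendall's tau-b — methods sections and results sections in this
   literature do not always agree on the coefficient, so the package refuses
   to guess and reports both.

No multiplicity correction is applied by default (per-measure alpha 0.05, as
is common in small exploratory imaging studies); `adjust = "BH"` appends a
clearly labelled adjusted column rather than silently replacing raw p-values.

### Test statistics: build vs delegate

The exact Mann-Whitney null distribution, Pearson chi-squared, Shapiro-Wilk,
Spearman/Kendall and OLS are standard, well-tested routines and are delegated
to base R (`wilcox.test`, `chisq.test`, `shapiro.test`, `cor.test`, `lm`) with
`car::Anova` supplying the type-III group F. The package's own contributions —
grid matching, completion/flam/HRS scoring, TCV residualization semantics, the
generators and the pipeline logic — are implemented here and validated against
independent oracles in the tests: exhaustive assignment search, full
enumeration of rank labelings, hand-computed ANOVA partitions, pairwise
concordance counting, numerically integrated Gaussian range expectations, and
noncentral-F power.

## Numerical choices and degenerate inputs

* Matching ties on |deviation| go to the earlier event; equal-score DP
  alternatives resolve toward earlier events/slots, so results are
  deterministic.
* Zero completed bars: flam table is empty and HRS is `NA` (absent), never 0.
* Degenerate samples: identical values in both Mann-Whitney samples give
  p = 1; a constant ANCOVA response gives F = 0, p = 1; zero-variance inputs
  to rank correlation raise an error rather than returning `NaN`.
* SMF I/O: note-on with velocity 0 is treated as note-off (the SMF
  convention); ticks convert to ms piecewise under tempo meta-events; the
  writer quantizes to the tick grid, so round-trips are exact to within one
  tick (~1 ms at 480 ppq, 120 bpm). SMPTE division and format-2 files are
  rejected loudly. MIDI onsets are used as-is with no audio-onset correction —
  electronic-kit MIDI is within a few ms of the physical onset.
* The default note map follows General MIDI percussion (36 kick, 38 snare,
  51 ride, 44 pedal hi-hat, 42 closed hi-hat); kits differ, so the map is
  overridable from YAML (`read_limb_map_yaml()`), and unmapped notes route to
  `other`/`unknown` instead of erroring.

## Problem sizes used in validation

The shipped tests run the matcher-vs-oracle comparison on 100 random 4-bar
streams, the analytic completion curve at 2000 simulated bars per parameter
point, lag-recovery on 1000 bars, Mann-Whitney enumeration on 50 fixtures up
to n = 10, null calibration of the pipeline on 500 simulated cohorts and
effect recovery on 200 — sizes chosen so Monte-Carlo standard errors are small
relative to the 3-SE acceptance bands while the whole suite stays comfortably
runnable on a laptop.

## Known limitations

* Scores depend on the configured tempo, window and offset; scoring a
  performance against the wrong anchor shifts every deviation (translation
  invariance holds only when events and grid shift together).
* The matcher's objective (max matches, then min total deviation) is a
  modelling choice; completion flags are insensitive to it in realistic
  regimes (tolerance at most half the slot spacing) but extreme-jitter streams
  can be assigned differently by other reasonable objectives.
* The cohort generator is Gaussian and additive; it does not emulate
  segmentation error distributions, scanner drift, or floor/ceiling structure
  of real derived measures beyond simple clamping, so calibration results
  speak to the pipeline's arithmetic, not to robustness on real data.
* With 31 subjects the per-measure ANCOVA has modest power; the pipeline's
  per-measure alpha reproduces the analysis convention it mirrors, and the
  optional BH column is the recommended guard when many measures are scanned.
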