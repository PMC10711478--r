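---
title: "Models and methods behind optomaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind optomaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific model behind each stage of the
pipeline, the parameters that matter with their defaults, the design
choices made where the procedure was genuinely open, and the limits of
what the synthetic data can show.  Empirical claims here are limited to
what the package's tests and acceptance script themselves compute.

## The maze and the lap model

The track is a ring of eight 4 × 40 cm paths (320 cm), feeders at the
four compass points, and an infrared beam-break sensor 15 cm upstream
of each feeder in the (clockwise) run direction.  Track coordinates
are cm clockwise from the start line on the half-open ring
`[0, ring_length)`.

A *lap* is delimited by successive crossings of the boundary sensor.
The recording convention never names a dedicated start-line device, so
the package defines the boundary as the first sensor reached from the
start position in the run direction — the start position is fixed
throughout an experiment, which makes this device stable across
sessions.  A session is bounded by 10 complete laps or 900 s from the
`session_start` event, whichever comes first; the 900-s bound is
applied inclusively to a lap's closing crossing (`t_end ≤ 900`).  A
lap in progress at truncation is kept with `complete = FALSE` and
excluded from every rate denominator: whether partial final laps
contributed to any denominator is not recorded in the protocol, and
excluding them avoids scoring a lap the animal never finished.  Pokes
before the first boundary crossing or after truncation are counted and
reported, never silently dropped.  Gates in the physical maze prevent
retracing; logs whose sensor crossings violate ring order are flagged
in the segmentation attributes but not rejected, since single-sensor
glitches should not discard a whole session.

## Behavioral rates

With `n` complete laps, the *correct response rate* is the fraction of
laps whose distinct-poked-feeder set is exactly the rewarded feeder;
the *rule learning rate* is the fraction whose set has exactly one
element.  Correct implies rule, so `correct ≤ rule` holds identically
— the test-suite asserts it across 10⁴ simulated sessions.  "Chose" is
read as *at least one nose poke*: poke multiplicity is retained in the
lap objects but ignored by the rates, which are defined on which
feeders were chosen.  Laps with no pokes count in denominators and in
neither numerator, since the total lap count is unqualified.  Day
values are unweighted means of the (up to four) session values per
animal; an undefined session rate (no scorable laps) is excluded from
that field's mean only.

Running speed divides the fixed 15-cm sensor-to-feeder distance by the
latency from that sensor's crossing to the first subsequent poke at
the rewarded feeder within the lap.  Laps missing either event are
skipped; a poke that precedes its crossing marks the lap invalid.
Both counts are reported alongside the speeds.

Under post-reward stimulation the rates are computed from the lap
*after* the first reward acquisition, so every scored lap was preceded
by at least one stimulation; pre- and opposite-stimulation sessions
score all complete laps, since stimulation there occurs from the first
lap.

## The trial-shuffled chance criterion

Chance levels for both rates come from shuffling "the trial number":
each poke keeps its feeder identity and receives a lap label drawn by
uniformly permuting the original multiset of lap labels across pokes,
after which per-lap feeder sets and the rate are rebuilt.  This is the
only reading that perturbs the rates at all — both depend only on
per-lap feeder sets, so reassigning intact laps to new positions would
change nothing.  Shuffling conserves the lap count and the poked-feeder
multiset by construction.

The default 1000 shuffles give a one-sided upper-tail p with the
add-one estimator `p = (1 + #{null ≥ observed})/(1 + 1000)`; ties count
against significance and p can never be zero.  The learning criterion
is *exceeding the entire distribution*, equivalent to
`p = 1/1001 < 0.001`.  For day-level chance bands each of the day's
sessions is shuffled independently within itself and the per-session
shuffled rates averaged per iteration; the band is the min–max of the
1000 day-level values.  Whether the original analysis pooled across
sessions is not stated; shuffling within session preserves each
session's poke count and lap structure and is the conservative choice.
On toy sessions the Monte-Carlo machinery is checked against exhaustive
enumeration over all distinct label assignments.

Because a null session's observed rate is exchangeable with its
shuffled rates, the criterion's type-I error is at most 1/1001; the
acceptance suite verifies this over 10⁴ sessions of an agent whose
pokes carry no lap information.

One structural property of this shuffle deserves emphasis: per-lap
poke *counts* are conserved (only the pairing of labels with pokes is
permuted), so a session whose pokes are all at a single feeder has a
degenerate null — every permutation reconstructs the same per-lap
sets, the nulls all tie the observed rate and p = 1.  The criterion
is therefore conservative: it fires when pokes are plentiful and
distributed so that reallocation breaks single-feeder laps, and a
flawlessly performing animal that pokes exactly once per lap can tie
but never exceed its own null.  This is inherent to the within-session
label-permutation definition, not an implementation artifact.

## Peri-event photometry

The recorded signal is a single 100-Hz fluorescence channel (the
wireless system is single-wavelength), so no isosbestic correction is
applied; percent ΔR/R₀ is computed directly.  Per stimulation onset:
baseline `R₀` is the mean raw signal over `[−1, 0)` s (closed–open,
immediately before onset); the window −1 s to +8 s is divided into
0.1-s left-closed right-open bins; each bin is
`100·(mean R in bin − R₀)/R₀`.  Samples are assigned to bins by
timestamp; trials with incomplete window coverage, an empty bin, or a
non-positive baseline are dropped and recorded — partial edge bins are
rejected rather than padded, because a half-filled bin would carry a
different variance.  Sampling jitter up to ±10% of the nominal period
is tolerated; beyond that the trace is linearly interpolated onto a
uniform grid (documented in the returned object).

Z-scores are per-trial: each row is centered and scaled by the mean
and SD of its own baseline *bins*, so baseline bins have mean 0 and
SD 1 by construction.  Phase averages are taken over bins whose whole
interval lies inside 0–1 s (stimulation), 2–5 s (early) and 5–8 s
(late).

The suprathreshold count marks a trial when Z exceeds 1.96 *strictly*
in *any* bin lying entirely within the 1.5-s epoch starting 0.05 s
after onset — "exceeded during the epoch" reads as an event within the
epoch, and a tie at the threshold is not exceedance.  An epoch-mean
variant is exposed via `rule = "mean"`.  One consequence of bin-level
Z-normalization is worth stating plainly: the any-bin rule has a
substantial false-alarm rate on pure noise (Z is scale-invariant, so
noise-only bins are approximately standard normal and one of the 14
epoch bins will often cross 1.96).  Counts are therefore meaningful as
*contrasts* between conditions, not as absolute detection rates; the
epoch-mean rule is the variant that goes to zero on amplitude-free
traces.

## Velocity-based behavioral states

Neck-point speed is the per-frame-interval Euclidean displacement over
the frame interval (~30 fps); optional boxcar smoothing exists but
defaults to off, as no smoothing is part of the stated definitions.
Classification precedence is ambulation > immobility > fine movement:
ambulation is the only positively defined criterion (a sustained
half-second window averaging above 2 cm/s), immobility is a run
criterion on what remains, and fine movement is the residual class.
Windows are evaluated at every frame with half-open `[t, t + 0.5 s)`
extent and a frame is ambulatory if *any* covering window passes
(strict `>`); immobility requires a maximal non-ambulatory run of
strictly sub-threshold frames lasting at least 1 s.  Frames at exactly
2 cm/s can only be fine movement.  Tracks shorter than 1 s cannot
satisfy either duration criterion and return a single fine-movement
segment with a warning.  Segments partition the track exactly, so
occupancy percentages sum to 100.

## Group statistics

The split-plot (two-way mixed) ANOVA uses the classical
sums-of-squares decomposition: the between factor is tested against
subjects-within-groups, the within factor and interaction against the
subject-by-day residual.  The Greenhouse–Geisser ε̂ comes from the
pooled within-group covariance of the subject-by-day score matrix via
an orthonormal contrast basis, with the 1/(k−1) lower bound enforced
and ε = 1 exactly at two within levels; within-effect degrees of
freedom are multiplied by ε̂ for the corrected p.  With one group the
model reduces to one-way repeated measures.  Designs with missing
cells are rejected rather than imputed.  The implementation is checked
against an independent sums-of-squares oracle and against the
multivariate reference fit (`car::Anova` with sum-to-zero contrasts).

Wilcoxon tests are exact by enumeration at small sample sizes — all
2ⁿ sign patterns for the signed-rank test (n ≤ 12 after dropping zero
differences, Wilcoxon's convention), all group assignments for the
rank-sum test — and tie-corrected normal approximations with
continuity correction above.  Bonferroni adjustment is `min(1, m·p)`.

## The synthetic-data generator

The maze agent is a per-feeder Bernoulli value learner: it holds
`V(f) ∈ [0, 1]` per feeder and pokes feeder `f` on encounter with
probability `plogis(β·(V(f) − b))`.  Rewarded pokes update
`V ← V + α′(1 − V)`, unrewarded pokes `V ← V + α′(0 − V)`, with
`α′ = α·κ` in stimulated sessions.  Independent per-feeder pokes (not
a single softmax choice) are deliberate: real mice nose-poke several
dispensers per lap while exploring, and multi-feeder laps are exactly
what separates the two rates.  Values persist across an animal's
sessions; in the changing-reward task the rewarded feeder is redrawn
each session uniformly among the other three, preserving no landmark
association.

Defaults were set from the policy's closed form, not fitted: α = 0.5,
β = 8, b = 0.35, initial V = 0.25 give an asymptotic correct rate of
`plogis(8·0.65)·(1 − plogis(−8·0.35))³ ≈ 0.83` — matching the ~80%
second-day performance level of trained animals on the fixed task —
a baseline exploration probability of 0.23 per feeder, and partial
within-session recovery after the reward moves (roughly half the laps
correct late in a changing-location session).  Because α·κ must stay
below 1, the stimulated preset uses κ = 1.9 (α′ = 0.95, near one-shot
relearning); the lesioned preset halves α and running speed and cuts
the lap-initiation rate to 0.3×, reproducing the direction of the
lesion deficits (fewer laps within the 900-s bound, halved measured
speeds).  Traverse times come from a truncated normal speed
(20 ± 5 cm/s) per leg; the first poke of a visit occurs at arrival at
the feeder, so the sensor-to-poke speed metric recovers the generating
speed exactly.  Stimulation bursts are emitted as twenty 20-Hz
`stim_on`/`stim_off` pulse pairs (10 or 40 ms), so duty-cycle
arithmetic (4/5 for 40 ms) is testable from the logs; triggers follow
the condition semantics — rewarded feeder's sensor (pre), the rewarded
poke (post; the protocol states illumination directly after the poke),
or the diametrically opposite feeder's sensor.

Photometry traces are baseline (100 a.u.) plus Gaussian noise plus a
response kernel at each onset of the 30-min, 10-s-cycle protocol (180
onsets, 2-s lead-in).  The double-exponential kernel rises during the
1-s burst and decays after it; presets encode the qualitative
sensor-by-duration pattern (calcium: long bursts larger and sustained,
τ = 4 s vs 1 s; dopamine: transient at both durations).  A square
kernel is available for closed-form checks — with zero noise the
stimulation-phase mean recovers the amplitude exactly.

Pose tracks integrate positions from a three-state Markov speed model
inside a 31-cm circular arena with a reflected random-walk heading.
The default model keeps the two major states far from the 2-cm/s
threshold (ambulation 5 ± 1 cm/s, immobility 0.1 cm/s) with ~20-s
dwells, and makes fine-movement bouts brief (0.4–0.8 s, between
ambulation bouts).  This is a deliberate classifier-aligned choice:
the any-window ambulation rule absorbs sub-second low-speed bouts
flanked by ambulation and extends ambulation ~0.3 s into each
adjacent immobility bout, so occupancy recovery is only clean when
boundary frames are rare relative to dwell length.  At 30 min the
recovered occupancy matches the generating occupancy within 2
percentage points; short tracks or models hovering near the threshold
would not, and that is a property of the velocity-threshold
definitions, not of the implementation.

## What the synthetic cohorts do and do not show

Passing tests on simulated data demonstrate that the analysis code
implements its definitions exactly (oracle equivalence, closed-form
recovery, conservation and invariance properties) and that the
pipeline reproduces the *direction* of the study's contrasts under
known effects: stimulated cohorts outperform controls on both rates in
the changing-reward task, lesion parameters reduce lap counts and
speeds, long bursts yield larger sustained photometry responses.  They
do not validate the biological effect sizes: the agent is not a mouse,
the photometry kernels are stylized, and real F statistics from the
animal cohorts are not reproduction targets.  Problem sizes in the
test-suite (10⁴ property sessions, 100 cohort replicates, 30-min
photometry and pose simulations) were chosen to make Monte-Carlo
bounds tight at desk scale.
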