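---
title: "Detecting crisis-repair episodes in session-rating series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting crisis-repair episodes in session-rating series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisisrepair)
```

## The problem

Temporary deteriorations of the therapeutic relationship — ruptures, or
crises — followed by a return to the previous level are a recurring feature
of psychotherapy processes, and their number, magnitude and length are
candidate process markers. When the relationship is rated once per session
(for instance with a weighted affiliation index condensed from
interpersonal circumplex cluster scores), an episode becomes a pattern in a
short, noisy time series: a qualifying decline followed by a qualifying
recovery. This package implements three formal criteria for finding such
episodes, a taxonomy of their shapes, and a seeded generator of synthetic
courses with planted episodes for validating the machinery.

## The three criteria

**Quadratic-trend residual rule** (`detect_stiles()`). Each course is
fitted by ordinary least squares with a centred quadratic,
$v_s = \beta_0 + \beta_1 (s - m) + \beta_2 (s - m)^2 + \varepsilon_s$ with
$m = (n+1)/2$, giving the four per-course parameters midtreatment
intercept, slope, curve and RMSE. A session is a rupture when its value
falls at least `rmse_multiplier` (default 2) times the RMSE below the
fitted curve. The original formulation adds four specifications: first and
last sessions never count; a course with negative fitted slope is excluded
outright; a rupture must be lower than its previous session; and the value
must fall below an absolute floor. No published floor value exists, so the
floor is a required, explicit analysis input under the original preset;
the modified preset drops the course-level exclusion and the floor. The
rule marks rupture sessions only — it defines no repair point — so its
output is a session list plus an exclusion verdict, not paired episodes.

**Step rule** (`detect_strauss()`). A rupture is a single
session-to-session decrease of at least the reference SD, a repair a
subsequent single-step increase of at least the same SD. In the original
form the reference is the interindividual SD (the mean of the per-course
SDs) at multiplier 1, and a course whose last rupture is unrepaired at the
end of treatment is discarded entirely. The switchable modifications are:
a 2-SD threshold alongside the 1-SD one; the stricter of intra- and
interindividual SD; keeping (flagged) end-unrepaired courses; demanding
that the repair of a deep (≥ 2 SD) rupture match its magnitude
cumulatively; and counting a run of consecutive threshold-reaching
decreases as one rupture with the summed magnitude. Consecutive
*sub*-threshold decreases never aggregate into a rupture — gradual slides
are invisible to this rule by construction, which is precisely the gap the
third criterion fills.

**Cumulative-decline (crisis-repair) rule** (`detect_crisis_repair()`).
Session-to-session differences are summed until the direction changes,
partitioning the course into maximal decline and incline runs
(`segment_runs()`). A constant value is not a direction change: constant
steps belong to the rupture, not the repair, which matters for length
accounting. A rupture is flagged when a decline run's cumulative drop from
its local start — the last session before its first strictly-down step —
reaches at least 1 or 2 SDs, the SD being the stricter of the intra- and
interindividual value by default (stand-alone long courses use the
intraindividual SD only, so that courses of very different lengths are not
merged into one reference value). This captures gradual downward trends no
single-step rule can see and locates the beginning and end of each decline
exactly.

### The repair clause

The repair rule we implement is: the episode is repaired at the first
session $t$, after at least one upward step since the trough, with
$v_t \ge v_{\text{start}} - k\,\sigma$ (where $k$ is the detection
multiplier); reaching or exceeding the start value always repairs. Two
choices deserve comment. First, the recovery band scales with the
multiplier: a 2-SD rupture must recover to within 2 SD of its start value,
which is the reading consistent with the principle that deep ruptures need
commensurate repairs. Second, the requirement of an upward step prevents a
decline of exactly threshold depth from being "repaired" at its own
trough. All threshold comparisons in the package are inclusive (`>=`),
matching the "at least" phrasing used throughout the criteria.

If the repair condition has not yet been met when a further
threshold-reaching decline begins, the episode extends — the trough tracks
the global minimum (ties resolved to the latest session, consistent with
the constant-step convention) — and the classifier labels it complex.
An episode still open at the last session is reported with
`repaired = FALSE`; no course is excluded by this criterion. One
consequence worth knowing: because the 1-SD repair band is *narrower* than
the 2-SD band, a 1-SD run can merge neighbouring declines that a 2-SD run
separates. Threshold nesting therefore holds at the level of decline runs
(every 2-SD episode's opening decline lies inside a 1-SD episode's span),
not at the level of identical start sessions.

## Pattern taxonomy

Episodes are classified (`classify_episodes()`) by whether decline and
repair comprise one session or more: pattern 1 "jump in – jump out" (the
simple V), 2 "jump in – slide out", 3 "slide in – jump out", 4 "slide in –
slide out", and 5 "complex" (two or more threshold-reaching declines
separated by a direction change before the repair). Slides carry subtype
`b` when a single step inside the decline itself reaches the threshold
("slide including a jump"), else `a`. The jump size reuses the detection
threshold rather than introducing a second parameter; it can be overridden
(`jump_threshold`). Repairs are not subdivided. Unrepaired episodes are
labelled from their decline shape plus the `repaired = FALSE` flag rather
than a class of their own. Summaries (`summarize_episodes()`) report
counts, percentages (one decimal, halves away from zero), courses with at
least one episode, and decline/repair/episode length statistics; complex
episodes are excluded from the length statistics, and episodes whose
decline contains attached constant sessions are flagged
(`leading_constant`) because their length accounting follows the
constants-belong-to-the-rupture convention.

## Variability thresholds

`intra_sd()` is the SD of one course's session values; `inter_sd()` is the
mean of these over a course set. The SD is taken over raw session values,
not over differences, and uses the sample (n−1) denominator by default
with an `"n"` switch, since either convention could have been used in
earlier work and the choice is immaterial beyond very short courses.
Missing sessions are rejected by default; `read_courses(interpolate_gaps =
TRUE)` fills gaps linearly and flags the course, because the criteria are
only meaningful on continuously measured series — sparse schedules distort
detection, which `subsample_schedule()` exists to demonstrate.

## The synthetic generator

`generate_course()` carves planted episodes into a flat baseline and adds
independent Gaussian noise per session afterwards, so the ground truth
stays geometric rather than statistical (an AR(1) hook exists because
session ratings are plausibly autocorrelated; it defaults to off).
Defaults emulate the data situation the criteria target: courses of about
30 sessions (`simulate_study_courses()` draws ten courses of 29–35
sessions plus one 200-session course), a unitless index scale with
per-course SDs of order 40, episode depths of about 2 thresholds, and
measurement noise at a tenth of the threshold. `target_course_sd` re-derives
the noise SD so the empirical course SD converges to a stated anchor.

Pattern geometries (`pattern_steps()`) are scaled to a reference threshold
so that noise-free detection recovers the planted episode exactly: slide
steps sit at 0.7–0.8 of the threshold (below the jump size but large
enough that their direction survives noise at a tenth of the threshold),
jumps at ≥ 1.7 thresholds, and intermediate repair steps stay a comfortable
margin outside the repair band. What the generator does *not* emulate:
bounded questionnaire scales (unless `clamp` is set), item-level response
processes, therapist–patient dyad dynamics, or drifting baselines. Passing
recovery tests therefore show that the algorithms implement their
definitions, not that the definitions are robust on real clinical data.

A property of the method itself, visible in noisy simulations: any
negative measurement wobble in the session immediately before a planted
drop extends the decline run backwards, shifting the detected start one
session earlier and turning a one-session "jump in" into a two-session
"slide in including a jump". Episode *identification* (which declines are
episodes, where they bottom out and when they repair) is robust at the
margins above; episode *boundaries and labels* are sensitive to noise at
exactly this one-step scale. This mirrors the practical caveat that
continuous, low-noise measurement is a precondition for fine-grained
pattern claims.

## Numerical choices and edge cases

* Quadratic-fit quantities (coefficients, fitted values, residuals, RMSE)
  are cleaned at 1e-9 — far below any rating precision — so that an
  exactly-zero slope in regular data is treated as zero by the
  negative-trend exclusion rather than by the sign of floating-point dust.
* RMSE uses residual degrees of freedom n−3 by default (`"n"` switch); the
  midpoint is (n+1)/2, allowing half-integer midpoints for even n.
* The rupture comparison is `v <= fitted − k·RMSE` (inclusive), and all
  SD-threshold comparisons are `>=`.
* An all-constant course is a single degenerate decline run with
  cumulative change 0 and can never contain an episode; a constant course
  set yields a zero threshold, which `detect_crisis_repair()` rejects as
  meaningless rather than flagging every downward wiggle.
* Detection is fully deterministic: the same configuration on the same
  input yields byte-identical episode tables.
* Episode spans never overlap, but a repair session may serve as the
  pre-decline start session of the next episode.

## Problem sizes used in validation

The test suite checks each criterion against an independently coded
brute-force oracle on every course of length 3–8 over a 5-point value grid
(about 490,000 courses) and on 1,000 seeded random courses of up to 35
sessions; planted-episode recovery runs noise-free and across 100 seeded
noisy replicates of all seven pattern templates. These sizes keep the full
suite in the minutes range on one CPU while covering the combinatorics of
short courses exhaustively.

## Known limitations

The criteria operate on one rating stream per course; multiple raters or
multivariate series are out of scope, as is within-session (moment-by-
moment) rupture detection. No smoothing or detrending is applied before
detection — the cumulative-decline rule is deliberately defined on raw
differences. The affiliation-index weights are an explicit analysis input
with no shipped default, since published weighting schemes for the
questionnaire vary. Finally, episode counts on synthetic data depend on
the planted mix and noise level and are illustrations of the machinery,
not clinical estimates.
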