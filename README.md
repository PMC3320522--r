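# crisisrepair

Detection and classification of rupture-repair ("crisis-repair") episodes
in session-by-session ratings of the therapeutic relationship.

## The problem

In psychotherapy process research, temporary deteriorations of the
therapeutic relationship followed by recovery — rupture-repair episodes —
are linked to treatment change. When patients rate the relationship after
every session (e.g. with a weighted affiliation index derived from
interpersonal circumplex cluster scores), an episode is a pattern in a
short time series: a decline of sufficient magnitude followed by a
qualifying recovery. Different formal criteria disagree on what counts,
and earlier step-based rules cannot see declines that build up gradually
over several sessions. This package is for process researchers who want
to detect such episodes reproducibly, compare criteria on the same data,
and characterise each episode's magnitude, length, and shape.

## What is implemented

Three detection criteria behind one front end, `detect_episodes()`:

* **Quadratic-trend residual rule** (`stiles`, `stiles_modified`): fit
  `v_s = b0 + b1 (s − m) + b2 (s − m)² + e_s`, `m = (n+1)/2`, per course;
  a session is a rupture when `v_s ≤ fitted_s − k·RMSE` (default `k = 2`),
  subject to the original rule's four specifications (no first/last
  session, negative-slope courses excluded, value below the previous
  session, value below an absolute floor). The modified preset drops the
  exclusions.
* **Step rule** (`strauss`, `strauss_modified`): a rupture is a
  session-to-session decrease `≥ σ`, repaired by a later single-step
  increase `≥ σ`, where `σ` is the interindividual SD (the mean of
  per-course SDs); originally, a course ending on an unrepaired rupture is
  discarded. Modifications: 1 and 2 SD thresholds, the stricter of intra-
  and interindividual SD, no exclusion, magnitude-matched repairs for deep
  ruptures, aggregation of consecutive threshold-reaching decreases.
* **Cumulative-decline crisis-repair rule** (`crisis_repair`): sum
  session-to-session differences until the direction changes (constant
  values belong to the rupture); flag a rupture when a decline's
  cumulative drop reaches `k·σ` (`k` = 1 or 2), with
  `σ = max(SD_intra, SD_inter)` by default; repair at the first session,
  after an upward step, with `v_t ≥ v_start − k·σ`. This also captures
  gradual slides and locates each decline's start, trough, and repair
  exactly.

Episodes are classified into the five-pattern taxonomy (V-shape
"jump in – jump out", "jump in – slide out", "slide in – jump out",
"slide in – slide out" — slides subtyped by whether they contain a jump —
and "complex"), summarised into frequency and length tables, and plotted.
A seeded generator plants episodes of known geometry in synthetic courses
for validation, and a small CLI (`inst/cli/crisisrepair.R`) wires
simulate/index/detect/compare together.

## Worked example

A six-session course with a gradual slide (5 points per session) that no
single-step rule can see, analysed stand-alone:

```r
library(crisisrepair)
crs  <- course(c(60, 55, 50, 45, 40, 60), course_id = "A")
prof <- variability_profile(crs)   # stand-alone: intraindividual SD
det  <- detect_crisis_repair(crs, prof, multiplier = 1)
det
#> course A: 1 crisis-repair episode(s) at 1 SD (threshold 8.165)
det$episodes[, 2:8]
#>   start_session trough_session repair_session rupture_magnitude decline_length
#> 1             1              5              6                20              4
#>   repair_length repaired
#> 1             1     TRUE
```

The rating slides from 60 to 40 over four sessions (cumulative drop 20,
well past the 1-SD threshold of 8.2), bottoms out at session 5, and
recovers to the start value in one step — a "slide in – jump out" episode.

On a study-like simulated batch (ten courses of 29–35 sessions with
planted episodes):

```r
sim <- simulate_study_courses(seed = 42)
fit <- detect_episodes(sim$courses, "crisis_repair", multiplier = 1)
fit
#> Rupture-repair detection (criterion: crisis_repair, multiplier 1)
#>   10 course(s): 31 episode(s)/rupture(s), 0 course(s) excluded
#>   patterns: 1:3 2:3 3a:3 3b:7 4a:4 4b:5 5:6
summary(fit)
#> ...
#> mean decline length 2.64, mean repair length 1.48, mean episode length 4.12 sessions
```

`fit$log` records, per course, the intra- and interindividual SD, which
one was the stricter, and the threshold actually used — the comparisons
between criteria hinge on this, so it is kept auditable. `plot(fit)`
draws the trajectories with episodes shaded.

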