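---
title: "Simulating and optimising sensor-triggered EMA protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and optimising sensor-triggered EMA protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emasim)
```

## The measurement setting

A combined physical/eating-behaviour EMA protocol prompts participants three
ways over a 7-day free-living week: seven **time-based** surveys per day at
random minutes inside fixed frames (06:00–09:45, 10:15–11:45, 12:15–13:45,
14:15–15:45, 16:15–17:45, 18:15–19:45, 20:15–22:00 — consecutive frames are
30 minutes apart, so no two prompts can ever be closer than 30 minutes); up
to ten **event-based** surveys triggered by sedentary, walking, or running
bouts detected in the wearable's minute-epoch step and heart-rate record; and
**self-initiated or prompted reports** of meals, snacks, and drinks.

`emasim` reproduces this machinery end to end so that trigger rules can be
tuned by simulation instead of fielding: a data model for minute-epoch
streams, a bout detector, a trigger engine with the device-sync delay, a
sweep harness, compliance analytics, and a synthetic cohort generator that
stands in for participant data.

## Event rules and bout detection

An event rule has five ingredients: a **kind** (sedentary, walking, running),
a **duration** `d` in minutes, inclusive **step bounds** per minute
(sedentary: exactly 0; walking: 60–139; running: ≥ 140), an **outlier
allowance** `k` with a **direction** (only minutes violating above the upper,
or only below the lower, threshold are tolerated), and a **wear control**
flag requiring at least one heart-rate sample every minute (used by sedentary
rules, where zero steps are otherwise indistinguishable from a device on a
table).

A window of `d` consecutive clock minutes qualifies when at most `k` minutes
violate the bounds, all violations are in the permitted direction, and the
first and last minutes are non-violating. Three choices here were genuinely
open and are fixed as follows:

* **Edge anchoring.** Without the first/last-minute condition, a walking bout
  could end on two stationary minutes, and a survey "about walking" would
  refer to something that stopped earlier. Anchoring both edges keeps the
  triggering event adjacent to the survey. A consequence worth knowing:
  shortening the duration is *not* universally monotone for rules with
  outliers (the shorter window can begin on a tolerated outlier and lose its
  anchor), so the monotonicity property is only guaranteed — and only
  tested — for zero-outlier rules.
* **Outliers count toward the duration.** A 5-minute walking window may
  contain 2 tolerated below-threshold minutes and only 3 walking minutes;
  the phrase "allowing for 2 outlier minutes" within an event is read this
  way, and the tension it creates (is 3 of 5 minutes still walking?) is a
  property of the protocol, not of the implementation.
* **Missing minutes.** A minute with no row behaves as zero steps and zero
  heart-rate samples. It can therefore never join a window under a rule that
  requires wear, but it can serve as a below-threshold outlier for walking
  rules — matching how a real engine sees a transmission gap.

`find_bouts()` emits one bout per qualifying **end-minute** rather than
maximal runs: the trigger engine only ever asks "does a qualifying window end
at (or just before) this sync?", and per-end-minute emission makes that query
trivial and makes the exhaustive oracle (`brute_force_bouts()`, which checks
every window directly) a line-for-line restatement of the definition. The two
are compared on thousands of randomised streams in the test suite.

## The trigger engine

Consumer wearables upload minute data roughly every 15 minutes, so triggering
is evaluated at sync times only. At each sync `t` the engine searches
backwards over a **span** (1, 2, or 17 minutes in the shipped presets) for
the most recent unconsumed bout whose end-minute lies in `[t − span, t)`, and
fires at most one survey per kind per sync. A span of 1 means the event must
continue until the very last minute before the sync; a span of 17 guarantees
— under a regular 15-minute sync — that no bout is ever missed, at the price
of surveys arriving up to 17 minutes after the event (both facts are
property-tested). Constraints are applied greedily in chronological order:

* a 90-minute per-kind refractory interval, enforced across the whole
  timeline (the natural reading of "minimum interval between two surveys";
  resetting it at midnight would allow a 23:50/00:05 pair);
* sedentary firing windows 08:00–14:00 and 14:00–20:00 (half-open, caps 2
  and 2) that constrain the *fire time*, not the bout location — a bout may
  begin before 08:00;
* per-kind daily caps (sedentary 4 via its windows, walking 3, running 3)
  and a joint daily cap of 10, all reset at midnight;
* ties between kinds at one sync resolved sedentary → walking → running,
  which mirrors a server iterating rules in a fixed order.

These choices make the engine deterministic given bouts and sync times, which
is what a parameter sweep needs. On a fully sedentary day the arithmetic is
forced: first eligible sync 08:00, then 09:30 (window 1 exhausted), 14:00,
15:30 — exactly 4 surveys, 90 minutes apart. The analogous walking result is
3. These, the 600-minute valid-day boundary, and the 3/6/7-minute reminders
with 8-minute expiry are the deterministic results the acceptance script
recomputes.

## The synthetic cohort

The generator's job is to exercise every downstream stage with data whose
summary statistics match the population the protocol was tuned on: free-living
adults wearing the device essentially around the clock, with mean daily wear
1,357 (SD 124) minutes and mean daily steps 11,189 (SD 2,881).

A day is assembled structurally: a worn, zero-step sleep window (23:00–07:00
by default); a per-day step target drawn from the profile's normal
distribution; a possible running session (probability 0.25, ~18 min at
140–165 steps/min); light-activity minutes (1–59 steps/min, ~170 min/day in
short chunks); walking bouts (gamma-distributed durations, mean 9 min, rate
~95 steps/min clipped to the 60–139 band) sized to absorb the remaining step
budget; and sedentary filler split across the gaps between the shuffled
active segments, which yields many sedentary runs in the 15–45-minute range —
the region the sedentary rule grid discriminates on. Non-wear is a Poisson
process (1.5 gaps/day, gamma-length with mean 55.3 min, so expected non-wear
is 83 = 1440 − 1357 minutes), carved out of sedentary stretches with
spill-over so the total is preserved. Cohorts add between-participant
heterogeneity by jittering the step target (60% of the SD between, 80%
within) and the non-wear propensity.

The behavioural layer mirrors the fitted compliance trends generatively:
responses follow a **linear probability model** `p = base + slope·(day − 1)`
clamped to [0, 1] (the published trends are in percentage points per day; a
logistic link would be equally defensible but is not what a linear trend
reports, so the linear form with clamping is the declared choice), with
defaults base 0.55 and slope −0.0166/day so the week's average sits near the
observed overall median response rate of 0.49. Latency is log-normal
(median 120 s) truncated at the 8-minute expiry via the inverse CDF;
completion time is normal (day-1 mean 72 s, slope −1.62 s/day, SD 20 s)
clamped at 10 s. Meal/snack/drink reports are per-category Poisson counts
(category rates defaulting to the two reporting arms' observed daily
medians) whose expected total declines by 0.17 reports/day, spread across
categories proportionally to their rates. Poisson is a declared modelling
choice — only medians and IQRs of the real counts are known.

What the generator does **not** emulate: circadian structure beyond the sleep
window, weekday/weekend contrast, autocorrelated compliance (a participant
who ignores one prompt is no likelier to ignore the next), heart-rate
*values* (only sample presence matters to the pipeline), and the long right
tail of real inter-individual variability. Passing recovery tests therefore
show that the estimators are unbiased and adequately powered under the stated
generating process, not that real cohorts are this well behaved.

## Statistical analyses

Compliance outcomes are summarised as **median (IQR) of participants'
averages** — participants, not prompts, are the unit — with latency and
completion averaged over answered prompts only (the unanswered carry no
times; this is the one reading that needs no imputation, and it is flagged as
a choice). Daily trends use `lmerTest::lmer(y ~ day + (1 | participant))`
with REML, on per-participant-day aggregates (response rate as a percentage,
so the slope is in percentage points/day). Modelling the aggregate rather
than per-prompt binary outcomes is the simplest model whose slope is directly
in the reported units. The meal-mode contrast uses `lm(avg ~ mode + age +
sex)` per category group, under either denominator: all 7 days, or only days
with at least one report *of any type* (so a drinks-only day still counts as
a reporting day for the meals row).

Numerical conventions, fixed and documented: quartiles use linear
interpolation between order statistics (`stats::quantile` type 7; the
convention behind any published median is unknowable, so one is pinned);
times are minute-resolution local civil time with no DST arithmetic (streams
are assumed DST-free); days are half-open at midnight; REML rather than ML;
trend fits on noiseless linear data recover slopes to numerical precision
(tested at 1e-8).

## Preset interpretation notes

Two details of the deployed protocols are ambiguous and resolved explicitly
in the shipped presets: the original running rule's outlier tolerance is set
to 0 (`cz_de_original`), and the relaxed arm's walking/running rules use 2
below-threshold outliers only (single-direction tolerance,
`ie_fr_relaxed`). The `optimal` preset carries the optimised sedentary
(20 min, no outliers, span 1) and walking (5 min, 2 below, span 17) rules;
no optimisation was possible for running, so it retains the relaxed running
rule.

Absolute sweep medians depend on the cohort — the published ones were
computed on private device data and are not reproduction targets. What the
sweep must (and does) reproduce on synthetic cohorts is structure: the
Original ≤ single-relaxation ≤ Optimal orderings, agreement of "Optimal"
with "Duration 20" on the sedentary grid, and cap-boundedness (≤ 4 sedentary,
≤ 3 walking per day).

## Problem sizes

The test suite and examples run at the study's own scale where that is cheap
(46 participants × 7 days for sweeps and trend recovery; 100 seeded
replicates for slope-recovery and power checks; 1,000 random streams per rule
for oracle equivalence) and smaller where a property is scale-free. All
randomness is seeded; generators are bit-reproducible given a seed.

## Known limitations

* The engine assumes the *regular* sync pattern when asked to; real syncing
  is irregular, so simulated trigger counts are upper bounds for a flaky
  connection (a jittered sync mode is available but no attempt is made to
  model outages).
* Bout emission at exact rule duration means downstream consumers cannot
  recover maximal-run lengths from the bout list; that is by design, but it
  makes the bout list unsuitable for, say, sedentary-time totals.
* The meal-mode comparison inherits the design's confounding: mode is a
  between-site assignment, and adjusting for age and sex cannot fix that.
  The function tests the adjusted contrast it is given, nothing more.
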