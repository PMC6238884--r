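---
title: "How glucoreason reasons: model, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How glucoreason reasons: model, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucoreason)
```

## The reasoning model

`glucoreason` is a hypothesize-and-test expert system over a declarative
knowledge base. A *hypothesis* is a claim about the diary ("the patient has
hyperglycemia", "the last insulin dose was insufficient", "data are not
distributed equally between days") that the engine resolves to one of three
states: **TRUE** (validated), **FALSE** (refuted) or **NA** (not
applicable — the context required to judge it is missing). NA is a
first-class outcome, not an error: a diary without carbohydrate
registrations cannot support or refute any carbohydrate-related claim, and
pretending otherwise would fabricate evidence.

A consultation run proceeds in four phases, iterated to a fixpoint:

1. **Plan generation.** The root plan lists the data-reliability tasks and
   the four event detectors in a fixed order.
2. **Activation.** Before a hypothesis is evaluated, its activation
   predicate checks that the required context is present (data types,
   profile fields, laboratory values). If not, the hypothesis is stored NA
   with a justification naming the missing context.
3. **Evaluation.** Leaf hypotheses dispatch to concrete rules with
   thresholds injected from `threshold_config()`. Combining hypotheses
   derive their state from their children's stored results.
4. **Plan update.** A stored result can trigger plan extensions: a TRUE
   event detector appends the event's cause sub-tree, once per event, to
   the pending queue. Triggers are idempotent, the trigger graph of the
   default knowledge base is acyclic, and the engine asserts a hard
   iteration cap it can never reach on acyclic knowledge bases.

Two combination semantics appear in the cause trees. The insulin and
carbohydrate branches are **default-TRUE**: the branch stands accused until
*every* child is FALSE or NA, which mirrors clinical caution — one
validated mechanism suffices to keep the explanation alive. The hypoglycemia
activity branch is **any-true**: it is TRUE when some child is TRUE, FALSE
when all children are FALSE, NA otherwise. Finally, *lack of evidence* is
TRUE exactly when every sibling branch is FALSE or NA; a TRUE result marks
an **information gap**, inviting the user to inspect the data around the
event rather than trust a fabricated cause.

Evaluation faults degrade to NA ("evaluation failure") instead of aborting:
a consultation must always produce a report.

## Event definitions

A blood glucose reading is classified *before-meal* when a meal-classed
intake follows within 30 minutes, otherwise *fasting* when no carbohydrate
intake occurred in the preceding 8 hours, otherwise *other*. The fasting
inference is deliberate design: diaries do not record fasting state, and
8 carb-free hours is a conservative proxy; both the window and the
precedence (before-meal over fasting, relevant when a first meal of the day
is imminent) are configurable. Hyperglycemia uses the fasting threshold for
before-meal readings as well (9 mmol/L) — the clinically intended pairing —
while hypoglycemia's 4 mmol/L bound applies to fasting readings only.

Consecutive out-of-range readings of the same kind, with no in-range
reading between them, form one continuous event, split when the span
exceeds 6 hours. The 6 h cap is stated for hyperglycemia; we apply it to
hypoglycemic runs too, by symmetry (configurable). The event's *reference
time* is its most extreme reading — where causes are easiest to localize —
with ties broken by the earliest reading.

Blood pressure events are per-reading (systolic > 140 **or** diastolic >
90, strict). Sleep is proxied per night by the gap between consecutive
*manual* registrations containing the 03:00 anchor; sensor-automatic rows
are excluded because they say nothing about the patient being awake. The
night window (20:00–12:00, anchor 03:00) is a design choice exposed in the
configuration.

## Reliability grading

Trust starts at 50 and each validated sub-hypothesis deducts its grade,
clamped at 0. Only the HbA1c-mismatch deduction (10) is externally fixed;
the remaining grades are package defaults chosen so that the worst case
reaches the bottom of the scale without any single family dominating:
missing data types 5 each, implausible values 10 each, registration counts
5, day/weekday distribution 5 each, ISF and I:C source inconsistencies 10
each. All grades are configuration data, not code.

The distribution rules use the sample standard deviation of per-day (or
per-weekday) registration counts, compared against 20% of the mean count.
A documented alternative statistic (maximum absolute deviation) can be
selected in the configuration. Days with zero registrations enter the
dispersion like any other day; absence of a whole data type is the
missing-type family's job and is skipped here.

Source-inconsistency checks compare a module-calculated value against an
external reference — laboratory HbA1c, or patient-reported ISF and I:C —
as `|calculated − reference| / reference`, tolerating 5%. The calculated
ISF and I:C come from the 1500/1800 and 500/450 rules applied to the mean
total daily dose over days with any insulin; bolus registrations mark the
regimen as rapid-acting.

## Calculators and their assumptions

* **Estimated HbA1c** inverts the linear estimated-average-glucose
  relation, `A1C% = (mean_BG × 18.016 + 46.7)/28.7`, over all readings in
  the period. It inherits that relation's population-level character; the
  5% source tolerance absorbs both its spread and meter inaccuracy.
* **Insulin on board** defaults to linear decay over the insulin action
  duration (DIA, default 4 h): the contract every rule relies on is only
  *1 at injection, 0 at DIA, non-increasing between*. A bilinear curve with
  a 75-minute activity peak is available behind the same contract; no rule
  outcome in the shipped knowledge base depends on the curve's shape
  between the endpoints.
* **Carbohydrates on board** subtracts the patient-reported constant
  absorption rate; without a reported rate the quantity is NA by design.
* **Period averages** of IOB/COB are sampled on a 5-minute grid over the
  whole diary period; the grid is tolerance-tested, not bit-pinned, and a
  1-minute grid changes the average by well under 1%. Taking the average
  over the whole period (rather than, say, the event's day) is an open
  modelling choice we fixed and flag here for future calibration.
* Dose-adequacy checks use the event's reference glucose: required dose =
  `(BG_ref − 5.5)/ISF`, with the fallback chain reported ISF → 1500/1800
  rule, and for I:C reported → same-day totals → 500/450 rule.
* The hypoglycemia child "active insulin greater than required per the
  I:C" is operationalized as IOB at the reference time exceeding
  carbs-in-window divided by I:C — the one place where a one-line clinical
  statement needed an explicit formula; it is documented as an
  interpretation.

## Numerical choices

Lookback windows are half-open — end-inclusive, start-exclusive — so a
registration exactly N hours before an event is excluded; one convention
everywhere. All event thresholds are strict inequalities (a reading of
exactly 13.9 mmol/L is not an event; a deviation of exactly 5% is not an
inconsistency). Because tolerance comparisons sit on meaningful boundaries,
they are guarded by a relative epsilon of 1e-9: a computed deviation equal
to the allowance up to floating-point round-off is treated as equal, far
below any clinically meaningful difference. Duplicate registrations
(identical timestamp, type and source — typical device re-syncs) collapse
to one with a warning rather than erroring. Timestamps are minute-resolution
local clock time with no timezone arithmetic: a diary is a single patient's
local log.

## The synthetic diary generator

`scenario_spec()` describes a diary: days, evenly spaced glucose checks,
three dosed meals, basal insulin, daily activity, a glucose process of
baseline + meal excursions + Gaussian noise, and a list of injectable
anomalies. The default scenario *is* the compliant study condition: 14
days, 5 checks/day, all four data types present daily, no anomalies —
constructed to satisfy every reliability predicate and produce no events,
which the test suite verifies by running the module (trust 50, zero events,
zero findings). Reported ISF/I:C and the laboratory HbA1c are derived from
the planned regimen and the honest glucose series, so the compliant diary
is source-consistent by construction; anomalies then perturb exactly one
of those couplings.

The glucose process is deliberately non-physiological: clamped between 4.5
and 9.0 mmol/L with linear 4-hour meal excursions, it is a threshold driver,
not a metabolic simulator. Consequently, passing tests demonstrate that the
rules fire exactly at their configured boundaries and that anomalies are
recovered — they do not demonstrate calibration against real patient
physiology (insulin kinetics, dawn phenomenon, sensor noise structure), and
no claim of that kind is made. The missed-bolus anomaly couples into the
glucose process (an uncovered meal leaves a large, flat excursion) because
a rule layer can only observe a missed bolus through the hyperglycemia it
causes.

Each anomaly kind is paired with the hypothesis it should flip, recorded in
the generator's ground-truth log: a missed bolus with "no insulin at a
meal", a missing day with the day-distribution rule, a mg/dL unit slip and
an extreme value with the error-value rules, injected readings with the
event detectors, a reported-ISF offset with the ISF source check. The
fabricated-smoothing anomaly (noise and excursions flattened to baseline)
is paired with the HbA1c source check: a fabricated series betrays itself
by disagreeing with the laboratory value derived from the honest series.

## Properties the suite verifies, and their scope

* **Oracle equivalence.** On 1 000 seeded small diaries, the plan-driven
  engine produces the same multiset of (hypothesis, scope, state) as an
  independent walker that calls the reliability checks, detectors and
  cause evaluators directly, with no plans or triggers.
* **Flip-point sweeps.** Sweeping each driving value across its boundary
  flips detection exactly once, at the configured constant, on the strict
  side stated above.
* **NA monotonicity, scoped.** Deleting insulin or activity data moves
  evidence-leaf hypotheses (cause leaves, source-inconsistency checks) to
  NA or leaves them unchanged — never across TRUE/FALSE. The property
  cannot hold for presence-testing hypotheses (missing-type, error-values,
  registration counts, external factors) whose very subject is the data's
  presence, nor for derived combiners whose state is a function of their
  children, nor under carbohydrate deletion, which reclassifies readings
  as fasting and legitimately changes the event set. The test is scoped
  accordingly.
* **Anomaly recovery.** Each anomaly kind validates its paired hypothesis
  on the injected diary and not on the anomaly-free twin with the same
  seed.

Problem sizes in the suite (diaries of 1–14 days, sweeps of 10–101 points,
1 000 oracle contexts) were chosen as the smallest sizes at which every
boundary and both event kinds are exercised; all results are deterministic
given the seeds.

## Known limitations

The knowledge base encodes the enumerated hypothesis tree (11 nodes under
hyperglycemia); insulin-pump temporary basal rates, CGM-specific analytics
(rate-of-change alarms, time-in-range), ketones, heart rate and
patient-defined target ranges are out of scope. The engine never retracts a
completed result; dynamic plans only extend. Hypothesis instances are
scoped per dataset (reliability) or per event (causes) — the generalization
from the one explicitly per-night rule (sleep) to all event kinds is a
design choice. Localization is a knowledge-base edit: templates are data,
not code.
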