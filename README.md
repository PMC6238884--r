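# glucoreason

Knowledge-based reasoning over self-collected type 1 diabetes diaries, for
clinical-decision-support researchers and digital-health engineers who need
an inspectable, rule-driven alternative to black-box analytics when
preparing patient–clinician consultations.

People with type 1 diabetes self-collect blood glucose, insulin doses,
carbohydrate intakes, physical activity, blood pressure and contextual
factors across apps and devices. Before a clinician can act on such a diary
two questions must be answered: *can the data be trusted*, and *what in it
deserves attention*? `glucoreason` answers both with a declarative knowledge
base and a hypothesize-and-test reasoning engine:

1. **Data reliability.** Thirteen sub-hypotheses (missing data types,
   implausible values, too few registrations, uneven distribution over days
   and weekdays, inconsistencies between sources) grade the diary on a
   **0–50 trust scale**: the scale maximum minus the grade of every
   validated sub-hypothesis. For example, when the HbA1c estimated from the
   diary deviates more than 5% from the laboratory value, trust drops by 10
   points.
2. **Noticeable events.** Hyperglycemia (> 9 mmol/L fasting or before a
   meal, > 13.9 mmol/L otherwise), hypoglycemia (< 4 / < 3.5 mmol/L),
   high blood pressure (> 140/90 mmHg) and short sleep (< 7 h between
   overnight manual registrations). Consecutive out-of-range readings merge
   into one continuous event (6 h maximum) whose most extreme reading sets
   the reference time.
3. **Causes or gaps.** Each event triggers a tree of cause hypotheses —
   e.g. for hyperglycemia: *not enough insulin* (active insulin below the
   period average; last dose below `(BG − 5.5)/ISF`; meal not covered per
   the I:C ratio; no bolus within 30 min of a meal), *too many
   carbohydrates* (carbs-on-board above average; intake above 75 g for a
   meal / 30 g for a snack), external factors, and missing physical
   activity. A default-TRUE branch is invalidated only when **all** its
   children are FALSE or not-applicable (NA). If every branch fails, the
   *lack of evidence* hypothesis flags an **information gap**.
4. **Interpretation.** Hedged findings ("this event *may* have been due
   to…"), per-event cause lists, hour/weekday event summaries and
   reliability alerts, rendered as JSON, markdown or HTML (the numeric
   trust grade is machine-readable only and never displayed in rendered
   reports).

Supporting calculators: estimated HbA1c via the linear estimated-average-
glucose relation `eAG(mg/dL) = 28.7·A1C − 46.7`; insulin sensitivity via
the 1500/1800 rule; insulin-to-carbohydrate ratio via the 500/450 rule;
insulin-on-board with a configurable decay curve; carbohydrates-on-board
from the patient-reported absorption rate.

## Worked example

```r
library(glucoreason)

diary   <- read_diary(system.file("extdata", "diary_example.csv",  package = "glucoreason"))
profile <- read_profile(system.file("extdata", "profile_example.yaml", package = "glucoreason"))
ctx <- build_context(diary, profile)
rr  <- run_consultation(ctx)
rr
#> <consultation run> trust 30/50, 1 event(s), 5 finding(s), 0 information gap(s)
for (f in rr$findings) print(f)
#> [warning] (dataset) calculated insulin sensitivity 2.81 mmol/L per U vs reported 2.5 (deviation 12.58%, tolerance 5%)
#>     - Your reported insulin sensitivity factor disagrees with the one derived from your total daily doses; consider reviewing it.
#> [warning] (dataset) calculated insulin-to-carbohydrate ratio 14.08 g per U vs reported 10 (deviation 40.85%, tolerance 5%)
#>     - Your reported insulin-to-carbohydrate ratio disagrees with the one derived from your diary; consider reviewing it.
#> [info] (hyperglycemia_1) This hyperglycemic event may have been due to not enough insulin.
#>     - The mealtime insulin (6 U) may not have covered 85 g of carbohydrates (about 8.5 U needed).
#> [info] (hyperglycemia_1) This hyperglycemic event may have been due to too many carbohydrates.
#>     - Carbohydrates on board (25 g) were above the period average (13.74 g).
#>     - The last intake (85 g) exceeded the recommended maximum of 75 g.
#> [info] (hyperglycemia_1) This hyperglycemic event may have been due to a lack of physical activity in the preceding 24 hours.
#>     - no physical activity registered in the 24 hours before the event
```

Reading the numbers: the one-day diary contains a 15.0 mmol/L reading two
hours after an 85 g lunch, which segments into one hyperglycemic event. The
engine validates three cause branches for it (the 6 U lunch bolus covers
only 60 g at the reported I:C of 10 g/U; carbs-on-board at the event exceed the
period average; the intake itself is above the 75 g meal recommendation) —
and, on the reliability side, both patient-reported dosing parameters
disagree with the diary-derived ones by more than the tolerated 5%, so the
trust level is 50 − 10 − 10 = 30. `render_report(rr, "markdown")` produces
the consultation document; the JSON report carries the numeric trust level.

A synthetic diary with injected anomalies is one call away:

```r
d <- generate_diary(scenario_spec(days = 14, seed = 1,
        anomalies = list(anomaly_hypo_injection(3, "15:00", 3.0))))
run_consultation(build_context(d$registrations, d$profile, d$lab))
#> <consultation run> trust 50/50, 1 event(s), 4 finding(s), 0 information gap(s)
```

A thin command-line front end (`inst/cli/glucoreason`) exposes `analyze`,
`generate` and `validate-kb`; the knowledge base itself round-trips through
an editable YAML document (`save_kb()` / `load_kb()`), and every numeric
constant lives in `threshold_config()` (mirrored by
`inst/extdata/config_default.yaml`).

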