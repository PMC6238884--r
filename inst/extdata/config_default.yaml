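# Default threshold configuration, field-for-field mirror of
# threshold_config(). Edit a value and pass the file to `analyze --config`
# to run the knowledge base under alternative guideline values.

# glycemic event thresholds (mmol/L); all comparisons are strict
hyper_fasting: 9.0        # hyperglycemia when fasting or before a meal
hyper_other: 13.9         # hyperglycemia at other times of the day
hypo_fasting: 4.0         # hypoglycemia when fasting
hypo_other: 3.5           # hypoglycemia at other times of the day
event_max_duration_hours: 6
bg_target: 5.5            # mid-range glucose target for dose checks

# lookback windows
meal_lookback_hours: 4          # meals considered causal for an event
insulin_meal_window_minutes: 30 # bolus-to-meal pairing window
fasting_lookback_hours: 8       # carb-free time implying a fasting reading
activity_lookback_moderate_hours: 4
activity_lookback_extreme_hours: 24

# light-to-moderate physical activity bounds (strictly below)
activity_light_minutes: 60
activity_light_steps: 3000
activity_light_mets: 6

# carbohydrate intake recommendations (g)
meal_carbs_high: 75
snack_carbs_high: 30
meal_carbs_low: 30
snack_carbs_low: 15

# blood pressure (mmHg), event when strictly above either bound
bp_systolic: 140
bp_diastolic: 90

sleep_min_hours: 7

# reliability rules
min_per_day:
  blood_glucose: 5
  carbohydrates: 1
  insulin: 1
  physical_activity: 0
distribution_tolerance: 0.20   # tolerated dispersion, fraction of mean count
dispersion_stat: sd            # or max_abs_dev
source_tolerance: 0.05         # tolerated deviation between data sources
hba1c_tolerance: 0.05
trust_max: 50

# trust-grade deduction per validated reliability sub-hypothesis
grades:
  no_blood_glucose_registered: 5
  no_carbohydrates_registered: 5
  no_insulin_registered: 5
  no_physical_activity_registered: 5
  error_values_blood_glucose: 10
  error_values_carbohydrates: 10
  error_values_insulin: 10
  not_enough_registrations: 5
  unequal_days_distribution: 5
  unequal_weekdays_distribution: 5
  source_inconsistency_hba1c: 10
  source_inconsistency_isf: 10
  source_inconsistency_icr: 10

# plausibility ranges; values outside are flagged as probable errors
bg_plausible_range: [1.1, 33.3]    # mmol/L
carbs_plausible_range: [0, 300]    # g
insulin_plausible_range: [0, 100]  # U
mgdl_per_mmol: 18.016

# insulin-on-board model
dia_default_hours: 4
iob_curve: linear       # or bilinear (activity peak at iob_peak_minutes)
iob_peak_minutes: 75
iob_grid_minutes: 5     # sampling grid for period averages

# sleep night window and anchor
night_start: "20:00"
night_end: "12:00"
night_anchor: "03:00"
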