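#' Threshold configuration for the knowledge base
#'
#' Collects every numeric constant used by the rules in one place, so a single
#' knowledge base can run under alternative guideline values. Defaults are the
#' co-designed clinical values: "high" hyperglycemia at 9 mmol/L fasting /
#' before meals and 13.9 mmol/L otherwise, "low" hypoglycemia at 4 / 3.5
#' mmol/L, blood pressure 140/90 mmHg, a 7-hour minimum sleep period, at least
#' 5 blood glucose checks per day, 20% tolerated dispersion in daily
#' registration counts and 5% tolerated deviation between data sources.
#'
#' Durations carry their unit in the field name (`_hours`, `_minutes`).
#' Glucose is always mmol/L internally (mg/dL inputs are divided by 18.016).
#'
#' @param ... named overrides of individual defaults, e.g.
#'   `threshold_config(hyper_other = 12)`.
#' @return A validated list of class `gr_config`.
#' @examples
#' cfg <- threshold_config()
#' cfg$hyper_other
#' threshold_config(sleep_min_hours = 8)$sleep_min_hours
#' @export
threshold_config <- function(...) {
  cfg <- list(
    # glycemic event thresholds (mmol/L); strict inequalities
    hyper_fasting = 9.0,
    hyper_other = 13.9,
    hypo_fasting = 4.0,
    hypo_other = 3.5,
    event_max_duration_hours = 6,
    bg_target = 5.5,
    # lookback windows
    meal_lookback_hours = 4,
    insulin_meal_window_minutes = 30,
    fasting_lookback_hours = 8,
    activity_lookback_moderate_hours = 4,
    activity_lookback_extreme_hours = 24,
    # light-to-moderate physical activity bounds (strict "less than")
    activity_light_minutes = 60,
    activity_light_steps = 3000,
    activity_light_mets = 6,
    # carbohydrate intake recommendations (g)
    meal_carbs_high = 75,
    snack_carbs_high = 30,
    meal_carbs_low = 30,
    snack_carbs_low = 15,
    # blood pressure (mmHg), strict "greater than 140/90"
    bp_systolic = 140,
    bp_diastolic = 90,
    sleep_min_hours = 7,
    # reliability rules
    min_per_day = list(blood_glucose = 5, carbohydrates = 1,
                       insulin = 1, physical_activity = 0),
    distribution_tolerance = 0.20,
    dispersion_stat = "sd",
    source_tolerance = 0.05,
    hba1c_tolerance = 0.05,
    trust_max = 50,
    grades = list(
      no_blood_glucose_registered = 5,
      no_carbohydrates_registered = 5,
      no_insulin_registered = 5,
      no_physical_activity_registered = 5,
      error_values_blood_glucose = 10,
      error_values_carbohydrates = 10,
      error_values_insulin = 10,
      not_enough_registrations = 5,
      unequal_days_distribution = 5,
      unequal_weekdays_distribution = 5,
      source_inconsistency_hba1c = 10,
      source_inconsistency_isf = 10,
      source_inconsistency_icr = 10
    ),
    # plausibility ranges; values outside are flagged as probable errors
    bg_plausible_range = c(1.1, 33.3),
    carbs_plausible_range = c(0, 300),
    insulin_plausible_range = c(0, 100),
    mgdl_per_mmol = 18.016,
    # insulin-on-board model
    dia_default_hours = 4,
    iob_curve = "linear",
    iob_peak_minutes = 75,
    iob_grid_minutes = 5,
    # sleep night window: gap must intersect it and contain the anchor
    night_start = "20:00",
    night_end = "12:00",
    night_anchor = "03:00"
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown)) {
      stop("unknown threshold_config field(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(overrides)] <- overrides
  }
  class(cfg) <- "gr_config"
  validate_config(cfg)
  cfg
}

#' Validate a threshold configuration
#'
#' Checks the structural invariants: tolerances in \[0, 1\], strictly positive
#' thresholds and durations, grades within the trust scale.
#'
#' @param cfg a `gr_config` list.
#' @return `cfg`, invisibly; stops with a message on violation.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "gr_config"))
  tol <- c(cfg$distribution_tolerance, cfg$source_tolerance, cfg$hba1c_tolerance)
  if (any(!is.finite(tol)) || any(tol < 0) || any(tol > 1)) {
    stop("tolerances must lie in [0, 1]")
  }
  pos <- c(cfg$hyper_fasting, cfg$hyper_other, cfg$hypo_fasting, cfg$hypo_other,
           cfg$event_max_duration_hours, cfg$bg_target, cfg$meal_lookback_hours,
           cfg$insulin_meal_window_minutes, cfg$fasting_lookback_hours,
           cfg$activity_lookback_moderate_hours, cfg$activity_lookback_extreme_hours,
           cfg$activity_light_minutes, cfg$activity_light_steps, cfg$activity_light_mets,
           cfg$meal_carbs_high, cfg$snack_carbs_high, cfg$meal_carbs_low,
           cfg$snack_carbs_low, cfg$bp_systolic, cfg$bp_diastolic,
           cfg$sleep_min_hours, cfg$trust_max, cfg$mgdl_per_mmol,
           cfg$dia_default_hours, cfg$iob_grid_minutes)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("all thresholds and durations must be finite and positive")
  }
  g <- unlist(cfg$grades)
  if (any(g < 0) || any(g > cfg$trust_max)) {
    stop("grade values must lie in [0, trust_max]")
  }
  if (!cfg$dispersion_stat %in% c("sd", "max_abs_dev")) {
    stop("dispersion_stat must be 'sd' or 'max_abs_dev'")
  }
  if (!cfg$iob_curve %in% c("linear", "bilinear")) {
    stop("iob_curve must be 'linear' or 'bilinear'")
  }
  invisible(cfg)
}
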