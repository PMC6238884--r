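# Noticeable-event segmentation (hyperglycemia, hypoglycemia, high blood
# pressure, short sleep) and the per-event causal hypothesis trees.

hyp_state <- function(id, state, justification = "", evidence = list()) {
  stopifnot(state %in% c("TRUE", "FALSE", "NA"))
  structure(list(hypothesis_id = id, state = state,
                 justification = justification, evidence = evidence),
            class = "gr_result")
}

#' @export
print.gr_result <- function(x, ...) {
  cat(sprintf("[%s] %s — %s\n", x$state, x$hypothesis_id, x$justification))
  invisible(x)
}

# classify a carbohydrate intake as meal or snack by its clock time against
# the profile's mealtime windows
classify_intake <- function(ts, profile) {
  m <- as.integer(format(ts, "%H")) * 60 + as.integer(format(ts, "%M"))
  for (w in profile$mealtime_windows) {
    if (m >= clock_minutes(w[1]) && m <= clock_minutes(w[2])) return("meal")
  }
  "snack"
}

#' Classify a blood glucose reading as fasting, before a meal, or other
#'
#' Fasting is inferred conservatively: no carbohydrate intake in the
#' preceding 8 hours. A reading is "before a meal" when a meal-classed
#' carbohydrate intake follows it within the insulin/meal pairing window
#' (default 30 minutes).
#'
#' @param ts POSIXct time of the reading.
#' @param ctx a `gr_context`.
#' @return `"fasting"`, `"before_meal"` or `"other"`.
#' @export
classify_reading <- function(ts, ctx) {
  cfg <- ctx$config
  carbs <- regs_of(ctx, "carbohydrates")
  if (nrow(carbs) == 0) return("fasting")
  ahead <- as.numeric(difftime(carbs$timestamp, ts, units = "mins"))
  upcoming <- which(ahead > 0 & ahead <= cfg$insulin_meal_window_minutes)
  for (i in upcoming) {
    if (classify_intake(carbs$timestamp[i], ctx$profile) == "meal") {
      return("before_meal")
    }
  }
  el <- as.numeric(difftime(ts, carbs$timestamp, units = "hours"))
  if (!any(el >= 0 & el < cfg$fasting_lookback_hours)) return("fasting")
  "other"
}

new_event <- function(kind, start, end, reference_time, extreme_value,
                      n_readings = 1L, extra = list()) {
  structure(c(list(kind = kind, start = start, end = end,
                   reference_time = reference_time,
                   extreme_value = extreme_value,
                   n_readings = n_readings), extra),
            class = "gr_event")
}

#' @export
print.gr_event <- function(x, ...) {
  cat(sprintf("<%s event> ref %s, extreme %.1f, %d reading(s)\n",
              x$kind, format(x$reference_time, "%Y-%m-%d %H:%M"),
              x$extreme_value, x$n_readings))
  invisible(x)
}

#' Segment continuous glycemic events
#'
#' A reading is hyperglycemic above 9 mmol/L when fasting or before a meal,
#' above 13.9 mmol/L otherwise (strict inequalities); hypoglycemic below
#' 4 mmol/L fasting, below 3.5 mmol/L otherwise. Maximal runs of consecutive
#' out-of-range readings of the same kind — with no in-range reading between
#' — form one continuous event, split when the span exceeds the maximum event
#' duration (default 6 h). The reference time is the reading with the most
#' extreme value (highest for hyper, lowest for hypo).
#'
#' @param ctx a `gr_context`.
#' @return list of `gr_event` objects (possibly empty).
#' @export
segment_glycemic_events <- function(ctx) {
  cfg <- ctx$config
  bg <- regs_of(ctx, "blood_glucose")
  if (nrow(bg) == 0) return(list())
  status <- character(nrow(bg))
  for (i in seq_len(nrow(bg))) {
    cls <- classify_reading(bg$timestamp[i], ctx)
    hyper_thr <- if (cls %in% c("fasting", "before_meal")) cfg$hyper_fasting else cfg$hyper_other
    hypo_thr <- if (cls == "fasting") cfg$hypo_fasting else cfg$hypo_other
    status[i] <- if (bg$value[i] > hyper_thr) "hyperglycemia"
    else if (bg$value[i] < hypo_thr) "hypoglycemia"
    else "normal"
  }
  events <- list()
  run_idx <- integer(0)
  run_kind <- ""
  flush <- function(idx, kind) {
    if (!length(idx)) return(NULL)
    vals <- bg$value[idx]
    ref_i <- idx[if (kind == "hyperglycemia") which.max(vals) else which.min(vals)]
    new_event(kind,
              start = bg$timestamp[idx[1]],
              end = bg$timestamp[idx[length(idx)]],
              reference_time = bg$timestamp[ref_i],
              extreme_value = bg$value[ref_i],
              n_readings = length(idx))
  }
  for (i in seq_len(nrow(bg))) {
    if (status[i] == "normal") {
      ev <- flush(run_idx, run_kind)
      if (!is.null(ev)) events[[length(events) + 1]] <- ev
      run_idx <- integer(0); run_kind <- ""
      next
    }
    span_ok <- length(run_idx) == 0 ||
      as.numeric(difftime(bg$timestamp[i], bg$timestamp[run_idx[1]],
                          units = "hours")) <= cfg$event_max_duration_hours
    if (status[i] == run_kind && span_ok) {
      run_idx <- c(run_idx, i)
    } else {
      ev <- flush(run_idx, run_kind)
      if (!is.null(ev)) events[[length(events) + 1]] <- ev
      run_idx <- i
      run_kind <- status[i]
    }
  }
  ev <- flush(run_idx, run_kind)
  if (!is.null(ev)) events[[length(events) + 1]] <- ev
  events
}

#' Detect high blood pressure events
#'
#' One event per reading with systolic strictly above 140 mmHg or diastolic
#' strictly above 90 mmHg. Systolic and diastolic registrations sharing a
#' timestamp are treated as one reading.
#'
#' @param ctx a `gr_context`.
#' @return list of `gr_event` objects of kind `high_bp`.
#' @export
detect_bp_events <- function(ctx) {
  cfg <- ctx$config
  bp <- regs_of(ctx, c("blood_pressure_systolic", "blood_pressure_diastolic"))
  if (nrow(bp) == 0) return(list())
  events <- list()
  for (ts in unique(bp$timestamp)) {
    rows <- bp[bp$timestamp == ts, , drop = FALSE]
    sys <- rows$value[rows$data_type == "blood_pressure_systolic"]
    dia <- rows$value[rows$data_type == "blood_pressure_diastolic"]
    high_sys <- length(sys) && any(sys > cfg$bp_systolic)
    high_dia <- length(dia) && any(dia > cfg$bp_diastolic)
    if (high_sys || high_dia) {
      tsp <- as.POSIXct(ts, tz = "UTC")
      events[[length(events) + 1]] <- new_event(
        "high_bp", start = tsp, end = tsp, reference_time = tsp,
        extreme_value = if (high_sys) max(sys) else max(dia),
        n_readings = 1L,
        extra = list(systolic = if (length(sys)) max(sys) else NA_real_,
                     diastolic = if (length(dia)) max(dia) else NA_real_))
    }
  }
  events
}

clock_at <- function(date, hhmm) {
  as_timestamp(paste(format(date, "%Y-%m-%d"), hhmm))
}

#' Detect short-sleep events
#'
#' One night at a time, sleep is proxied by the longest gap between
#' consecutive manual registrations that contains the night anchor (03:00).
#' Sensor-automatic registrations are ignored. A gap shorter than the
#' recommended minimum (default 7 h) produces a short-sleep event for that
#' night.
#'
#' @param ctx a `gr_context`.
#' @return list of `gr_event` objects of kind `short_sleep`.
#' @export
detect_short_sleep <- function(ctx) {
  cfg <- ctx$config
  manual <- ctx$registrations[ctx$registrations$manual %in% TRUE, , drop = FALSE]
  if (nrow(manual) < 2) return(list())
  ts <- sort(unique(manual$timestamp))
  days <- period_days(ctx)
  if (length(days) < 2) return(list())
  events <- list()
  for (d in seq_len(length(days) - 1)) {
    anchor <- clock_at(days[d + 1], cfg$night_anchor)
    before <- ts[ts <= anchor]
    after <- ts[ts >= anchor]
    if (!length(before) || !length(after)) next
    gap_start <- max(before)
    gap_end <- min(after)
    gap_h <- as.numeric(difftime(gap_end, gap_start, units = "hours"))
    if (gap_h < cfg$sleep_min_hours) {
      events[[length(events) + 1]] <- new_event(
        "short_sleep", start = gap_start, end = gap_end,
        reference_time = anchor, extreme_value = gap_h, n_readings = 2L,
        extra = list(night = format(days[d], "%Y-%m-%d")))
    }
  }
  events
}

# ---- cause-tree leaf rules -------------------------------------------------

fmt_num <- function(x, digits = 2) {
  if (is.null(x) || !length(x) || !is.finite(x)) return("NA")
  format(round(x, digits), nsmall = 0, trim = TRUE, scientific = FALSE)
}

rule_iob_vs_average <- function(ctx, event, above) {
  boluses <- regs_of(ctx, "insulin_bolus")
  cur <- iob_at(event$reference_time, boluses, ctx$profile$dia,
                ctx$config$iob_curve, ctx$config$iob_peak_minutes)
  avg <- average_iob(ctx)
  hit <- if (above) cur > avg else cur < avg
  hyp_state(if (above) "hypo_iob_above_average" else "hyper_iob_below_average",
            if (hit) "TRUE" else "FALSE",
            sprintf("active insulin at the event was %s U against a period average of %s U",
                    fmt_num(cur), fmt_num(avg)),
            list(current_iob = cur, average_iob = avg))
}

rule_last_dose <- function(ctx, event, too_low) {
  id <- if (too_low) "hyper_last_dose_insufficient" else "hypo_last_dose_too_high"
  boluses <- regs_of(ctx, "insulin_bolus")
  el <- as.numeric(difftime(event$reference_time, boluses$timestamp, units = "hours"))
  prior <- which(el >= 0)
  if (!length(prior)) {
    return(hyp_state(id, "NA", "required context missing: no insulin dose before the event"))
  }
  last_i <- prior[which.min(el[prior])]
  dose <- boluses$value[last_i]
  isf <- effective_isf(ctx)
  if (!is.finite(isf) || isf <= 0) {
    return(hyp_state(id, "NA", "required context missing: insulin sensitivity factor"))
  }
  required <- (event$extreme_value - ctx$config$bg_target) / isf
  hit <- if (too_low) dose < required else dose > required
  hyp_state(id, if (hit) "TRUE" else "FALSE",
            sprintf("last dose %s U vs %s U required to reach %s mmol/L (ISF %s mmol/L per U)",
                    fmt_num(dose), fmt_num(required),
                    fmt_num(ctx$config$bg_target), fmt_num(isf)),
            list(last_dose = dose, required_dose = required, isf = isf))
}

meals_before <- function(ctx, event) {
  win <- slice_window(ctx, "carbohydrates", event$reference_time,
                      ctx$config$meal_lookback_hours)
  if (nrow(win) == 0) return(win)
  cls <- vapply(seq_len(nrow(win)),
                function(i) classify_intake(win$timestamp[i], ctx$profile),
                character(1))
  win[cls == "meal", , drop = FALSE]
}

boluses_near <- function(ctx, ts, window_minutes) {
  boluses <- regs_of(ctx, "insulin_bolus")
  if (nrow(boluses) == 0) return(boluses)
  dm <- abs(as.numeric(difftime(boluses$timestamp, ts, units = "mins")))
  boluses[dm <= window_minutes, , drop = FALSE]
}

rule_icr_too_low <- function(ctx, event) {
  meals <- meals_before(ctx, event)
  if (nrow(meals) == 0) {
    return(hyp_state("hyper_icr_too_low", "NA",
                     "required context missing: no meal in the lookback window"))
  }
  icr <- effective_icr(ctx, event$reference_time)
  if (!is.finite(icr) || icr <= 0) {
    return(hyp_state("hyper_icr_too_low", "NA",
                     "required context missing: insulin-to-carbohydrate ratio"))
  }
  carbs <- sum(meals$value)
  required <- carbs / icr
  given <- 0
  for (i in seq_len(nrow(meals))) {
    nb <- boluses_near(ctx, meals$timestamp[i], ctx$config$insulin_meal_window_minutes)
    given <- given + sum(nb$value)
  }
  hit <- given < required
  hyp_state("hyper_icr_too_low", if (hit) "TRUE" else "FALSE",
            sprintf("%s g of meal carbohydrates would need %s U at an I:C of %s g per U; %s U were given at mealtime",
                    fmt_num(carbs), fmt_num(required), fmt_num(icr), fmt_num(given)),
            list(meal_carbs = carbs, required_insulin = required,
                 given_insulin = given, icr = icr))
}

rule_no_insulin_at_meal <- function(ctx, event) {
  meals <- meals_before(ctx, event)
  if (nrow(meals) == 0) {
    return(hyp_state("hyper_no_insulin_at_meal", "NA",
                     "required context missing: no meal in the lookback window"))
  }
  uncovered <- character(0)
  for (i in seq_len(nrow(meals))) {
    nb <- boluses_near(ctx, meals$timestamp[i], ctx$config$insulin_meal_window_minutes)
    if (nrow(nb) == 0) {
      uncovered <- c(uncovered, format(meals$timestamp[i], "%H:%M"))
    }
  }
  hit <- length(uncovered) > 0
  hyp_state("hyper_no_insulin_at_meal", if (hit) "TRUE" else "FALSE",
            if (hit) sprintf("no insulin within %d minutes of the meal(s) at %s",
                             ctx$config$insulin_meal_window_minutes,
                             paste(uncovered, collapse = ", "))
            else "every meal in the window had an insulin dose nearby",
            list(uncovered_meals = length(uncovered)))
}

rule_cob_vs_average <- function(ctx, event) {
  rate <- ctx$profile$carb_absorption_rate
  if (is.null(rate) || !is.finite(rate)) {
    return(hyp_state("hyper_cob_above_average", "NA",
                     "required context missing: carbohydrate absorption rate"))
  }
  intakes <- regs_of(ctx, "carbohydrates")
  cur <- cob_at(event$reference_time, intakes, rate)
  avg <- average_cob(ctx)
  hit <- cur > avg
  hyp_state("hyper_cob_above_average", if (hit) "TRUE" else "FALSE",
            sprintf("carbohydrates on board at the event were %s g against a period average of %s g",
                    fmt_num(cur), fmt_num(avg)),
            list(current_cob = cur, average_cob = avg))
}

rule_intake_reco <- function(ctx, event, high) {
  id <- if (high) "hyper_intake_above_recommendation" else "hypo_intake_below_recommendation"
  if (isTRUE(ctx$profile$low_carb_diet)) {
    return(hyp_state(id, "NA", "not applicable: patient follows a low-carb diet"))
  }
  win <- slice_window(ctx, "carbohydrates", event$reference_time,
                      ctx$config$meal_lookback_hours)
  if (nrow(win) == 0) {
    return(hyp_state(id, "NA",
                     "required context missing: no carbohydrate intake in the lookback window"))
  }
  last <- win[which.max(as.numeric(win$timestamp)), ]
  cls <- classify_intake(last$timestamp, ctx$profile)
  cfg <- ctx$config
  limit <- if (high) {
    if (cls == "meal") cfg$meal_carbs_high else cfg$snack_carbs_high
  } else {
    if (cls == "meal") cfg$meal_carbs_low else cfg$snack_carbs_low
  }
  hit <- if (high) last$value > limit else last$value < limit
  hyp_state(id, if (hit) "TRUE" else "FALSE",
            sprintf("last intake was a %s of %s g against a recommendation of %s %s g",
                    cls, fmt_num(last$value), if (high) "at most" else "at least",
                    fmt_num(limit)),
            list(intake = last$value, limit = limit, intake_class = cls))
}

rule_external_factors <- function(ctx, event, hyp_id) {
  id <- hyp_id
  facts <- regs_of(ctx, "external_factor")
  day <- as.Date(event$reference_time)
  hit_rows <- facts[as.Date(facts$timestamp) == day, , drop = FALSE]
  hit <- nrow(hit_rows) > 0
  hyp_state(id, if (hit) "TRUE" else "FALSE",
            if (hit) sprintf("external factor(s) present on %s: %s", format(day),
                             paste(unique(hit_rows$factor_tag), collapse = ", "))
            else "no external factor registered on the day of the event",
            list(factors = if (hit) unique(hit_rows$factor_tag) else character(0)))
}

rule_no_activity_24h <- function(ctx, event) {
  win <- slice_window(ctx, "physical_activity", event$reference_time,
                      ctx$config$activity_lookback_extreme_hours)
  hit <- nrow(win) == 0
  hyp_state("hyper_no_physical_activity", if (hit) "TRUE" else "FALSE",
            if (hit) "no physical activity registered in the 24 hours before the event"
            else sprintf("%d activity registration(s) within 24 hours of the event", nrow(win)),
            list(n_activity = nrow(win)))
}

# light-to-moderate: intensity tag light/moderate, or strictly under the
# configured minute/step/MET bounds
qualifies_light <- function(row, cfg) {
  switch(row$activity_kind,
         tag = row$activity_tag %in% c("light", "moderate"),
         minutes = row$value < cfg$activity_light_minutes,
         steps = row$value < cfg$activity_light_steps,
         mets = row$value < cfg$activity_light_mets,
         FALSE)
}

qualifies_extreme <- function(row, cfg) {
  switch(row$activity_kind,
         tag = identical(row$activity_tag, "extreme"),
         minutes = row$value >= cfg$activity_light_minutes,
         steps = row$value >= cfg$activity_light_steps,
         mets = row$value >= cfg$activity_light_mets,
         FALSE)
}

rule_light_activity_4h <- function(ctx, event) {
  win <- slice_window(ctx, "physical_activity", event$reference_time,
                      ctx$config$activity_lookback_moderate_hours)
  hit <- FALSE
  for (i in seq_len(nrow(win))) if (qualifies_light(win[i, ], ctx$config)) hit <- TRUE
  hyp_state("hypo_light_moderate_activity", if (hit) "TRUE" else "FALSE",
            if (hit) "light-to-moderate physical activity within 4 hours of the event"
            else "no light-to-moderate activity in the 4 hours before the event",
            list(n_activity = nrow(win)))
}

rule_extreme_activity_24h <- function(ctx, event) {
  win <- slice_window(ctx, "physical_activity", event$reference_time,
                      ctx$config$activity_lookback_extreme_hours)
  hit <- FALSE
  for (i in seq_len(nrow(win))) if (qualifies_extreme(win[i, ], ctx$config)) hit <- TRUE
  hyp_state("hypo_extreme_activity", if (hit) "TRUE" else "FALSE",
            if (hit) "extreme physical activity within 24 hours of the event"
            else "no extreme activity in the 24 hours before the event",
            list(n_activity = nrow(win)))
}

rule_no_carbs_4h <- function(ctx, event) {
  win <- slice_window(ctx, "carbohydrates", event$reference_time,
                      ctx$config$meal_lookback_hours)
  hit <- nrow(win) == 0
  hyp_state("hypo_no_carbs_4h", if (hit) "TRUE" else "FALSE",
            if (hit) "no carbohydrate intake in the 4 hours before the event"
            else sprintf("%d carbohydrate intake(s) within 4 hours of the event", nrow(win)),
            list(n_intakes = nrow(win)))
}

rule_iob_exceeds_need <- function(ctx, event) {
  boluses <- regs_of(ctx, "insulin_bolus")
  cur <- iob_at(event$reference_time, boluses, ctx$profile$dia,
                ctx$config$iob_curve, ctx$config$iob_peak_minutes)
  icr <- effective_icr(ctx, event$reference_time)
  if (!is.finite(icr) || icr <= 0) {
    return(hyp_state("hypo_active_insulin_exceeds_need", "NA",
                     "required context missing: insulin-to-carbohydrate ratio"))
  }
  win <- slice_window(ctx, "carbohydrates", event$reference_time,
                      ctx$config$meal_lookback_hours)
  need <- sum(win$value) / icr
  hit <- cur > need
  hyp_state("hypo_active_insulin_exceeds_need", if (hit) "TRUE" else "FALSE",
            sprintf("active insulin %s U vs %s U needed to cover %s g of recent carbohydrates (I:C %s)",
                    fmt_num(cur), fmt_num(need), fmt_num(sum(win$value)), fmt_num(icr)),
            list(current_iob = cur, needed_insulin = need, icr = icr))
}

# ---- combination semantics -------------------------------------------------

combine_invalidate <- function(id, children) {
  states <- vapply(children, `[[`, character(1), "state")
  hit <- any(states == "TRUE")
  hyp_state(id, if (hit) "TRUE" else "FALSE",
            if (hit) "supported by at least one validated sub-hypothesis"
            else "invalidated: every sub-hypothesis is false or not applicable",
            list(child_states = states))
}

combine_any_true <- function(id, children) {
  states <- vapply(children, `[[`, character(1), "state")
  state <- if (any(states == "TRUE")) "TRUE"
  else if (all(states == "FALSE")) "FALSE"
  else "NA"
  hyp_state(id, state,
            switch(state,
                   "TRUE" = "at least one activity sub-hypothesis is validated",
                   "FALSE" = "no activity sub-hypothesis is validated",
                   "NA" = "activity context insufficient to decide"),
            list(child_states = states))
}

combine_lack_of_evidence <- function(id, branches) {
  states <- vapply(branches, `[[`, character(1), "state")
  hit <- all(states %in% c("FALSE", "NA"))
  hyp_state(id, if (hit) "TRUE" else "FALSE",
            if (hit) "no candidate cause could be validated: potential information gap"
            else "at least one potential cause was identified",
            list(branch_states = states))
}

# run a leaf with its activation predicate; NA (naming the missing context)
# when the predicate fails, NA "evaluation failure" if the rule itself errors
run_leaf <- function(id, ctx, event, fn, ...) {
  miss <- check_requires(ctx, hypothesis_requires(id))
  if (!is.null(miss)) {
    return(hyp_state(id, "NA", paste0("required context missing: ", miss)))
  }
  tryCatch(fn(ctx, event, ...),
           error = function(e) hyp_state(id, "NA",
                                         paste0("evaluation failure: ", conditionMessage(e))))
}

#' Evaluate the hyperglycemia cause tree for one event
#'
#' Walks the five branches directly: "not enough insulin" (default TRUE,
#' invalidated only when its four children are all FALSE or NA), "too much
#' carbohydrates" (two children, same semantics), external factors, lack of
#' physical activity in the preceding 24 h, and "lack of evidence", which is
#' TRUE — flagging an information gap — exactly when every other branch is
#' FALSE or NA.
#'
#' @param event a `gr_event` of kind `hyperglycemia`.
#' @param ctx a `gr_context`.
#' @return named list of hypothesis results (`gr_result`).
#' @export
evaluate_hyper_causes <- function(event, ctx) {
  stopifnot(event$kind == "hyperglycemia")
  res <- list()
  res$hyper_iob_below_average <-
    run_leaf("hyper_iob_below_average", ctx, event, rule_iob_vs_average, above = FALSE)
  res$hyper_last_dose_insufficient <-
    run_leaf("hyper_last_dose_insufficient", ctx, event, rule_last_dose, too_low = TRUE)
  res$hyper_icr_too_low <-
    run_leaf("hyper_icr_too_low", ctx, event, rule_icr_too_low)
  res$hyper_no_insulin_at_meal <-
    run_leaf("hyper_no_insulin_at_meal", ctx, event, rule_no_insulin_at_meal)
  res$hyper_not_enough_insulin <- if (!is.null(check_requires(ctx, "profile:uses_insulin"))) {
    hyp_state("hyper_not_enough_insulin", "NA",
              "required context missing: patient does not use insulin")
  } else {
    combine_invalidate("hyper_not_enough_insulin",
                       res[c("hyper_iob_below_average", "hyper_last_dose_insufficient",
                             "hyper_icr_too_low", "hyper_no_insulin_at_meal")])
  }
  res$hyper_cob_above_average <-
    run_leaf("hyper_cob_above_average", ctx, event, rule_cob_vs_average)
  res$hyper_intake_above_recommendation <-
    run_leaf("hyper_intake_above_recommendation", ctx, event, rule_intake_reco, high = TRUE)
  res$hyper_too_much_carbohydrates <-
    combine_invalidate("hyper_too_much_carbohydrates",
                       res[c("hyper_cob_above_average", "hyper_intake_above_recommendation")])
  res$hyper_external_factors <-
    run_leaf("hyper_external_factors", ctx, event, rule_external_factors,
             hyp_id = "hyper_external_factors")
  res$hyper_no_physical_activity <-
    run_leaf("hyper_no_physical_activity", ctx, event, rule_no_activity_24h)
  res$hyper_lack_of_evidence <-
    combine_lack_of_evidence("hyper_lack_of_evidence",
                             res[c("hyper_not_enough_insulin", "hyper_too_much_carbohydrates",
                                   "hyper_external_factors", "hyper_no_physical_activity")])
  res
}

#' Evaluate the hypoglycemia cause tree for one event
#'
#' Mirror of [evaluate_hyper_causes()]: "too much insulin" (three children),
#' "too few carbohydrates" (two children), external factors, physical
#' activity (light-to-moderate within 4 h or extreme within 24 h), and "lack
#' of evidence".
#'
#' @param event a `gr_event` of kind `hypoglycemia`.
#' @param ctx a `gr_context`.
#' @return named list of hypothesis results (`gr_result`).
#' @export
evaluate_hypo_causes <- function(event, ctx) {
  stopifnot(event$kind == "hypoglycemia")
  res <- list()
  res$hypo_iob_above_average <-
    run_leaf("hypo_iob_above_average", ctx, event, rule_iob_vs_average, above = TRUE)
  res$hypo_last_dose_too_high <-
    run_leaf("hypo_last_dose_too_high", ctx, event, rule_last_dose, too_low = FALSE)
  res$hypo_active_insulin_exceeds_need <-
    run_leaf("hypo_active_insulin_exceeds_need", ctx, event, rule_iob_exceeds_need)
  res$hypo_too_much_insulin <- if (!is.null(check_requires(ctx, "profile:uses_insulin"))) {
    hyp_state("hypo_too_much_insulin", "NA",
              "required context missing: patient does not use insulin")
  } else {
    combine_invalidate("hypo_too_much_insulin",
                       res[c("hypo_iob_above_average", "hypo_last_dose_too_high",
                             "hypo_active_insulin_exceeds_need")])
  }
  res$hypo_no_carbs_4h <-
    run_leaf("hypo_no_carbs_4h", ctx, event, rule_no_carbs_4h)
  res$hypo_intake_below_recommendation <-
    run_leaf("hypo_intake_below_recommendation", ctx, event, rule_intake_reco, high = FALSE)
  res$hypo_too_few_carbohydrates <-
    combine_invalidate("hypo_too_few_carbohydrates",
                       res[c("hypo_no_carbs_4h", "hypo_intake_below_recommendation")])
  res$hypo_external_factors <-
    run_leaf("hypo_external_factors", ctx, event, rule_external_factors,
             hyp_id = "hypo_external_factors")
  res$hypo_light_moderate_activity <-
    run_leaf("hypo_light_moderate_activity", ctx, event, rule_light_activity_4h)
  res$hypo_extreme_activity <-
    run_leaf("hypo_extreme_activity", ctx, event, rule_extreme_activity_24h)
  res$hypo_physical_activity <-
    combine_any_true("hypo_physical_activity",
                     res[c("hypo_light_moderate_activity", "hypo_extreme_activity")])
  res$hypo_lack_of_evidence <-
    combine_lack_of_evidence("hypo_lack_of_evidence",
                             res[c("hypo_too_much_insulin", "hypo_too_few_carbohydrates",
                                   "hypo_external_factors", "hypo_physical_activity")])
  res
}

#' Evaluate the cause checks attached to a high blood pressure event
#'
#' @param event a `gr_event` of kind `high_bp`.
#' @param ctx a `gr_context`.
#' @return named list of hypothesis results.
#' @export
evaluate_bp_causes <- function(event, ctx) {
  stopifnot(event$kind == "high_bp")
  res <- list()
  res$bp_external_factors <-
    run_leaf("bp_external_factors", ctx, event, rule_external_factors,
             hyp_id = "bp_external_factors")
  res$bp_lack_of_evidence <-
    combine_lack_of_evidence("bp_lack_of_evidence", res["bp_external_factors"])
  res
}
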