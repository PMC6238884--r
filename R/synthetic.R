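# Seeded generator of synthetic type 1 diabetes diaries with controllable
# physiology patterns and injectable anomalies, plus small golden fixtures.
# The glucose process is a meal-excursion + Gaussian-noise model, not a
# physiological simulator: it is sufficient to drive threshold rules.

#' Describe a synthetic diary scenario
#'
#' The default scenario is the fully compliant diary: 14 days, 5 evenly
#' spaced glucose checks a day, three dosed meals, basal insulin, daily
#' light activity, no anomalies — a diary that satisfies every reliability
#' predicate and produces no noticeable event.
#'
#' @param days number of diary days.
#' @param start_date first day (a Monday by default so weekday grouping is
#'   balanced over whole weeks).
#' @param bg_per_day glucose checks per day, evenly spaced 07:00-21:30 when
#'   `bg_times` is not given.
#' @param bg_times optional character clock times for the checks.
#' @param meals data.frame with `time` (clock) and `carbs` (g).
#' @param bolus_icr grams of carbohydrate covered per bolus unit used to dose
#'   meal boluses.
#' @param basal_units,basal_time daily basal dose and its clock time.
#' @param activity data.frame with `time`, `kind`, `value` (and optional
#'   `tag`), one row per daily activity; NULL for none.
#' @param baseline,meal_rise,noise_sd glucose process: baseline mmol/L, peak
#'   meal excursion mmol/L (linear 4 h decay) and Gaussian noise sd.
#' @param anomalies list of anomaly descriptors, see [anomaly_missed_bolus()]
#'   and friends.
#' @param seed integer RNG seed; the same (spec, profile) pair always yields
#'   the identical diary.
#' @return list of class `gr_scenario`.
#' @export
scenario_spec <- function(days = 14, start_date = "2024-03-04",
                          bg_per_day = 5, bg_times = NULL,
                          meals = data.frame(time = c("08:00", "12:00", "18:00"),
                                             carbs = c(40, 60, 55)),
                          bolus_icr = 10, basal_units = 20, basal_time = "22:00",
                          activity = data.frame(time = "16:00", kind = "minutes",
                                                value = 30),
                          baseline = 5.5, meal_rise = 3, noise_sd = 0.4,
                          anomalies = list(), seed = 1) {
  if (is.null(bg_times)) {
    if (bg_per_day == 1) {
      bg_times <- "07:00"
    } else {
      mins <- round(seq(7 * 60, 21.5 * 60, length.out = bg_per_day))
      bg_times <- sprintf("%02d:%02d", mins %/% 60, mins %% 60)
    }
  }
  spec <- structure(list(days = days, start_date = as.Date(start_date),
                         bg_times = bg_times, meals = meals,
                         bolus_icr = bolus_icr, basal_units = basal_units,
                         basal_time = basal_time, activity = activity,
                         baseline = baseline, meal_rise = meal_rise,
                         noise_sd = noise_sd, anomalies = anomalies,
                         seed = as.integer(seed)),
                    class = "gr_scenario")
  validate_scenario(spec)
  spec
}

validate_scenario <- function(spec) {
  missing_days <- vapply(Filter(function(a) a$kind == "missing_day", spec$anomalies),
                         `[[`, numeric(1), "day")
  for (a in spec$anomalies) {
    if (a$kind %in% c("hypo_injection", "hyper_injection", "extreme_value",
                      "wrong_unit", "missed_bolus") &&
        !is.null(a$day) && a$day %in% missing_days) {
      stop(sprintf("contradictory anomalies: %s on day %d, but day %d is missing",
                   a$kind, a$day, a$day))
    }
    if (!is.null(a$day) && (a$day < 1 || a$day > spec$days)) {
      stop(sprintf("anomaly %s targets day %d outside 1..%d", a$kind, a$day, spec$days))
    }
  }
  invisible(spec)
}

#' Anomaly descriptors for the synthetic generator
#'
#' Each descriptor injects one error pattern and records which hypothesis it
#' should flip: a dropped meal bolus (with the hyperglycemic excursion it
#' causes), a fabricated noise-free glucose series, a day without any
#' registration, a day of glucose values logged in mg/dL as if they were
#' mmol/L, a single implausible value, an injected hypo- or hyperglycemic
#' reading, and a patient-reported insulin sensitivity offset from the
#' diary-derived one.
#'
#' @param day diary day index (1-based).
#' @param meal meal name: `"breakfast"`, `"lunch"` or `"dinner"`.
#' @param time clock time `"HH:MM"`.
#' @param type registration data type for the extreme value.
#' @param value,depth,height numeric value to inject.
#' @param source source label for the wrong-unit rows.
#' @param offset relative offset of the reported ISF (e.g. 0.3 = 30% high).
#' @return list describing the anomaly, for `scenario_spec(anomalies = ...)`.
#' @export
anomaly_missed_bolus <- function(day, meal = "lunch") {
  list(kind = "missed_bolus", day = day, meal = meal,
       expect = "hyper_no_insulin_at_meal")
}

#' @rdname anomaly_missed_bolus
#' @export
anomaly_fabricated_smoothing <- function() {
  list(kind = "fabricated_smoothing", day = NULL,
       expect = "source_inconsistency_hba1c")
}

#' @rdname anomaly_missed_bolus
#' @export
anomaly_missing_day <- function(day) {
  list(kind = "missing_day", day = day, expect = "unequal_days_distribution")
}

#' @rdname anomaly_missed_bolus
#' @export
anomaly_wrong_unit <- function(day, source = "meter_mgdl") {
  list(kind = "wrong_unit", day = day, source = source,
       expect = "error_values_blood_glucose")
}

#' @rdname anomaly_missed_bolus
#' @export
anomaly_extreme_value <- function(type, value, day, time = "15:00") {
  expect <- paste0("error_values_",
                   if (type %in% c("insulin_bolus", "insulin_basal")) "insulin" else type)
  list(kind = "extreme_value", type = type, value = value, day = day,
       time = time, expect = expect)
}

#' @rdname anomaly_missed_bolus
#' @export
anomaly_hypo_injection <- function(day, time = "15:00", depth = 3.0) {
  list(kind = "hypo_injection", day = day, time = time, value = depth,
       expect = "hypoglycemia")
}

#' @rdname anomaly_missed_bolus
#' @export
anomaly_hyper_injection <- function(day, time = "15:00", height = 16.0) {
  list(kind = "hyper_injection", day = day, time = time, value = height,
       expect = "hyperglycemia")
}

#' @rdname anomaly_missed_bolus
#' @export
anomaly_source_conflict <- function(offset = 0.3) {
  list(kind = "source_conflict", day = NULL, offset = offset,
       expect = "source_inconsistency_isf")
}

meal_name_of <- function(time, profile) {
  m <- clock_minutes(time)
  for (nm in names(profile$mealtime_windows)) {
    w <- profile$mealtime_windows[[nm]]
    if (m >= clock_minutes(w[1]) && m <= clock_minutes(w[2])) return(nm)
  }
  "snack"
}

#' Generate a synthetic diary
#'
#' Deterministic for a fixed (scenario, profile) pair: the RNG is seeded from
#' the scenario and restored afterwards. Returns the registrations, the
#' profile actually in force (the source-conflict anomaly perturbs the
#' reported ISF), a laboratory context whose HbA1c is derived from the
#' honest glucose series, and a machine-readable ground-truth log of every
#' injected anomaly and event for recovery tests.
#'
#' @param spec a [scenario_spec()].
#' @param profile base [patient_profile()]; reported ISF/I:C and the
#'   laboratory HbA1c are filled in consistently with the generated diary.
#' @return list with `registrations`, `profile`, `lab`, `truth`.
#' @examples
#' d <- generate_diary(scenario_spec(days = 3, seed = 7))
#' nrow(d$registrations)
#' @export
generate_diary <- function(spec, profile = patient_profile(carb_absorption_rate = 30)) {
  validate_scenario(spec)
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  smoothing <- any(vapply(spec$anomalies, function(a) a$kind == "fabricated_smoothing", logical(1)))
  missed <- Filter(function(a) a$kind == "missed_bolus", spec$anomalies)
  rows <- list()
  honest_bg <- numeric(0)
  truth <- list()
  add_row <- function(r) rows[[length(rows) + 1]] <<- r

  days <- spec$start_date + seq_len(spec$days) - 1
  for (d in seq_len(spec$days)) {
    date <- days[d]
    meal_ts <- as_timestamp(paste(format(date), spec$meals$time))
    dropped <- vapply(seq_len(nrow(spec$meals)), function(i) {
      any(vapply(missed, function(a) {
        a$day == d && identical(a$meal, meal_name_of(spec$meals$time[i], profile))
      }, logical(1)))
    }, logical(1))
    # blood glucose checks
    for (tm in spec$bg_times) {
      ts <- as_timestamp(paste(format(date), tm))
      excursion <- 0
      for (i in seq_len(nrow(spec$meals))) {
        el <- as.numeric(difftime(ts, meal_ts[i], units = "hours"))
        if (el > 0 && el < 4) excursion <- excursion + spec$meal_rise * (1 - el / 4)
      }
      v <- spec$baseline + excursion + stats::rnorm(1, 0, spec$noise_sd)
      v <- min(max(v, 4.5), 9.0)  # the compliant process stays in range
      honest_bg <- c(honest_bg, v)
      if (smoothing) v <- spec$baseline
      # an uncovered meal leaves glucose high for hours; the excursion is
      # larger and flatter than a covered meal's
      for (i in which(dropped)) {
        el <- as.numeric(difftime(ts, meal_ts[i], units = "hours"))
        if (el > 0 && el < 4) v <- v + 12 * (1 - el / 8)
      }
      add_row(registration(ts, "blood_glucose", round(v, 1)))
    }
    # meals and their boluses
    for (i in seq_len(nrow(spec$meals))) {
      add_row(registration(meal_ts[i], "carbohydrates", spec$meals$carbs[i]))
      if (!dropped[i]) {
        add_row(registration(meal_ts[i], "insulin_bolus",
                             round(spec$meals$carbs[i] / spec$bolus_icr, 1)))
      }
    }
    if (spec$basal_units > 0) {
      add_row(registration(as_timestamp(paste(format(date), spec$basal_time)),
                           "insulin_basal", spec$basal_units))
    }
    if (!is.null(spec$activity)) {
      for (i in seq_len(nrow(spec$activity))) {
        a <- spec$activity[i, ]
        add_row(registration(as_timestamp(paste(format(date), a$time)),
                             "physical_activity",
                             value = if (a$kind == "tag") NA_real_ else a$value,
                             activity_kind = a$kind,
                             activity_tag = if (a$kind == "tag") a$tag else NA_character_))
      }
    }
  }
  regs <- do.call(rbind, rows)

  planned_tdd <- sum(spec$meals$carbs) / spec$bolus_icr + spec$basal_units
  reported_isf <- isf_rule(planned_tdd, TRUE)
  reported_icr <- icr_rule(planned_tdd, TRUE)

  for (a in spec$anomalies) {
    truth[[length(truth) + 1]] <- a
    if (a$kind == "missing_day") {
      keep <- as.Date(regs$timestamp) != days[a$day]
      regs <- regs[keep, , drop = FALSE]
    } else if (a$kind == "wrong_unit") {
      sel <- regs$data_type == "blood_glucose" & as.Date(regs$timestamp) == days[a$day]
      regs$value[sel] <- round(regs$value[sel] * 18.016, 0)
      regs$source[sel] <- a$source
    } else if (a$kind == "extreme_value") {
      regs <- rbind(regs, registration(paste(format(days[a$day]), a$time),
                                       a$type, a$value))
    } else if (a$kind %in% c("hypo_injection", "hyper_injection")) {
      regs <- rbind(regs, registration(paste(format(days[a$day]), a$time),
                                       "blood_glucose", a$value))
    } else if (a$kind == "source_conflict") {
      reported_isf <- reported_isf * (1 + a$offset)
    }
  }

  profile$reported_isf <- reported_isf
  profile$reported_icr <- reported_icr
  lab <- lab_context(hba1c = estimate_hba1c(honest_bg))
  regs <- regs[order(regs$timestamp, regs$data_type), , drop = FALSE]
  rownames(regs) <- NULL
  list(registrations = regs, profile = profile, lab = lab, truth = truth)
}

#' Golden fixture diaries
#'
#' Hand-sized deterministic diaries (each well under 50 registrations)
#' exercising one hypothesis family each. Every fixture is a list with
#' `registrations`, `profile` and `lab`, ready for [build_context()].
#'
#' \describe{
#'   \item{hba1c_mismatch}{compliant 3-day diary whose laboratory HbA1c is
#'     set 30% above the diary estimate: trust drops by 10 to 40.}
#'   \item{gap_case}{glucose-only diary with one hypoglycemic reading and no
#'     insulin, carbohydrate or activity context: every cause branch is
#'     FALSE/NA, so lack-of-evidence flags an information gap.}
#'   \item{empty}{zero registrations; nothing crashes.}
#'   \item{hyper_meal}{an 85 g lunch followed by 15 mmol/L: hyperglycemia
#'     with the intake-above-recommendation cause.}
#'   \item{hypo_activity}{2500 steps two hours before a 3.0 mmol/L reading:
#'     hypoglycemia with the light-to-moderate-activity cause.}
#'   \item{bp_high}{one 150/85 mmHg reading.}
#'   \item{short_night}{manual registrations 23:30 and 05:30: a 6-hour
#'     night.}
#'   \item{wrong_unit_case}{a 180 "mmol/L" glucose value (a mg/dL slip):
#'     error-values flag.}
#' }
#'
#' @return named list of fixtures.
#' @export
golden_fixtures <- function() {
  p_plain <- patient_profile()
  fixtures <- list()

  # 3 compliant days; reported values match the diary-derived ones
  comp <- generate_diary(scenario_spec(days = 3, seed = 11))
  lab_mis <- lab_context(hba1c = comp$lab$hba1c * 1.3)
  fixtures$hba1c_mismatch <- list(registrations = comp$registrations,
                                  profile = comp$profile, lab = lab_mis)

  gap_regs <- registrations(
    registration("2024-03-04 07:00", "blood_glucose", 5.2),
    registration("2024-03-04 12:00", "blood_glucose", 5.8),
    registration("2024-03-04 15:00", "blood_glucose", 3.0),
    registration("2024-03-04 18:00", "blood_glucose", 5.1),
    registration("2024-03-04 21:00", "blood_glucose", 5.6))
  fixtures$gap_case <- list(registrations = gap_regs, profile = p_plain,
                            lab = lab_context())

  fixtures$empty <- list(registrations = empty_registrations(),
                         profile = p_plain, lab = lab_context())

  hyper_regs <- registrations(
    registration("2024-03-04 07:30", "blood_glucose", 5.4),
    registration("2024-03-04 12:00", "carbohydrates", 85),
    registration("2024-03-04 12:00", "insulin_bolus", 8),
    registration("2024-03-04 14:00", "blood_glucose", 15.0),
    registration("2024-03-04 20:00", "blood_glucose", 6.0))
  fixtures$hyper_meal <- list(registrations = hyper_regs, profile = p_plain,
                              lab = lab_context())

  hypo_regs <- registrations(
    registration("2024-03-04 08:00", "carbohydrates", 40),
    registration("2024-03-04 08:00", "insulin_bolus", 4),
    registration("2024-03-04 13:00", "physical_activity",
                 activity_kind = "steps", value = 2500),
    registration("2024-03-04 15:00", "blood_glucose", 3.0),
    registration("2024-03-04 19:00", "blood_glucose", 5.5))
  fixtures$hypo_activity <- list(registrations = hypo_regs, profile = p_plain,
                                 lab = lab_context())

  bp_regs <- registrations(
    registration("2024-03-04 10:00", "blood_pressure_systolic", 150),
    registration("2024-03-04 10:00", "blood_pressure_diastolic", 85),
    registration("2024-03-04 08:00", "blood_glucose", 5.5))
  fixtures$bp_high <- list(registrations = bp_regs, profile = p_plain,
                           lab = lab_context())

  sleep_regs <- registrations(
    registration("2024-03-04 08:00", "blood_glucose", 5.5),
    registration("2024-03-04 23:30", "blood_glucose", 6.1),
    registration("2024-03-05 05:30", "blood_glucose", 5.2),
    registration("2024-03-05 21:00", "blood_glucose", 5.9))
  fixtures$short_night <- list(registrations = sleep_regs, profile = p_plain,
                               lab = lab_context())

  wrong_regs <- registrations(
    registration("2024-03-04 07:30", "blood_glucose", 5.4),
    registration("2024-03-04 12:30", "blood_glucose", 180, source = "meter_mgdl"),
    registration("2024-03-04 18:30", "blood_glucose", 6.2))
  fixtures$wrong_unit_case <- list(registrations = wrong_regs, profile = p_plain,
                                   lab = lab_context())

  fixtures
}
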