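# Data-reliability hypothesis family and the 0-50 trust grading.

# tolerance comparisons are "strictly greater than the allowed deviation";
# a value equal to the allowance is permitted, so guard the comparison with
# a tiny relative epsilon against floating-point round-off at the boundary
exceeds_tolerance <- function(x, limit, rel_eps = 1e-9) {
  x > limit + rel_eps * max(1, abs(limit))
}

MISSING_TYPE_IDS <- c(blood_glucose = "no_blood_glucose_registered",
                      carbohydrates = "no_carbohydrates_registered",
                      insulin = "no_insulin_registered",
                      physical_activity = "no_physical_activity_registered")

missing_type_recommendation <- function(type) {
  switch(type,
         blood_glucose = "Registering blood glucose values lets the module detect highs and lows and estimate your HbA1c.",
         carbohydrates = "Registering carbohydrate intakes permits a better estimation of your insulin correction dosage and could help reduce highs and lows of your blood glucose values.",
         insulin = "Registering insulin doses lets the module judge whether doses matched your meals and glucose values.",
         physical_activity = "Registering physical activity helps explain glucose excursions up to a day after the activity.")
}

rel_missing_type <- function(ctx, type) {
  id <- MISSING_TYPE_IDS[[type]]
  types <- if (type == "insulin") c("insulin_bolus", "insulin_basal") else type
  n <- nrow(regs_of(ctx, types))
  hit <- n == 0
  hyp_state(id, if (hit) "TRUE" else "FALSE",
            if (hit) sprintf("no %s registered in the period", gsub("_", " ", type))
            else sprintf("%d %s registration(s) present", n, gsub("_", " ", type)),
            list(n = n,
                 recommendation = if (hit) missing_type_recommendation(type) else NULL))
}

#' Check for entirely missing data types
#'
#' One result per core data type (blood glucose, carbohydrates, insulin,
#' physical activity): TRUE when zero registrations of that type exist in the
#' period. The insulin check is not applicable for patients who do not use
#' insulin. TRUE results carry a recommendation inviting the patient to
#' register the type.
#'
#' @param ctx a `gr_context`.
#' @return named list of four `gr_result` objects.
#' @export
check_missing_types <- function(ctx) {
  out <- list()
  for (type in names(MISSING_TYPE_IDS)) {
    id <- MISSING_TYPE_IDS[[type]]
    miss <- check_requires(ctx, hypothesis_requires(id))
    out[[id]] <- if (!is.null(miss)) {
      hyp_state(id, "NA", paste0("required context missing: ", miss))
    } else {
      rel_missing_type(ctx, type)
    }
  }
  out
}

ERROR_VALUE_IDS <- c(blood_glucose = "error_values_blood_glucose",
                     carbohydrates = "error_values_carbohydrates",
                     insulin = "error_values_insulin")

rel_error_values <- function(ctx, type) {
  cfg <- ctx$config
  id <- ERROR_VALUE_IDS[[type]]
  rng <- switch(type,
                blood_glucose = cfg$bg_plausible_range,
                carbohydrates = cfg$carbs_plausible_range,
                insulin = cfg$insulin_plausible_range)
  types <- if (type == "insulin") c("insulin_bolus", "insulin_basal") else type
  rows <- regs_of(ctx, types)
  bad <- rows[rows$value < rng[1] | rows$value > rng[2], , drop = FALSE]
  hit <- nrow(bad) > 0
  hyp_state(id, if (hit) "TRUE" else "FALSE",
            if (hit) sprintf("%d %s value(s) outside the plausible range [%s, %s]: %s — please confirm these registrations",
                             nrow(bad), gsub("_", " ", type), fmt_num(rng[1]), fmt_num(rng[2]),
                             paste(fmt_num_vec(bad$value), collapse = ", "))
            else sprintf("all %s values inside the plausible range", gsub("_", " ", type)),
            list(flagged_values = bad$value,
                 flagged_times = format(bad$timestamp, "%Y-%m-%d %H:%M"),
                 range = rng,
                 recommendation = if (hit) "Please validate whether these extreme values are real measurements or registration errors." else NULL))
}

fmt_num_vec <- function(x) vapply(x, fmt_num, character(1))

#' Check for implausible values
#'
#' Flags values outside the plausibility ranges for blood glucose
#' (1.1-33.3 mmol/L), carbohydrates and insulin; flagged values are listed so
#' the user can validate their origin.
#'
#' @param ctx a `gr_context`.
#' @return named list of three `gr_result` objects.
#' @export
check_error_values <- function(ctx) {
  out <- list()
  for (type in names(ERROR_VALUE_IDS)) {
    out[[ERROR_VALUE_IDS[[type]]]] <- rel_error_values(ctx, type)
  }
  out
}

rel_registration_counts <- function(ctx) {
  cfg <- ctx$config
  dt <- daily_totals(ctx)
  offenders <- list()
  for (type in names(cfg$min_per_day)) {
    minimum <- cfg$min_per_day[[type]]
    if (minimum <= 0) next
    if (type == "insulin" && !isTRUE(ctx$profile$uses_insulin)) next
    counts <- if (type == "insulin") {
      dt$n_insulin_bolus + dt$n_insulin_basal
    } else {
      dt[[paste0("n_", type)]]
    }
    low <- which(counts < minimum)
    for (i in low) {
      offenders[[length(offenders) + 1]] <-
        list(day = format(dt$date[i]), type = type, count = counts[i],
             minimum = minimum)
    }
  }
  hit <- length(offenders) > 0
  hyp_state("not_enough_registrations", if (hit) "TRUE" else "FALSE",
            if (hit) sprintf("%d day/type combination(s) fall below the minimum registration count (e.g. %s: %d %s, minimum %d)",
                             length(offenders), offenders[[1]]$day,
                             offenders[[1]]$count, gsub("_", " ", offenders[[1]]$type),
                             offenders[[1]]$minimum)
            else "every day meets the minimum registration counts",
            list(offenders = offenders,
                 recommendation = if (hit) "Registering data more often — at least 5 blood glucose checks a day — lets the module calculate trends reliably." else NULL))
}

#' Check minimal registrations per day
#'
#' TRUE when any required data type falls below its per-day minimum on any
#' day (default: 5 blood glucose checks; 1 insulin and 1 carbohydrate
#' registration; no minimum for activity). NA for an empty diary.
#'
#' @param ctx a `gr_context`.
#' @return a `gr_result`.
#' @export
check_registration_counts <- function(ctx) {
  miss <- check_requires(ctx, hypothesis_requires("not_enough_registrations"))
  if (!is.null(miss)) {
    return(hyp_state("not_enough_registrations", "NA",
                     paste0("required context missing: ", miss)))
  }
  rel_registration_counts(ctx)
}

dispersion_of <- function(counts, stat) {
  if (stat == "max_abs_dev") return(max(abs(counts - mean(counts))))
  stats::sd(counts)
}

rel_distribution <- function(ctx, by_weekday) {
  cfg <- ctx$config
  id <- if (by_weekday) "unequal_weekdays_distribution" else "unequal_days_distribution"
  dt <- daily_totals(ctx)
  if (by_weekday) {
    wd <- format(dt$date, "%u")
    if (length(unique(wd)) < 2) {
      return(hyp_state(id, "NA", "required context missing: at least 2 distinct weekdays"))
    }
  } else if (nrow(dt) < 2) {
    return(hyp_state(id, "NA", "required context missing: at least 2 days of data"))
  }
  offenders <- list()
  for (type in c("blood_glucose", "carbohydrates", "insulin", "physical_activity")) {
    counts <- if (type == "insulin") {
      dt$n_insulin_bolus + dt$n_insulin_basal
    } else {
      dt[[paste0("n_", type)]]
    }
    if (sum(counts) == 0) next  # absence is the missing-type family's job
    if (by_weekday) {
      counts <- as.numeric(tapply(counts, format(dt$date, "%u"), sum))
    }
    disp <- dispersion_of(counts, cfg$dispersion_stat)
    allowed <- cfg$distribution_tolerance * mean(counts)
    if (exceeds_tolerance(disp, allowed)) {
      offenders[[length(offenders) + 1]] <-
        list(type = type, observed = disp, allowed = allowed)
    }
  }
  hit <- length(offenders) > 0
  hyp_state(id, if (hit) "TRUE" else "FALSE",
            if (hit) sprintf("registrations unevenly distributed (e.g. %s: dispersion %s allowed %s)",
                             gsub("_", " ", offenders[[1]]$type),
                             fmt_num(offenders[[1]]$observed),
                             fmt_num(offenders[[1]]$allowed))
            else "registration counts are evenly distributed",
            list(offenders = offenders,
                 recommendation = if (hit) "Try to spread registrations evenly across days so trends are not biased by your weekly routine." else NULL))
}

#' Check the distribution of registrations across days
#'
#' Per data type, TRUE when the dispersion (standard deviation by default) of
#' per-day registration counts exceeds the tolerated fraction (default 20%)
#' of the mean daily count.
#'
#' @param ctx a `gr_context`.
#' @return a `gr_result`.
#' @export
check_day_distribution <- function(ctx) rel_distribution(ctx, by_weekday = FALSE)

#' Check the distribution of registrations across weekdays
#'
#' Same principle as [check_day_distribution()] with counts aggregated per
#' weekday (Monday, Tuesday, ...), guarding against lifestyle-driven
#' registration patterns.
#'
#' @param ctx a `gr_context`.
#' @return a `gr_result`.
#' @export
check_weekday_distribution <- function(ctx) rel_distribution(ctx, by_weekday = TRUE)

rel_source_hba1c <- function(ctx) {
  calc <- estimate_hba1c(regs_of(ctx, "blood_glucose")$value)
  ref <- ctx$lab$hba1c
  dev <- abs(calc - ref) / ref
  hit <- exceeds_tolerance(dev, ctx$config$hba1c_tolerance)
  hyp_state("source_inconsistency_hba1c", if (hit) "TRUE" else "FALSE",
            sprintf("HbA1c estimated from self-measurements is %s%% vs laboratory %s%% (deviation %s%%, tolerance %s%%)",
                    fmt_num(calc), fmt_num(ref), fmt_num(100 * dev),
                    fmt_num(100 * ctx$config$hba1c_tolerance)),
            list(calculated = calc, reference = ref, deviation = dev,
                 recommendation = if (hit) "The glucose diary disagrees with the laboratory HbA1c; some measurements may be missing or inaccurate." else NULL))
}

rel_source_isf <- function(ctx) {
  calc <- isf_rule(mean_tdd(ctx), uses_rapid(ctx))
  ref <- ctx$profile$reported_isf
  dev <- abs(calc - ref) / ref
  hit <- exceeds_tolerance(dev, ctx$config$source_tolerance)
  hyp_state("source_inconsistency_isf", if (hit) "TRUE" else "FALSE",
            sprintf("calculated insulin sensitivity %s mmol/L per U vs reported %s (deviation %s%%, tolerance %s%%)",
                    fmt_num(calc), fmt_num(ref), fmt_num(100 * dev),
                    fmt_num(100 * ctx$config$source_tolerance)),
            list(calculated = calc, reference = ref, deviation = dev,
                 recommendation = if (hit) "Your reported insulin sensitivity factor disagrees with the one derived from your total daily doses; consider reviewing it." else NULL))
}

rel_source_icr <- function(ctx) {
  calc <- icr_rule(mean_tdd(ctx), uses_rapid(ctx))
  ref <- ctx$profile$reported_icr
  dev <- abs(calc - ref) / ref
  hit <- exceeds_tolerance(dev, ctx$config$source_tolerance)
  hyp_state("source_inconsistency_icr", if (hit) "TRUE" else "FALSE",
            sprintf("calculated insulin-to-carbohydrate ratio %s g per U vs reported %s (deviation %s%%, tolerance %s%%)",
                    fmt_num(calc), fmt_num(ref), fmt_num(100 * dev),
                    fmt_num(100 * ctx$config$source_tolerance)),
            list(calculated = calc, reference = ref, deviation = dev,
                 recommendation = if (hit) "Your reported insulin-to-carbohydrate ratio disagrees with the one derived from your diary; consider reviewing it." else NULL))
}

#' Check consistency between data sources
#'
#' Three sub-hypotheses compare a module-calculated value with an external
#' reference, allowing 5% relative deviation: estimated vs laboratory HbA1c,
#' 1500/1800-rule vs reported insulin sensitivity, and 500/450-rule vs
#' reported insulin-to-carbohydrate ratio. NA when either side is missing.
#'
#' @param ctx a `gr_context`.
#' @return named list of three `gr_result` objects.
#' @export
check_source_inconsistencies <- function(ctx) {
  out <- list()
  specs <- list(source_inconsistency_hba1c = rel_source_hba1c,
                source_inconsistency_isf = rel_source_isf,
                source_inconsistency_icr = rel_source_icr)
  for (id in names(specs)) {
    miss <- check_requires(ctx, hypothesis_requires(id))
    out[[id]] <- if (!is.null(miss)) {
      hyp_state(id, "NA", paste0("required context missing: ", miss))
    } else {
      specs[[id]](ctx)
    }
  }
  out
}

#' Evaluate the whole data-reliability family
#'
#' @param ctx a `gr_context`.
#' @return named list of 13 `gr_result` objects in canonical order.
#' @export
evaluate_reliability <- function(ctx) {
  c(check_missing_types(ctx),
    check_error_values(ctx),
    list(not_enough_registrations = check_registration_counts(ctx),
         unequal_days_distribution = check_day_distribution(ctx),
         unequal_weekdays_distribution = check_weekday_distribution(ctx)),
    check_source_inconsistencies(ctx))
}

#' Grade data reliability on the 0-50 trust scale
#'
#' The trust level starts at the scale maximum (50, full trust) and is
#' reduced by the configured grade of every reliability sub-hypothesis
#' evaluated TRUE, clamped at 0. The numeric grade is API-only and excluded
#' from rendered consultation reports.
#'
#' @param ctx a `gr_context`.
#' @param results named list of reliability results, e.g. from
#'   [evaluate_reliability()].
#' @return list of class `gr_reliability` with `trust_level`, `violations`
#'   and `recommendations`.
#' @export
grade_reliability <- function(ctx, results) {
  cfg <- ctx$config
  violations <- list()
  recommendations <- character(0)
  total <- 0
  for (r in results) {
    if (r$state != "TRUE") next
    g <- cfg$grades[[r$hypothesis_id]]
    if (is.null(g)) g <- 0
    total <- total + g
    violations[[length(violations) + 1]] <-
      list(hypothesis_id = r$hypothesis_id, grade = g,
           evidence = r$justification)
    rec <- r$evidence$recommendation
    if (!is.null(rec)) recommendations <- c(recommendations, rec)
  }
  trust <- max(0, min(cfg$trust_max, cfg$trust_max - total))
  structure(list(trust_level = trust, violations = violations,
                 recommendations = recommendations),
            class = "gr_reliability")
}

#' @export
print.gr_reliability <- function(x, ...) {
  cat(sprintf("<reliability> trust %d/50, %d violation(s)\n",
              as.integer(x$trust_level), length(x$violations)))
  for (v in x$violations) {
    cat(sprintf("  -%d %s\n", as.integer(v$grade), v$hypothesis_id))
  }
  invisible(x)
}
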