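# Core domain model: registrations, patient profile, laboratory context and
# the "current context" every rule reads from.

#' Recognised registration data types
#' @export
DATA_TYPES <- c("blood_glucose", "insulin_bolus", "insulin_basal",
                "carbohydrates", "physical_activity",
                "blood_pressure_systolic", "blood_pressure_diastolic",
                "weight", "external_factor")

ACTIVITY_KINDS <- c("minutes", "steps", "mets", "tag")
ACTIVITY_TAGS <- c("light", "moderate", "extreme")
FACTOR_TAGS <- c("menstruation", "polypharmacy", "sickness")

#' Parse a diary timestamp
#'
#' Timestamps are local clock time at minute resolution; no timezone
#' arithmetic is performed (internally everything is carried as UTC POSIXct).
#'
#' @param x character `"YYYY-MM-DD HH:MM"` (seconds tolerated and dropped),
#'   `Date`, or `POSIXct`.
#' @return POSIXct, minute resolution.
#' @export
as_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) {
    ts <- as.POSIXct(format(x, "%Y-%m-%d %H:%M", tz = "UTC"), tz = "UTC")
    return(ts)
  }
  ts <- as.POSIXct(x, tz = "UTC", tryFormats = c("%Y-%m-%d %H:%M:%OS",
                                                 "%Y-%m-%d %H:%M",
                                                 "%Y-%m-%dT%H:%M:%OS",
                                                 "%Y-%m-%dT%H:%M",
                                                 "%Y-%m-%d"))
  as.POSIXct(trunc(ts, "mins"))
}

#' Create a single diary registration
#'
#' One time-stamped typed measurement with its source. Activity fields are
#' only meaningful for `physical_activity` rows and `factor_tag` only for
#' `external_factor` rows.
#'
#' @param timestamp anything `as_timestamp()` accepts.
#' @param data_type one of [DATA_TYPES].
#' @param value numeric; units per type (mmol/L, U, g, mmHg, kg). For
#'   tag-only activity and external factors a placeholder 1 is stored.
#' @param activity_kind `"minutes"`, `"steps"`, `"mets"` or `"tag"`.
#' @param activity_tag `"light"`, `"moderate"` or `"extreme"` when
#'   `activity_kind = "tag"`.
#' @param factor_tag free text for external factors, e.g. `"menstruation"`.
#' @param source data-source identifier (device or app name).
#' @param manual logical: registered by hand (`TRUE`) or sensor-automatic.
#' @return A one-row data.frame in the canonical registration layout.
#' @examples
#' registration("2024-03-01 07:30", "blood_glucose", 5.6)
#' registration("2024-03-01 16:00", "physical_activity",
#'               activity_kind = "steps", value = 4200)
#' @export
registration <- function(timestamp, data_type, value = NA_real_,
                         activity_kind = NA_character_,
                         activity_tag = NA_character_,
                         factor_tag = NA_character_,
                         source = "manual_entry", manual = TRUE) {
  if (data_type == "physical_activity" && !is.na(activity_kind) &&
      activity_kind == "tag" && is.na(value)) {
    value <- 1
  }
  if (data_type == "external_factor" && is.na(value)) value <- 1
  data.frame(
    timestamp = as_timestamp(timestamp),
    data_type = as.character(data_type),
    value = as.numeric(value),
    activity_kind = as.character(activity_kind),
    activity_tag = as.character(activity_tag),
    factor_tag = as.character(factor_tag),
    source = as.character(source),
    manual = as.logical(manual),
    stringsAsFactors = FALSE
  )
}

#' Bind registrations into one diary table
#'
#' @param ... one-row data.frames from [registration()] or compatible frames.
#' @return A registration data.frame.
#' @export
registrations <- function(...) {
  do.call(rbind, list(...))
}

empty_registrations <- function() {
  registration("2000-01-01 00:00", "blood_glucose", 5)[0, ]
}

#' Validate a registration table
#'
#' @param regs registration data.frame.
#' @return character vector of problems (empty when valid), each naming the
#'   offending row index.
#' @export
validate_registrations <- function(regs) {
  problems <- character(0)
  needed <- c("timestamp", "data_type", "value", "activity_kind",
              "activity_tag", "factor_tag", "source", "manual")
  missing_cols <- setdiff(needed, names(regs))
  if (length(missing_cols)) {
    return(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  for (i in seq_len(nrow(regs))) {
    r <- regs[i, ]
    if (is.na(r$data_type) || !r$data_type %in% DATA_TYPES) {
      problems <- c(problems, sprintf("row %d: unknown data_type '%s'", i, r$data_type))
      next
    }
    if (!is.finite(r$value)) {
      problems <- c(problems, sprintf("row %d: non-finite value for %s", i, r$data_type))
    }
    if (r$data_type == "physical_activity") {
      if (is.na(r$activity_kind) || !r$activity_kind %in% ACTIVITY_KINDS) {
        problems <- c(problems, sprintf("row %d: physical_activity needs activity_kind in {%s}",
                                        i, paste(ACTIVITY_KINDS, collapse = ", ")))
      } else if (r$activity_kind == "tag" &&
                 (is.na(r$activity_tag) || !r$activity_tag %in% ACTIVITY_TAGS)) {
        problems <- c(problems, sprintf("row %d: activity tag must be one of {%s}",
                                        i, paste(ACTIVITY_TAGS, collapse = ", ")))
      }
    } else {
      if (!is.na(r$activity_kind) || !is.na(r$activity_tag)) {
        problems <- c(problems, sprintf("row %d: activity fields only allowed for physical_activity", i))
      }
      if (r$data_type == "external_factor") {
        if (is.na(r$factor_tag) || !nzchar(r$factor_tag)) {
          problems <- c(problems, sprintf("row %d: external_factor needs factor_tag", i))
        }
      } else if (!is.na(r$factor_tag)) {
        problems <- c(problems, sprintf("row %d: factor_tag only allowed for external_factor", i))
      }
    }
  }
  problems
}

#' Patient profile
#'
#' Per-patient parameters that feed the rules: reported insulin sensitivity
#' factor (ISF, mmol/L per U), reported insulin-to-carbohydrate ratio (I:C,
#' g per U), carbohydrate absorption rate (g/h), insulin action duration
#' (DIA, hours), mealtime windows and a low-carb-diet flag.
#'
#' @param diabetes_type 1 or 2.
#' @param uses_insulin logical.
#' @param age,sex optional demographics.
#' @param reported_isf optional patient-reported ISF (mmol/L per U).
#' @param reported_icr optional patient-reported I:C (g per U).
#' @param carb_absorption_rate optional g per hour; required for
#'   carbohydrates-on-board estimates.
#' @param low_carb_diet logical; intake-recommendation checks are skipped when
#'   `TRUE`.
#' @param mealtime_windows named list of `c(start, end)` clock times
#'   (`"HH:MM"`); non-overlapping. Defaults: breakfast 06:00-10:00,
#'   lunch 11:00-13:00, dinner 17:00-20:00. Intakes outside every window are
#'   snacks.
#' @param dia insulin action duration in hours (> 0).
#' @return list of class `gr_profile`.
#' @export
patient_profile <- function(diabetes_type = 1, uses_insulin = TRUE,
                            age = NULL, sex = NULL,
                            reported_isf = NULL, reported_icr = NULL,
                            carb_absorption_rate = NULL,
                            low_carb_diet = FALSE,
                            mealtime_windows = NULL,
                            dia = 4) {
  if (is.null(mealtime_windows)) {
    mealtime_windows <- list(breakfast = c("06:00", "10:00"),
                             lunch = c("11:00", "13:00"),
                             dinner = c("17:00", "20:00"))
  }
  stopifnot(diabetes_type %in% c(1, 2), is.logical(uses_insulin), dia > 0)
  mins <- lapply(mealtime_windows, function(w) vapply(w, clock_minutes, numeric(1)))
  if (length(mins) > 1) {
    ord <- order(vapply(mins, `[`, numeric(1), 1))
    m <- mins[ord]
    for (k in seq_len(length(m) - 1)) {
      if (m[[k]][2] > m[[k + 1]][1]) stop("mealtime windows must not overlap")
    }
  }
  structure(list(diabetes_type = diabetes_type, uses_insulin = uses_insulin,
                 age = age, sex = sex, reported_isf = reported_isf,
                 reported_icr = reported_icr,
                 carb_absorption_rate = carb_absorption_rate,
                 low_carb_diet = low_carb_diet,
                 mealtime_windows = mealtime_windows, dia = dia),
            class = "gr_profile")
}

#' Laboratory context
#'
#' @param hba1c laboratory glycated hemoglobin in percent, in (3, 20), or NULL.
#' @param hba1c_date optional sampling date.
#' @return list of class `gr_lab`.
#' @export
lab_context <- function(hba1c = NULL, hba1c_date = NULL) {
  if (!is.null(hba1c)) {
    stopifnot(is.finite(hba1c), hba1c > 3, hba1c < 20)
  }
  structure(list(hba1c = hba1c, hba1c_date = hba1c_date), class = "gr_lab")
}

# minutes after midnight for "HH:MM"
clock_minutes <- function(hhmm) {
  p <- as.integer(strsplit(hhmm, ":", fixed = TRUE)[[1]])
  p[1] * 60 + p[2]
}

#' Build the current context
#'
#' Instantiates the in-memory situation every rule reads: the validated,
#' time-sorted diary, the patient profile, the laboratory context and the
#' threshold configuration. Duplicate `(timestamp, data_type, source)` rows
#' (typical of device re-syncs) are collapsed to one with a warning.
#'
#' @param regs registration data.frame.
#' @param profile a [patient_profile()].
#' @param lab a [lab_context()].
#' @param config a [threshold_config()].
#' @param allow_empty permit an empty diary (all reliability checks then
#'   resolve to NA or TRUE as their activation rules dictate).
#' @return list of class `gr_context` with fields `registrations`, `profile`,
#'   `lab`, `config`, `period_start`, `period_end`, `system_generated`.
#' @examples
#' regs <- registrations(
#'   registration("2024-03-01 07:30", "blood_glucose", 5.6),
#'   registration("2024-03-01 12:05", "carbohydrates", 60))
#' ctx <- build_context(regs)
#' ctx$period_start
#' @export
build_context <- function(regs, profile = patient_profile(),
                          lab = lab_context(), config = threshold_config(),
                          allow_empty = FALSE) {
  if (is.null(regs) || nrow(regs) == 0) {
    if (!allow_empty) stop("empty diary; pass allow_empty = TRUE to permit it")
    regs <- empty_registrations()
    now <- as_timestamp("2000-01-01 00:00")
    ctx <- structure(list(registrations = regs, profile = profile, lab = lab,
                          config = config, period_start = now, period_end = now,
                          system_generated = list()), class = "gr_context")
    return(ctx)
  }
  problems <- validate_registrations(regs)
  if (length(problems)) {
    stop("invalid registrations:\n  ", paste(problems, collapse = "\n  "))
  }
  key <- paste(format(regs$timestamp, "%Y-%m-%d %H:%M"), regs$data_type, regs$source)
  if (anyDuplicated(key)) {
    n <- sum(duplicated(key))
    warning(sprintf("collapsed %d duplicate registration(s) with identical (timestamp, data_type, source)", n))
    regs <- regs[!duplicated(key), , drop = FALSE]
  }
  regs <- regs[order(regs$timestamp, regs$data_type, regs$source), , drop = FALSE]
  rownames(regs) <- NULL
  structure(list(registrations = regs, profile = profile, lab = lab,
                 config = config,
                 period_start = min(regs$timestamp),
                 period_end = max(regs$timestamp),
                 system_generated = list()),
            class = "gr_context")
}

#' @export
print.gr_context <- function(x, ...) {
  cat(sprintf("<glucoreason context> %d registrations, %s .. %s\n",
              nrow(x$registrations),
              format(x$period_start, "%Y-%m-%d %H:%M"),
              format(x$period_end, "%Y-%m-%d %H:%M")))
  tab <- table(x$registrations$data_type)
  if (length(tab)) {
    cat("  ", paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Slice a lookback window out of the context
#'
#' Windows are half-open: end-inclusive, start-exclusive, so a registration
#' exactly `lookback` hours before `end` is excluded. One consistent
#' convention serves every "up to N hours prior" rule.
#'
#' @param ctx a `gr_context`.
#' @param data_type one of [DATA_TYPES].
#' @param end POSIXct window end.
#' @param lookback_hours window length in hours (> 0; `Inf` allowed).
#' @return registrations with `end - lookback < timestamp <= end`, in order.
#' @export
slice_window <- function(ctx, data_type, end, lookback_hours) {
  stopifnot(lookback_hours > 0)
  r <- ctx$registrations
  r <- r[r$data_type == data_type, , drop = FALSE]
  if (nrow(r) == 0) return(r)
  el <- as.numeric(difftime(end, r$timestamp, units = "hours"))
  r[el >= 0 & el < lookback_hours, , drop = FALSE]
}

regs_of <- function(ctx, types) {
  ctx$registrations[ctx$registrations$data_type %in% types, , drop = FALSE]
}

period_days <- function(ctx) {
  seq(as.Date(ctx$period_start), as.Date(ctx$period_end), by = "day")
}
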