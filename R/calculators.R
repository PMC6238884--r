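# Medical formula layer: estimated HbA1c, the 1500/1800 and 500/450 rules,
# insulin on board, carbohydrates on board, daily totals.

#' Estimate HbA1c from self-measured blood glucose
#'
#' Inverts the linear estimated-average-glucose relation
#' `eAG (mg/dL) = 28.7 * A1C - 46.7`, so
#' `A1C% = (mean_BG * 18.016 + 46.7) / 28.7` with the mean taken over the
#' supplied series in mmol/L.
#'
#' @param bg_series numeric vector of blood glucose values, mmol/L.
#' @return estimated HbA1c in percent, or `NA_real_` for an empty series
#'   (the NA propagates to the hypothesis level rather than erroring).
#' @examples
#' estimate_hba1c(8.561)   # ~7.0 %
#' @export
estimate_hba1c <- function(bg_series) {
  bg_series <- bg_series[is.finite(bg_series)]
  if (length(bg_series) == 0) return(NA_real_)
  (mean(bg_series) * 18.016 + 46.7) / 28.7
}

#' Mean glucose implied by an HbA1c (forward relation)
#'
#' @param a1c HbA1c percent.
#' @return mean blood glucose, mmol/L.
#' @export
eag_from_hba1c <- function(a1c) {
  (28.7 * a1c - 46.7) / 18.016
}

#' Insulin sensitivity factor via the 1500/1800 rule
#'
#' @param tdd total daily insulin dose, U.
#' @param rapid_acting use 1800 (rapid) or 1500 (regular).
#' @return ISF in mmol/L per U, or `NA_real_` when `tdd <= 0` or missing.
#' @examples
#' isf_rule(40)          # 1800/40 mg/dL/U -> ~2.498 mmol/L/U
#' @export
isf_rule <- function(tdd, rapid_acting = TRUE) {
  if (!length(tdd) || !is.finite(tdd) || tdd <= 0) return(NA_real_)
  ((if (rapid_acting) 1800 else 1500) / tdd) / 18.016
}

#' Insulin-to-carbohydrate ratio via the 500/450 rule
#'
#' @inheritParams isf_rule
#' @return I:C in grams per U, or `NA_real_` when `tdd <= 0` or missing.
#' @export
icr_rule <- function(tdd, rapid_acting = TRUE) {
  if (!length(tdd) || !is.finite(tdd) || tdd <= 0) return(NA_real_)
  (if (rapid_acting) 500 else 450) / tdd
}

# remaining active fraction of a bolus after `elapsed` hours
iob_remaining <- function(elapsed, dia, curve = "linear", peak_minutes = 75) {
  if (curve == "linear") {
    return(pmax(0, 1 - elapsed / dia))
  }
  # bilinear: activity rises to a peak then falls to zero at DIA; the
  # remaining fraction is 1 minus the integrated (triangular) activity
  tp <- min(peak_minutes / 60, dia * 0.99)
  out <- numeric(length(elapsed))
  up <- elapsed <= tp & elapsed >= 0
  mid <- elapsed > tp & elapsed < dia
  out[elapsed < 0] <- 1
  out[up] <- 1 - elapsed[up]^2 / (tp * dia)
  out[mid] <- (dia - elapsed[mid])^2 / ((dia - tp) * dia)
  out
}

#' Insulin on board at a time point
#'
#' Sum over past boluses of dose times a remaining-activity fraction that is
#' 1 at injection, 0 at or past the insulin action duration (DIA) and
#' non-increasing in between. The default curve is linear decay; a bilinear
#' curve (activity peak at 75 minutes) is available behind the same contract.
#'
#' @param t POSIXct time point.
#' @param boluses data.frame with columns `timestamp` and `value` (U), or a
#'   registration table filtered to `insulin_bolus`.
#' @param dia insulin action duration, hours.
#' @param curve `"linear"` or `"bilinear"`.
#' @param peak_minutes bilinear activity peak.
#' @return active insulin, U (>= 0).
#' @export
iob_at <- function(t, boluses, dia, curve = "linear", peak_minutes = 75) {
  stopifnot(dia > 0)
  if (is.null(boluses) || nrow(boluses) == 0) return(0)
  el <- as.numeric(difftime(t, boluses$timestamp, units = "hours"))
  keep <- el >= 0
  if (!any(keep)) return(0)
  sum(boluses$value[keep] * iob_remaining(el[keep], dia, curve, peak_minutes))
}

#' Carbohydrates on board at a time point
#'
#' Each intake is absorbed at the patient-reported constant rate; what is not
#' yet absorbed is on board. Without a reported absorption rate the quantity
#' is undefined and `NA` propagates to the hypothesis level.
#'
#' @param t POSIXct time point.
#' @param intakes data.frame with `timestamp` and `value` (g).
#' @param absorption_rate grams per hour (> 0), or NULL/NA.
#' @return grams on board (>= 0), or `NA_real_` when the rate is missing.
#' @export
cob_at <- function(t, intakes, absorption_rate) {
  if (is.null(absorption_rate) || !is.finite(absorption_rate)) return(NA_real_)
  stopifnot(absorption_rate > 0)
  if (is.null(intakes) || nrow(intakes) == 0) return(0)
  el <- as.numeric(difftime(t, intakes$timestamp, units = "hours"))
  keep <- el >= 0
  if (!any(keep)) return(0)
  sum(pmax(0, intakes$value[keep] - absorption_rate * el[keep]))
}

sample_grid <- function(ctx, grid_minutes) {
  if (ctx$period_end <= ctx$period_start) return(ctx$period_start)
  seq(ctx$period_start, ctx$period_end, by = grid_minutes * 60)
}

#' Average insulin on board over the diary period
#'
#' Mean of [iob_at()] sampled on a regular grid (default 5 minutes) over
#' `[period_start, period_end]`.
#'
#' @param ctx a `gr_context`.
#' @param grid_minutes sampling step.
#' @return mean IOB in U; 0 with no boluses; `NA_real_` on an empty period.
#' @export
average_iob <- function(ctx, grid_minutes = ctx$config$iob_grid_minutes) {
  if (is.null(ctx$period_start)) return(NA_real_)
  boluses <- regs_of(ctx, "insulin_bolus")
  if (nrow(boluses) == 0) return(0)
  grid <- sample_grid(ctx, grid_minutes)
  vals <- vapply(grid, iob_at, numeric(1), boluses = boluses,
                 dia = ctx$profile$dia, curve = ctx$config$iob_curve,
                 peak_minutes = ctx$config$iob_peak_minutes)
  mean(vals)
}

#' Average carbohydrates on board over the diary period
#'
#' @inheritParams average_iob
#' @return mean COB in g; `NA_real_` when the absorption rate is missing.
#' @export
average_cob <- function(ctx, grid_minutes = ctx$config$iob_grid_minutes) {
  rate <- ctx$profile$carb_absorption_rate
  if (is.null(rate) || !is.finite(rate)) return(NA_real_)
  intakes <- regs_of(ctx, "carbohydrates")
  if (nrow(intakes) == 0) return(0)
  grid <- sample_grid(ctx, grid_minutes)
  vals <- vapply(grid, cob_at, numeric(1), intakes = intakes,
                 absorption_rate = rate)
  mean(vals)
}

#' Daily totals and registration counts
#'
#' One row per calendar day in the period, including zero-count days:
#' total rapid-acting (bolus) insulin, total basal insulin, total
#' carbohydrates, and a registration count per data type (`n_<type>`).
#'
#' @param ctx a `gr_context`.
#' @return data.frame with one row per day.
#' @export
daily_totals <- function(ctx) {
  days <- period_days(ctx)
  regs <- ctx$registrations
  rd <- as.Date(regs$timestamp)
  out <- data.frame(date = days)
  sum_by_day <- function(type) {
    vapply(days, function(d) {
      sum(regs$value[regs$data_type == type & rd == d])
    }, numeric(1))
  }
  out$total_rapid_insulin <- sum_by_day("insulin_bolus")
  out$total_basal_insulin <- sum_by_day("insulin_basal")
  out$total_carbs <- sum_by_day("carbohydrates")
  for (type in DATA_TYPES) {
    out[[paste0("n_", type)]] <- vapply(days, function(d) {
      sum(regs$data_type == type & rd == d)
    }, numeric(1))
  }
  out
}

# mean total daily insulin dose over days with any insulin registered;
# NA when the diary holds no insulin
mean_tdd <- function(ctx) {
  dt <- daily_totals(ctx)
  tot <- dt$total_rapid_insulin + dt$total_basal_insulin
  tot <- tot[tot > 0]
  if (length(tot) == 0) return(NA_real_)
  mean(tot)
}

# rapid-acting if any bolus registrations are present
uses_rapid <- function(ctx) {
  nrow(regs_of(ctx, "insulin_bolus")) > 0
}

# ISF fallback chain: patient-reported, else 1500/1800 from mean TDD
effective_isf <- function(ctx) {
  if (!is.null(ctx$profile$reported_isf)) return(ctx$profile$reported_isf)
  isf_rule(mean_tdd(ctx), uses_rapid(ctx))
}

# I:C fallback chain: reported, else same-day totals, else 500/450
effective_icr <- function(ctx, day = NULL) {
  if (!is.null(ctx$profile$reported_icr)) return(ctx$profile$reported_icr)
  if (!is.null(day)) {
    dt <- daily_totals(ctx)
    row <- dt[dt$date == as.Date(day), , drop = FALSE]
    if (nrow(row) == 1 && row$total_rapid_insulin > 0 && row$total_carbs > 0) {
      return(row$total_carbs / row$total_rapid_insulin)
    }
  }
  icr_rule(mean_tdd(ctx), uses_rapid(ctx))
}
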