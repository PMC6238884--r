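# Shared helpers: quick context builders, a seeded random diary generator
# for property tests, and an independent brute-force evaluator that walks
# the hypothesis tree directly (no engine, no plans).

quick_ctx <- function(..., profile = patient_profile(), lab = lab_context(),
                      config = threshold_config(), allow_empty = FALSE) {
  build_context(registrations(...), profile, lab, config,
                allow_empty = allow_empty)
}

bg_reg <- function(ts, v, ...) registration(ts, "blood_glucose", v, ...)

# small random diary (1-3 days) exercising every rule family
random_context <- function(seed) {
  set.seed(seed)
  days <- sample(1:3, 1)
  start <- as.Date("2024-03-04")
  rows <- list()
  add <- function(r) rows[[length(rows) + 1]] <<- r
  n_out <- 0
  for (d in seq_len(days)) {
    date <- start + d - 1
    for (i in seq_len(sample(2:5, 1))) {
      tm <- sprintf("%02d:%02d", sample(6:22, 1), sample(0:59, 1))
      v <- round(runif(1, 4.2, 8.8), 1)
      if (n_out < 2 && runif(1) < 0.25) {
        v <- if (runif(1) < 0.5) round(runif(1, 2.0, 3.4), 1) else round(runif(1, 14.0, 18.0), 1)
        n_out <- n_out + 1
      }
      add(bg_reg(paste(date, tm), v))
    }
    for (i in seq_len(sample(0:3, 1))) {
      add(registration(paste(date, sprintf("%02d:%02d", sample(7:21, 1), sample(0:59, 1))),
                       "carbohydrates", sample(15:90, 1)))
    }
    for (i in seq_len(sample(0:2, 1))) {
      add(registration(paste(date, sprintf("%02d:%02d", sample(7:21, 1), sample(0:59, 1))),
                       "insulin_bolus", sample(2:8, 1)))
    }
    if (runif(1) < 0.6) add(registration(paste(date, "22:00"), "insulin_basal", 18))
    if (runif(1) < 0.5) {
      kind <- sample(c("minutes", "steps", "mets", "tag"), 1)
      add(registration(paste(date, sprintf("%02d:00", sample(8:20, 1))), "physical_activity",
                       value = switch(kind, minutes = sample(20:90, 1),
                                      steps = sample(1000:6000, 1),
                                      mets = sample(2:9, 1), tag = NA_real_),
                       activity_kind = kind,
                       activity_tag = if (kind == "tag") sample(c("light", "moderate", "extreme"), 1)
                       else NA_character_))
    }
    if (runif(1) < 0.3) {
      add(registration(paste(date, "09:00"), "external_factor",
                       factor_tag = sample(c("menstruation", "sickness", "polypharmacy"), 1)))
    }
    if (runif(1) < 0.3) {
      ts <- paste(date, "10:00")
      add(registration(ts, "blood_pressure_systolic", sample(115:150, 1)))
      add(registration(ts, "blood_pressure_diastolic", sample(70:95, 1)))
    }
  }
  profile <- patient_profile(
    uses_insulin = runif(1) < 0.9,
    reported_isf = if (runif(1) < 0.4) round(runif(1, 1.5, 3.5), 2) else NULL,
    reported_icr = if (runif(1) < 0.4) round(runif(1, 8, 15), 1) else NULL,
    carb_absorption_rate = if (runif(1) < 0.5) 30 else NULL,
    low_carb_diet = runif(1) < 0.15)
  lab <- if (runif(1) < 0.4) lab_context(hba1c = round(runif(1, 4.5, 8), 1)) else lab_context()
  build_context(do.call(rbind, rows), profile, lab, threshold_config())
}

# brute-force walk of the hypothesis tree: reliability checks, detectors and
# per-event cause evaluators called directly, no plan machinery
oracle_walk <- function(ctx) {
  out <- list()
  push <- function(res, scope) {
    for (r in res) {
      out[[length(out) + 1]] <<- data.frame(hypothesis_id = r$hypothesis_id,
                                            scope = scope, state = r$state,
                                            stringsAsFactors = FALSE)
    }
  }
  push(evaluate_reliability(ctx), "dataset")
  has_bg <- any(ctx$registrations$data_type == "blood_glucose")
  gly <- if (has_bg) segment_glycemic_events(ctx) else list()
  for (kind in c("hyperglycemia", "hypoglycemia")) {
    evs <- Filter(function(e) e$kind == kind, gly)
    state <- if (!has_bg) "NA" else if (length(evs)) "TRUE" else "FALSE"
    out[[length(out) + 1]] <- data.frame(hypothesis_id = kind, scope = "dataset",
                                         state = state, stringsAsFactors = FALSE)
    for (i in seq_along(evs)) {
      scope <- paste0(kind, "_", i)
      res <- if (kind == "hyperglycemia") evaluate_hyper_causes(evs[[i]], ctx)
      else evaluate_hypo_causes(evs[[i]], ctx)
      push(res, scope)
    }
  }
  has_bp <- any(ctx$registrations$data_type %in%
                  c("blood_pressure_systolic", "blood_pressure_diastolic"))
  bp_evs <- if (has_bp) detect_bp_events(ctx) else list()
  out[[length(out) + 1]] <- data.frame(
    hypothesis_id = "high_blood_pressure", scope = "dataset",
    state = if (!has_bp) "NA" else if (length(bp_evs)) "TRUE" else "FALSE",
    stringsAsFactors = FALSE)
  for (i in seq_along(bp_evs)) {
    push(evaluate_bp_causes(bp_evs[[i]], ctx), paste0("high_bp_", i))
  }
  n_manual <- sum(ctx$registrations$manual %in% TRUE)
  sl_evs <- if (n_manual >= 2) detect_short_sleep(ctx) else list()
  out[[length(out) + 1]] <- data.frame(
    hypothesis_id = "short_sleep", scope = "dataset",
    state = if (n_manual < 2) "NA" else if (length(sl_evs)) "TRUE" else "FALSE",
    stringsAsFactors = FALSE)
  df <- do.call(rbind, out)
  df[order(df$hypothesis_id, df$scope, df$state), , drop = FALSE]
}

engine_multiset <- function(rr) {
  df <- run_results_df(rr)[, c("hypothesis_id", "scope", "state")]
  df <- df[order(df$hypothesis_id, df$scope, df$state), , drop = FALSE]
  rownames(df) <- NULL
  df
}
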