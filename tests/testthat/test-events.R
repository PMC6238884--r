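test_that("readings classify as fasting, before a meal, or other", {
  ctx <- quick_ctx(registration("2024-02-29 22:00", "carbohydrates", 20),
                   registration("2024-03-01 12:00", "carbohydrates", 60),
                   registration("2024-03-01 13:30", "carbohydrates", 10),
                   bg_reg("2024-03-01 07:00", 5.5))
  expect_equal(classify_reading(as_timestamp("2024-03-01 07:00"), ctx), "fasting")
  expect_equal(classify_reading(as_timestamp("2024-03-01 11:45"), ctx), "before_meal")
  expect_equal(classify_reading(as_timestamp("2024-03-01 15:00"), ctx), "other")
})

test_that("glycemic thresholds are strict and context-dependent", {
  mk <- function(v) quick_ctx(registration("2024-03-01 12:00", "carbohydrates", 50),
                              bg_reg("2024-03-01 15:00", v))
  expect_length(segment_glycemic_events(mk(14.0)), 1)
  expect_length(segment_glycemic_events(mk(13.9)), 0)
  expect_length(segment_glycemic_events(mk(3.4)), 1)
  expect_length(segment_glycemic_events(mk(3.5)), 0)
  # fasting reading: the lower hyper bound applies
  fast <- quick_ctx(bg_reg("2024-03-01 07:00", 9.1))
  expect_length(segment_glycemic_events(fast), 1)
  expect_length(segment_glycemic_events(quick_ctx(bg_reg("2024-03-01 07:00", 9.0))), 0)
})

test_that("consecutive out-of-range readings merge into one event with the extreme as reference", {
  ctx <- quick_ctx(registration("2024-03-01 09:00", "carbohydrates", 50),
                   bg_reg("2024-03-01 13:00", 14.2),
                   bg_reg("2024-03-01 14:30", 15.1),
                   bg_reg("2024-03-01 16:00", 14.0))
  evs <- segment_glycemic_events(ctx)
  expect_length(evs, 1)
  expect_equal(evs[[1]]$reference_time, as_timestamp("2024-03-01 14:30"))
  expect_equal(evs[[1]]$extreme_value, 15.1)
  expect_equal(evs[[1]]$n_readings, 3)
})

test_that("events split on an in-range reading and on the maximum duration", {
  ctx <- quick_ctx(registration("2024-03-01 06:00", "carbohydrates", 50),
                   bg_reg("2024-03-01 10:00", 14.2),
                   bg_reg("2024-03-01 12:00", 6.0),
                   bg_reg("2024-03-01 14:00", 14.8))
  expect_length(segment_glycemic_events(ctx), 2)
  long <- quick_ctx(registration("2024-03-01 06:00", "carbohydrates", 50),
                    bg_reg("2024-03-01 08:00", 14.2),
                    bg_reg("2024-03-01 11:00", 14.5),
                    bg_reg("2024-03-01 15:30", 14.8))  # 7.5 h after the first
  expect_length(segment_glycemic_events(long), 2)
})

test_that("every out-of-range reading belongs to exactly one event", {
  for (seed in 1:25) {
    ctx <- suppressWarnings(random_context(seed))
    evs <- segment_glycemic_events(ctx)
    bg <- ctx$registrations[ctx$registrations$data_type == "blood_glucose", ]
    out_of_range <- 0
    for (i in seq_len(nrow(bg))) {
      cls <- classify_reading(bg$timestamp[i], ctx)
      hyper_thr <- if (cls %in% c("fasting", "before_meal")) 9 else 13.9
      hypo_thr <- if (cls == "fasting") 4 else 3.5
      if (bg$value[i] > hyper_thr || bg$value[i] < hypo_thr) out_of_range <- out_of_range + 1
    }
    expect_equal(sum(vapply(evs, `[[`, integer(1), "n_readings")), out_of_range)
  }
})

test_that("blood pressure events follow the strict 140/90 OR rule", {
  mk <- function(sys, dia) quick_ctx(
    registration("2024-03-01 10:00", "blood_pressure_systolic", sys),
    registration("2024-03-01 10:00", "blood_pressure_diastolic", dia))
  expect_length(detect_bp_events(mk(141, 80)), 1)
  expect_length(detect_bp_events(mk(140, 90)), 0)
  expect_length(detect_bp_events(mk(135, 91)), 1)
  # brute-force truth table on a grid
  for (sys in c(130, 140, 141, 155)) {
    for (dia in c(80, 90, 91, 100)) {
      expect_equal(length(detect_bp_events(mk(sys, dia))), as.integer(sys > 140 || dia > 90))
    }
  }
})

test_that("short sleep uses the manual-registration gap around the night anchor", {
  mk <- function(t1, t2, auto_overnight = FALSE) {
    regs <- registrations(bg_reg("2024-03-01 08:00", 5.5),
                          bg_reg(t1, 5.6), bg_reg(t2, 5.4),
                          bg_reg("2024-03-02 21:00", 5.5))
    if (auto_overnight) {
      cgm <- do.call(rbind, lapply(0:6, function(h) {
        registration(sprintf("2024-03-02 0%d:00", h), "blood_glucose", 5.5,
                     source = "cgm", manual = FALSE)
      }))
      regs <- rbind(regs, cgm)
    }
    build_context(regs)
  }
  expect_length(detect_short_sleep(mk("2024-03-01 23:30", "2024-03-02 06:00")), 1)  # 6.5 h
  expect_length(detect_short_sleep(mk("2024-03-01 22:00", "2024-03-02 06:30")), 0)  # 8.5 h
  # automatic sensor readings all night do not mask a 9 h manual gap
  expect_length(detect_short_sleep(mk("2024-03-01 22:00", "2024-03-02 07:00", auto_overnight = TRUE)), 0)
  short_auto <- mk("2024-03-01 23:30", "2024-03-02 06:00", auto_overnight = TRUE)
  expect_length(detect_short_sleep(short_auto), 1)
})

test_that("an insufficient last dose is computed from the reference glucose and ISF", {
  ctx <- quick_ctx(registration("2024-03-01 12:00", "carbohydrates", 50),
                   registration("2024-03-01 12:30", "insulin_bolus", 1),
                   bg_reg("2024-03-01 15:00", 14.0),
                   profile = patient_profile(reported_isf = 2.5))
  ev <- segment_glycemic_events(ctx)[[1]]
  res <- evaluate_hyper_causes(ev, ctx)
  r <- res$hyper_last_dose_insufficient
  expect_equal(r$state, "TRUE")
  expect_equal(r$evidence$required_dose, (14.0 - 5.5) / 2.5)  # 3.4 U > 1 U given
  expect_equal(res$hyper_not_enough_insulin$state, "TRUE")
})

test_that("a large meal before a hyperglycemic event flags the intake recommendation", {
  mk <- function(grams, low_carb = FALSE) {
    quick_ctx(registration("2024-03-01 12:00", "carbohydrates", grams),
              bg_reg("2024-03-01 14:00", 15.0),
              profile = patient_profile(low_carb_diet = low_carb))
  }
  ctx <- mk(80)
  res <- evaluate_hyper_causes(segment_glycemic_events(ctx)[[1]], ctx)
  expect_equal(res$hyper_intake_above_recommendation$state, "TRUE")
  ctx75 <- mk(75)
  res75 <- evaluate_hyper_causes(segment_glycemic_events(ctx75)[[1]], ctx75)
  expect_equal(res75$hyper_intake_above_recommendation$state, "FALSE")
  lc <- mk(80, low_carb = TRUE)
  res_lc <- evaluate_hyper_causes(segment_glycemic_events(lc)[[1]], lc)
  expect_equal(res_lc$hyper_intake_above_recommendation$state, "NA")
})

test_that("all-FALSE/NA branches flag an information gap", {
  ctx <- quick_ctx(bg_reg("2024-03-01 15:00", 3.0),
                   bg_reg("2024-03-01 18:00", 5.5))
  res <- evaluate_hypo_causes(segment_glycemic_events(ctx)[[1]], ctx)
  states <- vapply(res[c("hypo_too_much_insulin", "hypo_too_few_carbohydrates",
                         "hypo_external_factors", "hypo_physical_activity")],
                   `[[`, character(1), "state")
  expect_true(all(states %in% c("FALSE", "NA")))
  expect_equal(res$hypo_lack_of_evidence$state, "TRUE")
})

test_that("activity before a hypoglycemic event distinguishes light from extreme", {
  mk <- function(kind, value) {
    quick_ctx(registration("2024-03-01 08:00", "carbohydrates", 40),
              registration("2024-03-01 13:00", "physical_activity",
                           value = value, activity_kind = kind),
              bg_reg("2024-03-01 15:00", 3.0))
  }
  walk <- mk("minutes", 45)  # 45-minute walk 2 h before
  res <- evaluate_hypo_causes(segment_glycemic_events(walk)[[1]], walk)
  expect_equal(res$hypo_light_moderate_activity$state, "TRUE")
  expect_equal(res$hypo_physical_activity$state, "TRUE")
  steps <- mk("steps", 3500)  # above the 3000-step light bound: extreme
  res2 <- evaluate_hypo_causes(segment_glycemic_events(steps)[[1]], steps)
  expect_equal(res2$hypo_light_moderate_activity$state, "FALSE")
  expect_equal(res2$hypo_extreme_activity$state, "TRUE")
})

test_that("a 5-hour carbohydrate void before a hypoglycemic event is flagged", {
  ctx <- quick_ctx(registration("2024-03-01 09:00", "carbohydrates", 40),
                   bg_reg("2024-03-01 15:00", 3.0))
  res <- evaluate_hypo_causes(segment_glycemic_events(ctx)[[1]], ctx)
  expect_equal(res$hypo_no_carbs_4h$state, "TRUE")
  expect_equal(res$hypo_too_few_carbohydrates$state, "TRUE")
})

test_that("detector sweeps flip exactly once at the configured boundary", {
  hyper_n <- vapply(seq(12, 16, by = 0.1), function(v) {
    ctx <- quick_ctx(registration("2024-03-01 12:00", "carbohydrates", 50),
                     bg_reg("2024-03-01 15:00", v))
    length(segment_glycemic_events(ctx))
  }, numeric(1))
  expect_equal(sum(diff(hyper_n) != 0), 1)           # one flip
  expect_true(all(diff(hyper_n) >= 0))               # monotone step
})
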