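test_that("build_context sorts registrations and computes the period", {
  ctx <- quick_ctx(
    bg_reg("2024-03-01 12:00", 6.1),
    bg_reg("2024-03-01 07:00", 5.2),
    bg_reg("2024-03-01 18:30", 5.8))
  expect_equal(format(ctx$registrations$timestamp, "%H:%M"),
               c("07:00", "12:00", "18:30"))
  expect_equal(ctx$period_start, as_timestamp("2024-03-01 07:00"))
  expect_equal(ctx$period_end, as_timestamp("2024-03-01 18:30"))
})

test_that("duplicate (timestamp, data_type, source) rows collapse with a warning", {
  regs <- registrations(bg_reg("2024-03-01 07:00", 5.2),
                        bg_reg("2024-03-01 07:00", 5.2))
  expect_warning(ctx <- build_context(regs), "duplicate")
  expect_equal(nrow(ctx$registrations), 1)
})

test_that("invalid registrations are rejected with the offending row named", {
  regs <- registrations(bg_reg("2024-03-01 07:00", 5.2),
                        bg_reg("2024-03-01 08:00", NaN))
  expect_error(build_context(regs), "row 2")
  regs2 <- bg_reg("2024-03-01 07:00", 5.2)
  regs2$data_type <- "heart_rate"
  expect_error(build_context(regs2), "unknown data_type")
})

test_that("activity and factor fields are restricted to their data types", {
  bad <- registration("2024-03-01 07:00", "blood_glucose", 5.2)
  bad$activity_kind <- "steps"
  expect_error(build_context(bad), "activity fields")
  expect_error(build_context(registration("2024-03-01 07:00", "physical_activity", 30)),
               "activity_kind")
  ok <- registration("2024-03-01 09:00", "external_factor", factor_tag = "sickness")
  expect_silent(build_context(ok))
})

test_that("build_context is idempotent", {
  ctx <- quick_ctx(bg_reg("2024-03-01 12:00", 6.1),
                   bg_reg("2024-03-01 07:00", 5.2))
  ctx2 <- build_context(ctx$registrations, ctx$profile, ctx$lab, ctx$config)
  expect_equal(ctx2, ctx)
})

test_that("slice_window is end-inclusive and start-exclusive", {
  ctx <- quick_ctx(registration("2024-03-01 11:30", "carbohydrates", 60),
                   registration("2024-03-01 10:59", "carbohydrates", 30),
                   registration("2024-03-01 11:00", "carbohydrates", 20),
                   bg_reg("2024-03-01 15:00", 6))
  end <- as_timestamp("2024-03-01 15:00")
  win <- slice_window(ctx, "carbohydrates", end, 4)
  # 11:30 kept; both 10:59 and the exactly-4-hours-old 11:00 are excluded
  expect_equal(win$value, 60)
  expect_equal(format(win$timestamp, "%H:%M"), "11:30")
  expect_equal(nrow(slice_window(ctx, "insulin_bolus", end, 4)), 0)
})

test_that("an infinite lookback returns everything at or before the end; disjoint windows partition", {
  times <- sprintf("2024-03-01 %02d:00", 6:20)
  ctx <- do.call(quick_ctx, lapply(times, function(t) bg_reg(t, 5.5)))
  end <- as_timestamp("2024-03-01 20:00")
  all_regs <- slice_window(ctx, "blood_glucose", end, Inf)
  expect_equal(nrow(all_regs), length(times))
  w1 <- slice_window(ctx, "blood_glucose", end, 7)
  w2 <- slice_window(ctx, "blood_glucose", end - 7 * 3600, 7)
  w3 <- slice_window(ctx, "blood_glucose", end - 14 * 3600, Inf)
  expect_equal(nrow(w1) + nrow(w2) + nrow(w3), length(times))
})

test_that("empty diaries need the explicit allow_empty flag", {
  expect_error(build_context(empty_regs <- NULL), "empty")
  ctx <- build_context(NULL, allow_empty = TRUE)
  expect_equal(nrow(ctx$registrations), 0)
})

test_that("patient profile enforces non-overlapping mealtime windows and positive DIA", {
  expect_error(patient_profile(mealtime_windows = list(a = c("08:00", "12:00"),
                                                       b = c("11:00", "14:00"))),
               "overlap")
  expect_error(patient_profile(dia = 0))
  expect_error(lab_context(hba1c = 25))
})
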