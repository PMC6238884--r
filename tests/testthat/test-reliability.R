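test_that("missing data types are detected per type", {
  ctx <- quick_ctx(bg_reg("2024-03-01 07:00", 5.5),
                   registration("2024-03-01 08:00", "insulin_bolus", 4))
  res <- check_missing_types(ctx)
  expect_equal(res$no_blood_glucose_registered$state, "FALSE")
  expect_equal(res$no_insulin_registered$state, "FALSE")
  expect_equal(res$no_carbohydrates_registered$state, "TRUE")
  expect_equal(res$no_physical_activity_registered$state, "TRUE")
})

test_that("the insulin check is not applicable for non-insulin users", {
  ctx <- quick_ctx(bg_reg("2024-03-01 07:00", 5.5),
                   profile = patient_profile(uses_insulin = FALSE))
  res <- check_missing_types(ctx)
  expect_equal(res$no_insulin_registered$state, "NA")
  expect_match(res$no_insulin_registered$justification, "insulin")
})

test_that("implausible values are flagged and listed", {
  ctx <- quick_ctx(bg_reg("2024-03-01 07:00", 1.0),
                   bg_reg("2024-03-01 12:00", 6.0),
                   registration("2024-03-01 12:30", "carbohydrates", 500))
  res <- check_error_values(ctx)
  expect_equal(res$error_values_blood_glucose$state, "TRUE")
  expect_equal(res$error_values_blood_glucose$evidence$flagged_values, 1.0)
  expect_equal(res$error_values_carbohydrates$state, "TRUE")
  expect_equal(res$error_values_insulin$state, "FALSE")
  ok <- quick_ctx(bg_reg("2024-03-01 07:00", 4.0), bg_reg("2024-03-01 12:00", 10.0))
  expect_equal(check_error_values(ok)$error_values_blood_glucose$state, "FALSE")
})

test_that("the 5-per-day glucose minimum drives the registration-count check", {
  mk <- function(per_day) {
    rows <- list()
    for (d in 1:7) {
      for (i in seq_len(per_day[d])) {
        rows[[length(rows) + 1]] <- bg_reg(sprintf("2024-03-%02d %02d:00", d, 6 + 2 * i), 5.5)
      }
      rows[[length(rows) + 1]] <- registration(sprintf("2024-03-%02d 12:00", d), "carbohydrates", 50)
      rows[[length(rows) + 1]] <- registration(sprintf("2024-03-%02d 12:00", d), "insulin_bolus", 5)
    }
    build_context(do.call(rbind, rows))
  }
  expect_equal(check_registration_counts(mk(rep(5, 7)))$state, "FALSE")
  low <- check_registration_counts(mk(c(5, 5, 4, 5, 5, 5, 5)))
  expect_equal(low$state, "TRUE")
  expect_equal(low$evidence$offenders[[1]]$day, "2024-03-03")
  empty <- build_context(NULL, allow_empty = TRUE)
  expect_equal(check_registration_counts(empty)$state, "NA")
})

make_count_ctx <- function(counts) {
  rows <- list()
  for (d in seq_along(counts)) {
    for (i in seq_len(counts[d])) {
      rows[[length(rows) + 1]] <-
        bg_reg(sprintf("2024-03-%02d %02d:%02d", 3 + d, 6 + (i * 37) %/% 60 %% 16, (i * 37) %% 60), 5.5)
    }
  }
  build_context(do.call(rbind, rows))
}

test_that("day-distribution dispersion compares the SD to 20% of the mean", {
  expect_equal(check_day_distribution(make_count_ctx(rep(14, 7)))$state, "FALSE")
  # sd ~ 6 against mean ~ 14: allowed ~ 2.8, violated
  uneven <- make_count_ctx(c(14, 22, 6, 14, 20, 8, 14))
  res <- check_day_distribution(uneven)
  expect_equal(res$state, "TRUE")
  off <- res$evidence$offenders[[1]]
  expect_equal(off$allowed, 0.2 * mean(c(14, 22, 6, 14, 20, 8, 14)))
  expect_equal(off$observed, stats::sd(c(14, 22, 6, 14, 20, 8, 14)))
  # scale-equivariance: doubling uniform counts stays FALSE
  expect_equal(check_day_distribution(make_count_ctx(rep(28, 7)))$state, "FALSE")
  expect_equal(check_day_distribution(make_count_ctx(14))$state, "NA")
})

test_that("weekday grouping aggregates across weeks", {
  # two weeks, every day 10 registrations: weekday totals are all 20
  expect_equal(check_weekday_distribution(make_count_ctx(rep(10, 14)))$state, "FALSE")
  # weekend-heavy pattern violates the weekday rule
  skew <- rep(c(10, 10, 10, 10, 10, 24, 2), 2)
  expect_equal(check_weekday_distribution(make_count_ctx(skew))$state, "TRUE")
})

test_that("source inconsistencies compare calculated against reference at 5%", {
  base <- function(profile = patient_profile(), lab = lab_context()) {
    quick_ctx(bg_reg("2024-03-01 07:00", 8.0), bg_reg("2024-03-01 19:00", 8.0),
              registration("2024-03-01 12:00", "insulin_bolus", 10),
              registration("2024-03-01 22:00", "insulin_basal", 30),
              profile = profile, lab = lab)
  }
  # calculated A1C vs a much lower laboratory value
  calc <- estimate_hba1c(c(8, 8))
  res <- check_source_inconsistencies(base(lab = lab_context(hba1c = calc / 4 * 3)))
  expect_equal(res$source_inconsistency_hba1c$state, "TRUE")
  # within 4.9% of the calculated ISF: consistent
  isf_calc <- isf_rule(40, TRUE)
  res2 <- check_source_inconsistencies(base(patient_profile(reported_isf = isf_calc / 1.049)))
  expect_equal(res2$source_inconsistency_isf$state, "FALSE")
  res3 <- check_source_inconsistencies(base(patient_profile(reported_isf = isf_calc / 1.2)))
  expect_equal(res3$source_inconsistency_isf$state, "TRUE")
  # missing references are NA, not violations
  res4 <- check_source_inconsistencies(base())
  expect_equal(res4$source_inconsistency_hba1c$state, "NA")
  expect_equal(res4$source_inconsistency_isf$state, "NA")
  expect_equal(res4$source_inconsistency_icr$state, "NA")
})

test_that("trust grading subtracts grades of validated sub-hypotheses and clamps", {
  ctx <- quick_ctx(bg_reg("2024-03-01 07:00", 5.5))
  none <- lapply(evaluate_reliability(ctx), function(r) r)
  all_false <- lapply(none, function(r) { r$state <- "FALSE"; r })
  expect_equal(grade_reliability(ctx, all_false)$trust_level, 50)
  only_hba1c <- all_false
  only_hba1c$source_inconsistency_hba1c$state <- "TRUE"
  expect_equal(grade_reliability(ctx, only_hba1c)$trust_level, 40)
  all_true <- lapply(none, function(r) { r$state <- "TRUE"; r })
  worst <- grade_reliability(ctx, all_true)
  expect_equal(worst$trust_level, 0)  # clamped, never negative
})

test_that("grading is order-independent and monotone in violations", {
  ctx <- quick_ctx(bg_reg("2024-03-01 07:00", 5.5))
  res <- evaluate_reliability(ctx)
  shuffled <- res[sample(seq_along(res))]
  expect_equal(grade_reliability(ctx, shuffled)$trust_level,
               grade_reliability(ctx, res)$trust_level)
  # flipping one FALSE result to TRUE can only lower the trust level
  base_trust <- grade_reliability(ctx, res)$trust_level
  for (id in names(res)) {
    if (res[[id]]$state != "FALSE") next
    bumped <- res
    bumped[[id]]$state <- "TRUE"
    expect_lte(grade_reliability(ctx, bumped)$trust_level, base_trust)
  }
})

test_that("every validated reliability finding carries a recommendation", {
  fx <- golden_fixtures()
  for (nm in c("gap_case", "wrong_unit_case", "hba1c_mismatch")) {
    f <- fx[[nm]]
    ctx <- build_context(f$registrations, f$profile, f$lab)
    for (r in evaluate_reliability(ctx)) {
      if (r$state == "TRUE") {
        expect_true(is.character(r$evidence$recommendation) &&
                      nzchar(r$evidence$recommendation),
                    label = paste("recommendation for", r$hypothesis_id))
      }
    }
  }
})
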