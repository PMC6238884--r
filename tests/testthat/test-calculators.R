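test_that("estimated HbA1c inverts the linear eAG relation", {
  # hand arithmetic: eAG = 28.7*A1C - 46.7, mean BG in mmol/L times 18.016
  expect_equal(estimate_hba1c(8.561), (8.561 * 18.016 + 46.7) / 28.7)
  expect_equal(estimate_hba1c(8.561), 7.00, tolerance = 1e-3)
  expect_equal(estimate_hba1c(5.572), 5.125, tolerance = 1e-3)
  expect_true(is.na(estimate_hba1c(numeric(0))))
})

test_that("HbA1c estimate is strictly increasing and round-trips the forward relation", {
  bgs <- seq(3, 20, by = 0.5)
  a1cs <- vapply(bgs, estimate_hba1c, numeric(1))
  expect_true(all(diff(a1cs) > 0))
  expect_equal(vapply(a1cs, eag_from_hba1c, numeric(1)), bgs, tolerance = 1e-9)
})

test_that("the 1500/1800 rule gives ISF in mmol/L per U", {
  expect_equal(isf_rule(40, rapid_acting = TRUE), 45 / 18.016)   # 2.498
  expect_equal(isf_rule(50, rapid_acting = FALSE), 30 / 18.016)  # 1.665
  expect_true(is.na(isf_rule(0)))
})

test_that("the 500/450 rule gives I:C in grams per U", {
  expect_equal(icr_rule(50, rapid_acting = TRUE), 10)
  expect_equal(icr_rule(45, rapid_acting = FALSE), 10)
  expect_true(is.na(icr_rule(-1)))
})

test_that("ISF and I:C rules are homogeneous of degree -1 in the daily dose", {
  for (tdd in c(20, 37.5, 60)) {
    expect_equal(isf_rule(2 * tdd), isf_rule(tdd) / 2)
    expect_equal(icr_rule(2 * tdd), icr_rule(tdd) / 2)
  }
})

test_that("insulin on board follows the decay contract", {
  t0 <- as_timestamp("2024-03-01 12:00")
  bolus <- data.frame(timestamp = t0, value = 4)
  expect_equal(iob_at(t0 + 2 * 3600, bolus, dia = 4), 2)  # midpoint of linear decay
  expect_equal(iob_at(t0 + 5 * 3600, bolus, dia = 4), 0)  # past DIA
  expect_equal(iob_at(t0, bolus, dia = 4), 4)             # all on board at injection
  expect_equal(iob_at(t0, bolus[0, ], dia = 4), 0)
  for (curve in c("linear", "bilinear")) {
    vals <- vapply(seq(0, 5, by = 0.1), function(h) {
      iob_at(t0 + h * 3600, bolus, dia = 4, curve = curve)
    }, numeric(1))
    expect_true(all(diff(vals) <= 1e-12))       # non-increasing
    expect_equal(vals[1], 4)
    expect_equal(vals[length(vals)], 0)
    expect_true(all(vals >= 0))
  }
  # additive over doses
  two <- rbind(bolus, data.frame(timestamp = t0 + 3600, value = 3))
  at <- t0 + 2.5 * 3600
  expect_equal(iob_at(at, two, dia = 4),
               iob_at(at, two[1, ], dia = 4) + iob_at(at, two[2, ], dia = 4))
})

test_that("carbohydrates on board absorb linearly and floor at zero", {
  t0 <- as_timestamp("2024-03-01 12:00")
  intake <- data.frame(timestamp = t0, value = 60)
  expect_equal(cob_at(t0 + 3600, intake, absorption_rate = 30), 30)
  expect_equal(cob_at(t0 + 2 * 3600, data.frame(timestamp = t0, value = 20), 30), 0)
  expect_true(is.na(cob_at(t0 + 3600, intake, absorption_rate = NULL)))
})

test_that("average IOB over a linear ramp equals the midpoint dose", {
  ctx <- quick_ctx(registration("2024-03-01 08:00", "insulin_bolus", 4),
                   bg_reg("2024-03-01 12:00", 5.5))
  expect_equal(average_iob(ctx), 2)
  ctx2 <- quick_ctx(bg_reg("2024-03-01 08:00", 5.5), bg_reg("2024-03-01 12:00", 5.5))
  expect_equal(average_iob(ctx2), 0)
  # grid refinement converges
  expect_lt(abs(average_iob(ctx, grid_minutes = 1) - average_iob(ctx, grid_minutes = 5)) /
              average_iob(ctx, grid_minutes = 1), 0.01)
})

test_that("daily totals cover every calendar day and recount registrations", {
  ctx <- quick_ctx(
    registration("2024-03-01 08:00", "insulin_bolus", 4),
    registration("2024-03-01 12:00", "insulin_bolus", 4),
    registration("2024-03-01 18:00", "insulin_bolus", 4),
    registration("2024-03-01 22:00", "insulin_basal", 20),
    bg_reg("2024-03-01 07:00", 5.5),
    bg_reg("2024-03-03 07:00", 6.0))
  dt <- daily_totals(ctx)
  expect_equal(nrow(dt), 3)  # includes the empty middle day
  expect_equal(dt$total_rapid_insulin, c(12, 0, 0))
  expect_equal(dt$total_basal_insulin, c(20, 0, 0))
  expect_equal(dt$n_blood_glucose, c(1, 0, 1))
  # brute-force recount
  regs <- ctx$registrations
  for (i in seq_len(nrow(dt))) {
    for (type in DATA_TYPES) {
      expect_equal(dt[[paste0("n_", type)]][i],
                   sum(regs$data_type == type & as.Date(regs$timestamp) == dt$date[i]))
    }
  }
})
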