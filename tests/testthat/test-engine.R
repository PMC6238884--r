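test_that("an in-range diary evaluates reliability only and terminates", {
  ctx <- quick_ctx(bg_reg("2024-03-01 07:00", 5.5),
                   bg_reg("2024-03-01 12:00", 6.0),
                   bg_reg("2024-03-01 19:00", 5.8))
  rr <- run_consultation(ctx)
  df <- run_results_df(rr)
  med <- df[df$hypothesis_id %in% c("hyperglycemia", "hypoglycemia",
                                    "high_blood_pressure", "short_sleep"), ]
  expect_false(any(med$state == "TRUE"))
  expect_length(rr$events, 0)
  rel <- df[df$hypothesis_id == "not_enough_registrations", ]
  expect_equal(nrow(rel), 1)
})

test_that("a detected hyperglycemic event appends its five cause branches per trigger", {
  ctx <- quick_ctx(registration("2024-03-01 12:00", "carbohydrates", 50),
                   bg_reg("2024-03-01 15:00", 14.5))
  rr <- run_consultation(ctx)
  expect_equal(hypothesis_state(rr, "hyperglycemia", "dataset"), "TRUE")
  eid <- names(rr$events)[1]
  branches <- c("hyper_not_enough_insulin", "hyper_too_much_carbohydrates",
                "hyper_external_factors", "hyper_no_physical_activity",
                "hyper_lack_of_evidence")
  for (b in branches) {
    expect_length(hypothesis_state(rr, b, eid), 1)
  }
})

test_that("re-running on the same context is deterministic", {
  ctx <- suppressWarnings(random_context(42))
  kb <- default_kb()
  a <- run_consultation(ctx, kb)
  b <- run_consultation(ctx, kb)
  expect_equal(engine_multiset(a), engine_multiset(b))
  expect_equal(render_report(a, "json"), render_report(b, "json"))
})

test_that("activation flags missing context with its name", {
  ctx <- quick_ctx(bg_reg("2024-03-01 15:00", 14.5))  # fasting hyper, nothing else
  kb <- default_kb()
  res <- activate_hypothesis("hyper_icr_too_low", ctx, kb)
  expect_equal(res$state, "NA")
  expect_match(res$justification, "required context missing")
  expect_null(activate_hypothesis("hyperglycemia", ctx, kb))
  # COB comparison without an absorption rate is not applicable
  ctx2 <- quick_ctx(registration("2024-03-01 12:00", "carbohydrates", 50),
                    bg_reg("2024-03-01 15:00", 14.5))
  res2 <- activate_hypothesis("hyper_cob_above_average", ctx2, kb)
  expect_match(res2$justification, "absorption rate")
})

test_that("a default-TRUE parent is invalidated only when all children are FALSE or NA", {
  # brute force over all 3^4 child-state combinations
  states <- c("TRUE", "FALSE", "NA")
  grid <- expand.grid(a = states, b = states, c = states, d = states,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    children <- lapply(unlist(grid[i, ]), function(s) {
      glucoreason:::hyp_state("x", s)
    })
    res <- glucoreason:::combine_invalidate("parent", children)
    expected <- if (any(unlist(grid[i, ]) == "TRUE")) "TRUE" else "FALSE"
    expect_equal(res$state, expected)
  }
  # the spec'd spot check: {FALSE, NA, NA, NA} invalidates the parent
  ch <- lapply(c("FALSE", "NA", "NA", "NA"), function(s) glucoreason:::hyp_state("x", s))
  expect_equal(glucoreason:::combine_invalidate("parent", ch)$state, "FALSE")
})

test_that("plan updates are idempotent for repeated delivery of the same result", {
  kb <- default_kb()
  ctx <- quick_ctx(registration("2024-03-01 12:00", "carbohydrates", 50),
                   bg_reg("2024-03-01 15:00", 14.5))
  pc <- glucoreason:::new_plan_case(kb)
  det <- glucoreason:::rule_detect_glycemic(ctx, "hyperglycemia")
  pc <- glucoreason:::register_events(pc, det)
  pc1 <- glucoreason:::update_plan(pc, det, "dataset", kb)
  n1 <- length(pc1$pending)
  pc2 <- glucoreason:::update_plan(pc1, det, "dataset", kb)
  expect_equal(length(pc2$pending), n1)
  expect_gt(n1, length(pc$pending))
  # a FALSE detection appends nothing
  none <- glucoreason:::hyp_state("hyperglycemia", "FALSE")
  pc3 <- glucoreason:::update_plan(pc, none, "dataset", kb)
  expect_equal(length(pc3$pending), length(pc$pending))
})

test_that("an evaluation fault degrades to NA and the run continues", {
  ctx <- quick_ctx(bg_reg("2024-03-01 07:00", 5.5), bg_reg("2024-03-01 12:00", 6.2))
  boom <- glucoreason:::LEAF_RULES
  boom$hyperglycemia <- function(ctx, e) stop("synthetic fault")
  testthat::local_mocked_bindings(LEAF_RULES = boom, .package = "glucoreason")
  rr <- run_consultation(ctx)
  expect_equal(hypothesis_state(rr, "hyperglycemia", "dataset"), "NA")
  df <- run_results_df(rr)
  expect_match(df$justification[df$hypothesis_id == "hyperglycemia"], "evaluation failure")
  expect_gt(nrow(df), 10)  # the rest of the consultation still ran
})

test_that("the plan-driven engine matches a direct walk of the hypothesis tree", {
  kb <- default_kb()
  for (seed in 1:40) {
    ctx <- suppressWarnings(random_context(seed))
    expected <- oracle_walk(ctx)
    rownames(expected) <- NULL
    expect_equal(engine_multiset(run_consultation(ctx, kb)), expected,
                 label = paste("seed", seed))
  }
})

test_that("deleting insulin or activity data only moves evidence leaves towards NA", {
  leaf_ids <- c("hyper_iob_below_average", "hyper_last_dose_insufficient",
                "hyper_icr_too_low", "hyper_no_insulin_at_meal",
                "hyper_cob_above_average", "hyper_intake_above_recommendation",
                "hyper_no_physical_activity",
                "hypo_iob_above_average", "hypo_last_dose_too_high",
                "hypo_active_insulin_exceeds_need", "hypo_no_carbs_4h",
                "hypo_intake_below_recommendation", "hypo_light_moderate_activity",
                "hypo_extreme_activity",
                "source_inconsistency_isf", "source_inconsistency_icr",
                "source_inconsistency_hba1c")
  kb <- default_kb()
  for (seed in 1:15) {
    ctx <- suppressWarnings(random_context(seed))
    base <- engine_multiset(run_consultation(ctx, kb))
    for (drop in list(c("insulin_bolus", "insulin_basal"), "physical_activity")) {
      regs <- ctx$registrations[!ctx$registrations$data_type %in% drop, , drop = FALSE]
      if (nrow(regs) == 0) next
      ctx2 <- build_context(regs, ctx$profile, ctx$lab, ctx$config)
      # a shrunken period would legitimately move the IOB/COB averages;
      # the deletion property is about evidence, so keep the window fixed
      if (ctx2$period_start != ctx$period_start || ctx2$period_end != ctx$period_end) next
      reduced <- engine_multiset(run_consultation(ctx2, kb))
      merged <- merge(base, reduced, by = c("hypothesis_id", "scope"),
                      suffixes = c("_base", "_red"))
      merged <- merged[merged$hypothesis_id %in% leaf_ids, ]
      ok <- merged$state_red == merged$state_base | merged$state_red == "NA"
      expect_true(all(ok), label = paste("seed", seed, paste(drop, collapse = "+")))
    }
  }
})

test_that("hypothesis lookups expose states by scope", {
  ctx <- quick_ctx(registration("2024-03-01 12:00", "carbohydrates", 50),
                   bg_reg("2024-03-01 15:00", 14.5))
  rr <- run_consultation(ctx)
  expect_equal(hypothesis_state(rr, "hyperglycemia"), "TRUE")
  expect_length(hypothesis_state(rr, "not_a_hypothesis"), 0)
})
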