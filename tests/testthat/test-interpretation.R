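test_that("validated causes become hedged findings with justifications", {
  fx <- golden_fixtures()$hyper_meal
  ctx <- build_context(fx$registrations, fx$profile, fx$lab)
  rr <- run_consultation(ctx)
  eid <- names(rr$events)[1]
  efind <- Filter(function(f) f$scope == eid, rr$findings)
  expect_gt(length(efind), 0)
  carb <- Filter(function(f) grepl("too many carbohydrates", f$headline), efind)
  expect_length(carb, 1)
  expect_match(carb[[1]]$headline, "may have been")
  expect_true(any(grepl("exceeded the recommended maximum", carb[[1]]$justifications)))
})

test_that("an information gap yields a gap finding inviting investigation", {
  fx <- golden_fixtures()$gap_case
  ctx <- build_context(fx$registrations, fx$profile, fx$lab)
  rr <- run_consultation(ctx)
  gap <- Filter(function(f) f$severity == "gap", rr$findings)
  expect_length(gap, 1)
  expect_match(gap[[1]]$headline, "lacked evidence")
  expect_equal(length(rr$gaps), 1)
})

test_that("a clean run produces no findings", {
  d <- generate_diary(scenario_spec(days = 3, seed = 5))
  rr <- run_consultation(build_context(d$registrations, d$profile, d$lab))
  expect_length(rr$findings, 0)
})

test_that("summaries bin events by hour and weekday and tally main causes", {
  spec <- scenario_spec(days = 7, seed = 3, anomalies = list(
    anomaly_hypo_injection(2, "07:10", 3.0),
    anomaly_hypo_injection(3, "07:40", 3.1),
    anomaly_hyper_injection(5, "19:00", 16.0)))
  d <- generate_diary(spec)
  rr <- run_consultation(build_context(d$registrations, d$profile, d$lab))
  s <- rr$summary
  expect_equal(unname(s$kinds["hypoglycemia"]), 2L)
  expect_equal(unname(s$kinds["hyperglycemia"]), 1L)
  expect_equal(unname(s$per_hour$hypoglycemia[["7"]]), 2L)
  expect_equal(unname(s$per_hour$hyperglycemia[["19"]]), 1L)
  for (k in names(s$kinds)) {
    expect_equal(sum(s$per_hour[[k]]), unname(s$kinds[k]))
    expect_equal(sum(s$per_weekday[[k]]), unname(s$kinds[k]))
  }
  # every tallied main cause traces back to a TRUE top-level branch
  for (cid in names(s$causes)) {
    n <- sum(vapply(rr$events, function(e) {
      !is.null(e$causes[[cid]]) && e$causes[[cid]]$state == "TRUE"
    }, logical(1)))
    expect_equal(s$causes[[cid]], n)
  }
})

test_that("a single event can contribute to multiple cause counts", {
  ctx <- quick_ctx(registration("2024-03-01 12:00", "carbohydrates", 85),
                   registration("2024-03-01 09:00", "external_factor",
                                factor_tag = "sickness"),
                   bg_reg("2024-03-01 14:00", 15.0))
  rr <- run_consultation(ctx)
  expect_gte(length(rr$summary$causes), 2)
  expect_equal(sum(unname(rr$summary$kinds)), 1)
})

test_that("rendering is deterministic and respects the trust-grade display rule", {
  fx <- golden_fixtures()$hba1c_mismatch
  ctx <- build_context(fx$registrations, fx$profile, fx$lab)
  rr <- run_consultation(ctx)
  expect_identical(render_report(rr, "markdown"), render_report(rr, "markdown"))
  expect_identical(render_report(rr, "json"), render_report(rr, "json"))
  md <- render_report(rr, "markdown")
  html <- render_report(rr, "html")
  expect_false(grepl("trust", md, ignore.case = TRUE))
  expect_false(grepl("40", md, fixed = TRUE))
  expect_false(grepl("trust", html, ignore.case = TRUE))
  js <- jsonlite::fromJSON(render_report(rr, "json"))
  expect_equal(js$reliability$trust_level, 40)
  expect_error(render_report(rr, "pdf"), "unknown report format")
})

test_that("empty runs render all-zero summaries", {
  ctx <- build_context(NULL, allow_empty = TRUE)
  rr <- run_consultation(ctx)
  expect_equal(sum(unname(rr$summary$kinds)), 0)
  expect_length(rr$summary$causes, 0)
  expect_silent(render_report(rr, "markdown"))
})
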