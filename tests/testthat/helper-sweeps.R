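# Flip-point sweep helpers used by the acceptance tests: each sweeps one
# driving value across its configured threshold and reports the boundary.

sweep_hyper_threshold <- function(grid = seq(9, 16, by = 0.1)) {
  quiet <- vapply(grid, function(v) {
    ctx <- quick_ctx(registration("2024-03-04 12:00", "carbohydrates", 50),
                     bg_reg("2024-03-04 15:00", v))
    length(Filter(function(e) e$kind == "hyperglycemia",
                  segment_glycemic_events(ctx))) == 0
  }, logical(1))
  max(grid[quiet])
}

sweep_hypo_threshold <- function(grid = seq(2, 5, by = 0.1)) {
  quiet <- vapply(grid, function(v) {
    ctx <- quick_ctx(registration("2024-03-04 12:00", "carbohydrates", 50),
                     bg_reg("2024-03-04 15:00", v))
    length(Filter(function(e) e$kind == "hypoglycemia",
                  segment_glycemic_events(ctx))) == 0
  }, logical(1))
  min(grid[quiet])
}

sweep_bp_threshold <- function(grid = 120:160) {
  quiet <- vapply(grid, function(sys) {
    ctx <- quick_ctx(registration("2024-03-04 10:00", "blood_pressure_systolic", sys),
                     registration("2024-03-04 10:00", "blood_pressure_diastolic", 80))
    length(detect_bp_events(ctx)) == 0
  }, logical(1))
  max(grid[quiet])
}

sweep_sleep_threshold <- function(grid = seq(4, 10, by = 0.5)) {
  quiet <- vapply(grid, function(g) {
    t2 <- as_timestamp("2024-03-04 23:00") + g * 3600
    ctx <- quick_ctx(bg_reg("2024-03-04 08:00", 5.5),
                     bg_reg("2024-03-04 23:00", 5.6),
                     bg_reg(t2, 5.4),
                     bg_reg("2024-03-05 21:00", 5.5))
    length(detect_short_sleep(ctx)) == 0
  }, logical(1))
  min(grid[quiet])
}

sweep_bg_count_minimum <- function(grid = 1:10, seed = 1) {
  ok <- vapply(grid, function(k) {
    d <- generate_diary(scenario_spec(days = 7, bg_per_day = k, seed = seed))
    ctx <- build_context(d$registrations, d$profile, d$lab)
    check_registration_counts(ctx)$state == "FALSE"
  }, logical(1))
  min(grid[ok])
}

sweep_meal_carbs <- function(grid = 40:120) {
  ok <- vapply(grid, function(g) {
    ctx <- quick_ctx(registration("2024-03-04 12:00", "carbohydrates", g),
                     bg_reg("2024-03-04 14:00", 15.0))
    ev <- Filter(function(e) e$kind == "hyperglycemia", segment_glycemic_events(ctx))[[1]]
    evaluate_hyper_causes(ev, ctx)$hyper_intake_above_recommendation$state == "FALSE"
  }, logical(1))
  max(grid[ok])
}

sweep_light_steps <- function(grid = seq(1000, 5000, by = 50)) {
  lm_true <- vapply(grid, function(steps) {
    ctx <- quick_ctx(registration("2024-03-04 13:00", "physical_activity",
                                  value = steps, activity_kind = "steps"),
                     bg_reg("2024-03-04 15:00", 3.0))
    ev <- Filter(function(e) e$kind == "hypoglycemia", segment_glycemic_events(ctx))[[1]]
    evaluate_hypo_causes(ev, ctx)$hypo_light_moderate_activity$state == "TRUE"
  }, logical(1))
  # strict "< threshold": the supremum of the TRUE region is one grid step
  # above the largest step count still classified light-to-moderate
  max(grid[lm_true]) + diff(grid)[1]
}

# smallest-sum-of-four-squares decomposition (Lagrange guarantees existence)
four_squares <- function(n) {
  if (n == 0) return(integer(0))
  for (a in floor(sqrt(n)):1) {
    m <- n - a^2
    if (m == 0) return(a)
    for (b in floor(sqrt(m)):1) {
      m2 <- m - b^2
      if (m2 == 0) return(c(a, b))
      for (cc in floor(sqrt(m2)):1) {
        m3 <- m2 - cc^2
        if (m3 == 0) return(c(a, b, cc))
        dd <- floor(sqrt(m3))
        if (dd * dd == m3) return(c(a, b, cc, dd))
      }
    }
  }
  stop("no four-square decomposition found for ", n)
}

counts_with_ss <- function(m, days = 14, base = 10) {
  counts <- rep(base, days)
  rs <- four_squares(m)
  for (j in seq_along(rs)) {
    counts[2 * j - 1] <- counts[2 * j - 1] + rs[j]
    counts[2 * j] <- counts[2 * j] - rs[j]
  }
  counts
}

diary_from_counts <- function(counts, start = as.Date("2024-03-04")) {
  rows <- list()
  for (d in seq_along(counts)) {
    for (i in seq_len(counts[d])) {
      rows[[length(rows) + 1]] <-
        bg_reg(paste(format(start + d - 1), sprintf("%02d:%02d", 6 + (i - 1) %/% 12, ((i - 1) %% 12) * 5)), 5.5)
    }
  }
  build_context(do.call(rbind, rows))
}

sweep_day_dispersion <- function(percents = 0:40) {
  achieved <- numeric(0)
  state <- character(0)
  for (p in percents) {
    m <- round(13 * p^2 / 200)  # sample sd over 14 days: sd^2 = 2m/13
    counts <- counts_with_ss(m)
    ctx <- diary_from_counts(counts)
    res <- check_day_distribution(ctx)
    achieved <- c(achieved, stats::sd(counts) / mean(counts) * 100)
    state <- c(state, res$state)
  }
  max(achieved[state == "FALSE"])
}

sweep_isf_tolerance <- function(grid = seq(0, 10, by = 0.1), seed = 2) {
  d <- generate_diary(scenario_spec(days = 7, seed = seed))
  base <- build_context(d$registrations, d$profile, d$lab)
  calc <- isf_rule(glucoreason:::mean_tdd(base), TRUE)
  ok <- vapply(grid, function(x) {
    p <- d$profile
    p$reported_isf <- calc / (1 + x / 100)
    ctx <- build_context(d$registrations, p, d$lab)
    check_source_inconsistencies(ctx)$source_inconsistency_isf$state == "FALSE"
  }, logical(1))
  max(grid[ok])
}

sweep_hba1c_tolerance <- function(grid = seq(0, 10, by = 0.1), seed = 2) {
  d <- generate_diary(scenario_spec(days = 7, seed = seed))
  base <- build_context(d$registrations, d$profile, d$lab)
  calc <- estimate_hba1c(base$registrations$value[
    base$registrations$data_type == "blood_glucose"])
  ok <- vapply(grid, function(x) {
    lab <- lab_context(hba1c = calc / (1 + x / 100))
    ctx <- build_context(d$registrations, d$profile, lab)
    check_source_inconsistencies(ctx)$source_inconsistency_hba1c$state == "FALSE"
  }, logical(1))
  max(grid[ok])
}

hba1c_trust_drop <- function(seed = 1) {
  d <- generate_diary(scenario_spec(days = 14, seed = seed))
  est <- estimate_hba1c(d$registrations$value[d$registrations$data_type == "blood_glucose"])
  trust_at <- function(lab_value) {
    ctx <- build_context(d$registrations, d$profile, lab_context(hba1c = lab_value))
    run_consultation(ctx)$trust_level
  }
  trust_at(est) - trust_at(est - 2)
}
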