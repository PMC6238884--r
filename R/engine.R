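# Hypothesize-and-test reasoning engine: generate the plan case, activate
# each hypothesis (NA on missing context), evaluate, store the result,
# update the plan on triggers, interpret.

rule_detect_glycemic <- function(ctx, kind) {
  evs <- Filter(function(e) e$kind == kind, segment_glycemic_events(ctx))
  hit <- length(evs) > 0
  hyp_state(if (kind == "hyperglycemia") "hyperglycemia" else "hypoglycemia",
            if (hit) "TRUE" else "FALSE",
            if (hit) sprintf("%d %s event(s) detected", length(evs), kind)
            else sprintf("no %s event detected", kind),
            list(events = evs, n_events = length(evs)))
}

rule_detect_bp <- function(ctx) {
  evs <- detect_bp_events(ctx)
  hit <- length(evs) > 0
  hyp_state("high_blood_pressure", if (hit) "TRUE" else "FALSE",
            if (hit) sprintf("%d high blood pressure reading(s) above %s/%s mmHg",
                             length(evs), fmt_num(ctx$config$bp_systolic),
                             fmt_num(ctx$config$bp_diastolic))
            else "no high blood pressure reading",
            list(events = evs, n_events = length(evs)))
}

rule_detect_sleep <- function(ctx) {
  manual <- ctx$registrations[ctx$registrations$manual %in% TRUE, , drop = FALSE]
  if (nrow(manual) < 2) {
    return(hyp_state("short_sleep", "NA",
                     "required context missing: at least 2 manual registrations spanning a night"))
  }
  evs <- detect_short_sleep(ctx)
  hit <- length(evs) > 0
  hyp_state("short_sleep", if (hit) "TRUE" else "FALSE",
            if (hit) sprintf("%d night(s) with less than %s hours between manual registrations",
                             length(evs), fmt_num(ctx$config$sleep_min_hours))
            else "no short-sleep night detected",
            list(events = evs, n_events = length(evs)))
}

# leaf evaluation dispatch: one entry per leaf hypothesis in the default KB
LEAF_RULES <- list(
  no_blood_glucose_registered = function(ctx, e) rel_missing_type(ctx, "blood_glucose"),
  no_carbohydrates_registered = function(ctx, e) rel_missing_type(ctx, "carbohydrates"),
  no_insulin_registered = function(ctx, e) rel_missing_type(ctx, "insulin"),
  no_physical_activity_registered = function(ctx, e) rel_missing_type(ctx, "physical_activity"),
  error_values_blood_glucose = function(ctx, e) rel_error_values(ctx, "blood_glucose"),
  error_values_carbohydrates = function(ctx, e) rel_error_values(ctx, "carbohydrates"),
  error_values_insulin = function(ctx, e) rel_error_values(ctx, "insulin"),
  not_enough_registrations = function(ctx, e) rel_registration_counts(ctx),
  unequal_days_distribution = function(ctx, e) rel_distribution(ctx, FALSE),
  unequal_weekdays_distribution = function(ctx, e) rel_distribution(ctx, TRUE),
  source_inconsistency_hba1c = function(ctx, e) rel_source_hba1c(ctx),
  source_inconsistency_isf = function(ctx, e) rel_source_isf(ctx),
  source_inconsistency_icr = function(ctx, e) rel_source_icr(ctx),
  hyperglycemia = function(ctx, e) rule_detect_glycemic(ctx, "hyperglycemia"),
  hypoglycemia = function(ctx, e) rule_detect_glycemic(ctx, "hypoglycemia"),
  high_blood_pressure = function(ctx, e) rule_detect_bp(ctx),
  short_sleep = function(ctx, e) rule_detect_sleep(ctx),
  hyper_iob_below_average = function(ctx, e) rule_iob_vs_average(ctx, e, above = FALSE),
  hyper_last_dose_insufficient = function(ctx, e) rule_last_dose(ctx, e, too_low = TRUE),
  hyper_icr_too_low = function(ctx, e) rule_icr_too_low(ctx, e),
  hyper_no_insulin_at_meal = function(ctx, e) rule_no_insulin_at_meal(ctx, e),
  hyper_cob_above_average = function(ctx, e) rule_cob_vs_average(ctx, e),
  hyper_intake_above_recommendation = function(ctx, e) rule_intake_reco(ctx, e, high = TRUE),
  hyper_external_factors = function(ctx, e) rule_external_factors(ctx, e, "hyper_external_factors"),
  hyper_no_physical_activity = function(ctx, e) rule_no_activity_24h(ctx, e),
  hypo_iob_above_average = function(ctx, e) rule_iob_vs_average(ctx, e, above = TRUE),
  hypo_last_dose_too_high = function(ctx, e) rule_last_dose(ctx, e, too_low = FALSE),
  hypo_active_insulin_exceeds_need = function(ctx, e) rule_iob_exceeds_need(ctx, e),
  hypo_no_carbs_4h = function(ctx, e) rule_no_carbs_4h(ctx, e),
  hypo_intake_below_recommendation = function(ctx, e) rule_intake_reco(ctx, e, high = FALSE),
  hypo_external_factors = function(ctx, e) rule_external_factors(ctx, e, "hypo_external_factors"),
  hypo_light_moderate_activity = function(ctx, e) rule_light_activity_4h(ctx, e),
  hypo_extreme_activity = function(ctx, e) rule_extreme_activity_24h(ctx, e),
  bp_external_factors = function(ctx, e) rule_external_factors(ctx, e, "bp_external_factors")
)

leaf_rule_known <- function(id) !is.null(LEAF_RULES[[id]])

result_key <- function(hyp_id, scope) paste(hyp_id, scope, sep = "@")

new_plan_case <- function(kb) {
  root <- kb$plans[[which(vapply(kb$plans, function(p) identical(p$trigger$on, "root"), logical(1)))[1]]]
  pending <- lapply(root$members, function(id) {
    list(task_id = paste0("task_", id), hypothesis_id = id,
         scope = "dataset", event = NULL)
  })
  structure(list(pending = pending, completed = list(), events = list(),
                 triggered = character(0), provenance = character(0),
                 event_counts = list()),
            class = "gr_plan_case")
}

#' Activate a bound hypothesis against the current context
#'
#' Checks the hypothesis' activation requirements; when required context is
#' missing, the hypothesis is flagged NA with a justification naming the
#' missing context type.
#'
#' @param hypothesis_id hypothesis identifier from the knowledge base.
#' @param ctx a `gr_context`.
#' @param kb a `gr_kb`.
#' @return `NULL` when activated, otherwise an NA `gr_result`.
#' @export
activate_hypothesis <- function(hypothesis_id, ctx, kb) {
  h <- kb$hypotheses[[hypothesis_id]]
  if (is.null(h)) stop("unknown hypothesis: ", hypothesis_id)
  miss <- check_requires(ctx, h$requires)
  if (is.null(miss)) return(NULL)
  hyp_state(hypothesis_id, "NA", paste0("required context missing: ", miss))
}

evaluate_entry <- function(entry, pc, ctx, kb) {
  id <- entry$hypothesis_id
  h <- kb$hypotheses[[id]]
  na_res <- activate_hypothesis(id, ctx, kb)
  if (!is.null(na_res)) return(na_res)
  if (h$combine == "leaf") {
    fn <- LEAF_RULES[[id]]
    return(tryCatch(fn(ctx, entry$event),
                    error = function(e) hyp_state(id, "NA",
                                                  paste0("evaluation failure: ", conditionMessage(e)))))
  }
  members <- h$children
  got <- lapply(members, function(ch) {
    r <- pc$completed[[result_key(ch, entry$scope)]]
    if (is.null(r)) hyp_state(ch, "NA", "not yet evaluated") else r
  })
  switch(h$combine,
         invalidate = combine_invalidate(id, got),
         any_true = combine_any_true(id, got),
         lack_of_evidence = combine_lack_of_evidence(id, got),
         hyp_state(id, "NA", paste0("evaluation failure: unknown combination ", h$combine)))
}

register_events <- function(pc, result) {
  evs <- result$evidence$events
  if (is.null(evs) || !length(evs)) return(pc)
  for (ev in evs) {
    n <- (pc$event_counts[[ev$kind]] %||% 0) + 1
    pc$event_counts[[ev$kind]] <- n
    eid <- paste0(ev$kind, "_", n)
    ev$event_id <- eid
    pc$events[[eid]] <- ev
  }
  pc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Append the entries whose triggers match the delivered result, once per
# (trigger, scope); repeated delivery of the same result leaves the plan
# case unchanged.
update_plan <- function(pc, result, scope, kb) {
  for (p in kb$plans) {
    trig <- p$trigger
    if (identical(trig$on, "root")) next
    if (!identical(trig$on, result$hypothesis_id)) next
    if (!identical(trig$state, result$state)) next
    if (isTRUE(trig$per_event)) {
      evs <- Filter(function(e) !is.null(e$trigger_hyp) && e$trigger_hyp == result$hypothesis_id,
                    pc$events)
      if (!length(evs)) {
        evs <- Filter(function(e) e$kind %in% event_kind_of(result$hypothesis_id), pc$events)
      }
      for (ev in evs) {
        key <- paste(p$plan_id, ev$event_id, sep = "@")
        if (key %in% pc$triggered) next
        pc$triggered <- c(pc$triggered, key)
        for (m in p$members) {
          pc$pending <- c(pc$pending,
                          list(list(task_id = paste0("task_", m), hypothesis_id = m,
                                    scope = ev$event_id, event = ev)))
        }
        pc$provenance <- c(pc$provenance,
                           sprintf("%s=%s triggered plan '%s' for %s",
                                   result$hypothesis_id, result$state, p$plan_id, ev$event_id))
      }
    } else {
      key <- paste(p$plan_id, scope, sep = "@")
      if (key %in% pc$triggered) next
      pc$triggered <- c(pc$triggered, key)
      for (m in p$members) {
        pc$pending <- c(pc$pending,
                        list(list(task_id = paste0("task_", m), hypothesis_id = m,
                                  scope = scope, event = NULL)))
      }
    }
  }
  pc
}

event_kind_of <- function(detection_id) {
  switch(detection_id,
         hyperglycemia = "hyperglycemia",
         hypoglycemia = "hypoglycemia",
         high_blood_pressure = "high_bp",
         short_sleep = "short_sleep",
         character(0))
}

#' Run a consultation: the full hypothesize-and-test cycle
#'
#' Generates the plan case from the root plan, then repeatedly activates and
#' evaluates pending hypotheses, storing each result and extending the plan
#' when a trigger fires (for instance, a detected hyperglycemic event
#' appends its five cause sub-hypotheses scoped to that event) until a
#' fixpoint is reached. Evaluation faults degrade to NA results — a
#' consultation never aborts. The run is deterministic for fixed inputs.
#'
#' @param ctx a `gr_context`.
#' @param kb a `gr_kb`; defaults to [default_kb()] built on the context's
#'   configuration.
#' @return list of class `gr_run` with `results`, `reliability` (trust
#'   report), `events` (each with attached cause results and a gap flag),
#'   `gaps`, `findings`, `summary` and a provenance log.
#' @examples
#' regs <- registrations(
#'   registration("2024-03-01 08:00", "blood_glucose", 5.2),
#'   registration("2024-03-01 15:00", "blood_glucose", 14.5))
#' rr <- run_consultation(build_context(regs))
#' rr$events[[1]]$event$kind
#' @export
run_consultation <- function(ctx, kb = default_kb(ctx$config)) {
  stopifnot(inherits(ctx, "gr_context"), inherits(kb, "gr_kb"))
  pc <- new_plan_case(kb)
  cap <- 50L * length(kb$hypotheses) * 20L + 1000L
  steps <- 0L
  while (length(pc$pending)) {
    steps <- steps + 1L
    if (steps > cap) stop("reasoning engine exceeded its iteration cap; knowledge base may be cyclic")
    entry <- pc$pending[[1]]
    pc$pending <- pc$pending[-1]
    key <- result_key(entry$hypothesis_id, entry$scope)
    if (!is.null(pc$completed[[key]])) next
    result <- evaluate_entry(entry, pc, ctx, kb)
    pc$completed[[key]] <- result
    pc$provenance <- c(pc$provenance,
                       sprintf("evaluated %s [%s] -> %s", entry$hypothesis_id,
                               entry$scope, result$state))
    pc <- register_events(pc, result)
    pc <- update_plan(pc, result, entry$scope, kb)
  }
  # assemble the run result
  results <- list()
  for (key in names(pc$completed)) {
    r <- pc$completed[[key]]
    scope <- sub("^[^@]*@", "", key)
    results[[length(results) + 1]] <-
      list(hypothesis_id = r$hypothesis_id, scope = scope, state = r$state,
           justification = r$justification, evidence = r$evidence)
  }
  rel_ids <- names(kb$hypotheses)[vapply(kb$hypotheses, function(h) h$family == "reliability", logical(1))]
  rel_results <- pc$completed[result_key(rel_ids, "dataset")]
  rel_results <- rel_results[!vapply(rel_results, is.null, logical(1))]
  reliability <- grade_reliability(ctx, rel_results)
  events <- list()
  gaps <- character(0)
  for (eid in names(pc$events)) {
    ev <- pc$events[[eid]]
    cause_keys <- names(pc$completed)[endsWith(names(pc$completed), paste0("@", eid))]
    causes <- pc$completed[cause_keys]
    names(causes) <- vapply(causes, `[[`, character(1), "hypothesis_id")
    if (!length(causes)) {
      det <- switch(ev$kind, short_sleep = "short_sleep", high_bp = "high_blood_pressure", ev$kind)
      causes <- stats::setNames(list(hyp_state(det, "TRUE",
                                               sprintf("%s detected with extreme value %s",
                                                       ev$kind, fmt_num(ev$extreme_value)))), det)
    }
    gap_id <- grep("lack_of_evidence$", names(causes), value = TRUE)
    gap <- length(gap_id) > 0 && causes[[gap_id[1]]]$state == "TRUE"
    if (gap) gaps <- c(gaps, eid)
    events[[eid]] <- list(event = ev, causes = causes, gap = gap)
  }
  rr <- structure(list(results = results, reliability = reliability,
                       trust_level = reliability$trust_level,
                       events = events, gaps = gaps,
                       provenance = pc$provenance, kb = kb),
                  class = "gr_run")
  rr$findings <- interpret(rr, kb)
  rr$summary <- summarize_events(rr)
  rr
}

#' @export
print.gr_run <- function(x, ...) {
  cat(sprintf("<consultation run> trust %d/50, %d event(s), %d finding(s), %d information gap(s)\n",
              as.integer(x$trust_level), length(x$events),
              length(x$findings), length(x$gaps)))
  invisible(x)
}

#' All hypothesis results of a run as a data.frame
#'
#' @param rr a `gr_run`.
#' @return data.frame with columns `hypothesis_id`, `scope`, `state`,
#'   `justification`.
#' @export
run_results_df <- function(rr) {
  data.frame(
    hypothesis_id = vapply(rr$results, `[[`, character(1), "hypothesis_id"),
    scope = vapply(rr$results, `[[`, character(1), "scope"),
    state = vapply(rr$results, `[[`, character(1), "state"),
    justification = vapply(rr$results, `[[`, character(1), "justification"),
    stringsAsFactors = FALSE
  )
}

#' Look up the state of a hypothesis in a run
#'
#' @param rr a `gr_run`.
#' @param hypothesis_id hypothesis identifier.
#' @param scope `"dataset"`, an event id, or `NULL` to match any scope.
#' @return character vector of states (`"TRUE"`, `"FALSE"`, `"NA"`);
#'   `character(0)` when the hypothesis was never instantiated.
#' @export
hypothesis_state <- function(rr, hypothesis_id, scope = NULL) {
  df <- run_results_df(rr)
  df <- df[df$hypothesis_id == hypothesis_id, , drop = FALSE]
  if (!is.null(scope)) df <- df[df$scope == scope, , drop = FALSE]
  df$state
}
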