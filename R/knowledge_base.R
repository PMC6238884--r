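# Declarative knowledge base: the hypothesis tree, activation requirements,
# plans, explanation templates, and its document (YAML) round-trip.

# activation requirements per hypothesis: which context must be present for
# the hypothesis to be applicable at all (NA otherwise)
REQUIRES_TABLE <- list(
  no_insulin_registered = "profile:uses_insulin",
  not_enough_registrations = "data:any",
  unequal_days_distribution = "data:any",
  unequal_weekdays_distribution = "data:any",
  source_inconsistency_hba1c = c("lab:hba1c", "data:blood_glucose"),
  source_inconsistency_isf = c("profile:reported_isf", "data:insulin"),
  source_inconsistency_icr = c("profile:reported_icr", "data:insulin"),
  hyperglycemia = "data:blood_glucose",
  hypoglycemia = "data:blood_glucose",
  high_blood_pressure = "data:blood_pressure",
  hyper_not_enough_insulin = "profile:uses_insulin",
  hyper_iob_below_average = c("profile:uses_insulin", "data:insulin_bolus"),
  hyper_last_dose_insufficient = c("profile:uses_insulin", "data:insulin_bolus"),
  hyper_icr_too_low = c("profile:uses_insulin", "data:insulin_bolus", "data:carbohydrates"),
  hyper_no_insulin_at_meal = c("profile:uses_insulin", "data:insulin_bolus", "data:carbohydrates"),
  hyper_cob_above_average = c("data:carbohydrates", "profile:carb_absorption_rate"),
  hyper_intake_above_recommendation = "data:carbohydrates",
  hyper_no_physical_activity = "data:physical_activity",
  hypo_too_much_insulin = "profile:uses_insulin",
  hypo_iob_above_average = c("profile:uses_insulin", "data:insulin_bolus"),
  hypo_last_dose_too_high = c("profile:uses_insulin", "data:insulin_bolus"),
  hypo_active_insulin_exceeds_need = c("profile:uses_insulin", "data:insulin_bolus", "data:carbohydrates"),
  hypo_no_carbs_4h = "data:carbohydrates",
  hypo_intake_below_recommendation = "data:carbohydrates",
  hypo_light_moderate_activity = "data:physical_activity",
  hypo_extreme_activity = "data:physical_activity"
)

hypothesis_requires <- function(id) {
  r <- REQUIRES_TABLE[[id]]
  if (is.null(r)) character(0) else r
}

token_description <- function(token) {
  switch(token,
         "data:any" = "any registrations",
         "data:insulin" = "insulin registrations",
         "data:insulin_bolus" = "insulin bolus registrations",
         "data:blood_pressure" = "blood pressure registrations",
         "profile:uses_insulin" = "patient uses insulin",
         "profile:reported_isf" = "patient-reported insulin sensitivity factor",
         "profile:reported_icr" = "patient-reported insulin-to-carbohydrate ratio",
         "profile:carb_absorption_rate" = "patient-reported carbohydrate absorption rate",
         "lab:hba1c" = "laboratory HbA1c",
         sub("^data:", "", paste(gsub("_", " ", token), "registrations")))
}

token_met <- function(ctx, token) {
  if (startsWith(token, "data:")) {
    what <- sub("^data:", "", token)
    types <- switch(what,
                    any = DATA_TYPES,
                    insulin = c("insulin_bolus", "insulin_basal"),
                    blood_pressure = c("blood_pressure_systolic", "blood_pressure_diastolic"),
                    what)
    return(nrow(regs_of(ctx, types)) > 0)
  }
  if (startsWith(token, "profile:")) {
    field <- sub("^profile:", "", token)
    v <- ctx$profile[[field]]
    if (field == "uses_insulin") return(isTRUE(v))
    return(!is.null(v) && is.finite(v))
  }
  if (startsWith(token, "lab:")) {
    v <- ctx$lab[[sub("^lab:", "", token)]]
    return(!is.null(v) && is.finite(v))
  }
  stop("unknown requirement token: ", token)
}

#' Check an activation predicate against the current context
#'
#' @param ctx a `gr_context`.
#' @param tokens character vector of requirement tokens, e.g.
#'   `"data:carbohydrates"`, `"profile:reported_isf"`, `"lab:hba1c"`.
#' @return `NULL` when every requirement is met, otherwise a human-readable
#'   description of the missing context.
#' @export
check_requires <- function(ctx, tokens) {
  for (tok in tokens) {
    if (!token_met(ctx, tok)) return(token_description(tok))
  }
  NULL
}

hdef <- function(id, label, family, parent = "", combine = "leaf",
                 event_kind = "", grade = 0, template = "",
                 evidence_keys = character(0), children = character(0)) {
  list(id = id, label = label, family = family, parent = parent,
       combine = combine, event_kind = event_kind, grade = grade,
       template = template, evidence_keys = evidence_keys,
       children = children, requires = hypothesis_requires(id))
}

#' Construct the default knowledge base
#'
#' Encodes the shipped hypothesis tree: the data-reliability family (missing
#' types, error values, registration counts, day/weekday distribution,
#' source inconsistencies), the four noticeable-event detectors, and the
#' per-event cause trees for hyperglycemia (five branches), hypoglycemia
#' (five mirror branches) and high blood pressure. Thresholds are injected
#' from the configuration so one knowledge base works under alternative
#' guideline values.
#'
#' @param config a [threshold_config()].
#' @return list of class `gr_kb` with `hypotheses`, `plans`, `tasks`,
#'   `config`.
#' @examples
#' kb <- default_kb()
#' length(kb$hypotheses)
#' @export
default_kb <- function(config = threshold_config()) {
  validate_config(config)
  H <- list()
  add <- function(h) H[[h$id]] <<- h
  # -- reliability family
  add(hdef("no_blood_glucose_registered", "No blood glucose registered", "reliability",
           grade = config$grades$no_blood_glucose_registered))
  add(hdef("no_carbohydrates_registered", "No carbohydrates registered", "reliability",
           grade = config$grades$no_carbohydrates_registered))
  add(hdef("no_insulin_registered", "No insulin registered", "reliability",
           grade = config$grades$no_insulin_registered))
  add(hdef("no_physical_activity_registered", "No physical activity registered", "reliability",
           grade = config$grades$no_physical_activity_registered))
  add(hdef("error_values_blood_glucose", "Error values in blood glucose", "reliability",
           grade = config$grades$error_values_blood_glucose))
  add(hdef("error_values_carbohydrates", "Error values in carbohydrates", "reliability",
           grade = config$grades$error_values_carbohydrates))
  add(hdef("error_values_insulin", "Error values in insulin", "reliability",
           grade = config$grades$error_values_insulin))
  add(hdef("not_enough_registrations", "Not enough data registrations", "reliability",
           grade = config$grades$not_enough_registrations))
  add(hdef("unequal_days_distribution", "Data not distributed equally between days", "reliability",
           grade = config$grades$unequal_days_distribution))
  add(hdef("unequal_weekdays_distribution", "Data not distributed equally between weekdays", "reliability",
           grade = config$grades$unequal_weekdays_distribution))
  add(hdef("source_inconsistency_hba1c", "Inconsistency between estimated and laboratory HbA1c", "reliability",
           grade = config$grades$source_inconsistency_hba1c,
           evidence_keys = c("calculated", "reference", "deviation")))
  add(hdef("source_inconsistency_isf", "Inconsistency between calculated and reported insulin sensitivity", "reliability",
           grade = config$grades$source_inconsistency_isf,
           evidence_keys = c("calculated", "reference", "deviation")))
  add(hdef("source_inconsistency_icr", "Inconsistency between calculated and reported insulin-to-carbohydrate ratio", "reliability",
           grade = config$grades$source_inconsistency_icr,
           evidence_keys = c("calculated", "reference", "deviation")))
  # -- detection roots
  add(hdef("hyperglycemia", "Patient has hyperglycemia", "detection"))
  add(hdef("hypoglycemia", "Patient has hypoglycemia", "detection"))
  add(hdef("high_blood_pressure", "Patient has high blood pressure", "detection"))
  add(hdef("short_sleep", "Patient slept less than the recommended period", "detection"))
  # -- hyperglycemia cause tree
  add(hdef("hyper_not_enough_insulin", "There is not enough insulin", "cause",
           combine = "invalidate", event_kind = "hyperglycemia",
           template = "This hyperglycemic event may have been due to not enough insulin.",
           children = c("hyper_iob_below_average", "hyper_last_dose_insufficient",
                        "hyper_icr_too_low", "hyper_no_insulin_at_meal")))
  add(hdef("hyper_iob_below_average", "Current active insulin below the period average", "cause",
           parent = "hyper_not_enough_insulin", event_kind = "hyperglycemia",
           template = "Active insulin at the event ({current_iob} U) was below the period average ({average_iob} U).",
           evidence_keys = c("current_iob", "average_iob")))
  add(hdef("hyper_last_dose_insufficient", "Dose of the last insulin shot insufficient", "cause",
           parent = "hyper_not_enough_insulin", event_kind = "hyperglycemia",
           template = "The last insulin dose ({last_dose} U) may have been insufficient: about {required_dose} U would have been needed to reach the glucose target.",
           evidence_keys = c("last_dose", "required_dose", "isf")))
  add(hdef("hyper_icr_too_low", "Mealtime insulin did not cover the carbohydrates", "cause",
           parent = "hyper_not_enough_insulin", event_kind = "hyperglycemia",
           template = "The mealtime insulin ({given_insulin} U) may not have covered {meal_carbs} g of carbohydrates (about {required_insulin} U needed).",
           evidence_keys = c("meal_carbs", "required_insulin", "given_insulin", "icr")))
  add(hdef("hyper_no_insulin_at_meal", "No insulin taken before or after a meal", "cause",
           parent = "hyper_not_enough_insulin", event_kind = "hyperglycemia",
           template = "No insulin was registered around a meal taken before the event.",
           evidence_keys = "uncovered_meals"))
  add(hdef("hyper_too_much_carbohydrates", "There are too many carbohydrates", "cause",
           combine = "invalidate", event_kind = "hyperglycemia",
           template = "This hyperglycemic event may have been due to too many carbohydrates.",
           children = c("hyper_cob_above_average", "hyper_intake_above_recommendation")))
  add(hdef("hyper_cob_above_average", "Carbohydrates on board above the period average", "cause",
           parent = "hyper_too_much_carbohydrates", event_kind = "hyperglycemia",
           template = "Carbohydrates on board ({current_cob} g) were above the period average ({average_cob} g).",
           evidence_keys = c("current_cob", "average_cob")))
  add(hdef("hyper_intake_above_recommendation", "Last intake above the recommendation", "cause",
           parent = "hyper_too_much_carbohydrates", event_kind = "hyperglycemia",
           template = "The last intake ({intake} g) exceeded the recommended maximum of {limit} g.",
           evidence_keys = c("intake", "limit", "intake_class")))
  add(hdef("hyper_external_factors", "External factors present", "cause",
           event_kind = "hyperglycemia",
           template = "This hyperglycemic event may have been affected by an external factor (e.g. menstruation, polypharmacy, sickness).",
           evidence_keys = "factors"))
  add(hdef("hyper_no_physical_activity", "No physical activity in the previous 24 hours", "cause",
           event_kind = "hyperglycemia",
           template = "This hyperglycemic event may have been due to a lack of physical activity in the preceding 24 hours.",
           evidence_keys = "n_activity"))
  add(hdef("hyper_lack_of_evidence", "Lack of evidence", "cause",
           combine = "lack_of_evidence", event_kind = "hyperglycemia",
           template = "The module lacked evidence to explain this event; consider investigating the data registered around this time.",
           children = c("hyper_not_enough_insulin", "hyper_too_much_carbohydrates",
                        "hyper_external_factors", "hyper_no_physical_activity")))
  # -- hypoglycemia cause tree (mirror)
  add(hdef("hypo_too_much_insulin", "There is too much insulin", "cause",
           combine = "invalidate", event_kind = "hypoglycemia",
           template = "This hypoglycemic event may have been due to too much insulin.",
           children = c("hypo_iob_above_average", "hypo_last_dose_too_high",
                        "hypo_active_insulin_exceeds_need")))
  add(hdef("hypo_iob_above_average", "Current active insulin above the period average", "cause",
           parent = "hypo_too_much_insulin", event_kind = "hypoglycemia",
           template = "Active insulin at the event ({current_iob} U) was above the period average ({average_iob} U).",
           evidence_keys = c("current_iob", "average_iob")))
  add(hdef("hypo_last_dose_too_high", "Dose of the last insulin shot too high", "cause",
           parent = "hypo_too_much_insulin", event_kind = "hypoglycemia",
           template = "The last insulin dose ({last_dose} U) may have been higher than the {required_dose} U required.",
           evidence_keys = c("last_dose", "required_dose", "isf")))
  add(hdef("hypo_active_insulin_exceeds_need", "Active insulin above the carbohydrate-covered need", "cause",
           parent = "hypo_too_much_insulin", event_kind = "hypoglycemia",
           template = "Active insulin ({current_iob} U) exceeded the {needed_insulin} U needed to cover recent carbohydrates.",
           evidence_keys = c("current_iob", "needed_insulin", "icr")))
  add(hdef("hypo_too_few_carbohydrates", "There are too few carbohydrates", "cause",
           combine = "invalidate", event_kind = "hypoglycemia",
           template = "This hypoglycemic event may have been due to too few carbohydrates.",
           children = c("hypo_no_carbs_4h", "hypo_intake_below_recommendation")))
  add(hdef("hypo_no_carbs_4h", "No carbohydrate intake up to 4 hours prior", "cause",
           parent = "hypo_too_few_carbohydrates", event_kind = "hypoglycemia",
           template = "No carbohydrate intake was registered in the 4 hours before the event.",
           evidence_keys = "n_intakes"))
  add(hdef("hypo_intake_below_recommendation", "Last intake below the recommendation", "cause",
           parent = "hypo_too_few_carbohydrates", event_kind = "hypoglycemia",
           template = "The last intake ({intake} g) was below the recommended minimum of {limit} g.",
           evidence_keys = c("intake", "limit", "intake_class")))
  add(hdef("hypo_external_factors", "External factors present", "cause",
           event_kind = "hypoglycemia",
           template = "This hypoglycemic event may have been affected by an external factor (e.g. menstruation, polypharmacy, sickness).",
           evidence_keys = "factors"))
  add(hdef("hypo_physical_activity", "Physical activity prior to the event", "cause",
           combine = "any_true", event_kind = "hypoglycemia",
           template = "This hypoglycemic event may have been due to physical activity.",
           children = c("hypo_light_moderate_activity", "hypo_extreme_activity")))
  add(hdef("hypo_light_moderate_activity", "Light-to-moderate activity up to 4 hours prior", "cause",
           parent = "hypo_physical_activity", event_kind = "hypoglycemia",
           template = "Light-to-moderate physical activity was registered within 4 hours of the event.",
           evidence_keys = "n_activity"))
  add(hdef("hypo_extreme_activity", "Extreme activity up to 24 hours prior", "cause",
           parent = "hypo_physical_activity", event_kind = "hypoglycemia",
           template = "Extreme physical activity was registered within 24 hours of the event.",
           evidence_keys = "n_activity"))
  add(hdef("hypo_lack_of_evidence", "Lack of evidence", "cause",
           combine = "lack_of_evidence", event_kind = "hypoglycemia",
           template = "The module lacked evidence to explain this event; consider investigating the data registered around this time.",
           children = c("hypo_too_much_insulin", "hypo_too_few_carbohydrates",
                        "hypo_external_factors", "hypo_physical_activity")))
  # -- high blood pressure checks
  add(hdef("bp_external_factors", "External factors present", "cause",
           event_kind = "high_bp",
           template = "This high blood pressure reading may have been affected by an external factor.",
           evidence_keys = "factors"))
  add(hdef("bp_lack_of_evidence", "Lack of evidence", "cause",
           combine = "lack_of_evidence", event_kind = "high_bp",
           template = "The module lacked evidence to explain this high blood pressure reading.",
           children = "bp_external_factors"))

  plans <- list(
    root = list(plan_id = "root", trigger = list(on = "root"),
                members = c(names(H)[vapply(H, function(h) h$family == "reliability", logical(1))],
                            "hyperglycemia", "hypoglycemia", "high_blood_pressure", "short_sleep")),
    hyper_causes = list(plan_id = "hyper_causes",
                        trigger = list(on = "hyperglycemia", state = "TRUE", per_event = TRUE),
                        members = c("hyper_iob_below_average", "hyper_last_dose_insufficient",
                                    "hyper_icr_too_low", "hyper_no_insulin_at_meal",
                                    "hyper_not_enough_insulin",
                                    "hyper_cob_above_average", "hyper_intake_above_recommendation",
                                    "hyper_too_much_carbohydrates",
                                    "hyper_external_factors", "hyper_no_physical_activity",
                                    "hyper_lack_of_evidence")),
    hypo_causes = list(plan_id = "hypo_causes",
                       trigger = list(on = "hypoglycemia", state = "TRUE", per_event = TRUE),
                       members = c("hypo_iob_above_average", "hypo_last_dose_too_high",
                                   "hypo_active_insulin_exceeds_need", "hypo_too_much_insulin",
                                   "hypo_no_carbs_4h", "hypo_intake_below_recommendation",
                                   "hypo_too_few_carbohydrates",
                                   "hypo_external_factors",
                                   "hypo_light_moderate_activity", "hypo_extreme_activity",
                                   "hypo_physical_activity",
                                   "hypo_lack_of_evidence")),
    bp_causes = list(plan_id = "bp_causes",
                     trigger = list(on = "high_blood_pressure", state = "TRUE", per_event = TRUE),
                     members = c("bp_external_factors", "bp_lack_of_evidence"))
  )
  tasks <- lapply(H, function(h) {
    list(task_id = paste0("task_", h$id), hypothesis_id = h$id,
         description = paste("check whether", tolower(h$label)),
         required_context = h$requires,
         evaluation_rule_id = if (h$combine == "leaf") paste0("rule_", h$id)
         else paste0("combine_", h$combine))
  })
  kb <- structure(list(hypotheses = H, plans = plans, tasks = tasks,
                       config = config), class = "gr_kb")
  diags <- validate_kb(kb)
  if (length(diags)) {
    stop("default knowledge base failed validation:\n  ",
         paste(diags, collapse = "\n  "))
  }
  kb
}

#' @export
print.gr_kb <- function(x, ...) {
  fam <- table(vapply(x$hypotheses, `[[`, character(1), "family"))
  cat(sprintf("<knowledge base> %d hypotheses (%s), %d plans\n",
              length(x$hypotheses),
              paste(sprintf("%s: %d", names(fam), as.integer(fam)), collapse = ", "),
              length(x$plans)))
  invisible(x)
}

#' Validate a knowledge base
#'
#' Reports dangling references (parents, children, plan members, trigger
#' hypotheses), cycles in plan membership, hypotheses unreachable from the
#' root plan or any trigger, template placeholders that no evidence key
#' produces, and unresolvable evaluation rules. An empty character vector
#' means the knowledge base is well-formed.
#'
#' @param kb a `gr_kb`.
#' @return character vector of diagnostics (empty when valid).
#' @export
validate_kb <- function(kb) {
  diags <- character(0)
  ids <- names(kb$hypotheses)
  for (h in kb$hypotheses) {
    if (nzchar(h$parent) && !h$parent %in% ids) {
      diags <- c(diags, sprintf("hypothesis '%s' references missing parent '%s'", h$id, h$parent))
    }
    for (ch in h$children) {
      if (!ch %in% ids) {
        diags <- c(diags, sprintf("hypothesis '%s' references missing child '%s'", h$id, ch))
      }
    }
    if (h$combine == "leaf" && !leaf_rule_known(h$id)) {
      diags <- c(diags, sprintf("hypothesis '%s' has no implemented evaluation rule", h$id))
    }
    if (!h$combine %in% c("leaf", "invalidate", "any_true", "lack_of_evidence")) {
      diags <- c(diags, sprintf("hypothesis '%s' has unknown combination '%s'", h$id, h$combine))
    }
    ph <- regmatches(h$template, gregexpr("\\{([a-z_]+)\\}", h$template))[[1]]
    ph <- gsub("[{}]", "", ph)
    bad <- setdiff(ph, h$evidence_keys)
    if (length(bad)) {
      diags <- c(diags, sprintf("hypothesis '%s' template references undeclared evidence key(s): %s",
                                h$id, paste(bad, collapse = ", ")))
    }
  }
  # plan references and membership cycles (plans may nest via "plan:<id>")
  visit <- function(pid, stack) {
    if (pid %in% stack) {
      diags <<- c(diags, sprintf("plan membership cycle: %s", paste(c(stack, pid), collapse = " -> ")))
      return(character(0))
    }
    p <- kb$plans[[pid]]
    if (is.null(p)) {
      diags <<- c(diags, sprintf("reference to missing plan '%s'", pid))
      return(character(0))
    }
    out <- character(0)
    for (m in p$members) {
      if (startsWith(m, "plan:")) {
        out <- c(out, visit(sub("^plan:", "", m), c(stack, pid)))
      } else if (!m %in% ids) {
        diags <<- c(diags, sprintf("plan '%s' references missing hypothesis '%s'", pid, m))
      } else {
        out <- c(out, m)
      }
    }
    out
  }
  reachable <- character(0)
  for (p in kb$plans) {
    trig <- p$trigger$on
    if (!identical(trig, "root") && !trig %in% ids) {
      diags <- c(diags, sprintf("plan '%s' triggered by missing hypothesis '%s'", p$plan_id, trig))
    }
    reachable <- c(reachable, visit(p$plan_id, character(0)))
  }
  unreachable <- setdiff(ids, reachable)
  for (u in unreachable) {
    diags <- c(diags, sprintf("hypothesis '%s' is unreachable from any plan or trigger", u))
  }
  diags
}

canon_chr <- function(x) if (is.null(x)) character(0) else as.character(x)

#' Serialize a knowledge base to a YAML document
#'
#' The knowledge base is plain data (no closures), so editing the document —
#' for instance to add a medication-adherence hypothesis for type 2 diabetes
#' — is a text edit, not a code change.
#'
#' @param kb a `gr_kb`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
save_kb <- function(kb, path) {
  doc <- list(
    hypotheses = lapply(unname(kb$hypotheses), function(h) {
      list(id = h$id, label = h$label, family = h$family, parent = h$parent,
           combine = h$combine, event_kind = h$event_kind, grade = h$grade,
           template = h$template,
           evidence_keys = as.list(canon_chr(h$evidence_keys)),
           children = as.list(canon_chr(h$children)))
    }),
    plans = lapply(unname(kb$plans), function(p) {
      list(plan_id = p$plan_id, trigger = p$trigger, members = as.list(p$members))
    }),
    config = unclass(kb$config)
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Load a knowledge base from a YAML document
#'
#' @param path file written by [save_kb()] or hand-edited in its schema.
#' @return a validated `gr_kb`; stops with the offending path on schema
#'   violations.
#' @export
load_kb <- function(path) {
  doc <- yaml::read_yaml(path)
  for (field in c("hypotheses", "plans", "config")) {
    if (is.null(doc[[field]])) stop("knowledge base document missing '", field, "'")
  }
  cfg <- doc$config
  cfg$bg_plausible_range <- as.numeric(unlist(cfg$bg_plausible_range))
  cfg$carbs_plausible_range <- as.numeric(unlist(cfg$carbs_plausible_range))
  cfg$insulin_plausible_range <- as.numeric(unlist(cfg$insulin_plausible_range))
  config <- do.call(threshold_config, cfg)
  H <- list()
  for (i in seq_along(doc$hypotheses)) {
    h <- doc$hypotheses[[i]]
    for (field in c("id", "label", "family", "combine")) {
      if (is.null(h[[field]])) {
        stop(sprintf("hypotheses[%d]: missing '%s'", i, field))
      }
    }
    H[[h$id]] <- list(id = h$id, label = h$label, family = h$family,
                      parent = if (is.null(h$parent)) "" else h$parent,
                      combine = h$combine,
                      event_kind = if (is.null(h$event_kind)) "" else h$event_kind,
                      grade = if (is.null(h$grade)) 0 else as.numeric(h$grade),
                      template = if (is.null(h$template)) "" else h$template,
                      evidence_keys = canon_chr(unlist(h$evidence_keys)),
                      children = canon_chr(unlist(h$children)),
                      requires = hypothesis_requires(h$id))
  }
  plans <- list()
  for (i in seq_along(doc$plans)) {
    p <- doc$plans[[i]]
    if (is.null(p$plan_id) || is.null(p$members)) {
      stop(sprintf("plans[%d]: missing 'plan_id' or 'members'", i))
    }
    plans[[p$plan_id]] <- list(plan_id = p$plan_id, trigger = p$trigger,
                               members = as.character(unlist(p$members)))
  }
  tasks <- lapply(H, function(h) {
    list(task_id = paste0("task_", h$id), hypothesis_id = h$id,
         description = paste("check whether", tolower(h$label)),
         required_context = h$requires,
         evaluation_rule_id = if (h$combine == "leaf") paste0("rule_", h$id)
         else paste0("combine_", h$combine))
  })
  kb <- structure(list(hypotheses = H, plans = plans, tasks = tasks,
                       config = config), class = "gr_kb")
  diags <- validate_kb(kb)
  if (length(diags)) {
    stop("loaded knowledge base failed validation:\n  ",
         paste(diags, collapse = "\n  "))
  }
  kb
}
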