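# Interpretation layer: hedged textual findings, event summaries with
# hour/weekday distributions, and report rendering.

fill_template <- function(template, evidence) {
  out <- template
  keys <- regmatches(template, gregexpr("\\{([a-z_]+)\\}", template))[[1]]
  for (k in gsub("[{}]", "", keys)) {
    v <- evidence[[k]]
    txt <- if (is.null(v)) "NA"
    else if (is.character(v)) paste(v, collapse = ", ")
    else paste(vapply(v, fmt_num, character(1)), collapse = ", ")
    out <- gsub(paste0("{", k, "}"), txt, out, fixed = TRUE)
  }
  out
}

new_finding <- function(scope, headline, justifications, severity) {
  structure(list(scope = scope, headline = headline,
                 justifications = justifications, severity = severity),
            class = "gr_finding")
}

#' @export
print.gr_finding <- function(x, ...) {
  cat(sprintf("[%s] (%s) %s\n", x$severity, x$scope, x$headline))
  for (j in x$justifications) cat("    - ", j, "\n", sep = "")
  invisible(x)
}

#' Interpret a consultation run into textual findings
#'
#' Maps hypothesis results through the explanation templates: one hedged
#' finding per validated top-level cause branch per event (its TRUE children
#' supply the justifications), one information-gap finding per event whose
#' lack-of-evidence hypothesis is TRUE, and one warning per validated
#' reliability sub-hypothesis carrying its recommendation. Findings are a
#' pure function of the run and the knowledge base.
#'
#' @param rr a `gr_run`.
#' @param kb a `gr_kb` (defaults to the one the run used).
#' @return list of `gr_finding` objects.
#' @export
interpret <- function(rr, kb = rr$kb) {
  findings <- list()
  add <- function(f) findings[[length(findings) + 1]] <<- f
  # reliability warnings, in knowledge-base order
  rel <- Filter(function(r) {
    h <- kb$hypotheses[[r$hypothesis_id]]
    !is.null(h) && h$family == "reliability" && r$state == "TRUE"
  }, rr$results)
  for (r in rel) {
    rec <- r$evidence$recommendation
    add(new_finding("dataset", r$justification,
                    if (is.null(rec)) character(0) else rec, "warning"))
  }
  # per-event cause findings and gaps
  for (eid in names(rr$events)) {
    causes <- rr$events[[eid]]$causes
    for (cid in names(causes)) {
      h <- kb$hypotheses[[cid]]
      if (is.null(h) || h$family != "cause") next
      if (nzchar(h$parent)) next  # only top-level branches headline a finding
      r <- causes[[cid]]
      if (r$state != "TRUE") next
      if (h$combine == "lack_of_evidence") {
        add(new_finding(eid, fill_template(h$template, r$evidence),
                        r$justification, "gap"))
        next
      }
      just <- character(0)
      for (ch in h$children) {
        cr <- causes[[ch]]
        if (!is.null(cr) && cr$state == "TRUE") {
          cht <- kb$hypotheses[[ch]]$template
          just <- c(just, fill_template(cht, cr$evidence))
        }
      }
      if (!length(just) && h$combine == "leaf") just <- r$justification
      add(new_finding(eid, fill_template(h$template, r$evidence), just, "info"))
    }
  }
  findings
}

WEEKDAYS <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

#' Summarize noticeable events
#'
#' Counts per event kind and per main potential cause (top-level branch — a
#' single event can contribute to several cause counts), plus per-hour
#' (24 bins) and per-weekday (7 bins) distributions of the events' reference
#' times, per kind.
#'
#' @param rr a `gr_run`.
#' @return list of class `gr_summary` with `kinds`, `causes`, `gaps`,
#'   `per_hour` and `per_weekday`.
#' @export
summarize_events <- function(rr) {
  kinds <- c(hyperglycemia = 0L, hypoglycemia = 0L, high_bp = 0L, short_sleep = 0L)
  per_hour <- lapply(kinds, function(x) stats::setNames(integer(24), 0:23))
  per_weekday <- lapply(kinds, function(x) stats::setNames(integer(7), WEEKDAYS))
  causes <- list()
  n_gap <- 0L
  for (eid in names(rr$events)) {
    e <- rr$events[[eid]]
    k <- e$event$kind
    kinds[k] <- kinds[k] + 1L
    hr <- as.integer(format(e$event$reference_time, "%H"))
    wd <- as.integer(format(as.Date(e$event$reference_time), "%u"))
    per_hour[[k]][hr + 1] <- per_hour[[k]][hr + 1] + 1L
    per_weekday[[k]][wd] <- per_weekday[[k]][wd] + 1L
    if (isTRUE(e$gap)) n_gap <- n_gap + 1L
    for (cid in names(e$causes)) {
      h <- rr$kb$hypotheses[[cid]]
      if (is.null(h) || h$family != "cause" || nzchar(h$parent)) next
      if (h$combine == "lack_of_evidence") next
      if (e$causes[[cid]]$state == "TRUE") {
        causes[[cid]] <- (causes[[cid]] %||% 0L) + 1L
      }
    }
  }
  structure(list(kinds = kinds, causes = causes, gaps = n_gap,
                 per_hour = per_hour, per_weekday = per_weekday),
            class = "gr_summary")
}

#' @export
print.gr_summary <- function(x, ...) {
  cat("<event summary>\n")
  for (k in names(x$kinds)) {
    if (x$kinds[k] > 0) cat(sprintf("  %s: %d\n", k, x$kinds[k]))
  }
  if (length(x$causes)) {
    cat("  main potential causes:\n")
    for (cid in names(x$causes)) cat(sprintf("    %s: %d\n", cid, x$causes[[cid]]))
  }
  cat(sprintf("  information gaps: %d\n", x$gaps))
  invisible(x)
}

report_list <- function(rr, include_trust) {
  ev <- lapply(names(rr$events), function(eid) {
    e <- rr$events[[eid]]
    list(event_id = eid, kind = e$event$kind,
         start = format(e$event$start, "%Y-%m-%d %H:%M"),
         end = format(e$event$end, "%Y-%m-%d %H:%M"),
         reference_time = format(e$event$reference_time, "%Y-%m-%d %H:%M"),
         extreme_value = e$event$extreme_value,
         information_gap = e$gap,
         causes = lapply(unname(e$causes), function(r) {
           list(hypothesis_id = r$hypothesis_id, state = r$state,
                justification = r$justification)
         }))
  })
  out <- list(
    findings = lapply(rr$findings, unclass),
    events = ev,
    summary = list(kinds = as.list(rr$summary$kinds),
                   causes = rr$summary$causes,
                   information_gaps = rr$summary$gaps,
                   per_hour = lapply(rr$summary$per_hour, as.list),
                   per_weekday = lapply(rr$summary$per_weekday, as.list)),
    results = lapply(rr$results, function(r) {
      list(hypothesis_id = r$hypothesis_id, scope = r$scope, state = r$state,
           justification = r$justification)
    })
  )
  if (include_trust) {
    out$reliability <- list(trust_level = rr$trust_level,
                            violations = rr$reliability$violations,
                            recommendations = as.list(rr$reliability$recommendations))
  } else {
    out$reliability <- list(alerts = as.list(rr$reliability$recommendations))
  }
  out
}

render_markdown <- function(rr) {
  lines <- c("# Consultation report", "")
  warn <- Filter(function(f) f$severity == "warning", rr$findings)
  if (length(warn)) {
    lines <- c(lines, "## Data reliability alerts", "")
    for (f in warn) {
      lines <- c(lines, paste0("- ", f$headline))
      for (j in f$justifications) lines <- c(lines, paste0("    - ", j))
    }
    lines <- c(lines, "")
  }
  if (length(rr$events)) {
    lines <- c(lines, "## Noticeable events", "")
    for (eid in names(rr$events)) {
      e <- rr$events[[eid]]
      lines <- c(lines, sprintf("### %s at %s (value %s)", e$event$kind,
                                format(e$event$reference_time, "%Y-%m-%d %H:%M"),
                                fmt_num(e$event$extreme_value)))
      efind <- Filter(function(f) f$scope == eid, rr$findings)
      if (!length(efind)) lines <- c(lines, "", "No potential cause was validated.")
      for (f in efind) {
        lines <- c(lines, "", paste0("- ", f$headline))
        for (j in f$justifications) lines <- c(lines, paste0("    - ", j))
      }
      lines <- c(lines, "")
    }
    lines <- c(lines, "## Summary", "")
    for (k in names(rr$summary$kinds)) {
      if (rr$summary$kinds[k] > 0) {
        lines <- c(lines, sprintf("- %s events: %d", k, rr$summary$kinds[k]))
      }
    }
    for (cid in names(rr$summary$causes)) {
      lines <- c(lines, sprintf("- events possibly caused by '%s': %d",
                                rr$kb$hypotheses[[cid]]$label, rr$summary$causes[[cid]]))
    }
    lines <- c(lines, sprintf("- information gaps: %d", rr$summary$gaps), "")
  } else {
    lines <- c(lines, "No noticeable events detected in the period.", "")
  }
  paste(lines, collapse = "\n")
}

#' Render a consultation report
#'
#' JSON reports carry the full machine-readable result including the numeric
#' trust level; markdown and HTML reports are for human display and omit the
#' numeric reliability grade, showing only the textual alerts. Rendering is
#' deterministic: the same run renders to byte-identical documents.
#'
#' @param rr a `gr_run`.
#' @param format `"json"`, `"markdown"` or `"html"`.
#' @return a character scalar (the document).
#' @export
render_report <- function(rr, format = c("json", "markdown", "html")) {
  if (length(format) > 1) format <- format[1]
  if (!format %in% c("json", "markdown", "html")) {
    stop("unknown report format: ", format)
  }
  if (format == "json") {
    return(as.character(jsonlite::toJSON(report_list(rr, include_trust = TRUE),
                                         auto_unbox = TRUE, digits = NA,
                                         null = "null")))
  }
  md <- render_markdown(rr)
  if (format == "markdown") return(md)
  paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/>",
         "<title>Consultation report</title></head>\n<body>\n<pre>\n",
         gsub("<", "&lt;", md, fixed = TRUE),
         "\n</pre>\n</body></html>\n")
}
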