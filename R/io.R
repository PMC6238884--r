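# Diary/profile/config readers and writers and the command-line interface.
#
# Diary dialect (versioned, documented in the README):
#   CSV columns: timestamp, data_type, value, unit, activity_kind,
#                activity_tag, factor_tag, source, manual
#   JSON: array with one object per registration, same field names.
# The unit column drives conversion (mg/dL -> mmol/L); unknown units are
# row errors, reported with 1-based file line numbers.

CANONICAL_UNITS <- list(blood_glucose = "mmol/L", insulin_bolus = "U",
                        insulin_basal = "U", carbohydrates = "g",
                        physical_activity = "", blood_pressure_systolic = "mmHg",
                        blood_pressure_diastolic = "mmHg", weight = "kg",
                        external_factor = "")

convert_unit <- function(value, data_type, unit, mgdl_per_mmol) {
  unit <- trimws(unit)
  if (is.na(unit)) unit <- ""
  canonical <- CANONICAL_UNITS[[data_type]]
  if (is.null(canonical)) return(NULL)
  if (unit == "" || tolower(unit) == tolower(canonical)) return(value)
  if (data_type == "blood_glucose" && tolower(unit) %in% c("mg/dl", "mgdl")) {
    return(value / mgdl_per_mmol)
  }
  NULL
}

parse_diary_row <- function(row, line_no, mgdl_per_mmol) {
  ts <- tryCatch(as_timestamp(row$timestamp), error = function(e) NA)
  if (is.na(ts)) {
    return(list(error = sprintf("line %d: unparseable timestamp '%s'", line_no, row$timestamp)))
  }
  if (!row$data_type %in% DATA_TYPES) {
    return(list(error = sprintf("line %d: unknown data_type '%s'", line_no, row$data_type)))
  }
  value <- suppressWarnings(as.numeric(row$value))
  conv <- convert_unit(value, row$data_type, row$unit, mgdl_per_mmol)
  if (is.null(conv)) {
    return(list(error = sprintf("line %d: unknown unit '%s' for %s", line_no,
                                row$unit, row$data_type)))
  }
  reg <- registration(ts, row$data_type, conv,
                      activity_kind = row$activity_kind %||% NA_character_,
                      activity_tag = row$activity_tag %||% NA_character_,
                      factor_tag = row$factor_tag %||% NA_character_,
                      source = row$source %||% "unknown",
                      manual = isTRUE(as.logical(row$manual %||% TRUE)))
  problems <- validate_registrations(reg)
  if (length(problems)) {
    return(list(error = sprintf("line %d: %s", line_no, sub("^row 1: ", "", problems[1]))))
  }
  list(registration = reg)
}

na_if_empty <- function(x) {
  x <- as.character(x)
  ifelse(is.na(x) | x == "", NA_character_, x)
}

#' Read a diary file
#'
#' Reads the CSV or JSON diary dialect, converting units to the canonical
#' internal ones (glucose to mmol/L). Row-level problems are collected and
#' reported with 1-based file line numbers; in partial mode the valid rows
#' are returned with a warning, otherwise any bad row is an error. A file
#' with no valid rows always fails.
#'
#' @param path file path.
#' @param format `"csv"`, `"json"`, or `NULL` to infer from the extension.
#' @param partial return valid rows despite row errors.
#' @param config a [threshold_config()] (supplies the mg/dL factor).
#' @return registration data.frame.
#' @export
read_diary <- function(path, format = NULL, partial = FALSE,
                       config = threshold_config()) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    line_nos <- seq_len(nrow(raw)) + 1L  # header is line 1
  } else if (format == "json") {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    raw[] <- lapply(raw, as.character)
    line_nos <- seq_len(nrow(raw))
  } else {
    stop("unknown diary format: ", format)
  }
  for (col in c("activity_kind", "activity_tag", "factor_tag", "source", "manual", "unit")) {
    if (is.null(raw[[col]])) raw[[col]] <- NA_character_
  }
  rows <- list()
  errors <- character(0)
  for (i in seq_len(nrow(raw))) {
    row <- lapply(raw[i, , drop = FALSE], na_if_empty)
    row$manual <- if (is.na(row$manual)) "TRUE" else row$manual
    parsed <- parse_diary_row(row, line_nos[i], config$mgdl_per_mmol)
    if (!is.null(parsed$error)) {
      errors <- c(errors, parsed$error)
    } else {
      rows[[length(rows) + 1]] <- parsed$registration
    }
  }
  if (length(rows) == 0) {
    stop("no valid rows in ", path, ":\n  ", paste(errors, collapse = "\n  "))
  }
  if (length(errors)) {
    if (!partial) {
      stop("invalid rows in ", path, ":\n  ", paste(errors, collapse = "\n  "))
    }
    warning(sprintf("skipped %d invalid row(s):\n  %s", length(errors),
                    paste(errors, collapse = "\n  ")))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a diary file
#'
#' Writes the canonical dialect (canonical units, ISO-8601 minute-resolution
#' timestamps). `read_diary(write_diary(x))` restores `x`.
#'
#' @param regs registration data.frame.
#' @param path output path.
#' @param format `"csv"` or `"json"` (inferred from the extension when NULL).
#' @return `path`, invisibly.
#' @export
write_diary <- function(regs, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  out <- data.frame(
    timestamp = format(regs$timestamp, "%Y-%m-%d %H:%M"),
    data_type = regs$data_type,
    value = regs$value,
    unit = vapply(regs$data_type, function(t) CANONICAL_UNITS[[t]], character(1)),
    activity_kind = regs$activity_kind,
    activity_tag = regs$activity_tag,
    factor_tag = regs$factor_tag,
    source = regs$source,
    manual = regs$manual,
    stringsAsFactors = FALSE
  )
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, na = "")
  } else if (format == "json") {
    writeLines(as.character(jsonlite::toJSON(out, dataframe = "rows", na = "null",
                                             auto_unbox = TRUE, digits = NA)), path)
  } else {
    stop("unknown diary format: ", format)
  }
  invisible(path)
}

#' Read a patient profile from YAML or JSON
#'
#' @param path file with [patient_profile()] fields.
#' @return a `gr_profile`.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(doc$mealtime_windows)) {
    doc$mealtime_windows <- lapply(doc$mealtime_windows, unlist)
  }
  do.call(patient_profile, doc)
}

#' Read a threshold configuration from YAML
#'
#' The document mirrors [threshold_config()] field-for-field; absent fields
#' keep their defaults.
#'
#' @param path YAML file.
#' @return a `gr_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- yaml::read_yaml(path)
  for (f in c("bg_plausible_range", "carbs_plausible_range", "insulin_plausible_range")) {
    if (!is.null(doc[[f]])) doc[[f]] <- as.numeric(unlist(doc[[f]]))
  }
  do.call(threshold_config, doc)
}

#' Read a laboratory context from YAML or JSON
#'
#' @param path file with `hba1c` (and optional `hba1c_date`).
#' @return a `gr_lab`.
#' @export
read_lab <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  lab_context(hba1c = doc$hba1c, hba1c_date = doc$hba1c_date)
}

cli_usage <- function() {
  paste(
    "usage: glucoreason <command> [options]",
    "",
    "commands:",
    "  analyze     --diary FILE --profile FILE [--lab FILE] [--config FILE]",
    "              [--kb FILE] [--format json|markdown|html] [--out FILE]",
    "  generate    [--days N] [--seed N] --out FILE",
    "  validate-kb --kb FILE",
    sep = "\n")
}

parse_cli_args <- function(args) {
  out <- list(command = if (length(args)) args[1] else NULL)
  args <- args[-1]
  i <- 1
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--")) stop("unexpected argument: ", key)
    if (i + 1 > length(args)) stop("missing value for ", key)
    out[[sub("^--", "", key)]] <- args[i + 1]
    i <- i + 2
  }
  out
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `inst/cli/glucoreason` script: `analyze` runs
#' a consultation on a diary and writes a report, `generate` writes a
#' synthetic diary, `validate-kb` checks a knowledge-base document. Returns
#' the exit status (0 success, 2 validation failure) rather than quitting,
#' so it is testable in-process.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    opts <- parse_cli_args(args)
    if (is.null(opts$command)) {
      message(cli_usage())
      return(invisible(2L))
    }
    switch(opts$command,
           analyze = cli_analyze(opts),
           generate = cli_generate(opts),
           `validate-kb` = cli_validate_kb(opts),
           {
             message("unknown command: ", opts$command)
             message(cli_usage())
             2L
           })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}

cli_analyze <- function(opts) {
  if (is.null(opts$diary) || is.null(opts$profile)) {
    message("analyze requires --diary and --profile")
    return(2L)
  }
  config <- if (!is.null(opts$config)) read_config(opts$config) else threshold_config()
  regs <- read_diary(opts$diary, config = config)
  profile <- read_profile(opts$profile)
  lab <- if (!is.null(opts$lab)) read_lab(opts$lab) else lab_context()
  kb <- if (!is.null(opts$kb)) load_kb(opts$kb) else default_kb(config)
  ctx <- build_context(regs, profile, lab, config)
  t0 <- proc.time()[["elapsed"]]
  rr <- run_consultation(ctx, kb)
  elapsed <- proc.time()[["elapsed"]] - t0
  message(sprintf("evaluated %d hypothesis instance(s), %d event(s), %d finding(s) in %.2fs",
                  length(rr$results), length(rr$events), length(rr$findings), elapsed))
  fmt <- opts$format %||% "json"
  doc <- render_report(rr, fmt)
  if (!is.null(opts$out)) {
    writeLines(doc, opts$out)
    message("report written to ", opts$out)
  } else {
    cat(doc, "\n")
  }
  0L
}

cli_generate <- function(opts) {
  if (is.null(opts$out)) {
    message("generate requires --out")
    return(2L)
  }
  spec <- scenario_spec(days = as.integer(opts$days %||% 14),
                        seed = as.integer(opts$seed %||% 1))
  d <- generate_diary(spec)
  write_diary(d$registrations, opts$out)
  message(sprintf("wrote %d registrations to %s", nrow(d$registrations), opts$out))
  0L
}

cli_validate_kb <- function(opts) {
  kb <- if (is.null(opts$kb)) default_kb() else load_kb(opts$kb)
  diags <- validate_kb(kb)
  if (length(diags)) {
    message(paste(diags, collapse = "\n"))
    return(2L)
  }
  message(sprintf("knowledge base OK: %d hypotheses, %d plans",
                  length(kb$hypotheses), length(kb$plans)))
  0L
}
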