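# Vocabulary systems the record model accepts.  Codes from unknown systems
# are preserved verbatim; they simply never match any concept set.
VALID_SYSTEMS <- c("SNOMED", "LOINC", "MEDCLASS", "ICD9", "LOCAL")

# Event kinds a visit record may carry.
VALID_KINDS <- c("problem", "lab", "medication", "exam", "discharge_dx")

#' Construct a concept code
#'
#' A concept code identifies one clinical concept in a named vocabulary
#' (SNOMED, LOINC, MEDCLASS, ICD9 or LOCAL).  Equality is exact
#' (system, code) pair equality, case-sensitive.
#'
#' @param system Vocabulary name (non-empty string).
#' @param code Opaque code string (non-empty).
#' @param display Optional human-readable label.
#' @return A `concept_code` object (a named list).
#' @export
concept_code <- function(system, code, display = NULL) {
  if (!is.character(system) || length(system) != 1L || !nzchar(system))
    stop("concept_code: `system` must be a non-empty string", call. = FALSE)
  if (!is.character(code) || length(code) != 1L || !nzchar(code))
    stop("concept_code: `code` must be a non-empty string", call. = FALSE)
  structure(list(system = system, code = code, display = display),
            class = "concept_code")
}

#' @export
print.concept_code <- function(x, ...) {
  cat(sprintf("<%s %s>%s\n", x$system, x$code,
              if (is.null(x$display)) "" else paste0(" ", x$display)))
  invisible(x)
}

# Zero-row events data.frame with the canonical column types.
empty_events <- function() {
  data.frame(kind = character(0), system = character(0), code = character(0),
             display = character(0), date = as.Date(character(0)),
             value = numeric(0), stringsAsFactors = FALSE)
}

#' Construct one clinical event row
#'
#' Events are the payload of a visit record: coded problems, dated and
#' (optionally) valued labs, active medication classes, exams, and
#' hospital discharge diagnoses.
#'
#' @param kind One of `"problem"`, `"lab"`, `"medication"`, `"exam"`,
#'   `"discharge_dx"`.
#' @param system,code Concept code identifying the event (see
#'   [concept_code()]).
#' @param date Event date (`Date` or ISO-8601 string).  Must not be after
#'   the enclosing visit's date.
#' @param value Optional numeric value (percent for HbA1c labs; `NA`
#'   otherwise).
#' @param display Optional label.
#' @return A one-row `data.frame` suitable for `rbind`ing into a record's
#'   event table.
#' @export
clinical_event <- function(kind, system, code, date, value = NA_real_,
                           display = NA_character_) {
  stopifnot(length(kind) == 1L)
  if (!kind %in% VALID_KINDS)
    stop(sprintf("clinical_event: unknown kind '%s'", kind), call. = FALSE)
  data.frame(kind = kind, system = system, code = code,
             display = as.character(display), date = as.Date(date),
             value = as.numeric(value), stringsAsFactors = FALSE)
}

#' Construct a patient visit record
#'
#' One visit's clinical snapshot: the record carries everything the rule
#' engine may consult as of the visit date.  All event dates must be on or
#' before the visit date; the event list may be empty (a patient with no
#' history).
#'
#' @param visit_id Opaque visit identifier, unique within a cohort.
#' @param patient_id Opaque patient identifier.
#' @param visit_date Visit date (`Date` or ISO-8601 string).
#' @param events A `data.frame` of events (see [clinical_event()]), or
#'   `NULL` for an empty history.
#' @param validate Validate invariants on construction (default `TRUE`).
#' @return A `visit_record` object.
#' @export
visit_record <- function(visit_id, patient_id, visit_date, events = NULL,
                         validate = TRUE) {
  if (is.null(events) || nrow(events) == 0L) events <- empty_events()
  events$date <- as.Date(events$date)
  if (!"value" %in% names(events)) events$value <- NA_real_
  if (!"display" %in% names(events)) events$display <- NA_character_
  events <- events[, c("kind", "system", "code", "display", "date", "value")]
  rownames(events) <- NULL
  rec <- structure(
    list(visit_id = as.character(visit_id),
         patient_id = as.character(patient_id),
         visit_date = as.Date(visit_date),
         events = events),
    class = "visit_record")
  if (validate) validate_visit_record(rec)
  rec
}

#' @export
print.visit_record <- function(x, ...) {
  cat(sprintf("<visit_record %s patient=%s date=%s events=%d>\n",
              x$visit_id, x$patient_id, format(x$visit_date),
              nrow(x$events)))
  invisible(x)
}

#' Validate a visit record's invariants
#'
#' Checks: non-empty identifiers; a valid visit date; event kinds drawn
#' from the documented set; non-empty event systems/codes; no event dated
#' after the visit; HbA1c labs (per the default vocabulary's HBA1C_LAB
#' concept set) carrying a numeric value in (0, 25).
#'
#' @param record A `visit_record`.
#' @return The record, invisibly; stops with a validation error naming the
#'   visit_id and offending field otherwise.
#' @export
validate_visit_record <- function(record) {
  vid <- record$visit_id
  fail <- function(field, msg)
    stop(sprintf("validation error [visit_id=%s, field=%s]: %s",
                 vid, field, msg), call. = FALSE)
  if (!nzchar(vid)) fail("visit_id", "must be non-empty")
  if (!nzchar(record$patient_id)) fail("patient_id", "must be non-empty")
  if (is.na(record$visit_date)) fail("visit_date", "not a valid date")
  ev <- record$events
  if (nrow(ev) == 0L) return(invisible(record))
  bad_kind <- !ev$kind %in% VALID_KINDS
  if (any(bad_kind))
    fail("events.kind", paste("unknown kind:", ev$kind[bad_kind][1L]))
  if (any(!nzchar(ev$system) | is.na(ev$system)))
    fail("events.system", "must be non-empty")
  if (any(!nzchar(ev$code) | is.na(ev$code)))
    fail("events.code", "must be non-empty")
  if (any(is.na(ev$date)))
    fail("events.date", "not a valid date")
  if (any(ev$date > record$visit_date))
    fail("events.date",
         sprintf("event dated %s after visit date %s",
                 format(max(ev$date)), format(record$visit_date)))
  # HbA1c labs must carry a plausible percent value.
  hba1c <- default_concept_set("HBA1C_LAB")
  is_hba1c_lab <- ev$kind == "lab" & in_concept_set(ev$system, ev$code, hba1c)
  if (any(is_hba1c_lab)) {
    v <- ev$value[is_hba1c_lab]
    if (any(is.na(v)) || any(v <= 0) || any(v >= 25))
      fail("events.value", "HbA1c lab value must be numeric in (0, 25)")
  }
  invisible(record)
}

# One visit record -> plain list ready for JSON serialization.
record_to_list <- function(record) {
  ev <- record$events
  events <- lapply(seq_len(nrow(ev)), function(i) {
    e <- list(kind = ev$kind[i], system = ev$system[i], code = ev$code[i],
              date = format(ev$date[i]))
    if (!is.na(ev$display[i])) e$display <- ev$display[i]
    if (!is.na(ev$value[i])) e$value <- ev$value[i]
    e
  })
  list(visit_id = record$visit_id, patient_id = record$patient_id,
       visit_date = format(record$visit_date), events = events)
}

# Parsed JSON list -> visit_record; `line` only for error messages.
record_from_list <- function(x, line = NA_integer_) {
  where <- if (is.na(line)) "" else sprintf(" (line %d)", line)
  req <- c("visit_id", "patient_id", "visit_date", "events")
  missing <- setdiff(req, names(x))
  if (length(missing) > 0L)
    stop(sprintf("parse error%s: missing field(s): %s",
                 where, paste(missing, collapse = ", ")), call. = FALSE)
  ev <- x$events
  events <- if (length(ev) == 0L) empty_events() else do.call(rbind, lapply(ev, function(e) {
    ereq <- c("kind", "system", "code", "date")
    emiss <- setdiff(ereq, names(e))
    if (length(emiss) > 0L)
      stop(sprintf("parse error%s: event missing field(s): %s",
                   where, paste(emiss, collapse = ", ")), call. = FALSE)
    clinical_event(kind = e$kind, system = e$system, code = e$code,
                   date = e$date,
                   value = if (is.null(e$value)) NA_real_ else e$value,
                   display = if (is.null(e$display)) NA_character_ else e$display)
  }))
  visit_record(x$visit_id, x$patient_id, x$visit_date, events)
}

#' Read a cohort of visit records from a JSON-Lines file
#'
#' The file format is one JSON object per line (UTF-8, LF endings) with
#' fields `visit_id`, `patient_id`, `visit_date` and an `events` array of
#' `{kind, system, code, display?, date, value?}` objects; the shipped
#' schema (`system.file("extdata", "visit_record_schema.json", package =
#' "cdsagree")`) documents the dialect.  Every record is validated; order
#' is preserved.
#'
#' @param path Path to the JSON-Lines cohort file.
#' @return A list of `visit_record` objects (empty list for an empty file).
#' @export
read_visit_records <- function(path) {
  if (!file.exists(path))
    stop(sprintf("I/O error: no such file: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  records <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    x <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                  error = function(e)
                    stop(sprintf("parse error (line %d): %s",
                                 i, conditionMessage(e)), call. = FALSE))
    records[[i]] <- record_from_list(x, line = i)
    ids[i] <- records[[i]]$visit_id
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop(sprintf("validation error [visit_id=%s, field=visit_id]: duplicated in cohort",
                 dup[1L]), call. = FALSE)
  records
}

#' Write a cohort of visit records to a JSON-Lines file
#'
#' Inverse of [read_visit_records()]: a write-then-read round trip yields
#' records equal field for field.
#'
#' @param records List of `visit_record` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_visit_records <- function(records, path) {
  lines <- vapply(records, function(r) {
    validate_visit_record(r)
    jsonlite::toJSON(record_to_list(r), auto_unbox = TRUE, digits = NA)
  }, character(1))
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e)
                    stop(sprintf("I/O error: cannot open %s for writing", path),
                         call. = FALSE))
  on.exit(close(con))
  if (length(lines) > 0L)
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
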