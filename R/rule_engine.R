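# The eleven preventive-care reminder rules, evaluated against one visit
# record under a configurable profile.  Two built-in profiles (CLOUD,
# LOCAL) encode the divergent parameterizations of a cloud-curated and a
# locally-curated implementation of the same guidelines.

# Exact reminder messages, bulleted action lines newline-separated.
REMINDER_MESSAGES <- c(
  "1" = "Diabetic patient is overdue for HgbA1c measurement (recommended every 6 months)\n\u2022 Order HgbA1c now.",
  "2" = "Diabetic patient is almost due for HgbA1c measurement (recommended every 6 months)\n\u2022 Order HgbA1c now.",
  "3" = "Last HgbA1c was greater than 8% and over 3 months ago (recommended every 3 months in poorly controlled patient)\n\u2022 Order HgbA1c now.",
  "4" = "Diabetic patient is due for urine microalbumin/creatinine ratio measurement (recommended yearly)\n\u2022 Order malb/creat ratio now.",
  "5" = "Diabetic patient with renal disease, consider starting angiotensin-converting enzyme inhibitor (ACE-I).\n\u2022 Start ACE-I.",
  "6" = "Diabetic patient with renal disease, contraindications to ACE-I present, consider starting angiotensin-2 receptor antagonist (ARB).\n\u2022 Start ARB.",
  "7" = "Diabetic patient is due for ophthalmologic exam (recommended yearly)\n\u2022 Document the eye exam.\n\u2022 Refer to Ophthalmologist.\n\u2022 Refer to Optometrist.",
  "8" = "Diabetic patient is due for foot exam (recommended yearly)\n\u2022 Document the foot exam.\n\u2022 Refer to Podiatrist.",
  "9" = "Patient is overdue for blood pressure assessment (recommended yearly)\n\u2022 Document the blood pressure.",
  "10" = "Patient has CAD or equivalent, consider starting anti-platelet therapy, but potential contraindications exist.\n\u2022 Start aspirin.\n\u2022 Start clopidogrel.",
  "11" = "Patient has CAD or equivalent, recommend starting anti-platelet therapy.\n\u2022 Start aspirin.\n\u2022 Start clopidogrel.")

# Mean Gregorian month length in days; the single documented constant
# behind all "N months" arithmetic.
DAYS_PER_MONTH <- 30.4375

#' Elapsed months between an event and the visit
#'
#' Month arithmetic is day-granular: elapsed months = (days between
#' dates) / 30.4375, the mean Gregorian month length.  This makes "within
#' last N months" (< N), "over N months ago" (> N) and "between A and B
#' months ago" (A <= elapsed < B) monotone in the event date and free of
#' calendar-end pathologies.
#'
#' @param visit_date,event_date `Date`s (or ISO-8601 strings);
#'   `event_date` must not be after `visit_date`.
#' @return Non-negative numeric months (vectorized over `event_date`).
#' @export
months_before <- function(visit_date, event_date) {
  d <- as.numeric(as.Date(visit_date) - as.Date(event_date))
  if (any(d < 0))
    stop("months_before: event_date after visit_date", call. = FALSE)
  d / DAYS_PER_MONTH
}

# Elapsed months for each event row of a record (no precondition check:
# records are validated on construction).
event_months <- function(record) {
  as.numeric(record$visit_date - record$events$date) / DAYS_PER_MONTH
}

# Any problem-list event in `set`?
has_problem <- function(record, set) {
  ev <- record$events
  any(ev$kind == "problem" & in_concept_set(ev$system, ev$code, set))
}

# Any active medication of class `set`?
has_medication <- function(record, set) {
  ev <- record$events
  any(ev$kind == "medication" & in_concept_set(ev$system, ev$code, set))
}

# Is there a lab in `set` with elapsed months strictly below `months`?
has_lab_within <- function(record, set, months) {
  ev <- record$events
  hit <- ev$kind == "lab" & in_concept_set(ev$system, ev$code, set)
  any(hit & event_months(record) < months)
}

# Is there an exam in `set` with elapsed months at most `months`?
# ("last exam over N months ago" is the complement.)
has_exam_within <- function(record, set, months) {
  ev <- record$events
  hit <- ev$kind == "exam" & in_concept_set(ev$system, ev$code, set)
  any(hit & event_months(record) <= months)
}

#' Latest lab result in a concept set
#'
#' Selects the maximum-dated lab event of the record whose concept
#' belongs to `lab_set`.  Same-date ties are broken by taking the
#' maximum value (deterministic, and conservative toward alerting for
#' the poor-control reminder).
#'
#' @param record A `visit_record`.
#' @param lab_set A `concept_set` of lab concepts.
#' @return A list with `value`, `date` and `months` (elapsed months
#'   before the visit), or `NULL` if the record has no matching lab.
#' @export
last_result <- function(record, lab_set) {
  ev <- record$events
  hit <- which(ev$kind == "lab" & in_concept_set(ev$system, ev$code, lab_set))
  if (length(hit) == 0L) return(NULL)
  d <- ev$date[hit]
  latest <- hit[d == max(d)]
  if (length(latest) > 1L) {
    v <- ev$value[latest]
    v[is.na(v)] <- -Inf
    latest <- latest[which.max(v)]
  }
  list(value = ev$value[latest], date = ev$date[latest],
       months = months_before(record$visit_date, ev$date[latest]))
}

#' Does the profile consider this patient diabetic?
#'
#' Diabetes may be asserted by any enabled evidence source: the problem
#' list (with an optional gestational-diabetes exclusion: a patient whose
#' only diabetes-set problems are gestational is then not diabetic),
#' active hypoglycemic medications (oral agents or insulin), or hospital
#' ICD9 discharge diagnoses.
#'
#' @param record A `visit_record`.
#' @param profile A `rule_profile`.
#' @return Logical.
#' @export
is_diabetic <- function(record, profile) {
  cs <- profile$concept_sets
  ev <- record$events
  if ("problem_list" %in% profile$diabetes_sources) {
    dm <- ev$kind == "problem" &
      in_concept_set(ev$system, ev$code, cs$DIABETES)
    if (any(dm)) {
      if (!profile$exclude_gestational_diabetes)
        return(TRUE)
      gest <- in_concept_set(ev$system[dm], ev$code[dm],
                             cs$GESTATIONAL_DIABETES)
      if (any(!gest)) return(TRUE)
    }
  }
  if ("hypoglycemic_meds" %in% profile$diabetes_sources) {
    if (has_medication(record, cs$ORAL_HYPOGLYCEMIC) ||
        has_medication(record, cs$INSULIN))
      return(TRUE)
  }
  if ("icd9_discharge" %in% profile$diabetes_sources) {
    dx <- ev$kind == "discharge_dx" &
      in_concept_set(ev$system, ev$code, cs$DIABETES_ICD9)
    if (any(dx)) return(TRUE)
  }
  FALSE
}

#' Does the profile consider this patient to have CAD?
#'
#' True for a coded coronary-artery-disease problem, or — when the
#' profile treats angina as a CAD indicator — a coded angina problem.
#'
#' @inheritParams is_diabetic
#' @return Logical.
#' @export
has_cad <- function(record, profile) {
  cs <- profile$concept_sets
  has_problem(record, cs$CAD) ||
    (profile$angina_implies_cad && has_problem(record, cs$ANGINA))
}

# Microalbuminuria lab evidence within the profile's ACE lookback.
has_ace_evidence <- function(record, profile) {
  lb <- profile$ace_evidence_lookback_months
  if (is.infinite(lb)) {
    ev <- record$events
    any(ev$kind == "lab" &
          in_concept_set(ev$system, ev$code,
                         profile$concept_sets$MICROALBUMIN_LAB))
  } else {
    has_lab_within(record, profile$concept_sets$MICROALBUMIN_LAB, lb)
  }
}

# Shared guard of the ACE-I/ARB reminders (rules 5 and 6), minus the
# contraindication clauses.
ace_arb_base <- function(record, profile) {
  cs <- profile$concept_sets
  is_diabetic(record, profile) &&
    has_problem(record, cs$RENAL_DISEASE) &&
    !has_problem(record, cs$ESRD) &&
    !has_medication(record, cs$ACE_I) &&
    !has_medication(record, cs$ARB) &&
    has_ace_evidence(record, profile)
}

# Fire/no-fire decision for one reminder id; message handling is layered
# on top in evaluate_reminder().
reminder_fires <- function(record, profile, reminder_id) {
  cs <- profile$concept_sets
  w <- profile$windows
  switch(as.character(reminder_id),
    "1" = {
      is_diabetic(record, profile) &&
        !has_lab_within(record, cs$HBA1C_LAB, w$hba1c_due)
    },
    "2" = {
      if (!is_diabetic(record, profile)) return(FALSE)
      last <- last_result(record, cs$HBA1C_LAB)
      !is.null(last) &&
        last$months >= w$hba1c_almost_due_lo && last$months < w$hba1c_due
    },
    "3" = {
      if (!is_diabetic(record, profile)) return(FALSE)
      last <- last_result(record, cs$HBA1C_LAB)
      !is.null(last) &&
        last$months >= w$hba1c_poor_lo && last$months < w$hba1c_poor_hi &&
        !is.na(last$value) && last$value > w$hba1c_poor_threshold
    },
    "4" = {
      if (!is_diabetic(record, profile)) return(FALSE)
      if (profile$microalbumin_excludes_renal_disease &&
          has_problem(record, cs$RENAL_DISEASE)) return(FALSE)
      !has_lab_within(record, cs$MICROALBUMIN_LAB, w$microalbumin_lookback)
    },
    "5" = {
      ace_arb_base(record, profile) &&
        !has_problem(record, cs$ACE_CONTRA)
    },
    "6" = {
      ace_arb_base(record, profile) &&
        has_problem(record, cs$ACE_CONTRA) &&
        !has_problem(record, cs$ARB_CONTRA)
    },
    "7" = {
      if (!is_diabetic(record, profile)) return(FALSE)
      if ("blindness" %in% profile$eye_exam_exclusions &&
          has_problem(record, cs$BLINDNESS)) return(FALSE)
      if ("eye_clinic_visit_within_12mo" %in% profile$eye_exam_exclusions) {
        ev <- record$events
        clinic <- in_concept_set(ev$system, ev$code, cs$EYE_CLINIC_VISIT)
        if (any(clinic & event_months(record) < 12)) return(FALSE)
      }
      !has_exam_within(record, cs$EYE_EXAM, w$eye_exam_lookback)
    },
    "8" = {
      is_diabetic(record, profile) &&
        !has_exam_within(record, cs$FOOT_EXAM, w$foot_exam_lookback)
    },
    "9" = {
      !has_lab_within(record, cs$BP_LAB, w$bp_lookback)
    },
    "10" = {
      has_cad(record, profile) &&
        !has_medication(record, cs$ANTIPLATELET) &&
        has_problem(record, cs$ANTIPLATELET_CONTRA)
    },
    "11" = {
      has_cad(record, profile) &&
        !has_medication(record, cs$ANTIPLATELET) &&
        !has_problem(record, cs$ANTIPLATELET_CONTRA)
    },
    stop(sprintf("unknown reminder_id: %s", reminder_id), call. = FALSE))
}

#' Evaluate one reminder rule against a visit record
#'
#' Pure function: the record is never mutated and repeated evaluation is
#' identical.  When the rule fires, the returned message is the exact
#' display text of that reminder (action bullets newline-separated);
#' otherwise the message is empty.
#'
#' @param record A `visit_record`.
#' @param profile A `rule_profile`.
#' @param reminder_id Integer 1--11.
#' @return A list with `visit_id`, `reminder_id`, `fired`, `message`.
#' @export
evaluate_reminder <- function(record, profile, reminder_id) {
  if (!(length(reminder_id) == 1L && reminder_id %in% 1:11))
    stop("evaluate_reminder: reminder_id must be a single integer in 1..11",
         call. = FALSE)
  reminder_id <- as.integer(reminder_id)
  fired <- reminder_fires(record, profile, reminder_id)
  list(visit_id = record$visit_id, reminder_id = reminder_id,
       fired = fired,
       message = if (fired) unname(REMINDER_MESSAGES[as.character(reminder_id)])
                 else "")
}

#' Evaluate all eleven reminders against a visit record
#'
#' @inheritParams evaluate_reminder
#' @return A `data.frame` with one row per reminder (ordered 1--11) and
#'   columns `visit_id`, `reminder_id`, `fired`, `message`.
#' @export
evaluate_all <- function(record, profile) {
  fired <- vapply(1:11, function(i) reminder_fires(record, profile, i),
                  logical(1))
  data.frame(visit_id = record$visit_id, reminder_id = 1:11,
             fired = fired,
             message = ifelse(fired, unname(REMINDER_MESSAGES), ""),
             stringsAsFactors = FALSE)
}

#' Evaluate a cohort under one profile
#'
#' @param records List of `visit_record`s.
#' @param profile A `rule_profile`.
#' @return A logical matrix, one row per visit (rownames = visit ids),
#'   one column per reminder (`"1"` ... `"11"`); `TRUE` where the
#'   reminder fired.
#' @export
evaluate_cohort <- function(records, profile) {
  m <- t(vapply(records, function(r) evaluate_all(r, profile)$fired,
                logical(11)))
  dimnames(m) <- list(vapply(records, `[[`, character(1), "visit_id"),
                      as.character(1:11))
  m
}
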