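# Record-building helpers shared across test files.

VISIT_DATE <- as.Date("2011-11-15")

# Quick event constructor: ev("problem", "SNOMED", "DM-TYPE2", days = 400)
ev <- function(kind, system, code, days = 365, value = NA_real_) {
  clinical_event(kind, system, code, VISIT_DATE - days, value = value)
}

# A visit record from a list of events built with ev().
rec <- function(..., visit_id = "v1", patient_id = "p1",
                visit_date = VISIT_DATE) {
  events <- list(...)
  visit_record(visit_id, patient_id, visit_date,
               if (length(events) > 0L) do.call(rbind, events) else NULL)
}

# Days corresponding to m months under the engine's month constant,
# biased one day into the interior of the interval.
months_days <- function(m, inside = TRUE) {
  d <- m * 30.4375
  if (inside) floor(d) else ceiling(d)
}

# A diabetic whose preventive care is fully up to date: recent HbA1c,
# microalbumin, BP, eye and foot exams, on ACE-I and antiplatelet.
up_to_date_diabetic <- function() {
  rec(ev("problem", "SNOMED", "DM-TYPE2", days = 700),
      ev("lab", "LOINC", "HBA1C-PCT", days = 30, value = 6.8),
      ev("lab", "LOINC", "MALB-RATIO", days = 60),
      ev("lab", "LOINC", "8480-6", days = 10),
      ev("exam", "LOCAL", "EYE-EXAM", days = 90),
      ev("exam", "LOCAL", "FOOT-EXAM", days = 90),
      ev("medication", "MEDCLASS", "ACE_I", days = 0),
      ev("medication", "MEDCLASS", "ANTIPLATELET", days = 0))
}

# The printed per-rule 2x2 counts used throughout the statistics tests.
reference_counts <- function() {
  read_counts_csv(system.file("extdata", "table3_counts.csv",
                              package = "cdsagree"))
}

# Reference agreement values (2 dp) the counts above must reproduce.
reference_stats <- function() {
  data.frame(
    reminder_id = 1:11,
    kappa = c(0.82, 0.88, 0.28, 0.74, 0.13, 0.40, 0.90, 0.82, 0.34, 0.37, 0.10),
    bi = c(-0.03, 0.00, 0.03, 0.04, 0.02, 0.01, -0.01, -0.05, -0.29, 0.16, -0.07),
    pi = c(-0.51, -0.94, -0.93, -0.34, -0.75, -0.99, 0.06, -0.22, -0.25, -0.63, -0.91),
    pabak = c(0.87, 0.99, 0.91, 0.77, 0.61, 0.99, 0.90, 0.83, 0.33, 0.60, 0.85),
    ci_low = c(0.82, 0.97, 0.86, 0.70, 0.54, 0.97, 0.86, 0.78, 0.24, 0.53, 0.79),
    ci_high = c(0.91, 1.00, 0.95, 0.83, 0.69, 1.00, 0.94, 0.89, 0.42, 0.68, 0.90))
}

# Brute-force kappa oracle: chance agreement enumerated over all n^2
# cross-pairings of the expanded outcome sequence, independent of the
# closed-form marginal formula.
oracle_kappa <- function(t) {
  p <- expand_table(t)
  pe <- mean(outer(p$first, p$second, `==`))
  p0 <- mean(p$first == p$second)
  if (pe >= 1) return(NA_real_)
  (p0 - pe) / (1 - pe)
}
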