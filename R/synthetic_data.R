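# Synthetic cohort generator.
#
# Emulates the clinical structure the agreement analysis assumes — a
# primary-care cohort rich in diabetes, renal disease and CAD, with
# dated labs and exams whose recency spans the rules' lookback windows —
# plus tunable "discordance knobs", one per discrepancy class, that
# inject exactly the kinds of engine disagreement the built-in CLOUD and
# LOCAL profiles differ on.  All defaults are stand-ins for an
# undeposited clinic population: they are chosen to put per-rule firing
# prevalences in a plausible primary-care range, not to reproduce any
# real cohort.

#' Configuration for the synthetic cohort generator
#'
#' All `p_*` arguments are probabilities in \[0, 1\].  Knobs fall in two
#' groups: base clinical structure (condition prevalences, medication
#' use, lab/exam presence and recency), and discordance knobs that only
#' matter because the two built-in profiles read them differently
#' (`p_gestational_only`, `p_hypoglycemic_med_without_problem`,
#' `p_discharge_dx_without_problem`, `p_angina_without_cad`,
#' `p_bp_sitting_code`, `p_ace_contra_cloud_only`,
#' `p_antiplatelet_contra_extended_only`, `p_blindness`,
#' `p_eye_clinic_visit`, `microalbumin_stale_frac`).
#'
#' @param n_visits Cohort size (default 405, one visit per patient).
#' @param seed RNG seed; the cohort is fully determined by the config
#'   and seed.
#' @param p_diabetes Probability of a coded (non-gestational) diabetes
#'   problem.
#' @param p_gestational_only Probability a non-diabetic patient carries a
#'   gestational-diabetes-only history.
#' @param p_cad Probability of a coded CAD problem.
#' @param p_angina_without_cad Probability a non-CAD patient carries a
#'   coded angina problem.
#' @param p_renal Probability of a chronic-renal-disease problem.
#' @param p_esrd_given_renal Conditional probability of ESRD given renal
#'   disease.
#' @param p_on_ace,p_on_arb,p_on_antiplatelet Active-medication-class
#'   probabilities.
#' @param p_oral_hypoglycemic_given_diabetes Probability a diabetic is on
#'   an oral hypoglycemic.
#' @param p_hypoglycemic_med_without_problem Probability a patient with
#'   no diabetes problem is nevertheless on insulin (diabetes evidence
#'   only the local profile reads).
#' @param p_discharge_dx_without_problem Probability of a hospital ICD9
#'   diabetes discharge diagnosis without a problem-list entry.
#' @param lab_presence Named vector of presence probabilities for
#'   `hba1c`, `microalbumin`, `bp`, `eye_exam`, `foot_exam`.
#' @param max_lookback_months Upper end of the uniform recency
#'   distribution applied to labs and exams (default 24), so boundary
#'   cases around the 3/5/6/11/12-month windows occur with positive
#'   probability.
#' @param hba1c_mean,hba1c_sd HbA1c value distribution, Normal truncated
#'   to (4, 15) percent.
#' @param p_bp_sitting_code Probability a blood-pressure lab carries the
#'   sitting-systolic LOINC code (8459-0) instead of plain systolic
#'   (8480-6).
#' @param p_ace_contra Probability of an ACE-inhibitor allergy (a
#'   contraindication both profiles recognize).
#' @param p_ace_contra_cloud_only Probability of pregnancy or
#'   hyperkalemia (contraindications only the cloud profile recognizes).
#' @param p_antiplatelet_contra_core Probability of a core antiplatelet
#'   contraindication (bleeding disorder, thrombocytopenia, GI bleed).
#' @param p_antiplatelet_contra_extended_only Probability of an
#'   extended-set-only contraindication (esophageal varices, coagulation
#'   factor deficiency, cerebral hemorrhage).
#' @param p_blindness Probability of coded blindness.
#' @param p_eye_clinic_visit Probability of an eye-clinic visit event in
#'   the record.
#' @param microalbumin_stale_frac If non-`NULL`, the probability that a
#'   present microalbumin lab is stale (recency uniform in 12.5--24
#'   months) rather than recent (uniform in 0--10.5 months); `NULL`
#'   (default) samples recency uniformly over the full lookback.
#' @return A `synthetic_cohort_config` list.
#' @export
synthetic_cohort_config <- function(
    n_visits = 405, seed = 20111001,
    p_diabetes = 0.60, p_gestational_only = 0.02,
    p_cad = 0.20, p_angina_without_cad = 0.02,
    p_renal = 0.15, p_esrd_given_renal = 0.10,
    p_on_ace = 0.30, p_on_arb = 0.08, p_on_antiplatelet = 0.35,
    p_oral_hypoglycemic_given_diabetes = 0.60,
    p_hypoglycemic_med_without_problem = 0.03,
    p_discharge_dx_without_problem = 0.02,
    lab_presence = c(hba1c = 0.85, microalbumin = 0.65, bp = 0.90,
                     eye_exam = 0.55, foot_exam = 0.60),
    max_lookback_months = 24,
    hba1c_mean = 7.5, hba1c_sd = 1.5,
    p_bp_sitting_code = 0.30,
    p_ace_contra = 0.03, p_ace_contra_cloud_only = 0.03,
    p_antiplatelet_contra_core = 0.04,
    p_antiplatelet_contra_extended_only = 0.04,
    p_blindness = 0.02, p_eye_clinic_visit = 0.05,
    microalbumin_stale_frac = NULL) {
  cfg <- list(
    n_visits = n_visits, seed = seed,
    p_diabetes = p_diabetes, p_gestational_only = p_gestational_only,
    p_cad = p_cad, p_angina_without_cad = p_angina_without_cad,
    p_renal = p_renal, p_esrd_given_renal = p_esrd_given_renal,
    p_on_ace = p_on_ace, p_on_arb = p_on_arb,
    p_on_antiplatelet = p_on_antiplatelet,
    p_oral_hypoglycemic_given_diabetes = p_oral_hypoglycemic_given_diabetes,
    p_hypoglycemic_med_without_problem = p_hypoglycemic_med_without_problem,
    p_discharge_dx_without_problem = p_discharge_dx_without_problem,
    lab_presence = lab_presence,
    max_lookback_months = max_lookback_months,
    hba1c_mean = hba1c_mean, hba1c_sd = hba1c_sd,
    p_bp_sitting_code = p_bp_sitting_code,
    p_ace_contra = p_ace_contra,
    p_ace_contra_cloud_only = p_ace_contra_cloud_only,
    p_antiplatelet_contra_core = p_antiplatelet_contra_core,
    p_antiplatelet_contra_extended_only = p_antiplatelet_contra_extended_only,
    p_blindness = p_blindness, p_eye_clinic_visit = p_eye_clinic_visit,
    microalbumin_stale_frac = microalbumin_stale_frac)
  validate_cohort_config(cfg)
  structure(cfg, class = "synthetic_cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (!(is.numeric(cfg$n_visits) && cfg$n_visits >= 1))
    stop("config error: n_visits must be >= 1", call. = FALSE)
  probs <- c(cfg$p_diabetes, cfg$p_gestational_only, cfg$p_cad,
             cfg$p_angina_without_cad, cfg$p_renal, cfg$p_esrd_given_renal,
             cfg$p_on_ace, cfg$p_on_arb, cfg$p_on_antiplatelet,
             cfg$p_oral_hypoglycemic_given_diabetes,
             cfg$p_hypoglycemic_med_without_problem,
             cfg$p_discharge_dx_without_problem,
             cfg$lab_presence, cfg$p_bp_sitting_code, cfg$p_ace_contra,
             cfg$p_ace_contra_cloud_only, cfg$p_antiplatelet_contra_core,
             cfg$p_antiplatelet_contra_extended_only, cfg$p_blindness,
             cfg$p_eye_clinic_visit, cfg$microalbumin_stale_frac)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    stop("config error: all probabilities must lie in [0, 1]",
         call. = FALSE)
  req <- c("hba1c", "microalbumin", "bp", "eye_exam", "foot_exam")
  if (!all(req %in% names(cfg$lab_presence)))
    stop("config error: lab_presence must name ",
         paste(req, collapse = ", "), call. = FALSE)
  if (!(cfg$max_lookback_months > 0))
    stop("config error: max_lookback_months must be positive",
         call. = FALSE)
  invisible(cfg)
}

# Date `months` (numeric) before `date`, on day granularity.
date_months_before <- function(date, months) {
  date - floor(months * DAYS_PER_MONTH)
}

# Generate one visit record (RNG state supplied by the caller).
generate_visit <- function(cfg, i, study_start) {
  visit_date <- study_start + floor(stats::runif(1, 0, 92))
  ev <- list()
  add <- function(kind, system, code, months_ago = NULL, value = NA_real_) {
    date <- if (is.null(months_ago)) {
      visit_date - floor(stats::runif(1, 0, 1825))
    } else {
      date_months_before(visit_date, months_ago)
    }
    ev[[length(ev) + 1L]] <<- clinical_event(kind, system, code, date, value)
  }
  rec <- function(max = cfg$max_lookback_months) stats::runif(1, 0, max)

  diabetic <- stats::runif(1) < cfg$p_diabetes
  if (diabetic) {
    add("problem", "SNOMED", "DM-TYPE2")
    if (stats::runif(1) < cfg$p_oral_hypoglycemic_given_diabetes)
      add("medication", "MEDCLASS", "ORAL_HYPOGLYCEMIC", months_ago = 0)
  } else {
    if (stats::runif(1) < cfg$p_gestational_only)
      add("problem", "SNOMED", "DM-GEST")
    if (stats::runif(1) < cfg$p_hypoglycemic_med_without_problem)
      add("medication", "MEDCLASS", "INSULIN", months_ago = 0)
    if (stats::runif(1) < cfg$p_discharge_dx_without_problem)
      add("discharge_dx", "ICD9", "250-X")
  }

  if (stats::runif(1) < cfg$p_renal) {
    add("problem", "SNOMED", "CKD-1")
    if (stats::runif(1) < cfg$p_esrd_given_renal)
      add("problem", "SNOMED", "ESRD-1")
  }

  if (stats::runif(1) < cfg$p_cad) {
    add("problem", "SNOMED", "CAD-1")
  } else if (stats::runif(1) < cfg$p_angina_without_cad) {
    add("problem", "SNOMED", "194828000")
  }

  if (stats::runif(1) < cfg$p_on_ace)
    add("medication", "MEDCLASS", "ACE_I", months_ago = 0)
  if (stats::runif(1) < cfg$p_on_arb)
    add("medication", "MEDCLASS", "ARB", months_ago = 0)
  if (stats::runif(1) < cfg$p_on_antiplatelet)
    add("medication", "MEDCLASS", "ANTIPLATELET", months_ago = 0)

  if (stats::runif(1) < cfg$p_ace_contra)
    add("problem", "SNOMED", "ACE-ALLERGY")
  if (stats::runif(1) < cfg$p_ace_contra_cloud_only)
    add("problem", "SNOMED", sample(c("PREG-1", "HYPERK-1"), 1L))
  if (stats::runif(1) < cfg$p_antiplatelet_contra_core)
    add("problem", "SNOMED",
        sample(c("BLEED-DIS-1", "THROMBO-1", "GIBLEED-1"), 1L))
  if (stats::runif(1) < cfg$p_antiplatelet_contra_extended_only)
    add("problem", "SNOMED",
        sample(c("ESOPH-VAR-1", "COAG-DEF-1", "CEREB-HEM-1"), 1L))
  if (stats::runif(1) < cfg$p_blindness)
    add("problem", "SNOMED", "BLIND-1")
  if (stats::runif(1) < cfg$p_eye_clinic_visit)
    add("exam", "LOCAL", "EYE-CLINIC", months_ago = rec())

  if (stats::runif(1) < cfg$lab_presence[["hba1c"]]) {
    v <- stats::rnorm(1, cfg$hba1c_mean, cfg$hba1c_sd)
    while (v <= 4 || v >= 15) v <- stats::rnorm(1, cfg$hba1c_mean, cfg$hba1c_sd)
    add("lab", "LOINC", "HBA1C-PCT", months_ago = rec(), value = v)
  }
  if (stats::runif(1) < cfg$lab_presence[["microalbumin"]]) {
    m <- if (is.null(cfg$microalbumin_stale_frac)) rec()
    else if (stats::runif(1) < cfg$microalbumin_stale_frac)
      stats::runif(1, 12.5, cfg$max_lookback_months)
    else stats::runif(1, 0, 10.5)
    add("lab", "LOINC", "MALB-RATIO", months_ago = m)
  }
  if (stats::runif(1) < cfg$lab_presence[["bp"]]) {
    code <- if (stats::runif(1) < cfg$p_bp_sitting_code) "8459-0" else "8480-6"
    add("lab", "LOINC", code, months_ago = rec())
  }
  if (stats::runif(1) < cfg$lab_presence[["eye_exam"]])
    add("exam", "LOCAL", "EYE-EXAM", months_ago = rec())
  if (stats::runif(1) < cfg$lab_presence[["foot_exam"]])
    add("exam", "LOCAL", "FOOT-EXAM", months_ago = rec())

  events <- if (length(ev) == 0L) NULL else do.call(rbind, ev)
  visit_record(sprintf("V%04d", i), sprintf("P%04d", i), visit_date, events)
}

#' Generate a synthetic cohort of visit records
#'
#' Deterministic given the config (which carries the seed): identical
#' configs yield byte-identical cohorts.  One visit per synthetic
#' patient; every record passes [validate_visit_record()].
#'
#' @param config A [synthetic_cohort_config()].
#' @return A list of `visit_record`s of length `config$n_visits`.
#' @export
generate_cohort <- function(config = synthetic_cohort_config()) {
  validate_cohort_config(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  study_start <- as.Date("2011-10-01")
  lapply(seq_len(config$n_visits),
         function(i) generate_visit(config, i, study_start))
}

# Which reminder rules each discrepancy class can perturb, given how the
# built-in profiles differ.  terminology: the sitting-BP LOINC code is
# read only by rule 9.  practice_variation: diabetes-definition knobs
# (gestational-only, meds-without-problem, discharge dx) reach every
# diabetes-guarded rule the stress cohort leaves active (renal prevalence
# is zeroed, so 5/6 are off), and angina-without-CAD reaches 10/11.
# temporal: a stale microalbumin exercises the ACE-evidence lookback
# (5/6) and, in renal patients, the screening reminder's renal exclusion
# (4).  exclusions: renal exclusion (4), ACE contraindication sets (5/6),
# eye-exam exclusions (7), antiplatelet contraindication sets (10/11).
DISCREPANCY_CLASSES <- list(
  terminology = 9L,
  practice_variation = c(1L, 2L, 3L, 4L, 7L, 8L, 10L, 11L),
  temporal = c(4L, 5L, 6L),
  exclusions = c(4L, 5L, 6L, 7L, 10L, 11L))

#' Stress cohort for one discrepancy class
#'
#' Builds a cohort in which only the discordance knobs of the named
#' class are active, at the given intensity; every other source of
#' CLOUD-vs-LOCAL disagreement is switched off.  At intensity 0 the two
#' built-in profiles agree on every visit and every rule.  The rule
#' subset each class can perturb is
#' `cdsagree:::DISCREPANCY_CLASSES[[discrepancy_class]]`.
#'
#' @param discrepancy_class One of `"terminology"`,
#'   `"practice_variation"`, `"temporal"`, `"exclusions"`.
#' @param intensity Knob intensity in \[0, 1\].
#' @param n Cohort size.
#' @param seed RNG seed.
#' @return A list of `visit_record`s.
#' @export
concordance_stress_cohort <- function(discrepancy_class, intensity = 1,
                                      n = 405, seed = 20111001) {
  if (!discrepancy_class %in% names(DISCREPANCY_CLASSES))
    stop(sprintf("unknown discrepancy class: %s", discrepancy_class),
         call. = FALSE)
  if (!(is.numeric(intensity) && intensity >= 0 && intensity <= 1))
    stop("intensity must lie in [0, 1]", call. = FALSE)
  # Concordant base: no knob that the two profiles read differently, and
  # no renal disease (the microalbumin renal exclusion and the ACE
  # lookback would otherwise produce discordance on their own).
  base <- list(
    n_visits = n, seed = seed,
    p_gestational_only = 0, p_hypoglycemic_med_without_problem = 0,
    p_discharge_dx_without_problem = 0, p_angina_without_cad = 0,
    p_bp_sitting_code = 0, p_ace_contra_cloud_only = 0,
    p_antiplatelet_contra_extended_only = 0, p_blindness = 0,
    p_eye_clinic_visit = 0, p_renal = 0, microalbumin_stale_frac = 0)
  tweak <- switch(discrepancy_class,
    terminology = list(p_bp_sitting_code = intensity),
    practice_variation = list(
      p_gestational_only = intensity,
      p_hypoglycemic_med_without_problem = intensity,
      p_discharge_dx_without_problem = intensity,
      p_angina_without_cad = intensity),
    temporal = list(
      p_renal = 0.3,
      # Microalbumin always present: at intensity 0 every result is
      # recent and the profiles agree perfectly; staleness alone then
      # drives the discordance.
      lab_presence = c(hba1c = 0.85, microalbumin = 1, bp = 0.90,
                       eye_exam = 0.55, foot_exam = 0.60),
      microalbumin_stale_frac = intensity),
    exclusions = list(
      p_renal = 0.3 * intensity,
      p_ace_contra_cloud_only = 0.3 * intensity,
      p_blindness = 0.2 * intensity,
      p_eye_clinic_visit = 0.3 * intensity,
      p_antiplatelet_contra_extended_only = 0.3 * intensity))
  cfg <- do.call(synthetic_cohort_config, utils::modifyList(base, tweak))
  generate_cohort(cfg)
}
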