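# Concept sets and rule profiles.
#
# A concept set is a named collection of (system, code) pairs; rule
# predicates test exact, case-sensitive membership.  A rule profile is a
# named parameterization of the 11 reminder rules: 22 concept-set roles
# plus the scalar switches and lookback windows that differ between the
# cloud-curated and locally-curated implementations.

.cdsagree_cache <- new.env(parent = emptyenv())

#' Construct a concept set
#'
#' @param name Set identifier.
#' @param members A `data.frame` with columns `system` and `code` (may
#'   have zero rows), or a list of `concept_code` objects.
#' @return A `concept_set` object.
#' @export
concept_set <- function(name, members) {
  if (is.list(members) && !is.data.frame(members)) {
    members <- if (length(members) == 0L)
      data.frame(system = character(0), code = character(0),
                 stringsAsFactors = FALSE)
    else
      do.call(rbind, lapply(members, function(m)
        data.frame(system = m$system, code = m$code,
                   stringsAsFactors = FALSE)))
  }
  stopifnot(is.data.frame(members),
            all(c("system", "code") %in% names(members)))
  members <- unique(members[, c("system", "code")])
  rownames(members) <- NULL
  structure(list(name = name, members = members,
                 keys = paste(members$system, members$code, sep = "\r")),
            class = "concept_set")
}

#' @export
print.concept_set <- function(x, ...) {
  cat(sprintf("<concept_set %s: %d member(s)>\n", x$name, nrow(x$members)))
  invisible(x)
}

#' Test membership of (system, code) pairs in a concept set
#'
#' Vectorized over its first two arguments.  Membership is exact pair
#' lookup; codes from vocabularies the set does not mention never match.
#'
#' @param system,code Character vectors of equal length.
#' @param set A `concept_set`.
#' @return Logical vector.
#' @export
in_concept_set <- function(system, code, set) {
  paste(system, code, sep = "\r") %in% set$keys
}

#' Load the shipped fixture vocabulary
#'
#' A versioned CSV (`set_name`, `system`, `code`, `display`) naming every
#' concept the built-in profiles reference.  Apart from the two systolic
#' blood pressure LOINC codes (8480-6, 8459-0) and the SNOMED code for
#' angina (194828000), all codes are invented placeholders, flagged as
#' such in their display strings.
#'
#' @param path Optional path to an alternative vocabulary CSV.
#' @return A `data.frame` with columns `set_name`, `system`, `code`,
#'   `display`.
#' @export
load_vocabulary <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.cdsagree_cache$vocabulary)) {
      p <- system.file("extdata", "vocabulary.csv", package = "cdsagree")
      .cdsagree_cache$vocabulary <-
        utils::read.csv(p, stringsAsFactors = FALSE)
    }
    return(.cdsagree_cache$vocabulary)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Concept set for one set_name of the fixture vocabulary.
default_concept_set <- function(name) {
  voc <- load_vocabulary()
  concept_set(name, voc[voc$set_name == name, c("system", "code")])
}

# Roles every profile must populate (possibly with an empty set).
PROFILE_ROLES <- c(
  "DIABETES", "GESTATIONAL_DIABETES", "DIABETES_ICD9", "RENAL_DISEASE",
  "ESRD", "CAD", "ANGINA", "HBA1C_LAB", "MICROALBUMIN_LAB", "BP_LAB",
  "EYE_EXAM", "FOOT_EXAM", "BLINDNESS", "EYE_CLINIC_VISIT", "ACE_I",
  "ARB", "ANTIPLATELET", "ORAL_HYPOGLYCEMIC", "INSULIN", "ACE_CONTRA",
  "ARB_CONTRA", "ANTIPLATELET_CONTRA")

DIABETES_SOURCES <- c("problem_list", "hypoglycemic_meds", "icd9_discharge")
EYE_EXAM_EXCLUSIONS <- c("blindness", "eye_clinic_visit_within_12mo")

#' Construct a rule profile
#'
#' @param name Profile identifier.
#' @param concept_sets Named list of `concept_set` objects covering every
#'   role in `cdsagree:::PROFILE_ROLES`.
#' @param diabetes_sources Subset of `"problem_list"`,
#'   `"hypoglycemic_meds"`, `"icd9_discharge"`: which evidence sources
#'   assert diabetes.
#' @param exclude_gestational_diabetes If `TRUE`, a patient whose only
#'   diabetes-set problems are gestational is not considered diabetic.
#' @param angina_implies_cad If `TRUE`, a coded angina problem counts as
#'   coronary artery disease.
#' @param microalbumin_excludes_renal_disease If `TRUE`, the microalbumin
#'   screening reminder is suppressed for patients with established renal
#'   disease.
#' @param ace_evidence_lookback_months Months of lab history searched for
#'   microalbuminuria evidence by the ACE-I/ARB reminders; `Inf` for an
#'   unbounded lookback.
#' @param eye_exam_exclusions Subset of `"blindness"`,
#'   `"eye_clinic_visit_within_12mo"`.
#' @param windows Named list of lookback windows (months) and the HbA1c
#'   poor-control threshold (percent); defaults are the guideline values
#'   shared by both built-in profiles.
#' @return A `rule_profile` object.
#' @export
rule_profile <- function(name, concept_sets,
                         diabetes_sources = "problem_list",
                         exclude_gestational_diabetes = TRUE,
                         angina_implies_cad = TRUE,
                         microalbumin_excludes_renal_disease = TRUE,
                         ace_evidence_lookback_months = 12,
                         eye_exam_exclusions = character(0),
                         windows = list()) {
  defaults <- list(hba1c_due = 6, hba1c_almost_due_lo = 5,
                   hba1c_poor_lo = 3, hba1c_poor_hi = 5,
                   hba1c_poor_threshold = 8.0,
                   microalbumin_lookback = 11, eye_exam_lookback = 11,
                   foot_exam_lookback = 11, bp_lookback = 12)
  windows <- utils::modifyList(defaults, windows)
  missing_roles <- setdiff(PROFILE_ROLES, names(concept_sets))
  if (length(missing_roles) > 0L)
    stop("rule_profile: missing concept set role(s): ",
         paste(missing_roles, collapse = ", "), call. = FALSE)
  if (!all(diabetes_sources %in% DIABETES_SOURCES))
    stop("rule_profile: unknown diabetes source", call. = FALSE)
  if (!all(eye_exam_exclusions %in% EYE_EXAM_EXCLUSIONS))
    stop("rule_profile: unknown eye exam exclusion", call. = FALSE)
  if (!(is.numeric(ace_evidence_lookback_months) &&
        ace_evidence_lookback_months > 0))
    stop("rule_profile: ace_evidence_lookback_months must be positive ",
         "(use Inf for unbounded)", call. = FALSE)
  win_scalar <- unlist(windows[setdiff(names(windows), "hba1c_poor_threshold")])
  if (any(win_scalar <= 0))
    stop("rule_profile: all windows must be positive", call. = FALSE)
  if (!(windows$hba1c_almost_due_lo < windows$hba1c_due))
    stop("rule_profile: hba1c_almost_due_lo must be < hba1c_due",
         call. = FALSE)
  if (!(windows$hba1c_poor_lo < windows$hba1c_poor_hi))
    stop("rule_profile: hba1c_poor_lo must be < hba1c_poor_hi",
         call. = FALSE)
  structure(list(
    name = name,
    concept_sets = concept_sets[PROFILE_ROLES],
    diabetes_sources = sort(unique(diabetes_sources)),
    exclude_gestational_diabetes = isTRUE(exclude_gestational_diabetes),
    angina_implies_cad = isTRUE(angina_implies_cad),
    microalbumin_excludes_renal_disease =
      isTRUE(microalbumin_excludes_renal_disease),
    ace_evidence_lookback_months = ace_evidence_lookback_months,
    eye_exam_exclusions = sort(unique(eye_exam_exclusions)),
    windows = windows), class = "rule_profile")
}

#' @export
print.rule_profile <- function(x, ...) {
  cat(sprintf("<rule_profile %s>\n", x$name))
  cat("  diabetes sources:", paste(x$diabetes_sources, collapse = ", "), "\n")
  cat("  exclude gestational diabetes:", x$exclude_gestational_diabetes, "\n")
  cat("  angina implies CAD:", x$angina_implies_cad, "\n")
  cat("  microalbumin excludes renal disease:",
      x$microalbumin_excludes_renal_disease, "\n")
  cat("  ACE evidence lookback (months):",
      x$ace_evidence_lookback_months, "\n")
  cat("  eye exam exclusions:",
      if (length(x$eye_exam_exclusions) == 0L) "(none)"
      else paste(x$eye_exam_exclusions, collapse = ", "), "\n")
  invisible(x)
}

#' Load a rule profile from a config file
#'
#' Profiles are JSON objects naming every concept-set member by
#' (system, code) plus all scalar parameters; the two built-in profiles
#' ship with the package and are loadable by name via [cloud_profile()]
#' and [local_profile()].
#'
#' @param path Path to a profile JSON file.
#' @return A `rule_profile`.
#' @export
load_profile <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  sets <- lapply(names(x$concept_sets), function(role) {
    concept_set(role, lapply(x$concept_sets[[role]], function(m)
      list(system = m$system, code = m$code)))
  })
  names(sets) <- names(x$concept_sets)
  for (role in setdiff(PROFILE_ROLES, names(sets)))
    sets[[role]] <- concept_set(role, list())
  lb <- x$ace_evidence_lookback_months
  rule_profile(
    name = x$name,
    concept_sets = sets,
    diabetes_sources = unlist(x$diabetes_sources),
    exclude_gestational_diabetes = isTRUE(x$exclude_gestational_diabetes),
    angina_implies_cad = isTRUE(x$angina_implies_cad),
    microalbumin_excludes_renal_disease =
      isTRUE(x$microalbumin_excludes_renal_disease),
    ace_evidence_lookback_months = if (is.null(lb)) Inf else lb,
    eye_exam_exclusions = as.character(unlist(x$eye_exam_exclusions)),
    windows = x$windows)
}

#' Built-in cloud-curated rule profile
#'
#' Asserts diabetes from the problem list only, excludes gestational-only
#' diabetes, treats angina as a CAD indicator, suppresses microalbumin
#' screening in established renal disease, searches only 12 months for
#' microalbuminuria evidence, recognizes only the plain systolic blood
#' pressure LOINC code (8480-6), uses the broader ACE-I contraindication
#' set (allergy, pregnancy, hyperkalemia) and the extended antiplatelet
#' contraindication set, and applies no eye-exam exclusions.
#'
#' @return A `rule_profile`.
#' @export
cloud_profile <- function() {
  if (is.null(.cdsagree_cache$cloud))
    .cdsagree_cache$cloud <- load_profile(
      system.file("extdata", "profile_cloud.json", package = "cdsagree"))
  .cdsagree_cache$cloud
}

#' Built-in locally-curated rule profile
#'
#' Asserts diabetes from problem list, hypoglycemic medications and ICD9
#' discharge diagnoses; keeps gestational diabetes in the diabetic
#' population; does not treat angina as CAD; screens for microalbumin
#' regardless of renal disease; searches lab history without a time bound
#' for microalbuminuria evidence; recognizes both systolic blood pressure
#' LOINC codes (8480-6, 8459-0); uses allergy as the only ACE-I
#' contraindication and the core antiplatelet contraindication set; and
#' excludes blind patients and recent eye-clinic visitors from the eye
#' exam reminder.
#'
#' @return A `rule_profile`.
#' @export
local_profile <- function() {
  if (is.null(.cdsagree_cache$local))
    .cdsagree_cache$local <- load_profile(
      system.file("extdata", "profile_local.json", package = "cdsagree"))
  .cdsagree_cache$local
}
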