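test_that("month arithmetic is day-granular around the 6-month boundary", {
  d0 <- as.Date("2011-11-15")
  expect_identical(months_before(d0, d0), 0)
  # 183 days is strictly more than 6 mean Gregorian months ...
  expect_equal(months_before(d0, d0 - 183), 183 / 30.4375)
  expect_gt(months_before(d0, d0 - 183), 6)
  # ... 182 days strictly less
  expect_lt(months_before(d0, d0 - 182), 6)
  # and 152 days is strictly less than 5 months
  expect_lt(months_before(d0, d0 - 152), 5)
  expect_error(months_before(d0, d0 + 1), "after visit_date")
})

test_that("HbA1c at the 6-month boundary flips the overdue reminder", {
  for (p in list(cloud_profile(), local_profile())) {
    overdue <- rec(ev("problem", "SNOMED", "DM-TYPE2"),
                   ev("lab", "LOINC", "HBA1C-PCT", days = 183, value = 7.0))
    within <- rec(ev("problem", "SNOMED", "DM-TYPE2"),
                  ev("lab", "LOINC", "HBA1C-PCT", days = 182, value = 7.0))
    expect_true(evaluate_reminder(overdue, p, 1)$fired)
    expect_false(evaluate_reminder(within, p, 1)$fired)
    # 182 days falls in the almost-due band [5, 6)
    expect_true(evaluate_reminder(within, p, 2)$fired)
  }
})

test_that("last_result picks the latest lab and breaks date ties by value", {
  hba1c <- cloud_profile()$concept_sets$HBA1C_LAB
  expect_null(last_result(rec(), hba1c))
  r <- rec(ev("lab", "LOINC", "HBA1C-PCT", days = 200, value = 9.5),
           ev("lab", "LOINC", "HBA1C-PCT", days = 100, value = 7.1))
  expect_equal(last_result(r, hba1c)$value, 7.1)
  tie <- rec(ev("lab", "LOINC", "HBA1C-PCT", days = 100, value = 7.1),
             ev("lab", "LOINC", "HBA1C-PCT", days = 100, value = 9.0))
  expect_equal(last_result(tie, hba1c)$value, 9.0)
})

test_that("diabetes assertion honours each profile's evidence sources", {
  gest <- rec(ev("problem", "SNOMED", "DM-GEST"))
  expect_false(is_diabetic(gest, cloud_profile()))
  expect_true(is_diabetic(gest, local_profile()))
  insulin <- rec(ev("medication", "MEDCLASS", "INSULIN", days = 0))
  expect_false(is_diabetic(insulin, cloud_profile()))
  expect_true(is_diabetic(insulin, local_profile()))
  discharge <- rec(ev("discharge_dx", "ICD9", "250-X"))
  expect_false(is_diabetic(discharge, cloud_profile()))
  expect_true(is_diabetic(discharge, local_profile()))
  # gestational plus true diabetes is diabetic everywhere
  both <- rec(ev("problem", "SNOMED", "DM-GEST"),
              ev("problem", "SNOMED", "DM-TYPE2"))
  expect_true(is_diabetic(both, cloud_profile()))
  expect_true(is_diabetic(both, local_profile()))
})

test_that("angina counts as CAD only where the profile says so", {
  angina <- rec(ev("problem", "SNOMED", "194828000"))
  expect_true(has_cad(angina, cloud_profile()))
  expect_false(has_cad(angina, local_profile()))
  expect_false(has_cad(rec(), cloud_profile()))
  expect_false(has_cad(rec(), local_profile()))
})

test_that("the sitting-BP code splits the blood pressure reminder", {
  sitting <- rec(ev("lab", "LOINC", "8459-0", days = 30))
  expect_true(evaluate_reminder(sitting, cloud_profile(), 9)$fired)
  expect_false(evaluate_reminder(sitting, local_profile(), 9)$fired)
  standard <- rec(ev("lab", "LOINC", "8480-6", days = 30))
  expect_false(evaluate_reminder(standard, cloud_profile(), 9)$fired)
  expect_false(evaluate_reminder(standard, local_profile(), 9)$fired)
})

test_that("extended antiplatelet contraindications route rule 10 vs 11", {
  varices <- rec(ev("problem", "SNOMED", "CAD-1"),
                 ev("problem", "SNOMED", "ESOPH-VAR-1"))
  out_cloud <- evaluate_all(varices, cloud_profile())
  out_local <- evaluate_all(varices, local_profile())
  expect_true(out_cloud$fired[10])
  expect_false(out_cloud$fired[11])
  expect_false(out_local$fired[10])
  expect_true(out_local$fired[11])
  # a core contraindication routes to rule 10 under both profiles
  gib <- rec(ev("problem", "SNOMED", "CAD-1"),
             ev("problem", "SNOMED", "GIBLEED-1"))
  expect_true(evaluate_reminder(gib, cloud_profile(), 10)$fired)
  expect_true(evaluate_reminder(gib, local_profile(), 10)$fired)
})

test_that("ACE-I/ARB reminders respect evidence lookback and contraindications", {
  renal_base <- list(ev("problem", "SNOMED", "DM-TYPE2"),
                     ev("problem", "SNOMED", "CKD-1"))
  stale <- do.call(rec, c(renal_base,
                          list(ev("lab", "LOINC", "MALB-RATIO", days = 500))))
  # evidence 500 days old: outside the cloud 12-month lookback, inside the
  # local unbounded one
  expect_false(evaluate_reminder(stale, cloud_profile(), 5)$fired)
  expect_true(evaluate_reminder(stale, local_profile(), 5)$fired)
  fresh <- do.call(rec, c(renal_base,
                          list(ev("lab", "LOINC", "MALB-RATIO", days = 60))))
  expect_true(evaluate_reminder(fresh, cloud_profile(), 5)$fired)
  # pregnancy is contraindicating only for the cloud profile: rule 6 there
  preg <- do.call(rec, c(renal_base,
                         list(ev("lab", "LOINC", "MALB-RATIO", days = 60),
                              ev("problem", "SNOMED", "PREG-1"))))
  expect_false(evaluate_reminder(preg, cloud_profile(), 5)$fired)
  expect_true(evaluate_reminder(preg, cloud_profile(), 6)$fired)
  expect_true(evaluate_reminder(preg, local_profile(), 5)$fired)
  # ESRD and ACE-I use suppress both
  esrd <- do.call(rec, c(renal_base,
                         list(ev("problem", "SNOMED", "ESRD-1"),
                              ev("lab", "LOINC", "MALB-RATIO", days = 60))))
  expect_false(evaluate_reminder(esrd, cloud_profile(), 5)$fired)
  on_ace <- do.call(rec, c(renal_base,
                           list(ev("medication", "MEDCLASS", "ACE_I", days = 0),
                                ev("lab", "LOINC", "MALB-RATIO", days = 60))))
  expect_false(evaluate_reminder(on_ace, cloud_profile(), 5)$fired)
})

test_that("microalbumin screening honours the renal-disease exclusion switch", {
  renal_nolab <- rec(ev("problem", "SNOMED", "DM-TYPE2"),
                     ev("problem", "SNOMED", "CKD-1"))
  expect_false(evaluate_reminder(renal_nolab, cloud_profile(), 4)$fired)
  expect_true(evaluate_reminder(renal_nolab, local_profile(), 4)$fired)
  plain <- rec(ev("problem", "SNOMED", "DM-TYPE2"))
  expect_true(evaluate_reminder(plain, cloud_profile(), 4)$fired)
  expect_true(evaluate_reminder(plain, local_profile(), 4)$fired)
})

test_that("eye exam exclusions apply only in the local profile", {
  blind <- rec(ev("problem", "SNOMED", "DM-TYPE2"),
               ev("problem", "SNOMED", "BLIND-1"))
  expect_true(evaluate_reminder(blind, cloud_profile(), 7)$fired)
  expect_false(evaluate_reminder(blind, local_profile(), 7)$fired)
  clinic <- rec(ev("problem", "SNOMED", "DM-TYPE2"),
                ev("exam", "LOCAL", "EYE-CLINIC", days = 100))
  expect_true(evaluate_reminder(clinic, cloud_profile(), 7)$fired)
  expect_false(evaluate_reminder(clinic, local_profile(), 7)$fired)
  # an old clinic visit does not exclude
  old_clinic <- rec(ev("problem", "SNOMED", "DM-TYPE2"),
                    ev("exam", "LOCAL", "EYE-CLINIC", days = 400))
  expect_true(evaluate_reminder(old_clinic, local_profile(), 7)$fired)
})

test_that("an empty record can fire only the blood pressure reminder", {
  for (p in list(cloud_profile(), local_profile())) {
    out <- evaluate_all(rec(), p)
    expect_identical(out$reminder_id, 1:11)
    expect_identical(which(out$fired), 9L)
  }
})

test_that("a fully up-to-date diabetic fires nothing", {
  for (p in list(cloud_profile(), local_profile())) {
    out <- evaluate_all(up_to_date_diabetic(), p)
    expect_false(any(out$fired))
  }
})

test_that("messages are non-empty exactly when a reminder fires", {
  overdue <- rec(ev("problem", "SNOMED", "DM-TYPE2"))
  out <- evaluate_all(overdue, cloud_profile())
  expect_identical(nzchar(out$message), out$fired)
  expect_match(out$message[1], "^Diabetic patient is overdue for HgbA1c")
  expect_match(out$message[1], "\n\u2022 Order HgbA1c now\\.$")
  expect_error(evaluate_reminder(overdue, cloud_profile(), 12),
               "reminder_id")
})

test_that("the built-in profiles differ in at least 8 parameters", {
  cp <- cloud_profile()
  lp <- local_profile()
  diffs <- c(
    !identical(cp$diabetes_sources, lp$diabetes_sources),
    cp$exclude_gestational_diabetes != lp$exclude_gestational_diabetes,
    cp$angina_implies_cad != lp$angina_implies_cad,
    cp$microalbumin_excludes_renal_disease !=
      lp$microalbumin_excludes_renal_disease,
    cp$ace_evidence_lookback_months != lp$ace_evidence_lookback_months,
    !identical(cp$eye_exam_exclusions, lp$eye_exam_exclusions),
    !identical(cp$concept_sets$BP_LAB$members, lp$concept_sets$BP_LAB$members),
    !identical(cp$concept_sets$ACE_CONTRA$members,
               lp$concept_sets$ACE_CONTRA$members),
    !identical(cp$concept_sets$ANTIPLATELET_CONTRA$members,
               lp$concept_sets$ANTIPLATELET_CONTRA$members))
  expect_gte(sum(diffs), 8)
  # cloud recognizes only plain systolic BP; local adds the sitting code
  expect_true(in_concept_set("LOINC", "8480-6", cp$concept_sets$BP_LAB))
  expect_false(in_concept_set("LOINC", "8459-0", cp$concept_sets$BP_LAB))
  expect_true(in_concept_set("LOINC", "8459-0", lp$concept_sets$BP_LAB))
  expect_identical(lp$eye_exam_exclusions,
                   c("blindness", "eye_clinic_visit_within_12mo"))
})

test_that("equalizing every parameter makes the two profiles behave identically", {
  cp <- cloud_profile()
  equalized <- rule_profile(
    name = "LOCAL_EQUALIZED",
    concept_sets = cp$concept_sets,
    diabetes_sources = cp$diabetes_sources,
    exclude_gestational_diabetes = cp$exclude_gestational_diabetes,
    angina_implies_cad = cp$angina_implies_cad,
    microalbumin_excludes_renal_disease =
      cp$microalbumin_excludes_renal_disease,
    ace_evidence_lookback_months = cp$ace_evidence_lookback_months,
    eye_exam_exclusions = cp$eye_exam_exclusions,
    windows = cp$windows)
  cohort <- generate_cohort(synthetic_cohort_config(n_visits = 150, seed = 11))
  expect_identical(evaluate_cohort(cohort, equalized),
                   evaluate_cohort(cohort, cp))
})

test_that("evaluation is pure and repeatable", {
  r <- rec(ev("problem", "SNOMED", "DM-TYPE2"),
           ev("lab", "LOINC", "HBA1C-PCT", days = 170, value = 9.1))
  before <- r
  out1 <- evaluate_all(r, cloud_profile())
  out2 <- evaluate_all(r, cloud_profile())
  expect_identical(out1, out2)
  expect_identical(r, before)
})

test_that("mutual exclusion and diabetes-guard monotonicity hold on random records", {
  cohort <- generate_cohort(synthetic_cohort_config(n_visits = 400, seed = 23))
  for (p in list(cloud_profile(), local_profile())) {
    fired <- evaluate_cohort(cohort, p)
    expect_true(all(rowSums(fired[, c(1, 2, 3)]) <= 1))
    expect_true(all(rowSums(fired[, c(5, 6)]) <= 1))
    expect_true(all(rowSums(fired[, c(10, 11)]) <= 1))
  }
  # strip every diabetes-asserting event: rules 1-8 all turn off
  diabetes_codes <- c("DM-TYPE1", "DM-TYPE2", "DM-GEST", "250-X",
                      "ORAL_HYPOGLYCEMIC", "INSULIN")
  stripped <- lapply(cohort, function(r) {
    keep <- !(r$events$code %in% diabetes_codes)
    visit_record(r$visit_id, r$patient_id, r$visit_date,
                 r$events[keep, , drop = FALSE])
  })
  for (p in list(cloud_profile(), local_profile())) {
    fired <- evaluate_cohort(stripped, p)
    expect_false(any(fired[, 1:8]))
  }
})
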