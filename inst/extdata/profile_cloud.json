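{
  "name": "CLOUD",
  "diabetes_sources": ["problem_list"],
  "exclude_gestational_diabetes": true,
  "angina_implies_cad": true,
  "microalbumin_excludes_renal_disease": true,
  "ace_evidence_lookback_months": 12,
  "eye_exam_exclusions": [],
  "windows": {
    "hba1c_due": 6,
    "hba1c_almost_due_lo": 5,
    "hba1c_poor_lo": 3,
    "hba1c_poor_hi": 5,
    "hba1c_poor_threshold": 8.0,
    "microalbumin_lookback": 11,
    "eye_exam_lookback": 11,
    "foot_exam_lookback": 11,
    "bp_lookback": 12
  },
  "concept_sets": {
    "DIABETES": [
      {"system": "SNOMED", "code": "DM-TYPE1"},
      {"system": "SNOMED", "code": "DM-TYPE2"},
      {"system": "SNOMED", "code": "DM-GEST"}
    ],
    "GESTATIONAL_DIABETES": [
      {"system": "SNOMED", "code": "DM-GEST"}
    ],
    "DIABETES_ICD9": [
      {"system": "ICD9", "code": "250-X"}
    ],
    "RENAL_DISEASE": [
      {"system": "SNOMED", "code": "CKD-1"}
    ],
    "ESRD": [
      {"system": "SNOMED", "code": "ESRD-1"}
    ],
    "CAD": [
      {"system": "SNOMED", "code": "CAD-1"}
    ],
    "ANGINA": [
      {"system": "SNOMED", "code": "194828000"}
    ],
    "HBA1C_LAB": [
      {"system": "LOINC", "code": "HBA1C-PCT"}
    ],
    "MICROALBUMIN_LAB": [
      {"system": "LOINC", "code": "MALB-RATIO"}
    ],
    "BP_LAB": [
      {"system": "LOINC", "code": "8480-6"}
    ],
    "EYE_EXAM": [
      {"system": "LOCAL", "code": "EYE-EXAM"}
    ],
    "FOOT_EXAM": [
      {"system": "LOCAL", "code": "FOOT-EXAM"}
    ],
    "BLINDNESS": [
      {"system": "SNOMED", "code": "BLIND-1"}
    ],
    "EYE_CLINIC_VISIT": [
      {"system": "LOCAL", "code": "EYE-CLINIC"}
    ],
    "ACE_I": [
      {"system": "MEDCLASS", "code": "ACE_I"}
    ],
    "ARB": [
      {"system": "MEDCLASS", "code": "ARB"}
    ],
    "ANTIPLATELET": [
      {"system": "MEDCLASS", "code": "ANTIPLATELET"}
    ],
    "ORAL_HYPOGLYCEMIC": [
      {"system": "MEDCLASS", "code": "ORAL_HYPOGLYCEMIC"}
    ],
    "INSULIN": [
      {"system": "MEDCLASS", "code": "INSULIN"}
    ],
    "ACE_CONTRA": [
      {"system": "SNOMED", "code": "ACE-ALLERGY"},
      {"system": "SNOMED", "code": "PREG-1"},
      {"system": "SNOMED", "code": "HYPERK-1"}
    ],
    "ARB_CONTRA": [
      {"system": "SNOMED", "code": "ARB-ALLERGY"}
    ],
    "ANTIPLATELET_CONTRA": [
      {"system": "SNOMED", "code": "BLEED-DIS-1"},
      {"system": "SNOMED", "code": "THROMBO-1"},
      {"system": "SNOMED", "code": "GIBLEED-1"},
      {"system": "SNOMED", "code": "ESOPH-VAR-1"},
      {"system": "SNOMED", "code": "COAG-DEF-1"},
      {"system": "SNOMED", "code": "CEREB-HEM-1"}
    ]
  }
}
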