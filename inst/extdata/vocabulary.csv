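set_name,system,code,display
DIABETES,SNOMED,DM-TYPE1,Diabetes mellitus type 1 (synthetic placeholder)
DIABETES,SNOMED,DM-TYPE2,Diabetes mellitus type 2 (synthetic placeholder)
DIABETES,SNOMED,DM-GEST,Gestational diabetes mellitus (synthetic placeholder)
GESTATIONAL_DIABETES,SNOMED,DM-GEST,Gestational diabetes mellitus (synthetic placeholder)
DIABETES_ICD9,ICD9,250-X,Diabetes mellitus discharge diagnosis (synthetic placeholder)
RENAL_DISEASE,SNOMED,CKD-1,Chronic kidney disease (synthetic placeholder)
ESRD,SNOMED,ESRD-1,End-stage renal disease (synthetic placeholder)
CAD,SNOMED,CAD-1,Coronary artery disease (synthetic placeholder)
ANGINA,SNOMED,194828000,Angina
HBA1C_LAB,LOINC,HBA1C-PCT,Hemoglobin A1c percent (synthetic placeholder)
MICROALBUMIN_LAB,LOINC,MALB-RATIO,Urine microalbumin/creatinine ratio (synthetic placeholder)
BP_STANDARD,LOINC,8480-6,Systolic blood pressure
BP_SITTING,LOINC,8459-0,Systolic blood pressure - sitting
EYE_EXAM,LOCAL,EYE-EXAM,Diabetic ophthalmologic exam (synthetic placeholder)
FOOT_EXAM,LOCAL,FOOT-EXAM,Diabetic foot exam (synthetic placeholder)
BLINDNESS,SNOMED,BLIND-1,Blindness (synthetic placeholder)
EYE_CLINIC_VISIT,LOCAL,EYE-CLINIC,Eye clinic visit (synthetic placeholder)
ACE_I,MEDCLASS,ACE_I,ACE inhibitor drug class
ARB,MEDCLASS,ARB,Angiotensin-2 receptor antagonist drug class
ANTIPLATELET,MEDCLASS,ANTIPLATELET,Antiplatelet drug class
ORAL_HYPOGLYCEMIC,MEDCLASS,ORAL_HYPOGLYCEMIC,Oral hypoglycemic drug class
INSULIN,MEDCLASS,INSULIN,Insulin drug class
ACE_ALLERGY,SNOMED,ACE-ALLERGY,Allergy to ACE inhibitors (synthetic placeholder)
PREGNANCY,SNOMED,PREG-1,Pregnancy (synthetic placeholder)
HYPERKALEMIA,SNOMED,HYPERK-1,Hyperkalemia (synthetic placeholder)
ARB_ALLERGY,SNOMED,ARB-ALLERGY,Allergy to ARBs (synthetic placeholder)
ANTIPLATELET_CONTRA_CORE,SNOMED,BLEED-DIS-1,Bleeding disorder (synthetic placeholder)
ANTIPLATELET_CONTRA_CORE,SNOMED,THROMBO-1,Thrombocytopenia (synthetic placeholder)
ANTIPLATELET_CONTRA_CORE,SNOMED,GIBLEED-1,Gastrointestinal bleed (synthetic placeholder)
ANTIPLATELET_CONTRA_EXT,SNOMED,ESOPH-VAR-1,Esophageal varices (synthetic placeholder)
ANTIPLATELET_CONTRA_EXT,SNOMED,COAG-DEF-1,Coagulation factor deficiency syndrome (synthetic placeholder)
ANTIPLATELET_CONTRA_EXT,SNOMED,CEREB-HEM-1,Cerebral hemorrhage (synthetic placeholder)
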