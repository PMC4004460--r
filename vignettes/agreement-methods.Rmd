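---
title: "Measuring agreement between two preventive-care reminder engines"
author: "cdsagree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring agreement between two preventive-care reminder engines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdsagree)
```

## The problem and the design

Two clinical decision support (CDS) engines — one maintained centrally
in the cloud for many institutions, one curated by local informatics
experts — implement the same eleven preventive-care guidelines: HbA1c
monitoring in diabetes (rules 1–3), urine microalbumin screening (4),
ACE-inhibitor/ARB advice in diabetic renal disease (5–6), annual eye
and foot exams (7–8), blood-pressure assessment (9), and antiplatelet
therapy in coronary artery disease (10–11). Run over the same visit
records, they do not always give the same advice. `cdsagree` treats the
two engines as two raters making a binary fire/no-fire call per
(visit, rule) pair and quantifies their agreement.

The package models each engine as a `rule_profile`: the *same* rule
logic evaluated under a different parameterization — concept sets,
evidence sources, lookback windows, and exclusion switches. The
built-in `cloud_profile()` and `local_profile()` differ in nine
parameters, grouped into four discrepancy classes:

* **terminology** — the cloud profile's blood-pressure concept set
  contains only the plain systolic LOINC code (8480-6); the local one
  also recognizes the sitting variant (8459-0) the clinics actually
  record. Only rule 9 reads this set.
* **local practice variation** — the cloud profile treats a coded
  angina problem as a CAD indicator (rules 10–11); the profiles also
  define diabetes differently: cloud from the problem list only, with a
  gestational-diabetes exclusion; local additionally from hypoglycemic
  medications and hospital ICD9 discharge diagnoses, with no
  gestational exclusion (all diabetes-guarded rules).
* **temporal windows** — the ACE-I/ARB rules require microalbuminuria
  lab evidence; the cloud profile searches only 12 months back, the
  local one has no time bound.
* **use of exclusions** — the cloud profile suppresses microalbumin
  screening in established renal disease and recognizes more ACE-I
  contraindications (pregnancy, hyperkalemia) and more antiplatelet
  contraindications (esophageal varices, coagulation-factor deficiency,
  cerebral hemorrhage); the local profile alone excludes blind patients
  and recent eye-clinic visitors from the eye-exam reminder.

## Agreement statistics

For each rule, the paired outcomes over *n* visits form a 2×2 table:
*a* both fired, *b* first (cloud) only, *c* second (local) only, *d*
neither. The statistics:

* observed agreement `P0 = (a + d)/n`;
* Cohen's `kappa = (P0 − Pe)/(1 − Pe)`,
  `Pe = [(a+b)(a+c) + (c+d)(b+d)]/n²`. When both raters are constant
  (`Pe = 1`) kappa is undefined and reported as `NA` rather than forced
  to a number;
* Bias Index `BI = (c − b)/n` — the difference between the raters'
  firing proportions. The sign convention is chosen so the shipped
  reference table reproduces exactly: negative BI means the first
  (cloud) rater fired more often;
* Prevalence Index `PI = (a − d)/n`;
* `PABAK = 2·P0 − 1` (Byrt–Bishop–Carlin): the kappa obtained after
  replacing the observed table by one with balanced prevalence and zero
  bias at the same P0. The identity `PABAK ≡ 2·P0 − 1` and the sign
  relation `PABAK − kappa = (1 − P0)(2·Pe − 1)/(1 − Pe)` are asserted
  by property tests; when `BI = PI = 0`, kappa and PABAK coincide.
* Landis–Koch bands label the coefficient: (0.80, 1] almost perfect,
  (0.60, 0.80] substantial, (0.40, 0.60] moderate, (0.20, 0.40] fair,
  (0, 0.20] slight, ≤ 0 poor/none. The boundary values printed in the
  conventional ranges (0.61, 0.81, …) are included in the higher band.

Why PABAK matters here: preventive reminders are often rare events, and
for a rare event `Pe` is close to 1, so kappa is small even when the
engines almost always agree. In the shipped reference counts, rule 3
has `P0 = 0.95` but `kappa = 0.28`; PABAK (0.91) restores an accurate
impression. Conversely rule 9's kappa (0.34) is *flattered* by rater
bias; PABAK (0.33) removes that too.

### Bootstrap confidence intervals

95% intervals for PABAK use the percentile bootstrap: resample the *n*
visit pairs with replacement, recompute PABAK per replicate (10,000 by
default), take the 2.5th and 97.5th percentiles (`stats::quantile`,
default type). The percentile method was chosen as the simplest
resampling scheme consistent with the reference intervals — all 22
published bounds are matched within ±0.02 Monte-Carlo tolerance in the
test suite. Resampling is per rule (independent streams seeded
`seed + rule`); marginal intervals are identical to joint-across-rules
resampling. `expand_table()` deterministically reconstructs the pair
sequence from printed counts so the bootstrap can run without patient
records.

Full precision is kept everywhere internally; rounding (half away from
zero, 2 decimals) happens only in the presentation layer
(`round_half_up()`, `write_report_csv()`).

## Rule evaluation choices

The guidelines phrase windows in months but never define month
arithmetic, so the engine uses one documented constant: elapsed months
= days / 30.4375 (mean Gregorian month). Interval conventions: "within
last N months" ⇔ elapsed < N; "over N months ago" ⇔ elapsed > N;
"between A and B months ago" ⇔ A ≤ elapsed < B. These make rules 1–3
partition the timeline (no HbA1c within 6 months / last result in
[5, 6) / in [3, 5) with value > 8%), which their mutual exclusion
requires; the 182-vs-183-day boundary is exercised explicitly in the
tests (183/30.4375 ≈ 6.012 > 6, 182/30.4375 ≈ 5.98 < 6).

Other decisions a reader should know:

* "Greater than 8%" is strict. Same-date lab ties resolve to the
  maximum value — deterministic, and conservative toward alerting for
  the poor-control rule.
* A diabetic with *no* eye or foot exam on record is due (the rules
  say "last exam over 11 months ago"; absence is treated as maximally
  overdue, matching the explicit "no result within…" phrasing of
  rule 1).
* "Established renal disease" (rule 4) and "chronic renal disease"
  (rules 5–6) resolve to the same concept set; ESRD is separate. The
  source guidelines give no finer distinction.
* The ACE-I/ARB rules require microalbuminuria evidence under both
  profiles; only the lookback differs (12 months vs unbounded). The
  requirement itself is switchable via `ace_evidence_lookback_months`.
* Rule 9 applies to every visit: the record model carries no age, so
  the "adults" qualifier of the blood-pressure guideline is not
  enforced.
* Medication exposure is class-level (`MEDCLASS` codes `ACE_I`, `ARB`,
  `ANTIPLATELET`, `ORAL_HYPOGLYCEMIC`, `INSULIN`); every rule tests
  class membership only, so individual-drug mapping is out of scope.
* Apart from LOINC 8480-6/8459-0 and SNOMED 194828000 (angina), all
  codes in the shipped vocabulary are invented placeholders, marked
  "synthetic placeholder" in their display strings; real concept lists
  are proprietary to the original systems. Codes from unknown
  vocabularies are preserved verbatim and match no concept set —
  mirroring how real engines silently ignore unrecognized codes.

## The synthetic cohort generator

`generate_cohort()` emulates the *structure* the analysis assumes, not
any real population: one visit per synthetic patient (the reference
design analyzes visit-level pairs and does not model within-patient
correlation), condition prevalences (diabetes 0.60, CAD 0.20, renal
disease 0.15 by default — a diabetes-heavy primary-care panel chosen so
all eleven rules fire at plausible rates), per-modality lab/exam
presence probabilities, and recency sampled uniformly over 0–24 months
so every window boundary (3/5/6/11/12 months) occurs with positive
probability. HbA1c values are Normal(7.5, 1.5) truncated to (4, 15)%.
Dates are day-granular via the same month constant the engine uses.

Discordance knobs inject exactly the disagreements the profiles can
express: `p_bp_sitting_code` (default 0.30 — sitting-coded blood
pressures), `p_gestational_only`, `p_hypoglycemic_med_without_problem`,
`p_discharge_dx_without_problem`, `p_angina_without_cad`,
`p_ace_contra_cloud_only`, `p_antiplatelet_contra_extended_only`,
`p_blindness`, `p_eye_clinic_visit`, and `microalbumin_stale_frac`
(evidence older than 12 months). With every knob at zero the two
profiles are observationally identical on any generated cohort — the
null-concordance test asserts bit-identical outputs and PABAK = 1.

`concordance_stress_cohort()` activates one discrepancy class at a
time. Because some profile differences are latent in *base* clinical
structure (the renal-disease exclusion of rule 4 needs renal patients;
the ACE lookback needs microalbumin labs), the stress configurations
control that structure too: renal prevalence is zeroed outside the
temporal/exclusions classes, the temporal class forces microalbumin
always-present (so intensity 0 is perfectly concordant and staleness
alone drives discordance), and the exclusions class caps microalbumin
recency below 11 months (so the temporal mechanism cannot leak in). The
resulting rule subsets, asserted in tests:

| class               | rules that can disagree |
|---------------------|-------------------------|
| terminology         | 9                       |
| practice_variation  | 1–4, 7, 8, 10, 11       |
| temporal            | 4, 5, 6                 |
| exclusions          | 4, 5, 6, 7, 10, 11      |

(The temporal class includes rule 4 because a stale microalbumin also
leaves the 11-month screening window empty, which the renal exclusion
then turns into disagreement.)

What passing these tests shows — and does not. They show the engine
plumbing, the statistics, and the class isolation are correct under a
cohort whose marginal structure is known exactly. They do not show the
generator reproduces any real clinic: recency is uniform rather than
guideline-driven (real patients cluster near due dates), comorbidity
correlations are absent, demographics are not generated at all (no
rule reads them), and coding noise is limited to the modeled variants.

## Problem sizes and numerical notes

The test suite runs the full reference regression (all 11 rules, 2 dp),
22 bootstrap bounds at 10,000 replicates, an exhaustive
kappa-oracle sweep of every 2×2 table with n ≤ 14 plus random tables to
n = 50 (the oracle enumerates all n² cross-pairings, independent of the
closed form), mutual-exclusion checks on a 10,000-record synthetic
cohort under both profiles, and monotone-discordance checks at n =
2,000 per knob level. Bootstrap quantiles use R's default type-7; at
10,000 replicates the difference from other percentile definitions is
far below the reported precision. Degenerate inputs are defined, not
accidental: empty tables raise an error, Pe = 1 yields `NA` kappa,
single-pair bootstraps are rejected, and zero-width CIs arise naturally
when all pairs agree.

## Known limitations

* The record model is a reconstruction sufficient for the eleven rules:
  no age/sex, no encounter history beyond one visit, no free text.
* Concept sets are placeholders; results on real data depend entirely
  on the locally correct vocabulary mapping — which is precisely the
  discordance mechanism this package exists to measure.
* Kappa variants beyond PABAK (weighted kappa, multi-rater) and
  analytic CIs are out of scope.
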