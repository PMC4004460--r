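# cdsagree

Measuring agreement between two clinical decision support (CDS) rule
engines that implement the same preventive-care guidelines.

## The problem

Health systems increasingly consume clinical reminders from a shared,
cloud-hosted rules service instead of (or alongside) rules curated by
local informatics experts. Both implementations encode the *same*
guidelines — HbA1c monitoring in diabetes, microalbumin screening,
ACE-inhibitor/ARB advice in diabetic renal disease, annual eye and foot
exams, blood-pressure checks, antiplatelet therapy in coronary artery
disease (CAD) — but they differ in terminology mappings, evidence
sources, lookback windows and exclusion policies. `cdsagree` is for
informaticists and biostatisticians who need to quantify how often two
such engines give the same advice on the same patient visits, and to
diagnose *why* they disagree.

The package provides:

* a visit-level clinical record model with a JSON-Lines serialization
  (coded problems, dated/valued labs, active medication classes, exams,
  discharge diagnoses);
* a rule engine for eleven preventive-care reminders, parameterized by a
  `rule_profile` (concept sets, evidence sources, lookback windows,
  exclusion switches) with two built-in profiles, `cloud_profile()` and
  `local_profile()`, embodying a cloud-curated vs. a locally-curated
  implementation;
* per-rule agreement statistics on the resulting 2×2 tables;
* a synthetic cohort generator with tunable "discordance knobs", so the
  whole pipeline is testable without patient data.

## The statistics

For each rule, paired fire/no-fire decisions over *n* visits are
tabulated as *a* (both fired), *b* (first engine only), *c* (second
engine only), *d* (neither). The package computes

* observed agreement **P₀ = (a + d) / n**;
* **Cohen's κ = (P₀ − Pₑ)/(1 − Pₑ)** with chance agreement
  Pₑ = [(a+b)(a+c) + (c+d)(b+d)] / n²;
* **Bias Index BI = (c − b)/n** and **Prevalence Index
  PI = (a − d)/n**;
* prevalence-adjusted bias-adjusted kappa **PABAK = 2·P₀ − 1**
  (Byrt–Bishop–Carlin), with 95% percentile bootstrap confidence
  intervals (10,000 resamples of the n visit pairs);
* the Landis–Koch verbal band (slight … almost perfect).

κ is notoriously sensitive to prevalence and rater bias: a rule that
almost never triggers can combine P₀ = 0.95 with κ = 0.28. PABAK removes
both distortions and is the headline measure here.

## Worked example

Agreement for the "overdue for HbA1c" rule from its 2×2 counts, and a
full report from a counts CSV:

```r
library(cdsagree)

t <- two_by_two(a = 85, b = 20, c = 7, d = 293)
cohen_kappa(t)          # 0.8191152  -> 0.82 at 2 dp
pabak(t)                # 0.8666667  -> 0.87
summarize_agreement(t, replicates = 10000, seed = 1)
#> <agreement n=405  P0=0.93  kappa=0.82  BI=-0.03  PI=-0.51
#>   PABAK=0.87 (0.82 - 0.91) [almost perfect]>

counts <- read_counts_csv(system.file("extdata", "table3_counts.csv",
                                      package = "cdsagree"))
report <- stats_from_counts(counts, replicates = 10000, seed = 20140410)
report$totals
#> first second
#>   965    889
```

`print(report)` lists all eleven rules; PABAK ranges from 0.33 (blood
pressure — the first engine recognizes only the plain systolic LOINC
code 8480-6, not the sitting variant 8459-0 the clinics use) to 0.99,
with seven rules in the almost-perfect band.

End-to-end on synthetic data:

```r
cohort <- generate_cohort(synthetic_cohort_config(n_visits = 405, seed = 1))
run_comparison(cohort, cloud_profile(), local_profile(),
               replicates = 10000, seed = 1)
```

## Analysis workflow

Numbered drivers under `analysis/` re-run the full study pipeline and
write their tables to `results/`:

1. `01_reproduce_reference_tables.R` — agreement statistics and engine
   totals from the shipped per-rule counts;
2. `02_simulate_cohort.R` — a 405-visit synthetic cohort (JSON Lines +
   config echo);
3. `03_compare_engines.R` — CLOUD vs LOCAL evaluation of that cohort;
4. `04_stress_discrepancy_classes.R` — per-class discordance
   decomposition (terminology / practice variation / temporal windows /
   exclusions), showing each class perturbs only its own rule subset.

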