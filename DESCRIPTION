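Package: cdsagree
Title: Agreement Between Clinical Decision Support Reminder Engines
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Executes two independently parameterized implementations of
    eleven preventive-care reminder rules (diabetes monitoring, blood
    pressure screening, antiplatelet therapy in coronary artery disease)
    over the same patient-visit records and measures their agreement.
    Provides per-rule 2x2 tabulation, observed agreement, Cohen's kappa,
    the Bias and Prevalence Indices, prevalence-adjusted bias-adjusted
    kappa (PABAK) with percentile bootstrap confidence intervals, and
    Landis-Koch interpretation bands.  Includes a synthetic cohort
    generator that emulates the clinical structure such comparisons
    assume (condition prevalences, lab and exam recency, coding-variant
    noise) so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
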