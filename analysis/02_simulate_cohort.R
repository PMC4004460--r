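#!/usr/bin/env Rscript
# Stage 2 — synthetic study cohort.
#
# Generates a 405-visit synthetic primary-care cohort with the default
# clinical structure (diabetes-heavy population, uniform lab/exam
# recency over 24 months, 30% of blood pressures carried on the
# sitting-systolic code) and writes it as JSON Lines plus a config echo
# for provenance.  The cohort is a structural stand-in for the
# undeposited clinic data: its prevalences are plausible, not fitted.

suppressPackageStartupMessages(library(cdsagree))

dir.create("results", showWarnings = FALSE)

cfg <- synthetic_cohort_config(n_visits = 405, seed = 20111001)
cohort <- generate_cohort(cfg)
write_visit_records(cohort, "results/synthetic_cohort.jsonl")
jsonlite::write_json(unclass(cfg), "results/synthetic_cohort_config.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)
cat(sprintf("wrote %d visit records to results/synthetic_cohort.jsonl\n",
            length(cohort)))
cat("config echoed to results/synthetic_cohort_config.json\n")
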