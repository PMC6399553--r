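#!/usr/bin/env Rscript
# Simulate the synthetic preoperative cohorts used throughout the analysis:
# a 909-patient model-development cohort (20.13% SSI) and a 228-patient
# held-out test cohort (21.93% SSI), with the 14-test catalog. Writes the
# raw tables under results/data/ and prints the cohort summary.

suppressPackageStartupMessages(library(preopssi))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
catalog <- default_catalog()
write_catalog_json(catalog, file.path(out, "catalog.json"))

dev <- generate_cohort(cohort_spec(909, prevalence = 0.2013, seed = 101),
                       catalog)
tst <- generate_cohort(cohort_spec(228, prevalence = 0.2193, seed = 102),
                       catalog)

write_labs_csv(dev$labs, file.path(out, "dev_labs.csv"))
write_patients_csv(dev$patients, file.path(out, "dev_patients.csv"))
write_labs_csv(tst$labs, file.path(out, "test_labs.csv"))
write_patients_csv(tst$patients, file.path(out, "test_patients.csv"))

cat(sprintf("development cohort: %d patients, %d SSI cases (%.2f%%)\n",
            nrow(dev$patients), sum(dev$patients$ssi),
            100 * mean(dev$patients$ssi)))
cat(sprintf("test cohort:        %d patients, %d SSI cases (%.2f%%)\n",
            nrow(tst$patients), sum(tst$patients$ssi),
            100 * mean(tst$patients$ssi)))

recent <- dev$labs[dev$labs$day <= 29, ]
rate <- table(factor(recent$test_name, levels = catalog$test_name)) /
  nrow(dev$patients)
cat("\nmeasurements per patient over the last 30 days (target rate30):\n")
for (i in order(-rate))
  cat(sprintf("  %-16s %5.2f  (%.2f)\n", catalog$test_name[i],
              rate[i], catalog$rate30[i]))

grid <- aggregate_daily(dev$labs, 60, dev$patients$patient_id,
                        catalog$test_name)
miss <- 100 * (1 - apply(grid$mask, 2, mean))
cat(sprintf("\ndaily-grid missingness: %.2f%% (%s) to %.2f%% (%s)\n",
            min(miss), grid$tests[which.min(miss)],
            max(miss), grid$tests[which.max(miss)]))
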