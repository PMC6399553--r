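#!/usr/bin/env Rscript
# Automatic temporal-window selection: exhaustively score candidate
# partitionings of the 60-day observation window by the product of
# per-window group-contrast distances between the SSI and non-SSI daily
# mean curves, for CRP and the other planted-signal tests. Writes the
# optimized windows to results/windows/windows.json.

suppressPackageStartupMessages(library(preopssi))

catalog <- read_catalog_json("results/data/catalog.json")
labs <- read_labs_csv("results/data/dev_labs.csv", catalog)
patients <- read_patients_csv("results/data/dev_patients.csv")
out <- "results/windows"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

en <- enumerate_partitionings(60, 3)
cat(sprintf("search space: %d candidate 3-partitionings of the 60-day window\n",
            en$count))

tests <- c("CRP", "Leukocytes", "Hemoglobin")
found <- list()
for (tn in tests) {
  b <- best_partitioning(labs, patients, tn, k_max = 3, obs_days = 60)
  w <- vapply(b$windows, function(x) sprintf("[%d, %d]", x[1], x[2]), "")
  cat(sprintf("%-12s best k = %d, score = %.3f, windows (newest first): %s\n",
              tn, b$k, b$score, paste(w, collapse = " ")))
  found[[tn]] <- list(k = b$k, cuts = b$cuts,
                      windows = lapply(b$windows, as.integer),
                      score = b$score)
}
jsonlite::write_json(found, file.path(out, "windows.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("windows written to", file.path(out, "windows.json"), "\n")
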