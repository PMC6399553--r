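#!/usr/bin/env Rscript
# Repeated-holdout evaluation of the model-variant battery on the
# development cohort: CRP baseline, basic lasso (BLM), full lasso (FLM),
# and price-penalized (PPM) models, with and without the p_max cap.
# 25 holdout repetitions per variant keep the full battery to a few
# minutes; increase n_repeats for tighter intervals. Writes the summary
# table, the FLM selection-frequency table, and the FLM-vs-PPM cost
# comparison under results/evaluation/.

suppressPackageStartupMessages(library(preopssi))

catalog <- read_catalog_json("results/data/catalog.json")
labs <- read_labs_csv("results/data/dev_labs.csv", catalog)
patients <- read_patients_csv("results/data/dev_patients.csv")
read_X <- function(fs) {
  df <- utils::read.csv(sprintf("results/features/%s_features.csv", fs),
                        check.names = FALSE)
  rownames(df) <- df$patient_id
  df$patient_id <- NULL
  df
}
out <- "results/evaluation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

variants <- list(
  CRP      = list(fs = "crp", p_max = NULL, price = FALSE),
  BLM      = list(fs = "blm", p_max = NULL, price = FALSE),
  BLM_p20  = list(fs = "blm", p_max = 20, price = FALSE),
  FLM      = list(fs = "flm", p_max = NULL, price = FALSE),
  FLM_p50  = list(fs = "flm", p_max = 50, price = FALSE),
  PPM      = list(fs = "flm", p_max = NULL, price = TRUE),
  PPM_p20  = list(fs = "flm", p_max = 20, price = TRUE))

n_repeats <- 25
rows <- list(); runs <- list()
for (nm in names(variants)) {
  vv <- variants[[nm]]
  X <- read_X(vv$fs)
  y <- patients$ssi[match(rownames(X), patients$patient_id)]
  r <- repeated_holdout(X, y,
                        experiment_spec(n_repeats = n_repeats,
                                        p_max = vv$p_max,
                                        price_penalty = vv$price,
                                        folds = 10, seed = 401),
                        catalog = catalog, labs = labs)
  runs[[nm]] <- r
  s <- r$summary
  rows[[nm]] <- data.frame(
    variant = nm,
    n_features = round(s["n_selected", "mean"], 1),
    auc = round(s["auc", "mean"], 3),
    auc_lo = round(s["auc", "lo"], 3), auc_hi = round(s["auc", "hi"], 3),
    auprc = round(s["auprc", "mean"], 3),
    sens = round(s["sens", "mean"], 3), spec = round(s["spec", "mean"], 3),
    ppv = round(s["ppv", "mean"], 3), npv = round(s["npv", "mean"], 3),
    cost_nok = r$cost_total)
  cat(sprintf("%-8s AUC %.3f [%.3f, %.3f]  features %5.1f  cost %12.0f NOK\n",
              nm, s["auc", "mean"], s["auc", "lo"], s["auc", "hi"],
              s["n_selected", "mean"], r$cost_total))
}
tab <- do.call(rbind, rows)
utils::write.csv(tab, file.path(out, "variant_summary.csv"),
                 row.names = FALSE)

sel <- runs$FLM$selection
sel <- sel[sel$n_selected > n_repeats / 2, ]
utils::write.csv(sel, file.path(out, "flm_selection_frequency.csv"),
                 row.names = FALSE)
cat(sprintf("\nFLM features selected in more than half of %d repeats:\n",
            n_repeats))
print(sel, row.names = FALSE)

red <- cost_reduction(runs$FLM$cost_total, runs$PPM_p20$cost_total)
cat(sprintf("\nprovisional validation-set test cost, FLM %0.f NOK vs PPM(p_max=20) %0.f NOK: %.1f%% reduction\n",
            runs$FLM$cost_total, runs$PPM_p20$cost_total, 100 * red))
jsonlite::write_json(list(cost_flm = runs$FLM$cost_total,
                          cost_ppm_p20 = runs$PPM_p20$cost_total,
                          relative_reduction = red,
                          n_validation_total = runs$FLM$n_validation_total),
                     file.path(out, "cost_comparison.json"),
                     auto_unbox = TRUE, digits = NA)
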