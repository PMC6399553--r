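#!/usr/bin/env Rscript
# Fit the penalized models once on the full development cohort to inspect
# the regularization path, the price-derived penalty factors, and the
# effect of the p_max early-stopping cap. Writes the fitted coefficient
# tables under results/models/.

suppressPackageStartupMessages(library(preopssi))

catalog <- read_catalog_json("results/data/catalog.json")
read_X <- function(fs) {
  df <- utils::read.csv(sprintf("results/features/%s_features.csv", fs),
                        check.names = FALSE)
  rownames(df) <- df$patient_id
  df$patient_id <- NULL
  df
}
patients <- read_patients_csv("results/data/dev_patients.csv")
out <- "results/models"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

X <- read_X("flm")
y <- patients$ssi[match(rownames(X), patients$patient_id)]

v <- compute_penalty_factors(catalog, colnames(X))
cat("price-derived penalty factors v_j = r_max / r_j (by test):\n")
vt <- sort(tapply(as.numeric(v), feature_test_name <- sub("_.*$", "",
                                                          names(v)),
                  unique))
print(round(vt[names(vt) != "age" & names(vt) != "sex"], 3))

path <- fit_lasso_path(X, y)
cat(sprintf("\nlasso path: %d lambda values, lambda_max = %.4f, df 0 -> %d\n",
            length(path$lambda), path$lambda[1], max(path$df)))

set.seed(301)
for (cfg in list(list(name = "FLM  (no cap)", pen = NULL, p_max = NULL),
                 list(name = "FLM  (p_max=50)", pen = NULL, p_max = 50),
                 list(name = "PPM  (no cap)", pen = v, p_max = NULL),
                 list(name = "PPM  (p_max=20)", pen = v, p_max = 20))) {
  m <- select_lambda_cv(X, y, penalty = cfg$pen, folds = 10,
                        p_max = cfg$p_max)
  cat(sprintf("%-16s lambda = %.4f, %2d features, CV AUC = %.3f\n",
              cfg$name, m$lambda, length(m$nonzero),
              max(m$cv$score)))
  coefs <- data.frame(feature = m$nonzero,
                      beta = round(m$beta[m$nonzero], 5))
  fn <- file.path(out, paste0(gsub("[^A-Za-z0-9]+", "_",
                                   tolower(cfg$name)), "coef.csv"))
  utils::write.csv(coefs[order(-abs(coefs$beta)), ], fn, row.names = FALSE)
}
cat("\ncoefficient tables written under", out, "\n")
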