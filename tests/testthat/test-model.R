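sim_logit_data <- function(n, p, beta = NULL, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  if (is.null(beta)) beta <- c(1.5, -1.5, rep(0, p - 2))
  y <- rbinom(n, 1, plogis(as.numeric(X %*% beta)))
  list(X = X, y = y)
}

test_that("penalty factors are price ratios with unit demographics", {
  cat14 <- default_catalog()
  fn <- c("Leukocytes_nmbr_test_M", "Glucose_mean_S",
          "Bilirubin.total_mean_M", "age", "sex")
  v <- compute_penalty_factors(cat14, fn)
  expect_equal(unname(v["Leukocytes_nmbr_test_M"]), 1.0)
  expect_equal(unname(v["Glucose_mean_S"]), 58 / 23)
  expect_equal(unname(v["age"]), 1)
  expect_equal(unname(v["sex"]), 1)
  bt_price <- cat14$price[cat14$test_name == "Bilirubin.total"]
  expect_equal(unname(v["Bilirubin.total_mean_M"]), 58 / bt_price)
  # all prices equal -> all factors 1
  flat <- cat14; flat$price <- 30
  vf <- compute_penalty_factors(flat, fn)
  expect_true(all(vf == 1))
  expect_error(compute_penalty_factors(cat14, "Mystery_mean_S"),
               "unknown test")
})

test_that("the path starts at the null model with lambda_max from the score equation", {
  d <- sim_logit_data(200, 20, seed = 2)
  v <- structure(stats::setNames(runif(20, 0.5, 3), colnames(d$X)),
                 class = "penalty_spec")
  fit <- fit_lasso_path(d$X, d$y, penalty = v)
  expect_equal(fit$df[1], 0L)
  expect_true(all(fit$beta[, 1] == 0))
  expect_true(all(diff(fit$lambda) < 0))
  # lambda_max = max_j |z_j . (y - ybar)| / (n v_j) on standardized columns
  sdn <- apply(d$X, 2, function(c) sqrt(mean((c - mean(c))^2)))
  z <- scale(d$X, TRUE, sdn)
  lam_max <- max(abs(crossprod(z, d$y - mean(d$y))) / (200 * fit$penalty))
  expect_equal(fit$lambda[1], lam_max, tolerance = 1e-8)
  # user-supplied lambda at or above lambda_max also gives the null model
  f2 <- fit_lasso_path(d$X, d$y, penalty = v, lambda = c(2 * lam_max, lam_max))
  expect_true(all(f2$beta[, 1] == 0))
})

test_that("KKT conditions hold at every returned lambda", {
  d <- sim_logit_data(200, 20, seed = 3)
  v <- structure(stats::setNames(runif(20, 0.5, 3), colnames(d$X)),
                 class = "penalty_spec")
  fit <- fit_lasso_path(d$X, d$y, penalty = v, nlambda = 40)
  for (li in seq_along(fit$lambda)) {
    r <- kkt_residuals(fit, d$X, d$y, li)
    expect_lt(r$inactive, 1e-5)
    expect_lt(r$active, 1e-5)
  }
})

test_that("penalty-factor fits equal rescaled unit-penalty fits", {
  d <- sim_logit_data(200, 20, seed = 4)
  v <- structure(stats::setNames(runif(20, 0.5, 3), colnames(d$X)),
                 class = "penalty_spec")
  L <- exp(seq(log(0.2), log(0.002), length.out = 25))
  f1 <- fit_lasso_path(d$X, d$y, penalty = v, lambda = L,
                       standardize = FALSE)
  vn <- as.numeric(v) / mean(v)             # solver-normalized factors
  f2 <- fit_lasso_path(sweep(d$X, 2, vn, "/"), d$y, lambda = L,
                       standardize = FALSE)
  expect_equal(as.matrix(f1$beta), as.matrix(f2$beta) / vn,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(f1$a0, f2$a0, tolerance = 1e-6)
})

test_that("the path limit recovers the unpenalized logistic fit", {
  d <- sim_logit_data(300, 5, beta = c(1, -1, 0.5, 0, 0), seed = 5)
  fit <- fit_lasso_path(d$X, d$y, lambda = c(0.1, 1e-2, 1e-4, 1e-7))
  ref <- glm(d$y ~ d$X, family = binomial)
  got <- c(fit$a0[4], as.numeric(fit$beta[, 4]))
  expect_equal(got, unname(coef(ref)), tolerance = 1e-4)
})

test_that("price changes move a test's penalty (and coefficients) monotonically", {
  # under v_j = r_max / r_j a pricier test carries a smaller penalty
  # factor, so raising Alpha's price (below r_max) weakly grows its
  # coefficient at fixed effective lambda
  cat2 <- tiny_catalog()
  cat2$price[cat2$test_name == "Gamma"] <- 58   # pins r_max across settings
  set.seed(6)
  X <- matrix(rnorm(150 * 2), 150, 2,
              dimnames = list(NULL, c("Alpha_mean_S", "Beta_mean_S")))
  y <- rbinom(150, 1, plogis(X[, 1] + X[, 2]))
  lam_eff <- 0.05
  coef_alpha <- sapply(c(25, 35, 45, 58), function(price_a) {
    cc <- cat2; cc$price[cc$test_name == "Alpha"] <- price_a
    v <- compute_penalty_factors(cc, colnames(X))
    # compensate the solver's mean-1 normalization so the competing
    # feature's absolute penalty stays fixed across price settings
    lam <- lam_eff * mean(as.numeric(v))
    f <- fit_lasso_path(X, y, penalty = v, lambda = c(10 * lam, lam))
    abs(f$beta["Alpha_mean_S", 2])
  })
  expect_true(all(diff(coef_alpha) >= -1e-8))
  expect_gt(coef_alpha[4], coef_alpha[1])
})

test_that("lambda selection respects the p_max early-stopping cap", {
  d <- sim_logit_data(300, 15, beta = c(2, -2, 2, rep(0, 12)), seed = 7)
  # inactive cap: identical to unrestricted selection
  set.seed(1); m_unres <- select_lambda_cv(d$X, d$y, folds = 5)
  set.seed(1); m_wide <- select_lambda_cv(d$X, d$y, folds = 5, p_max = 15)
  expect_equal(m_wide$nonzero, m_unres$nonzero)
  expect_equal(m_wide$lambda, m_unres$lambda)
  # p_max = 0: intercept-only, prediction equals the prevalence
  m0 <- select_lambda_cv(d$X, d$y, folds = 5, p_max = 0)
  expect_length(m0$nonzero, 0)
  expect_equal(predict_proba(m0, d$X), rep(mean(d$y), 300))
  # hard cap and planted-support recovery across seeds
  hits <- 0L
  for (s in 1:6) {
    ds <- sim_logit_data(500, 15, beta = c(2, -2, 2, rep(0, 12)),
                         seed = 100 + s)
    m2 <- select_lambda_cv(ds$X, ds$y, folds = 5, p_max = 2)
    expect_lte(length(m2$nonzero), 2)
    if (all(m2$nonzero %in% c("f1", "f2", "f3"))) hits <- hits + 1L
  }
  expect_gte(hits, 5L)
})

test_that("CV scoring ties prefer the more regularized model", {
  d <- sim_logit_data(200, 10, seed = 8)
  m <- select_lambda_cv(d$X, d$y, folds = 5)
  cv <- m$cv
  best <- max(cv$score)
  expect_equal(m$lambda, max(cv$lambda[cv$score >= best - 1e-12]))
})

test_that("ROSE oversampling balances classes via a smoothed bootstrap", {
  d <- sim_logit_data(400, 6, seed = 9)
  rb <- rose_oversample(d$X, d$y, seed = 1)
  expect_equal(sum(rb$y == 1), sum(rb$y == 0))
  # bandwidth 0: plain duplication of original rows
  rb0 <- rose_oversample(d$X, d$y, seed = 2, bandwidth = 0)
  key <- apply(round(d$X, 10), 1, paste, collapse = ",")
  key0 <- apply(round(as.matrix(rb0$X), 10), 1, paste, collapse = ",")
  expect_true(all(key0 %in% key))
  # per-class feature means reproduce the source class means
  d2 <- sim_logit_data(2000, 4, beta = c(1, 0, 0, 0), seed = 10)
  rb2 <- rose_oversample(d2$X, d2$y, seed = 3)
  for (cl in 0:1) {
    src <- colMeans(d2$X[d2$y == cl, , drop = FALSE])
    out <- colMeans(as.matrix(rb2$X)[rb2$y == cl, , drop = FALSE])
    expect_equal(out, src, tolerance = 0.15, ignore_attr = TRUE)
  }
})

test_that("predicted probabilities follow the logistic linear predictor", {
  m <- structure(list(beta0 = 0,
                      beta = c(a = 0, b = 0),
                      lambda = 0.1, penalty = NULL,
                      nonzero = character(0), p_max = NULL,
                      feature_names = c("a", "b")),
                 class = "fitted_model")
  X <- cbind(a = c(-1, 0, 2), b = c(5, -5, 0))
  expect_equal(predict_proba(m, X), rep(0.5, 3))
  m$beta <- c(a = 2, b = -1); m$beta0 <- 0.5
  expect_equal(predict_proba(m, X),
               plogis(0.5 + 2 * X[, "a"] - X[, "b"]))
  # monotone in a positively weighted feature
  X2 <- cbind(a = seq(-2, 2, length.out = 9), b = 0)
  expect_true(all(diff(predict_proba(m, X2)) > 0))
  # column mismatch is an error; reordering is tolerated
  expect_error(predict_proba(m, cbind(a = 1)), "missing")
  expect_equal(predict_proba(m, X[, c("b", "a")]), predict_proba(m, X))
})

test_that("degenerate model inputs are rejected", {
  d <- sim_logit_data(50, 3, seed = 11)
  expect_error(fit_lasso_path(d$X, rep(1, 50)), "both classes")
  expect_error(fit_lasso_path(d$X, d$y * 2), "binary")
  Xb <- d$X; Xb[1, 1] <- NA
  expect_error(fit_lasso_path(Xb, d$y), "non-finite")
  expect_error(fit_lasso_path(d$X, d$y,
                              penalty = unit_penalty(c("a", "b"))),
               "length")
})
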