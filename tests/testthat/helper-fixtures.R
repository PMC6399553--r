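# Shared fixtures and independent oracles. Oracles are deliberately naive
# (brute-force pair counts, profiled SSE minimization, day loops) so they
# stay independent of the implementation paths they check.

tiny_catalog <- function() {
  data.frame(
    test_name = c("Alpha", "Beta", "Gamma"),
    price = c(58, 23, 40),
    ref_low = c(4, 10, 0.5),
    ref_high = c(10, 20, 2.5),
    rate30 = c(4, 2, 1.5),
    stringsAsFactors = FALSE
  )
}

# build a daily_grid directly from per-test patient x day matrices
# (columns ordered oldest day -> day 0, NA = unobserved)
manual_grid <- function(mats, obs_days) {
  tests <- names(mats)
  np <- nrow(mats[[1]])
  pid <- sprintf("P%03d", seq_len(np))
  days <- obs_days:0
  dn <- list(pid, tests, paste0("d", days))
  vals <- array(NA_real_, dim = c(np, length(tests), length(days)),
                dimnames = dn)
  for (j in seq_along(tests)) vals[, j, ] <- mats[[j]]
  structure(list(values = vals, mask = !is.na(vals),
                 obs_days = as.integer(obs_days),
                 patients = pid, tests = tests),
            class = "daily_grid")
}

small_cohort <- function(n = 120, seed = 99, effects = effect_spec(),
                         prevalence = 0.25, obs_days = 60) {
  generate_cohort(cohort_spec(n, prevalence = prevalence,
                              obs_days = obs_days, seed = seed,
                              effects = effects))
}

# brute-force AUC: count concordant positive-negative pairs, ties 1/2
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(pos) * length(neg))
}

# brute-force OLS slope: minimize profiled SSE over the slope by 1-d
# numerical optimization (intercept profiled out analytically)
brute_slope <- function(t, y) {
  sse <- function(b) sum((y - (mean(y) - b * mean(t)) - b * t)^2)
  stats::optimize(sse, c(-1e3, 1e3), tol = 1e-10)$minimum
}

# standardized-scale KKT residuals of a lasso_path at one lambda index
kkt_residuals <- function(path, X, y, li) {
  x <- as.matrix(X)
  sdn <- apply(x, 2, function(c) sqrt(mean((c - mean(c))^2)))
  ok <- sdn > 0
  z <- scale(x[, ok, drop = FALSE], TRUE, sdn[ok])
  beta <- as.numeric(path$beta[, li])
  pr <- stats::plogis(path$a0[li] + x %*% beta)
  g <- as.numeric(crossprod(z, pr - y)) / length(y)
  act <- beta[ok] != 0
  lamv <- path$lambda[li] * path$penalty[ok]
  list(
    inactive = if (any(!act)) max(pmax(abs(g[!act]) - lamv[!act], 0)) else 0,
    active = if (any(act)) max(abs(abs(g[act]) - lamv[act])) else 0
  )
}
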