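test_that("window specs partition the observation interval", {
  for (od in c(60, 30)) {
    ws <- windows_for(window_spec(od), "CRP")
    days <- sort(unname(unlist(lapply(ws, function(w) w[2]:w[1]))))
    expect_equal(days, 0:od)                     # disjoint cover
    expect_equal(ws$S, c(2, 0))
    expect_equal(ws$M, c(15, 3))
    expect_equal(ws$L, c(od, 16))
  }
  ws15 <- windows_for(window_spec(15), "CRP")
  expect_equal(ws15, list(W = c(15, 0)))
  expect_error(window_spec(60, s_hi = 5))        # s_hi outside 0..2
  expect_error(window_spec(60, m_hi = 25))       # m_hi outside 13..18
  # per-test overrides
  wst <- window_spec(60, s_hi = c(1, 2), m_hi = c(13, 18),
                     tests = c("CRP", "Albumin"))
  expect_equal(windows_for(wst, "CRP")$S, c(1, 0))
  expect_equal(windows_for(wst, "Albumin")$M, c(18, 3))
})

test_that("window means match direct enumeration", {
  m <- matrix(7.5, nrow = 2, ncol = 61)
  g <- manual_grid(list(Alpha = m), obs_days = 60)
  expect_equal(window_mean(g, "Alpha", c(15, 3)), c(7.5, 7.5))

  m2 <- matrix(0, 1, 61); m2[1, 59:61] <- c(1, 2, 3)   # days 2,1,0
  g2 <- manual_grid(list(Alpha = m2), obs_days = 60)
  expect_equal(window_mean(g2, "Alpha", c(2, 0)), 2.0)

  set.seed(42)
  m3 <- matrix(rnorm(3 * 61), 3, 61)
  g3 <- manual_grid(list(Alpha = m3), obs_days = 60)
  for (w in list(c(2, 0), c(15, 3), c(60, 16), c(60, 0))) {
    days <- 60:0
    cols <- which(days <= w[1] & days >= w[2])
    expect_equal(window_mean(g3, "Alpha", w), rowMeans(m3[, cols]))
  }
})

test_that("window slopes equal brute-force least squares, rising toward surgery positive", {
  flat <- manual_grid(list(Alpha = matrix(3, 1, 61)), obs_days = 60)
  expect_equal(window_slope(flat, "Alpha", c(15, 3)), 0)

  # two points one day apart, value up by 2 approaching surgery
  m <- matrix(NA_real_, 1, 3); m[1, ] <- c(0, 1, 3)
  g <- manual_grid(list(Alpha = m), obs_days = 2)
  expect_equal(window_slope(g, "Alpha", c(1, 0)), 2.0)
  # (t, y) = (0,0), (1,1), (2,3) -> 1.5
  expect_equal(window_slope(g, "Alpha", c(2, 0)), 1.5)
  expect_equal(window_slope(g, "Alpha", c(2, 0)),
               brute_slope(c(0, 1, 2), c(0, 1, 3)))
  # single-day window has slope 0 by convention
  expect_equal(window_slope(g, "Alpha", c(0, 0)), 0)

  set.seed(7)
  m4 <- matrix(rnorm(4 * 61), 4, 61)
  g4 <- manual_grid(list(Alpha = m4), obs_days = 60)
  for (w in list(c(2, 0), c(15, 3), c(60, 16))) {
    days <- 60:0
    cols <- which(days <= w[1] & days >= w[2])
    t <- -days[cols]
    expected <- apply(m4[, cols], 1, function(yy) brute_slope(t, yy))
    expect_equal(window_slope(g4, "Alpha", w), expected, tolerance = 1e-6)
  }
})

test_that("count features use the pre-imputation mask and conserve proportions", {
  m <- matrix(NA_real_, 1, 61)
  days <- 60:0
  m[1, days %in% c(0, 1, 2)] <- 5          # 3 observed in S
  m[1, days %in% c(5, 20, 40)] <- 5        # 3 observed elsewhere
  g <- manual_grid(list(Alpha = m), obs_days = 60)
  cs <- window_counts(g, "Alpha", c(2, 0))
  expect_equal(cs$nmbr_test, 3)
  expect_equal(cs$prop_nmbr_test, 0.5)

  empty <- manual_grid(list(Alpha = matrix(NA_real_, 1, 61)), obs_days = 60)
  ce <- window_counts(empty, "Alpha", c(2, 0))
  expect_equal(ce$nmbr_test, 0)
  expect_equal(ce$prop_nmbr_test, 0)

  # conservation over random masks: counts sum to the total, proportions
  # sum to 1 (or 0 for a patient with no measurements)
  set.seed(11)
  for (rep in 1:5) {
    mm <- matrix(ifelse(runif(6 * 61) < 0.1, 1, NA_real_), 6, 61)
    gg <- manual_grid(list(Alpha = mm), obs_days = 60)
    ws <- windows_for(window_spec(60), "Alpha")
    nm <- sapply(ws, function(w) window_counts(gg, "Alpha", w)$nmbr_test)
    pr <- sapply(ws, function(w) window_counts(gg, "Alpha", w)$prop_nmbr_test)
    expect_equal(rowSums(nm), rowSums(!is.na(mm)))
    expect_true(all(rowSums(pr) %in% c(0, 1)))
    expect_true(all(pr >= 0 & pr <= 1))
  }
})

test_that("abnormal-value features flag observed values against the reference range", {
  # Alpha reference range [4, 10]; window values {3, 5, 12, 12}
  m <- matrix(NA_real_, 1, 61)
  m[1, 58:61] <- c(3, 5, 12, 12)            # days 3..0
  g <- manual_grid(list(Alpha = m), obs_days = 60)
  ab <- abnormal_features(g, tiny_catalog(), "Alpha", c(3, 0))
  expect_equal(ab$nmbr_abn, 3)
  expect_equal(ab$high_abn_prop, 0.5)
  expect_equal(ab$low_abn_prop, 0.25)
  expect_equal(ab$abn_prop, 0.75)
  # empty window -> all zeros
  ab0 <- abnormal_features(g, tiny_catalog(), "Alpha", c(30, 20))
  expect_true(all(ab0 == 0))
  # high + low = total proportion on random inputs
  set.seed(3)
  mm <- matrix(ifelse(runif(5 * 61) < 0.2, rnorm(5 * 61, 7, 5), NA_real_),
               5, 61)
  gg <- manual_grid(list(Alpha = mm), obs_days = 60)
  abr <- abnormal_features(gg, tiny_catalog(), "Alpha", c(60, 0))
  expect_equal(abr$high_abn_prop + abr$low_abn_prop, abr$abn_prop)
  expect_true(all(abr$abn_prop >= 0 & abr$abn_prop <= 1))
})

test_that("feature matrices have the canonical shapes and names", {
  co <- small_cohort(n = 25, seed = 13)
  cat14 <- default_catalog()
  g <- impute_locf(aggregate_daily(co$labs, 60, co$patients$patient_id,
                                   cat14$test_name), cat14)
  flm <- build_feature_matrix(g, window_spec(60), cat14, co$patients, "FLM")
  expect_equal(ncol(flm), 14 * 3 * 6 + 2)            # 252 + age + sex
  expect_equal(attr(flm, "feature_set"), "FLM")
  expect_true(all(c("Leukocytes_nmbr_test_M", "CRP_mean_M",
                    "Hemoglobin_prop_nmbr_test_S", "ALP_high_abn_prop_M",
                    "Albumin_slope_L", "age", "sex") %in% names(flm)))
  expect_false(anyNA(flm))

  blm <- build_feature_matrix(g, window_spec(60), cat14, co$patients, "BLM")
  expect_equal(ncol(blm), 14 * 3 * 3 + 2)            # 126 + age + sex = 128
  crp <- build_feature_matrix(g, window_spec(60), cat14, co$patients, "CRP")
  expect_equal(sort(names(crp)),
               sort(c("CRP_mean_S", "CRP_mean_M", "CRP_mean_L",
                      "age", "sex")))
  expect_error(build_feature_matrix(g, window_spec(60), cat14,
                                    co$patients, "XGB"))

  # 15-day single-window interval: 14 x 1 x 6 = 84 test-derived columns
  co15 <- small_cohort(n = 25, seed = 13, obs_days = 15)
  g15 <- impute_locf(aggregate_daily(co15$labs, 15,
                                     co15$patients$patient_id,
                                     cat14$test_name), cat14)
  flm15 <- build_feature_matrix(g15, window_spec(15), cat14,
                                co15$patients, "FLM")
  expect_equal(ncol(flm15), 14 * 1 * 6 + 2)

  # column-count formula holds for any catalog size
  g3 <- impute_locf(aggregate_daily(co$labs[co$labs$test_name %in%
                                              c("CRP", "Albumin"), ],
                                    60, co$patients$patient_id,
                                    c("CRP", "Albumin")), cat14)
  f3 <- build_feature_matrix(g3, window_spec(60), cat14, co$patients, "FLM")
  expect_equal(ncol(f3), 2 * 3 * 6 + 2)
})

test_that("features are invariant to measurement ordering in the input", {
  co <- small_cohort(n = 20, seed = 17)
  cat14 <- default_catalog()
  shuffled <- co$labs[sample(nrow(co$labs)), ]
  build <- function(lb) {
    g <- impute_locf(aggregate_daily(lb, 60, co$patients$patient_id,
                                     cat14$test_name), cat14)
    build_feature_matrix(g, window_spec(60), cat14, co$patients, "FLM")
  }
  expect_equal(build(co$labs), build(shuffled), ignore_attr = TRUE)
})
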