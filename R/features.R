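#' Temporal window specification
#'
#' Partitions the observation interval \code{[obs_days, 0]} into per-test
#' short (S), medium (M), and long (L) contiguous windows:
#' S = \code{[s_hi, 0]}, M = \code{[m_hi, s_hi + 1]},
#' L = \code{[obs_days, m_hi + 1]} (inclusive day ranges, days before
#' surgery). S captures the days immediately before surgery in which
#' testing is densest, M the mid-term, and L the remaining history. A
#' 15-day interval uses a single window \code{W = [15, 0]}.
#'
#' @param obs_days observation-interval length (e.g. 60, 30, 15).
#' @param s_hi oldest day of the S window (default 2; must be in 0..2).
#' @param m_hi oldest day of the M window (default 15; must be in 13..18).
#' @param tests optional character vector of test names with per-test
#'   boundaries: \code{s_hi}/\code{m_hi} may be vectors aligned to it.
#' @return A \code{window_spec}: named list (per test, or the single
#'   element \code{".default"}) of lists of \code{c(hi, lo)} day ranges.
#' @export
window_spec <- function(obs_days = 60, s_hi = 2, m_hi = 15, tests = NULL) {
  if (obs_days <= 15) {
    w <- list(W = c(obs_days, 0))
    return(structure(list(".default" = w), obs_days = obs_days,
                     class = "window_spec"))
  }
  mk <- function(s, m) {
    stopifnot(s >= 0, s <= 2, m >= 13, m <= 18, m > s + 1, obs_days > m + 1)
    list(S = c(s, 0), M = c(m, s + 1), L = c(obs_days, m + 1))
  }
  if (is.null(tests)) {
    ws <- list(".default" = mk(s_hi, m_hi))
  } else {
    s_hi <- rep_len(s_hi, length(tests))
    m_hi <- rep_len(m_hi, length(tests))
    ws <- stats::setNames(
      lapply(seq_along(tests), function(i) mk(s_hi[i], m_hi[i])), tests)
  }
  structure(ws, obs_days = obs_days, class = "window_spec")
}

windows_for <- function(windows, test) {
  if (!is.null(windows[[test]])) windows[[test]] else windows[[".default"]]
}

# indices into the day dimension (ordered obs_days..0) for window c(hi, lo)
window_day_idx <- function(obs_days, window) {
  days <- obs_days:0
  which(days <= window[1] & days >= window[2])
}

#' Per-window summary features
#'
#' The six per-test, per-window feature families extracted from the daily
#' grid:
#' \itemize{
#'   \item \code{window_mean}: arithmetic mean of the (imputed) daily values.
#'   \item \code{window_slope}: OLS slope of daily value against time, with
#'     the time axis running forward toward surgery (t = -day), so a value
#'     rising toward surgery has a positive slope. A single-day window has
#'     slope 0.
#'   \item \code{window_counts}: number of observed days in the window
#'     (pre-imputation mask) and its proportion of all observed days in the
#'     whole observation interval (0 when the patient has none).
#'   \item \code{abnormal_features}: counts/proportions of observed daily
#'     values outside the reference range; proportions use the window's
#'     observed count as denominator (0 for an empty window).
#' }
#'
#' @param grid an imputed \code{daily_grid} (mask still pre-imputation).
#' @param test test name.
#' @param window integer \code{c(hi, lo)} day range, days before surgery.
#' @return numeric vector per patient (\code{window_counts} and
#'   \code{abnormal_features} return data.frames of per-patient columns).
#' @export
window_mean <- function(grid, test, window) {
  j <- match(test, grid$tests)
  idx <- window_day_idx(grid$obs_days, window)
  x <- matrix(grid$values[, j, idx], nrow = length(grid$patients))
  rowMeans(x)
}

#' @rdname window_mean
#' @export
window_slope <- function(grid, test, window) {
  j <- match(test, grid$tests)
  idx <- window_day_idx(grid$obs_days, window)
  if (length(idx) < 2) return(rep(0, length(grid$patients)))
  t <- -(grid$obs_days:0)[idx]
  tc <- t - mean(t)
  x <- matrix(grid$values[, j, idx], nrow = length(grid$patients))
  as.numeric(x %*% tc) / sum(tc^2)
}

#' @rdname window_mean
#' @export
window_counts <- function(grid, test, window) {
  j <- match(test, grid$tests)
  idx <- window_day_idx(grid$obs_days, window)
  m <- matrix(grid$mask[, j, ], nrow = length(grid$patients))
  nmbr <- rowSums(m[, idx, drop = FALSE])
  total <- rowSums(m)
  data.frame(nmbr_test = nmbr,
             prop_nmbr_test = ifelse(total > 0, nmbr / total, 0))
}

#' @rdname window_mean
#' @param catalog test catalog supplying the reference range.
#' @export
abnormal_features <- function(grid, catalog, test, window) {
  j <- match(test, grid$tests)
  r <- catalog[catalog$test_name == test, ]
  if (nrow(r) != 1) stop("test not in catalog: ", test)
  idx <- window_day_idx(grid$obs_days, window)
  np <- length(grid$patients)
  v <- matrix(grid$values[, j, idx], nrow = np)
  m <- matrix(grid$mask[, j, idx], nrow = np)
  hi <- rowSums(m & v > r$ref_high)
  lo <- rowSums(m & v < r$ref_low)
  n_obs <- rowSums(m)
  prop <- function(x) ifelse(n_obs > 0, x / n_obs, 0)
  data.frame(nmbr_abn = hi + lo,
             high_abn_prop = prop(hi),
             low_abn_prop = prop(lo),
             abn_prop = prop(hi + lo))
}

flm_kinds <- c("mean", "slope", "nmbr_test", "prop_nmbr_test",
               "high_abn_prop", "low_abn_prop")
blm_kinds <- c("mean", "slope", "abn_prop")

#' Assemble a feature matrix
#'
#' Builds the patient-by-feature design matrix for one of the three model
#' feature sets, with columns named \code{{Test}_{kind}_{window}} plus
#' \code{age} and \code{sex}:
#' \itemize{
#'   \item \code{"FLM"} (full lasso model): per test and window the six
#'     kinds mean, slope, nmbr_test, prop_nmbr_test, high_abn_prop,
#'     low_abn_prop — 14 tests x 3 windows x 6 = 252 test-derived columns
#'     on a 60/30-day interval, 84 on the single-window 15-day interval.
#'   \item \code{"BLM"} (basic lasso model): value-derived kinds only —
#'     mean, slope, abn_prop — 126 test-derived columns (+ age + sex = 128).
#'   \item \code{"CRP"}: the baseline — CRP window means only (+ age, sex).
#' }
#'
#' @param grid an imputed \code{daily_grid}.
#' @param windows a \code{\link{window_spec}}.
#' @param catalog test catalog.
#' @param patients patients data.frame (patient_id, age, sex, ...).
#' @param feature_set one of \code{"CRP"}, \code{"BLM"}, \code{"FLM"}.
#' @return data.frame, one row per patient (ordered as \code{grid$patients}),
#'   with attribute \code{feature_set}.
#' @export
build_feature_matrix <- function(grid, windows, catalog, patients,
                                 feature_set = c("FLM", "BLM", "CRP")) {
  feature_set <- match.arg(feature_set)
  stopifnot(inherits(grid, "daily_grid"), inherits(windows, "window_spec"))
  if (!is_complete(grid)) stop("grid must be fully imputed")
  pid <- grid$patients
  po <- match(pid, patients$patient_id)
  if (anyNA(po)) stop("grid patients missing from patients table")

  tests <- if (feature_set == "CRP") "CRP" else
    intersect(grid$tests, catalog$test_name)
  kinds <- switch(feature_set, FLM = flm_kinds, BLM = blm_kinds, CRP = "mean")

  cols <- list()
  for (tn in tests) {
    ws <- windows_for(windows, tn)
    for (wn in names(ws)) {
      w <- ws[[wn]]
      cnt <- if (any(c("nmbr_test", "prop_nmbr_test") %in% kinds))
        window_counts(grid, tn, w) else NULL
      abn <- if (any(c("high_abn_prop", "low_abn_prop", "abn_prop",
                       "nmbr_abn") %in% kinds))
        abnormal_features(grid, catalog, tn, w) else NULL
      for (kd in kinds) {
        v <- switch(kd,
                    mean = window_mean(grid, tn, w),
                    slope = window_slope(grid, tn, w),
                    nmbr_test = cnt$nmbr_test,
                    prop_nmbr_test = cnt$prop_nmbr_test,
                    high_abn_prop = abn$high_abn_prop,
                    low_abn_prop = abn$low_abn_prop,
                    abn_prop = abn$abn_prop,
                    nmbr_abn = abn$nmbr_abn)
        cols[[paste(tn, kd, wn, sep = "_")]] <- v
      }
    }
  }
  cols$age <- patients$age[po]
  cols$sex <- patients$sex[po]
  X <- data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(X) <- pid
  if (anyDuplicated(names(X))) stop("duplicate feature names")
  attr(X, "feature_set") <- feature_set
  X
}

# parse "{Test}_{kind}_{window}" -> test name; demographics -> NA
feature_test_name <- function(feature_names) {
  ifelse(feature_names %in% c("age", "sex"), NA_character_,
         sub("_.*$", "", feature_names))
}
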