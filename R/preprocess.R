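#' Aggregate raw measurements to a patient x test x day grid
#'
#' Builds the daily grid underlying all downstream feature extraction: one
#' cell per patient, test, and preoperative day in \code{[obs_days, 0]}
#' (day 0 = day of surgery). When more than one value is recorded for the
#' same patient/test/day, the cell holds their arithmetic mean. The
#' observed mask records pre-imputation occupancy and is never altered by
#' imputation, so counting features can be computed after imputation.
#'
#' Measurements with \code{day > obs_days} are excluded.
#'
#' @param labs long-format measurements (patient_id, test_name, day, value).
#' @param obs_days observation-interval length in days.
#' @param patient_ids,test_names optional explicit axes (defaults: values
#'   present in \code{labs}, sorted).
#' @return A \code{daily_grid}: list with 3-d arrays \code{values} and
#'   \code{mask} (patient x test x day, day ordered \code{obs_days..0}),
#'   plus \code{obs_days}, \code{patients}, \code{tests}.
#' @export
aggregate_daily <- function(labs, obs_days,
                            patient_ids = NULL, test_names = NULL) {
  if (is.null(patient_ids)) patient_ids <- sort(unique(labs$patient_id))
  if (is.null(test_names)) test_names <- sort(unique(labs$test_name))
  days <- obs_days:0
  dn <- list(patient_ids, test_names, paste0("d", days))
  vals <- array(NA_real_,
                dim = c(length(patient_ids), length(test_names), length(days)),
                dimnames = dn)
  mask <- array(FALSE, dim = dim(vals), dimnames = dn)
  keep <- labs$day <= obs_days & labs$day >= 0 &
    labs$patient_id %in% patient_ids & labs$test_name %in% test_names
  labs <- labs[keep, , drop = FALSE]
  if (nrow(labs) > 0) {
    key <- paste(labs$patient_id, labs$test_name, labs$day, sep = "\r")
    m <- tapply(labs$value, key, mean)
    parts <- strsplit(names(m), "\r", fixed = TRUE)
    pi <- match(vapply(parts, `[[`, "", 1L), patient_ids)
    ti <- match(vapply(parts, `[[`, "", 2L), test_names)
    di <- match(as.integer(vapply(parts, `[[`, "", 3L)), days)
    ind <- cbind(pi, ti, di)
    vals[ind] <- as.numeric(m)
    mask[ind] <- TRUE
  }
  structure(list(values = vals, mask = mask, obs_days = as.integer(obs_days),
                 patients = patient_ids, tests = test_names),
            class = "daily_grid")
}

is_complete <- function(grid) !anyNA(grid$values)

# Per-test cohort mean of observed values; fallback to the reference-range
# midpoint (with a warning) for a test with zero observations cohort-wide.
test_cohort_means <- function(grid, catalog = NULL) {
  vapply(seq_along(grid$tests), function(j) {
    v <- grid$values[, j, ][grid$mask[, j, ]]
    if (length(v)) return(mean(v))
    warning("test '", grid$tests[j],
            "' has no observations cohort-wide; filled with reference midpoint")
    if (!is.null(catalog)) {
      r <- catalog[catalog$test_name == grid$tests[j], ]
      if (nrow(r) == 1) return((r$ref_low + r$ref_high) / 2)
    }
    0
  }, numeric(1))
}

#' Last-observation-carried-forward imputation
#'
#' Within each patient-test daily series ordered from day \code{obs_days}
#' toward day 0, each missing cell takes the most recent earlier value.
#' Leading cells with no earlier observation are filled with the per-test
#' cohort mean of observed values (a neutral finite fill). The observed
#' mask is unchanged.
#'
#' @param grid a \code{daily_grid}.
#' @param catalog optional catalog; supplies the reference-midpoint
#'   fallback for a test with no observations at all.
#' @return the grid with \code{values} fully imputed.
#' @export
impute_locf <- function(grid, catalog = NULL) {
  stopifnot(inherits(grid, "daily_grid"))
  tmeans <- test_cohort_means(grid, catalog)
  vals <- grid$values
  nd <- dim(vals)[3]
  for (j in seq_along(grid$tests)) {
    x <- vals[, j, , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = dim(vals)[1])
    if (nd > 1) for (d in 2:nd) {
      na <- is.na(x[, d])
      x[na, d] <- x[na, d - 1L]
    }
    x[is.na(x)] <- tmeans[j]
    vals[, j, ] <- x
  }
  grid$values <- vals
  grid
}

#' k-nearest-neighbour imputation
#'
#' Each missing cell is filled with the mean of that cell's value among the
#' k nearest patients. Nearness is computed within the same test: the mean
#' absolute difference over the pair's jointly observed days, after
#' standardizing the test's observed values. Patients without the cell
#' observed (or with no jointly observed days) are not candidates; fewer
#' than k candidates means all are used, and zero candidates fall back to
#' the per-test cohort mean. The observed mask is unchanged.
#'
#' @param grid a \code{daily_grid}.
#' @param k number of neighbours (default 5).
#' @param catalog optional catalog for the zero-observation fallback.
#' @return the grid with \code{values} fully imputed.
#' @export
impute_knn <- function(grid, k = 5, catalog = NULL) {
  stopifnot(inherits(grid, "daily_grid"), k >= 1)
  tmeans <- test_cohort_means(grid, catalog)
  vals <- grid$values
  np <- dim(vals)[1]
  for (j in seq_along(grid$tests)) {
    x <- matrix(vals[, j, ], nrow = np)
    if (!anyNA(x)) next
    obs <- !is.na(x)
    mu <- tmeans[j]
    sdv <- stats::sd(x[obs])
    if (!length(x[obs])) { vals[, j, ][is.na(vals[, j, ])] <- mu; next }
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    xs <- (x - mu) / sdv
    dist <- pairwise_mean_abs_diff(xs)
    diag(dist) <- NA_real_
    for (d in seq_len(ncol(x))) {
      if (anyNA(x[, d]))
        x[, d] <- knn_col_fill(dist, x[, d], mu, as.integer(k))
    }
    vals[, j, ] <- x
  }
  grid$values <- vals
  grid
}

#' Hybrid LOCF + KNN imputation
#'
#' The column at the farthest time point (day \code{obs_days}) is imputed
#' by carrying each patient-test's earliest available observation back
#' (cohort-mean fallback when the series is empty); all other missing
#' cells are imputed by KNN. This combines patient history at the interval
#' edge with neighbour information elsewhere. The observed mask is
#' unchanged.
#'
#' @inheritParams impute_knn
#' @return the grid with \code{values} fully imputed.
#' @export
impute_hybrid <- function(grid, k = 5, catalog = NULL) {
  stopifnot(inherits(grid, "daily_grid"))
  tmeans <- test_cohort_means(grid, catalog)
  np <- dim(grid$values)[1]
  nd <- dim(grid$values)[3]
  for (j in seq_along(grid$tests)) {
    x <- matrix(grid$values[, j, ], nrow = np)
    miss_far <- is.na(x[, 1L])
    if (any(miss_far)) {
      # earliest (oldest-day) available observation per patient series
      first_obs <- apply(x, 1L, function(r) {
        o <- which(!is.na(r))
        if (length(o)) r[o[1L]] else NA_real_
      })
      fill <- ifelse(is.na(first_obs), tmeans[j], first_obs)
      x[miss_far, 1L] <- fill[miss_far]
      grid$values[, j, ] <- x
    }
  }
  impute_knn(grid, k = k, catalog = catalog)
}

#' Write / read a daily grid as wide CSV
#'
#' One row per patient-test pair, columns \code{d<obs_days>..d0}; the
#' observed mask is written alongside as 0/1 with the same layout.
#'
#' @param grid a \code{daily_grid}.
#' @param values_path,mask_path output CSV paths.
#' @export
write_grid_csv <- function(grid, values_path, mask_path) {
  flat <- function(a) {
    do.call(rbind, lapply(seq_along(grid$tests), function(j) {
      df <- as.data.frame(matrix(a[, j, ], nrow = length(grid$patients)))
      names(df) <- dimnames(grid$values)[[3]]
      cbind(data.frame(patient_id = grid$patients,
                       test_name = grid$tests[j],
                       stringsAsFactors = FALSE), df)
    }))
  }
  utils::write.csv(flat(grid$values), values_path, row.names = FALSE)
  utils::write.csv(flat(grid$mask * 1), mask_path, row.names = FALSE)
  invisible(values_path)
}
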