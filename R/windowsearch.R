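#' Daily group-mean curves with confidence bands
#'
#' For one blood test, computes the per-day mean of patient daily values
#' (patients first reduced to daily means) separately for the SSI and
#' non-SSI groups, with normal-approximation 95% confidence half-widths.
#' Days with no observation in a group are NA in the raw columns and
#' linearly interpolated in the \code{*_i} columns used by the distance
#' function.
#'
#' @param labs raw measurements.
#' @param labels data.frame with \code{patient_id} and \code{ssi}, or a
#'   named 0/1 vector keyed by patient id.
#' @param test test name.
#' @param obs_days observation interval length.
#' @return data.frame with one row per day \code{obs_days..0}: columns
#'   \code{day}, \code{mean_case}, \code{hw_case}, \code{mean_ctrl},
#'   \code{hw_ctrl} and interpolated \code{mean_case_i} etc.
#' @export
group_curves <- function(labs, labels, test, obs_days = 60) {
  if (is.data.frame(labels))
    labels <- stats::setNames(labels$ssi, labels$patient_id)
  lb <- labs[labs$test_name == test & labs$day <= obs_days, ]
  if (nrow(lb) == 0) stop("no measurements for test ", test)
  lb$ssi <- labels[lb$patient_id]
  if (anyNA(lb$ssi)) stop("measurements for patients without labels")
  if (length(unique(lb$ssi)) < 2)
    stop("both outcome groups must have measurements")
  days <- obs_days:0
  one_group <- function(g) {
    gl <- lb[lb$ssi == g, ]
    key <- paste(gl$patient_id, gl$day, sep = "\r")
    daily <- tapply(gl$value, key, mean)
    dday <- as.integer(sub("^.*\r", "", names(daily)))
    mu <- hw <- rep(NA_real_, length(days))
    for (i in seq_along(days)) {
      v <- daily[dday == days[i]]
      if (length(v)) {
        mu[i] <- mean(v)
        hw[i] <- if (length(v) > 1)
          1.96 * stats::sd(v) / sqrt(length(v)) else 0
      }
    }
    list(mu = mu, hw = hw)
  }
  ca <- one_group(1); co <- one_group(0)
  interp <- function(x) {
    if (all(is.na(x))) return(rep(0, length(x)))
    if (sum(!is.na(x)) == 1) return(rep(x[!is.na(x)], length(x)))
    stats::approx(seq_along(x)[!is.na(x)], x[!is.na(x)],
                  xout = seq_along(x), rule = 2)$y
  }
  data.frame(day = days,
             mean_case = ca$mu, hw_case = ca$hw,
             mean_ctrl = co$mu, hw_ctrl = co$hw,
             mean_case_i = interp(ca$mu), hw_case_i = interp(ca$hw),
             mean_ctrl_i = interp(co$mu), hw_ctrl_i = interp(co$hw))
}

#' Group-contrast distance of a temporal window
#'
#' Default distance between the SSI and non-SSI daily mean curves over a
#' window: the mean over window days of
#' \eqn{|m_{case} - m_{ctrl}| / (\sqrt{hw_{case}^2 + hw_{ctrl}^2} +
#' \epsilon)} — the absolute group gap in units of the combined 95% CI
#' half-width. Interpolated curve values are used on days without
#' observations. Alternative day-wise distances can be plugged in.
#'
#' @param curves output of \code{\link{group_curves}}.
#' @param window integer \code{c(hi, lo)} day range.
#' @param eps denominator guard against degenerate (zero-width) CIs.
#' @param day_distance optional function(curves_row_subset) returning a
#'   per-day distance vector, overriding the default.
#' @return non-negative scalar distance.
#' @export
window_distance <- function(curves, window, eps = 1e-9,
                            day_distance = NULL) {
  keep <- curves$day <= window[1] & curves$day >= window[2]
  if (!any(keep)) stop("window outside the observation interval")
  cv <- curves[keep, ]
  d <- if (is.null(day_distance)) {
    abs(cv$mean_case_i - cv$mean_ctrl_i) /
      (sqrt(cv$hw_case_i^2 + cv$hw_ctrl_i^2) + eps)
  } else day_distance(cv)
  mean(d)
}

#' Enumerate candidate window partitionings
#'
#' Enumerates all unordered selections of k cut days from an n-day
#' observation window — \code{choose(n, k)} candidates, the counting
#' convention under which a 60-day window with k = 3 yields 34,220
#' partitions. Each selection of sorted cut days \eqn{c_1 < \dots < c_k}
#' maps to contiguous windows that are half-open on the older side: the
#' newest window spans days \eqn{[c_1 - 1, 0]}, interior windows
#' \eqn{[c_i - 1, c_{i-1}]}, and the oldest window always extends to the
#' interval edge (absorbing the final cut), so distinct selections may map
#' to the same day partition.
#'
#' @param n_days window length in days.
#' @param k number of cut days, \code{1 <= k <= n_days}.
#' @return list with \code{count} (= \code{choose(n_days, k)}) and
#'   \code{cuts} (k x count integer matrix, columns in lexicographic
#'   order).
#' @export
enumerate_partitionings <- function(n_days, k) {
  if (k < 1 || k > n_days) stop("need 1 <= k <= n_days")
  cuts <- utils::combn(n_days, k)
  list(count = ncol(cuts), cuts = cuts)
}

#' Map cut days to contiguous day windows
#'
#' @param cuts sorted increasing cut days (in 1..n_days).
#' @param obs_days oldest day of the interval (the oldest window extends
#'   to it).
#' @return list of \code{c(hi, lo)} day ranges, newest window first.
#' @export
cuts_to_windows <- function(cuts, obs_days) {
  k <- length(cuts)
  if (k == 1) return(list(c(obs_days, 0)))
  w <- vector("list", k)
  w[[1]] <- c(cuts[1] - 1, 0)
  if (k > 2) for (i in 2:(k - 1)) w[[i]] <- c(cuts[i] - 1, cuts[i - 1])
  w[[k]] <- c(obs_days, cuts[k - 1])
  w
}

#' Exhaustive best window partitioning
#'
#' The two-step search: for each window count k up to \code{k_max}, score
#' every enumerated k-partitioning by the product (or sum) of its windows'
#' group-contrast distances and keep the argmax; then take the best k.
#' Ties go to the smaller k and then to the lexicographically earliest cut
#' selection, so flat (null) data returns deterministically.
#'
#' @param labs raw measurements.
#' @param labels patient labels (see \code{\link{group_curves}}).
#' @param test blood test to optimize windows for.
#' @param k_max maximum number of windows.
#' @param obs_days observation interval length (search over an
#'   \code{obs_days}-day window).
#' @param score \code{"product"} (default) or \code{"sum"} combination of
#'   window distances.
#' @param eps distance denominator guard.
#' @return list with \code{k}, \code{cuts}, \code{windows} (day ranges,
#'   newest first), \code{score}, and \code{best_by_k}.
#' @export
best_partitioning <- function(labs, labels, test, k_max = 3, obs_days = 60,
                              score = c("product", "sum"), eps = 1e-9) {
  score <- match.arg(score)
  if (k_max > obs_days) stop("k_max cannot exceed the number of days")
  curves <- group_curves(labs, labels, test, obs_days)
  # per-day distance over days obs_days..0; reorder to day 0..obs_days
  dvec <- abs(curves$mean_case_i - curves$mean_ctrl_i) /
    (sqrt(curves$hw_case_i^2 + curves$hw_ctrl_i^2) + eps)
  dvec <- rev(dvec)                      # index i -> day i-1
  cs <- c(0, cumsum(dvec))               # sum over days a..b = cs[b+2]-cs[a+1]
  wmean <- function(a, b) (cs[b + 2] - cs[a + 1]) / (b - a + 1)
  comb <- if (score == "product") `*` else `+`

  best <- NULL
  best_by_k <- data.frame(k = integer(0), score = numeric(0))
  for (k in seq_len(k_max)) {
    en <- enumerate_partitionings(obs_days, k)
    sc <- if (k == 1) {
      rep(wmean(0, obs_days), en$count)
    } else {
      apply(en$cuts, 2, function(cuts) {
        s <- wmean(0, cuts[1] - 1)
        if (k > 2) for (i in 2:(k - 1))
          s <- comb(s, wmean(cuts[i - 1], cuts[i] - 1))
        comb(s, wmean(cuts[k - 1], obs_days))
      })
    }
    i_best <- which.max(sc)              # lexicographically earliest argmax
    best_by_k <- rbind(best_by_k, data.frame(k = k, score = sc[i_best]))
    if (is.null(best) || sc[i_best] > best$score) {
      best <- list(k = k, cuts = en$cuts[, i_best],
                   windows = cuts_to_windows(en$cuts[, i_best], obs_days),
                   score = sc[i_best])
    }
  }
  best$best_by_k <- best_by_k
  best
}
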