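#' ROC and precision-recall AUC
#'
#' \code{roc_auc} is the Mann-Whitney pair statistic: the probability that
#' a random case outscores a random control, ties counted 1/2 (computed
#' via midranks). \code{pr_auc} is the area under the precision-recall
#' step curve, integrating precision over recall increments at each
#' distinct score threshold (descending); with a constant score it equals
#' the prevalence.
#'
#' @param scores numeric predicted scores.
#' @param labels binary 0/1 labels, both classes present.
#' @return scalar in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_binary_y(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname roc_auc
#' @export
pr_auc <- function(scores, labels) {
  labels <- check_binary_y(labels)
  n1 <- sum(labels == 1)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yl <- labels[ord]
  tp <- cumsum(yl)
  fp <- cumsum(1 - yl)
  last <- !duplicated(s, fromLast = TRUE)   # threshold at each distinct score
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Confusion-table metrics at a threshold
#'
#' Scores at or above the threshold are classified positive. Ratios with a
#' zero denominator are returned as 0 and flagged in the
#' \code{"undefined"} attribute.
#'
#' @param scores predicted scores.
#' @param labels binary 0/1 labels.
#' @param threshold classification threshold.
#' @return named vector (sens, spec, ppv, npv).
#' @export
classification_metrics <- function(scores, labels, threshold) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  safe <- function(num, den) if (den > 0) num / den else 0
  out <- c(sens = safe(tp, tp + fn), spec = safe(tn, tn + fp),
           ppv = safe(tp, tp + fp), npv = safe(tn, tn + fn))
  undef <- c(tp + fn, tn + fp, tp + fp, tn + fn) == 0
  attr(out, "undefined") <- names(out)[undef]
  out
}

#' Choose a classification threshold by Youden's J
#'
#' Maximizes J = sensitivity + specificity - 1 over candidate thresholds
#' (the distinct scores and the midpoints between consecutive distinct
#' scores); ties go to the lowest threshold, so perfectly separated
#' scores return the midpoint of the separating gap.
#'
#' @param scores predicted scores (typically on training data).
#' @param labels binary 0/1 labels.
#' @return the selected threshold.
#' @export
choose_threshold <- function(scores, labels) {
  labels <- check_binary_y(labels)
  u <- sort(unique(scores))
  if (length(u) == 1) return(u)
  idx <- match(scores, u)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  cpos <- cumsum(tabulate(idx[labels == 1], length(u)))
  cneg <- cumsum(tabulate(idx[labels == 0], length(u)))
  # at threshold u_i (predict positive when score >= u_i):
  sens <- (n1 - c(0, cpos)[seq_along(u)]) / n1
  spec <- c(0, cneg)[seq_along(u)] / n0
  j <- sens + spec - 1
  i <- which(j >= max(j) - 1e-12)[1]
  # the midpoint below u_i classifies identically and is the lower tied
  # candidate, except at the smallest score
  if (i == 1) u[1] else (u[i - 1] + u[i]) / 2
}

#' Experiment specification for repeated holdout evaluation
#'
#' @param n_repeats number of holdout repetitions (default 100).
#' @param train_frac training fraction (default 0.8; the validation set
#'   has exactly \code{floor((1 - train_frac) * n)} patients, stratified).
#' @param p_max feature cap passed to \code{\link{select_lambda_cv}}.
#' @param price_penalty use price-derived penalty factors (PPM) instead of
#'   unit factors.
#' @param folds internal CV folds for lambda tuning.
#' @param rose apply ROSE rebalancing to each training set (default FALSE).
#' @param seed master seed for splits, folds, and rebalancing.
#' @return an \code{experiment_spec}.
#' @export
experiment_spec <- function(n_repeats = 100, train_frac = 0.8, p_max = NULL,
                            price_penalty = FALSE, folds = 10, rose = FALSE,
                            seed = 1) {
  stopifnot(n_repeats >= 1, train_frac > 0, train_frac < 1)
  structure(list(n_repeats = as.integer(n_repeats), train_frac = train_frac,
                 p_max = p_max, price_penalty = price_penalty,
                 folds = folds, rose = rose, seed = as.integer(seed)),
            class = "experiment_spec")
}

stratified_split <- function(y, val_n) {
  n <- length(y)
  n1 <- sum(y == 1)
  v1 <- round(val_n * n1 / n)
  v0 <- val_n - v1
  val <- c(sample(which(y == 1), v1), sample(which(y == 0), v0))
  sort(val)
}

t_ci <- function(x, level = 0.95) {
  m <- mean(x)
  if (length(x) < 2 || stats::sd(x) == 0)
    return(c(mean = m, lo = m, hi = m))
  half <- stats::qt(1 - (1 - level) / 2, length(x) - 1) *
    stats::sd(x) / sqrt(length(x))
  c(mean = m, lo = m - half, hi = m + half)
}

#' Repeated-holdout evaluation harness
#'
#' Runs \code{n_repeats} stratified train/validation splits (validation
#' size \code{floor((1 - train_frac) * n)}), fits the penalized model on
#' each training set via \code{\link{select_lambda_cv}}, chooses the
#' classification threshold on training-side predictions (Youden), and
#' scores the validation set. Reports per-repeat and aggregated metrics
#' (mean with 95% t-interval over repeats), per-feature selection
#' frequencies with modal coefficient signs, and — when \code{labs} and
#' \code{catalog} are supplied — the provisional blood-test cost of each
#' repeat's validation patients (every recorded measurement of every
#' selected test billed at the catalog price).
#'
#' @param X feature matrix (patients x features, rownames = patient ids).
#' @param y binary SSI labels aligned to \code{X} rows.
#' @param spec an \code{\link{experiment_spec}}.
#' @param catalog test catalog (penalties and costs).
#' @param labs optional raw measurements for cost accounting.
#' @return list with \code{metrics} (per-repeat data.frame),
#'   \code{summary} (mean/lo/hi per metric), \code{selection}
#'   (feature, n_selected, modal_sign), \code{cost_total} (NOK, NA without
#'   \code{labs}), and \code{n_validation_total}.
#' @export
repeated_holdout <- function(X, y, spec, catalog = NULL, labs = NULL) {
  stopifnot(inherits(spec, "experiment_spec"))
  x <- as_design_matrix(X)
  y <- check_binary_y(y)
  n <- length(y)
  val_n <- floor(round((1 - spec$train_frac) * n, 9))
  if (val_n < 1) stop("validation set is empty at this train_frac")
  penalty <- if (spec$price_penalty) {
    if (is.null(catalog)) stop("price_penalty requires a catalog")
    compute_penalty_factors(catalog, colnames(x))
  } else unit_penalty(colnames(x))

  set.seed(spec$seed)
  metric_names <- c("auc", "auprc", "threshold", "sens", "spec", "ppv",
                    "npv", "n_selected")
  met <- matrix(NA_real_, nrow = spec$n_repeats, ncol = length(metric_names),
                dimnames = list(NULL, metric_names))
  sel_count <- stats::setNames(integer(ncol(x)), colnames(x))
  sign_sum <- stats::setNames(numeric(ncol(x)), colnames(x))
  cost_total <- if (is.null(labs)) NA_real_ else 0

  cost_lu <- NULL
  if (!is.null(labs)) {
    stopifnot(!is.null(catalog))
    # per patient x test measurement counts in the observation interval
    cost_lu <- table(labs$patient_id, labs$test_name)
  }

  for (r in seq_len(spec$n_repeats)) {
    repeat {
      val <- stratified_split(y, val_n)
      if (length(unique(y[val])) == 2 && length(unique(y[-val])) == 2) break
      message("degenerate split in repeat ", r, "; resampling")
    }
    xt <- x[-val, , drop = FALSE]; yt <- y[-val]
    if (spec$rose) {
      rb <- rose_oversample(xt, yt)
      xt <- as_design_matrix(rb$X); yt <- rb$y
    }
    model <- select_lambda_cv(xt, yt, penalty = penalty,
                              folds = spec$folds, p_max = spec$p_max)
    thr <- choose_threshold(predict_proba(model, xt), yt)
    pv <- predict_proba(model, x[val, , drop = FALSE])
    yv <- y[val]
    cm <- classification_metrics(pv, yv, thr)
    met[r, ] <- c(roc_auc(pv, yv), pr_auc(pv, yv), thr,
                  cm[["sens"]], cm[["spec"]], cm[["ppv"]], cm[["npv"]],
                  length(model$nonzero))
    nz <- model$nonzero
    sel_count[nz] <- sel_count[nz] + 1L
    sign_sum[nz] <- sign_sum[nz] + sign(model$beta[nz])
    if (!is.null(cost_lu)) {
      sel_tests <- unique(stats::na.omit(feature_test_name(nz)))
      sel_tests <- intersect(sel_tests, colnames(cost_lu))
      pid <- rownames(x)[val]
      pid <- intersect(pid, rownames(cost_lu))
      if (length(sel_tests) && length(pid)) {
        counts <- cost_lu[pid, sel_tests, drop = FALSE]
        prices <- catalog$price[match(sel_tests, catalog$test_name)]
        cost_total <- cost_total + sum(t(counts) * prices)
      }
    }
  }

  summ <- t(apply(met, 2, t_ci))
  selection <- data.frame(
    feature = names(sel_count),
    n_selected = as.integer(sel_count),
    modal_sign = ifelse(sign_sum > 0, "+", ifelse(sign_sum < 0, "-", "")),
    stringsAsFactors = FALSE)
  selection <- selection[order(-selection$n_selected), ]
  rownames(selection) <- NULL
  list(metrics = as.data.frame(met),
       summary = as.data.frame(summ),
       selection = selection,
       cost_total = cost_total,
       n_validation_total = spec$n_repeats * val_n)
}

#' Provisional blood-test cost of a selected-feature set
#'
#' Bills, for each listed patient, every recorded measurement (within the
#' observation interval) of every test appearing in the selected-feature
#' set at the catalog price, and sums over patients.
#'
#' @param selected_features character vector of selected feature names.
#' @param labs raw measurements.
#' @param catalog test catalog with prices.
#' @param patient_ids patients to bill (default: all in \code{labs}).
#' @return total cost in NOK.
#' @export
cost_of_selection <- function(selected_features, labs, catalog,
                              patient_ids = NULL) {
  sel_tests <- unique(stats::na.omit(feature_test_name(selected_features)))
  if (!length(sel_tests)) return(0)
  if (is.null(patient_ids)) patient_ids <- unique(labs$patient_id)
  keep <- labs$patient_id %in% patient_ids & labs$test_name %in% sel_tests
  if (!any(keep)) return(0)
  lb <- labs[keep, ]
  prices <- catalog$price[match(lb$test_name, catalog$test_name)]
  if (anyNA(prices)) stop("selected test missing from catalog")
  sum(prices)
}

#' Cost comparison between model variants
#'
#' @param cost_a,cost_b total costs (NOK) of two variants.
#' @return relative reduction \code{1 - cost_b / cost_a}.
#' @export
cost_reduction <- function(cost_a, cost_b) {
  if (cost_a == 0) return(0)
  1 - cost_b / cost_a
}
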