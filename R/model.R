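#' Price-derived per-feature penalty factors
#'
#' Every feature derived from blood test j receives the L1 penalty factor
#' v_j = r_max / r_j, where r_j is the test's price and r_max the price of
#' the most expensive test in the catalog. The most expensive tests carry
#' factor 1 and cheaper tests proportionally larger factors, so selection
#' concentrates on fewer distinct tests; combined with the feature cap
#' p_max this is what drives the billed-test cost down (see the methods
#' vignette for a discussion of this convention). Demographic columns
#' (age, sex) receive factor 1.
#'
#' @param catalog test catalog with prices.
#' @param feature_names character vector of feature-matrix column names.
#' @return numeric vector of penalty factors aligned to
#'   \code{feature_names} (class \code{penalty_spec}).
#' @export
compute_penalty_factors <- function(catalog, feature_names) {
  tn <- feature_test_name(feature_names)
  v <- rep(1, length(feature_names))
  derived <- !is.na(tn)
  if (any(derived)) {
    idx <- match(tn[derived], catalog$test_name)
    if (anyNA(idx))
      stop("feature(s) reference unknown test(s): ",
           paste(unique(tn[derived][is.na(idx)]), collapse = ", "))
    v[derived] <- max(catalog$price) / catalog$price[idx]
  }
  structure(stats::setNames(v, feature_names), class = "penalty_spec")
}

#' Unit penalty factors
#' @param feature_names feature-matrix column names.
#' @return all-ones \code{penalty_spec} (price penalization off).
#' @export
unit_penalty <- function(feature_names) {
  structure(stats::setNames(rep(1, length(feature_names)), feature_names),
            class = "penalty_spec")
}

as_design_matrix <- function(X) {
  x <- as.matrix(as.data.frame(X, check.names = FALSE))
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("non-finite entries in the feature matrix")
  x
}

check_binary_y <- function(y) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1")
  if (length(unique(y)) < 2) stop("both classes must be present")
  y
}

#' Fit an L1-penalized logistic regression path
#'
#' Minimizes the negative Bernoulli log-likelihood plus
#' \eqn{\lambda \sum_j v_j |\beta_j|} over a decreasing \eqn{\lambda} grid
#' (coordinate descent via glmnet, warm starts, features standardized
#' internally, coefficients reported on the original scale). Penalty
#' factors are normalized to mean 1 before fitting, so the reported
#' \eqn{\lambda} is expressed per unit average penalty; only the products
#' \eqn{\lambda v_j} are identified.
#'
#' @param X feature matrix (data.frame or matrix), complete.
#' @param y binary 0/1 labels, both classes present.
#' @param penalty \code{penalty_spec} (default: unit factors).
#' @param lambda optional explicit decreasing lambda sequence; by default
#'   100 values from \eqn{\lambda_{max}} down to \eqn{10^{-3}\lambda_{max}}.
#' @param nlambda,lambda_min_ratio grid size and lower ratio when
#'   \code{lambda} is NULL.
#' @param standardize standardize features inside the solver (default TRUE).
#' @param thresh coordinate-descent convergence tolerance.
#' @return A \code{lasso_path}: list with \code{lambda}, \code{a0}
#'   (intercepts), \code{beta} (p x nlambda sparse matrix, original scale),
#'   \code{df} (nonzero counts), \code{penalty} (normalized factors used),
#'   \code{feature_names}, and the underlying \code{glmnet} fit.
#' @export
fit_lasso_path <- function(X, y, penalty = NULL, lambda = NULL,
                           nlambda = 100, lambda_min_ratio = 1e-3,
                           standardize = TRUE, thresh = 1e-9) {
  x <- as_design_matrix(X)
  y <- check_binary_y(y)
  if (nrow(x) != length(y)) stop("nrow(X) must match length(y)")
  if (is.null(penalty)) penalty <- unit_penalty(colnames(x))
  if (length(penalty) != ncol(x))
    stop("penalty length must match feature count")
  v <- as.numeric(penalty) / mean(penalty)   # mean-1 normalization
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        penalty.factor = v, lambda = lambda,
                        nlambda = nlambda,
                        lambda.min.ratio = lambda_min_ratio,
                        standardize = standardize, thresh = thresh)
  structure(list(lambda = fit$lambda,
                 a0 = as.numeric(fit$a0),
                 beta = fit$beta,
                 df = as.integer(fit$df),
                 penalty = stats::setNames(v, colnames(x)),
                 feature_names = colnames(x),
                 standardize = standardize,
                 glmnet_fit = fit),
            class = "lasso_path")
}

path_model_at <- function(path, lambda_index, p_max = NULL) {
  beta <- as.numeric(path$beta[, lambda_index])
  names(beta) <- path$feature_names
  nz <- path$feature_names[beta != 0]
  structure(list(beta0 = path$a0[lambda_index],
                 beta = beta,
                 lambda = path$lambda[lambda_index],
                 penalty = path$penalty,
                 nonzero = nz,
                 p_max = p_max,
                 feature_names = path$feature_names),
            class = "fitted_model")
}

stratified_folds <- function(y, folds) {
  fid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fid
}

#' Select lambda by cross-validation with a feature-count cap
#'
#' Tunes \eqn{\lambda} by stratified k-fold cross-validation over the
#' decreasing \eqn{\lambda} grid of the full-data path, scoring each
#' candidate by validation AUC (or binomial deviance). The cap
#' \code{p_max} acts as an early-stopping rule on the path: candidate
#' \eqn{\lambda} values are restricted to the prefix of the grid before
#' the first \eqn{\lambda} at which the full-data fit selects more than
#' \code{p_max} features, so the returned model — the full-data fit at the
#' winning \eqn{\lambda} — never exceeds \code{p_max} nonzero
#' coefficients. Ties in the CV score go to the largest (most regularized)
#' \eqn{\lambda}. \code{p_max = 0} yields the intercept-only model.
#'
#' @inheritParams fit_lasso_path
#' @param folds number of CV folds (default 10, stratified).
#' @param p_max maximum number of selected features, or NULL for no cap.
#' @param criterion \code{"auc"} (maximized) or \code{"deviance"}
#'   (minimized).
#' @return A \code{fitted_model} with elements \code{beta0}, \code{beta}
#'   (original scale), \code{lambda}, \code{penalty}, \code{nonzero},
#'   \code{p_max}, plus the CV table in \code{cv}.
#' @export
select_lambda_cv <- function(X, y, penalty = NULL, folds = 10, p_max = NULL,
                             criterion = c("auc", "deviance"), ...) {
  criterion <- match.arg(criterion)
  x <- as_design_matrix(X)
  y <- check_binary_y(y)
  if (folds < 2) stop("folds must be >= 2")
  path <- fit_lasso_path(x, y, penalty = penalty, ...)

  cand <- seq_along(path$lambda)
  if (!is.null(p_max)) {
    over <- which(path$df > p_max)
    if (length(over)) cand <- cand[cand < min(over)]
    if (!length(cand)) {
      # even the most regularized fit exceeds p_max (p_max = 0 with an
      # unpenalized column, say): fall back to the intercept-only model
      b0 <- stats::qlogis(mean(y))
      return(structure(list(beta0 = b0,
                            beta = stats::setNames(rep(0, ncol(x)),
                                                   colnames(x)),
                            lambda = Inf, penalty = path$penalty,
                            nonzero = character(0), p_max = p_max,
                            feature_names = colnames(x), cv = NULL),
                       class = "fitted_model"))
    }
  }
  lam <- path$lambda[cand]

  fid <- stratified_folds(y, folds)
  score <- matrix(NA_real_, nrow = folds, ncol = length(lam))
  for (f in seq_len(folds)) {
    tr <- fid != f
    fit_f <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr],
                            family = "binomial", alpha = 1,
                            penalty.factor = path$penalty,
                            lambda = lam,
                            standardize = path$standardize)
    pr <- stats::predict(fit_f, x[!tr, , drop = FALSE], s = lam,
                         type = "response", exact = FALSE)
    yv <- y[!tr]
    score[f, ] <- apply(pr, 2, function(p) {
      if (criterion == "auc") roc_auc(p, yv)
      else -mean(yv * log(pmax(p, 1e-12)) +
                   (1 - yv) * log(pmax(1 - p, 1e-12)))
    })
  }
  mscore <- colMeans(score)
  best <- if (criterion == "auc") {
    which(mscore >= max(mscore) - 1e-12)[1]   # ties -> largest lambda
  } else {
    which(mscore <= min(mscore) + 1e-12)[1]
  }
  model <- path_model_at(path, cand[best], p_max = p_max)
  model$cv <- data.frame(lambda = lam, score = mscore,
                         df = path$df[cand])
  model
}

#' Predict class probabilities
#'
#' Logistic transform of the linear predictor
#' \eqn{\beta_0 + \beta^T x}; columns of \code{X} must match the training
#' feature names.
#'
#' @param model a \code{fitted_model}.
#' @param X feature matrix with the training columns.
#' @return vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "fitted_model"))
  x <- as_design_matrix(X)
  if (!identical(colnames(x), model$feature_names)) {
    if (!all(model$feature_names %in% colnames(x)))
      stop("feature columns missing: ",
           paste(setdiff(model$feature_names, colnames(x)), collapse = ", "))
    x <- x[, model$feature_names, drop = FALSE]
  }
  as.numeric(stats::plogis(model$beta0 + x %*% model$beta))
}

#' ROSE-style smoothed-bootstrap oversampling
#'
#' Draws a class-balanced synthetic sample: rows are resampled with
#' replacement within class and perturbed with Gaussian kernel noise whose
#' per-feature bandwidth is a Silverman-type multiple of the within-class
#' standard deviation. With \code{bandwidth = 0} this reduces to plain
#' duplication of resampled rows.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param seed optional integer seed.
#' @param n_per_class output rows per class (default \code{round(n/2)}).
#' @param bandwidth kernel bandwidth multiplier (default 1 = Silverman
#'   rule; 0 disables smoothing).
#' @return list with balanced \code{X} and \code{y}
#'   (\code{sum(y==1) == sum(y==0)}).
#' @export
rose_oversample <- function(X, y, seed = NULL, n_per_class = NULL,
                            bandwidth = 1) {
  x <- as_design_matrix(X)
  y <- check_binary_y(y)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_per_class)) n_per_class <- round(length(y) / 2)
  p <- ncol(x)
  parts <- lapply(c(0, 1), function(cl) {
    idx <- which(y == cl)
    nc <- length(idx)
    h <- bandwidth * (4 / ((p + 2) * nc))^(1 / (p + 4))
    sds <- apply(x[idx, , drop = FALSE], 2, stats::sd)
    sds[!is.finite(sds)] <- 0
    pick <- sample(idx, n_per_class, replace = TRUE)
    noise <- matrix(stats::rnorm(n_per_class * p), ncol = p) *
      rep(h * sds, each = n_per_class)
    x[pick, , drop = FALSE] + noise
  })
  Xb <- rbind(parts[[1]], parts[[2]])
  list(X = as.data.frame(Xb, check.names = FALSE),
       y = rep(c(0, 1), each = n_per_class))
}
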