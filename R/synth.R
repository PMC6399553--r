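#' Default blood-test catalog
#'
#' The 14 most frequently measured preoperative blood tests in a
#' gastrointestinal-surgery cohort, with their expected number of
#' measurements per patient over the last 30 preoperative days
#' (\code{rate30}), adult reference ranges, and per-test prices in NOK.
#' Leukocytes and thrombocytes are the most expensive tests at 58 NOK and
#' glucose the cheapest at 23 NOK; the remaining prices are not published
#' and default to a linear ramp between 23 and 58 NOK in catalog order
#' (override via \code{prices} or a catalog JSON file).
#'
#' @param prices optional named numeric vector of price overrides (NOK).
#' @return A data.frame with columns \code{test_name}, \code{price},
#'   \code{ref_low}, \code{ref_high}, \code{rate30}.
#' @export
default_catalog <- function(prices = NULL) {
  cat <- data.frame(
    test_name = c("Hemoglobin", "Leukocytes", "Sodium", "CRP", "Potassium",
                  "Albumin", "Creatinine", "Thrombocytes", "ALAT",
                  "Bilirubin.total", "ASAT", "Glucose", "Amylase", "ALP"),
    price = round(seq(23, 58, length.out = 14), 1),
    ref_low  = c(11.7, 3.5, 137, 0.1, 3.6, 36, 60, 145, 10,  5, 15, 4.0,  25,  35),
    ref_high = c(15.3, 10.0, 145, 5.0, 4.6, 45, 105, 390, 70, 25, 45, 6.3, 120, 105),
    rate30 = c(5.37, 4.43, 4.24, 4.11, 3.97, 2.87, 1.94, 1.53, 1.23,
               1.22, 1.14, 1.06, 1.06, 1.04),
    stringsAsFactors = FALSE
  )
  cat$price[cat$test_name %in% c("Leukocytes", "Thrombocytes")] <- 58
  cat$price[cat$test_name == "Glucose"] <- 23
  if (!is.null(prices)) {
    idx <- match(names(prices), cat$test_name)
    if (anyNA(idx)) stop("unknown test in price overrides: ",
                         paste(names(prices)[is.na(idx)], collapse = ", "))
    cat$price[idx] <- as.numeric(prices)
  }
  validate_catalog(cat)
  cat
}

validate_catalog <- function(catalog) {
  stopifnot(is.data.frame(catalog),
            all(c("test_name", "price", "ref_low", "ref_high", "rate30")
                %in% names(catalog)))
  if (nrow(catalog) == 0L) stop("catalog is empty")
  if (any(grepl("_", catalog$test_name, fixed = TRUE)))
    stop("test names must not contain underscores (reserved for feature names)")
  if (anyDuplicated(catalog$test_name)) stop("duplicate test names in catalog")
  if (any(catalog$price <= 0)) stop("catalog prices must be positive")
  if (any(catalog$rate30 <= 0)) stop("catalog rate30 must be positive")
  if (any(catalog$ref_low >= catalog$ref_high))
    stop("catalog reference ranges must satisfy ref_low < ref_high")
  invisible(catalog)
}

#' Effect specification for the synthetic cohort generator
#'
#' Encodes the case-group signals the generator plants: an elevated CRP
#' level in the medium preoperative window, an elevated testing frequency
#' ("physician suspicion") for designated tests in the medium window, and a
#' higher probability of out-of-reference values in the medium window.
#'
#' @param crp_shift_M standardized upward shift of case-group CRP values
#'   measured in the medium window (units: within-test SDs; >= 0).
#' @param test_rate_multiplier multiplicative boost (>= 1) of the
#'   case-group sampling intensity in the medium window for `rate_tests`.
#' @param abn_prob_shift increase in the probability that a case-group
#'   value measured in the medium window falls outside the reference range.
#' @param rate_tests tests whose sampling intensity is boosted for cases.
#' @return An object of class \code{effect_spec}.
#' @export
effect_spec <- function(crp_shift_M = 1.0,
                        test_rate_multiplier = 2.0,
                        abn_prob_shift = 0.15,
                        rate_tests = c("Leukocytes", "Sodium",
                                       "Hemoglobin", "Thrombocytes")) {
  stopifnot(crp_shift_M >= 0, test_rate_multiplier >= 1,
            abn_prob_shift >= 0, abn_prob_shift < 0.9)
  structure(list(crp_shift_M = crp_shift_M,
                 test_rate_multiplier = test_rate_multiplier,
                 abn_prob_shift = abn_prob_shift,
                 rate_tests = rate_tests),
            class = "effect_spec")
}

#' Neutral (null) effect specification
#'
#' All planted effects switched off; case and control distributions are
#' identical, so any downstream classifier should score AUC ~ 0.5.
#' @return An \code{effect_spec} with all effects neutral.
#' @export
neutral_effects <- function() {
  effect_spec(crp_shift_M = 0, test_rate_multiplier = 1, abn_prob_shift = 0)
}

#' Cohort specification for the synthetic generator
#'
#' @param n_patients number of patients (positive integer).
#' @param prevalence SSI prevalence, in (0, 1). The generated case count is
#'   exactly \code{round(n_patients * prevalence)}.
#' @param obs_days observation-interval length in days before surgery
#'   (day 0 = day of surgery; the grid spans \code{[obs_days, 0]}).
#' @param seed integer RNG seed; the full cohort is reproducible from it.
#' @param effects an \code{\link{effect_spec}}.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_patients, prevalence = 0.2013, obs_days = 60,
                        seed = 1, effects = effect_spec()) {
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("n_patients must be a positive integer")
  if (!(prevalence > 0 && prevalence < 1))
    stop("prevalence must be in (0, 1)")
  if (obs_days < 1) stop("obs_days must be a positive integer")
  stopifnot(inherits(effects, "effect_spec"))
  structure(list(n_patients = as.integer(n_patients),
                 prevalence = prevalence,
                 obs_days = as.integer(obs_days),
                 seed = as.integer(seed),
                 effects = effects),
            class = "cohort_spec")
}

# Per-day sampling weight on [obs_days, 0]: the short window (days 2-0) is
# sampled most densely, the medium window (days 15-3) at an intermediate
# rate, and the long tail at baseline, mirroring how preoperative testing
# concentrates near surgery. Weights normalized so the expected count over
# the most recent 30 days equals rate30.
day_weights <- function(obs_days, w_s = 3, w_m = 1.5, w_l = 1) {
  days <- obs_days:0
  w <- ifelse(days <= 2, w_s, ifelse(days <= 15, w_m, w_l))
  names(w) <- paste0("d", days)
  w
}

#' Generate a synthetic preoperative cohort
#'
#' Draws a seeded synthetic EHR cohort: binary SSI labels with an exact
#' case count of \code{round(n_patients * prevalence)}, demographics (age
#' uniform 40-85 years, sex 0/1), and irregular per-test measurement series
#' over the preoperative interval. Measurement days follow an independent
#' per-day Poisson process with a piecewise-constant intensity (densest in
#' the short window) scaled so the expected count over the most recent 30
#' days equals the catalog \code{rate30}; values are Gaussian around the
#' reference-range midpoint with an SD such that ~10% of control values
#' fall outside the range. Case-group effects (CRP shift, testing-rate
#' boost, abnormality inflation) are applied on medium-window days per
#' \code{spec$effects}.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param catalog a test catalog (see \code{\link{default_catalog}}).
#' @param dup_prob probability that a measurement is accompanied by a
#'   second same-day draw, so downstream daily-mean aggregation is
#'   exercised.
#' @return A list with \code{patients} (patient_id, age, sex, ssi) and
#'   \code{labs} (patient_id, test_name, day, value).
#' @export
generate_cohort <- function(spec, catalog = default_catalog(),
                            dup_prob = 0.05) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_catalog(catalog)
  n <- spec$n_patients
  eff <- spec$effects
  set.seed(spec$seed)

  n_cases <- as.integer(round(n * spec$prevalence))
  ssi <- integer(n)
  ssi[sample.int(n, n_cases)] <- 1L
  patients <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = round(stats::runif(n, 40, 85), 1),
    sex = sample(0:1, n, replace = TRUE),
    ssi = ssi,
    stringsAsFactors = FALSE
  )

  days <- spec$obs_days:0
  w <- day_weights(spec$obs_days)
  recent <- days <= 29                    # most recent 30 days: 29..0
  base_int <- w / sum(w[recent])          # per-day intensity per unit rate30
  in_M <- days <= 15 & days >= 3

  # baseline SD: ~10% of control values outside the reference range
  z0 <- stats::qnorm(0.95)

  out <- vector("list", n * nrow(catalog))
  idx <- 0L
  for (j in seq_len(nrow(catalog))) {
    tn <- catalog$test_name[j]
    mid <- (catalog$ref_low[j] + catalog$ref_high[j]) / 2
    hw <- (catalog$ref_high[j] - catalog$ref_low[j]) / 2
    sd0 <- hw / z0
    p_abn_case <- min(0.10 + eff$abn_prob_shift, 0.95)
    sd_case_M <- hw / stats::qnorm(1 - p_abn_case / 2)
    boosted <- tn %in% eff$rate_tests
    lam0 <- catalog$rate30[j] * base_int
    for (i in seq_len(n)) {
      lam <- lam0
      is_case <- patients$ssi[i] == 1L
      if (is_case && boosted && eff$test_rate_multiplier > 1)
        lam[in_M] <- lam[in_M] * eff$test_rate_multiplier
      cnt <- stats::rpois(length(lam), lam)
      extra <- stats::rbinom(length(lam), cnt, dup_prob)
      cnt <- cnt + extra
      tot <- sum(cnt)
      if (tot == 0L) next
      d <- rep(days, cnt)
      dM <- d <= 15 & d >= 3
      sdv <- rep(sd0, tot)
      muv <- rep(mid, tot)
      if (is_case) {
        sdv[dM] <- sd_case_M
        if (tn == "CRP") muv[dM] <- muv[dM] + eff$crp_shift_M * sd0
      }
      idx <- idx + 1L
      out[[idx]] <- data.frame(
        patient_id = patients$patient_id[i],
        test_name = tn,
        day = d,
        value = round(stats::rnorm(tot, muv, sdv), 3),
        stringsAsFactors = FALSE
      )
    }
  }
  labs <- if (idx > 0L) do.call(rbind, out[seq_len(idx)]) else
    data.frame(patient_id = character(), test_name = character(),
               day = integer(), value = numeric(), stringsAsFactors = FALSE)
  labs <- labs[order(labs$patient_id, labs$test_name, -labs$day), ]
  rownames(labs) <- NULL
  list(patients = patients, labs = labs)
}

#' Read / write lab measurements as CSV
#'
#' Long-format CSV with header \code{patient_id,test_name,day,value};
#' \code{day} is integer days before surgery (0 = day of surgery).
#' Round-trips losslessly through \code{write_labs_csv}.
#'
#' @param path file path.
#' @param catalog optional catalog; when given, unknown test names error.
#' @return data.frame of measurements.
#' @export
read_labs_csv <- function(path, catalog = NULL) {
  if (!file.exists(path)) stop("labs file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "test_name", "day", "value")
  if (!all(need %in% names(df)))
    stop("labs CSV must have header: ", paste(need, collapse = ","))
  if (nrow(df) > 0) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df$value))) |
                   !is.finite(suppressWarnings(as.numeric(df$day))))
    if (length(bad))
      stop("malformed labs rows (non-numeric day/value) at line(s): ",
           paste(bad + 1L, collapse = ", "))  # +1 for the header line
    df$day <- as.integer(df$day)
    df$value <- as.numeric(df$value)
    if (any(df$day < 0)) stop("negative day values in labs file")
    if (!is.null(catalog)) {
      unk <- setdiff(unique(df$test_name), catalog$test_name)
      if (length(unk))
        stop("unknown test name(s) not in catalog: ",
             paste(unk, collapse = ", "))
    }
  }
  df[need]
}

#' @rdname read_labs_csv
#' @param labs data.frame of measurements.
#' @export
write_labs_csv <- function(labs, path) {
  utils::write.csv(labs[c("patient_id", "test_name", "day", "value")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the patients table as CSV
#'
#' Header \code{patient_id,age,sex,ssi}; \code{ssi} is the binary label.
#' @param path file path.
#' @return data.frame of patients.
#' @export
read_patients_csv <- function(path) {
  if (!file.exists(path)) stop("patients file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "age", "sex", "ssi")
  if (!all(need %in% names(df)))
    stop("patients CSV must have header: ", paste(need, collapse = ","))
  if (nrow(df) > 0 && !all(df$ssi %in% 0:1))
    stop("ssi labels must be 0/1")
  df[need]
}

#' @rdname read_patients_csv
#' @param patients data.frame of patients.
#' @export
write_patients_csv <- function(patients, path) {
  utils::write.csv(patients[c("patient_id", "age", "sex", "ssi")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a test catalog as JSON
#'
#' JSON array of objects with fields \code{test_name}, \code{price},
#' \code{ref_low}, \code{ref_high}, \code{rate30}.
#' @param path file path.
#' @return validated catalog data.frame.
#' @export
read_catalog_json <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  cat <- jsonlite::fromJSON(path)
  validate_catalog(cat)
  cat[c("test_name", "price", "ref_low", "ref_high", "rate30")]
}

#' @rdname read_catalog_json
#' @param catalog catalog data.frame.
#' @export
write_catalog_json <- function(catalog, path) {
  validate_catalog(catalog)
  jsonlite::write_json(catalog, path, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  invisible(path)
}
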