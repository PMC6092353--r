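#' Framingham general-CVD risk coefficients
#'
#' Loads a sex-specific coefficient table for the continuous (Cox-model)
#' Framingham risk score. The packaged default is the D'Agostino 2008
#' general-cardiovascular-disease formulation: log-age, log-total-cholesterol,
#' log-HDL, log-SBP (separate coefficients for treated and untreated blood
#' pressure), current smoking and diabetes, with a sex-specific 10-year
#' baseline survival and mean linear predictor.
#'
#' @param version_id Identifier of the coefficient set within the file.
#' @param path Optional path to an alternative coefficient file with columns
#'   version_id, sex, term, value.
#' @return A list of class \code{"frs_coefficients"}: \code{version_id} plus
#'   per-sex lists with \code{beta} (named coefficient vector), \code{s0}
#'   (10-year baseline survival) and \code{mean_lp}.
#' @export
frs_coefficients <- function(version_id = "dagostino2008_general_cvd",
                             path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "frs_dagostino2008.csv", package = "lbsiz",
                        mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- tab[tab$version_id == version_id, , drop = FALSE]
  if (nrow(tab) == 0L)
    stop("no coefficient set named '", version_id, "' in ", path, call. = FALSE)
  beta_terms <- c("log_age", "log_tc", "log_hdl", "log_sbp_untreated",
                  "log_sbp_treated", "smoker", "diabetes")
  per_sex <- lapply(c(male = "male", female = "female"), function(sx) {
    sub <- tab[tab$sex == sx, , drop = FALSE]
    val <- stats::setNames(sub$value, sub$term)
    missing <- setdiff(c(beta_terms, "s0_10yr", "mean_lp"), names(val))
    if (length(missing))
      stop("coefficient set '", version_id, "' is missing ", sx, " term(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    s0 <- unname(val["s0_10yr"])
    if (!is.finite(s0) || s0 <= 0 || s0 >= 1)
      stop("baseline survival must lie strictly in (0, 1)", call. = FALSE)
    list(beta = val[beta_terms], s0 = s0, mean_lp = unname(val["mean_lp"]))
  })
  structure(c(list(version_id = version_id), per_sex),
            class = "frs_coefficients")
}

frs_required_fields <- c("sex", "age", "tc", "hdl", "sbp", "bp_treat",
                         "smoking", "diabetes")

frs_check_record <- function(record) {
  missing <- setdiff(frs_required_fields, names(record))
  if (length(missing))
    stop("record is missing field(s) required for the Framingham score: ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (f in c("age", "tc", "hdl", "sbp")) {
    if (any(!is.finite(record[[f]]) | record[[f]] <= 0))
      stop("field '", f, "' must be positive and finite for the Framingham score",
           call. = FALSE)
  }
}

#' Framingham linear predictor
#'
#' Sum of coefficient x transformed-covariate terms for the record's sex.
#' Smoking enters as current smoking only (never- and ex-smokers both score
#' zero on the smoking term).
#'
#' @param record A list or data.frame (vectorised over rows) with fields
#'   \code{sex} ("male"/"female"), \code{age} (years), \code{tc}, \code{hdl}
#'   (mg/dL), \code{sbp} (mmHg), \code{bp_treat} (0/1), \code{smoking}
#'   ("never"/"ex"/"current" or 0/1 current-smoker flag) and \code{diabetes}
#'   (0/1).
#' @param coeffs An \code{\link{frs_coefficients}} object.
#' @return Dimensionless linear predictor, one value per record.
#' @export
frs_linear_predictor <- function(record, coeffs = frs_coefficients()) {
  stopifnot(inherits(coeffs, "frs_coefficients"))
  frs_check_record(record)
  sex <- as.character(record$sex)
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'", call. = FALSE)
  smoker <- if (is.character(record$smoking) || is.factor(record$smoking)) {
    as.numeric(as.character(record$smoking) == "current")
  } else as.numeric(record$smoking)
  treated <- as.numeric(record$bp_treat)
  n <- length(sex)
  lp <- numeric(n)
  for (sx in c("male", "female")) {
    idx <- sex == sx
    if (!any(idx)) next
    b <- coeffs[[sx]]$beta
    lp[idx] <-
      b["log_age"] * log(record$age[idx]) +
      b["log_tc"]  * log(record$tc[idx]) +
      b["log_hdl"] * log(record$hdl[idx]) +
      ifelse(treated[idx] == 1,
             b["log_sbp_treated"] * log(record$sbp[idx]),
             b["log_sbp_untreated"] * log(record$sbp[idx])) +
      b["smoker"] * smoker[idx] +
      b["diabetes"] * as.numeric(record$diabetes[idx])
  }
  unname(lp)
}

#' Framingham 10-year cardiovascular risk
#'
#' risk = 1 - S0 ^ exp(lp - mean_lp), the Cox-model survival-function form.
#' Strictly increasing in the linear predictor and bounded in (0, 1).
#'
#' @inheritParams frs_linear_predictor
#' @return 10-year CVD risk in (0, 1), one value per record.
#' @examples
#' rec <- list(sex = "female", age = 61, tc = 180, hdl = 47, sbp = 124,
#'             bp_treat = 0, smoking = "current", diabetes = 0)
#' frs_risk10(rec)  # ~0.105
#' @export
frs_risk10 <- function(record, coeffs = frs_coefficients()) {
  lp <- frs_linear_predictor(record, coeffs)
  sex <- as.character(record$sex)
  s0 <- ifelse(sex == "male", coeffs$male$s0, coeffs$female$s0)
  mean_lp <- ifelse(sex == "male", coeffs$male$mean_lp, coeffs$female$mean_lp)
  unname(1 - s0^exp(lp - mean_lp))
}
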