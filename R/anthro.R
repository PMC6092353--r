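#' Anthropometry record
#'
#' Bundle one participant's waist circumference, weight and height in the
#' canonical units used throughout the package (metres / kilograms). Values
#' outside plausible adult ranges trigger a warning, not an error, so that
#' unusual but real measurements are never silently dropped.
#'
#' @param wc_m Waist circumference in metres.
#' @param weight_kg Body weight in kilograms.
#' @param height_m Standing height in metres.
#' @return A list of class \code{"anthropometry"} with the three fields.
#'   All arguments are vectorised; lengths are recycled by the usual rules.
#' @examples
#' anthropometry(0.825, 63.0, 1.60)
#' @export
anthropometry <- function(wc_m, weight_kg, height_m) {
  if (any(!is.finite(wc_m)) || any(!is.finite(weight_kg)) || any(!is.finite(height_m)))
    stop("anthropometry values must be finite", call. = FALSE)
  if (any(wc_m <= 0) || any(weight_kg <= 0) || any(height_m <= 0))
    stop("anthropometry values must be strictly positive", call. = FALSE)
  if (any(wc_m < 0.40 | wc_m > 1.80))
    warning("waist circumference outside plausible adult range (0.40-1.80 m)", call. = FALSE)
  if (any(weight_kg < 25 | weight_kg > 250))
    warning("weight outside plausible adult range (25-250 kg)", call. = FALSE)
  if (any(height_m < 1.20 | height_m > 2.20))
    warning("height outside plausible adult range (1.20-2.20 m)", call. = FALSE)
  structure(list(wc_m = wc_m, weight_kg = weight_kg, height_m = height_m),
            class = "anthropometry")
}

#' Allometric scaling coefficients for waist circumference
#'
#' The log-log model ln(WC) = c + a ln(weight) + b ln(height) + residual.
#' Defaults are the published Korean reference set (-2.69, 0.73, -1.06).
#'
#' @param intercept_c Log-scale intercept.
#' @param weight_exp_a Exponent on weight.
#' @param height_exp_b Exponent on height.
#' @param source_label Free-text provenance label.
#' @return A list of class \code{"allometric_coefficients"}.
#' @export
allometric_coefficients <- function(intercept_c = -2.69, weight_exp_a = 0.73,
                                    height_exp_b = -1.06,
                                    source_label = "korean_kns_2018") {
  vals <- c(intercept_c, weight_exp_a, height_exp_b)
  if (any(!is.finite(vals)))
    stop("allometric coefficients must be finite", call. = FALSE)
  structure(list(intercept_c = intercept_c, weight_exp_a = weight_exp_a,
                 height_exp_b = height_exp_b, source_label = source_label),
            class = "allometric_coefficients")
}

#' Standardization constants for LBSI
#'
#' Reference-population mean and standard deviation of LBSI used to form the
#' z-score. Defaults are the Korean reference values (-0.02, 0.06).
#'
#' @param mean_lbsi Reference mean of LBSI.
#' @param sd_lbsi Reference SD of LBSI; must be strictly positive.
#' @param source_label Free-text provenance label.
#' @return A list of class \code{"standardization_constants"}.
#' @export
standardization_constants <- function(mean_lbsi = -0.02, sd_lbsi = 0.06,
                                      source_label = "korean_kns_2018") {
  if (!is.finite(mean_lbsi) || !is.finite(sd_lbsi))
    stop("standardization constants must be finite", call. = FALSE)
  if (sd_lbsi <= 0)
    stop("sd_lbsi must be strictly positive", call. = FALSE)
  structure(list(mean_lbsi = mean_lbsi, sd_lbsi = sd_lbsi,
                 source_label = source_label),
            class = "standardization_constants")
}

#' Load a named reference coefficient set
#'
#' Reads the packaged table of published allometric and standardization
#' constants and returns the named set.
#'
#' @param name Set name; see the packaged file for available sets.
#' @param path Optional path to an alternative constants file with the same
#'   column layout.
#' @return A list with elements \code{coefficients}
#'   (\code{allometric_coefficients}) and \code{standardization}
#'   (\code{standardization_constants}).
#' @export
reference_constants <- function(name = "korean_kns_2018", path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_constants.csv", package = "lbsiz",
                        mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  row <- tab[tab$name == name, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown reference constant set: ", name,
         " (available: ", paste(tab$name, collapse = ", "), ")", call. = FALSE)
  list(
    coefficients = allometric_coefficients(row$intercept_c, row$weight_exp_a,
                                           row$height_exp_b, source_label = name),
    standardization = standardization_constants(row$mean_lbsi, row$sd_lbsi,
                                                source_label = name)
  )
}

#' Body mass index
#'
#' @param weight_kg Weight in kilograms.
#' @param height_m Height in metres.
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(63.0, 1.60)
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(weight_kg <= 0) || any(height_m <= 0))
    stop("weight and height must be strictly positive", call. = FALSE)
  weight_kg / height_m^2
}

#' A Body Shape Index (ABSI)
#'
#' The standard (Krakauer) definition is WC / (BMI^(2/3) * height^(1/2)),
#' equal to WC * height^(5/6) / weight^(2/3). Some sources print the formula
#' with the height exponent in the denominator, WC / (weight^(2/3) *
#' height^(5/6)); both conventions are available, and the non-standard one
#' warns when used so the choice is always explicit in logs.
#'
#' @param anthro An \code{\link{anthropometry}} object.
#' @param convention \code{"krakauer"} (default, the standard definition) or
#'   \code{"as_printed"} (height exponent in the denominator).
#' @return Dimensionless ABSI value(s).
#' @export
compute_absi <- function(anthro, convention = c("krakauer", "as_printed")) {
  stopifnot(inherits(anthro, "anthropometry"))
  convention <- match.arg(convention)
  w23 <- anthro$weight_kg^(2 / 3)
  h56 <- anthro$height_m^(5 / 6)
  if (convention == "krakauer") {
    anthro$wc_m * h56 / w23
  } else {
    warning("convention 'as_printed' places height^(5/6) in the denominator; ",
            "the standard ABSI definition is convention = 'krakauer'",
            call. = FALSE)
    anthro$wc_m / (w23 * h56)
  }
}

#' Fit allometric scaling exponents by log-log regression
#'
#' Ordinary least squares of ln(WC) on ln(weight) and ln(height) across a
#' cohort, the estimation step that produces population-specific ABSI
#' exponents.
#'
#' @param anthro An \code{\link{anthropometry}} object holding the cohort's
#'   vectors (or a data.frame with columns \code{wc_m}, \code{weight_kg},
#'   \code{height_m}).
#' @return A list with \code{coefficients}
#'   (\code{\link{allometric_coefficients}}), \code{r_squared},
#'   \code{residual_sd} (n - 3 denominator) and \code{n}.
#' @export
fit_allometric_exponents <- function(anthro) {
  if (is.data.frame(anthro))
    anthro <- anthropometry(anthro$wc_m, anthro$weight_kg, anthro$height_m)
  stopifnot(inherits(anthro, "anthropometry"))
  n <- length(anthro$wc_m)
  if (n < 3L)
    stop("at least 3 observations are required to fit the allometric model",
         call. = FALSE)
  lw <- log(anthro$weight_kg)
  lh <- log(anthro$height_m)
  X <- cbind(1, lw, lh)
  if (qr(X)$rank < 3L)
    stop("log(weight) and log(height) are collinear across the cohort; ",
         "the allometric exponents are not identifiable", call. = FALSE)
  fit <- stats::lm.fit(X, log(anthro$wc_m))
  cf <- unname(fit$coefficients)
  res <- fit$residuals
  tss <- sum((log(anthro$wc_m) - mean(log(anthro$wc_m)))^2)
  rss <- sum(res^2)
  list(
    coefficients = allometric_coefficients(cf[1], cf[2], cf[3],
                                           source_label = "fitted in-sample"),
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    residual_sd = if (n > 3L) sqrt(rss / (n - 3L)) else 0,
    n = n
  )
}

#' Log-transformed body shape index (LBSI)
#'
#' LBSI is the natural-log residual of waist circumference about its
#' allometric prediction: ln(WC) - c - a ln(weight) - b ln(height), with WC
#' and height in metres and weight in kilograms. With the Korean reference
#' coefficients a typical adult sits near the reference mean of -0.02.
#'
#' @param anthro An \code{\link{anthropometry}} object.
#' @param coeffs An \code{\link{allometric_coefficients}} object.
#' @return Dimensionless LBSI value(s).
#' @examples
#' compute_lbsi(anthropometry(0.825, 63.0, 1.60), allometric_coefficients())
#' @export
compute_lbsi <- function(anthro, coeffs = allometric_coefficients()) {
  stopifnot(inherits(anthro, "anthropometry"),
            inherits(coeffs, "allometric_coefficients"))
  log(anthro$wc_m) - coeffs$intercept_c -
    coeffs$weight_exp_a * log(anthro$weight_kg) -
    coeffs$height_exp_b * log(anthro$height_m)
}

#' Z-score of LBSI (LBSIZ)
#'
#' @param lbsi Numeric LBSI value(s).
#' @param constants A \code{\link{standardization_constants}} object.
#' @return LBSIZ, the z-score (lbsi - mean) / sd.
#' @export
standardize_lbsi <- function(lbsi, constants = standardization_constants()) {
  stopifnot(inherits(constants, "standardization_constants"))
  (lbsi - constants$mean_lbsi) / constants$sd_lbsi
}

#' Estimate standardization constants from a cohort
#'
#' Sample mean and sample SD (n - 1 denominator) of LBSI, for re-deriving the
#' z-score reference on a new population.
#'
#' @param lbsi Numeric vector of LBSI values, length >= 2.
#' @return A \code{\link{standardization_constants}} object.
#' @export
estimate_standardization <- function(lbsi) {
  if (length(lbsi) < 2L)
    stop("at least 2 values are required to estimate standardization constants",
         call. = FALSE)
  if (any(!is.finite(lbsi)))
    stop("LBSI values must be finite", call. = FALSE)
  s <- stats::sd(lbsi)
  if (s == 0)
    stop("LBSI values are constant; standardization is degenerate", call. = FALSE)
  standardization_constants(mean(lbsi), s, source_label = "estimated in-sample")
}

#' Friedewald LDL cholesterol
#'
#' LDL-C = TC - HDL-C - TG/5, all in mg/dL. The equation is not valid at
#' triglycerides >= 400 mg/dL; such inputs return NA with a warning rather
#' than a misleading value.
#'
#' @param tc Total cholesterol, mg/dL.
#' @param hdl HDL cholesterol, mg/dL.
#' @param tg Triglycerides, mg/dL.
#' @return LDL-C in mg/dL; NA where tg >= 400.
#' @examples
#' friedewald_ldl(190.4, 44.7, 160.8)
#' @export
friedewald_ldl <- function(tc, hdl, tg) {
  if (any(tc < 0) || any(hdl < 0) || any(tg < 0))
    stop("lipid concentrations must be non-negative", call. = FALSE)
  out <- tc - hdl - tg / 5
  bad <- tg >= 400
  if (any(bad)) {
    warning(sum(bad), " record(s) with triglycerides >= 400 mg/dL: ",
            "Friedewald LDL-C is not valid and is returned as NA", call. = FALSE)
    out[bad] <- NA_real_
  }
  out
}
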