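#' Follow-up time from calendar dates
#'
#' Years from the baseline examination to the event or to the administrative
#' end of follow-up (default 2012-12-31), whichever comes first, using the
#' days/365.25 convention. The event indicator is 1 only when an event date
#' exists and falls on or before the end of follow-up.
#'
#' @param baseline_date Baseline date (coerced with \code{as.Date}).
#' @param event_date Event date, or NA/NULL for no event. Vectorised.
#' @param end_of_followup Administrative censoring date.
#' @return A data.frame with columns \code{time} (years) and \code{event}.
#' @examples
#' follow_up_years("2002-01-01", NA)           # censored at 2012-12-31
#' follow_up_years("2002-01-01", "2003-01-01") # ~1 year, event = 1
#' @export
follow_up_years <- function(baseline_date, event_date = NA,
                            end_of_followup = as.Date("2012-12-31")) {
  baseline_date <- as.Date(baseline_date)
  end_of_followup <- as.Date(end_of_followup)
  if (is.null(event_date)) event_date <- as.Date(NA)
  event_date <- as.Date(event_date)
  k <- max(length(baseline_date), length(event_date))
  baseline_date <- rep_len(baseline_date, k)
  event_date <- rep_len(event_date, k)
  if (any(!is.na(event_date) & event_date < baseline_date))
    stop("event date precedes baseline date", call. = FALSE)
  if (any(baseline_date > end_of_followup))
    stop("baseline date is after the end of follow-up", call. = FALSE)
  event <- as.integer(!is.na(event_date) & event_date <= end_of_followup)
  stop_date <- end_of_followup
  stop_vec <- as.Date(ifelse(event == 1, event_date, stop_date),
                      origin = "1970-01-01")
  data.frame(time = as.numeric(stop_vec - baseline_date) / 365.25,
             event = event)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate with Greenwood-based 95% confidence intervals
#' (log-transformed, the survfit default).
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators.
#' @return A list of class \code{"km_fit"} with a \code{table} data.frame
#'   (time, n_risk, n_event, surv, lower, upper) and \code{surv_fn}, a
#'   right-continuous step function evaluating S(t).
#' @export
kaplan_meier <- function(times, events) {
  if (length(times) == 0L) stop("no observations", call. = FALSE)
  if (any(times <= 0)) stop("times must be strictly positive", call. = FALSE)
  sf <- survival::survfit(survival::Surv(times, events) ~ 1, conf.type = "log")
  tab <- data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                    surv = sf$surv, lower = sf$lower, upper = sf$upper)
  surv_fn <- stats::stepfun(sf$time, c(1, sf$surv), right = FALSE)
  structure(list(table = tab, surv_fn = surv_fn, n = length(times)),
            class = "km_fit")
}

#' Log-rank test
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators.
#' @param groups Group labels (>= 2 groups, each non-empty).
#' @return A list with \code{statistic} (chi-square), \code{df} and
#'   \code{p_value}.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    stop("log-rank test needs at least two groups", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood (Efron tie correction by default,
#' Breslow available) by Newton-Raphson, via \code{survival::coxph}. The
#' design matrix is checked for full column rank up front so collinear
#' covariates fail loudly instead of returning NA coefficients.
#'
#' @param data Data.frame with columns \code{time}, \code{event} and the
#'   covariates.
#' @param covariates Character vector of covariate column names.
#' @param ties "efron" or "breslow".
#' @return A list of class \code{"cox_fit"}: \code{coefficients},
#'   \code{vcov}, a \code{summary} data.frame (coef, se, hr and Wald 95% CI,
#'   z, p), \code{loglik} (partial log-likelihood at the solution),
#'   \code{iter}, \code{converged}, \code{ties}, \code{n}, \code{n_event}.
#' @export
fit_cox <- function(data, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event") %in% names(data)))
  if (sum(data$event) < 1L)
    stop("at least one event is required to fit a Cox model", call. = FALSE)
  X <- stats::model.matrix(
    stats::reformulate(covariates, intercept = FALSE),
    data = data)
  if (qr(X)$rank < ncol(X))
    stop("covariate matrix is rank-deficient (collinear covariates): ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  df <- data.frame(time = data$time, event = data$event, X,
                   check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = ties)
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  se <- sqrt(diag(V))
  summ <- data.frame(
    term = names(cf), coef = unname(cf), se = unname(se),
    hr = exp(unname(cf)),
    hr_lower = exp(unname(cf) - 1.96 * unname(se)),
    hr_upper = exp(unname(cf) + 1.96 * unname(se)),
    z = unname(cf / se),
    p = 2 * stats::pnorm(-abs(unname(cf / se))),
    row.names = NULL)
  structure(list(coefficients = cf, vcov = V, summary = summ,
                 loglik = fit$loglik[2], iter = fit$iter,
                 converged = is.null(fit$info) || fit$iter < fit$control$iter.max,
                 ties = ties, n = fit$n, n_event = fit$nevent),
            class = "cox_fit")
}

#' Decile group assignment
#'
#' Rank-based deciles: group d = ceiling(10 * rank / n) with minimum ranks
#' for ties, so tied values at a boundary all fall in the lower decile and
#' group sizes differ by at most one when there are no ties. Decile 1 holds
#' the smallest values.
#'
#' @param values Numeric vector, length >= 10, not all equal.
#' @return Integer vector of decile indices 1..10, with the decile
#'   boundaries (sample deciles) attached as attribute "boundaries".
#' @export
decile_groups <- function(values) {
  n <- length(values)
  if (n < 10L) stop("at least 10 values are required for deciles", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (max(values) == min(values))
    stop("all values are equal; decile boundaries are degenerate", call. = FALSE)
  r <- rank(values, ties.method = "min")
  d <- as.integer(ceiling(10 * r / n))
  d[d < 1L] <- 1L
  attr(d, "boundaries") <- stats::quantile(values, seq(0.1, 0.9, by = 0.1))
  d
}

#' Decile hazard ratios
#'
#' Cox model with indicator covariates for deciles 2..10 of the exposure
#' (decile 1 is the reference, HR fixed at 1) plus any adjusters.
#'
#' @param data Data.frame with \code{time}, \code{event}, the exposure and
#'   adjuster columns.
#' @param exposure Name of the exposure column to be deciled.
#' @param adjusters Character vector of adjuster column names (possibly
#'   empty for the unadjusted model).
#' @param ties Tie handling passed to \code{\link{fit_cox}}.
#' @return A list with \code{table} (decile, hr, hr_lower, hr_upper, p;
#'   decile 1 has hr = 1 and NA limits) and the underlying \code{fit}.
#' @export
decile_hazard_ratios <- function(data, exposure, adjusters = character(),
                                 ties = "efron") {
  d <- decile_groups(data[[exposure]])
  work <- data
  dcols <- character(9)
  for (k in 2:10) {
    nm <- paste0(".decile", k)
    work[[nm]] <- as.numeric(d == k)
    dcols[k - 1] <- nm
  }
  fit <- fit_cox(work, c(dcols, adjusters), ties = ties)
  s <- fit$summary
  idx <- match(dcols, s$term)
  tab <- data.frame(
    decile = 1:10,
    hr = c(1, s$hr[idx]),
    hr_lower = c(NA, s$hr_lower[idx]),
    hr_upper = c(NA, s$hr_upper[idx]),
    p = c(NA, s$p[idx]))
  list(table = tab, fit = fit)
}

#' Restricted cubic spline specification
#'
#' @param n_knots Number of knots (>= 3; default 4).
#' @param percentiles Knot placement percentiles in (0, 100); defaults to
#'   Harrell's recommended 5/35/65/95 for 4 knots.
#' @param reference Exposure value at which the hazard ratio is anchored to
#'   1; NULL (default) uses the sample median.
#' @return A list of class \code{"spline_spec"}.
#' @export
spline_spec <- function(n_knots = 4,
                        percentiles = NULL,
                        reference = NULL) {
  if (n_knots < 3) stop("a restricted cubic spline needs >= 3 knots", call. = FALSE)
  if (is.null(percentiles)) {
    percentiles <- switch(as.character(n_knots),
                          "3" = c(10, 50, 90),
                          "4" = c(5, 35, 65, 95),
                          "5" = c(5, 27.5, 50, 72.5, 95),
                          seq(5, 95, length.out = n_knots))
  }
  if (length(percentiles) != n_knots || is.unsorted(percentiles, strictly = TRUE))
    stop("percentiles must be strictly increasing with one per knot", call. = FALSE)
  structure(list(n_knots = n_knots, percentiles = percentiles,
                 reference = reference),
            class = "spline_spec")
}

#' Restricted cubic spline basis
#'
#' Harrell-convention truncated-power basis: the linear term plus k - 2
#' restricted cubic terms, each normalized by (t_k - t_1)^2, constrained to
#' be linear beyond the boundary knots. Below the first knot every nonlinear
#' column is exactly zero.
#'
#' @param x Numeric vector of exposure values.
#' @param knots Strictly increasing knot locations (length >= 3).
#' @return Matrix with length(x) rows and length(knots) - 1 columns; column
#'   1 is x itself.
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  if (k < 3) stop("need at least 3 knots", call. = FALSE)
  if (is.unsorted(knots, strictly = TRUE))
    stop("knots must be strictly increasing", call. = FALSE)
  cube <- function(u) pmax(u, 0)^3
  tk <- knots[k]; tk1 <- knots[k - 1]
  norm2 <- (tk - knots[1])^2
  B <- matrix(0, length(x), k - 1)
  B[, 1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    B[, j + 1] <- (cube(x - tj) -
                     cube(x - tk1) * (tk - tj) / (tk - tk1) +
                     cube(x - tk) * (tk1 - tj) / (tk - tk1)) / norm2
  }
  colnames(B) <- c("linear", paste0("rcs", seq_len(k - 2)))
  B
}

#' Adjusted spline hazard-ratio curve
#'
#' Fits a Cox model with a restricted-cubic-spline expansion of the exposure
#' plus adjusters, and returns the hazard-ratio curve
#' HR(x) = exp(f(x) - f(reference)) with delta-method (Wald) 95% confidence
#' intervals on the log scale, anchored to HR = 1 at the reference value.
#' Also reports the joint Wald test of the nonlinear spline terms (the test
#' of departure from log-linearity).
#'
#' @param data Data.frame with \code{time}, \code{event}, exposure,
#'   adjusters.
#' @param exposure Name of the exposure column.
#' @param adjusters Character vector of adjuster column names.
#' @param spec A \code{\link{spline_spec}}.
#' @param grid Evaluation grid; default 100 points spanning the 1st to 99th
#'   exposure percentiles.
#' @param ties Tie handling passed to \code{\link{fit_cox}}.
#' @return A list with \code{curve} (data.frame x, hr, hr_lower, hr_upper),
#'   \code{reference}, \code{knots}, \code{nonlinear_wald}
#'   (statistic, df, p_value) and the underlying \code{fit}.
#' @export
spline_hazard_curve <- function(data, exposure, adjusters = character(),
                                spec = spline_spec(), grid = NULL,
                                ties = "efron") {
  x <- data[[exposure]]
  knots <- unname(stats::quantile(x, spec$percentiles / 100, type = 7))
  if (any(duplicated(knots)))
    stop("tied knot locations; exposure has too little spread", call. = FALSE)
  reference <- if (is.null(spec$reference)) stats::median(x) else spec$reference
  if (is.null(grid))
    grid <- seq(stats::quantile(x, 0.01), stats::quantile(x, 0.99),
                length.out = 100)
  B <- rcs_basis(x, knots)
  scols <- paste0(".spl_", colnames(B))
  work <- data
  for (j in seq_along(scols)) work[[scols[j]]] <- B[, j]
  fit <- fit_cox(work, c(scols, adjusters), ties = ties)
  beta <- fit$coefficients[seq_along(scols)]
  V <- fit$vcov[seq_along(scols), seq_along(scols), drop = FALSE]
  Bg <- rcs_basis(grid, knots)
  Br <- rcs_basis(reference, knots)
  contrast <- sweep(Bg, 2, as.numeric(Br))
  log_hr <- as.numeric(contrast %*% beta)
  se <- sqrt(pmax(rowSums((contrast %*% V) * contrast), 0))
  # joint Wald test on the nonlinear terms
  nl <- seq(2, length(scols))
  bn <- beta[nl]
  Wn <- tryCatch(as.numeric(bn %*% solve(V[nl, nl, drop = FALSE], bn)),
                 error = function(e) NA_real_)
  list(
    curve = data.frame(x = grid, hr = exp(log_hr),
                       hr_lower = exp(log_hr - 1.96 * se),
                       hr_upper = exp(log_hr + 1.96 * se)),
    reference = reference, knots = knots,
    nonlinear_wald = list(statistic = Wn, df = length(nl),
                          p_value = stats::pchisq(Wn, length(nl),
                                                  lower.tail = FALSE)),
    fit = fit)
}
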