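cohort_required_cols <- c("sex", "age", "wc_m", "weight_kg", "height_m",
                          "event", "follow_up_years")
cohort_numeric_cols <- c("age", "wc_m", "weight_kg", "height_m", "sbp", "dbp",
                         "tc", "hdl", "tg", "ldl", "glucose", "hba1c",
                         "diabetes", "hypertension", "dyslipidaemia",
                         "bp_treat", "lipid_med", "event", "follow_up_years")

#' Validate a cohort table
#'
#' Checks the canonical-unit cohort layout shared by the simulator and the
#' analysis functions: required columns, strictly positive anthropometry and
#' follow-up, a binary event indicator, and (when the lipid panel is
#' present) LDL consistency with the Friedewald equation.
#'
#' @param cohort A data.frame of participant records in canonical units
#'   (metres, kg, mg/dL, years).
#' @return The validated data.frame, invisibly unchanged.
#' @export
validate_cohort <- function(cohort) {
  missing <- setdiff(cohort_required_cols, names(cohort))
  if (length(missing))
    stop("cohort is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!all(cohort$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'", call. = FALSE)
  if (any(cohort$wc_m <= 0 | cohort$weight_kg <= 0 | cohort$height_m <= 0))
    stop("anthropometry must be strictly positive", call. = FALSE)
  if (!all(cohort$event %in% c(0, 1)))
    stop("event must be 0/1", call. = FALSE)
  if (any(cohort$follow_up_years <= 0))
    stop("follow_up_years must be strictly positive", call. = FALSE)
  if (all(c("tc", "hdl", "tg", "ldl") %in% names(cohort))) {
    ok <- is.na(cohort$ldl) |
      abs(cohort$ldl - (cohort$tc - cohort$hdl - cohort$tg / 5)) < 1e-6
    if (!all(ok))
      stop(sum(!ok), " record(s) violate the Friedewald LDL identity",
           call. = FALSE)
  }
  if ("smoking" %in% names(cohort) &&
      !all(cohort$smoking %in% c("never", "ex", "current")))
    stop("smoking must be one of never/ex/current", call. = FALSE)
  invisible(cohort)
}

#' Write a cohort table as CSV
#'
#' Canonical cohort CSV dialect: UTF-8, header row, canonical column names,
#' canonical units (metres, kg, mg/dL, years).
#'
#' @param cohort A validated cohort data.frame.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Load and normalize a cohort CSV
#'
#' Reads a cohort file, renames columns to the canonical names through an
#' optional column map, converts waist circumference and height to metres
#' when supplied in centimetres, drops records with missing required fields
#' (with a message reporting the count), and validates the result. Loading
#' a file already in canonical units is idempotent.
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector mapping canonical names
#'   (names) to the file's headers (values).
#' @param units List with elements \code{wc} and \code{height}, each
#'   \code{"m"} or \code{"cm"}.
#' @return A validated cohort data.frame in canonical units.
#' @export
load_cohort <- function(path, column_map = NULL,
                        units = list(wc = "m", height = "m")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(tab))
        stop("column '", src, "' (for '", canon, "') not found; available: ",
             paste(names(tab), collapse = ", "), call. = FALSE)
      names(tab)[names(tab) == src] <- canon
    }
  }
  missing <- setdiff(cohort_required_cols, names(tab))
  if (length(missing))
    stop("cohort file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (identical(units$wc, "cm")) tab$wc_m <- tab$wc_m / 100
  if (identical(units$height, "cm")) tab$height_m <- tab$height_m / 100
  complete <- stats::complete.cases(tab[cohort_required_cols])
  if (any(!complete)) {
    message(sum(!complete), " record(s) with incomplete required fields excluded")
    tab <- tab[complete, , drop = FALSE]
  }
  if (nrow(tab) == 0L)
    stop("no complete records remain after exclusions", call. = FALSE)
  validate_cohort(tab)
  tab
}

#' Score a cohort with the obesity indices and Framingham risk
#'
#' Adds BMI, waist circumference in cm, ABSI, LBSI, LBSIZ, the Framingham
#' linear predictor and 10-year risk as columns.
#'
#' @param cohort A validated cohort data.frame.
#' @param constants A list with \code{coefficients} and
#'   \code{standardization} as returned by \code{\link{reference_constants}}.
#' @param frs An \code{\link{frs_coefficients}} object.
#' @return The cohort with score columns \code{bmi}, \code{wc_cm},
#'   \code{absi}, \code{lbsi}, \code{lbsiz}, \code{frs_lp}, \code{frs_risk}
#'   appended.
#' @export
score_cohort <- function(cohort,
                         constants = list(
                           coefficients = allometric_coefficients(),
                           standardization = standardization_constants()),
                         frs = frs_coefficients()) {
  validate_cohort(cohort)
  anthro <- anthropometry(cohort$wc_m, cohort$weight_kg, cohort$height_m)
  cohort$bmi <- compute_bmi(cohort$weight_kg, cohort$height_m)
  cohort$wc_cm <- cohort$wc_m * 100
  cohort$absi <- compute_absi(anthro)
  cohort$lbsi <- compute_lbsi(anthro, constants$coefficients)
  cohort$lbsiz <- standardize_lbsi(cohort$lbsi, constants$standardization)
  if (all(frs_required_fields %in% names(cohort))) {
    cohort$frs_lp <- frs_linear_predictor(cohort, frs)
    cohort$frs_risk <- frs_risk10(cohort, frs)
  }
  cohort
}

summarise_continuous <- function(x0, x1, var_equal = TRUE) {
  fmt <- function(x) sprintf("%.1f ± %.1f", mean(x), stats::sd(x))
  p <- if (stats::sd(x0) == 0 && stats::sd(x1) == 0) {
    NA_real_
  } else {
    stats::t.test(x0, x1, var.equal = var_equal)$p.value
  }
  list(g0 = fmt(x0), g1 = fmt(x1), p = p)
}

#' Baseline characteristics table
#'
#' Group-wise summary in the conventional cohort-paper layout: mean +/- SD
#' with an independent two-sample t-test for continuous variables, n (%)
#' with Pearson's chi-square for categoricals, compared across the two
#' levels of the grouping column (by default the event indicator).
#'
#' @param cohort A cohort data.frame (scored or not).
#' @param group Name of the binary grouping column.
#' @param var_equal Use the classical equal-variance t-test (default); set
#'   FALSE for Welch.
#' @param yates Apply Yates continuity correction to 2x2 chi-square tables.
#' @return A data.frame with variable, level, the two group summaries and p.
#' @export
baseline_table <- function(cohort, group = "event", var_equal = TRUE,
                           yates = FALSE) {
  g <- cohort[[group]]
  lv <- sort(unique(g))
  if (length(lv) != 2L) stop("grouping column must have two levels", call. = FALSE)
  i0 <- g == lv[1]; i1 <- g == lv[2]
  cont <- intersect(c("age", "bmi", "wc_cm", "lbsiz", "sbp", "dbp", "glucose",
                      "hba1c", "tc", "hdl", "tg", "ldl"), names(cohort))
  cat_vars <- intersect(c("sex", "smoking", "diabetes", "hypertension",
                          "dyslipidaemia"), names(cohort))
  rows <- list()
  n0 <- sum(i0); n1 <- sum(i1)
  for (v in cont) {
    x0 <- cohort[[v]][i0]; x1 <- cohort[[v]][i1]
    keep <- stats::complete.cases(x0); x0 <- x0[keep]
    keep <- stats::complete.cases(x1); x1 <- x1[keep]
    s <- summarise_continuous(x0, x1, var_equal)
    rows[[length(rows) + 1L]] <-
      data.frame(variable = v, level = "", group0 = s$g0, group1 = s$g1, p = s$p)
  }
  for (v in cat_vars) {
    f <- as.factor(cohort[[v]])
    tab <- table(f, g)
    p <- if (any(rowSums(tab) == 0) || nlevels(f) < 2) NA_real_ else
      suppressWarnings(stats::chisq.test(tab, correct = yates)$p.value)
    for (l in levels(f)) {
      c0 <- sum(f[i0] == l); c1 <- sum(f[i1] == l)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = l,
        group0 = sprintf("%d (%.1f%%)", c0, 100 * c0 / n0),
        group1 = sprintf("%d (%.1f%%)", c1, 100 * c1 / n1),
        p = p)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "group_sizes") <- c(n0, n1)
  out
}

#' Spearman correlations of LBSIZ with the other anthropometric measures
#'
#' @param cohort A cohort data.frame; scored columns are added if absent.
#' @return A data.frame with the midrank Spearman rho of LBSIZ against
#'   waist circumference, BMI, weight and height.
#' @export
index_correlations <- function(cohort) {
  if (!"lbsiz" %in% names(cohort)) cohort <- score_cohort(cohort)
  if (nrow(cohort) < 3L) stop("need at least 3 records", call. = FALSE)
  pairs <- c(wc = "wc_cm", bmi = "bmi", weight = "weight_kg",
             height = "height_m")
  rho <- vapply(pairs, function(col) {
    y <- cohort[[col]]
    if (stats::sd(y) == 0 || stats::sd(cohort$lbsiz) == 0) {
      warning("constant column; Spearman rho undefined for ", col, call. = FALSE)
      return(NA_real_)
    }
    stats::cor(cohort$lbsiz, y, method = "spearman")
  }, 0)
  data.frame(measure = names(pairs), rho = unname(rho))
}

default_adjusters <- function(scored) {
  scored$sex_male <- as.numeric(scored$sex == "male")
  scored$smoking_ex <- as.numeric(scored$smoking == "ex")
  scored$smoking_current <- as.numeric(scored$smoking == "current")
  scored
}

adjuster_cols <- c("age", "sex_male", "smoking_ex", "smoking_current", "sbp",
                   "hypertension", "diabetes", "ldl", "lipid_med")

#' Run the full cohort analysis
#'
#' End-to-end pipeline on a synthetic or loaded cohort: scores every
#' participant (BMI, WC, LBSIZ, Framingham), builds the baseline
#' characteristics table, the LBSIZ correlation table, the ROC/AUC table
#' with paired DeLong comparisons and Framingham-plus-parameter integrated
#' AUCs, Kaplan-Meier curves with log-rank tests per obesity grouping,
#' adjusted decile hazard ratios, and adjusted restricted-cubic-spline
#' hazard curves. Fully deterministic given the configuration (the
#' simulator's seed lives in the config).
#'
#' @param config A \code{\link{cohort_config}} (the cohort is simulated) or
#'   a path to a cohort CSV in canonical units.
#' @param output_dir Optional directory; when given the report bundle is
#'   written there via \code{\link{write_report}}.
#' @param exposures Score columns analysed as obesity measures.
#' @param adjusters Adjuster columns for the decile and spline models
#'   (defaults to age, sex, smoking, systolic blood pressure, hypertension,
#'   diabetes, LDL cholesterol and lipid medication).
#' @param km_cutoffs List of dichotomization rules for the Kaplan-Meier
#'   groupings: \code{bmi} (kg/m^2), \code{wc_male}/\code{wc_female} (cm),
#'   \code{lbsiz}.
#' @return A list of class \code{"analysis_report"}; see the individual
#'   table components.
#' @export
run_full_analysis <- function(config = cohort_config(), output_dir = NULL,
                              exposures = c("bmi", "wc_cm", "lbsiz"),
                              adjusters = adjuster_cols,
                              km_cutoffs = list(bmi = 25, wc_male = 90,
                                                wc_female = 85, lbsiz = 0)) {
  cohort <- if (inherits(config, "cohort_config")) {
    generate_cohort(config)
  } else if (is.character(config)) {
    load_cohort(config)
  } else stop("config must be a cohort_config or a CSV path", call. = FALSE)

  scored <- default_adjusters(score_cohort(cohort))
  scored$time <- scored$follow_up_years

  baseline <- baseline_table(scored)
  correlations <- index_correlations(scored)

  # --- discrimination ---------------------------------------------------
  score_set <- c(exposures, if ("frs_lp" %in% names(scored)) "frs_lp")
  rocs <- lapply(score_set, function(s) roc_curve(scored[[s]], scored$event))
  names(rocs) <- score_set
  auc_table <- do.call(rbind, lapply(score_set, function(s) {
    r <- rocs[[s]]
    se <- sqrt(r$auc_var)
    data.frame(score = s, auc = r$auc,
               ci_lower = max(0, r$auc - 1.96 * se),
               ci_upper = min(1, r$auc + 1.96 * se))
  }))
  cmp <- list()
  for (other in setdiff(exposures, "lbsiz")) {
    d <- delong_compare(scored$lbsiz, scored[[other]], scored$event)
    cmp[[length(cmp) + 1L]] <- data.frame(
      comparison = paste0("lbsiz_vs_", other), delta_auc = d$delta_auc,
      z = d$z, p = d$p_value)
  }
  integrated <- NULL
  if ("frs_lp" %in% names(scored)) {
    integrated <- do.call(rbind, lapply(exposures, function(s) {
      ia <- integrated_auc(scored$frs_lp, scored[[s]], scored$event)
      data.frame(parameter = s, auc_frs = ia$auc_base,
                 auc_integrated = ia$auc_combined,
                 delta_auc = ia$comparison$delta_auc,
                 p = ia$comparison$p_value)
    }))
  }
  auc_comparisons <- if (length(cmp)) do.call(rbind, cmp) else NULL

  # --- Kaplan-Meier by obesity grouping --------------------------------
  km_groups <- list(
    bmi = scored$bmi >= km_cutoffs$bmi,
    wc_cm = ifelse(scored$sex == "male",
                   scored$wc_cm >= km_cutoffs$wc_male,
                   scored$wc_cm >= km_cutoffs$wc_female),
    lbsiz = scored$lbsiz >= km_cutoffs$lbsiz)
  km <- lapply(names(km_groups), function(nm) {
    grp <- km_groups[[nm]]
    lr <- logrank_test(scored$time, scored$event, grp)
    curves <- do.call(rbind, lapply(c(FALSE, TRUE), function(obese) {
      kt <- kaplan_meier(scored$time[grp == obese],
                         scored$event[grp == obese])$table
      kt$group <- ifelse(obese, "obese", "non_obese")
      kt
    }))
    list(measure = nm, logrank = lr, curves = curves)
  })
  names(km) <- names(km_groups)
  km_table <- do.call(rbind, lapply(km, function(k)
    data.frame(measure = k$measure, chisq = k$logrank$statistic,
               df = k$logrank$df, p = k$logrank$p_value)))

  # --- decile hazard ratios --------------------------------------------
  deciles <- lapply(exposures, function(s) {
    dh <- decile_hazard_ratios(scored, s, adjusters)
    tab <- dh$table
    tab$measure <- s
    tab
  })
  decile_table <- do.call(rbind, deciles)

  # --- spline hazard curves --------------------------------------------
  splines <- lapply(exposures, function(s) {
    sp <- spline_hazard_curve(scored, s, adjusters)
    sp$curve$measure <- s
    sp
  })
  names(splines) <- exposures
  spline_table <- do.call(rbind, lapply(splines, `[[`, "curve"))
  spline_tests <- do.call(rbind, lapply(exposures, function(s) {
    w <- splines[[s]]$nonlinear_wald
    data.frame(measure = s, statistic = w$statistic, df = w$df,
               p_nonlinear = w$p_value)
  }))

  meta <- list(
    package_version = as.character(utils::packageVersion("lbsiz")),
    seed = if (inherits(config, "cohort_config")) config$seed else NA,
    n = nrow(scored), n_event = sum(scored$event),
    config = if (inherits(config, "cohort_config")) {
      cfg <- unclass(config)
      cfg$coefficients <- unclass(cfg$coefficients)
      cfg
    } else list(path = config))

  report <- list(cohort = scored, baseline = baseline,
                 correlations = correlations,
                 auc_table = auc_table, auc_comparisons = auc_comparisons,
                 integrated_auc = integrated,
                 km = km, km_table = km_table,
                 decile_table = decile_table,
                 spline_table = spline_table, spline_tests = spline_tests,
                 splines = splines,
                 metadata = meta)
  class(report) <- "analysis_report"
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' Write an analysis report bundle
#'
#' Serializes every report table as CSV plus a metadata JSON, so a run is
#' fully re-creatable and diffable.
#'
#' @param report An \code{analysis_report} from \code{\link{run_full_analysis}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(tab, name) {
    if (!is.null(tab))
      utils::write.csv(tab, file.path(dir, paste0(name, ".csv")),
                       row.names = FALSE)
  }
  wr(report$baseline, "baseline")
  wr(report$correlations, "correlations")
  wr(report$auc_table, "auc")
  wr(report$auc_comparisons, "auc_comparisons")
  wr(report$integrated_auc, "integrated_auc")
  wr(report$km_table, "logrank")
  wr(do.call(rbind, lapply(report$km, function(k) {
    k$curves$measure <- k$measure
    k$curves
  })), "km_curves")
  wr(report$decile_table, "decile_hr")
  wr(report$spline_table, "spline_hr")
  wr(report$spline_tests, "spline_nonlinearity")
  jsonlite::write_json(report$metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Cohort analysis report\n")
  cat(sprintf("  n = %d participants, %d events (%.1f%%)\n",
              x$metadata$n, x$metadata$n_event,
              100 * x$metadata$n_event / x$metadata$n))
  cat("  AUC:", paste(sprintf("%s %.3f", x$auc_table$score, x$auc_table$auc),
                      collapse = ", "), "\n")
  if (!is.null(x$auc_comparisons))
    cat("  DeLong:", paste(sprintf("%s p=%.3g", x$auc_comparisons$comparison,
                                   x$auc_comparisons$p),
                           collapse = ", "), "\n")
  invisible(x)
}
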