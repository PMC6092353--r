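#' Plot ROC curves from an analysis report
#'
#' Base-graphics ROC overlay of the obesity measures (and Framingham score
#' when present).
#'
#' @param report An \code{analysis_report}.
#' @param scores Which scores to draw; defaults to every score in the AUC
#'   table.
#' @return Invisibly, NULL; called for the plot side effect.
#' @export
plot_roc_curves <- function(report, scores = report$auc_table$score) {
  plot(0:1, 0:1, type = "l", lty = 3, col = "grey50",
       xlab = "1 - specificity", ylab = "Sensitivity", main = "ROC curves")
  cols <- seq_along(scores) + 1
  for (i in seq_along(scores)) {
    rc <- roc_curve(report$cohort[[scores[i]]], report$cohort$event)
    lines(rc$curve$fpr, rc$curve$sensitivity, col = cols[i], lwd = 2)
  }
  legend("bottomright",
         legend = sprintf("%s (AUC %.3f)", scores,
                          report$auc_table$auc[match(scores,
                                                     report$auc_table$score)]),
         col = cols, lwd = 2, bty = "n")
  invisible(NULL)
}

#' Plot Kaplan-Meier curves for one obesity grouping
#'
#' @param report An \code{analysis_report}.
#' @param measure One of the grouping measures in the report (e.g. "lbsiz").
#' @return Invisibly, NULL.
#' @export
plot_km_curves <- function(report, measure = "lbsiz") {
  k <- report$km[[measure]]
  if (is.null(k)) stop("no KM grouping for measure: ", measure, call. = FALSE)
  plot(NULL, xlim = c(0, max(k$curves$time)),
       ylim = c(min(k$curves$surv) * 0.995, 1),
       xlab = "Years of follow-up", ylab = "Event-free survival",
       main = sprintf("Kaplan-Meier by %s (log-rank p = %.3g)",
                      measure, k$logrank$p_value))
  for (g in unique(k$curves$group)) {
    sub <- k$curves[k$curves$group == g, ]
    lines(stats::stepfun(sub$time, c(1, sub$surv)),
          col = if (g == "obese") 2 else 4, do.points = FALSE, lwd = 2)
  }
  legend("bottomleft", legend = c("non-obese", "obese"), col = c(4, 2),
         lwd = 2, bty = "n")
  invisible(NULL)
}

#' Plot an adjusted spline hazard-ratio curve
#'
#' @param report An \code{analysis_report}.
#' @param measure Exposure name (e.g. "bmi").
#' @return Invisibly, NULL.
#' @export
plot_spline_curve <- function(report, measure = "bmi") {
  sp <- report$splines[[measure]]
  if (is.null(sp)) stop("no spline curve for measure: ", measure, call. = FALSE)
  cu <- sp$curve
  plot(cu$x, cu$hr, type = "l", lwd = 2, log = "y",
       ylim = range(c(cu$hr_lower, cu$hr_upper)),
       xlab = measure, ylab = "Adjusted hazard ratio",
       main = sprintf("Dose-response for %s", measure))
  lines(cu$x, cu$hr_lower, lty = 2)
  lines(cu$x, cu$hr_upper, lty = 2)
  abline(h = 1, col = "grey60")
  rug(sp$knots)
  invisible(NULL)
}
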