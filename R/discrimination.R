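check_binary_labels <- function(labels) {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || !all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  labels
}

# Midrank placement values: V10[i] = P-hat(score of case i beats a random
# control), V01[j] = P-hat(a random case beats control j); ties count 1/2.
# mean(V10) = mean(V01) = the Mann-Whitney AUC.
delong_placements <- function(scores, labels) {
  m <- sum(labels == 1L)
  n <- sum(labels == 0L)
  r_all <- rank(scores, ties.method = "average")
  r_case <- rank(scores[labels == 1L], ties.method = "average")
  r_ctrl <- rank(scores[labels == 0L], ties.method = "average")
  v10 <- (r_all[labels == 1L] - r_case) / n
  v01 <- 1 - (r_all[labels == 0L] - r_ctrl) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Mann-Whitney AUC
#'
#' Probability that a randomly chosen case outscores a randomly chosen
#' control, with ties counted one half (midranks). Invariant under strictly
#' increasing transforms of the scores.
#'
#' @param scores Numeric scores, higher = more case-like.
#' @param labels Binary 0/1 outcome, both classes present.
#' @return AUC in [0, 1].
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have the same length", call. = FALSE)
  delong_placements(scores, labels)$auc
}

#' Empirical ROC curve
#'
#' Sensitivity and specificity at every distinct score threshold, the
#' trapezoidal area under the curve, the midrank Mann-Whitney AUC (equal to
#' the trapezoidal area by construction), and the DeLong variance of the
#' AUC. The per-subject placement components are retained for paired
#' comparisons.
#'
#' @inheritParams auc_mann_whitney
#' @return A list of class \code{"roc_result"} with \code{curve} (threshold,
#'   sensitivity, specificity, fpr), \code{auc}, \code{auc_var} (DeLong),
#'   and \code{placements}.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have the same length", call. = FALSE)
  m <- sum(labels == 1L); n <- sum(labels == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  idx <- cumsum(rle(s)$lengths)  # last index of each distinct threshold
  sens <- cumsum(l == 1L)[idx] / m
  fpr <- cumsum(l == 0L)[idx] / n
  curve <- data.frame(threshold = c(Inf, s[idx]),
                      sensitivity = c(0, sens),
                      specificity = c(1, 1 - fpr),
                      fpr = c(0, fpr))
  pl <- delong_placements(scores, labels)
  v10 <- pl$v10; v01 <- pl$v01
  auc_var <- stats::var(v10) / m + stats::var(v01) / n
  trap <- sum(diff(curve$fpr) *
                (utils::head(curve$sensitivity, -1) +
                   utils::tail(curve$sensitivity, -1)) / 2)
  structure(list(curve = curve, auc = pl$auc, auc_trapezoid = trap,
                 auc_var = auc_var, placements = pl,
                 n_case = m, n_control = n),
            class = "roc_result")
}

#' DeLong comparison of two correlated AUCs
#'
#' Paired comparison of the AUCs of two scores measured on the same
#' subjects, using DeLong's structural-component covariance estimate. The
#' z statistic is (AUC_a - AUC_b) / sqrt(var), with a two-sided normal
#' p-value. When both scores rank the subjects identically the difference
#' and its variance are both zero; that degenerate case returns z = 0,
#' p = 1.
#'
#' @param scores_a,scores_b Two score vectors on the same subjects.
#' @param labels Binary 0/1 outcome.
#' @return A list with \code{auc_a}, \code{auc_b}, \code{delta_auc},
#'   \code{var_delta}, \code{z} and \code{p_value}.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  labels <- check_binary_labels(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels))
    stop("scores_a, scores_b and labels must have the same length", call. = FALSE)
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- sum(labels == 1L); n <- sum(labels == 0L)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- pa$auc - pb$auc
  if (var_delta <= .Machine$double.eps) {
    z <- if (abs(delta) <= .Machine$double.eps) 0 else sign(delta) * Inf
  } else {
    z <- delta / sqrt(var_delta)
  }
  list(auc_a = pa$auc, auc_b = pb$auc, delta_auc = delta,
       var_delta = var_delta, z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Integrated AUC of a base risk score plus one parameter
#'
#' Combines a base score (e.g. the Framingham linear predictor) with an
#' additional parameter through a maximum-likelihood logistic regression of
#' the event indicator on both, takes the fitted linear predictor as the
#' combined score, and compares its AUC against the base score alone with
#' the paired DeLong test.
#'
#' @param base_scores Base risk score (linear-predictor scale).
#' @param parameter_values Additional parameter to integrate.
#' @param labels Binary 0/1 outcome.
#' @return A list with \code{auc_base}, \code{auc_combined},
#'   \code{combined_scores}, the logistic \code{coefficients}, and the
#'   DeLong \code{comparison} of combined vs base.
#' @export
integrated_auc <- function(base_scores, parameter_values, labels) {
  labels <- check_binary_labels(labels)
  if (length(base_scores) != length(labels) ||
      length(parameter_values) != length(labels))
    stop("all inputs must have the same length", call. = FALSE)
  fit <- stats::glm(labels ~ base_scores + parameter_values,
                    family = stats::binomial())
  if (!fit$converged)
    stop("logistic combination model failed to converge", call. = FALSE)
  combined <- as.numeric(stats::predict(fit, type = "link"))
  cmp <- delong_compare(combined, base_scores, labels)
  list(auc_base = cmp$auc_b, auc_combined = cmp$auc_a,
       combined_scores = combined,
       coefficients = stats::coef(fit),
       comparison = cmp)
}
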