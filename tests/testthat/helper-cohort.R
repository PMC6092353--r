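# shared fixtures, built in code

small_cohort <- function(n = 200, seed = 42, ...) {
  generate_cohort(cohort_config(n = n, seed = seed, ...))
}

# hand-coded Cox partial log-likelihood for an untied single-covariate
# sample, used as the brute-force oracle
partial_loglik_1cov <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# delete-one jackknife variance of the paired AUC difference
jackknife_var_delta_auc <- function(scores_a, scores_b, labels) {
  n <- length(labels)
  theta <- vapply(seq_len(n), function(i) {
    auc_mann_whitney(scores_a[-i], labels[-i]) -
      auc_mann_whitney(scores_b[-i], labels[-i])
  }, 0)
  (n - 1) / n * sum((theta - mean(theta))^2)
}
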