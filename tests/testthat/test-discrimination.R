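test_that("AUC matches exhaustive pair counting on toys", {
  expect_equal(auc_mann_whitney(c(0.9, 0.6, 0.7, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc_mann_whitney(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_mann_whitney(rep(3, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(auc_mann_whitney(1:4, c(1, 1, 1, 1)), "both classes")
  expect_error(auc_mann_whitney(1:4, c(1, 0, 2, 0)), "binary")
})

test_that("trapezoidal ROC area equals the midrank Mann-Whitney AUC", {
  set.seed(20)
  for (i in 1:5) {
    n <- sample(30:120, 1)
    scores <- round(rnorm(n), i %% 3)  # coarse rounding induces ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    r <- roc_curve(scores, labels)
    expect_equal(r$auc_trapezoid, r$auc, tolerance = 1e-12)
    expect_true(all(diff(r$curve$sensitivity) >= 0))
    expect_true(all(diff(r$curve$fpr) >= 0))
  }
})

test_that("ROC/AUC agree with an independent implementation", {
  set.seed(21)
  scores <- rnorm(300)
  labels <- rbinom(300, 1, 0.3)
  r <- roc_curve(scores, labels)
  p <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(p)), tolerance = 1e-12)
  expect_equal(r$auc_var, as.numeric(pROC::var(p, method = "delong")),
               tolerance = 1e-10)
})

test_that("AUC is invariant under strictly monotone transforms", {
  co <- small_cohort(n = 500, seed = 30)
  sc <- score_cohort(co)
  a1 <- auc_mann_whitney(sc$lbsiz, sc$event)
  expect_equal(auc_mann_whitney(sc$lbsi, sc$event), a1, tolerance = 1e-12)
  # ABSI with the same exponents is exp(LBSI) up to a constant factor
  expect_equal(auc_mann_whitney(exp(sc$lbsi), sc$event), a1, tolerance = 1e-12)
  expect_equal(auc_mann_whitney(qlogis(plogis(sc$lbsiz)), sc$event), a1,
               tolerance = 1e-12)
})

test_that("the paired DeLong test is degenerate-safe and antisymmetric", {
  set.seed(22)
  s <- rnorm(80)
  l <- rbinom(80, 1, 0.5)
  same <- delong_compare(s, s, l)
  expect_equal(same$delta_auc, 0)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  mono <- delong_compare(s, exp(s) + 3, l)
  expect_equal(mono$delta_auc, 0)
  expect_equal(mono$p_value, 1)

  s2 <- rnorm(80)
  ab <- delong_compare(s, s2, l)
  ba <- delong_compare(s2, s, l)
  expect_equal(ab$delta_auc, -ba$delta_auc)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("DeLong variance agrees with the delete-one jackknife on small data", {
  set.seed(23)
  labels <- rep(c(1, 0), c(8, 12))
  scores_a <- rnorm(20) + labels
  scores_b <- rnorm(20) + 0.5 * labels
  d <- delong_compare(scores_a, scores_b, labels)
  vj <- jackknife_var_delta_auc(scores_a, scores_b, labels)
  expect_lt(abs(d$var_delta - vj) / vj, 0.10)
})

test_that("DeLong comparison agrees with an independent implementation", {
  set.seed(24)
  l <- rbinom(150, 1, 0.4)
  a <- rnorm(150) + l
  b <- rnorm(150) + 0.8 * l
  d <- delong_compare(a, b, l)
  rt <- pROC::roc.test(pROC::roc(l, a, quiet = TRUE, direction = "<"),
                       pROC::roc(l, b, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(d$p_value, rt$p.value, tolerance = 1e-10)
  expect_equal(unname(d$z), unname(rt$statistic), tolerance = 1e-10)
})

test_that("integrated AUC improves on the base score given independent signal", {
  set.seed(25)
  wins <- replicate(20, {
    n <- 3000
    base <- rnorm(n)
    extra <- rnorm(n)
    p <- plogis(-2.5 + 0.8 * base + 0.8 * extra)
    y <- rbinom(n, 1, p)
    ia <- integrated_auc(base, extra, y)
    ia$auc_combined > ia$auc_base
  })
  expect_gte(mean(wins), 0.95)
})

test_that("a pure-noise parameter leaves the integrated AUC unchanged", {
  set.seed(26)
  n <- 8000
  base <- rnorm(n)
  y <- rbinom(n, 1, plogis(-2.5 + 0.9 * base))
  ia <- integrated_auc(base, rnorm(n), y)
  expect_lt(abs(ia$auc_combined - ia$auc_base), 0.01)
  # in-sample, the fitted combination never discriminates worse
  expect_gte(ia$auc_combined, ia$auc_base - 1e-9)
})
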