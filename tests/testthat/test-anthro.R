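test_that("BMI is weight over height squared with domain checks", {
  expect_equal(compute_bmi(80, 2.0), 20.0)
  expect_equal(compute_bmi(63.0, 1.60), 63 / 2.56, tolerance = 1e-12)
  expect_equal(compute_bmi(1, 1), 1)
  expect_error(compute_bmi(-1, 1.7), "positive")
  expect_error(compute_bmi(70, 0), "positive")
})

test_that("ABSI conventions evaluate correctly and respond to WC", {
  unit <- suppressWarnings(anthropometry(1, 1, 1))
  expect_equal(compute_absi(unit, "krakauer"), 1)
  expect_equal(suppressWarnings(compute_absi(unit, "as_printed")), 1)
  a <- anthropometry(0.90, 80, 1.75)
  expect_equal(compute_absi(a, "krakauer"),
               0.90 * 1.75^(5 / 6) / 80^(2 / 3), tolerance = 1e-12)
  expect_equal(round(compute_absi(a, "krakauer"), 4), 0.0773)
  wider <- anthropometry(0.95, 80, 1.75)
  expect_gt(compute_absi(wider), compute_absi(a))
  expect_warning(compute_absi(a, "as_printed"), "denominator")
  expect_error(compute_absi(a, "typo"))
})

test_that("anthropometry validates positivity and warns on implausible values", {
  expect_error(anthropometry(-0.8, 70, 1.7), "positive")
  expect_warning(anthropometry(0.3, 70, 1.7), "waist")
  expect_warning(anthropometry(0.8, 300, 1.7), "weight")
  expect_silent(anthropometry(0.825, 63, 1.60))
})

test_that("noise-free allometric data recover the generating exponents exactly", {
  set.seed(1)
  w <- runif(50, 45, 100)
  h <- runif(50, 1.45, 1.90)
  wc <- exp(-2.69) * w^0.73 * h^-1.06
  fit <- fit_allometric_exponents(anthropometry(wc, w, h))
  expect_equal(fit$coefficients$intercept_c, -2.69, tolerance = 1e-10)
  expect_equal(fit$coefficients$weight_exp_a, 0.73, tolerance = 1e-10)
  expect_equal(fit$coefficients$height_exp_b, -1.06, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # three non-collinear points interpolate exactly
  fit3 <- fit_allometric_exponents(anthropometry(wc[1:3], w[1:3], h[1:3]))
  expect_equal(fit3$residual_sd, 0, tolerance = 1e-10)
})

test_that("allometric fit rejects insufficient or collinear data", {
  expect_error(fit_allometric_exponents(anthropometry(c(0.8, 0.9), c(60, 70),
                                                      c(1.6, 1.7))),
               "at least 3")
  w <- c(60, 70, 80, 90)
  h <- w / 50  # log-collinear with weight up to a constant
  expect_error(fit_allometric_exponents(anthropometry(rep(0.8, 4), w, h)),
               "collinear")
})

test_that("LBSI is the log residual about the allometric prediction", {
  cf <- allometric_coefficients()
  # identity case: WC exactly on the allometric surface
  wc <- exp(-2.69) * 70^0.73 * 1.7^-1.06
  expect_equal(compute_lbsi(anthropometry(wc, 70, 1.7), cf), 0, tolerance = 1e-12)
  # printed-constant evaluation near the reference mean
  lbsi <- compute_lbsi(anthropometry(0.825, 63.0, 1.60), cf)
  expect_equal(lbsi, log(0.825 / (exp(-2.69) * 63^0.73 * 1.60^-1.06)),
               tolerance = 1e-12)
  expect_lt(abs(lbsi - (-0.0287)), 0.0005)
})

test_that("in-sample fitted coefficients give mean-zero LBSI (OLS residual)", {
  co <- small_cohort(n = 300)
  a <- anthropometry(co$wc_m, co$weight_kg, co$height_m)
  fit <- fit_allometric_exponents(a)
  expect_equal(mean(compute_lbsi(a, fit$coefficients)), 0, tolerance = 1e-10)
})

test_that("LBSI is monotone in each measurement with the Korean exponents", {
  cf <- allometric_coefficients()
  base <- compute_lbsi(anthropometry(0.85, 70, 1.70), cf)
  expect_gt(compute_lbsi(anthropometry(0.90, 70, 1.70), cf), base)  # wider waist
  expect_lt(compute_lbsi(anthropometry(0.85, 75, 1.70), cf), base)  # heavier
  expect_gt(compute_lbsi(anthropometry(0.85, 70, 1.75), cf), base)  # taller
})

test_that("LBSIZ standardization and its estimation behave as a z-score", {
  ko <- standardization_constants()
  expect_equal(standardize_lbsi(-0.02, ko), 0)
  expect_equal(standardize_lbsi(0.04, ko), 1.0)
  expect_equal(standardize_lbsi(-0.0287, ko), (-0.0287 + 0.02) / 0.06)
  expect_equal(round(standardize_lbsi(-0.0287, ko), 3), -0.145)
  expect_error(standardization_constants(sd_lbsi = 0), "positive")

  est <- estimate_standardization(c(-0.08, 0.04))
  expect_equal(est$mean_lbsi, -0.02)
  expect_equal(round(est$sd_lbsi, 4), 0.0849)
  expect_error(estimate_standardization(rep(0.01, 5)), "constant")
  expect_error(estimate_standardization(0.01), "at least 2")

  # round trip: standardizing with in-sample constants gives mean 0, SD 1
  set.seed(7)
  x <- rnorm(500, -0.02, 0.06)
  z <- standardize_lbsi(x, estimate_standardization(x))
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
})

test_that("LBSIZ preserves every rank statistic of LBSI", {
  co <- small_cohort(n = 400)
  a <- anthropometry(co$wc_m, co$weight_kg, co$height_m)
  lbsi <- compute_lbsi(a)
  lbsiz <- standardize_lbsi(lbsi)
  expect_equal(cor(lbsi, lbsiz, method = "spearman"), 1)
  expect_equal(auc_mann_whitney(lbsiz, co$event),
               auc_mann_whitney(lbsi, co$event), tolerance = 1e-12)
})

test_that("Friedewald LDL reproduces the cohort group means and is linear", {
  expect_equal(round(friedewald_ldl(190.4, 44.7, 160.8), 1), 113.5)
  expect_equal(round(friedewald_ldl(196.2, 43.3, 181.6), 1), 116.6)
  expect_equal(friedewald_ldl(100, 100, 0), 0)
  expect_warning(v <- friedewald_ldl(200, 40, 450), "400")
  expect_true(is.na(v))
  expect_error(friedewald_ldl(-1, 40, 100), "non-negative")
  # linearity: LDL of means equals mean of per-record LDLs
  set.seed(3)
  tc <- rnorm(100, 190, 30); hdl <- rnorm(100, 45, 8); tg <- runif(100, 50, 390)
  expect_equal(friedewald_ldl(mean(tc), mean(hdl), mean(tg)),
               mean(friedewald_ldl(tc, hdl, tg)), tolerance = 1e-10)
})

test_that("packaged reference constants load and round-trip the Korean set", {
  rc <- reference_constants("korean_kns_2018")
  expect_equal(rc$coefficients$intercept_c, -2.69)
  expect_equal(rc$coefficients$weight_exp_a, 0.73)
  expect_equal(rc$coefficients$height_exp_b, -1.06)
  expect_equal(rc$standardization$mean_lbsi, -0.02)
  expect_equal(rc$standardization$sd_lbsi, 0.06)
  expect_error(reference_constants("nope"), "unknown")
})
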