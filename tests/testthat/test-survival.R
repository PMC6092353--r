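test_that("follow-up time applies the calendar rule with 2012-12-31 censoring", {
  fu <- follow_up_years("2002-01-01", NA)
  expect_equal(fu$time, as.numeric(as.Date("2012-12-31") -
                                     as.Date("2002-01-01")) / 365.25)
  expect_equal(round(fu$time, 3), 10.998)  # 4017 days / 365.25
  expect_equal(fu$event, 0L)

  ev <- follow_up_years("2002-01-01", as.Date("2002-01-01") + 365)
  expect_equal(ev$time, 365 / 365.25)
  expect_equal(ev$event, 1L)

  late <- follow_up_years("2002-01-01", "2013-06-01")
  expect_equal(late$event, 0L)
  expect_equal(late$time, fu$time)

  expect_error(follow_up_years("2002-01-01", "2001-12-31"), "precedes")
})

test_that("Kaplan-Meier matches the product-limit arithmetic on toys", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$table$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$surv_fn(c(0.5, 1, 2.5, 3)), c(1, 2 / 3, 1 / 3, 0))

  cens <- kaplan_meier(c(1, 2, 3, 4), c(0, 0, 0, 0))
  expect_true(all(cens$surv_fn(c(1, 2, 3, 4)) == 1))
  expect_error(kaplan_meier(numeric(0), integer(0)), "no observations")
  expect_error(kaplan_meier(c(0, 1), c(1, 1)), "positive")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(10)
  t <- rexp(200, 0.2)
  km <- kaplan_meier(t, rep(1, 200))
  emp <- vapply(km$table$time, function(u) mean(t > u), 0)
  expect_equal(km$table$surv, emp, tolerance = 1e-12)
})

test_that("KM tracks the exponential closed form under censoring", {
  set.seed(11)
  n <- 5000
  lambda <- 0.1
  t <- rexp(n, lambda)
  event <- as.integer(t < 10)
  time <- pmin(t, 10)
  km <- kaplan_meier(time, event)
  grid <- km$table$time[km$table$time <= 10]
  expect_lt(max(abs(km$surv_fn(grid) - exp(-lambda * grid))), 0.02)
})

test_that("log-rank matches the hand-worked two-group table", {
  lr <- logrank_test(c(1, 3, 2, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  # hand calculation: O_A - E_A = 2/3, hypergeometric variance 13/18
  expect_equal(lr$statistic, (2 / 3)^2 / (13 / 18), tolerance = 1e-10)
  expect_equal(lr$df, 1L)

  dup <- logrank_test(rep(c(1, 2, 5), 2), rep(c(1, 0, 1), 2),
                      rep(c("A", "B"), each = 3))
  expect_equal(dup$statistic, 0, tolerance = 1e-12)
  expect_error(logrank_test(1:3, c(1, 1, 1), rep("A", 3)), "two groups")
})

test_that("log-rank holds its nominal type-I error under the null", {
  set.seed(12)
  reject <- replicate(1000, {
    t <- rexp(120, 0.1)
    e <- as.integer(t < 8)
    logrank_test(pmin(t, 8), e, rep(c("A", "B"), each = 60))$p_value < 0.05
  })
  expect_lt(abs(mean(reject) - 0.05), 0.02)
})

test_that("Cox fit matches brute-force partial-likelihood maximization", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 1, 1, 1)
  x <- c(1, 0, 1, 0, 1, 0)
  d <- data.frame(time = time, event = event, x = x)
  fit <- fit_cox(d, "x")
  oracle <- optimize(function(b) partial_loglik_1cov(b, time, event, x),
                     c(-5, 5), maximum = TRUE, tol = 1e-10)
  expect_equal(unname(fit$coefficients), oracle$maximum, tolerance = 1e-6)
  expect_equal(fit$loglik, oracle$objective, tolerance = 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$summary$hr, exp(fit$summary$coef))
  expect_equal(fit$summary$hr_lower,
               exp(fit$summary$coef - 1.96 * fit$summary$se))
})

test_that("Efron and Breslow agree exactly without tied event times", {
  set.seed(13)
  d <- data.frame(time = rexp(80) + (1:80) * 1e-6, event = rbinom(80, 1, 0.6),
                  x = rnorm(80))
  expect_equal(fit_cox(d, "x", ties = "efron")$coefficients,
               fit_cox(d, "x", ties = "breslow")$coefficients,
               tolerance = 1e-10)
})

test_that("Cox fit rejects degenerate designs", {
  d <- data.frame(time = 1:10, event = rep(1, 10), x = rnorm(10))
  d$y <- 2 * d$x
  expect_error(fit_cox(d, c("x", "y")), "rank-deficient")
  d$event <- 0
  expect_error(fit_cox(d, "x"), "at least one event")
})

test_that("Wald CI for a null covariate covers 1 at the nominal rate", {
  set.seed(14)
  cover <- replicate(200, {
    n <- 2000
    t <- rexp(n, 0.1)
    d <- data.frame(time = pmin(t, 10), event = as.integer(t < 10),
                    x = rnorm(n))
    s <- fit_cox(d, "x")$summary
    s$hr_lower <= 1 && 1 <= s$hr_upper
  })
  expect_lt(abs(mean(cover) - 0.95), 0.03)
})

test_that("decile assignment is rank-based with lower-decile ties", {
  d <- decile_groups(1:100)
  expect_equal(d[5], 1L)
  expect_equal(d[95], 10L)
  expect_equal(as.vector(table(d)), rep(10L, 10))
  expect_error(decile_groups(rep(3, 20)), "equal")
  expect_error(decile_groups(1:5), "at least 10")
  # a tied block straddling a boundary goes entirely to the lower decile
  x <- c(1:10, rep(10, 3), 11:97)
  dd <- decile_groups(x)
  expect_true(all(dd[x == 10] == dd[x == 10][1]))
  # sizes differ by at most 1 without ties
  set.seed(15)
  sizes <- table(decile_groups(rnorm(8485)))
  expect_lte(diff(range(sizes)), 1)
})

test_that("decile hazard ratios anchor decile 1 at exactly 1", {
  co <- small_cohort(n = 600, seed = 21)
  co$time <- co$follow_up_years
  dh <- decile_hazard_ratios(co, "wc_m")
  expect_equal(dh$table$hr[1], 1)
  expect_true(is.na(dh$table$hr_lower[1]))
  expect_equal(nrow(dh$table), 10)
})

test_that("decile-10 HR recovers the decile-mean contrast of a log-linear hazard", {
  set.seed(16)
  n <- 8485
  z <- rnorm(n)
  rate0 <- -log(1 - 0.07) / 10
  t <- rexp(n, rate0 * exp(0.3 * z))
  d <- data.frame(time = pmin(t, 10), event = as.integer(t < 10), z = z)
  dec <- decile_groups(z)
  gap <- mean(z[dec == 10]) - mean(z[dec == 1])  # ~3.5 for a standard normal
  dh <- decile_hazard_ratios(d, "z")
  expect_lt(abs(log(dh$table$hr[10]) - 0.3 * gap), 0.5)
})

test_that("the restricted cubic spline basis is Harrell's truncated-power form", {
  knots <- c(-1, 0, 1, 2)
  x <- seq(-3, 4, by = 0.01)
  B <- rcs_basis(x, knots)
  expect_equal(ncol(B), 3)
  expect_equal(B[, 1], x)
  # below the first knot the nonlinear columns vanish
  expect_true(all(B[x < -1, 2:3] == 0))
  # beyond the last knot each column is linear: second differences ~ 0
  h <- 0.01
  above <- x > 2.1 & x < 3.9
  for (j in 1:3) {
    d2 <- diff(B[, j], differences = 2)[above[2:(length(x) - 1)]] / h^2
    expect_lt(max(abs(d2)), 1e-6)
  }
  expect_error(rcs_basis(x, c(0, 0, 1)), "increasing")
  expect_error(rcs_basis(x, c(0, 1)), "3 knots")
})

test_that("spline hazard curve anchors the reference at HR 1 and is shift-invariant", {
  co <- small_cohort(n = 1200, seed = 22)
  co$time <- co$follow_up_years
  sc <- score_cohort(co)
  ref <- median(sc$lbsiz)
  sp <- spline_hazard_curve(sc, "lbsiz", grid = c(ref, -1, 0, 1))
  expect_equal(sp$curve$hr[1], 1, tolerance = 1e-12)
  expect_equal(sp$nonlinear_wald$df, 2)
  # adding a constant to the exposure shifts the curve, not the HRs
  sc$shifted <- sc$lbsiz + 5
  sp2 <- spline_hazard_curve(sc, "shifted", grid = c(ref, -1, 0, 1) + 5)
  expect_equal(sp2$curve$hr, sp$curve$hr, tolerance = 1e-6)
})
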