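test_that("Kaplan-Meier product-limit values match hand computation", {
  km <- km_estimator(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$fn(1.5), 2 / 3)
  expect_equal(km$fn(2.5), 1 / 3)
  expect_equal(km$fn(0), 1)
  # all censored -> S == 1
  expect_equal(km_estimator(c(1, 2, 3), c(0, 0, 0))$fn(5), 1)
  # single event at t=1 among n=2
  expect_equal(km_estimator(c(1, 2), c(1, 0))$fn(1), 1 / 2)
})

test_that("Harrell's C matches pair enumeration and tie conventions", {
  expect_equal(harrell_c(c(1, 2, 3), c(1, 1, 1), c(3, 2, 1)), 1)
  expect_equal(harrell_c(c(1, 2, 3), c(1, 1, 1), c(2, 3, 1)), 2 / 3)
  expect_equal(harrell_c(c(1, 2, 3), c(1, 1, 1), c(1, 1, 1)), 0.5)
  # complement identity on tie-free data
  set.seed(1)
  tt <- rexp(40); rr <- rnorm(40)
  expect_equal(harrell_c(tt, rep(1, 40), rr) +
                 harrell_c(tt, rep(1, 40), -rr), 1)
  expect_error(harrell_c(c(1, 2), c(0, 0), c(1, 2)), "no usable")
})

test_that("Uno's C equals Harrell's C without censoring, and both are rank-invariant", {
  expect_equal(uno_c(c(1, 2, 3), c(1, 1, 1), c(2, 3, 1), tau = 4), 2 / 3)
  set.seed(2)
  tt <- rexp(100); rr <- rnorm(100)
  expect_equal(uno_c(tt, rep(1, 100), rr, tau = max(tt) + 1),
               harrell_c(tt, rep(1, 100), rr), tolerance = 1e-12)
  # strictly monotone transform of the scores changes nothing
  expect_equal(harrell_c(tt, rep(1, 100), exp(rr)),
               harrell_c(tt, rep(1, 100), rr))
  co <- exp_cohort(300, beta = 1, cens_max = 15, seed = 3)
  r <- 1 - exp(-0.1 * exp(co$X$x))
  expect_equal(uno_c(co$t, co$y, exp(r), tau = 8),
               uno_c(co$t, co$y, r, tau = 8))
})

test_that("Brier score reduces to MSE without censoring", {
  # constant risk 1/2 -> 0.25
  expect_equal(brier_score(c(1, 2, 3, 4), c(1, 1, 1, 1),
                           rep(0.5, 4), horizon = 2.5), 0.25)
  # oracle predictions -> 0
  tt <- c(1, 2, 10, 12); yy <- c(1, 1, 1, 1)
  expect_equal(brier_score(tt, yy, c(1, 1, 0, 0), horizon = 5), 0)
  # equals plain MSE of risk vs event-by-horizon on censoring-free data
  set.seed(4)
  tt <- rexp(200, 0.2); rr <- runif(200)
  ind <- as.numeric(tt <= 3)
  expect_equal(brier_score(tt, rep(1, 200), rr, 3), mean((ind - rr)^2),
               tolerance = 1e-12)
})

test_that("Brier approximates E[risk(1-risk)] on calibrated data", {
  gen <- generate_cohort(generator_config(n = 5000), seed = 5)
  co <- gen$cohort; r <- gen$truth$risk
  b <- brier_score(co$t, co$y, r, 60)
  expect_equal(b, mean(r * (1 - r)), tolerance = 0.02)
})

test_that("O/E ratio behaves as calibration-in-the-large", {
  gen <- generate_cohort(generator_config(n = 5000), seed = 6)
  co <- gen$cohort; r <- gen$truth$risk
  expect_equal(oe_ratio(co$t, co$y, r, 60), 1, tolerance = 0.05)
  # doubling predictions halves the ratio
  r2 <- pmin(r * 2, 1 - 1e-9)
  expect_equal(oe_ratio(co$t, co$y, r2, 60),
               oe_ratio(co$t, co$y, r, 60) * mean(r) / mean(r2),
               tolerance = 1e-12)
  # no censoring: observed = event fraction before horizon
  tt <- c(1, 2, 10, 20); rr <- rep(0.5, 4)
  expect_equal(oe_ratio(tt, rep(1, 4), rr, 5), (2 / 4) / 0.5)
})

test_that("smoothed calibration is near the truth on calibrated data", {
  gen <- generate_cohort(generator_config(n = 5000), seed = 7)
  co <- gen$cohort; r <- gen$truth$risk
  obs <- smoothed_calibration(co$t, co$y, r, 60)
  expect_lt(mean(abs(obs - r)), 0.03)
  # feeding miscalibrated risks must register a larger ICI
  obs2 <- smoothed_calibration(co$t, co$y, r^2, 60)
  expect_gt(calibration_errors(obs2, r^2)["ici"],
            calibration_errors(obs, r)["ici"])
})

test_that("degenerate constant risks fall back to the KM estimate", {
  gen <- generate_cohort(generator_config(n = 500), seed = 8)
  co <- gen$cohort
  obs <- smoothed_calibration(co$t, co$y, rep(0.3, 500), 60)
  expect_equal(unique(obs), 1 - km_estimator(co$t, co$y)$fn(60))
})

test_that("calibration error summaries are order statistics of |obs - pred|", {
  obs <- c(0.2, 0.3, 0.4, 1.0); pred <- c(0.1, 0.2, 0.3, 0.5)
  ce <- calibration_errors(obs, pred)
  expect_equal(unname(ce["ici"]), 0.2)
  expect_equal(unname(ce["e50"]), 0.1)
  expect_equal(unname(ce["emax"]), 0.5)
  expect_equal(unname(ce["e90"]),
               unname(quantile(abs(obs - pred), 0.9, type = 7)))
  # identical inputs -> all zero; orderings always hold
  z <- calibration_errors(pred, pred)
  expect_true(all(z == 0))
  set.seed(9)
  o <- runif(50); p <- runif(50)
  ce2 <- calibration_errors(o, p)
  expect_lte(ce2["ici"], ce2["emax"])
  expect_lte(ce2["e50"], ce2["e90"])
  expect_lte(ce2["e90"], ce2["emax"])
})

test_that("calibration slope is 1 in-sample and halves when the lp doubles", {
  gen <- small_confounded(n = 600, seed = 10)
  fit <- fit_cox(gen$cohort, include_treatment = TRUE)
  expect_equal(calibration_slope(fit, gen$cohort), 1, tolerance = 1e-6)
  doubled <- fit
  doubled$coefficients <- 2 * fit$coefficients
  expect_equal(calibration_slope(doubled, gen$cohort), 0.5,
               tolerance = 1e-6)
})

test_that("overfit models show slope < 1 and Harrell C drop on fresh data", {
  below <- 0L
  for (s in 1:10) {
    train <- small_confounded(n = 120, seed = 1100 + s)$cohort
    test <- small_confounded(n = 1000, seed = 2100 + s)$cohort
    fit <- fit_cox(train)
    if (calibration_slope(fit, test) < 1) below <- below + 1L
  }
  expect_gte(below, 9L)
})

test_that("metrics are deterministic given fixed inputs", {
  gen <- small_confounded(n = 400, seed = 12)
  co <- gen$cohort
  fit <- fit_cox(co, include_treatment = TRUE)
  m1 <- suppressWarnings(evaluate_model(fit, co, 60))
  m2 <- suppressWarnings(evaluate_model(fit, co, 60))
  expect_identical(m1, m2)
})
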