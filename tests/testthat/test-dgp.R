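# Data-generating process: covariate structure, model linear predictors,
# calibration procedures, potential-outcome coupling, true estimands.

test_that("covariate matrix has the designed marginals and correlation", {
  X <- generate_covariates(2e5, seed = 31)
  expect_equal(dim(X), c(2e5, 10))
  expect_true(all(X[, 6:10] %in% c(0, 1)))
  expect_equal(unname(colMeans(X[, 6:10])), c(0.1, 0.2, 0.3, 0.4, 0.5),
               tolerance = 0.02)
  expect_equal(cor(X[, 1], X[, 2]), 0.2, tolerance = 0.02)
  expect_equal(cor(X[, 3], X[, 4]), 0.2, tolerance = 0.02)
  expect_identical(X, generate_covariates(2e5, seed = 31))
  expect_error(generate_covariates(0), "positive")
})

test_that("treatment linear predictor evaluates the stated coefficients", {
  zero <- matrix(0, 1, 10)
  expect_equal(treatment_linear_predictor(zero, 0, 1), 0)
  expect_equal(plogis(treatment_linear_predictor(zero, 0, 1)), 0.5)
  x5 <- zero; x5[1, 5] <- 1
  expect_equal(treatment_linear_predictor(x5, 0, 1), log(2))
  x1 <- zero; x1[1, 1] <- 1
  expect_equal(treatment_linear_predictor(x1, 0, sigma_scale = 2),
               2 * log(1.1))
})

test_that("intercept calibration hits the target prevalence", {
  X <- generate_covariates(2e5, seed = 32)
  for (p in c(0.1, 0.5, 0.9)) {
    a0 <- calibrate_treatment_intercept(X, p)
    expect_lt(abs(mean(plogis(treatment_linear_predictor(X, a0))) - p), 1e-4)
  }
  # prevalence monotonicity of the intercept
  a <- sapply(seq(0.1, 0.9, 0.2),
              function(p) calibrate_treatment_intercept(X, p))
  expect_true(all(diff(a) > 0))
  # symmetric logistic: all-zero covariates and target 0.5 give intercept 0
  expect_equal(calibrate_treatment_intercept(matrix(0, 100, 10), 0.5), 0)
  expect_error(calibrate_treatment_intercept(X, 1.2), "\\(0, 1\\)")
})

test_that("treatment assignment is Bernoulli with the given probabilities", {
  expect_error(assign_treatment(c(0.2, 1)), "strictly")
  Z <- assign_treatment(rep(0.5, 1e6), seed = 4)
  expect_equal(mean(Z), 0.5, tolerance = 0.002)
  expect_true(all(assign_treatment(rep(1 - 1e-12, 100), seed = 4) == 1))
  probs <- runif(100, 0.2, 0.8)
  expect_identical(assign_treatment(probs, seed = 9),
                   assign_treatment(probs, seed = 9))
})

test_that("error variance calibration yields R-squared 0.25 in controls", {
  X <- small_pop()$covariates
  s2 <- calibrate_error_variance(X)
  lp <- drop(X %*% continuous_outcome_coefficients())
  expect_equal(s2, 3 * var(lp))
  # brute-force 1-D search oracle over candidate error variances
  r2 <- function(s) var(lp) / (var(lp) + s)
  cand <- seq(0.5 * s2, 1.5 * s2, length.out = 2000)
  expect_equal(s2, cand[which.min(abs(sapply(cand, r2) - 0.25))],
               tolerance = 1e-3)
  # realized outcomes: empirical R-squared among untreated
  pop <- small_pop()
  fit <- lm(pop$y_cont_0 ~ lp)
  expect_equal(summary(fit)$r.squared, 0.25, tolerance = 0.01)
  expect_error(calibrate_error_variance(matrix(0, 50, 10)), "variance")
})

test_that("continuous potential outcomes share noise and have effect 2", {
  X <- generate_covariates(500, seed = 33)
  yc <- generate_continuous_potential_outcomes(X, sigma2 = 4, seed = 1)
  expect_equal(yc$y1 - yc$y0, rep(2, 500))
  zero <- matrix(0, 3, 10)
  yi <- generate_continuous_potential_outcomes(zero, 1, interactions = TRUE,
                                               seed = 1)
  expect_equal(yi$y1 - yi$y0, rep(2, 3))
  x1 <- zero; x1[, 1] <- 1
  yi1 <- generate_continuous_potential_outcomes(x1, 1, interactions = TRUE,
                                                seed = 1)
  expect_equal(yi1$y1 - yi1$y0, rep(2 + 0.25 * 2.5, 3))
})

test_that("binary-outcome calibration: intercept, then treatment log-odds", {
  X <- small_pop()$covariates
  a0 <- calibrate_outcome_intercept(X, 0.2)
  expect_lt(abs(mean(plogis(a0 + drop(X %*% binary_outcome_coefficients()))) -
                  0.2), 1e-4)
  # order invariance: a mean does not care about subject order
  expect_equal(calibrate_outcome_intercept(X[sample(nrow(X)), ], 0.2), a0,
               tolerance = 1e-6)
  expect_equal(calibrate_outcome_intercept(matrix(0, 50, 10), 0.5), 0)
  at <- calibrate_treatment_log_odds(X, a0, target_rd = -0.02)
  eta0 <- a0 + drop(X %*% binary_outcome_coefficients())
  expect_lt(abs(mean(plogis(eta0 + at)) - mean(plogis(eta0)) + 0.02), 1e-4)
  expect_equal(calibrate_treatment_log_odds(X, a0, target_rd = 0), 0)
  # monotonicity: the achieved risk difference increases with alpha_treat
  rd <- sapply(seq(-0.5, 0.5, 0.25),
               function(a) mean(plogis(eta0 + a)) - mean(plogis(eta0)))
  expect_true(all(diff(rd) > 0))
})

test_that("binary potential outcomes use comonotone coupling", {
  X <- generate_covariates(5000, seed = 34)
  a0 <- calibrate_outcome_intercept(X, 0.2)
  null <- generate_binary_potential_outcomes(X, a0, alpha_treat = 0, seed = 3)
  expect_identical(null$y0, null$y1)
  at <- calibrate_treatment_log_odds(X, a0, -0.02)
  yb <- generate_binary_potential_outcomes(X, a0, at, seed = 3)
  expect_lt(abs(mean(yb$y0) - 0.2), 0.02)
  expect_true(mean(yb$y1) < mean(yb$y0))
})

test_that("super-population generation is deterministic and calibrated", {
  pop <- small_pop()
  pop2 <- make_super_population(20000, 0.5, seed = 5)
  expect_identical(pop$covariates, pop2$covariates)
  expect_identical(pop$y_cont, pop2$y_cont)
  expect_equal(mean(pop$treatment), 0.5, tolerance = 0.02)
  expect_true(all(pop$true_ps > 0 & pop$true_ps < 1))
  # observed outcome equals the potential outcome selected by treatment
  expect_equal(pop$y_cont,
               ifelse(pop$treatment == 1, pop$y_cont_1, pop$y_cont_0))
  expect_equal(pop$y_bin,
               ifelse(pop$treatment == 1, pop$y_bin_1, pop$y_bin_0))
})

test_that("true estimands: uniform effect 2, and ATT matches subsetting", {
  pop <- small_pop()
  for (fam in c("ATE", "ATT", "MW", "OW"))
    expect_equal(true_estimands(pop, fam)$mean_diff, 2)
  att <- true_estimands(pop, "ATT")
  # independent oracle: average the contrast directly over treated subjects
  treated <- pop$treatment == 1
  expect_lt(abs(att$risk_diff -
                  (mean(pop$y_bin_1[treated]) - mean(pop$y_bin_0[treated]))),
            0.01)
  ate <- true_estimands(pop, "ATE")
  expect_lt(abs(ate$risk_diff - (mean(pop$y_bin_1) - mean(pop$y_bin_0))),
            1e-12)
  expect_lt(abs(ate$risk_diff + 0.02), 0.01)
})

test_that("samples are drawn without replacement and reproducibly", {
  pop <- small_pop()
  s1 <- draw_sample(pop, 500, seed = 8)
  s2 <- draw_sample(pop, 500, seed = 8)
  expect_identical(s1$idx, s2$idx)
  expect_false(any(duplicated(s1$idx)))
  expect_error(draw_sample(pop, 1e9), "exceeds")
})
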