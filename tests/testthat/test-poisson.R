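# Modified Poisson regression: estimator identity between the aggregated
# and individual-level routes, robust variance behaviour, convergence
# bookkeeping and prediction.

test_that("cell-aggregated fit equals the individual-level glm with sandwich vcov", {
  ds <- quick_dataset("categorical", "common", n = 3000, seed = 51)
  fit <- fit_prevalence(ds, "main_effects")
  # independent route: plain glm on individual rows + sandwich::vcovHC
  d <- ds$data
  for (p in paste0("x", 1:6)) d[[p]] <- factor(d[[p]])
  ref <- glm(y ~ x1 + x2 + x3 + x4 + x5 + x6, poisson(), data = d)
  expect_equal(coef(fit), coef(ref), tolerance = 1e-5)
  expect_equal(fit$vcov_robust, sandwich::vcovHC(ref, type = "HC0"),
               tolerance = 1e-3)
  # same check for the correctly-specified design
  fit2 <- fit_prevalence(ds, "correct_spec")
  ref2 <- glm(y ~ x1 * x2 + x3 * x4 * x5 + x6, poisson(), data = d)
  expect_equal(coef(fit2), coef(ref2), tolerance = 1e-5)
  expect_equal(fit2$vcov_robust, sandwich::vcovHC(ref2, type = "HC0"),
               tolerance = 1e-3)
})

test_that("an effect-free model recovers the intercept and null effects", {
  ds <- quick_dataset("categorical", "common", n = 100000, seed = 52,
                      coefficients = null_draw("categorical", "common"))
  fit <- fit_prevalence(ds, "main_effects")
  expect_true(fit$converged)
  # intercept ~ log prevalence = -1.5; every RR ~ 1
  expect_equal(unname(coef(fit)[1]), -1.5, tolerance = 0.05)
  expect_lt(max(abs(coef(fit)[-1])), 0.1)
  # null-model prediction: all intersections near the overall prevalence
  est <- predict(fit, ds)
  expect_lt(diff(range(est$estimate)), 0.05)
})

test_that("robust standard errors agree with a nonparametric bootstrap oracle", {
  ds <- quick_dataset("categorical", "common", n = 800, seed = 53)
  fit <- fit_prevalence(ds, "main_effects")
  d <- ds$data
  for (p in paste0("x", 1:6)) d[[p]] <- factor(d[[p]])
  set.seed(530)
  boot <- replicate(500, {
    idx <- sample.int(nrow(d), replace = TRUE)
    coef(glm(y ~ x1 + x2 + x3 + x4 + x5 + x6, poisson(), data = d[idx, ]))
  })
  boot_se <- apply(boot, 1, sd)
  ratio <- fit$robust_se / boot_se
  # Monte-Carlo agreement on the well-identified coefficients
  expect_true(all(ratio > 0.75 & ratio < 1.33))
})

test_that("robust variance is no larger than model-based variance for binary outcomes", {
  # a Bernoulli outcome is underdispersed relative to Poisson, so the
  # sandwich shrinks the model-based SEs
  ds <- quick_dataset("categorical", "rare", n = 20000, seed = 54)
  fit <- fit_prevalence(ds, "main_effects")
  model_se <- sqrt(diag(vcov(fit$model)))
  expect_true(all(fit$robust_se <= model_se * 1.001))
  # robust covariance is symmetric positive semi-definite
  expect_equal(fit$vcov_robust, t(fit$vcov_robust), tolerance = 1e-10)
  expect_gte(min(eigen(fit$vcov_robust, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)
})

test_that("correctly-specified regression is consistent across sample sizes", {
  # median MAD decreases monotonically over the design's sample sizes
  meds <- vapply(c(2000, 5000, 50000, 200000), function(N) {
    mads <- vapply(1:3, function(r) {
      ds <- quick_dataset("categorical", "common", n = N, seed = 60 + r)
      fit <- fit_prevalence(ds, "correct_spec")
      compute_mad(predict(fit, ds), true_intersection_prevalence(ds),
                  ds$sample_prevalence)$mad
    }, numeric(1))
    median(mads)
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("main-effects regression is biased when interactions generated the data", {
  cf <- coefficient_draw("categorical", intercept = -1.5,
                         beta = c(b2 = log(0.7), b3 = log(1.25),
                                  b4 = log(1.25), b5 = log(0.8),
                                  b8 = log(1.6)),
                         prevalence_tier = "common")
  ds <- quick_dataset("categorical", "common", n = 100000, seed = 61,
                      coefficients = cf)
  truth <- true_intersection_prevalence(ds)
  fit <- fit_prevalence(ds, "main_effects")
  est <- predict(fit, ds)
  err <- abs(est$estimate - truth[as.character(est$intersection_id)])
  n_i <- ds$intersections$n[match(est$intersection_id,
                                  ds$intersections$intersection_id)]
  bin_sd <- sqrt(truth[as.character(est$intersection_id)] *
                   (1 - truth[as.character(est$intersection_id)]) / n_i)
  expect_gt(sum(err > 3 * bin_sd), 0) # mis-specification bias shows up
  # while the correctly-specified fit stays consistent
  fitc <- fit_prevalence(ds, "correct_spec")
  estc <- predict(fitc, ds)
  errc <- abs(estc$estimate - truth[as.character(estc$intersection_id)])
  expect_lt(mean(errc), mean(err))
})

test_that("saturated-fit convergence bookkeeping records aliasing and divergence", {
  # small N: empty cells make the saturated design rank deficient
  ds <- quick_dataset("categorical", "common", n = 1000, seed = 62)
  fit <- fit_prevalence(ds, "saturated")
  expect_false(fit$converged)
  expect_error(predict(fit, ds), "non-converged")
  # large N: all 192 cells populated, fit converges and reproduces the
  # cell proportions (a saturated model is the cross-classification)
  ds2 <- quick_dataset("categorical", "common", n = 50000, seed = 63)
  fit2 <- fit_prevalence(ds2, "saturated")
  expect_true(fit2$converged)
  est2 <- predict(fit2, ds2)
  cc <- predict(fit_prevalence(ds2, "cross_classification"), ds2)
  expect_equal(est2$estimate, cc$estimate, tolerance = 1e-5)
})

test_that("cross-classification matches event proportions exactly", {
  df <- data.frame(g = rep(c("a", "b"), c(10, 8)),
                   h = "z",
                   y = c(rep(1, 3), rep(0, 7), rep(1, 2), rep(0, 6)))
  ds <- toy_dataset(df, predictors = c("g", "h"))
  est <- predict(fit_prevalence(ds, "cross_classification"), ds)
  expect_equal(sort(est$estimate), c(2 / 8, 3 / 10))
  # all-zero outcomes give all-zero estimates
  df$y <- 0
  est0 <- predict(fit_prevalence(toy_dataset(df, c("g", "h")),
                                 "cross_classification"))
  expect_equal(est0$estimate, c(0, 0))
})
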