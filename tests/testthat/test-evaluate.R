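# The MAD metric and the cross-iteration summaries.

test_that("MAD matches hand arithmetic and its edge cases", {
  expect_equal(compute_mad(c(`0` = 0.2, `1` = 0.4), c(`0` = 0.1, `1` = 0.3),
                           p = 0.2)$mad, 0.5)
  truth <- c(`0` = 0.1, `1` = 0.3, `2` = 0.2)
  expect_equal(compute_mad(truth, truth, p = 0.2)$mad, 0)
  # linearity: doubling every deviation doubles the MAD
  est <- truth + c(0.02, -0.04, 0.06)
  est2 <- truth + 2 * c(0.02, -0.04, 0.06)
  expect_equal(compute_mad(est2, truth, 0.2)$mad,
               2 * compute_mad(est, truth, 0.2)$mad)
  expect_error(compute_mad(est, truth, 0), "positive")
  expect_error(compute_mad(c(`0` = 0.1, `9` = NA), truth, 0.2,
                           method = "cart"), "cart")
})

test_that("MAD weights intersections equally regardless of their size", {
  est <- data.frame(intersection_id = c(0, 1), n = c(10, 10),
                    estimate = c(0.2, 0.45))
  truth <- c(`0` = 0.1, `1` = 0.3)
  m1 <- compute_mad(est, truth, 0.2)$mad
  expect_equal(m1, ((0.1 + 0.15) / 2) / 0.2)
  est$n <- c(10, 5000) # same estimates, very different membership
  expect_equal(compute_mad(est, truth, 0.2)$mad, m1)
  # an individual-weighted average would differ
  expect_false(isTRUE(all.equal(
    sum(c(10, 5000) / 5010 * abs(est$estimate - truth)) / 0.2, m1)))
})

test_that("empty intersections are excluded and counted", {
  est <- c(`0` = 0.2, `1` = 0.4)
  truth <- c(`0` = 0.1, `1` = 0.3, `2` = 0.5) # id 2 unobserved
  r <- compute_mad(est, truth, 0.2)
  expect_equal(r$n_intersections_used, 2)
  expect_equal(r$n_excluded, 1)
})

test_that("convergence proportions aggregate correctly", {
  res <- data.frame(scenario = "s", method = "saturated", n = 2000,
                    converged = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(summarize_convergence(res)$pct_converged, 25)
  res$converged <- TRUE
  expect_equal(summarize_convergence(res)$pct_converged, 100)
})

test_that("splitting percentages count iterations using each variable", {
  fits <- list(c("x1", "x3"), c("x3"), character(0))
  sp <- splitting_percentages(fits)
  expect_equal(sp$splitting_percentage[sp$variable == "x3"], 200 / 3)
  expect_equal(sp$splitting_percentage[sp$variable == "x1"], 100 / 3)
  expect_equal(sp$splitting_percentage[sp$variable == "x6"], 0)
  expect_equal(unique(sp$n_iterations), 3)
})

test_that("bias and variance of a constant estimator follow the closed form", {
  truth <- c(`0` = 0.1, `1` = 0.3)
  est <- do.call(rbind, lapply(1:5, function(it)
    data.frame(iteration = it, intersection_id = c(0, 1),
               estimate = 0.2)))
  bv <- bias_variance_by_intersection(est, truth)
  expect_equal(bv$per_intersection$variance, c(0, 0))
  expect_equal(bv$per_intersection$bias, c(100 * (0.2 - 0.1),
                                           100 * (0.2 - 0.3)))
  expect_error(bias_variance_by_intersection(est, truth,
                                             draw_id = c(1, 2)),
               "different")
})

test_that("cross-classification is unbiased with binomial-oracle variance", {
  sc <- scenario_config("categorical", "common", 5000)
  res <- run_grid(sc, methods = "cross_classification", reps = 80,
                  master_seed = 150, fixed_coefficients = TRUE,
                  keep_estimates = TRUE)
  # regenerate the fixed draw exactly as run_grid does
  set.seed(derive_seed(150, 1, 0)); fixed <- draw_coefficients(sc)
  ds <- generate_dataset(sc, coefficients = fixed,
                         rng_seed = derive_seed(150, 1, 1))
  truth <- true_intersection_prevalence(ds)
  bv <- bias_variance_by_intersection(res$estimates, truth)
  per <- bv$per_intersection
  tab <- ds$intersections
  big <- per[per$intersection_id %in%
               tab$intersection_id[tab$n >= 40] & per$n_iterations == 80, ]
  expect_gt(nrow(big), 10)
  # unbiasedness: bias within Monte-Carlo error of zero on average
  expect_lt(median(abs(big$bias)), 1)
  # variance magnitude matches 10^4 p(1-p)/E[n_i]
  p_i <- truth[as.character(big$intersection_id)]
  en <- tab$n[match(big$intersection_id, tab$intersection_id)]
  expected_var <- 1e4 * p_i * (1 - p_i) / en
  ratio <- big$variance / expected_var
  expect_gt(median(ratio), 0.6)
  expect_lt(median(ratio), 1.6)
})

test_that("main effects trades bias for variance against cross-classification at small N", {
  sc <- scenario_config("categorical", "common", 2000)
  reps <- 200 # enough iterations that cross-classification's Monte-Carlo
              # bias noise sits well below main-effects' structural bias
  res <- run_grid(sc, methods = c("cross_classification", "main_effects"),
                  reps = reps, master_seed = 151, fixed_coefficients = TRUE,
                  keep_estimates = TRUE)
  set.seed(derive_seed(151, 1, 0)); fixed <- draw_coefficients(sc)
  ds <- generate_dataset(sc, coefficients = fixed,
                         rng_seed = derive_seed(151, 1, 1))
  truth <- true_intersection_prevalence(ds)
  bv <- lapply(split(res$estimates, res$estimates$method), function(e) {
    per <- bias_variance_by_intersection(e, truth)$per_intersection
    per[per$n_iterations == reps, ] # cells populated in every iteration
  })
  # lower variance but higher bias for the mis-specified main effects
  expect_lt(median(bv$main_effects$variance),
            median(bv$cross_classification$variance))
  expect_gt(median(abs(bv$main_effects$bias)),
            median(abs(bv$cross_classification$bias)))
})

test_that("MAD survives a round trip through the long-format CSV", {
  ds <- quick_dataset("categorical", "common", n = 3000, seed = 152)
  truth <- true_intersection_prevalence(ds)
  est <- predict(fit_prevalence(ds, "cross_classification"), ds)
  direct <- compute_mad(est, truth, ds$sample_prevalence)$mad
  path <- file.path(tempdir(), "est_roundtrip.csv")
  write_estimates_csv(est, path, scenario = "t", iteration = 1)
  back <- read.csv(path)
  again <- compute_mad(setNames(back$estimate, back$intersection_id),
                      truth, ds$sample_prevalence)$mad
  expect_equal(again, direct, tolerance = 1e-12)
  unlink(path)
})
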