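# The data-generating process: coefficient sampling, covariate structure,
# intersection labelling and true prevalences.

test_that("sampled effect sizes respect the tier truncation windows and X6 is null", {
  for (tier in c("rare", "common")) {
    sc <- scenario_config("categorical", tier, 1000)
    for (seed in 1:15) {
      cf <- draw_coefficients(sc, rng_seed = seed)
      expect_true(all(in_rr_windows(exp(cf$beta), tier)),
                  label = sprintf("%s tier seed %d inside windows", tier, seed))
      expect_identical(cf$beta_x6, 0)
      expect_equal(cf$intercept, if (tier == "rare") -3 else -1.5)
    }
  }
  # mixed model has its own coefficient set, same windows
  scm <- scenario_config("mixed", "rare", 1000)
  cfm <- draw_coefficients(scm, rng_seed = 3)
  expect_named(cfm$beta, c("b1", "b2", "b3", "b4", "b5", "b6", "b7"))
  expect_true(all(in_rr_windows(exp(cfm$beta), "rare")))
})

test_that("interaction boost draws interaction terms from the harmful window only", {
  sc <- scenario_config("categorical", "common", 1000, interaction_boost = TRUE)
  for (seed in 1:10) {
    cf <- draw_coefficients(sc, rng_seed = seed)
    rr_int <- exp(cf$beta[c("b6", "b7", "b8")])
    expect_true(all(rr_int >= 1.11 & rr_int <= 1.80))
    # main effects still use both windows (protective values must be possible)
    expect_true(all(in_rr_windows(exp(cf$beta), "common")))
  }
})

test_that("the truncated-normal center reproduces the nominal tier prevalence analytically", {
  # the frozen centers solve E[sample prevalence] = 3% (rare) / 15% (common)
  expect_equal(intersim:::expected_prevalence(intersim:::rr_center("rare"),
                                              "rare"), 0.03, tolerance = 1e-7)
  expect_equal(intersim:::expected_prevalence(intersim:::rr_center("common"),
                                              "common"), 0.15,
               tolerance = 1e-7)
  expect_equal(intersim:::calibrate_rr_center("rare"),
               intersim:::rr_center("rare"), tolerance = 1e-6)
})

test_that("an all-null draw gives constant true probability exp(intercept)", {
  ds <- quick_dataset("categorical", "rare", n = 500, seed = 5,
                      coefficients = null_draw())
  expect_equal(unique(ds$data$true_prob), exp(-3))
  tp <- true_intersection_prevalence(ds)
  expect_length(tp, 192)
  expect_equal(unname(tp), rep(exp(-3), 192))
})

test_that("categorical true probability matches the hand-evaluated generation formula", {
  cf <- coefficient_draw("categorical", intercept = -3,
                         beta = c(b1.2 = log(1.5), b2 = log(0.5),
                                  b3 = log(1.3), b4 = log(0.8),
                                  b5 = log(1.25), b6 = log(1.4),
                                  b8 = log(1.6)),
                         prevalence_tier = "rare")
  ds <- quick_dataset("categorical", "rare", n = 4000, seed = 9,
                      coefficients = cf)
  d <- ds$data
  i <- which(d$x1 == 2 & d$x2 == 1 & d$x3 == 1 & d$x4 == 1 & d$x5 == 1)[1]
  # hand evaluation: intercept + b1.2 + b2 + b3 + b4 + b5 + b6 (X1=2 & X2=1)
  # + b8 (X3*X4*X5); X6 contributes nothing
  hand <- exp(-3 + log(1.5) + log(0.5) + log(1.3) + log(0.8) + log(1.25) +
                log(1.4) + log(1.6))
  expect_equal(d$true_prob[i], hand)
  # and the intersection-table truth agrees with the formula at that pattern
  tp <- true_intersection_prevalence(ds)
  expect_equal(unname(tp[as.character(d$intersection_id[i])]), hand)
})

test_that("covariate marginals and the X3->X4 mediation match the design", {
  ds <- quick_dataset("categorical", "common", n = 200000, seed = 13)
  d <- ds$data
  expect_equal(mean(d$x2), 0.2, tolerance = 0.02)
  expect_equal(mean(d$x3), 0.5, tolerance = 0.02)
  expect_equal(mean(d$x5), 0.25, tolerance = 0.02)
  expect_equal(mean(d$x4[d$x3 == 0]), 0.4, tolerance = 0.02)
  expect_equal(mean(d$x4[d$x3 == 1]), 0.7, tolerance = 0.02)
  expect_equal(unname(table(d$x1) / nrow(d)), rep(0.25, 4), tolerance = 0.05,
               ignore_attr = TRUE)
  expect_equal(unname(table(d$x6) / nrow(d)), rep(1 / 3, 3), tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("the design yields exactly 192 possible intersections", {
  ds <- quick_dataset("categorical", "common", n = 200000, seed = 2)
  expect_equal(nrow(ds$intersections), 192)
  expect_setequal(ds$intersections$intersection_id, 0:191)
  expect_true(all(ds$data$intersection_id %in% 0:191))
  # mixed inputs map onto the same 192 ids via quartile/tertile binning
  dm <- quick_dataset("mixed", "common", n = 20000, seed = 2)
  expect_equal(nrow(dm$intersections), 192)
  # binned intersections average ~N/192 members
  expect_equal(mean(dm$intersections$n), 20000 / 192, tolerance = 1e-9)
  expect_gt(min(table(intersim:::quantile_bin(dm$data$x1, 4))), 4990)
})

test_that("no realized true probability ever exceeds 1", {
  for (seed in 1:8) {
    ds <- quick_dataset("categorical", "common", n = 3000, seed = seed)
    expect_lte(max(ds$data$true_prob), 1)
  }
  for (seed in 1:4) {
    dm <- quick_dataset("mixed", "common", n = 3000, seed = seed)
    expect_lte(max(dm$data$true_prob), 1)
  }
})

test_that("inadmissible user-supplied draws are rejected with an error", {
  bad_cat <- coefficient_draw("categorical", intercept = -1.5,
                              beta = c(b2 = 1.2, b3 = 1.2, b4 = 1.2))
  sc <- scenario_config("categorical", "common", 200)
  expect_error(generate_dataset(sc, coefficients = bad_cat, rng_seed = 1),
               "probabilities above 1")
  bad_mix <- coefficient_draw("mixed", intercept = -1.5, beta = c(b1 = 1.5))
  scm <- scenario_config("mixed", "common", 2000)
  expect_error(generate_dataset(scm, coefficients = bad_mix, rng_seed = 1),
               "probabilities above 1")
})

test_that("categorical empirical prevalences converge to the formula truth", {
  cf <- draw_coefficients(scenario_config("categorical", "common", 1), 31)
  ds <- quick_dataset("categorical", "common", n = 200000, seed = 31,
                      coefficients = cf)
  tp <- true_intersection_prevalence(ds)
  tab <- ds$intersections
  emp <- vapply(seq_len(nrow(tab)), function(i) {
    m <- ds$data$intersection_id == tab$intersection_id[i]
    mean(ds$data$y[m])
  }, numeric(1))
  # every intersection within 4 binomial SDs of its formula prevalence
  sds <- sqrt(tab$true_prevalence * (1 - tab$true_prevalence) / tab$n)
  expect_true(all(abs(emp - tab$true_prevalence) <= 4 * sds + 1e-12))
})

test_that("mixed-input intersection truth matches a fresh-Bernoulli Monte-Carlo oracle", {
  dm <- quick_dataset("mixed", "common", n = 5000, seed = 41)
  tab <- dm$intersections
  big <- tab$intersection_id[which.max(tab$n)]
  members <- dm$data$true_prob[dm$data$intersection_id == big]
  truth <- true_intersection_prevalence(dm)[as.character(big)]
  expect_equal(unname(truth), mean(members))
  set.seed(99)
  mc <- replicate(400, mean(rbinom(length(members), 1, members)))
  se <- sd(mc) / sqrt(length(mc))
  expect_lt(abs(mean(mc) - truth), 5 * se + 1e-3)
})

test_that("X6 is independent of the outcome (null-variable rejection rate is nominal)", {
  rej <- vapply(1:30, function(seed) {
    ds <- quick_dataset("categorical", "common", n = 4000, seed = 200 + seed)
    suppressWarnings(stats::chisq.test(table(ds$data$x6, ds$data$y))$p.value) < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.2) # ~5% nominal, wide Monte-Carlo margin
})

test_that("datasets round-trip through CSV plus JSON sidecar", {
  ds <- quick_dataset("categorical", "rare", n = 300, seed = 77)
  path <- file.path(tempdir(), "ds_roundtrip.csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$data, ds$data, tolerance = 1e-12)
  expect_equal(back$intersections$true_prevalence,
               ds$intersections$true_prevalence, tolerance = 1e-12)
  expect_equal(back$scenario$prevalence_tier, "rare")
  expect_equal(back$coefficients$beta, ds$coefficients$beta,
               tolerance = 1e-12)
  unlink(c(path, paste0(path, ".json")))
})
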