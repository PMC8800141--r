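# Shared fixtures, built in code.

# a coefficient draw with every relative risk forced to 1 (all betas 0)
null_draw <- function(input_type = "categorical", tier = "rare") {
  coefficient_draw(input_type,
                   intercept = switch(tier, rare = -3, common = -1.5,
                                      half = log(0.5)),
                   prevalence_tier = tier)
}

quick_dataset <- function(input_type = "categorical", tier = "common",
                          n = 2000, seed = 1, coefficients = NULL) {
  sc <- scenario_config(input_type, tier, n, master_seed = seed)
  generate_dataset(sc, coefficients = coefficients, rng_seed = seed)
}

# dataset from explicit columns via the real-data constructor
toy_dataset <- function(df, predictors, outcome = "y") {
  as_intersim_data(df, predictors = predictors, outcome = outcome)
}

# union-window membership check on the relative-risk scale
in_rr_windows <- function(rr, tier) {
  w <- if (tier == "rare") list(c(0.20, 0.76), c(1.24, 1.80))
       else list(c(0.20, 0.89), c(1.11, 1.80))
  (rr >= w[[1]][1] & rr <= w[[1]][2]) | (rr >= w[[2]][1] & rr <= w[[2]][2])
}
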