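# Coefficient draws for the outcome-generating models.
#
# Effect sizes live on the relative-risk scale: each is sampled from a
# normal (SD 0.30) truncated to the union of a protective and a harmful
# window, then stored as log(RR). X6 never affects the outcome.

# sample n relative risks by rejection from N(mu, RR_SD) into the windows
sample_rr <- function(n, tier, harmful_only = FALSE) {
  w <- rr_windows(tier)
  mu <- rr_center(tier)
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(max(8L * n, 32L), mu, RR_SD)
    keep <- (x >= w$upper[1] & x <= w$upper[2])
    if (!harmful_only) keep <- keep | (x >= w$lower[1] & x <= w$lower[2])
    out <- c(out, x[keep])
  }
  out[seq_len(n)]
}

coef_names <- function(input_type) {
  if (input_type == "categorical") {
    c("b1.1", "b1.2", "b1.3", "b2", "b3", "b4", "b5", "b6", "b7", "b8")
  } else {
    c("b1", "b2", "b3", "b4", "b5", "b6", "b7")
  }
}

interaction_names <- function(input_type) {
  if (input_type == "categorical") c("b6", "b7", "b8") else c("b6", "b7")
}

#' Construct a coefficient draw manually
#'
#' Builds the coefficient object used by [generate_dataset()] from explicit
#' values, bypassing the truncated-normal sampling — useful for controlled
#' experiments (e.g. an all-null draw where every relative risk is 1).
#'
#' @param input_type `"categorical"` or `"mixed"`.
#' @param intercept Log-risk intercept.
#' @param beta Named numeric vector of log relative risks. Categorical
#'   model: `b1.1`, `b1.2`, `b1.3` (X1 dummies), `b2`..`b5`, `b6` (X1=2 &
#'   X2=1), `b7` (X1=3 & X2=1), `b8` (X3*X4*X5). Mixed model: `b1`..`b5`,
#'   `b6` (X1*X2 when X1>1 & X2=1), `b7` (X3*X4*X5). Missing entries
#'   default to 0. The X6 coefficient is always exactly 0.
#' @param prevalence_tier Tier label carried along for bookkeeping.
#' @return An object of class `intersim_coefficients`.
#' @examples
#' coefficient_draw("categorical", intercept = -3) # all relative risks 1
#' @export
coefficient_draw <- function(input_type = c("categorical", "mixed"),
                             intercept,
                             beta = numeric(0),
                             prevalence_tier = NA_character_) {
  input_type <- match.arg(input_type)
  nm <- coef_names(input_type)
  full <- setNames(numeric(length(nm)), nm)
  if (length(beta)) {
    bad <- setdiff(names(beta), nm)
    if (length(bad)) stop("unknown coefficient name(s): ",
                          paste(bad, collapse = ", "))
    full[names(beta)] <- beta
  }
  structure(list(input_type = input_type,
                 prevalence_tier = prevalence_tier,
                 intercept = intercept,
                 beta = full,
                 beta_x6 = 0,
                 redraws = 0L),
            class = "intersim_coefficients")
}

#' Draw effect sizes for a scenario
#'
#' Samples every main-effect and interaction relative risk from a normal
#' (SD 0.30) truncated to the scenario tier's protective/harmful windows
#' (rare: \[0.20, 0.76\] and \[1.24, 1.80\]; common: \[0.20, 0.89\] and
#' \[1.11, 1.80\]) and stores them as log relative risks. The intercept is
#' fixed by tier (-3 rare, -1.5 common, log 0.5 for the 50% sensitivity
#' tier) and the X6 coefficient is exactly 0. For categorical inputs the
#' draw is rejected and resampled until no covariate pattern yields an
#' outcome probability above 1 (for mixed inputs that check must wait for
#' realized data; see [generate_dataset()]). With `interaction_boost` the
#' interaction terms sample only from the harmful window.
#'
#' @param scenario An [scenario_config()] object.
#' @param rng_seed Optional integer seed set before sampling.
#' @param max_redraws Bound on admissibility rejections before erroring.
#' @return An object of class `intersim_coefficients`.
#' @examples
#' sc <- scenario_config("categorical", "rare", 1000)
#' cf <- draw_coefficients(sc, rng_seed = 1)
#' exp(cf$beta) # relative risks, all inside the stated windows
#' @export
draw_coefficients <- function(scenario, rng_seed = NULL, max_redraws = 1000L) {
  stopifnot(inherits(scenario, "intersim_scenario"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  tier <- scenario$prevalence_tier
  nm <- coef_names(scenario$input_type)
  int_nm <- interaction_names(scenario$input_type)
  for (attempt in 0:max_redraws) {
    beta <- setNames(log(sample_rr(length(nm), tier)), nm)
    if (scenario$interaction_boost) {
      beta[int_nm] <- log(sample_rr(length(int_nm), tier, harmful_only = TRUE))
    }
    draw <- coefficient_draw(scenario$input_type, tier_intercept(tier),
                             beta, tier)
    draw$redraws <- attempt
    if (scenario$input_type == "mixed") return(draw)  # checked at generation
    if (max_pattern_lp(draw) <= 0) return(draw)
  }
  stop(sprintf(
    "no admissible coefficient draw after %d rejections (%s inputs, %s tier, N=%d)",
    max_redraws, scenario$input_type, tier, scenario$n_individuals))
}

#' @export
print.intersim_coefficients <- function(x, ...) {
  cat(sprintf("Coefficient draw (%s inputs, %s tier): intercept %.4f\n",
              x$input_type, x$prevalence_tier, x$intercept))
  print(round(rbind(`log RR` = x$beta, RR = exp(x$beta)), 4))
  cat("X6 coefficient: 0 (null variable)\n")
  invisible(x)
}

# all 2^5 * 4 / 2 outcome-relevant covariate patterns of the categorical
# model (X6 never enters the linear predictor)
categorical_patterns <- function() {
  expand.grid(x1 = 0:3, x2 = 0:1, x3 = 0:1, x4 = 0:1, x5 = 0:1,
              KEEP.OUT.ATTRS = FALSE)
}

# linear predictor of the categorical generating formula at given patterns
categorical_lp <- function(coeffs, d) {
  b <- coeffs$beta
  coeffs$intercept +
    b["b1.1"] * (d$x1 == 1) + b["b1.2"] * (d$x1 == 2) + b["b1.3"] * (d$x1 == 3) +
    b["b2"] * d$x2 + b["b3"] * d$x3 + b["b4"] * d$x4 + b["b5"] * d$x5 +
    b["b6"] * (d$x1 == 2 & d$x2 == 1) + b["b7"] * (d$x1 == 3 & d$x2 == 1) +
    b["b8"] * d$x3 * d$x4 * d$x5
}

# linear predictor of the mixed generating formula
mixed_lp <- function(coeffs, d) {
  b <- coeffs$beta
  coeffs$intercept +
    b["b1"] * d$x1 + b["b2"] * d$x2 + b["b3"] * d$x3 + b["b4"] * d$x4 +
    b["b5"] * d$x5 +
    b["b6"] * d$x1 * d$x2 * (d$x1 > 1 & d$x2 == 1) +
    b["b7"] * d$x3 * d$x4 * d$x5
}

max_pattern_lp <- function(coeffs) {
  max(categorical_lp(coeffs, categorical_patterns()))
}
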