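# Dataset generation: covariates per the generating model, Bernoulli
# outcome from the exp-link linear predictor, intersection labelling, and
# the per-intersection true prevalence table.

N_INTERSECTIONS <- 192L # 4 * 2 * 2 * 2 * 2 * 3

# 0-based intersection id from the six (binned) category codes
intersection_code <- function(x1, x2, x3, x4, x5, x6) {
  as.integer(x1 * 48L + x2 * 24L + x3 * 12L + x4 * 6L + x5 * 3L + x6)
}

# enumeration of all 192 intersections in id order
all_intersections <- function() {
  g <- expand.grid(x6 = 0:2, x5 = 0:1, x4 = 0:1, x3 = 0:1, x2 = 0:1,
                   x1 = 0:3, KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("x1", "x2", "x3", "x4", "x5", "x6")]
  g$intersection_id <- intersection_code(g$x1, g$x2, g$x3, g$x4, g$x5, g$x6)
  g[order(g$intersection_id), ]
}

# bin a continuous vector into k sample-quantile groups, coded 0..k-1
quantile_bin <- function(x, k) {
  cuts <- quantile(x, probs = seq_len(k - 1) / k, names = FALSE, type = 7)
  as.integer(findInterval(x, cuts, left.open = TRUE))
}

#' Generate one simulated dataset
#'
#' Draws covariates (X1 uniform four-category or standard normal; X2
#' Bernoulli 0.2; X3 Bernoulli 0.5; X4 Bernoulli 0.4 if X3=0 else 0.7 — the
#' X3 to X4 mediation; X5 Bernoulli 0.25; X6 uniform three-category or
#' standard normal), assembles the exp-link linear predictor of the
#' scenario's generating formula, and samples the binary outcome from the
#' resulting true probability. Continuous X1/X6 are additionally binned
#' into sample quartiles/tertiles so that every individual belongs to one
#' of the 192 intersections. For mixed inputs, any realized probability
#' above 1 rejects the whole coefficient draw and a fresh one is sampled
#' (bounded by `max_redraws`).
#'
#' @param scenario An [scenario_config()] object.
#' @param coefficients Optional [coefficient_draw()]/[draw_coefficients()]
#'   result; drawn internally when `NULL`. A user-supplied inadmissible
#'   draw is an error rather than a silent redraw.
#' @param rng_seed Optional integer seed.
#' @param max_redraws Bound on coefficient redraws for mixed inputs.
#' @return An object of class `intersim_data`: a list with `data` (one row
#'   per individual: `x1`..`x6`, `y`, `true_prob`, `intersection_id`),
#'   `intersections` (all 192 rows: category pattern, member count `n`,
#'   `true_prevalence`), the scenario, the accepted coefficient draw, the
#'   realized sample prevalence, and an `empty_intersections` flag.
#' @examples
#' sc <- scenario_config("categorical", "rare", 5000)
#' ds <- generate_dataset(sc, rng_seed = 7)
#' ds
#' @export
generate_dataset <- function(scenario, coefficients = NULL, rng_seed = NULL,
                             max_redraws = 1000L) {
  stopifnot(inherits(scenario, "intersim_scenario"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  user_coeffs <- !is.null(coefficients)
  if (!user_coeffs) coefficients <- draw_coefficients(scenario)
  stopifnot(inherits(coefficients, "intersim_coefficients"),
            coefficients$input_type == scenario$input_type)
  n <- scenario$n_individuals

  d <- data.frame(
    x2 = rbinom(n, 1L, 0.2),
    x3 = rbinom(n, 1L, 0.5))
  d$x4 <- rbinom(n, 1L, ifelse(d$x3 == 0L, 0.4, 0.7))
  d$x5 <- rbinom(n, 1L, 0.25)
  if (scenario$input_type == "categorical") {
    d$x1 <- sample(0:3, n, replace = TRUE)
    d$x6 <- sample(0:2, n, replace = TRUE)
    if (user_coeffs && max_pattern_lp(coefficients) > 0)
      stop("supplied coefficient draw admits outcome probabilities above 1")
    lp <- categorical_lp(coefficients, d)
  } else {
    d$x1 <- rnorm(n)
    d$x6 <- rnorm(n)
    lp <- mixed_lp(coefficients, d)
    redraws <- 0L
    while (max(lp) > 0) { # realized probability above 1: reject the draw
      if (user_coeffs)
        stop("supplied coefficient draw yields outcome probabilities above 1 ",
             "for this sample")
      redraws <- redraws + 1L
      if (redraws > max_redraws)
        stop(sprintf(
          "no admissible coefficient draw after %d rejections (mixed inputs, %s tier, N=%d)",
          max_redraws, scenario$prevalence_tier, n))
      coefficients <- draw_coefficients(scenario)
      lp <- mixed_lp(coefficients, d)
    }
    coefficients$redraws <- coefficients$redraws +
      if (exists("redraws")) redraws else 0L
  }
  d$true_prob <- exp(lp)
  d$y <- rbinom(n, 1L, d$true_prob)

  if (scenario$input_type == "categorical") {
    c1 <- d$x1; c6 <- d$x6
  } else {
    c1 <- quantile_bin(d$x1, 4L)
    c6 <- quantile_bin(d$x6, 3L)
  }
  d$intersection_id <- intersection_code(c1, d$x2, d$x3, d$x4, d$x5, c6)

  tab <- all_intersections()
  tab$n <- tabulate(d$intersection_id + 1L, nbins = N_INTERSECTIONS)
  if (scenario$input_type == "categorical") {
    # formula truth: evaluate the generating formula at each pattern
    tab$true_prevalence <- exp(categorical_lp(coefficients, tab))
  } else {
    s <- rowsum(d$true_prob, d$intersection_id)
    tp <- rep(NA_real_, N_INTERSECTIONS)
    tp[as.integer(rownames(s)) + 1L] <- s[, 1] / tab$n[as.integer(rownames(s)) + 1L]
    tab$true_prevalence <- tp
  }

  d <- d[, c("x1", "x2", "x3", "x4", "x5", "x6", "y", "true_prob",
             "intersection_id")]
  structure(list(data = d,
                 intersections = tab,
                 predictors = paste0("x", 1:6),
                 types = setNames(
                   if (scenario$input_type == "categorical")
                     rep("categorical", 6)
                   else c("continuous", rep("categorical", 4), "continuous"),
                   paste0("x", 1:6)),
                 input_type = scenario$input_type,
                 outcome = "y",
                 scenario = scenario,
                 coefficients = coefficients,
                 sample_prevalence = mean(d$y),
                 empty_intersections = sum(tab$n == 0L),
                 simulated = TRUE),
            class = "intersim_data")
}

#' @export
print.intersim_data <- function(x, ...) {
  cat(sprintf("intersim dataset: %d individuals, %s inputs%s\n",
              nrow(x$data), x$input_type,
              if (isTRUE(x$simulated))
                sprintf(", %s tier", x$scenario$prevalence_tier) else ""))
  cat(sprintf("  sample prevalence %.4f; %d of %d intersections populated\n",
              x$sample_prevalence,
              sum(x$intersections$n > 0L), nrow(x$intersections)))
  invisible(x)
}

#' True prevalence of the outcome per intersection
#'
#' Returns the generating-model prevalence for every intersection: for
#' categorical inputs, the generation formula evaluated at the
#' intersection's covariate pattern (so it is defined even for empty
#' intersections); for mixed inputs, the mean of members' true
#' probabilities (`NA` for empty intersections, since the within-bin
#' distribution of the continuous covariates is not observed there).
#'
#' @param dataset An `intersim_data` object carrying `true_prob`.
#' @return A named numeric vector of length 192; names are intersection
#'   ids `"0"`..`"191"`.
#' @export
true_intersection_prevalence <- function(dataset) {
  stopifnot(inherits(dataset, "intersim_data"))
  if (is.null(dataset$intersections$true_prevalence))
    stop("dataset carries no true prevalence (real data?)")
  setNames(dataset$intersections$true_prevalence,
           dataset$intersections$intersection_id)
}

#' Wrap a flat table as an analysis-ready dataset
#'
#' Builds the container consumed by [fit_prevalence()] from an arbitrary
#' individual-level table: declares which columns are predictors (all must
#' be categorical for the real-data path), which is the binary outcome,
#' and assigns each observed combination of predictor categories an
#' intersection id over the full cross of observed levels.
#'
#' @param df Data frame with one row per individual.
#' @param predictors Character vector of predictor column names.
#' @param outcome Name of the 0/1 outcome column.
#' @return An `intersim_data` object (without simulation truth).
#' @export
as_intersim_data <- function(df, predictors, outcome = "y") {
  stopifnot(is.data.frame(df), all(predictors %in% names(df)),
            outcome %in% names(df))
  y <- df[[outcome]]
  stopifnot(all(y %in% c(0, 1)))
  fac <- lapply(df[predictors], function(v) factor(v))
  grid <- expand.grid(rev(lapply(fac, levels)), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = TRUE)
  grid <- grid[, rev(seq_along(predictors)), drop = FALSE]
  names(grid) <- predictors
  key <- function(d) do.call(paste, c(d, sep = "\r"))
  id_of <- setNames(seq_len(nrow(grid)) - 1L, key(grid))
  d <- as.data.frame(fac)
  d$y <- as.integer(y)
  d$intersection_id <- as.integer(id_of[key(d[predictors])])
  tab <- grid
  tab$intersection_id <- seq_len(nrow(grid)) - 1L
  tab$n <- tabulate(d$intersection_id + 1L, nbins = nrow(grid))
  structure(list(data = d,
                 intersections = tab,
                 predictors = predictors,
                 types = setNames(rep("categorical", length(predictors)),
                                  predictors),
                 input_type = "categorical",
                 outcome = "y",
                 scenario = NULL,
                 coefficients = NULL,
                 sample_prevalence = mean(d$y),
                 empty_intersections = sum(tab$n == 0L),
                 simulated = FALSE),
            class = "intersim_data")
}

#' Write / read a simulated dataset as CSV plus a JSON sidecar
#'
#' The CSV holds the individual-level records (`x1`..`x6`, `y`,
#' `true_prob`, `intersection_id`); the sidecar JSON records the scenario
#' and the accepted coefficient draw so the dataset round-trips losslessly.
#'
#' @param dataset An `intersim_data` object from [generate_dataset()].
#' @param path CSV file path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly (`write_dataset`); an `intersim_data` object
#'   (`read_dataset`).
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "intersim_data"), isTRUE(dataset$simulated))
  write.csv(dataset$data, path, row.names = FALSE)
  sc <- dataset$scenario
  cf <- dataset$coefficients
  meta <- list(scenario = sc[c("input_type", "prevalence_tier",
                               "n_individuals", "n_iterations",
                               "master_seed", "interaction_boost")],
               coefficients = list(input_type = cf$input_type,
                                   prevalence_tier = cf$prevalence_tier,
                                   intercept = cf$intercept,
                                   beta = as.list(cf$beta)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  sc <- do.call(scenario_config, meta$scenario)
  cf <- coefficient_draw(meta$coefficients$input_type,
                         meta$coefficients$intercept,
                         unlist(meta$coefficients$beta),
                         meta$coefficients$prevalence_tier)
  d <- read.csv(path)
  out <- generate_dataset_from_rows(sc, cf, d)
  out
}

# rebuild the intersim_data container from stored individual rows
generate_dataset_from_rows <- function(scenario, coefficients, d) {
  tab <- all_intersections()
  tab$n <- tabulate(d$intersection_id + 1L, nbins = N_INTERSECTIONS)
  if (scenario$input_type == "categorical") {
    tab$true_prevalence <- exp(categorical_lp(coefficients, tab))
  } else {
    s <- rowsum(d$true_prob, d$intersection_id)
    tp <- rep(NA_real_, N_INTERSECTIONS)
    tp[as.integer(rownames(s)) + 1L] <-
      s[, 1] / tab$n[as.integer(rownames(s)) + 1L]
    tab$true_prevalence <- tp
  }
  structure(list(data = d, intersections = tab,
                 predictors = paste0("x", 1:6),
                 types = setNames(
                   if (scenario$input_type == "categorical")
                     rep("categorical", 6)
                   else c("continuous", rep("categorical", 4), "continuous"),
                   paste0("x", 1:6)),
                 input_type = scenario$input_type, outcome = "y",
                 scenario = scenario, coefficients = coefficients,
                 sample_prevalence = mean(d$y),
                 empty_intersections = sum(tab$n == 0L),
                 simulated = TRUE),
            class = "intersim_data")
}
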