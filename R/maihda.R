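# MAIHDA: multilevel logistic regression with fixed main effects for each
# social position variable and a random intercept for every intersection,
# fitted by Laplace-approximated maximum likelihood (lme4::glmer). The
# intersection residuals (BLUPs, posterior modes) shrink toward zero as the
# intersection's sample size shrinks — the partial-pooling behaviour that
# stabilises small-intersection estimates.

fit_maihda <- function(dataset, ...) {
  if (sum(dataset$intersections$n > 0L) < 2L)
    stop("MAIHDA requires at least two populated intersections")
  rhs <- paste(dataset$predictors, collapse = " + ")
  if (dataset$input_type == "categorical") {
    # covariates are constant within an intersection, so the individual
    # Bernoulli likelihood aggregates exactly to cell-level binomial counts
    d <- dataset$data
    ev <- rowsum(d$y, d$intersection_id)
    cells <- dataset$intersections[dataset$intersections$n > 0L, ,
                                   drop = FALSE]
    cells$events <- ev[match(cells$intersection_id,
                             as.integer(rownames(ev))), 1]
    cells <- poisson_frame(dataset, cells)
    cells$.isect <- factor(cells$intersection_id)
    fml <- as.formula(paste("cbind(events, n - events) ~", rhs,
                            "+ (1 | .isect)"))
    fit_data <- cells
  } else {
    fit_data <- poisson_frame(dataset, dataset$data)
    fit_data$.isect <- factor(fit_data$intersection_id)
    fml <- as.formula(paste("y ~", rhs, "+ (1 | .isect)"))
  }
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::glmer(fml, data = fit_data, family = binomial(), nAGQ = 1L,
                  ...))),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(new_intersim_fit("intersim_fit_maihda", converged = FALSE,
                            dataset = dataset,
                            metadata = list(error = conditionMessage(fit))))
  }
  theta <- lme4::getME(fit, "theta")
  vc <- as.numeric(theta)^2
  re <- lme4::ranef(fit)$.isect
  blups <- setNames(re[, 1], rownames(re))
  cf <- lme4::fixef(fit)
  conv_ok <- all(is.finite(cf)) && is.finite(vc)
  new_intersim_fit("intersim_fit_maihda",
                   model = fit,
                   coefficients = cf,
                   random_intercept_variance = vc,
                   blups = blups,
                   converged = conv_ok,
                   dataset = dataset,
                   metadata = list(
                     boundary = vc < 1e-8,
                     note = if (vc < 1e-8)
                       "variance component at zero: reduces to main-effects logistic"
                     else NULL,
                     messages = length(fit@optinfo$conv$lme4$messages)))
}

#' @export
predict_impl.intersim_fit_maihda <- function(object, dataset) {
  # inverse-logit(fixed linear predictor + BLUP); unseen intersections get
  # BLUP 0 (allow.new.levels); member-level risks averaged per cell when
  # covariates vary within intersections (mixed inputs)
  if (dataset$input_type == "categorical") {
    cells <- dataset$intersections[dataset$intersections$n > 0L, ,
                                   drop = FALSE]
    nd <- poisson_frame(dataset, cells)
    nd$events <- 0; nd$n <- 1
    nd$.isect <- factor(nd$intersection_id)
    p <- predict(object$model, newdata = nd, type = "response",
                 allow.new.levels = TRUE)
    data.frame(intersection_id = cells$intersection_id, estimate = p)
  } else {
    nd <- poisson_frame(dataset, dataset$data)
    nd$.isect <- factor(nd$intersection_id)
    p <- predict(object$model, newdata = nd, type = "response",
                 allow.new.levels = TRUE)
    average_by_intersection(p, dataset$data$intersection_id)
  }
}

# fixed-effects-only per-intersection prediction (BLUPs set to zero);
# used to study shrinkage/partial pooling
maihda_fixed_prediction <- function(object, dataset) {
  if (dataset$input_type == "categorical") {
    cells <- dataset$intersections[dataset$intersections$n > 0L, ,
                                   drop = FALSE]
    nd <- poisson_frame(dataset, cells)
    nd$events <- 0; nd$n <- 1
    nd$.isect <- factor(nd$intersection_id)
    p <- predict(object$model, newdata = nd, type = "response",
                 re.form = NA)
    data.frame(intersection_id = cells$intersection_id, estimate = p)
  } else {
    nd <- poisson_frame(dataset, dataset$data)
    nd$.isect <- factor(nd$intersection_id)
    p <- predict(object$model, newdata = nd, type = "response",
                 re.form = NA)
    average_by_intersection(p, dataset$data$intersection_id)
  }
}
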