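# Modified Poisson regression: log-link Poisson likelihood on a binary
# outcome, giving relative-risk coefficients, with a robust (sandwich)
# covariance A^-1 B A^-1 in place of the model-based one.
#
# When every predictor is categorical the intersections index the covariate
# patterns exactly, so the fit runs on cell-aggregated counts with an
# exposure offset (identical likelihood and MLE to the individual-level
# fit) and the individual-level HC0 sandwich is recovered in closed form
# from the cell aggregates. Mixed inputs use the individual-level glm and
# sandwich::vcovHC.

poisson_rhs <- function(dataset, spec) {
  p <- dataset$predictors
  switch(spec,
    main_effects = paste(p, collapse = " + "),
    correct_spec = {
      if (!identical(p, paste0("x", 1:6)))
        stop("correct_spec is defined only for the simulated X1..X6 design")
      "x1*x2 + x3*x4*x5 + x6"
    },
    saturated = paste(p, collapse = " * "))
}

# model frame with categorical predictors as factors
poisson_frame <- function(dataset, d) {
  for (p in dataset$predictors)
    if (dataset$types[[p]] == "categorical") d[[p]] <- factor(d[[p]])
  d
}

fit_modified_poisson <- function(dataset, spec = c("main_effects",
                                                   "correct_spec",
                                                   "saturated"), ...) {
  spec <- match.arg(spec)
  rhs <- poisson_rhs(dataset, spec)
  categorical <- dataset$input_type == "categorical"

  if (categorical) {
    cells <- dataset$intersections
    d <- dataset$data
    ev <- rowsum(d$y, d$intersection_id)
    cells$events <- 0
    cells$events[match(as.integer(rownames(ev)),
                       cells$intersection_id)] <- ev[, 1]
    cells <- cells[cells$n > 0L, , drop = FALSE]
    cells <- poisson_frame(dataset, cells)
    fml <- as.formula(paste("events ~", rhs, "+ offset(log(n))"))
    fit <- tryCatch(suppressWarnings(glm(fml, family = poisson(),
                                         data = cells)),
                    error = function(e) e)
  } else {
    d <- poisson_frame(dataset, dataset$data)
    fml <- as.formula(paste("y ~", rhs))
    fit <- tryCatch(suppressWarnings(glm(fml, family = poisson(), data = d)),
                    error = function(e) e)
  }
  if (inherits(fit, "error")) {
    # numerical divergence (e.g. overflow during step halving): recorded,
    # not raised
    return(new_intersim_fit("intersim_fit_poisson", spec = spec,
                            converged = FALSE, dataset = dataset,
                            metadata = list(design = rhs,
                                            aggregated = categorical,
                                            error = conditionMessage(fit))))
  }

  cf <- coef(fit)
  aliased <- names(cf)[is.na(cf)]
  finite <- all(is.finite(cf[!is.na(cf)]))
  converged <- isTRUE(fit$converged) && finite
  if (spec == "saturated" && length(aliased) > 0L) {
    # rank-deficient saturated design (empty intersection cells): the model
    # cannot estimate all pattern parameters; counted as non-converged
    converged <- FALSE
  }

  robust <- NULL
  if (converged) {
    robust <- tryCatch({
      if (categorical) aggregated_sandwich(fit)
      else sandwich::vcovHC(fit, type = "HC0")
    }, error = function(e) NULL)
  }
  robust_se <- if (!is.null(robust)) {
    dg <- diag(robust)
    sqrt(ifelse(dg >= 0, dg, NA_real_)) # boundary fits: ill-conditioned bread
  } else NULL

  new_intersim_fit("intersim_fit_poisson",
                   spec = spec,
                   model = fit,
                   coefficients = cf,
                   vcov_robust = robust,
                   robust_se = robust_se,
                   converged = converged,
                   dataset = dataset,
                   metadata = list(design = rhs,
                                   aggregated = categorical,
                                   aliased = aliased,
                                   glm_converged = isTRUE(fit$converged)))
}

# Individual-level HC0 sandwich from a cell-aggregated Poisson fit with
# offset log(n). Scores of the n_c binary individuals in cell c are
# (y_i - mu_c) x_c, so the meat is
#   sum_c [ events_c (1-mu_c)^2 + (n_c - events_c) mu_c^2 ] x_c x_c'
# and the bread is the expected information X' diag(n_c mu_c) X, which is
# exactly the aggregated glm's working-weight crossproduct.
aggregated_sandwich <- function(fit) {
  X <- model.matrix(fit)
  cf <- coef(fit)
  if (anyNA(cf)) X <- X[, !is.na(cf), drop = FALSE]
  mu_tot <- fitted(fit)                      # n_c * mu_c
  n <- fit$data$n
  events <- fit$y
  mu <- mu_tot / n
  A <- crossprod(X, X * mu_tot)
  m <- events * (1 - mu)^2 + (n - events) * mu^2
  B <- crossprod(X, X * m)
  Ai <- solve(A)
  V <- Ai %*% B %*% Ai
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

#' @export
predict_impl.intersim_fit_poisson <- function(object, dataset) {
  fit <- object$model
  if (object$metadata$aggregated) {
    cells <- dataset$intersections[dataset$intersections$n > 0L, ,
                                   drop = FALSE]
    nd <- poisson_frame(dataset, cells)
    nd$n <- 1 # offset log(1) = 0: response is the per-individual rate
    mu <- suppressWarnings(predict(fit, newdata = nd, type = "response"))
    data.frame(intersection_id = cells$intersection_id, estimate = mu)
  } else {
    nd <- poisson_frame(dataset, dataset$data)
    mu <- suppressWarnings(predict(fit, newdata = nd, type = "response"))
    average_by_intersection(mu, dataset$data$intersection_id)
  }
}
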