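#' Fit an intersection-prevalence estimator
#'
#' Single front-end to the nine estimation methods compared by the
#' package. All methods consume an `intersim_data` object (from
#' [generate_dataset()] or [as_intersim_data()]) and, through
#' [predict.intersim_fit()], emit the estimated outcome prevalence for
#' every intersection observed in the training data.
#'
#' Methods:
#' \describe{
#'   \item{`cross_classification`}{raw within-intersection event
#'     proportion, no statistical adjustment.}
#'   \item{`main_effects`}{modified Poisson regression (log link, robust
#'     sandwich variance) with main effects X1..X6 only — the
#'     non-intersectional comparator.}
#'   \item{`correct_spec`}{modified Poisson including exactly the
#'     interactions present in the generating model (X1*X2 and
#'     X3*X4*X5 with all lower-order products); simulated data only.}
#'   \item{`saturated`}{modified Poisson with all interactions among the
#'     predictors (continuous predictors entered linearly).}
#'   \item{`maihda`}{multilevel logistic regression: fixed effects X1..X6
#'     plus a random intercept per intersection, Laplace-approximated ML
#'     via \pkg{lme4}.}
#'   \item{`cart`}{Gini-split classification tree, cost-complexity pruned
#'     at the complexity parameter with minimal 10-fold cross-validation
#'     error (\pkg{rpart}).}
#'   \item{`ctree`}{conditional-inference-style tree: per-node association
#'     tests with Bonferroni-adjusted stopping at `alpha`.}
#'   \item{`chaid`}{Kass-style CHAID: per-variable category merging then
#'     Bonferroni-adjusted multiway splits; categorical predictors only.}
#'   \item{`random_forest`}{500-tree random forest (\pkg{ranger}),
#'     `mtry` tuned over a unit-step grid by out-of-bag Brier score,
#'     minimum terminal node size 1.}
#' }
#'
#' @param dataset An `intersim_data` object.
#' @param method One of the method tags above.
#' @param ... Method-specific options, passed to the internal fitters
#'   (e.g. `alpha`, `num_trees`, `permutation_pvalues`).
#' @return An object of class `intersim_fit` (with a method-specific
#'   subclass) carrying the fitted model, a `converged` flag and fit
#'   metadata.
#' @examples
#' sc <- scenario_config("categorical", "common", 4000)
#' ds <- generate_dataset(sc, rng_seed = 11)
#' fit <- fit_prevalence(ds, "main_effects")
#' head(predict(fit))
#' @export
fit_prevalence <- function(dataset,
                           method = c("cross_classification", "main_effects",
                                      "correct_spec", "saturated", "maihda",
                                      "cart", "ctree", "chaid",
                                      "random_forest"),
                           ...) {
  stopifnot(inherits(dataset, "intersim_data"))
  method <- match.arg(method)
  fit <- switch(method,
    cross_classification = fit_cross_classification(dataset),
    main_effects = fit_modified_poisson(dataset, "main_effects", ...),
    correct_spec = fit_modified_poisson(dataset, "correct_spec", ...),
    saturated = fit_modified_poisson(dataset, "saturated", ...),
    maihda = fit_maihda(dataset, ...),
    cart = fit_cart(dataset, ...),
    ctree = fit_ctree(dataset, ...),
    chaid = fit_chaid(dataset, ...),
    random_forest = fit_random_forest(dataset, ...))
  fit$method <- method
  fit$input_type <- dataset$input_type
  class(fit) <- unique(c(class(fit), "intersim_fit"))
  fit
}

new_intersim_fit <- function(subclass, ...) {
  structure(list(...), class = c(subclass, "intersim_fit"))
}

#' @export
print.intersim_fit <- function(x, ...) {
  cat(sprintf("intersim fit: %s (%s inputs), %s\n", x$method, x$input_type,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  if (!is.null(x$metadata) && length(x$metadata))
    cat("  metadata:", paste(names(x$metadata),
                             vapply(x$metadata, function(v)
                               paste(format(v), collapse = ","), ""),
                             sep = "=", collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.intersim_fit <- function(object, ...) {
  print(object)
  if (isTRUE(object$converged)) {
    est <- predict(object)
    cat(sprintf("  %d intersection estimates, range %.4f-%.4f\n",
                nrow(est), min(est$estimate), max(est$estimate)))
  }
  invisible(object)
}

#' @export
coef.intersim_fit <- function(object, ...) {
  object$coefficients
}

#' Per-intersection prevalence estimates from a fitted method
#'
#' Realizes the method's estimated outcome prevalence for every
#' intersection observed in the training data: pattern-level prediction
#' where intersections determine the covariates exactly (categorical
#' inputs), otherwise the average of member-level predicted risks.
#' Log-link predictions can exceed 1 and are clipped to \[0, 1\]; the clip
#' count is reported in the attribute `n_clipped`.
#'
#' @param object An `intersim_fit`.
#' @param dataset Dataset to predict for; defaults to the training data.
#' @param ... Unused.
#' @return A data frame (`intersection_id`, `n`, `estimate`) with
#'   attributes `method`, `converged` and `n_clipped`. Requesting
#'   predictions from a non-converged fit is an error.
#' @export
predict.intersim_fit <- function(object, dataset = NULL, ...) {
  if (!isTRUE(object$converged))
    stop(sprintf("cannot predict from non-converged %s fit", object$method))
  if (is.null(dataset)) dataset <- object$dataset
  stopifnot(inherits(dataset, "intersim_data"))
  res <- predict_impl(object, dataset)
  keep <- dataset$intersections$n > 0L
  out <- data.frame(intersection_id =
                      dataset$intersections$intersection_id[keep],
                    n = dataset$intersections$n[keep])
  est <- res$estimate[match(out$intersection_id, res$intersection_id)]
  if (anyNA(est))
    stop(sprintf("method %s produced no estimate for %d populated intersection(s)",
                 object$method, sum(is.na(est))))
  n_clip <- sum(est > 1 | est < 0)
  out$estimate <- pmin(1, pmax(0, est))
  structure(out, method = object$method, converged = TRUE,
            n_clipped = n_clip)
}

predict_impl <- function(object, dataset) UseMethod("predict_impl")

# --- cross-classification ---------------------------------------------------

fit_cross_classification <- function(dataset) {
  d <- dataset$data
  ev <- rowsum(d$y, d$intersection_id)
  nn <- rowsum(rep(1L, nrow(d)), d$intersection_id)
  est <- data.frame(intersection_id = as.integer(rownames(ev)),
                    estimate = ev[, 1] / nn[, 1])
  new_intersim_fit("intersim_fit_cc",
                   converged = TRUE,
                   estimates = est,
                   dataset = dataset,
                   metadata = list(note = "raw within-intersection proportion"))
}

#' @export
predict_impl.intersim_fit_cc <- function(object, dataset) {
  d <- dataset$data
  ev <- rowsum(d$y, d$intersection_id)
  nn <- rowsum(rep(1L, nrow(d)), d$intersection_id)
  data.frame(intersection_id = as.integer(rownames(ev)),
             estimate = ev[, 1] / nn[, 1])
}

# average member-level predicted risks within each intersection
average_by_intersection <- function(pred, intersection_id) {
  s <- rowsum(pred, intersection_id)
  n <- rowsum(rep(1L, length(pred)), intersection_id)
  data.frame(intersection_id = as.integer(rownames(s)),
             estimate = s[, 1] / n[, 1])
}
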