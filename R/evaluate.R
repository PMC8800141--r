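# Accuracy and variable-selection metrics.

#' Prevalence-scaled mean absolute deviation (MAD)
#'
#' The package's primary accuracy metric: the mean over intersections of
#' the absolute difference between estimated and true prevalence, divided
#' by the overall sample prevalence,
#' `MAD = (1/n) * sum_i |Phat_i - P_i| / p`. Each intersection is weighted
#' equally, so accuracy is scored at the subpopulation level rather than
#' the individual level; a MAD of 0 occurs only under perfect estimation
#' of every intersection. Intersections empty in the realized sample carry
#' no estimate and are excluded, with `n` reduced accordingly and the
#' exclusion counted.
#'
#' @param estimates Either the data frame returned by
#'   [predict.intersim_fit()] or a numeric vector named by intersection id.
#' @param truth Numeric vector of true prevalences named by intersection id
#'   (e.g. [true_intersection_prevalence()]).
#' @param p Overall outcome prevalence in the sample; must be positive.
#' @param method Method label used in error messages.
#' @return A list: `mad`, `n_intersections_used`, `n_excluded`.
#' @examples
#' compute_mad(c(`0` = 0.2, `1` = 0.4), c(`0` = 0.1, `1` = 0.3), p = 0.2)
#' @export
compute_mad <- function(estimates, truth, p, method = "estimator") {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0)
    stop("overall prevalence p must be a single positive number")
  if (is.data.frame(estimates)) {
    est <- setNames(estimates$estimate, estimates$intersection_id)
  } else {
    est <- estimates
  }
  if (is.null(names(est)) || is.null(names(truth)))
    stop("estimates and truth must be named by intersection id")
  ids <- names(est)
  tr <- truth[ids]
  if (anyNA(tr))
    stop(sprintf("no true prevalence for %d intersection(s) estimated by %s",
                 sum(is.na(tr)), method))
  if (anyNA(est))
    stop(sprintf("method %s is missing estimates for %d intersection(s)",
                 method, sum(is.na(est))))
  n_excluded <- length(setdiff(names(truth)[!is.na(truth)], ids))
  list(mad = mean(abs(est - tr)) / p,
       n_intersections_used = length(ids),
       n_excluded = n_excluded)
}

#' Convergence proportions across iterations
#'
#' @param results Data frame with at least `converged` (logical) and the
#'   grouping columns in `by`.
#' @param by Character vector of grouping columns.
#' @return Data frame with `n_iterations` and `pct_converged` per group.
#' @export
summarize_convergence <- function(results,
                                  by = intersect(c("scenario", "method", "n"),
                                                 names(results))) {
  stopifnot("converged" %in% names(results))
  agg <- aggregate(results["converged"], results[by],
                   function(z) c(n = length(z), pct = 100 * mean(z)))
  out <- agg[by]
  out$n_iterations <- agg$converged[, "n"]
  out$pct_converged <- agg$converged[, "pct"]
  out
}

#' Variable-splitting percentages across tree fits
#'
#' For single-tree methods, the percentage of iterations in which each
#' variable was used at least once as a splitting variable.
#'
#' @param fits List of tree fits (each with a `variables_used` field), or a
#'   list of character vectors of used variables.
#' @param variables Variables to report on.
#' @return Data frame `variable`, `splitting_percentage`, `n_iterations`.
#' @export
splitting_percentages <- function(fits, variables = paste0("x", 1:6)) {
  used <- lapply(fits, function(f)
    if (is.character(f)) f else f$variables_used)
  pct <- vapply(variables, function(v)
    100 * mean(vapply(used, function(u) v %in% u, logical(1))), numeric(1))
  data.frame(variable = variables, splitting_percentage = unname(pct),
             n_iterations = length(used))
}

#' Per-intersection bias and variance across iterations
#'
#' For a single fixed coefficient draw replicated across iterations,
#' computes for every intersection the bias (mean estimate minus truth) and
#' the variance of the estimates over iterations, both on the
#' percentage-point scale (bias x100; variance x100^2), plus their
#' median/min/max over intersections.
#'
#' @param estimates Long data frame with columns `iteration`,
#'   `intersection_id`, `estimate`.
#' @param truth Named numeric vector of true prevalences.
#' @param draw_id Optional vector (same length as `estimates` rows or one
#'   per iteration is not supported) identifying the coefficient draw of
#'   each row; an error is raised when more than one distinct draw is mixed.
#' @return A list: `per_intersection` data frame (`intersection_id`,
#'   `n_iterations`, `bias`, `variance`) and `summary` data frame with
#'   median/min/max of each.
#' @export
bias_variance_by_intersection <- function(estimates, truth, draw_id = NULL) {
  stopifnot(all(c("iteration", "intersection_id", "estimate") %in%
                  names(estimates)))
  if (!is.null(draw_id) && length(unique(draw_id)) > 1L)
    stop("bias/variance assessment mixes iterations from different ",
         "coefficient draws")
  ids <- sort(unique(estimates$intersection_id))
  tr <- truth[as.character(ids)]
  if (anyNA(tr)) stop("truth missing for some estimated intersections")
  per <- do.call(rbind, lapply(seq_along(ids), function(i) {
    e <- estimates$estimate[estimates$intersection_id == ids[i]]
    data.frame(intersection_id = ids[i],
               n_iterations = length(e),
               bias = 100 * (mean(e) - tr[i]),
               variance = 1e4 * if (length(e) > 1L) var(e) else 0)
  }))
  s <- function(v) c(median = median(v), min = min(v), max = max(v))
  list(per_intersection = per,
       summary = data.frame(statistic = c("median", "min", "max"),
                            bias = unname(s(per$bias)),
                            variance = unname(s(per$variance))))
}

#' Write per-intersection estimates to long-format CSV
#'
#' @param estimates Data frame from [predict.intersim_fit()].
#' @param path Output CSV path.
#' @param scenario,iteration Labels recorded in the output columns.
#' @return `path`, invisibly.
#' @export
write_estimates_csv <- function(estimates, path, scenario = NA,
                                iteration = NA) {
  out <- data.frame(scenario = scenario, iteration = iteration,
                    method = attr(estimates, "method"),
                    intersection_id = estimates$intersection_id,
                    estimate = estimates$estimate,
                    converged = attr(estimates, "converged"))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
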