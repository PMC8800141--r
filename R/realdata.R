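# Real-data demonstration path: a flat survey-style table with four social
# position variables and repeated blood-pressure readings is turned into a
# binary high-blood-pressure outcome over the cross-classified
# intersections, and every applicable estimation method is fitted.

#' Describe the columns and outcome rule of a real-data table
#'
#' @param sex,race,age,poverty Names of the four social position columns.
#' @param sbp,dbp Character vectors naming up to three systolic and three
#'   diastolic reading columns; available readings are averaged per person.
#' @param sbp_threshold,dbp_threshold High-blood-pressure thresholds in
#'   mmHg; the outcome is 1 when the systolic average is at or above
#'   `sbp_threshold` and/or the diastolic average is at or above
#'   `dbp_threshold`.
#' @return A list of class `intersim_realdata_spec`.
#' @export
real_data_spec <- function(sex = "sex", race = "race_ethnicity",
                           age = "age_group", poverty = "poverty",
                           sbp = c("sbp1", "sbp2", "sbp3"),
                           dbp = c("dbp1", "dbp2", "dbp3"),
                           sbp_threshold = 130, dbp_threshold = 80) {
  structure(list(columns = c(sex = sex, race = race, age = age,
                             poverty = poverty),
                 sbp = sbp, dbp = dbp,
                 sbp_threshold = sbp_threshold,
                 dbp_threshold = dbp_threshold),
            class = "intersim_realdata_spec")
}

# average a person's available readings; NA when none are available
mean_readings <- function(df, cols) {
  m <- as.matrix(df[, cols, drop = FALSE])
  rowMeans(m, na.rm = TRUE)
}

#' Run the method suite on a real-data table
#'
#' Computes the binary high-blood-pressure outcome (average of available
#' readings, threshold rule with OR logic), forms intersections by
#' cross-classifying the four social position variables, drops rows with
#' missing identity columns or no usable reading of either type
#' (complete-case), and fits every applicable method.
#'
#' @param table Data frame per the spec (e.g. from
#'   [generate_nhanes_like_fixture()]).
#' @param spec A [real_data_spec()].
#' @param methods Methods to fit; `correct_spec` is not applicable to real
#'   data and is refused.
#' @param ... Passed to [fit_prevalence()].
#' @return A list: `estimates` (long data frame: intersection labels x
#'   method x estimate, with convergence flags), `variable_selection`
#'   (per-method splitting indicators and random-forest VIMs),
#'   `n_dropped_missing`, `prevalence`, and the underlying `dataset`.
#' @export
run_real_data <- function(table, spec = real_data_spec(),
                          methods = c("cross_classification", "main_effects",
                                      "saturated", "maihda", "cart", "ctree",
                                      "chaid", "random_forest"),
                          ...) {
  stopifnot(inherits(spec, "intersim_realdata_spec"))
  if ("correct_spec" %in% methods)
    stop("correct_spec requires known generating interactions; not ",
         "applicable to real data")
  cols <- spec$columns
  stopifnot(all(cols %in% names(table)))
  sbp <- mean_readings(table, intersect(spec$sbp, names(table)))
  dbp <- mean_readings(table, intersect(spec$dbp, names(table)))
  keep <- stats::complete.cases(table[, cols]) & is.finite(sbp) &
    is.finite(dbp)
  n_dropped <- sum(!keep)
  df <- table[keep, , drop = FALSE]
  df$y <- as.integer(sbp[keep] >= spec$sbp_threshold |
                       dbp[keep] >= spec$dbp_threshold)
  ds <- as_intersim_data(df, predictors = unname(cols), outcome = "y")
  absent <- ds$intersections[ds$intersections$n == 0L, , drop = FALSE]
  if (nrow(absent))
    warning(sprintf("%d intersection(s) have no observations and are omitted",
                    nrow(absent)))

  est_rows <- list(); vs_rows <- list(); rf_vim <- NULL
  labels <- ds$intersections
  lab_str <- do.call(paste, c(labels[unname(cols)], sep = " | "))
  for (m in methods) {
    fit <- tryCatch(fit_prevalence(ds, m, ...), error = function(e) e)
    failed <- inherits(fit, "error") || !isTRUE(fit$converged)
    if (!failed) {
      pr <- predict(fit, ds)
      i <- match(pr$intersection_id, labels$intersection_id)
      est_rows[[m]] <- data.frame(intersection = lab_str[i],
                                  intersection_id = pr$intersection_id,
                                  n = pr$n, method = m,
                                  estimate = pr$estimate,
                                  converged = TRUE)
      if (m %in% c("cart", "ctree", "chaid"))
        vs_rows[[m]] <- data.frame(method = m, variable = unname(cols),
                                   used = unname(cols) %in%
                                     fit$variables_used)
      if (m == "random_forest") rf_vim <- variable_importance(fit)
    } else {
      est_rows[[m]] <- data.frame(intersection = NA, intersection_id = NA,
                                  n = NA, method = m, estimate = NA,
                                  converged = FALSE)
    }
  }
  list(estimates = do.call(rbind, c(est_rows, make.row.names = FALSE)),
       variable_selection = do.call(rbind, c(vs_rows,
                                             make.row.names = FALSE)),
       random_forest_vim = rf_vim,
       n_dropped_missing = n_dropped,
       prevalence = ds$sample_prevalence,
       dataset = ds)
}
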