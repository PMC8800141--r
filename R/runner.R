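# Experiment runner: replicated scenario grids with per-iteration child
# seeds, collecting MAD rows, convergence flags and variable-selection
# records. Results are deterministic given the master seed, independent of
# method order or which subset of methods is requested (each fit reseeds
# from its own derived seed).

#' Run a simulation grid
#'
#' For every scenario and iteration: derive a child seed, draw effect
#' sizes, generate a dataset, fit every requested method, and record the
#' prevalence-scaled MAD, convergence flag and (for single-tree methods)
#' the splitting variables. Any single-iteration fit failure is recorded
#' as non-converged, never fatal to the grid.
#'
#' @param scenarios A single [scenario_config()] or a list of them.
#' @param methods Character vector of method tags (see [fit_prevalence()]).
#'   CHAID is refused for mixed-input scenarios.
#' @param reps Iterations per scenario; defaults to each scenario's
#'   `n_iterations`.
#' @param master_seed Master seed; defaults to the first scenario's.
#' @param fixed_coefficients If `TRUE`, one coefficient draw per scenario
#'   is reused across all iterations (the bias/variance sensitivity
#'   design).
#' @param keep_estimates If `TRUE`, per-intersection estimates are returned
#'   in a long data frame (needed for [bias_variance_by_intersection()]).
#' @param out_dir Optional directory; results are also written there as
#'   CSV files plus a JSON manifest.
#' @param ... Extra arguments passed to every [fit_prevalence()] call.
#' @return A list of data frames: `mad`, `convergence`, `splits`,
#'   optionally `estimates`, and a `manifest` list of seeds and counters.
#' @export
run_grid <- function(scenarios, methods = c("cross_classification",
                                            "main_effects", "maihda"),
                     reps = NULL, master_seed = NULL,
                     fixed_coefficients = FALSE,
                     keep_estimates = FALSE, out_dir = NULL, ...) {
  if (inherits(scenarios, "intersim_scenario")) scenarios <- list(scenarios)
  stopifnot(all(vapply(scenarios, inherits, logical(1),
                       "intersim_scenario")))
  methods <- match.arg(methods, c("cross_classification", "main_effects",
                                  "correct_spec", "saturated", "maihda",
                                  "cart", "ctree", "chaid", "random_forest"),
                       several.ok = TRUE)
  for (sc in scenarios)
    if ("chaid" %in% methods && sc$input_type == "mixed")
      stop("CHAID requires categorical inputs; remove it from `methods` ",
           "or drop the mixed-input scenario")
  if (is.null(master_seed)) master_seed <- scenarios[[1]]$master_seed
  tree_methods <- c("cart", "ctree", "chaid")
  method_index <- setNames(seq_len(9L) * 1000L,
                           c("cross_classification", "main_effects",
                             "correct_spec", "saturated", "maihda", "cart",
                             "ctree", "chaid", "random_forest"))

  mad_rows <- list(); conv_rows <- list(); split_rows <- list()
  est_rows <- list(); failures <- list()
  for (s in seq_along(scenarios)) {
    sc <- scenarios[[s]]
    n_reps <- if (is.null(reps)) sc$n_iterations else reps
    scen_label <- sprintf("%s_%s_N%d", sc$input_type, sc$prevalence_tier,
                          sc$n_individuals)
    fixed_draw <- NULL
    if (fixed_coefficients) {
      set.seed(derive_seed(master_seed, s, 0L))
      fixed_draw <- draw_coefficients(sc)
    }
    for (it in seq_len(n_reps)) {
      ds <- generate_dataset(sc, coefficients = fixed_draw,
                             rng_seed = derive_seed(master_seed, s, it))
      truth <- true_intersection_prevalence(ds)
      for (m in methods) {
        set.seed(derive_seed(master_seed, s,
                             it + method_index[[m]]))
        fit <- tryCatch(fit_prevalence(ds, m, ...), error = function(e) e)
        row_id <- length(conv_rows) + 1L
        if (inherits(fit, "error")) {
          failures[[length(failures) + 1L]] <-
            list(scenario = scen_label, iteration = it, method = m,
                 message = conditionMessage(fit))
          conv_rows[[row_id]] <- data.frame(
            scenario = scen_label, input_type = sc$input_type,
            tier = sc$prevalence_tier, n = sc$n_individuals,
            iteration = it, method = m, converged = FALSE)
          next
        }
        conv_rows[[row_id]] <- data.frame(
          scenario = scen_label, input_type = sc$input_type,
          tier = sc$prevalence_tier, n = sc$n_individuals,
          iteration = it, method = m, converged = isTRUE(fit$converged))
        if (m %in% tree_methods) {
          split_rows[[length(split_rows) + 1L]] <- data.frame(
            scenario = scen_label, n = sc$n_individuals, iteration = it,
            method = m,
            variable = ds$predictors,
            used = ds$predictors %in% fit$variables_used)
        }
        if (isTRUE(fit$converged)) {
          est <- predict(fit, ds)
          md <- compute_mad(est, truth, ds$sample_prevalence, method = m)
          mad_rows[[length(mad_rows) + 1L]] <- data.frame(
            scenario = scen_label, input_type = sc$input_type,
            tier = sc$prevalence_tier, n = sc$n_individuals,
            iteration = it, method = m, mad = md$mad,
            n_intersections_used = md$n_intersections_used)
          if (keep_estimates)
            est_rows[[length(est_rows) + 1L]] <- data.frame(
              scenario = scen_label, iteration = it, method = m,
              intersection_id = est$intersection_id,
              estimate = est$estimate)
        }
      }
    }
  }
  out <- list(mad = do.call(rbind, mad_rows),
              convergence = do.call(rbind, conv_rows),
              splits = do.call(rbind, split_rows),
              manifest = list(master_seed = master_seed,
                              methods = methods,
                              fixed_coefficients = fixed_coefficients,
                              n_scenarios = length(scenarios),
                              failures = failures))
  if (keep_estimates) out$estimates <- do.call(rbind, est_rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("mad", "convergence", "splits", "estimates"))
      if (!is.null(out[[nm]]))
        write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                  row.names = FALSE)
    jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}
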