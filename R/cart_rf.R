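# CART (rpart) and random forest (ranger) estimators.

tree_frame <- function(dataset) {
  d <- poisson_frame(dataset, dataset$data)
  d$y <- factor(d$y, levels = c(0, 1))
  d[, c(dataset$predictors, "y")]
}

# Gini-split classification tree; cost-complexity path pruned at the
# complexity parameter with minimal 10-fold cross-validation error.
fit_cart <- function(dataset, cp = 1e-5, minsplit = 20L, xval = 10L) {
  d <- tree_frame(dataset)
  fit <- rpart::rpart(y ~ ., data = d, method = "class",
                      control = rpart::rpart.control(
                        minsplit = minsplit, cp = cp, xval = xval,
                        maxcompete = 0L, maxsurrogate = 0L,
                        usesurrogate = 0L))
  cptab <- fit$cptable
  best <- which.min(cptab[, "xerror"])
  pruned <- rpart::prune(fit, cp = cptab[best, "CP"])
  vars <- setdiff(unique(as.character(pruned$frame$var)), "<leaf>")
  new_intersim_fit("intersim_fit_cart",
                   model = pruned,
                   converged = TRUE,
                   variables_used = vars,
                   dataset = dataset,
                   metadata = list(cp = unname(cptab[best, "CP"]),
                                   cp_table = cptab,
                                   n_splits = sum(pruned$frame$var != "<leaf>")))
}

#' @export
predict_impl.intersim_fit_cart <- function(object, dataset) {
  nd <- tree_frame(dataset)
  p <- predict(object$model, newdata = nd, type = "prob")[, "1"]
  average_by_intersection(p, dataset$data$intersection_id)
}

# Random forest of probability trees: num_trees trees, minimum terminal
# node size 1, mtry tuned over a unit-step grid by out-of-bag Brier score.
# Impurity VIM = total Gini decrease; permutation VIM p-values (optional,
# refit-intensive) by the Altmann response-permutation null.
fit_random_forest <- function(dataset, num_trees = 500L, mtry_grid = NULL,
                              permutation_pvalues = FALSE,
                              n_permutations = 100L, seed = NULL) {
  d <- tree_frame(dataset)
  if (is.null(mtry_grid)) mtry_grid <- seq_along(dataset$predictors)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  oob <- vapply(mtry_grid, function(m) {
    rf <- ranger::ranger(y ~ ., data = d, num.trees = num_trees, mtry = m,
                         min.node.size = 1L, probability = TRUE,
                         seed = derive_seed(seed, m), num.threads = 1L)
    rf$prediction.error
  }, numeric(1))
  mtry <- mtry_grid[which.min(oob)]
  fit <- ranger::ranger(y ~ ., data = d, num.trees = num_trees, mtry = mtry,
                        min.node.size = 1L, probability = TRUE,
                        importance = "impurity",
                        seed = derive_seed(seed, 100L + mtry),
                        num.threads = 1L)
  perm <- NULL
  if (permutation_pvalues) {
    rf_perm <- ranger::ranger(y ~ ., data = d, num.trees = num_trees,
                              mtry = mtry, min.node.size = 1L,
                              probability = TRUE,
                              importance = "permutation",
                              seed = derive_seed(seed, 200L),
                              num.threads = 1L)
    pv <- ranger::importance_pvalues(rf_perm, method = "altmann",
                                     num.permutations = n_permutations,
                                     formula = y ~ ., data = d,
                                     seed = derive_seed(seed, 300L),
                                     num.threads = 1L)
    perm <- data.frame(variable = rownames(pv),
                       importance = pv[, "importance"],
                       p_value = pv[, "pvalue"], row.names = NULL)
  }
  new_intersim_fit("intersim_fit_rf",
                   model = fit,
                   converged = TRUE,
                   impurity_vim = fit$variable.importance,
                   permutation_vim = perm,
                   dataset = dataset,
                   metadata = list(mtry = mtry, num_trees = num_trees,
                                   oob_brier = setNames(oob, mtry_grid),
                                   n_permutations =
                                     if (permutation_pvalues) n_permutations
                                     else 0L))
}

#' @export
predict_impl.intersim_fit_rf <- function(object, dataset) {
  nd <- tree_frame(dataset)
  p <- predict(object$model, data = nd, num.threads = 1L)$predictions[, "1"]
  average_by_intersection(p, dataset$data$intersection_id)
}

#' Variable importance report from a fitted random forest
#'
#' @param fit An `intersim_fit` produced with `method = "random_forest"`.
#' @return Data frame with the impurity VIM (total Gini decrease) and, when
#'   the fit was run with `permutation_pvalues = TRUE`, the permutation VIM
#'   and its Altmann permutation-null p-value.
#' @export
variable_importance <- function(fit) {
  stopifnot(inherits(fit, "intersim_fit_rf"))
  out <- data.frame(variable = names(fit$impurity_vim),
                    impurity = unname(fit$impurity_vim))
  if (!is.null(fit$permutation_vim)) {
    i <- match(out$variable, fit$permutation_vim$variable)
    out$permutation <- fit$permutation_vim$importance[i]
    out$p_value <- fit$permutation_vim$p_value[i]
  }
  out
}
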