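# CHAID (chi-square automatic interaction detection), Kass-style, built
# from scratch. Per candidate variable the least-significantly-different
# pair of categories is merged while its 2x2 chi-square p-value exceeds the
# merge threshold; the merged table's split p-value is then Bonferroni
# adjusted by the number of ways the original categories can be partitioned
# into the merged groups. The node splits (multiway, one child per merged
# group) on the variable with the smallest adjusted p-value, if below
# alpha. Chi-square analysis requires categorical predictors throughout.

# Kass Bonferroni multiplier for a nominal predictor: number of ways to
# partition c original categories into r non-empty groups
# B = sum_{i=0}^{r-1} (-1)^i (r-i)^c / (i! (r-i)!)
chaid_bonferroni <- function(c_orig, r) {
  i <- 0:(r - 1)
  sum((-1)^i * (r - i)^c_orig / (factorial(i) * factorial(r - i)))
}

# greedy merge of category groups; counts: per-level totals and events
chaid_merge <- function(n_lev, s_lev, alpha_merge) {
  groups <- lapply(which(n_lev > 0), function(i) i)
  gn <- n_lev[n_lev > 0]; gs <- s_lev[n_lev > 0]
  while (length(groups) > 1L) {
    pairs <- utils::combn(length(groups), 2L)
    pvals <- apply(pairs, 2L, function(pr) {
      chisq_k2_p(gn[pr], gs[pr])$p
    })
    worst <- which.max(pvals)
    if (pvals[worst] <= alpha_merge) break
    pr <- pairs[, worst]
    groups[[pr[1]]] <- c(groups[[pr[1]]], groups[[pr[2]]])
    gn[pr[1]] <- gn[pr[1]] + gn[pr[2]]
    gs[pr[1]] <- gs[pr[1]] + gs[pr[2]]
    groups <- groups[-pr[2]]
    gn <- gn[-pr[2]]; gs <- gs[-pr[2]]
  }
  list(groups = groups, n = gn, s = gs)
}

# adjusted split p-value for one variable at a node
chaid_variable_p <- function(x, y, alpha_merge) {
  codes <- as.integer(x)
  k <- nlevels(x)
  n_lev <- tabulate(codes, nbins = k)
  s_lev <- tabulate(codes[y == 1L], nbins = k)
  c_present <- sum(n_lev > 0)
  if (c_present < 2L) return(NULL)
  mg <- chaid_merge(n_lev, s_lev, alpha_merge)
  r <- length(mg$groups)
  if (r < 2L) return(NULL) # fully merged: variable not splittable here
  raw <- chisq_k2_p(mg$n, mg$s)$p
  p_adj <- min(1, raw * chaid_bonferroni(c_present, r))
  list(p_adj = p_adj, p_raw = raw, groups = mg$groups, n = mg$n, s = mg$s)
}

fit_chaid <- function(dataset, alpha = 0.05, alpha_merge = 0.05,
                      minsplit = 20L) {
  if (any(dataset$types[dataset$predictors] != "categorical"))
    stop("CHAID is based on chi-squared analysis and requires categorical ",
         "predictors; this dataset has continuous inputs")
  d <- poisson_frame(dataset, dataset$data)
  y <- dataset$data$y
  preds <- dataset$predictors
  used <- character(0)
  node_id <- 0L

  build <- function(idx) {
    node_id <<- node_id + 1L
    n <- length(idx)
    node <- list(id = node_id, n = n, prop = mean(y[idx]), leaf = TRUE)
    if (n < minsplit || node$prop %in% c(0, 1)) return(node)
    cand <- lapply(preds, function(v)
      chaid_variable_p(droplevels(d[[v]][idx]), y[idx], alpha_merge))
    ok <- !vapply(cand, is.null, logical(1))
    if (!any(ok)) return(node)
    p_adj <- vapply(cand, function(cc) if (is.null(cc)) Inf else cc$p_adj,
                    numeric(1))
    if (min(p_adj) > alpha) return(node)
    w <- which.min(p_adj) # ties: smallest variable index
    winner <- preds[w]
    info <- cand[[w]]
    lev <- levels(droplevels(d[[winner]][idx]))
    group_levels <- lapply(info$groups, function(g) lev[g])
    used <<- union(used, winner)
    codes <- as.character(d[[winner]][idx])
    node$leaf <- FALSE
    node$var <- winner
    node$groups <- group_levels
    node$p_adj <- info$p_adj
    node$children <- lapply(group_levels, function(g)
      build(idx[codes %in% g]))
    node
  }

  root <- build(seq_len(nrow(d)))
  new_intersim_fit("intersim_fit_chaid",
                   root = root,
                   converged = TRUE,
                   variables_used = used,
                   dataset = dataset,
                   metadata = list(alpha = alpha, alpha_merge = alpha_merge,
                                   minsplit = minsplit, n_nodes = node_id))
}

route_chaid <- function(node, d, idx, out) {
  if (node$leaf) {
    out[idx] <- node$prop
    return(out)
  }
  x <- as.character(d[[node$var]][idx])
  assigned <- rep(0L, length(idx))
  for (g in seq_along(node$groups))
    assigned[x %in% node$groups[[g]]] <- g
  # unseen categories fall through to the largest child
  if (any(assigned == 0L))
    assigned[assigned == 0L] <-
      which.max(vapply(node$children, `[[`, numeric(1), "n"))
  for (g in seq_along(node$children))
    out <- route_chaid(node$children[[g]], d, idx[assigned == g], out)
  out
}

#' @export
predict_impl.intersim_fit_chaid <- function(object, dataset) {
  d <- poisson_frame(dataset, dataset$data)
  p <- route_chaid(object$root, d, seq_len(nrow(d)), numeric(nrow(d)))
  average_by_intersection(p, dataset$data$intersection_id)
}

#' @export
print.intersim_fit_chaid <- function(x, ...) {
  cat(sprintf("CHAID tree: %d nodes, splits on {%s} (alpha %.2f)\n",
              x$metadata$n_nodes, paste(x$variables_used, collapse = ", "),
              x$metadata$alpha))
  invisible(x)
}
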