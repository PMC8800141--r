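# Conditional-inference-style tree, built from scratch: at every node each
# candidate variable is tested for association with the outcome using an
# asymptotic chi-square statistic (Pearson form for categorical variables,
# squared-correlation form for continuous ones), p-values are Bonferroni
# adjusted across the candidates, and the node stops unless the smallest
# adjusted p-value is below alpha. The winning variable is split at the
# binary partition maximising the two-sample chi-square statistic.

# Pearson chi-square p-value for a k x 2 table given per-level totals and
# event counts; levels with zero total are dropped.
chisq_k2_p <- function(n_lev, s_lev) {
  keep <- n_lev > 0
  n_lev <- n_lev[keep]; s_lev <- s_lev[keep]
  k <- length(n_lev)
  n <- sum(n_lev); s <- sum(s_lev)
  if (k < 2L || s == 0 || s == n) return(list(p = 1, stat = 0, df = 0))
  e1 <- n_lev * s / n
  e0 <- n_lev - e1
  o1 <- s_lev; o0 <- n_lev - s_lev
  stat <- sum((o1 - e1)^2 / e1 + (o0 - e0)^2 / e0)
  list(p = pchisq(stat, df = k - 1L, lower.tail = FALSE), stat = stat,
       df = k - 1L)
}

# chi-square statistic of a 2x2 split (left/right x event/non-event),
# vectorised over candidate split positions
chisq_2x2_stat <- function(nL, sL, n, s) {
  nL <- as.numeric(nL); sL <- as.numeric(sL)
  n <- as.numeric(n); s <- as.numeric(s)
  nR <- n - nL; sR <- s - sL
  num <- n * (sL * (nR - sR) - sR * (nL - sL))^2
  den <- nL * nR * s * (n - s)
  out <- num / den
  out[den == 0] <- 0
  out
}

ctree_test <- function(x, y, type, n) {
  if (type == "categorical") {
    codes <- as.integer(x)
    n_lev <- tabulate(codes, nbins = nlevels(x))
    s_lev <- tabulate(codes[y == 1L], nbins = nlevels(x))
    chisq_k2_p(n_lev, s_lev)$p
  } else {
    if (sd(x) == 0) return(NA_real_)
    r <- suppressWarnings(cor(x, y))
    if (!is.finite(r)) return(NA_real_)
    stat <- (n - 1) * r^2
    pchisq(stat, df = 1L, lower.tail = FALSE)
  }
}

# best binary partition of the winning variable; returns NULL when no
# partition satisfies the minimum child size
ctree_best_split <- function(x, y, type, minbucket) {
  n <- length(y); s <- sum(y)
  if (type == "continuous") {
    o <- order(x)
    xs <- x[o]; ys <- y[o]
    cs <- cumsum(ys)
    i <- seq_len(n - 1L)
    ok <- (xs[i] < xs[i + 1L]) & (i >= minbucket) & ((n - i) >= minbucket)
    if (!any(ok)) return(NULL)
    stat <- chisq_2x2_stat(i[ok], cs[ok], n, s)
    b <- which.max(stat)
    pos <- i[ok][b]
    list(type = "continuous", cutpoint = (xs[pos] + xs[pos + 1L]) / 2)
  } else {
    codes <- as.integer(x)
    lev <- levels(x)
    n_lev <- tabulate(codes, nbins = length(lev))
    s_lev <- tabulate(codes[y == 1L], nbins = length(lev))
    present <- which(n_lev > 0)
    k <- length(present)
    if (k < 2L) return(NULL)
    best <- NULL; best_stat <- -Inf
    for (mask in 1:(2^(k - 1L) - 1L)) { # partitions, first level fixed right
      left <- present[bitwAnd(bitwShiftL(1L, seq_len(k) - 1L), mask) > 0L]
      nL <- sum(n_lev[left]); sL <- sum(s_lev[left])
      if (nL < minbucket || (n - nL) < minbucket) next
      stat <- chisq_2x2_stat(nL, sL, n, s)
      if (stat > best_stat) {
        best_stat <- stat
        best <- lev[left]
      }
    }
    if (is.null(best)) return(NULL)
    list(type = "categorical", left_levels = best)
  }
}

fit_ctree <- function(dataset, alpha = 0.05, minsplit = 20L, minbucket = 7L) {
  d <- poisson_frame(dataset, dataset$data)
  y <- dataset$data$y
  preds <- dataset$predictors
  types <- dataset$types
  used <- character(0)
  node_id <- 0L

  build <- function(idx) {
    node_id <<- node_id + 1L
    n <- length(idx)
    node <- list(id = node_id, n = n, prop = mean(y[idx]), leaf = TRUE)
    if (n < minsplit || node$prop %in% c(0, 1)) return(node)
    p <- vapply(preds, function(v)
      ctree_test(d[[v]][idx], y[idx], types[[v]], n), numeric(1))
    tested <- !is.na(p)
    if (!any(tested)) return(node)
    p_adj <- pmin(1, p * sum(tested))
    p_adj[!tested] <- Inf
    if (min(p_adj) > alpha) return(node)
    winner <- which.min(p_adj) # ties: smallest variable index
    sp <- ctree_best_split(d[[preds[winner]]][idx], y[idx],
                           types[[preds[winner]]], minbucket)
    if (is.null(sp)) return(node)
    used <<- union(used, preds[winner])
    go_left <- if (sp$type == "continuous")
      d[[preds[winner]]][idx] <= sp$cutpoint
    else d[[preds[winner]]][idx] %in% sp$left_levels
    node$leaf <- FALSE
    node$var <- preds[winner]
    node$split <- sp
    node$p_adj <- min(p_adj)
    node$children <- list(build(idx[go_left]), build(idx[!go_left]))
    node
  }

  root <- build(seq_len(nrow(d)))
  new_intersim_fit("intersim_fit_ctree",
                   root = root,
                   converged = TRUE,
                   variables_used = used,
                   dataset = dataset,
                   metadata = list(alpha = alpha, minsplit = minsplit,
                                   minbucket = minbucket,
                                   n_nodes = node_id))
}

route_binary_tree <- function(node, d, idx, out) {
  if (node$leaf) {
    out[idx] <- node$prop
    return(out)
  }
  x <- d[[node$var]][idx]
  go_left <- if (node$split$type == "continuous") x <= node$split$cutpoint
             else x %in% node$split$left_levels
  out <- route_binary_tree(node$children[[1]], d, idx[go_left], out)
  route_binary_tree(node$children[[2]], d, idx[!go_left], out)
}

#' @export
predict_impl.intersim_fit_ctree <- function(object, dataset) {
  d <- poisson_frame(dataset, dataset$data)
  p <- route_binary_tree(object$root, d, seq_len(nrow(d)),
                         numeric(nrow(d)))
  average_by_intersection(p, dataset$data$intersection_id)
}

#' @export
print.intersim_fit_ctree <- function(x, ...) {
  cat(sprintf(
    "conditional-inference tree: %d nodes, splits on {%s} (alpha %.2f)\n",
    x$metadata$n_nodes, paste(x$variables_used, collapse = ", "),
    x$metadata$alpha))
  invisible(x)
}

#' Serialize a fitted single-tree model to JSON
#'
#' Writes the node structure (split variables, rules, node sizes and event
#' proportions) of a CTree or CHAID fit as JSON.
#'
#' @param fit An `intersim_fit` from `method = "ctree"` or `"chaid"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(fit, path) {
  stopifnot(inherits(fit, "intersim_fit_ctree") ||
              inherits(fit, "intersim_fit_chaid"))
  jsonlite::write_json(list(method = fit$method,
                            variables_used = fit$variables_used,
                            tree = fit$root),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
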