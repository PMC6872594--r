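# Comparison selectors: ReliefF, random-forest permutation importance, lasso.
# All are deterministic given (data, params, seed) and return gene_ranking
# tibbles, so they are drop-in alternatives to fisher_score() in the pipeline.

#' Rank genes with ReliefF weights
#'
#' Weights start at zero. Each of `m` iterations draws a target sample T
#' (without replacement until the pool is exhausted, then reshuffles), finds
#' its nearest hit H (same class) and nearest miss M (different class) by
#' Manhattan distance over range-normalized features, and updates every
#' feature weight by `(-diff(f, T, H) + diff(f, T, M)) / m`, where
#' `diff(f, a, b) = |a_f - b_f| / range(f)`. Constant features have
#' `diff = 0` and finish with weight exactly 0. With `n_neighbors > 1` the
#' hit/miss contributions are averaged over the k nearest hits and misses.
#'
#' @param expression,sample_info Labelled expression data; every class needs
#'   >= 2 samples.
#' @param m Number of weight-update iterations.
#' @param n_neighbors Nearest hits/misses averaged per update (default 1,
#'   the single-neighbor update).
#' @param seed RNG seed for the target draw.
#' @return A `gene_ranking` tibble `(gene, score)` of final weights.
#' @export
relieff_rank <- function(expression, sample_info, m = 100, n_neighbors = 1,
                         seed = 1) {
  x <- as_expr_matrix(expression)
  check_sample_info(expression, sample_info)
  m <- check_count(m, "m")
  n_neighbors <- check_count(n_neighbors, "n_neighbors")
  label <- aligned_annotation(expression, sample_info, "label")
  if (any(table(label) < 2)) {
    abort("ReliefF needs >= 2 samples per class (nearest hit undefined).")
  }
  xs <- t(x)                                   # samples x features
  rng <- apply(xs, 2, function(col) diff(range(col)))
  ok <- rng > 0
  xn <- xs
  xn[, ok] <- sweep(xs[, ok, drop = FALSE], 2, rng[ok], "/")
  xn[, !ok] <- 0                               # constant features contribute 0
  n <- nrow(xn)
  targets <- withr::with_seed(seed, {
    reps <- ceiling(m / n)
    unlist(lapply(seq_len(reps), function(i) sample.int(n)))[seq_len(m)]
  })
  w <- rep(0, ncol(xn))
  for (t_idx in targets) {
    d <- rowSums(abs(xn - rep(xn[t_idx, ], each = n)))
    same <- label == label[t_idx]
    hits <- which(same)
    hits <- hits[hits != t_idx]
    misses <- which(!same)
    # deterministic ties: order by distance then sample id
    pick <- function(idx, k) {
      o <- idx[order(d[idx], rownames(xn)[idx])]
      o[seq_len(min(k, length(o)))]
    }
    h <- pick(hits, n_neighbors)
    mi <- pick(misses, n_neighbors)
    diff_h <- colMeans(abs(xn[h, , drop = FALSE] -
                             rep(xn[t_idx, ], each = length(h))))
    diff_m <- colMeans(abs(xn[mi, , drop = FALSE] -
                             rep(xn[t_idx, ], each = length(mi))))
    w <- w + (-diff_h + diff_m) / m
  }
  new_gene_ranking(colnames(xn), unname(w), method = "relieff")
}

#' Rank genes with random-forest permutation importance
#'
#' Grows a classification forest (CART splits on Gini impurity, sqrt(p)
#' candidate features per split, trees grown to purity on bootstrap
#' resamples) and scores each gene by the unscaled mean decrease in
#' out-of-bag accuracy: per tree, the OOB misclassification rate after
#' permuting the gene among the OOB samples minus the rate before, summed
#' over trees and divided by the number of trees.
#'
#' @param expression,sample_info Labelled expression data.
#' @param n_trees Forest size.
#' @param seed RNG seed (bootstrap, split and permutation randomness).
#' @return A `gene_ranking` tibble `(gene, score)` of importances.
#' @export
rf_importance <- function(expression, sample_info, n_trees = 500, seed = 1) {
  x <- as_expr_matrix(expression)
  check_sample_info(expression, sample_info)
  n_trees <- check_count(n_trees, "n_trees")
  label <- factor(aligned_annotation(expression, sample_info, "label"))
  if (nlevels(label) < 2) abort("need >= 2 classes.")
  fit <- withr::with_seed(seed, {
    randomForest::randomForest(x = t(x), y = label, ntree = n_trees,
                               importance = TRUE)
  })
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  new_gene_ranking(rownames(x), unname(imp[rownames(x)]), method = "rf")
}

soft_threshold <- function(z, a) sign(z) * pmax(abs(z) - a, 0)

#' Rank genes by absolute lasso coefficients
#'
#' Fits L1-penalized least squares of the 0/1 class indicator on internally
#' standardized genes (mean 0, variance 1 with denominator n) by cyclic
#' coordinate descent, objective
#' `1/(2n) * ||y - b0 - X b||^2 + alpha * ||b||_1`.
#' Convergence requires the largest coefficient change in a sweep to fall
#' below `tol`; non-convergence is an error reporting the final change. The
#' ranking keeps only genes with nonzero coefficients, ordered by
#' `|coefficient|` descending (capped at `k`). When
#' `alpha >= max_j |<x_j, y - mean(y)>| / n` every coefficient is zero and
#' the ranking is empty. With duplicated (perfectly correlated) genes,
#' cyclic descent awards the full-magnitude coefficient to one copy — the
#' instability that motivates comparing lasso against variance-ratio
#' selectors on correlated panels.
#'
#' @param expression,sample_info Labelled expression data (two classes).
#' @param alpha L1 penalty (>= 0).
#' @param k Cap on the number of ranked genes (default 1000).
#' @param positive_class Class encoded as 1; defaults to the
#'   lexicographically last label.
#' @param tol Convergence tolerance on coefficient change (default 1e-8).
#' @param max_sweeps Maximum coordinate-descent sweeps (default 1e5).
#' @return A `gene_ranking` tibble `(gene, score, coefficient)` with
#'   `score = |coefficient|`, restricted to nonzero coefficients.
#' @export
lasso_rank <- function(expression, sample_info, alpha, k = 1000,
                       positive_class = NULL, tol = 1e-8, max_sweeps = 1e5) {
  x <- as_expr_matrix(expression)
  check_sample_info(expression, sample_info)
  if (alpha < 0) abort("`alpha` must be >= 0.")
  label <- aligned_annotation(expression, sample_info, "label")
  classes <- sort(unique(label))
  if (length(classes) != 2) abort("lasso ranking expects exactly 2 classes.")
  positive_class <- positive_class %||% classes[2]
  y <- as.numeric(label == positive_class)
  xs <- t(x)                                   # n x p
  n <- nrow(xs)
  mu <- colMeans(xs)
  sdev <- sqrt(colMeans(sweep(xs, 2, mu)^2))   # denominator n
  active <- sdev > 0
  xstd <- sweep(xs[, active, drop = FALSE], 2, mu[active], "-")
  xstd <- sweep(xstd, 2, sdev[active], "/")
  p <- ncol(xstd)
  beta <- rep(0, p)
  r <- y - mean(y)
  delta <- Inf
  sweeps <- 0L
  while (delta >= tol && sweeps < max_sweeps) {
    delta <- 0
    for (j in seq_len(p)) {
      z <- beta[j] + sum(xstd[, j] * r) / n
      b_new <- soft_threshold(z, alpha)
      if (b_new != beta[j]) {
        r <- r - xstd[, j] * (b_new - beta[j])
        delta <- max(delta, abs(b_new - beta[j]))
        beta[j] <- b_new
      }
    }
    sweeps <- sweeps + 1L
  }
  if (delta >= tol) {
    abort(sprintf("lasso coordinate descent did not converge in %d sweeps (last max coefficient change %.3e).",
                  as.integer(max_sweeps), delta))
  }
  genes <- colnames(xstd)
  nz <- which(beta != 0)
  ord <- nz[order(-abs(beta[nz]), genes[nz])]
  ord <- ord[seq_len(min(length(ord), check_count(k, "k")))]
  new_gene_ranking(genes[ord], abs(beta[ord]), method = "lasso",
                   extra = tibble(coefficient = beta[ord]))
}

#' Rank genes with any of the four selectors
#'
#' Convenience dispatcher used by the pipeline and the command-line
#' interface.
#'
#' @param expression,sample_info Labelled expression data.
#' @param method One of `"fisher"`, `"relieff"`, `"rf"`, `"lasso"`.
#' @param ... Passed to the selector (e.g. `m`, `n_trees`, `alpha`, `seed`).
#' @return A `gene_ranking` tibble.
#' @export
rank_genes <- function(expression, sample_info,
                       method = c("fisher", "relieff", "rf", "lasso"), ...) {
  method <- match.arg(method)
  switch(method,
         fisher = fisher_score(expression, sample_info),
         relieff = relieff_rank(expression, sample_info, ...),
         rf = rf_importance(expression, sample_info, ...),
         lasso = lasso_rank(expression, sample_info, ...))
}

#' Plot the score profile of a gene ranking
#' @param ranking A `gene_ranking`.
#' @param top How many leading genes to label on the x axis.
#' @return A ggplot object.
#' @export
plot_ranking <- function(ranking, top = 30) {
  d <- ranking[seq_len(min(top, nrow(ranking))), ]
  d$gene <- factor(d$gene, levels = rev(d$gene))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, y = .data$gene)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(title = sprintf("Top %d genes (%s)", nrow(d),
                                  attr(ranking, "method") %||% "ranking"),
                  x = "score", y = NULL) +
    ggplot2::theme_minimal()
}
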