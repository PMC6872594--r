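# Gene rankings are tibbles (gene, score) sorted by score descending with
# ties broken lexicographically by gene id, carrying the method name as an
# attribute. All four selectors share this container.

new_gene_ranking <- function(gene, score, method, extra = NULL) {
  tbl <- tibble(gene = gene, score = score)
  if (!is.null(extra)) tbl <- dplyr::bind_cols(tbl, extra)
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$score), .data$gene)
  structure(tbl, method = method,
            class = c("gene_ranking", class(tbl)))
}

#' Rank genes with the Fisher score
#'
#' For gene l with classes k = 1..C of sizes n_k, the Fisher score is
#' \deqn{f(l) = \frac{\sum_k n_k (\mu_k^l - \mu^l)^2}{\sum_k n_k (\sigma_k^l)^2}}
#' the ratio of the between-class weighted squared mean deviation to the
#' within-class weighted variance (sample variance, ddof = 1). A gene that is
#' constant everywhere scores 0; a gene with zero within-class variance but
#' distinct class means scores `Inf` and ranks above every finite score. The
#' score is invariant to affine transformations of a gene and to sample
#' reordering.
#'
#' @param expression Expression tibble (`gene` + one numeric column per sample).
#' @param sample_info Annotation tibble with `sample`, `label`; every class
#'   needs >= 2 samples.
#' @return A `gene_ranking` tibble `(gene, score)`, scores non-increasing,
#'   ties lexicographic.
#' @examples
#' sim <- simulate_expression(synthetic_config(n_genes = 100, seed = 1))
#' fisher_score(sim$expression, sim$sample_info)
#' @export
fisher_score <- function(expression, sample_info) {
  x <- as_expr_matrix(expression)
  check_sample_info(expression, sample_info)
  label <- aligned_annotation(expression, sample_info, "label")
  classes <- sort(unique(label))
  if (length(classes) < 2) abort("need >= 2 classes for the Fisher score.")
  n_k <- table(label)[classes]
  if (any(n_k < 2)) {
    abort(sprintf("class(es) with a single sample (sd undefined): %s",
                  paste(classes[n_k < 2], collapse = ", ")))
  }
  mu <- rowMeans(x)
  num <- rep(0, nrow(x))
  den <- rep(0, nrow(x))
  for (k in classes) {
    xk <- x[, label == k, drop = FALSE]
    nk <- ncol(xk)
    mk <- rowMeans(xk)
    vk <- rowSums((xk - mk)^2) / (nk - 1)   # sample variance, ddof = 1
    num <- num + nk * (mk - mu)^2
    den <- den + nk * vk
  }
  score <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  new_gene_ranking(rownames(x), unname(score), method = "fisher")
}

#' Take the top-k genes of a ranking
#'
#' @param ranking A `gene_ranking` (already deterministically ordered).
#' @param k Subset size; defaults to 1000, the conventional feature-subset
#'   size for tumor expression panels.
#' @return Character vector of `k` gene ids in rank order.
#' @export
select_top_k <- function(ranking, k = 1000) {
  k <- check_count(k, "k")
  if (k > nrow(ranking)) {
    abort(sprintf("k = %d exceeds the number of ranked genes (%d).",
                  k, nrow(ranking)))
  }
  ranking$gene[seq_len(k)]
}

#' @export
print.gene_ranking <- function(x, ...) {
  cat(sprintf("<gene_ranking: %s, %d genes>\n",
              attr(x, "method") %||% "?", nrow(x)))
  NextMethod()
}
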