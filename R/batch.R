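#' Detect batch structure with principal components
#'
#' Computes PCA over samples on gene-centered values and summarizes how much
#' of the variance in the PC1-PC2 plane is explained by batch membership:
#' `separation` is the between-batch sum of squares divided by the total sum
#' of squares of the two-dimensional sample coordinates. Values near 1 mean
#' the leading principal components are dominated by batch.
#'
#' @param expression Expression tibble.
#' @param sample_info Annotation tibble with a `batch` column covering all
#'   samples (>= 2 distinct batches).
#' @param scale If `TRUE`, genes are standardized (not just centered) before
#'   the PCA.
#' @return An object of class `batch_report`: list with `pc_coordinates`
#'   (tibble: sample, batch, PC1, PC2), `separation`, and the per-component
#'   variance shares. `tidy()` returns the coordinates, `glance()` the
#'   separation; `plot_batch()` draws the PC plane.
#' @export
detect_batch <- function(expression, sample_info, scale = FALSE) {
  x <- as_expr_matrix(expression)
  check_sample_info(expression, sample_info, require_batch = TRUE,
                    require_label = FALSE)
  if (ncol(x) < 3) abort("need >= 3 samples for a PCA batch report.")
  batch <- aligned_annotation(expression, sample_info, "batch")
  if (length(unique(batch)) < 2) {
    abort("nothing to detect: only one batch present.")
  }
  if (scale) {
    keep <- apply(x, 1, sd) > 0
    x <- x[keep, , drop = FALSE]
  }
  pc <- prcomp(t(x), center = TRUE, scale. = scale)
  coords <- pc$x[, 1:2, drop = FALSE]
  # coords are centered; between-batch SS over total SS in the plane
  total_ss <- sum(coords^2)
  sums <- rowsum(coords, batch)
  n_b <- as.vector(table(batch)[rownames(sums)])
  centroids <- sums / n_b
  between_ss <- sum(n_b * rowSums(centroids^2))
  separation <- if (total_ss > 0) between_ss / total_ss else 0
  structure(list(
    pc_coordinates = tibble(sample = colnames(x), batch = batch,
                            PC1 = coords[, 1], PC2 = coords[, 2]),
    separation = separation,
    var_explained = (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  ), class = "batch_report")
}

#' @export
print.batch_report <- function(x, ...) {
  cat(sprintf("PCA batch report: %d samples, %d batches\n",
              nrow(x$pc_coordinates), length(unique(x$pc_coordinates$batch))))
  cat(sprintf("between-batch share of PC1-PC2 variance: %.3f\n", x$separation))
  invisible(x)
}

#' @method tidy batch_report
#' @export
tidy.batch_report <- function(x, ...) x$pc_coordinates

#' @method glance batch_report
#' @export
glance.batch_report <- function(x, ...) {
  tibble(separation = x$separation,
         pc1_var = x$var_explained[1], pc2_var = x$var_explained[2])
}

#' Remove additive batch effects with a per-gene linear model
#'
#' For every gene, fits least squares of expression on sum-to-zero batch
#' indicators (plus class indicators when `preserve_labels` is `TRUE`) and
#' subtracts only the fitted batch component, re-centering so each gene's
#' grand mean is preserved exactly. The operation is a linear projection:
#' applying it twice equals applying it once, and with `preserve_labels` the
#' tumor/normal contrast within each batch is untouched.
#'
#' @param expression Expression tibble.
#' @param sample_info Annotations with `batch` (>= 2 batches, each with >= 2
#'   samples) and, when `preserve_labels`, `label`.
#' @param preserve_labels Protect the class contrast while estimating batch
#'   effects (default `TRUE`).
#' @return A corrected expression tibble.
#' @export
remove_batch <- function(expression, sample_info, preserve_labels = TRUE) {
  x <- as_expr_matrix(expression)
  check_sample_info(expression, sample_info, require_batch = TRUE,
                    require_label = preserve_labels)
  batch <- factor(aligned_annotation(expression, sample_info, "batch"))
  if (nlevels(batch) < 2) abort("nothing to remove: only one batch present.")
  small <- names(which(table(batch) < 2))
  if (length(small) > 0) {
    abort(sprintf("batch effect inestimable: batch(es) with < 2 samples: %s",
                  paste(small, collapse = ", ")))
  }
  b_mat <- stats::model.matrix(~batch, contrasts.arg = list(batch = "contr.sum"))
  batch_cols <- 2:ncol(b_mat)
  design <- b_mat
  if (preserve_labels) {
    label <- factor(aligned_annotation(expression, sample_info, "label"))
    if (nlevels(label) > 1) {
      l_mat <- stats::model.matrix(~label)[, -1, drop = FALSE]
      design <- cbind(b_mat, l_mat)
    }
  }
  fit <- stats::lm.fit(design, t(x))
  coefs <- as.matrix(fit$coefficients)   # p x genes even for one gene
  coefs[is.na(coefs)] <- 0
  batch_component <- design[, batch_cols, drop = FALSE] %*%
    coefs[batch_cols, , drop = FALSE]          # samples x genes
  corrected <- x - t(batch_component)
  corrected <- corrected + rowMeans(t(batch_component))  # keep grand means
  as_expr_tibble(corrected)
}

#' Plot the PC1-PC2 plane of a batch report
#' @param report A [detect_batch()] result.
#' @return A ggplot object.
#' @export
plot_batch <- function(report) {
  stopifnot(inherits(report, "batch_report"))
  ggplot2::ggplot(report$pc_coordinates,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$batch)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(
      title = "Sample principal components by batch",
      subtitle = sprintf("between-batch share of PC1-PC2 variance = %.2f",
                         report$separation)) +
    ggplot2::theme_minimal()
}
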