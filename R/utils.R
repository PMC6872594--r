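# Shared validation helpers for the central tabular containers:
#   expression: tibble, first column `gene` (character, unique), remaining
#               columns numeric, one per sample (unique names).
#   sample_info: tibble with columns sample, label (+ optional batch),
#               covering every sample column of the expression table.

check_expression <- function(expression, arg = "expression") {
  if (!is.data.frame(expression) || ncol(expression) < 2) {
    abort(sprintf("`%s` must be a data frame with a gene column and >= 1 sample column.", arg))
  }
  genes <- expression[[1]]
  if (!is.character(genes)) {
    abort(sprintf("first column of `%s` must be character gene ids.", arg))
  }
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate gene ids in `%s`: %s", arg,
                  paste(head(dup, 5), collapse = ", ")))
  }
  samp <- names(expression)[-1]
  dup_s <- unique(samp[duplicated(samp)])
  if (length(dup_s) > 0) {
    abort(sprintf("duplicate sample ids in `%s`: %s", arg,
                  paste(head(dup_s, 5), collapse = ", ")))
  }
  for (j in seq_along(samp)) {
    col <- expression[[j + 1L]]
    if (!is.numeric(col)) {
      abort(sprintf("sample column '%s' of `%s` is not numeric.", samp[j], arg))
    }
    if (anyNA(col)) {
      abort(sprintf("missing values in sample column '%s' of `%s`.", samp[j], arg))
    }
  }
  invisible(expression)
}

# genes x samples numeric matrix with dimnames
as_expr_matrix <- function(expression) {
  check_expression(expression)
  m <- as.matrix(expression[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expression[[1]]
  m
}

as_expr_tibble <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(gene = rownames(m)), out)
}

check_sample_info <- function(expression, sample_info, require_batch = FALSE,
                              require_label = TRUE) {
  if (!is.data.frame(sample_info) || !all(c("sample") %in% names(sample_info))) {
    abort("`sample_info` must be a data frame with at least a `sample` column.")
  }
  if (require_label && !"label" %in% names(sample_info)) {
    abort("`sample_info` must have a `label` column.")
  }
  if (require_batch && !"batch" %in% names(sample_info)) {
    abort("`sample_info` must have a `batch` column for this operation.")
  }
  samples <- names(expression)[-1]
  missing <- setdiff(samples, sample_info$sample)
  if (length(missing) > 0) {
    abort(sprintf("samples missing from `sample_info`: %s",
                  paste(head(missing, 10), collapse = ", ")))
  }
  if (anyDuplicated(sample_info$sample)) {
    abort("duplicate sample ids in `sample_info`.")
  }
  invisible(sample_info)
}

# label / batch vectors aligned to the expression sample order
aligned_annotation <- function(expression, sample_info, column) {
  samples <- names(expression)[-1]
  idx <- match(samples, sample_info$sample)
  as.character(sample_info[[column]][idx])
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}
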