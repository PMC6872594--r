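#' Read a genes-by-samples expression matrix from TSV/CSV
#'
#' Expects a header row of sample ids and a first column of gene (or probe)
#' ids. Values must be numeric log2-scale intensities with no missing cells
#' (pass `impute = "row-mean"` to fill occasional gaps with the gene's mean).
#'
#' @param path Matrix file; delimiter inferred from the extension
#'   (`.csv` -> comma, otherwise tab).
#' @param impute `"none"` (reject missing values, default) or `"row-mean"`.
#' @return A validated expression tibble (`gene` + one column per sample).
#' @export
read_expression <- function(path, impute = c("none", "row-mean")) {
  impute <- match.arg(impute)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, name_repair = "minimal")
  if (ncol(raw) < 2) abort(sprintf("'%s': need a gene column plus >= 1 sample column.", path))
  names(raw)[1] <- "gene"
  raw$gene <- as.character(raw$gene)
  for (j in 2:ncol(raw)) {
    col <- raw[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))
      abort(sprintf("'%s': non-numeric value in column '%s' (e.g. data row %s).",
                    path, names(raw)[j],
                    if (length(bad)) bad[1] else "?"))
    }
    if (anyNA(col)) {
      if (impute == "none") {
        abort(sprintf("'%s': missing values in column '%s'; rerun with impute = \"row-mean\".",
                      path, names(raw)[j]))
      }
    }
  }
  if (impute == "row-mean") {
    m <- as.matrix(raw[, -1])
    rm <- rowMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    if (nrow(idx)) m[idx] <- rm[idx[, 1]]
    raw[, -1] <- as_tibble(m, .name_repair = "minimal")
  }
  check_expression(as_tibble(raw))
  as_tibble(raw)
}

#' Read per-sample annotations (labels and optional batches)
#'
#' @param path TSV with columns `sample`, `label` and optionally `batch`.
#' @param expression If given, validated against this matrix: every sample
#'   column must be annotated.
#' @return A tibble with columns `sample`, `label` (and `batch` if present).
#' @export
read_sample_info <- function(path, expression = NULL) {
  info <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample", "label") %in% names(info))) {
    abort(sprintf("'%s': needs columns `sample` and `label`.", path))
  }
  info$sample <- as.character(info$sample)
  if (!is.null(expression)) check_sample_info(expression, info)
  as_tibble(info)
}

#' Write an expression tibble as TSV
#' @param expression Expression tibble.
#' @param path Output file.
#' @export
write_expression <- function(expression, path) {
  check_expression(expression)
  readr::write_tsv(expression, path, progress = FALSE)
  invisible(path)
}

#' Read a two-column probe-to-symbol map
#'
#' @param path TSV with probe id in column 1 and gene symbol in column 2; a
#'   probe appearing on several rows maps to several symbols.
#' @return A tibble with columns `probe`, `symbol`.
#' @export
read_probe_map <- function(path) {
  pm <- readr::read_tsv(path, col_names = c("probe", "symbol"),
                        col_types = "cc", progress = FALSE)
  dplyr::distinct(pm)
}

#' Collapse probe-level rows to gene symbols
#'
#' Probes mapping to no symbol or to two or more symbols are dropped; each
#' symbol's expression row is the arithmetic mean of its surviving probes.
#' Output genes are sorted lexicographically so downstream rankings are
#' reproducible.
#'
#' @param expression Probe-level expression tibble.
#' @param probe_map Tibble with columns `probe`, `symbol` (see
#'   [read_probe_map()]).
#' @return Symbol-level expression tibble.
#' @export
collapse_probes <- function(expression, probe_map) {
  x <- as_expr_matrix(expression)
  if (!all(c("probe", "symbol") %in% names(probe_map))) {
    abort("`probe_map` needs columns `probe` and `symbol`.")
  }
  pm <- dplyr::distinct(as_tibble(probe_map[, c("probe", "symbol")]))
  multi <- pm |> count(.data$probe) |> filter(.data$n > 1) |> pull(.data$probe)
  pm <- pm |> filter(!.data$probe %in% multi, .data$probe %in% rownames(x))
  if (nrow(pm) == 0) abort("no mappable probes: every probe maps to 0 or >= 2 symbols.")
  groups <- split(pm$probe, pm$symbol)
  symbols <- sort(names(groups))
  out <- t(vapply(symbols, function(sym) {
    colMeans(x[groups[[sym]], , drop = FALSE])
  }, numeric(ncol(x))))
  rownames(out) <- symbols
  as_expr_tibble(out)
}

#' Integrate expression datasets sharing an identifier space
#'
#' Joins on the intersection of gene ids (inner join), concatenates samples,
#' and records each sample's source dataset as its batch. Sample ids must be
#' pairwise disjoint across inputs.
#'
#' @param matrices Named list of >= 2 expression tibbles; names become batch
#'   labels.
#' @param sample_infos Optional named list of annotation tibbles aligned with
#'   `matrices`; labels are concatenated and batches overwritten with the
#'   dataset name.
#' @return A list with `expression` and `sample_info` tibbles.
#' @export
integrate_datasets <- function(matrices, sample_infos = NULL) {
  if (!is.list(matrices) || length(matrices) < 2) {
    abort("`matrices` must be a named list of >= 2 expression tibbles.")
  }
  nms <- names(matrices)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms)) {
    abort("`matrices` must have unique non-empty names (used as batch labels).")
  }
  mats <- lapply(matrices, as_expr_matrix)
  all_samples <- unlist(lapply(mats, colnames))
  dup <- unique(all_samples[duplicated(all_samples)])
  if (length(dup) > 0) {
    abort(sprintf("sample ids collide across datasets: %s",
                  paste(head(dup, 5), collapse = ", ")))
  }
  shared <- Reduce(intersect, lapply(mats, rownames))
  if (length(shared) == 0) {
    counts <- paste(sprintf("%s=%d", nms, vapply(mats, nrow, 1L)), collapse = ", ")
    abort(sprintf("integration failed: empty gene intersection (per-input gene counts: %s).",
                  counts))
  }
  merged <- do.call(cbind, lapply(mats, function(m) m[shared, , drop = FALSE]))
  batch <- rep(nms, vapply(mats, ncol, 1L))
  info <- tibble(sample = colnames(merged), batch = batch)
  if (!is.null(sample_infos)) {
    labels <- dplyr::bind_rows(sample_infos)[, c("sample", "label")]
    info <- dplyr::left_join(info, labels, by = "sample")
    info <- info[, c("sample", "label", "batch")]
  }
  list(expression = as_expr_tibble(merged), sample_info = info)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line — name, description, then tab-separated
#' member gene ids.
#'
#' @param path GMT file.
#' @return A named list of character vectors with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    abort(sprintf("'%s': line %d has fewer than 3 tab-separated fields.", path, bad[1]))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) abort(sprintf("'%s': duplicate set names.", path))
  attr(sets, "descriptions") <- setNames(vapply(fields, `[[`, "", 2L), names(sets))
  sets
}

# Accept gene sets as a named list or a long tibble (set, gene)
as_gene_set_list <- function(gene_sets) {
  if (is.list(gene_sets) && !is.data.frame(gene_sets)) {
    if (is.null(names(gene_sets)) || any(names(gene_sets) == "")) {
      abort("gene sets must be named.")
    }
    return(lapply(gene_sets, as.character))
  }
  if (is.data.frame(gene_sets) && all(c("set", "gene") %in% names(gene_sets))) {
    return(split(as.character(gene_sets$gene), gene_sets$set))
  }
  abort("`gene_sets` must be a named list or a data frame with columns `set`, `gene`.")
}
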