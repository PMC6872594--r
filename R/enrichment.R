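#' Over-representation analysis with the hypergeometric tail
#'
#' For each gene set (restricted to the measured universe before size
#' accounting), tests whether the query list overlaps the set more than
#' expected under sampling without replacement:
#' `p = P[X >= overlap]` for X hypergeometric with population `|universe|`,
#' successes `|set ∩ universe|` and draws `|query|`. FDR is
#' Benjamini-Hochberg across the tested sets. A row is flagged significant
#' when `p < p_cutoff` **and** the overlap count exceeds `min_count` — the
#' conventional joint filter for expression panels (defaults 0.05 and 10).
#'
#' @param query Character vector of gene ids; must be a subset of `universe`.
#' @param gene_sets Named list of member vectors, long tibble
#'   (`set`, `gene`) or [read_gmt()] output.
#' @param universe Character vector of measured gene ids.
#' @param p_cutoff,min_count The significance filter.
#' @return A tibble: `set`, `overlap`, `set_size`, `p_value`, `fdr`,
#'   `significant`, plus a list-column `overlap_genes`.
#' @export
ora <- function(query, gene_sets, universe, p_cutoff = 0.05, min_count = 10) {
  sets <- as_gene_set_list(gene_sets)
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  stray <- setdiff(query, universe)
  if (length(stray) > 0) {
    abort(sprintf("query gene(s) not in the universe: %s",
                  paste(head(stray, 10), collapse = ", ")))
  }
  n_univ <- length(universe)
  n_query <- length(query)
  rows <- imap(sets, function(members, nm) {
    in_univ <- intersect(unique(members), universe)
    ov <- intersect(query, in_univ)
    m <- length(in_univ)
    k <- length(ov)
    p <- if (m == 0) 1 else phyper(k - 1, m, n_univ - m, n_query,
                                   lower.tail = FALSE)
    tibble(set = nm, overlap = k, set_size = m, p_value = p,
           overlap_genes = list(sort(ov)))
  })
  out <- list_rbind(rows)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < p_cutoff & out$overlap > min_count
  out[, c("set", "overlap", "set_size", "p_value", "fdr", "significant",
          "overlap_genes")]
}

# Weighted KS running sum for one set over a ranked list (weight exponent 1).
# Returns es, the extremum index, and the leading-edge genes.
gsea_walk <- function(ranked_genes, metric, set_members) {
  hit <- ranked_genes %in% set_members
  n <- length(ranked_genes)
  nh <- sum(hit)
  w <- abs(metric)
  nr <- sum(w[hit])
  inc <- numeric(n)
  inc[hit] <- if (nr > 0) w[hit] / nr else 1 / nh
  inc[!hit] <- -1 / (n - nh)
  running <- cumsum(inc)
  i <- which.max(abs(running))
  es <- running[i]
  leading <- if (es >= 0) ranked_genes[seq_len(i)][hit[seq_len(i)]]
             else ranked_genes[i:n][hit[i:n]]
  list(es = es, peak = i, leading_edge = leading)
}

# Signal-to-noise ranking metric (muA - muB) / (sdA + sdB), sd floor 1e-8.
signal_to_noise <- function(x, label, positive_class) {
  a <- x[, label == positive_class, drop = FALSE]
  b <- x[, label != positive_class, drop = FALSE]
  mu_a <- rowMeans(a); mu_b <- rowMeans(b)
  sd_a <- apply(a, 1, sd); sd_b <- apply(b, 1, sd)
  s <- sd_a + sd_b
  if (any(s == 0)) {
    warning("gene(s) with zero within-class sd in both classes; using sd floor 1e-8.")
    s <- pmax(s, 1e-8)
  }
  (mu_a - mu_b) / s
}

#' Gene set enrichment analysis with gene-set permutation
#'
#' Genes are ranked by the signal-to-noise metric
#' `(mu_A - mu_B) / (sd_A + sd_B)` (ties broken lexicographically). Each
#' set's enrichment score (ES) is the maximum deviation of the weighted
#' Kolmogorov-Smirnov running sum with hit increments proportional to
#' `|metric|` (weight exponent 1) and uniform miss decrements. The null for
#' each set is `n_perm` random gene sets of equal size drawn from the ranked
#' list (gene-set permutation). NES divides ES by the mean `|null ES|` of
#' matching sign; the nominal p value is the fraction of same-sign null ES at
#' least as extreme; the FDR q value uses the standard pooled-NES procedure.
#'
#' @param expression,sample_info Labelled expression data (two classes).
#' @param gene_sets Gene sets (named list, long tibble or [read_gmt()]).
#' @param positive_class Class whose up-regulated genes head the list;
#'   defaults to the lexicographically last label.
#' @param n_perm Number of permutations (default 1000).
#' @param min_size,max_size Set-size window applied after restriction to the
#'   measured genes (defaults 10 and 500); sets outside it are skipped.
#' @param seed RNG seed for the permutations.
#' @return A tibble: `set`, `size`, `es`, `nes`, `nominal_p`, `fdr_q` and a
#'   list-column `leading_edge`, sorted by `nes` descending. The parameters
#'   are recorded in attribute `params`.
#' @export
gsea <- function(expression, sample_info, gene_sets, positive_class = NULL,
                 n_perm = 1000, min_size = 10, max_size = 500, seed = 1) {
  x <- as_expr_matrix(expression)
  check_sample_info(expression, sample_info)
  label <- aligned_annotation(expression, sample_info, "label")
  classes <- sort(unique(label))
  if (length(classes) != 2) abort("GSEA expects exactly 2 classes.")
  positive_class <- positive_class %||% classes[2]
  sets <- as_gene_set_list(gene_sets)
  metric <- signal_to_noise(x, label, positive_class)
  ord <- order(-metric, rownames(x))
  ranked_genes <- rownames(x)[ord]
  ranked_metric <- metric[ord]

  sets <- lapply(sets, function(s) intersect(unique(s), ranked_genes))
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size
  sets <- sets[keep]
  if (length(sets) == 0) {
    out <- tibble(set = character(), size = integer(), es = numeric(),
                  nes = numeric(), nominal_p = numeric(), fdr_q = numeric(),
                  leading_edge = list())
    attr(out, "params") <- list(n_perm = n_perm, min_size = min_size,
                                max_size = max_size, metric = "signal2noise",
                                permutation = "gene_set", weight = 1,
                                positive_class = positive_class, seed = seed)
    return(out)
  }

  obs <- map(sets, ~gsea_walk(ranked_genes, ranked_metric, .x))
  es_obs <- map_dbl(obs, "es")

  null_by_size <- withr::with_seed(seed, {
    out <- list()
    for (s in sort(unique(lengths(sets)))) {
      out[[as.character(s)]] <- vapply(seq_len(n_perm), function(i) {
        gsea_walk(ranked_genes, ranked_metric,
                  sample(ranked_genes, s))$es
      }, numeric(1))
    }
    out
  })

  nes_obs <- numeric(length(sets))
  p_nom <- numeric(length(sets))
  null_nes <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    nulls <- null_by_size[[as.character(length(sets[[i]]))]]
    same <- if (es_obs[i] >= 0) nulls[nulls >= 0] else nulls[nulls < 0]
    denom <- if (length(same) > 0) mean(abs(same)) else NA_real_
    nes_obs[i] <- if (!is.na(denom) && denom > 0) es_obs[i] / denom else NA_real_
    p_nom[i] <- if (length(same) > 0) mean(abs(same) >= abs(es_obs[i])) else NA_real_
    pos_m <- mean(abs(nulls[nulls >= 0]))
    neg_m <- mean(abs(nulls[nulls < 0]))
    null_nes[[i]] <- ifelse(nulls >= 0,
                            nulls / ifelse(pos_m > 0, pos_m, NA_real_),
                            nulls / ifelse(neg_m > 0, neg_m, NA_real_))
  }
  pooled <- unlist(null_nes)
  pooled <- pooled[is.finite(pooled)]
  fdr_q <- vapply(seq_along(sets), function(i) {
    nes <- nes_obs[i]
    if (!is.finite(nes)) return(NA_real_)
    if (nes >= 0) {
      null_frac <- if (any(pooled >= 0)) mean(pooled[pooled >= 0] >= nes) else NA_real_
      obs_frac <- mean(nes_obs[is.finite(nes_obs) & nes_obs >= 0] >= nes)
    } else {
      null_frac <- if (any(pooled < 0)) mean(pooled[pooled < 0] <= nes) else NA_real_
      obs_frac <- mean(nes_obs[is.finite(nes_obs) & nes_obs < 0] <= nes)
    }
    if (!is.finite(null_frac) || obs_frac == 0) return(NA_real_)
    min(1, null_frac / obs_frac)
  }, numeric(1))

  out <- tibble(set = names(sets), size = lengths(sets), es = unname(es_obs),
                nes = nes_obs, nominal_p = p_nom, fdr_q = fdr_q,
                leading_edge = unname(map(obs, "leading_edge")))
  out <- dplyr::arrange(out, dplyr::desc(.data$nes))
  attr(out, "params") <- list(n_perm = n_perm, min_size = min_size,
                              max_size = max_size, metric = "signal2noise",
                              permutation = "gene_set", weight = 1,
                              positive_class = positive_class, seed = seed)
  out
}

#' Bar chart of over-representation results
#' @param ora_table An [ora()] result.
#' @param top How many sets to show (ordered by p value).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(ora_table, top = 20) {
  d <- dplyr::arrange(ora_table, .data$p_value)
  d <- d[seq_len(min(top, nrow(d))), ]
  d$set <- factor(d$set, levels = rev(d$set))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$p_value), y = .data$set,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "-log10 p", y = NULL,
                  title = "Over-representation of gene sets") +
    ggplot2::theme_minimal()
}
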