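#' Run the full hub-gene identification pipeline
#'
#' Executes the end-to-end method on in-memory objects:
#' optional probe collapse, optional batch detection/correction (triggered
#' when `sample_info` carries >= 2 batches), selector ranking, top-k feature
#' subset, over-representation analysis of the subset against the supplied
#' gene sets (universe = all measured genes), restriction to genes belonging
#' to at least one significant set, Maximal Clique Centrality on the
#' interaction subgraph induced by those genes, top hub extraction, and a
#' median-split log-rank survival report when a cohort is supplied. The
#' containment `hubs ⊆ enriched_genes ⊆ feature_set` is asserted at run
#' time; if no gene set passes the significance filter the pipeline errors
#' rather than silently passing all genes through.
#'
#' @param expression Expression tibble (probe- or symbol-level).
#' @param sample_info Annotations (`sample`, `label`, optional `batch`).
#' @param gene_sets Gene-set collection for the over-representation stage.
#' @param graph Interaction network (igraph or edge data frame).
#' @param cohort Optional survival cohort tibble (see [simulate_survival()]).
#' @param probe_map Optional probe-to-symbol map; triggers
#'   [collapse_probes()] first.
#' @param selector Ranking method: `"fisher"` (default), `"relieff"`,
#'   `"rf"` or `"lasso"`.
#' @param k Feature-subset size (default 1000).
#' @param hub_k Number of hubs (default 10).
#' @param ora_p,ora_min_count Significance filter for the enrichment stage
#'   (defaults 0.05 and 10).
#' @param selector_params Named list of extra selector arguments
#'   (e.g. `alpha` for lasso, `m` for ReliefF).
#' @param correct_batch Force batch correction on/off; default `NULL`
#'   corrects exactly when >= 2 batches are annotated.
#' @param seed Seed forwarded to stochastic selectors.
#' @return An object of class `hub_pipeline`: list with `ranking`,
#'   `feature_set`, `ora`, `enriched_genes`, `hub_scores`, `hubs`,
#'   `survival`, `batch_report` and `provenance` (config, seed, per-stage
#'   counts). `tidy()` returns the hub table, `glance()` the stage counts.
#' @export
run_pipeline <- function(expression, sample_info, gene_sets, graph,
                         cohort = NULL, probe_map = NULL,
                         selector = c("fisher", "relieff", "rf", "lasso"),
                         k = 1000, hub_k = 10,
                         ora_p = 0.05, ora_min_count = 10,
                         selector_params = list(), correct_batch = NULL,
                         seed = 1) {
  selector <- match.arg(selector)
  stages <- list()
  log_stage <- function(name, ...) {
    stages[[name]] <<- list(...)
    message(sprintf("[%s] %s", name,
                    paste(sprintf("%s=%s", names(list(...)), unlist(list(...))),
                          collapse = " ")))
  }

  check_expression(expression)
  check_sample_info(expression, sample_info)
  log_stage("input", genes = nrow(expression), samples = ncol(expression) - 1)

  if (!is.null(probe_map)) {
    expression <- collapse_probes(expression, probe_map)
    log_stage("collapse", genes = nrow(expression))
  }

  batch_report <- NULL
  n_batches <- if ("batch" %in% names(sample_info)) {
    length(unique(aligned_annotation(expression, sample_info, "batch")))
  } else 1L
  do_batch <- correct_batch %||% (n_batches >= 2)
  if (do_batch) {
    batch_report <- detect_batch(expression, sample_info)
    expression <- remove_batch(expression, sample_info)
    after <- detect_batch(expression, sample_info)
    log_stage("batch", separation_before = round(batch_report$separation, 4),
              separation_after = round(after$separation, 4))
  }

  args <- c(list(expression = expression, sample_info = sample_info,
                 method = selector), selector_params)
  if (selector %in% c("relieff", "rf") && is.null(selector_params$seed)) {
    args$seed <- seed
  }
  ranking <- do.call(rank_genes, args)
  feature_set <- select_top_k(ranking, min(k, nrow(ranking)))
  log_stage("rank", method = selector, ranked = nrow(ranking),
            feature_set = length(feature_set))

  universe <- expression$gene
  ora_table <- ora(feature_set, gene_sets, universe,
                   p_cutoff = ora_p, min_count = ora_min_count)
  sig <- dplyr::filter(ora_table, .data$significant)
  if (nrow(sig) == 0) {
    abort("pipeline stage 'ora': no gene set passed the significance filter; cannot define the enriched gene list.")
  }
  enriched_genes <- sort(intersect(unique(unlist(sig$overlap_genes)),
                                   feature_set))
  log_stage("ora", sets_tested = nrow(ora_table), significant = nrow(sig),
            enriched_genes = length(enriched_genes))

  sub <- induce_subgraph(graph, enriched_genes)
  scores <- mcc_scores(sub)
  if (hub_k > nrow(scores)) {
    abort(sprintf("pipeline stage 'hubs': requested %d hubs but the induced network has %d nodes.",
                  hub_k, nrow(scores)))
  }
  hubs <- top_hubs(scores, hub_k)
  log_stage("hubs", nodes = igraph::vcount(sub), edges = igraph::ecount(sub),
            hubs = length(hubs))

  stopifnot(all(hubs %in% enriched_genes),
            all(enriched_genes %in% feature_set))

  surv_table <- NULL
  if (!is.null(cohort)) {
    surv_table <- hub_survival_report(cohort, hubs)
    log_stage("survival", hubs_tested = nrow(surv_table),
              significant = sum(surv_table$p_value < 0.05, na.rm = TRUE))
  }

  structure(list(
    ranking = ranking, feature_set = feature_set, ora = ora_table,
    enriched_genes = enriched_genes, hub_scores = scores, hubs = hubs,
    survival = surv_table, batch_report = batch_report,
    provenance = list(
      selector = selector, k = k, hub_k = hub_k, ora_p = ora_p,
      ora_min_count = ora_min_count, seed = seed,
      selector_params = selector_params,
      package_version = as.character(utils::packageVersion("hubfisher")),
      stages = stages)
  ), class = "hub_pipeline")
}

#' @export
print.hub_pipeline <- function(x, ...) {
  cat("Hub-gene identification pipeline\n")
  cat(sprintf("  selector: %s | feature set: %d genes | enriched: %d | hubs: %d\n",
              x$provenance$selector, length(x$feature_set),
              length(x$enriched_genes), length(x$hubs)))
  cat("  hubs:", paste(x$hubs, collapse = ", "), "\n")
  if (!is.null(x$survival)) {
    sig <- sum(x$survival$p_value < 0.05, na.rm = TRUE)
    cat(sprintf("  survival: %d/%d hubs with log-rank p < 0.05\n",
                sig, nrow(x$survival)))
  }
  invisible(x)
}

#' @method tidy hub_pipeline
#' @export
tidy.hub_pipeline <- function(x, ...) {
  out <- dplyr::filter(x$hub_scores, .data$gene %in% x$hubs)
  out$rank <- match(out$gene, x$hubs)
  out <- dplyr::arrange(out, .data$rank)[, c("rank", "gene", "mcc", "degree")]
  if (!is.null(x$survival)) {
    out <- dplyr::left_join(out, x$survival, by = "gene")
  }
  out
}

#' @method glance hub_pipeline
#' @export
glance.hub_pipeline <- function(x, ...) {
  tibble(selector = x$provenance$selector,
         n_features = length(x$feature_set),
         n_significant_sets = sum(x$ora$significant),
         n_enriched_genes = length(x$enriched_genes),
         n_hubs = length(x$hubs),
         n_hubs_prognostic = if (is.null(x$survival)) NA_integer_
           else sum(x$survival$p_value < 0.05, na.rm = TRUE))
}

#' Intersect hub lists from different selection methods
#'
#' Builds the gene-by-method membership matrix together with all pairwise
#' and full intersection counts — the tabular equivalent of a Venn diagram
#' across selector arms.
#'
#' @param hub_lists Named list (>= 2 entries, unique names) of hub gene id
#'   vectors.
#' @return An object of class `hub_comparison`: list with `membership`
#'   (tibble, gene x method logicals), `pairwise` (tibble: method_a,
#'   method_b, overlap) and `common` (genes present in every list).
#'   `tidy()` returns the long membership table.
#' @export
compare_methods <- function(hub_lists) {
  if (!is.list(hub_lists) || length(hub_lists) < 2) {
    abort("`hub_lists` must be a named list with >= 2 entries.")
  }
  nms <- names(hub_lists)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms)) {
    abort("method names must be unique and non-empty.")
  }
  hub_lists <- lapply(hub_lists, function(x) unique(as.character(x)))
  genes <- sort(unique(unlist(hub_lists)))
  membership <- tibble(gene = genes)
  for (m in nms) membership[[m]] <- genes %in% hub_lists[[m]]
  pairs <- combn(nms, 2)
  pairwise <- tibble(
    method_a = pairs[1, ], method_b = pairs[2, ],
    overlap = map_int(seq_len(ncol(pairs)), function(i) {
      length(intersect(hub_lists[[pairs[1, i]]], hub_lists[[pairs[2, i]]]))
    }))
  structure(list(membership = membership, pairwise = pairwise,
                 common = sort(Reduce(intersect, hub_lists))),
            class = "hub_comparison")
}

#' @export
print.hub_comparison <- function(x, ...) {
  cat(sprintf("Hub-list comparison across %d methods (%d distinct genes)\n",
              ncol(x$membership) - 1, nrow(x$membership)))
  print(x$pairwise)
  cat("common to all:", if (length(x$common)) paste(x$common, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' @method tidy hub_comparison
#' @export
tidy.hub_comparison <- function(x, ...) {
  pivot_longer(x$membership, -"gene", names_to = "method",
               values_to = "member")
}

#' Membership-tile plot of a hub-list comparison
#' @param comparison A [compare_methods()] result.
#' @return A ggplot object.
#' @export
plot_comparison <- function(comparison) {
  stopifnot(inherits(comparison, "hub_comparison"))
  d <- tidy(comparison)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$gene,
                                  fill = .data$member)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey90")) +
    ggplot2::labs(x = NULL, y = NULL, title = "Hub-gene membership by method") +
    ggplot2::theme_minimal()
}
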