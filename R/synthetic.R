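#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the simulated study: a two-class (tumor/normal)
#' log2-scale expression matrix with planted differential genes, correlated
#' gene modules and additive batch shifts; and a survival cohort whose hazard
#' is tied to one gene's expression. Defaults describe the study conditions
#' used throughout the package's own validation: 2000 genes of which 50 are
#' informative with a class-mean shift of 1.5 within-class standard
#' deviations, 50 + 50 samples, and a per-SD log hazard ratio of 0.7.
#'
#' @param n_genes Number of genes.
#' @param n_informative Number of planted differentially expressed genes.
#' @param n_tumor,n_normal Samples per class.
#' @param effect_size Class-mean shift (log2 units) added to tumor samples of
#'   informative genes.
#' @param base_sd Within-class standard deviation (log2 units).
#' @param n_modules Number of correlated gene blocks (0 disables).
#' @param module_size Genes per block.
#' @param module_rho Target pairwise correlation within a block, in `[0, 1)`.
#' @param n_batches Number of batches (0 or 1 disables batch shifts).
#' @param batch_shift_sd Standard deviation (log2 units) of the per
#'   gene-by-batch additive offsets.
#' @param hazard_beta Log hazard ratio per standard deviation of the tied
#'   gene's expression.
#' @param baseline_hazard Baseline event rate (events per time unit).
#' @param censor_rate Expected fraction of censored patients, in `[0, 1)`.
#' @param overlap_modules If `TRUE`, module blocks start at gene 1 so that
#'   informative genes can fall inside correlated blocks (used to probe
#'   selector instability on correlated duplicates); by default informative
#'   genes and module blocks are disjoint.
#' @param seed RNG seed; identical configurations reproduce identical data.
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000, n_informative = 50,
                             n_tumor = 50, n_normal = 50,
                             effect_size = 0.75, base_sd = 0.5,
                             n_modules = 5, module_size = 20, module_rho = 0.7,
                             n_batches = 1, batch_shift_sd = 1,
                             hazard_beta = 0.7, baseline_hazard = 0.1,
                             censor_rate = 0.3, overlap_modules = FALSE,
                             seed = 1) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes"),
    n_informative = check_count(n_informative, "n_informative", min = 0L),
    n_tumor = check_count(n_tumor, "n_tumor"),
    n_normal = check_count(n_normal, "n_normal"),
    effect_size = effect_size, base_sd = base_sd,
    n_modules = check_count(n_modules, "n_modules", min = 0L),
    module_size = check_count(module_size, "module_size", min = 0L),
    module_rho = module_rho,
    n_batches = check_count(n_batches, "n_batches", min = 0L),
    batch_shift_sd = batch_shift_sd,
    hazard_beta = hazard_beta, baseline_hazard = baseline_hazard,
    censor_rate = censor_rate,
    overlap_modules = isTRUE(overlap_modules),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$n_informative > cfg$n_genes) {
    abort("invalid config: `n_informative` exceeds `n_genes`.")
  }
  if (cfg$n_modules * cfg$module_size > cfg$n_genes) {
    abort("invalid config: `n_modules` * `module_size` exceeds `n_genes`.")
  }
  if (!cfg$overlap_modules &&
      cfg$n_informative + cfg$n_modules * cfg$module_size > cfg$n_genes) {
    abort("invalid config: disjoint informative genes and module blocks exceed `n_genes`.")
  }
  if (cfg$module_rho < 0 || cfg$module_rho >= 1) {
    abort("invalid config: `module_rho` must be in [0, 1).")
  }
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1) {
    abort("invalid config: `censor_rate` must be in [0, 1).")
  }
  if (cfg$base_sd <= 0) abort("invalid config: `base_sd` must be positive.")
  if (cfg$baseline_hazard <= 0) abort("invalid config: `baseline_hazard` must be positive.")
  structure(cfg, class = "synthetic_config")
}

#' Simulate a labelled two-class expression matrix with known truth
#'
#' Draws gene-wise independent Gaussian log2 values around per-gene baselines,
#' adds the configured class-mean shift to tumor samples of the informative
#' genes, gives each module block a shared latent factor scaled so pairwise
#' within-block correlation is approximately `module_rho`, and adds one
#' per-gene-by-batch Gaussian offset to every sample of a batch.
#'
#' @param config A [synthetic_config()].
#' @return A list with `expression` (tibble: `gene` + one numeric column per
#'   sample), `sample_info` (tibble: `sample`, `label`, `batch`) and `truth`
#'   (list: `informative_genes`, `module_assignments`, `batch_assignments`,
#'   and the configured effect size).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_tumor + config$n_normal
  withr::with_seed(config$seed, {
    genes <- sprintf("g%05d", seq_len(config$n_genes))
    samples <- c(sprintf("T%03d", seq_len(config$n_tumor)),
                 sprintf("N%03d", seq_len(config$n_normal)))
    label <- rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal))
    baseline <- rnorm(config$n_genes, mean = 7, sd = 1)
    x <- matrix(rnorm(config$n_genes * n, sd = config$base_sd),
                nrow = config$n_genes, dimnames = list(genes, samples))
    x <- x + baseline

    informative <- genes[seq_len(config$n_informative)]
    if (config$n_informative > 0) {
      x[informative, label == "tumor"] <-
        x[informative, label == "tumor"] + config$effect_size
    }

    module_assignments <- setNames(rep(NA_integer_, config$n_genes), genes)
    if (config$n_modules > 0 && config$module_size > 1) {
      offset <- if (config$overlap_modules) 0L else config$n_informative
      loading <- config$base_sd * sqrt(config$module_rho / (1 - config$module_rho))
      for (b in seq_len(config$n_modules)) {
        idx <- offset + (b - 1L) * config$module_size + seq_len(config$module_size)
        z <- rnorm(n)
        x[idx, ] <- x[idx, ] + loading * rep(z, each = length(idx))
        module_assignments[idx] <- b
      }
    }

    batch <- rep("B1", n)
    if (config$n_batches > 1) {
      batch <- paste0("B", rep_len(seq_len(config$n_batches), n))
      batch <- sample(batch)  # random assignment, balanced up to rounding
      for (b in unique(batch)) {
        shift <- rnorm(config$n_genes, sd = config$batch_shift_sd)
        x[, batch == b] <- x[, batch == b] + shift
      }
    }

    list(
      expression = as_expr_tibble(x),
      sample_info = tibble(sample = samples, label = label, batch = batch),
      truth = list(
        informative_genes = informative,
        module_assignments = module_assignments,
        batch_assignments = setNames(batch, samples),
        effect_size = config$effect_size
      )
    )
  })
}

#' Simulate a protein-interaction graph with a planted high-MCC hub
#'
#' The hub node is placed in `hub_cliques` otherwise-disjoint cliques of
#' `clique_size` nodes; with no background noise its Maximal Clique
#' Centrality is exactly `hub_cliques * factorial(clique_size - 1)` while
#' every other clique member scores `factorial(clique_size - 1)`. All node
#' pairs not inside a planted clique are connected independently with
#' probability `background_p`.
#'
#' @param nodes Either a node count or a character vector of node ids. The
#'   first id is the planted hub.
#' @param hub_cliques Number of planted cliques through the hub (>= 1).
#' @param clique_size Nodes per planted clique (>= 3).
#' @param background_p Background edge probability.
#' @param seed RNG seed.
#' @return A list with `graph` (an [igraph::graph] over the node ids) and
#'   `truth` (list with `planted_hub` and `clique_members`).
#' @export
simulate_ppi <- function(nodes = 60, hub_cliques = 3, clique_size = 4,
                         background_p = 0.05, seed = 1) {
  hub_cliques <- check_count(hub_cliques, "hub_cliques")
  clique_size <- check_count(clique_size, "clique_size", min = 3L)
  if (is.numeric(nodes) && length(nodes) == 1) {
    nodes <- sprintf("g%05d", seq_len(check_count(nodes, "nodes")))
  }
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) abort("duplicate node ids.")
  need <- 1L + hub_cliques * (clique_size - 1L)
  if (need > length(nodes)) {
    abort(sprintf(
      "invalid config: %d planted cliques of size %d need %d nodes but only %d supplied.",
      hub_cliques, clique_size, need, length(nodes)))
  }
  if (background_p < 0 || background_p > 1) {
    abort("invalid config: `background_p` must be in [0, 1].")
  }
  withr::with_seed(seed, {
    hub <- nodes[1]
    members <- vector("list", hub_cliques)
    edges <- list()
    for (k in seq_len(hub_cliques)) {
      others <- nodes[1L + (k - 1L) * (clique_size - 1L) + seq_len(clique_size - 1L)]
      members[[k]] <- c(hub, others)
      pairs <- combn(members[[k]], 2)
      edges[[k]] <- tibble(from = pairs[1, ], to = pairs[2, ])
    }
    planted <- dplyr::bind_rows(edges)
    if (background_p > 0) {
      all_pairs <- combn(nodes, 2)
      key <- function(a, b) paste(pmin(a, b), pmax(a, b))
      planted_key <- key(planted$from, planted$to)
      cand <- !(key(all_pairs[1, ], all_pairs[2, ]) %in% planted_key)
      keep <- cand & (runif(ncol(all_pairs)) < background_p)
      planted <- dplyr::bind_rows(
        planted, tibble(from = all_pairs[1, keep], to = all_pairs[2, keep]))
    }
    g <- igraph::graph_from_data_frame(
      planted, directed = FALSE,
      vertices = data.frame(name = nodes))
    g <- igraph::simplify(g)
    list(graph = g,
         truth = list(planted_hub = hub, clique_members = members))
  })
}

# Event times with hazard h0 * exp(beta * z); administrative censoring at the
# cutoff that hits `censor_rate` in expectation. Returns tibble(time, event).
simulate_survival_times <- function(z, hazard_beta, baseline_hazard, censor_rate) {
  rate <- baseline_hazard * exp(hazard_beta * z)
  t_event <- rexp(length(z), rate = rate)
  if (censor_rate <= 0) {
    return(tibble(time = t_event, event = rep(1L, length(z))))
  }
  # mean over patients of P(T_i > c) = censor_rate
  f <- function(cc) mean(exp(-rate * cc)) - censor_rate
  cutoff <- uniroot(f, lower = 1e-12, upper = 1e12, tol = 1e-10)$root
  event <- as.integer(t_event <= cutoff)
  tibble(time = pmin(t_event, cutoff), event = event)
}

#' Simulate a survival cohort tied to one gene's expression
#'
#' For the tumor samples of an expression matrix, draws exponential event
#' times with hazard `baseline_hazard * exp(hazard_beta * z)`, where `z` is
#' the gene's expression standardized across the tumor samples, then applies
#' administrative censoring at the uniform cutoff whose expected censored
#' fraction equals `censor_rate`.
#'
#' @param expression,sample_info The labelled expression data (tumor samples
#'   are those with `label == "tumor"`).
#' @param gene Gene id driving the hazard.
#' @param config A [synthetic_config()] supplying `hazard_beta`,
#'   `baseline_hazard`, `censor_rate` and `seed`.
#' @return A cohort tibble: `sample`, `time`, `event` (0/1), then one column
#'   per gene carrying that patient's expression.
#' @export
simulate_survival <- function(expression, sample_info, gene, config) {
  stopifnot(inherits(config, "synthetic_config"))
  x <- as_expr_matrix(expression)
  check_sample_info(expression, sample_info)
  if (!gene %in% rownames(x)) {
    abort(sprintf("gene '%s' not found in the expression matrix.", gene))
  }
  label <- aligned_annotation(expression, sample_info, "label")
  tumor <- colnames(x)[label == "tumor"]
  if (length(tumor) < 2) abort("need >= 2 tumor samples for a cohort.")
  v <- x[gene, tumor]
  s <- sd(v)
  z <- if (s > 0) (v - mean(v)) / s else v * 0
  withr::with_seed(config$seed, {
    surv <- simulate_survival_times(z, config$hazard_beta,
                                    config$baseline_hazard, config$censor_rate)
  })
  expr_cols <- as_tibble(t(x[, tumor, drop = FALSE]), .name_repair = "minimal")
  dplyr::bind_cols(tibble(sample = tumor), surv, expr_cols)
}
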