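# Protein-interaction graphs are held as igraph objects over gene symbols;
# every constructor enforces a simple graph (no self-loops, no multi-edges).

#' Coerce an edge table (or igraph) to a simple gene graph
#'
#' @param x An igraph object, or a data frame whose first two columns are
#'   edge endpoints (optional numeric third column `confidence`).
#' @param nodes Optional character vector of node ids to include even when
#'   isolated.
#' @return A simple undirected igraph over gene ids.
#' @export
as_gene_graph <- function(x, nodes = NULL) {
  if (igraph::is_igraph(x)) {
    g <- igraph::as_undirected(x, mode = "collapse")
    if (!is.null(nodes)) {
      extra <- setdiff(nodes, igraph::V(g)$name)
      if (length(extra)) g <- igraph::add_vertices(g, length(extra), name = extra)
    }
    return(igraph::simplify(g))
  }
  if (is.data.frame(x)) {
    if (nrow(x) == 0) {
      return(igraph::make_empty_graph(directed = FALSE) |>
               igraph::add_vertices(length(nodes %||% character()),
                                    name = nodes %||% character()))
    }
    ends <- tibble(from = as.character(x[[1]]), to = as.character(x[[2]]))
    verts <- union(unique(c(ends$from, ends$to)), nodes %||% character())
    g <- igraph::graph_from_data_frame(ends, directed = FALSE,
                                       vertices = data.frame(name = verts))
    return(igraph::simplify(g))
  }
  abort("cannot interpret `x` as a gene graph (need igraph or edge data frame).")
}

#' Read an undirected edge list, filtering on confidence
#'
#' Two tab-separated endpoint columns with an optional third numeric
#' confidence column in `[0, 1]` (the STRING-export convention). Edges below
#' `min_confidence` are dropped; duplicate edges and self-loops are removed
#' with a message reporting how many.
#'
#' @param path Edge-list TSV (no header).
#' @param min_confidence Confidence threshold (default 0.4, the conventional
#'   medium-confidence cutoff for STRING exports).
#' @param node_path Optional file of node ids (one per line) kept even when
#'   isolated.
#' @return A simple undirected igraph.
#' @export
read_edge_list <- function(path, min_confidence = 0.4, node_path = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  n_fields <- lengths(fields)
  bad <- which(n_fields < 2 | n_fields > 3)
  if (length(bad) > 0) {
    abort(sprintf("'%s': malformed row at line %d (expected 2 or 3 tab-separated fields).",
                  path, lineno[bad[1]]))
  }
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  conf <- rep(NA_real_, length(fields))
  has3 <- n_fields == 3
  if (any(has3)) {
    vals <- suppressWarnings(as.numeric(vapply(fields[has3], `[[`, "", 3L)))
    if (anyNA(vals)) {
      abort(sprintf("'%s': non-numeric confidence at line %d.",
                    path, lineno[has3][which(is.na(vals))[1]]))
    }
    conf[has3] <- vals
  }
  drop_conf <- !is.na(conf) & conf < min_confidence
  if (any(drop_conf)) {
    message(sprintf("dropped %d edge(s) below confidence %.2f",
                    sum(drop_conf), min_confidence))
  }
  edges <- tibble(from = from, to = to)[!drop_conf, ]
  self <- edges$from == edges$to
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  dup <- duplicated(key) & !self
  if (any(self) || any(dup)) {
    message(sprintf("removed %d self-loop(s) and %d duplicate edge(s)",
                    sum(self), sum(dup)))
  }
  nodes <- if (!is.null(node_path)) trimws(readLines(node_path, warn = FALSE)) else NULL
  nodes <- nodes[nzchar(nodes %||% character())]
  as_gene_graph(edges[!self & !dup, ], nodes = nodes)
}

#' Restrict a graph to a gene list
#'
#' @param graph igraph or edge data frame.
#' @param genes Gene ids to keep; the result's nodes are the intersection
#'   with the graph's nodes (possibly empty).
#' @return The induced simple subgraph.
#' @export
induce_subgraph <- function(graph, genes) {
  g <- as_gene_graph(graph)
  keep <- intersect(igraph::V(g)$name, as.character(genes))
  if (length(keep) == 0) message("induced subgraph is empty.")
  igraph::induced_subgraph(g, keep)
}

#' Enumerate all maximal cliques
#'
#' Complete, duplicate-free enumeration (pivoting branch-and-bound with
#' degeneracy ordering under the hood) returned in canonical order: larger
#' cliques first, then lexicographically by the sorted member tuple. A
#' maximal clique of size 1 occurs only for isolated nodes.
#'
#' @param graph igraph or edge data frame.
#' @return List of character vectors (members sorted within each clique).
#' @export
maximal_cliques <- function(graph) {
  g <- as_gene_graph(graph)
  cl <- igraph::max_cliques(g, min = 1)
  cl <- lapply(cl, function(v) sort(igraph::V(g)$name[as.integer(v)]))
  key <- vapply(cl, paste, "", collapse = "\r")
  cl[order(-lengths(cl), key)]
}

#' Maximal Clique Centrality scores
#'
#' `MCC(v)` is the sum of `(|C| - 1)!` over all maximal cliques C of size
#' >= 2 containing v; isolated nodes score 0. Factorial sums stay exact in
#' double precision for cliques up to 19 members. For any node with at least
#' one edge, `MCC(v) >= deg(v)`.
#'
#' @param graph igraph or edge data frame.
#' @return A tibble `(gene, mcc, degree)` ordered by `mcc` descending, then
#'   degree descending, then gene id.
#' @export
mcc_scores <- function(graph) {
  g <- as_gene_graph(graph)
  nodes <- igraph::V(g)$name
  mcc <- setNames(rep(0, length(nodes)), nodes)
  for (cl in maximal_cliques(g)) {
    if (length(cl) < 2) next
    mcc[cl] <- mcc[cl] + factorial(length(cl) - 1)
  }
  deg <- igraph::degree(g)[nodes]
  tibble(gene = nodes, mcc = unname(mcc), degree = unname(deg)) |>
    dplyr::arrange(dplyr::desc(.data$mcc), dplyr::desc(.data$degree),
                   .data$gene)
}

#' Extract the top-k hub genes by MCC
#'
#' @param scores An [mcc_scores()] tibble.
#' @param k Number of hubs (default 10, the conventional hub-panel size).
#' @return Character vector of k gene ids; ties resolved by MCC, then
#'   degree, then gene id — fully deterministic.
#' @export
top_hubs <- function(scores, k = 10) {
  k <- check_count(k, "k")
  if (k > nrow(scores)) {
    abort(sprintf("k = %d exceeds the number of scored nodes (%d).",
                  k, nrow(scores)))
  }
  scores$gene[seq_len(k)]
}
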