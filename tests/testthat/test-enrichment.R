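test_that("a set equal to the universe overlaps fully with p = 1", {
  universe <- sprintf("g%02d", 1:10)
  out <- ora(universe[1:4], list(ALL = universe), universe)
  expect_equal(out$overlap, 4)
  expect_equal(out$p_value, 1)
})

test_that("hypergeometric p equals exhaustive enumeration of draws", {
  # universe 10, set of 4, query of 5 with overlap 3
  universe <- sprintf("g%02d", 1:10)
  set_idx <- 1:4
  query <- universe[c(1, 2, 3, 7, 8)]
  out <- ora(query, list(S = universe[set_idx]), universe)
  expect_equal(out$overlap, 3)
  expect_equal(out$p_value, ora_enumeration_p(10, set_idx, 5, 3), tolerance = 1e-12)

  # a small sweep of other urn configurations
  set.seed(31)
  for (i in 1:15) {
    n <- sample(5:12, 1)
    uni <- sprintf("u%02d", seq_len(n))
    k_set <- sample(1:n, 1)
    q <- sample(1:n, 1)
    set_i <- sample(n, k_set)
    query_i <- sample(n, q)
    out <- ora(uni[query_i], list(S = uni[set_i]), uni, min_count = 0)
    expect_equal(out$p_value,
                 ora_enumeration_p(n, set_i, q, length(intersect(set_i, query_i))),
                 tolerance = 1e-12)
  }
})

test_that("the significance filter requires both p < 0.05 and count > 10", {
  universe <- sprintf("g%03d", 1:200)
  query <- universe[1:30]
  sets <- list(BIG_HIT = universe[1:11],   # overlap 11, tiny p
               SMALL_HIT = universe[1:9])  # overlap 9, tiny p
  out <- ora(query, sets, universe)
  expect_lt(max(out$p_value), 0.05)
  expect_true(out$significant[out$set == "BIG_HIT"])
  expect_false(out$significant[out$set == "SMALL_HIT"])
})

test_that("p values are monotone non-increasing in overlap at fixed margins", {
  ps <- vapply(1:6, function(k) {
    phyper(k - 1, 6, 14, 8, lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
  # and BH output is monotone when p sorted ascending
  p_sorted <- sort(runif(20))
  expect_true(all(diff(p.adjust(p_sorted, "BH")[order(p_sorted)]) >= -1e-15))
})

test_that("query genes outside the universe are rejected by name", {
  expect_error(ora(c("g1", "weird"), list(S = "g1"), c("g1", "g2")), "weird")
})

make_gsea_data <- function(seed = 1, n_genes = 60, n = 20) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n), n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n))))
  list(expr = expr_tbl(m),
       info = info_tbl(colnames(m), rep(c("normal", "tumor"), each = n / 2)))
}

test_that("the enrichment score equals a brute-force running-sum walk", {
  d <- make_gsea_data(seed = 4, n_genes = 10, n = 12)
  m <- as.matrix(d$expr[, -1])
  rownames(m) <- d$expr$gene
  lab <- d$info$label[match(colnames(m), d$info$sample)]
  s2n <- (rowMeans(m[, lab == "tumor"]) - rowMeans(m[, lab == "normal"])) /
    (apply(m[, lab == "tumor"], 1, sd) + apply(m[, lab == "normal"], 1, sd))
  ord <- order(-s2n, rownames(m))
  ranked <- rownames(m)[ord]
  for (set in list(ranked[1:2], ranked[c(1, 5, 9)], ranked[8:10])) {
    res <- gsea(d$expr, d$info, list(S = set), positive_class = "tumor",
                n_perm = 10, min_size = 2, max_size = 10, seed = 1)
    expect_equal(res$es, es_walk_oracle(ranked, s2n[ord], set),
                 tolerance = 1e-12)
  }
})

test_that("reversing the ranked list negates the enrichment score", {
  d <- make_gsea_data(seed = 6, n_genes = 30, n = 16)
  set <- d$expr$gene[c(2, 7, 11, 25)]
  up <- gsea(d$expr, d$info, list(S = set), positive_class = "tumor",
             n_perm = 5, min_size = 2, max_size = 30, seed = 1)
  down <- gsea(d$expr, d$info, list(S = set), positive_class = "normal",
               n_perm = 5, min_size = 2, max_size = 30, seed = 1)
  expect_equal(up$es, -down$es, tolerance = 1e-12)
})

test_that("a set made of the top-ranked genes maximizes the enrichment score", {
  d <- make_gsea_data(seed = 9, n_genes = 40, n = 20)
  m <- as.matrix(d$expr[, -1])
  rownames(m) <- d$expr$gene
  lab <- d$info$label[match(colnames(m), d$info$sample)]
  s2n <- (rowMeans(m[, lab == "tumor"]) - rowMeans(m[, lab == "normal"])) /
    (apply(m[, lab == "tumor"], 1, sd) + apply(m[, lab == "normal"], 1, sd))
  top_set <- rownames(m)[order(-s2n, rownames(m))][1:5]
  set.seed(17)
  others <- replicate(20, sample(rownames(m), 5), simplify = FALSE)
  sets <- c(list(TOP = top_set), setNames(others, sprintf("R%02d", 1:20)))
  res <- gsea(d$expr, d$info, sets, positive_class = "tumor",
              n_perm = 5, min_size = 2, max_size = 40, seed = 2)
  expect_gt(res$es[res$set == "TOP"], 0)
  expect_equal(res$set[which.max(res$es)], "TOP")
})

test_that("GSEA defaults are recorded in the result parameters", {
  d <- make_gsea_data(seed = 2, n_genes = 40, n = 12)
  res <- gsea(d$expr, d$info, list(S = d$expr$gene[1:12]),
              positive_class = "tumor", seed = 3)
  p <- attr(res, "params")
  expect_equal(p$n_perm, 1000)
  expect_equal(p$min_size, 10)
  expect_equal(p$max_size, 500)
  expect_equal(p$permutation, "gene_set")
})

test_that("the leading edge is the hit prefix (or suffix) up to the extremum", {
  d <- make_gsea_data(seed = 12, n_genes = 25, n = 14)
  set <- d$expr$gene[1:11]
  res <- gsea(d$expr, d$info, list(S = set), positive_class = "tumor",
              n_perm = 20, seed = 5)
  expect_true(all(res$leading_edge[[1]] %in% set))
  expect_gt(length(res$leading_edge[[1]]), 0)
})

test_that("the enrichment walk matches an established implementation", {
  skip_if_not_installed("fgsea")
  d <- make_gsea_data(seed = 15, n_genes = 50, n = 16)
  m <- as.matrix(d$expr[, -1])
  rownames(m) <- d$expr$gene
  lab <- d$info$label[match(colnames(m), d$info$sample)]
  s2n <- (rowMeans(m[, lab == "tumor"]) - rowMeans(m[, lab == "normal"])) /
    (apply(m[, lab == "tumor"], 1, sd) + apply(m[, lab == "normal"], 1, sd))
  ord <- order(-s2n, rownames(m))
  ranked <- rownames(m)[ord]
  set <- ranked[c(3, 9, 17, 33, 41)]
  res <- gsea(d$expr, d$info, list(S = set), positive_class = "tumor",
              n_perm = 5, min_size = 2, max_size = 50, seed = 1)
  ref <- fgsea::calcGseaStat(setNames(s2n[ord], ranked),
                             selectedStats = match(set, ranked),
                             gseaParam = 1)
  expect_equal(res$es, ref, tolerance = 1e-10)
})
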