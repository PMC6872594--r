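test_that("Fisher score matches hand evaluation of the per-gene formula", {
  m <- matrix(c(0, 2, 4, 6), nrow = 1,
              dimnames = list("g1", paste0("s", 1:4)))
  info <- info_tbl(paste0("s", 1:4), c("a", "a", "b", "b"))
  rk <- fisher_score(expr_tbl(m), info)
  # numerator 2*(1-3)^2 + 2*(5-3)^2 = 16; denominator 2*2 + 2*2 = 8
  expect_equal(rk$score, 2)
})

test_that("Fisher score equals the direct formula on random matrices", {
  for (s in 1:10) {
    set.seed(s)
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    m <- matrix(rnorm(8 * (n1 + n2)), nrow = 8,
                dimnames = list(sprintf("g%02d", 1:8),
                                sprintf("s%02d", seq_len(n1 + n2))))
    label <- rep(c("a", "b"), c(n1, n2))
    rk <- fisher_score(expr_tbl(m), info_tbl(colnames(m), label))
    oracle <- fisher_oracle(m, label)
    expect_equal(rk$score[match(rownames(m), rk$gene)], unname(oracle),
                 tolerance = 1e-12)
  }
})

test_that("Fisher score is invariant to affine maps and sample order", {
  set.seed(2)
  m <- matrix(rnorm(20 * 10), 20,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  label <- rep(c("a", "b"), each = 5)
  info <- info_tbl(colnames(m), label)
  base <- fisher_score(expr_tbl(m), info)
  m2 <- m
  m2[3, ] <- -2.5 * m2[3, ] + 7
  expect_equal(fisher_score(expr_tbl(m2), info), base, tolerance = 1e-12)
  perm <- sample(ncol(m))
  m3 <- m[, perm]
  expect_equal(fisher_score(expr_tbl(m3), info_tbl(colnames(m3), label[perm])),
               base, tolerance = 1e-12)
})

test_that("constant genes score zero and perfect separators rank first", {
  m <- matrix(c(5, 5, 5, 5,
                0, 0, 1, 1,
                rnorm(4)), nrow = 3, byrow = TRUE,
              dimnames = list(c("const", "perfect", "noise"), paste0("s", 1:4)))
  info <- info_tbl(paste0("s", 1:4), c("a", "a", "b", "b"))
  rk <- fisher_score(expr_tbl(m), info)
  expect_equal(rk$score[rk$gene == "const"], 0)
  expect_equal(rk$gene[1], "perfect")
  expect_equal(rk$score[1], Inf)
})

test_that("single-sample classes are rejected", {
  m <- matrix(rnorm(6), 2, dimnames = list(c("g1", "g2"), paste0("s", 1:3)))
  expect_error(fisher_score(expr_tbl(m),
                            info_tbl(paste0("s", 1:3), c("a", "a", "b"))),
               "single sample")
})

test_that("top-k selection is deterministic with lexicographic tie breaks", {
  rk <- structure(tibble::tibble(gene = c("d", "b", "c", "a"),
                                 score = c(3, 2, 2, 1)),
                  method = "fisher",
                  class = c("gene_ranking", class(tibble::tibble())))
  expect_equal(select_top_k(rk, 2), c("d", "b"))
  expect_equal(select_top_k(rk, 4), c("d", "b", "c", "a"))
  expect_error(select_top_k(rk, 5), "4")
})

test_that("ReliefF gives constant features weight exactly zero", {
  set.seed(1)
  m <- rbind(const = rep(4, 8), signal = c(0, 0, 0, 0, 1, 1, 1, 1),
             noise = rnorm(8))
  colnames(m) <- paste0("s", 1:8)
  info <- info_tbl(colnames(m), rep(c("a", "b"), each = 4))
  rk <- relieff_rank(expr_tbl(m), info, m = 25, seed = 3)
  expect_equal(rk$score[rk$gene == "const"], 0)
})

test_that("ReliefF matches exhaustive hand evaluation over all targets", {
  m <- matrix(c(0, 0.1, 1, 1.1), nrow = 1,
              dimnames = list("f1", paste0("s", 1:4)))
  info <- info_tbl(paste0("s", 1:4), c("a", "a", "b", "b"))
  # m = 4 draws every sample exactly once; order is irrelevant to the sum
  rk <- relieff_rank(expr_tbl(m), info, m = 4, seed = 99)
  oracle <- relieff_oracle(m, c("a", "a", "b", "b"), targets = 1:4)
  expect_equal(rk$score, oracle, tolerance = 1e-12)
  # hand value: ((1 - .1) + (.9 - .1) + (.9 - .1) + (1 - .1)) / (1.1 * 4)
  expect_equal(rk$score, 3.4 / (1.1 * 4), tolerance = 1e-12)
})

test_that("ReliefF weights are centred on zero under permuted labels", {
  set.seed(5)
  m <- matrix(rnorm(5 * 20), 5,
              dimnames = list(sprintf("f%d", 1:5), sprintf("s%02d", 1:20)))
  w <- replicate(200, {
    lab <- sample(rep(c("a", "b"), each = 10))
    rk <- relieff_rank(expr_tbl(m), info_tbl(colnames(m), lab),
                       m = 20, seed = sample.int(1e6, 1))
    rk$score[match(rownames(m), rk$gene)]
  })
  z <- abs(rowMeans(w)) / (apply(w, 1, sd) / sqrt(ncol(w)))
  expect_true(all(z < 3.5))
})

test_that("random-forest importance finds a perfect separator among noise", {
  hits <- vapply(1:25, function(s) {
    set.seed(s)
    m <- matrix(rnorm(51 * 30), 51,
                dimnames = list(c("signal", sprintf("n%02d", 1:50)),
                                sprintf("s%02d", 1:30)))
    lab <- rep(c("a", "b"), each = 15)
    m["signal", ] <- ifelse(lab == "a", 0, 1) + rnorm(30, sd = 0.05)
    rk <- rf_importance(expr_tbl(m), info_tbl(colnames(m), lab),
                        n_trees = 50, seed = s)
    rk$gene[1] == "signal"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("random-forest importance is centred on zero for pure noise", {
  imp <- vapply(1:30, function(s) {
    set.seed(s + 100)
    m <- matrix(rnorm(10 * 24), 10,
                dimnames = list(sprintf("f%02d", 1:10), sprintf("s%02d", 1:24)))
    lab <- sample(rep(c("a", "b"), each = 12))
    rk <- rf_importance(expr_tbl(m), info_tbl(colnames(m), lab),
                        n_trees = 50, seed = s)
    mean(rk$score)
  }, numeric(1))
  z <- abs(mean(imp)) / (sd(imp) / sqrt(length(imp)))
  expect_lt(z, 3.5)
})

test_that("lasso returns an empty ranking above the kill penalty", {
  set.seed(8)
  m <- matrix(rnorm(6 * 12), 6,
              dimnames = list(sprintf("g%d", 1:6), sprintf("s%02d", 1:12)))
  lab <- rep(c("a", "b"), each = 6)
  info <- info_tbl(colnames(m), lab)
  y <- as.numeric(lab == "b")
  xs <- t(m)
  xs <- scale(xs, scale = sqrt(colMeans(scale(xs, scale = FALSE)^2)))
  alpha_max <- max(abs(crossprod(xs, y - mean(y)))) / nrow(xs)
  expect_equal(nrow(lasso_rank(expr_tbl(m), info, alpha = alpha_max * 1.0001)), 0)
  expect_gt(nrow(lasso_rank(expr_tbl(m), info, alpha = alpha_max * 0.5)), 0)
})

test_that("lasso coefficients equal the soft threshold on an orthonormal design", {
  # 4 mutually orthogonal mean-zero columns from an 8-row Hadamard design,
  # scaled so each standardized column has 1/n inner product 1
  h <- matrix(c(1, 1, 1, 1, 1, 1, 1, 1,
                1, -1, 1, -1, 1, -1, 1, -1,
                1, 1, -1, -1, 1, 1, -1, -1,
                1, -1, -1, 1, 1, -1, -1, 1,
                1, 1, 1, 1, -1, -1, -1, -1), ncol = 5)
  x <- h[, 2:5]                      # orthogonal, mean zero, entries +-1
  rownames(x) <- sprintf("s%d", 1:8)
  colnames(x) <- c("ga", "gb", "gc", "gd")
  y <- c(1, 1, 0, 1, 0, 0, 1, 0)
  lab <- ifelse(y == 1, "b", "a")
  m <- t(x)
  alpha <- 0.05
  rk <- lasso_rank(expr_tbl(m), info_tbl(colnames(m), lab), alpha = alpha)
  b_uni <- drop(crossprod(x, y - mean(y))) / nrow(x)
  expected <- sign(b_uni) * pmax(abs(b_uni) - alpha, 0)
  got <- setNames(rep(0, 4), colnames(x))
  got[rk$gene] <- rk$coefficient
  expect_equal(got, expected, tolerance = 1e-7)
})

test_that("duplicated informative genes: Fisher ties them, lasso keeps one", {
  for (s in 1:20) {
    cfg <- synthetic_config(n_genes = 60, n_informative = 5, n_tumor = 15,
                            n_normal = 15, n_modules = 0, seed = s)
    sim <- simulate_expression(cfg)
    expr <- sim$expression
    dup_src <- sim$truth$informative_genes[1]
    dup <- expr[expr$gene == dup_src, ]
    dup$gene <- "zz_dup"
    expr2 <- dplyr::bind_rows(expr, dup)

    rk_f <- fisher_score(expr2, sim$sample_info)
    expect_equal(rk_f$score[rk_f$gene == dup_src],
                 rk_f$score[rk_f$gene == "zz_dup"])

    m <- as.matrix(expr2[, -1])
    lab <- sim$sample_info$label[match(colnames(m), sim$sample_info$sample)]
    y <- as.numeric(lab == sort(unique(lab))[2])
    xs <- scale(t(m), scale = sqrt(colMeans(scale(t(m), scale = FALSE)^2)))
    alpha_max <- max(abs(crossprod(xs, y - mean(y)))) / nrow(xs)
    rk_l <- lasso_rank(expr2, sim$sample_info, alpha = alpha_max / 2)
    # "full magnitude" = the coefficient the gene earns when it has no twin;
    # with the duplicate present the two copies share it, so at most one of
    # them can carry (essentially) the whole weight
    rk_single <- lasso_rank(expr, sim$sample_info, alpha = alpha_max / 2)
    full <- sum(rk_single$score[rk_single$gene == dup_src])
    mags <- c(rk_l$score[rk_l$gene == dup_src], rk_l$score[rk_l$gene == "zz_dup"])
    mags <- c(mags, rep(0, 2 - length(mags)))
    if (full > 1e-8) {
      expect_lte(sum(mags >= 0.9 * full), 1)
      expect_equal(sum(mags), full, tolerance = 1e-4)
    } else {
      expect_lt(sum(mags), 1e-6)
    }
  }
})

test_that("lasso agrees with an established solver", {
  skip_if_not_installed("glmnet")
  set.seed(21)
  m <- matrix(rnorm(15 * 40), 15,
              dimnames = list(sprintf("g%02d", 1:15), sprintf("s%02d", 1:40)))
  lab <- rep(c("a", "b"), each = 20)
  m[1:3, lab == "b"] <- m[1:3, lab == "b"] + 1
  info <- info_tbl(colnames(m), lab)
  alpha <- 0.05
  rk <- lasso_rank(expr_tbl(m), info, alpha = alpha)
  y <- as.numeric(lab == "b")
  fit <- glmnet::glmnet(t(m), y, family = "gaussian", lambda = alpha,
                        standardize = TRUE, thresh = 1e-14)
  ref <- drop(as.matrix(fit$beta))
  sd_n <- sqrt(colMeans(scale(t(m), scale = FALSE)^2))
  ref_std <- ref * sd_n            # back to the standardized-x scale
  got <- setNames(rep(0, nrow(m)), rownames(m))
  got[rk$gene] <- rk$coefficient
  expect_equal(got, ref_std[names(got)], tolerance = 1e-4)
})

test_that("selectors are deterministic given identical seeds", {
  cfg <- synthetic_config(n_genes = 40, n_informative = 5, n_tumor = 10,
                          n_normal = 10, n_modules = 0, seed = 2)
  sim <- simulate_expression(cfg)
  expect_identical(relieff_rank(sim$expression, sim$sample_info, m = 15, seed = 4),
                   relieff_rank(sim$expression, sim$sample_info, m = 15, seed = 4))
  expect_identical(rf_importance(sim$expression, sim$sample_info, n_trees = 20, seed = 4),
                   rf_importance(sim$expression, sim$sample_info, n_trees = 20, seed = 4))
})

test_that("Fisher recovers planted signal genes in the top of the ranking", {
  for (s in 1:5) {
    cfg <- synthetic_config(n_genes = 2000, n_informative = 50, n_tumor = 50,
                            n_normal = 50, effect_size = 0.75, base_sd = 0.5,
                            n_modules = 0, seed = s)
    sim <- simulate_expression(cfg)
    rk <- fisher_score(sim$expression, sim$sample_info)
    top <- select_top_k(rk, 100)
    expect_gte(length(intersect(top, sim$truth$informative_genes)) / 50, 0.9)
  }
})
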