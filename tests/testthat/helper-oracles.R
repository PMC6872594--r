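# Independent oracles used across the suite. Each re-derives the quantity
# under test from first principles (exhaustive enumeration or a literal
# transcription of the defining formula) without touching package internals.

expr_tbl <- function(m) {
  dplyr::bind_cols(tibble::tibble(gene = rownames(m)),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

info_tbl <- function(samples, label, batch = NULL) {
  out <- tibble::tibble(sample = samples, label = label)
  if (!is.null(batch)) out$batch <- batch
  out
}

# named adjacency matrix for a random Erdos-Renyi graph
random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n, dimnames = list(letters[seq_len(n)], letters[seq_len(n)]))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  }
  adj
}

adjacency_to_graph <- function(adj) {
  idx <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(from = rownames(adj)[idx[, 1]], to = rownames(adj)[idx[, 2]])
  as_gene_graph(edges, nodes = rownames(adj))
}

# Exhaustive maximal-clique enumeration over all 2^n - 1 non-empty subsets.
brute_force_cliques <- function(adj) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  bits <- as.integer(2^(seq_len(n) - 1))
  nb <- vapply(seq_len(n), function(i) {
    as.integer(sum(bits[adj[i, ] > 0]))
  }, integer(1))
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    members <- which(bitwAnd(mask, bits) != 0L)
    is_clique <- TRUE
    for (i in members) {
      others <- bitwAnd(mask, bitwNot(bits[i]))
      if (bitwAnd(nb[i], others) != others) { is_clique <- FALSE; break }
    }
    if (!is_clique) next
    maximal <- TRUE
    for (v in seq_len(n)[-members]) {
      if (bitwAnd(nb[v], mask) == mask) { maximal <- FALSE; break }
    }
    if (maximal) out[[length(out) + 1L]] <- sort(nodes[members])
  }
  out
}

brute_force_mcc <- function(adj) {
  mcc <- setNames(rep(0, nrow(adj)), rownames(adj))
  for (s in brute_force_cliques(adj)) {
    if (length(s) >= 2) mcc[s] <- mcc[s] + factorial(length(s) - 1)
  }
  mcc
}

clique_keys <- function(cliques) {
  sort(vapply(cliques, function(s) paste(sort(s), collapse = "|"), ""))
}

# Literal per-gene Fisher score: sum_k n_k (mu_k - mu)^2 / sum_k n_k sd_k^2.
fisher_oracle <- function(m, label) {
  vapply(seq_len(nrow(m)), function(l) {
    x <- m[l, ]
    mu <- mean(x)
    num <- 0; den <- 0
    for (k in unique(label)) {
      xk <- x[label == k]
      num <- num + length(xk) * (mean(xk) - mu)^2
      den <- den + length(xk) * sd(xk)^2
    }
    if (den == 0) { if (num == 0) 0 else Inf } else num / den
  }, numeric(1))
}

# ReliefF update summed over an explicit target sequence (Manhattan distance
# over range-normalized features, single nearest hit/miss).
relieff_oracle <- function(m, label, targets) {
  xs <- t(m)
  rng <- apply(xs, 2, function(v) diff(range(v)))
  xn <- xs
  for (j in seq_len(ncol(xs))) {
    xn[, j] <- if (rng[j] > 0) xs[, j] / rng[j] else 0
  }
  w <- rep(0, ncol(xn))
  for (t_idx in targets) {
    d <- rowSums(abs(sweep(xn, 2, xn[t_idx, ])))
    hits <- setdiff(which(label == label[t_idx]), t_idx)
    misses <- which(label != label[t_idx])
    h <- hits[order(d[hits], rownames(xn)[hits])][1]
    mi <- misses[order(d[misses], rownames(xn)[misses])][1]
    w <- w + (-abs(xn[h, ] - xn[t_idx, ]) + abs(xn[mi, ] - xn[t_idx, ])) / length(targets)
  }
  unname(w)
}

# Exact upper-tail hypergeometric p by enumerating every equally likely draw.
ora_enumeration_p <- function(n_universe, set_idx, query_size, observed_overlap) {
  draws <- combn(n_universe, query_size)
  hits <- apply(draws, 2, function(d) sum(d %in% set_idx))
  mean(hits >= observed_overlap)
}

# Step-by-step weighted KS running sum (weight exponent 1).
es_walk_oracle <- function(ranked_genes, metric, set_members) {
  n <- length(ranked_genes)
  hit <- ranked_genes %in% set_members
  nr <- sum(abs(metric[hit]))
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) abs(metric[i]) / nr else -1 / (n - sum(hit))
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# O/E/V table over distinct event times; returns the 1-df chi-square.
logrank_oracle <- function(t1, e1, t2, e2) {
  time <- c(t1, t2); event <- c(e1, e2)
  grp <- rep(1:2, c(length(t1), length(t2)))
  O <- 0; E <- 0; V <- 0
  for (s in sort(unique(time[event == 1]))) {
    at_risk <- time >= s
    n <- sum(at_risk); n1 <- sum(at_risk & grp == 1)
    d <- sum(time == s & event == 1)
    d1 <- sum(time == s & event == 1 & grp == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Product-limit estimate evaluated at the sorted distinct observed times.
km_oracle <- function(time, event) {
  ts <- sort(unique(time))
  surv <- numeric(length(ts)); s <- 1
  for (i in seq_along(ts)) {
    n <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  tibble::tibble(time = ts, survival = surv)
}
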