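# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive each definition by direct enumeration and
# share no code with the package internals.

# P(X >= k) for a hypergeometric draw, by enumerating every one of the
# choose(N, n) draws of n items from a universe of N with K marked items.
oracle_hypergeom_tail <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)  # items 1..K are the marked ones
  mean(overlaps >= k)
}

# P(X >= k) by the direct combinatorial sum of counting fractions,
# usable where full draw enumeration is infeasible.
oracle_hypergeom_sum <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
oracle_signed_rank <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  list(W = w_obs, p = min(1, 2 * min(p_le, p_ge)), null_W = ws)
}

# Exact two-sided Mann-Whitney p by enumerating all labelings of the pool.
oracle_mann_whitney <- function(x, y) {
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  pool <- c(x, y)
  idxs <- utils::combn(length(pool), length(x))
  us <- apply(idxs, 2, function(i) u_of(pool[i], pool[-i]))
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Direct per-gene application of the fold-change/floor filter and vote rule.
# stats_list: one data.frame per contrast with gene, log2fc, max_group_mean.
oracle_votes <- function(stats_list, fc_log2 = 1, expr_floor = 5) {
  genes <- sort(unique(unlist(lapply(stats_list, `[[`, "gene"))))
  up <- setNames(integer(length(genes)), genes)
  down <- up
  for (st in stats_list) {
    for (i in seq_len(nrow(st))) {
      g <- st$gene[i]
      if (st$max_group_mean[i] >= expr_floor) {
        if (st$log2fc[i] > fc_log2) up[g] <- up[g] + 1L
        else if (st$log2fc[i] < -fc_log2) down[g] <- down[g] + 1L
      }
    }
  }
  data.frame(gene = genes, up_votes = unname(up), down_votes = unname(down))
}

# Hand quantile normalization: sort, average ranks across columns, reassign.
oracle_quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(x) ref[rank(x, ties.method = "first")])
}

# Small random stats tables for property tests.
random_stats <- function(n_genes, contrasts, seed) {
  set.seed(seed)
  lapply(contrasts, function(cn) {
    data.frame(gene = sprintf("g%03d", seq_len(n_genes)),
               contrast = cn,
               log2fc = round(rnorm(n_genes, 0, 1.2), 3),
               max_group_mean = round(runif(n_genes, 3, 9), 3))
  })
}
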