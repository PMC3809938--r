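# brute-force one-sided exact signed-rank p-value: literal enumeration of
# all 2^n sign assignments applied to the midranked magnitudes
brute_signed_rank_p <- function(scores, tau) {
  d <- scores - tau
  d <- d[d != 0]
  if (length(d) == 0) return(1.0)
  r <- rank(abs(d), ties.method = "average")
  w_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  mean(ws >= w_obs - 1e-12)
}

# exact rank-1 positive matrix with a seeded 5% deletion mask
rank1_masked <- function(G = 50, S = 5, frac = 0.05, seed = 7) {
  u <- withr::with_seed(seed, stats::runif(G, 10, 1000))
  v <- withr::with_seed(seed + 1, stats::runif(S, 0.5, 2))
  cd <- outer(u, v)
  dimnames(cd) <- list(sprintf("g%d", seq_len(G)), sprintf("s%d", seq_len(S)))
  delete_entries(cd, frac, seed = seed + 2)
}

# small correlated positive matrix for generic imputation tests
small_expr_matrix <- function(G = 80, S = 5, seed = 11) {
  generate_expression_matrix(generator_config(
    n_probe_sets = G, n_replicates = S, block_size = 20, seed = seed))
}

max_rel_err <- function(res, m) {
  truth <- m$truth[m$mask]
  max(abs(res$values[m$mask] - truth) / abs(truth))
}
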