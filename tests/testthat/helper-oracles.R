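# Independent brute-force oracles used across the suite. These never call
# the package functions they are used to check.

# exact expected PFP for the rank-product permutation null: under independent
# within-pairing rank permutations each null gene's rank vector is marginally
# uniform on {1..G}^K, so E[#null RP <= r] = G * P(prod_k U_k <= r^K),
# enumerated exhaustively for small G, K
oracle_expected_null_count <- function(r, G, K) {
  grids <- rep(list(seq_len(G)), K)
  prods <- Reduce(function(a, b) as.vector(outer(a, b)), grids)
  G * mean(prods <= r^K + 1e-9)
}

# two-sided Fisher exact p by full enumeration of the hypergeometric support:
# sum the probabilities of all tables (fixed margins) no more likely than the
# observed one
oracle_fisher_two_sided <- function(k, n, K, N) {
  lo <- max(0, n + K - N)
  hi <- min(n, K)
  support <- lo:hi
  probs <- stats::dhyper(support, K, N - K, n)
  p_obs <- probs[support == k]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# upper-tail hypergeometric sum with the EASE deflation (overlap minus one,
# floored at zero), by direct summation
oracle_ease <- function(k, n, K, N) {
  k_def <- max(k - 1, 0)
  support <- 0:min(n, K)
  sum(stats::dhyper(support[support >= k_def], K, N - K, n))
}

# classical Fisher upper tail (no deflation), by direct summation
oracle_fisher_upper <- function(k, n, K, N) {
  support <- 0:min(n, K)
  sum(stats::dhyper(support[support >= k], K, N - K, n))
}

# analytic CDF of the t distribution with 2 degrees of freedom
oracle_t_cdf_df2 <- function(t) 0.5 + t / (2 * sqrt(2) * sqrt(1 + t^2 / 2))

# paired t-test by the textbook closed form
oracle_paired_t <- function(diffs) {
  m <- length(diffs)
  t_stat <- mean(diffs) / (stats::sd(diffs) / sqrt(m))
  list(t = t_stat, p = 2 * stats::pt(abs(t_stat), m - 1, lower.tail = FALSE))
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# small three-condition design + matrix builders used across tests
toy_design <- function(n_rep = 3, conds = c("baseline", "mid", "high")) {
  data.frame(sample = paste(rep(conds, each = n_rep),
                            seq_len(n_rep), sep = "_"),
             condition = rep(conds, each = n_rep),
             replicate = rep(seq_len(n_rep), length(conds)),
             stringsAsFactors = FALSE)
}

toy_matrix <- function(n_genes, design, mu = 8, sd = 1) {
  m <- matrix(rnorm(n_genes * nrow(design), mu, sd), n_genes, nrow(design),
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              design$sample))
  m
}
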