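# Independent brute-force oracles used across the suite.

# Exact two-sided rank-sum p-value by exhaustive enumeration, derived from
# the pair-counting definition of the Mann-Whitney statistic:
# U(S) = #{(i in S, j not in S): x_i > x_j} + 0.5 * #ties.
# For any subset S of positions, sum over i in S of the per-position pair
# totals minus the within-subset pair count C(|S|, 2) gives U(S).
oracle_ranksum_exact <- function(a, b) {
  x <- c(a, b)
  n1 <- length(a); N <- length(x)
  M <- outer(x, x, function(u, v) (u > v) + 0.5 * (u == v))
  diag(M) <- 0
  pair_tot <- rowSums(M)
  U_obs <- sum(M[seq_len(n1), (n1 + 1):N, drop = FALSE])
  combos <- combn(N, n1)
  Us <- colSums(matrix(pair_tot[combos], nrow = n1)) - choose(n1, 2)
  mu <- n1 * (N - n1) / 2
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
}

# Direct per-cell counting of transmitter categories from a dense matrix.
oracle_transmitter_categories <- function(vals, tau) {
  classes <- c("ACh", "Glu", "GABA")
  apply(vals > tau, 2L, function(v) {
    s <- paste(classes[v], collapse = "+")
    if (s == "") "none" else s
  })
}

# Small atlas used by several tests; generated once per test run.
small_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_atlas(atlas_config(n_cells = 600, n_genes = 800,
                                            n_clusters = 4, n_batches = 2,
                                            seed = 42))
    }
    cache
  }
})

# Dense toy count matrix with named dims.
toy_counts <- function(values, genes = NULL, cells = NULL) {
  m <- matrix(values, nrow = if (is.null(genes)) nrow(values) else length(genes))
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  if (is.null(cells)) cells <- paste0("c", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  m
}
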