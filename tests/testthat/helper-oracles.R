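## Independent oracles used by the unit and acceptance tests.  These are
## deliberately naive (enumeration, double loops, closed forms) and share
## no code with the package implementation.

## Two-sided rank-sum p by full enumeration of group assignments: for
## every way of assigning n_a of the pooled observations to group A,
## compute the average-rank sum and count assignments at least as far
## from its null mean as the observed one.
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n <- length(pooled)
  n_a <- length(a)
  w_obs <- sum(r[seq_len(n_a)])
  mu <- n_a * (n + 1) / 2
  sets <- utils::combn(n, n_a)
  hits <- 0L
  for (j in seq_len(ncol(sets))) {
    w <- sum(r[sets[, j]])
    if (abs(w - mu) >= abs(w_obs - mu) - 1e-9) hits <- hits + 1L
  }
  hits / ncol(sets)
}

## O(m^2) Benjamini-Hochberg step-up: sort ascending, then for each
## position take the minimum of p_(j) * m / j over all j >= i with an
## explicit inner loop; return in input order, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, ps[j] * m / j)
    q[i] <- min(best, 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

## Adjusted Rand index straight from the contingency-table formula.
oracle_ari <- function(x, y) {
  tab <- table(x, y)
  comb2 <- function(v) sum(choose(v, 2))
  idx <- comb2(as.vector(tab))
  a <- comb2(rowSums(tab))
  b <- comb2(colSums(tab))
  n2 <- choose(sum(tab), 2)
  expected <- a * b / n2
  maxidx <- (a + b) / 2
  if (maxidx == expected) return(0)
  (idx - expected) / (maxidx - expected)
}

## Spearman rho from the closed form on average ranks.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

## A small abundance matrix whose rows form planted blocks of perfectly
## correlated genes plus independent noise rows.
block_abundance <- function(n_blocks = 3, genes_per_block = 4, n_samples = 12,
                            seed = 42) {
  set.seed(seed)
  rows <- list()
  for (b in seq_len(n_blocks)) {
    base <- exp(rnorm(n_samples))
    for (g in seq_len(genes_per_block))
      rows[[length(rows) + 1]] <- base * exp(rnorm(1))
  }
  x <- do.call(rbind, rows)
  dimnames(x) <- list(sprintf("b%d_g%d", rep(seq_len(n_blocks),
                                             each = genes_per_block),
                              rep(seq_len(genes_per_block), n_blocks)),
                      sprintf("s%02d", seq_len(n_samples)))
  x
}

## Small simulated dataset used by several unit tests (cheap sizes).
small_sim <- function(seed = 1, ...) {
  cfg <- simulation_config(n_species = 10L, genes_per_species = 50L,
                           n_samples_per_group = c(30L, 30L),
                           depth = 100000L, seed = seed, ...)
  simulate_dataset(cfg)
}
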