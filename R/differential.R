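## Two-cohort differential abundance: Wilcoxon rank-sum tests with
## Benjamini-Hochberg control and directional significance calls.

## Exact two-sided rank-sum p by enumeration of all C(n+m, n) group
## assignments of the pooled (average) ranks.  Handles ties naturally;
## feasible for min(n, m) <= 8 at the sample sizes used here.
.ranksum_exact <- function(ranks_a, ranks_pooled, n_a) {
  n <- length(ranks_pooled)
  mu <- n_a * (n + 1) / 2
  obs <- abs(sum(ranks_a) - mu)
  combos <- utils::combn(n, n_a)
  w <- colSums(matrix(ranks_pooled[combos], nrow = n_a))
  mean(abs(w - mu) >= obs - 1e-9)
}

## Normal approximation with tie correction and continuity correction,
## matching the classical large-sample Wilcoxon test.  Vectorised over
## the rows of a feature x sample matrix.
.ranksum_normal <- function(x, idx_a, idx_b) {
  n_a <- length(idx_a); n_b <- length(idx_b); n <- n_a + n_b
  r <- t(apply(x, 1L, rank))
  w <- rowSums(r[, idx_a, drop = FALSE])
  u <- w - n_a * (n_a + 1) / 2
  ## tie correction: sum over tie groups of t^3 - t, per feature
  tie_term <- apply(r, 1L, function(rr) {
    t <- tabulate(match(rr, unique(rr)))
    sum(t^3 - t)
  })
  sigma2 <- (n_a * n_b / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  z <- u - n_a * n_b / 2
  p <- ifelse(sigma2 <= 0, 1,
              pmin(1, 2 * stats::pnorm(-abs((z - sign(z) * 0.5) /
                                              sqrt(pmax(sigma2, 1e-300))))))
  mean_rank_a <- w / n_a
  mean_rank_b <- (rowSums(r) - w) / n_b
  list(p = p, mean_rank_a = mean_rank_a, mean_rank_b = mean_rank_b)
}

#' Two-sample Wilcoxon rank-sum test with direction
#'
#' Two-sided test of a location difference between two groups of
#' abundances.  When `exact = NULL` the p-value is computed exactly by
#' enumerating all group assignments whenever `min(n, m) <= 8`
#' (average ranks, so tied data are handled); otherwise the normal
#' approximation with tie and continuity correction is used.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param exact `NULL` (automatic), `TRUE`, or `FALSE`.
#' @return List with `p_value`, `direction` (`"a"`, `"b"`, or `"tie"`,
#'   the group with the higher mean rank) and `method`.
#' @export
rank_sum_test <- function(values_a, values_b, exact = NULL) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    .stopf("each group needs >= 2 observations")
  if (anyNA(values_a) || anyNA(values_b))
    .stopf("missing values are not allowed")
  n_a <- length(values_a); n_b <- length(values_b)
  if (is.null(exact)) exact <- min(n_a, n_b) <= 8L
  pooled <- c(values_a, values_b)
  r <- rank(pooled)
  mean_a <- mean(r[seq_len(n_a)])
  mean_b <- mean(r[n_a + seq_len(n_b)])
  direction <- if (isTRUE(all.equal(mean_a, mean_b))) "tie"
               else if (mean_a > mean_b) "a" else "b"
  if (exact) {
    p <- .ranksum_exact(r[seq_len(n_a)], r, n_a)
    method <- "exact"
  } else {
    res <- .ranksum_normal(matrix(pooled, nrow = 1L),
                           seq_len(n_a), n_a + seq_len(n_b))
    p <- res$p
    method <- "normal"
  }
  list(p_value = p, direction = direction, method = method)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns q-values in input order: with p sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1.
#'
#' @param p_values Numeric vector with all entries in (0, 1].
#' @return Numeric vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1))
    .stopf("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-feature two-cohort differential abundance
#'
#' Runs a two-sided Wilcoxon rank-sum test on every feature of an
#' abundance matrix, adjusts with Benjamini-Hochberg, and calls a
#' feature significant when its q-value falls strictly below
#' `q_threshold`.  The direction is the group with the higher mean rank
#' (the group the feature is enriched in).  Features that are zero in
#' every sample are untestable and dropped before the correction; their
#' count is reported via `attr(result, "n_dropped")` and a message.
#'
#' @param abund Abundance matrix (features x samples).
#' @param labels Named group labels covering all samples (exactly two
#'   groups).
#' @param q_threshold Significance threshold on the q-value (default
#'   0.001).
#' @return `data.frame` with columns `feature_id`, `p_value`, `q_value`,
#'   `direction`, `significant`, ordered as the input features.
#' @export
differential_features <- function(abund, labels, q_threshold = 0.001) {
  abund <- validate_abundance_matrix(abund)
  labels <- validate_cohort_labels(labels, samples = colnames(abund))
  groups <- sort(unique(unname(labels[colnames(abund)])))
  idx_a <- which(labels[colnames(abund)] == groups[1L])
  idx_b <- which(labels[colnames(abund)] == groups[2L])
  if (length(idx_a) < 2L || length(idx_b) < 2L)
    .stopf("each group needs >= 2 samples")

  keep <- rowSums(abund) > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("differential_features: dropped %d all-zero feature(s)",
                    n_dropped))
  x <- abund[keep, , drop = FALSE]
  if (nrow(x) == 0L) .stopf("no testable features")

  res <- .ranksum_normal(x, idx_a, idx_b)
  direction <- ifelse(abs(res$mean_rank_a - res$mean_rank_b) < 1e-9, "tie",
                      ifelse(res$mean_rank_a > res$mean_rank_b,
                             groups[1L], groups[2L]))
  q <- bh_adjust(res$p)
  out <- data.frame(feature_id = rownames(x),
                    p_value = res$p, q_value = q,
                    direction = direction,
                    significant = q < q_threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  attr(out, "groups") <- groups
  out
}
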