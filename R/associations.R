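## Spearman association between MGS abundance profiles and dietary
## nutrient intake, with the raw-P significance flags used in the
## classical diet-vs-MGS correlation heatmap.

#' Spearman correlation of MGS profiles with nutrient variables
#'
#' For every (MGS, nutrient) pair, Spearman's rho (average ranks) is
#' computed over the pairwise-complete samples; the two-sided p-value
#' uses the t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom.  Flags follow the usual convention:
#' `"+"` for `P < 0.05`, `"*"` for `P < 0.01`.  Pairs with fewer than
#' `min_pairs` complete observations are reported with missing rho and a
#' reason.  No multiple-testing correction is applied to the flags; a
#' separately labelled Benjamini-Hochberg column (`q_value`) is emitted
#' in addition.
#'
#' @param mgs_profiles MGS x sample abundance matrix.
#' @param nutrients Nutrient x sample matrix (may contain `NA`).
#' @param min_pairs Minimum complete pairs per cell (default 5).
#' @return `data.frame` with columns `mgs_id`, `nutrient_id`, `n`,
#'   `rho`, `p_value`, `flag`, `q_value`, `note`.
#' @export
diet_correlation <- function(mgs_profiles, nutrients, min_pairs = 5L) {
  common <- intersect(colnames(mgs_profiles), colnames(nutrients))
  if (length(common) < min_pairs)
    .stopf("fewer than %d shared samples between profiles and nutrients",
           min_pairs)
  p_mat <- mgs_profiles[, common, drop = FALSE]
  n_mat <- nutrients[, common, drop = FALSE]
  grid <- expand.grid(nutrient_id = rownames(n_mat),
                      mgs_id = rownames(p_mat),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("mgs_id", "nutrient_id")]
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- p_mat[grid$mgs_id[i], ]
    y <- n_mat[grid$nutrient_id[i], ]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < min_pairs)
      return(data.frame(n = n, rho = NA_real_, p_value = NA_real_,
                        flag = "", note = sprintf(
                          "fewer than %d complete pairs", min_pairs)))
    rho <- stats::cor(x[ok], y[ok], method = "spearman")
    if (is.na(rho))
      return(data.frame(n = n, rho = NA_real_, p_value = NA_real_,
                        flag = "", note = "constant variable"))
    p <- spearman_pvalue(rho, n)
    flag <- if (p < 0.01) "*" else if (p < 0.05) "+" else ""
    data.frame(n = n, rho = rho, p_value = p, flag = flag, note = "")
  })
  out <- cbind(grid, do.call(rbind, res))
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  if (any(ok)) out$q_value[ok] <- bh_adjust(out$p_value[ok])
  rownames(out) <- NULL
  out
}

#' Two-sided p-value for a Spearman correlation (t-approximation)
#'
#' @param rho Spearman correlation.
#' @param n Number of complete pairs (>= 3).
#' @return Two-sided p-value in (0, 1] (clipped below at 1e-300 for
#'   `|rho| = 1`).
#' @export
spearman_pvalue <- function(rho, n) {
  if (n < 3L) .stopf("need >= 3 pairs")
  if (abs(rho) >= 1) return(1e-300)
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  max(2 * stats::pt(-abs(t), df = n - 2), 1e-300)
}

#' Pivot a diet correlation table to an MGS x nutrient matrix
#'
#' @param corr Table from [diet_correlation()].
#' @param value Column to pivot (`"rho"`, `"p_value"`, or `"flag"`).
#' @return Matrix with MGS rows and nutrient columns.
#' @export
correlation_matrix <- function(corr, value = "rho") {
  stopifnot(value %in% names(corr))
  mgs <- unique(corr$mgs_id); nut <- unique(corr$nutrient_id)
  out <- matrix(if (is.character(corr[[value]])) "" else NA_real_,
                length(mgs), length(nut), dimnames = list(mgs, nut))
  out[cbind(corr$mgs_id, corr$nutrient_id)] <- corr[[value]]
  out
}
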