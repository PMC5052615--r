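## Community summaries: alpha diversity, Bray-Curtis dissimilarity and
## principal coordinates analysis.

#' Shannon diversity index
#'
#' `H = -sum p_i log p_i` over the renormalised non-zero proportions of
#' a profile (natural log by default).
#'
#' @param profile Non-negative numeric vector with positive sum, or a
#'   feature x sample matrix (one index per sample column).
#' @param base Logarithm base (default `exp(1)`; use 2 for bits).
#' @return Numeric value (or named vector for matrix input).
#' @export
shannon_index <- function(profile, base = exp(1)) {
  if (is.matrix(profile))
    return(apply(profile, 2L, shannon_index, base = base))
  if (anyNA(profile) || any(profile < 0)) .stopf("profile must be non-negative")
  if (sum(profile) <= 0) .stopf("profile sums to zero")
  unname(vegan::diversity(profile, index = "shannon", base = base))
}

#' Feature richness
#'
#' Number of features detected strictly above `detection_min`.
#'
#' @param profile Non-negative vector or feature x sample matrix.
#' @param detection_min Strict detection threshold (default 0).
#' @return Integer count (or named vector for matrix input).
#' @export
richness <- function(profile, detection_min = 0) {
  if (is.matrix(profile)) return(colSums(profile > detection_min))
  sum(profile > detection_min)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` for every sample
#' pair; values lie in `[0, 1]` for non-negative profiles.
#'
#' @param abund Abundance matrix (features x samples), >= 2 samples.
#' @return Symmetric sample x sample distance matrix with zero diagonal.
#' @export
bray_curtis <- function(abund) {
  if (ncol(abund) < 2L) .stopf("need >= 2 samples")
  if (anyNA(abund) || any(abund < 0)) .stopf("abundances must be non-negative")
  zero <- colSums(abund) == 0
  if (sum(zero) >= 2L)
    .stopf("Bray-Curtis undefined for a pair of all-zero samples: %s",
           paste(utils::head(colnames(abund)[zero], 2), collapse = ", "))
  d <- as.matrix(vegan::vegdist(t(abund), method = "bray"))
  diag(d) <- 0
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centres `-D^2 / 2`, eigendecomposes, and returns coordinates
#' `eigenvector * sqrt(eigenvalue)` for the positive eigenvalues in
#' decreasing order.  Negative eigenvalues (possible for non-Euclidean
#' dissimilarities such as Bray-Curtis) are reported but never used for
#' axes; no Lingoes/Cailliez correction is applied.  Axis signs are
#' fixed so each axis's largest-magnitude coordinate is positive.
#'
#' @param dist Symmetric distance matrix with zero diagonal.
#' @param n_axes Number of axes requested (default 2); if fewer positive
#'   eigenvalues exist, all available axes are returned with a warning.
#' @return List of class `pcoa_result` with `coordinates` (samples x
#'   axes), `eigenvalues` (all, decreasing), and `prop_explained`
#'   (relative to the positive eigenvalue total).
#' @export
pcoa <- function(dist, n_axes = 2L) {
  dist <- as.matrix(dist)
  if (!isSymmetric(unname(dist), tol = 1e-8))
    .stopf("distance matrix must be symmetric")
  if (any(abs(diag(dist)) > 1e-12)) .stopf("distance diagonal must be zero")
  n <- nrow(dist)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(dist), k = n - 1L, eig = TRUE))
  eig <- fit$eig
  n_pos <- sum(eig > 1e-9 * max(abs(eig)))
  if (n_pos < n_axes) {
    warning(sprintf("only %d positive eigenvalue(s); returning %d axis/axes",
                    n_pos, n_pos), call. = FALSE)
    n_axes <- n_pos
  }
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    i_max <- which.max(abs(coords[, j]))
    if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- sprintf("PCo%d", seq_len(ncol(coords)))
  pos_total <- sum(eig[eig > 0])
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 prop_explained = eig[seq_len(n_axes)] / pos_total),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d axes (%s of positive inertia)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * x$prop_explained),
                    collapse = " + ")))
  invisible(x)
}
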