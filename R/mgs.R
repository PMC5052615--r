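## Metagenomic species (MGS): co-abundance clustering of differential
## genes, cluster fusion, tracer genes, abundance profiles, consensus
## taxonomy, and the MGS co-occurrence network.

#' Spearman correlation matrix between features
#'
#' Rank correlation (average ranks for ties) of feature profiles across
#' all samples, both cohorts pooled.  Constant features have undefined
#' rank correlation; their entries are recorded as 0 with a warning.
#'
#' @param abund Abundance matrix (features x samples), >= 3 samples.
#' @param features Optional subset of feature ids.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(abund, features = NULL) {
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(abund))
    if (length(missing) > 0)
      .stopf("feature(s) not in matrix: %s", missing[1])
    abund <- abund[features, , drop = FALSE]
  }
  if (nrow(abund) == 0L) .stopf("empty feature subset")
  if (ncol(abund) < 3L) .stopf("need >= 3 samples")
  rho <- suppressWarnings(stats::cor(t(abund), method = "spearman"))
  if (anyNA(rho)) {
    warning(sprintf("%d constant feature(s): undefined correlations set to 0",
                    sum(apply(abund, 1L, function(r) length(unique(r))) == 1L)),
            call. = FALSE)
    rho[is.na(rho)] <- 0
  }
  diag(rho) <- 1
  rho
}

#' Single-linkage clustering at a correlation threshold
#'
#' Cuts single-linkage clustering at similarity `threshold`, which is
#' equivalent to taking the connected components of the graph with an
#' edge wherever `rho > threshold` (strict).
#'
#' @param rho Symmetric correlation matrix with feature dimnames.
#' @param threshold Strict correlation threshold (default 0.8).
#' @return Named list of clusters (character vectors of feature ids,
#'   singletons included), ordered by decreasing size then by first
#'   member id.
#' @export
single_linkage_clusters <- function(rho, threshold = 0.8) {
  if (!isSymmetric(unname(rho), tol = 1e-12))
    .stopf("correlation matrix must be symmetric")
  ids <- rownames(rho)
  adj <- rho > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  clusters <- split(ids, comp)
  first <- vapply(clusters, function(x) sort(x)[1L], "")
  clusters <- clusters[order(-lengths(clusters), first)]
  names(clusters) <- sprintf("C%04d", seq_along(clusters))
  clusters
}

.median_profile <- function(abund, genes) {
  apply(abund[genes, , drop = FALSE], 2L, stats::median)
}

#' Fuse large co-abundance clusters into MGS bins
#'
#' Clusters with more than `min_size` genes are eligible; the pair of
#' eligible clusters whose representative profiles (per-sample median of
#' member-gene abundances) have the highest Spearman correlation is
#' fused while that correlation strictly exceeds `threshold`, the
#' representative being recomputed after each fusion (ties broken by the
#' lexicographically smaller cluster-id pair).  Clusters that still hold
#' `<= min_size` genes are not reported as MGS but retained in a side
#' table.
#'
#' @param partition Cluster list from [single_linkage_clusters()].
#' @param abund Gene-level abundance matrix covering all clustered
#'   genes.
#' @param min_size Minimum MGS size, exclusive (default 25: an MGS has
#'   more than 25 genes).
#' @param threshold Strict fusion threshold on the representative-
#'   profile correlation (default 0.8).
#' @return List with `mgs` (list of `mgs_bin` objects, ids `MGS001`...
#'   by decreasing size) and `small` (`data.frame` of discarded
#'   clusters: id, size, member genes).
#' @export
fuse_clusters <- function(partition, abund, min_size = 25L, threshold = 0.8) {
  sizes <- lengths(partition)
  eligible <- partition[sizes > min_size]
  small <- partition[sizes <= min_size]

  if (length(eligible) >= 2L && ncol(abund) >= 3L) {
    reps <- t(vapply(eligible, function(g) .median_profile(abund, g),
                     numeric(ncol(abund))))
    repeat {
      if (nrow(reps) < 2L) break
      rho <- suppressWarnings(stats::cor(t(reps), method = "spearman"))
      rho[is.na(rho)] <- 0
      diag(rho) <- -Inf
      best <- max(rho)
      if (best <= threshold) break
      cand <- which(rho == best, arr.ind = TRUE)
      cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
      pairs <- cbind(rownames(reps)[cand[, 1L]], rownames(reps)[cand[, 2L]])
      ord <- order(pairs[, 1L], pairs[, 2L])
      keep_id <- pairs[ord[1L], 1L]; drop_id <- pairs[ord[1L], 2L]
      eligible[[keep_id]] <- sort(c(eligible[[keep_id]], eligible[[drop_id]]))
      eligible[[drop_id]] <- NULL
      reps <- reps[setdiff(rownames(reps), drop_id), , drop = FALSE]
      reps[keep_id, ] <- .median_profile(abund, eligible[[keep_id]])
    }
  }

  keep <- lengths(eligible) > min_size
  small <- c(small, eligible[!keep])
  eligible <- eligible[keep]
  first <- vapply(eligible, function(x) sort(x)[1L],
                  FUN.VALUE = "", USE.NAMES = FALSE)
  ord <- order(-lengths(eligible), first)
  mgs <- lapply(seq_along(ord), function(i) {
    structure(list(mgs_id = sprintf("MGS%03d", i),
                   gene_ids = sort(eligible[[ord[i]]]),
                   tracer_gene_ids = NULL, profile = NULL,
                   taxon = "unassigned", taxon_rank = NA_character_,
                   enriched_in = NA_character_),
              class = "mgs_bin")
  })
  small_df <- if (length(small) > 0)
    data.frame(cluster_id = names(small), size = lengths(small),
               gene_ids = vapply(small, paste, "", collapse = ","),
               row.names = NULL, stringsAsFactors = FALSE)
  else data.frame(cluster_id = character(), size = integer(),
                  gene_ids = character(), stringsAsFactors = FALSE)
  list(mgs = mgs, small = small_df)
}

#' @export
print.mgs_bin <- function(x, ...) {
  cat(sprintf("%s: %d genes, taxon %s%s%s\n", x$mgs_id, length(x$gene_ids),
              x$taxon,
              if (!is.na(x$taxon_rank)) sprintf(" (%s)", x$taxon_rank) else "",
              if (!is.na(x$enriched_in))
                sprintf(", enriched in %s", x$enriched_in) else ""))
  invisible(x)
}

#' Select tracer genes for an MGS
#'
#' The `k` member genes whose profiles correlate best (Spearman) with
#' the cluster's per-sample median profile; ties broken by higher mean
#' abundance, then lexicographic gene id.  If the MGS has `<= k` genes,
#' all members are tracers.
#'
#' @param gene_ids Member gene ids.
#' @param abund Gene-level abundance matrix.
#' @param k Number of tracers (default 25).
#' @return Ordered character vector of tracer gene ids.
#' @export
select_tracers <- function(gene_ids, abund, k = 25L) {
  if (length(gene_ids) == 0L) .stopf("empty MGS")
  med <- .median_profile(abund, gene_ids)
  x <- abund[gene_ids, , drop = FALSE]
  rho <- suppressWarnings(
    stats::cor(t(x), med, method = "spearman"))[, 1L]
  rho[is.na(rho)] <- 0
  ord <- order(-rho, -rowMeans(x), gene_ids)
  gene_ids[ord[seq_len(min(k, length(gene_ids)))]]
}

#' MGS abundance profile
#'
#' Per-sample median of the tracer-gene abundances.
#'
#' @param tracer_gene_ids Tracer gene ids (or all members).
#' @param abund Gene-level abundance matrix.
#' @return Named numeric vector, one value per sample.
#' @export
mgs_profile <- function(tracer_gene_ids, abund) {
  .median_profile(abund, tracer_gene_ids)
}

#' Consensus taxonomy of an MGS
#'
#' Considers only best hits with identity strictly above `identity_min`
#' and query overlap strictly above `overlap_min`, and walks the ranks
#' from strain up to superkingdom: the MGS is assigned the deepest rank
#' at which a single taxon name accounts for strictly more than
#' `consensus` of the MGS's genes.  By default the denominator is all
#' member genes, so genes without a qualifying hit count against the
#' consensus (`strict = FALSE` restricts the denominator to genes with a
#' qualifying hit).
#'
#' @param gene_ids Member gene ids.
#' @param hits Best-hit table.
#' @param identity_min,overlap_min Strict hit qualification thresholds.
#' @param consensus Strict consensus fraction (default 0.90).
#' @param strict Use all member genes as denominator (default `TRUE`).
#' @return List with `taxon` (name or `"unassigned"`), `rank` (or
#'   `NA`), and `support` (winning fraction, or `NA`).
#' @export
assign_taxonomy <- function(gene_ids, hits, identity_min = 95,
                            overlap_min = 90, consensus = 0.90,
                            strict = TRUE) {
  if (!"species" %in% colnames(hits)) hits <- validate_gene_hits(hits)
  idx <- match(gene_ids, hits$gene_id)
  ok <- !is.na(idx)
  qual <- ok
  qual[ok] <- hits$pct_identity[idx[ok]] > identity_min &
    hits$pct_overlap[idx[ok]] > overlap_min
  for (rank in rev(names(LINEAGE_RANKS))) {  # strain first
    name <- character(0)
    if (any(qual)) {
      name <- hits[[rank]][idx[qual]]
      name <- name[nzchar(name)]
    }
    if (length(name) == 0L) next
    tab <- table(name)
    denom <- if (strict) length(gene_ids) else sum(qual)
    frac <- max(tab) / denom
    if (frac > consensus)
      return(list(taxon = names(tab)[which.max(tab)], rank = rank,
                  support = unname(frac)))
  }
  list(taxon = "unassigned", rank = NA_character_, support = NA_real_)
}

#' Cluster differential genes into MGS
#'
#' Convenience wrapper running the full MGS stage: Spearman correlation
#' of the selected genes across all samples, single-linkage clustering
#' at `rho > rho_cluster`, fusion of clusters with more than `min_size`
#' genes, tracer selection and profile computation, and (when `hits`
#' and/or `labels` are given) consensus taxonomy and enrichment
#' direction of each MGS (rank-sum direction of its profile between the
#' two cohorts).
#'
#' @param abund Gene-level abundance matrix.
#' @param gene_ids Genes to cluster (typically the significant genes of
#'   [differential_features()]).
#' @param rho_cluster Strict clustering threshold (default 0.8).
#' @param min_size Minimum MGS size, exclusive (default 25).
#' @param tracer_k Tracer genes per MGS (default 25).
#' @param hits Optional best-hit table for consensus taxonomy.
#' @param labels Optional cohort labels for the enrichment direction.
#' @return List with `mgs` (list of completed `mgs_bin`s), `small`
#'   (side table of discarded clusters), and `profiles` (MGS x sample
#'   abundance matrix).
#' @export
mgs_cluster <- function(abund, gene_ids, rho_cluster = 0.8, min_size = 25L,
                        tracer_k = 25L, hits = NULL, labels = NULL) {
  rho <- spearman_matrix(abund, gene_ids)
  part <- single_linkage_clusters(rho, threshold = rho_cluster)
  fused <- fuse_clusters(part, abund, min_size = min_size,
                         threshold = rho_cluster)
  bins <- fused$mgs
  if (!is.null(hits) && !"species" %in% colnames(hits))
    hits <- validate_gene_hits(hits)
  for (i in seq_along(bins)) {
    bins[[i]]$tracer_gene_ids <- select_tracers(bins[[i]]$gene_ids, abund,
                                                k = tracer_k)
    bins[[i]]$profile <- mgs_profile(bins[[i]]$tracer_gene_ids, abund)
    if (!is.null(hits)) {
      tax <- assign_taxonomy(bins[[i]]$gene_ids, hits)
      bins[[i]]$taxon <- tax$taxon
      bins[[i]]$taxon_rank <- tax$rank
    }
    if (!is.null(labels)) {
      lab <- labels[colnames(abund)]
      groups <- sort(unique(unname(lab)))
      ts <- rank_sum_test(bins[[i]]$profile[lab == groups[1L]],
                          bins[[i]]$profile[lab == groups[2L]],
                          exact = FALSE)
      bins[[i]]$enriched_in <- switch(ts$direction, a = groups[1L],
                                      b = groups[2L], "tie")
    }
  }
  profiles <- if (length(bins) > 0)
    do.call(rbind, lapply(bins, `[[`, "profile"))
  else matrix(numeric(), 0L, ncol(abund),
              dimnames = list(NULL, colnames(abund)))
  if (length(bins) > 0)
    rownames(profiles) <- vapply(bins, `[[`, "", "mgs_id")
  list(mgs = bins, small = fused$small, profiles = profiles)
}

#' Build the MGS co-occurrence network
#'
#' Nodes are MGS; two nodes are linked when the Spearman correlation of
#' their abundance profiles strictly exceeds `rho_min`.  Node
#' attributes carry the mean relative abundance (node size in the
#' classical visualisation) and the order-level taxon name (node
#' colour).
#'
#' @param profiles MGS x sample abundance matrix (>= 2 MGS).
#' @param mgs_bins Optional list of `mgs_bin`s supplying order-level
#'   taxon names (via each bin's hit-derived lineage); otherwise orders
#'   are `""`.
#' @param hits Optional best-hit table used to look up the order of each
#'   MGS's assigned taxon.
#' @param rho_min Strict edge threshold (default 0.6).
#' @return An [mgs_network()] object.
#' @export
build_network <- function(profiles, mgs_bins = NULL, hits = NULL,
                          rho_min = 0.6) {
  if (nrow(profiles) < 2L) .stopf("need >= 2 MGS to build a network")
  rho <- spearman_matrix(profiles)
  ids <- rownames(profiles)
  orders <- rep("", length(ids))
  if (!is.null(mgs_bins)) {
    if (!is.null(hits) && !"order" %in% colnames(hits))
      hits <- validate_gene_hits(hits)
    for (i in seq_along(mgs_bins)) {
      b <- mgs_bins[[i]]
      j <- match(b$mgs_id, ids)
      if (is.na(j)) next
      if (!is.null(hits) && !is.na(b$taxon_rank)) {
        row <- which(hits[[b$taxon_rank]] == b$taxon)[1L]
        if (!is.na(row)) orders[j] <- hits$order[row]
      }
    }
  }
  nodes <- data.frame(mgs_id = ids,
                      mean_abundance = rowMeans(profiles),
                      taxon_order = orders, stringsAsFactors = FALSE)
  ## strict exceedance with a guard against floating-point wobble, so a
  ## correlation that equals the threshold up to rounding yields no edge
  pairs <- which(upper.tri(rho) & rho - rho_min > 1e-12, arr.ind = TRUE)
  edges <- data.frame(from = ids[pairs[, 1L]], to = ids[pairs[, 2L]],
                      rho = rho[pairs], stringsAsFactors = FALSE)
  mgs_network(nodes, edges, rho_min = rho_min)
}
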