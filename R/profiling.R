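## From mapped read-pair counts to length-normalised relative abundances,
## and aggregation of gene abundances to KO/OG and taxon profiles.

#' Length-normalised relative gene abundance
#'
#' Per sample, `a_g = (x_g / L_g) / sum_j (x_j / L_j)` where `x_g` is
#' the mapped read-pair count and `L_g` the gene length in bp.  Columns
#' of the result sum to 1.
#'
#' @param counts Count matrix (genes x samples).
#' @param genes Gene length table (`gene_id`, `length_bp`) covering
#'   every gene in `counts`.
#' @return Relative abundance matrix (genes x samples).
#' @export
gene_relative_abundance <- function(counts, genes) {
  counts <- validate_count_matrix(counts)
  genes <- validate_gene_table(genes)
  idx <- match(rownames(counts), genes$gene_id)
  if (anyNA(idx))
    .stopf("gene length missing for: %s",
           rownames(counts)[which(is.na(idx))[1]])
  len <- genes$length_bp[idx]
  w <- counts / len
  cs <- colSums(w)
  zero <- which(cs == 0)
  if (length(zero) > 0)
    .stopf("sample with no mapped read pairs: %s",
           paste(utils::head(colnames(counts)[zero], 5), collapse = ", "))
  sweep(w, 2L, cs, "/")
}

#' Accumulate gene abundances by functional annotation
#'
#' The abundance of a KO (or OG) is the sum of the relative abundances
#' of its member genes.  A gene annotated to several features
#' contributes its full abundance to each of them (documented
#' double-counting; set `split = TRUE` to divide a gene's abundance
#' equally among its annotations instead).  Unannotated genes contribute
#' to no feature, so column sums may fall below 1.
#'
#' @param abund Gene-level relative abundance matrix.
#' @param ann Named list mapping gene id to a character vector of
#'   feature ids (KO/OG).
#' @param split Divide multi-annotated genes' abundance equally among
#'   their features (default `FALSE`).
#' @return Feature-level abundance matrix (features x samples), features
#'   sorted by id.
#' @export
aggregate_by_annotation <- function(abund, ann, split = FALSE) {
  abund <- validate_abundance_matrix(abund)
  if (length(ann) == 0L || all(lengths(ann) == 0L))
    .stopf("empty annotation map")
  ann <- ann[names(ann) %in% rownames(abund)]
  genes <- rep(names(ann), lengths(ann))
  feats <- unlist(ann, use.names = FALSE)
  if (length(genes) == 0L) .stopf("no annotated gene present in the matrix")
  x <- abund[genes, , drop = FALSE]
  if (split) x <- x / lengths(ann)[match(genes, names(ann))]
  out <- rowsum(x, group = feats, reorder = TRUE)
  validate_abundance_matrix(out)
}

#' Accumulate gene abundances by best-hit taxon
#'
#' Sums gene abundances by the name at `rank` of each gene's best hit,
#' considering only hits with identity strictly above `identity_min`
#' and query overlap strictly above `overlap_min`.  Genes with no
#' qualifying hit (including genes absent from the hit table or unnamed
#' at `rank`) are pooled under `"unclassified"`, so columns of a
#' relative input still sum to 1.
#'
#' @param abund Gene-level relative abundance matrix.
#' @param hits Best-hit table from [read_gene_hits()] /
#'   [validate_gene_hits()].
#' @param rank One of the ranks in [LINEAGE_RANKS].
#' @param identity_min,overlap_min Strict qualification thresholds
#'   (percent), defaults 95 and 90.
#' @return Taxon-level abundance matrix (taxa x samples).
#' @export
aggregate_by_taxon <- function(abund, hits, rank = "species",
                               identity_min = 95, overlap_min = 90) {
  abund <- validate_abundance_matrix(abund)
  if (!rank %in% names(LINEAGE_RANKS))
    .stopf("unknown rank '%s' (use one of: %s)", rank,
           paste(names(LINEAGE_RANKS), collapse = ", "))
  if (!rank %in% colnames(hits)) hits <- validate_gene_hits(hits)
  idx <- match(rownames(abund), hits$gene_id)
  name <- rep("unclassified", nrow(abund))
  ok <- !is.na(idx)
  qual <- ok
  qual[ok] <- hits$pct_identity[idx[ok]] > identity_min &
    hits$pct_overlap[idx[ok]] > overlap_min &
    nzchar(hits[[rank]][idx[ok]])
  name[qual] <- hits[[rank]][idx[qual]]
  rowsum(abund, group = name, reorder = TRUE)
}
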