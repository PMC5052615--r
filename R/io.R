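## Tabular IO and shared domain containers.
##
## Orientation is fixed throughout the package: rows are features (genes,
## KOs, taxa, MGS, nutrients), columns are samples.  All tables are UTF-8
## TSV with a header row; "NA" marks missing values where a reader allows
## them.  Joins across tables always align by identifier, never by
## position.

#' Taxonomic ranks used throughout the package
#'
#' Ordered from superkingdom down to strain, with the one-letter prefixes
#' used in semicolon-separated lineage strings
#' (`k__...;p__...;c__...;o__...;f__...;g__...;s__...;t__...`).
#'
#' @format A named character vector mapping rank name to lineage prefix.
#' @export
LINEAGE_RANKS <- c(
  superkingdom = "k", phylum = "p", class = "c", order = "o",
  family = "f", genus = "g", species = "s", strain = "t"
)

## ---- internal helpers -------------------------------------------------

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.read_tsv <- function(path) {
  if (!file.exists(path)) .stopf("input file does not exist: %s", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "", na.strings = NULL,
                    colClasses = "character")
}

.check_unique <- function(ids, what, path) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    .stopf("duplicated %s in %s: %s", what, path,
           paste(utils::head(dup, 5), collapse = ", "))
}

## Parse the body of a feature x sample table into a numeric matrix,
## reporting the first offending cell by row/column coordinates.
.parse_matrix_body <- function(tab, path, allow_na = FALSE) {
  ids <- tab[[1L]]
  .check_unique(ids, "feature ids", path)
  .check_unique(colnames(tab)[-1L], "sample ids", path)
  body <- as.matrix(tab[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(vals) & !(allow_na & body == "NA"), arr.ind = TRUE)
  if (nrow(bad) > 0)
    .stopf("non-numeric cell in %s at row '%s', column '%s': '%s'",
           path, ids[bad[1, 1]], colnames(body)[bad[1, 2]],
           body[bad[1, 1], bad[1, 2]])
  neg <- which(vals < 0, arr.ind = TRUE)
  if (!allow_na && nrow(neg) > 0)
    .stopf("negative cell in %s at row '%s', column '%s'",
           path, ids[neg[1, 1]], colnames(body)[neg[1, 2]])
  dimnames(vals) <- list(ids, colnames(body))
  vals
}

## Lossless numeric formatting for writers (%.17g round-trips doubles).
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.write_matrix <- function(values, path, id_col, digits = NULL) {
  body <- if (is.null(digits)) {
    if (is.integer(values) || all(values == round(values), na.rm = TRUE))
      matrix(format(values, scientific = FALSE, trim = TRUE),
             nrow = nrow(values))
    else matrix(.fmt_num(values), nrow = nrow(values))
  } else {
    matrix(sprintf(paste0("%.", digits, "f"), values), nrow = nrow(values))
  }
  body[is.na(values)] <- "NA"
  lines <- c(paste(c(id_col, colnames(values)), collapse = "\t"),
             paste(rownames(values), apply(body, 1, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

## ---- count matrix -----------------------------------------------------

#' Validate a gene-by-sample count matrix
#'
#' A count matrix holds the number of read pairs mapped to each catalogue
#' gene in each sample (both mates of a pair must map to the same gene to
#' be counted).  Entries are non-negative integers; gene and sample ids
#' are unique.
#'
#' @param counts Numeric matrix, rows = genes, columns = samples, with
#'   rownames and colnames set.
#' @return The validated matrix, invisibly coerced to storage mode double.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts)))
    .stopf("counts must be a matrix with gene rownames and sample colnames")
  .check_unique(rownames(counts), "gene ids", "count matrix")
  .check_unique(colnames(counts), "sample ids", "count matrix")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    .stopf("count matrix entries must be non-negative integers")
  counts
}

#' Read a gene-by-sample count matrix from TSV
#'
#' First column holds gene ids, first row holds sample ids.
#'
#' @param path Path to a tab-separated text file.
#' @return Numeric matrix of mapped read-pair counts (genes x samples).
#' @export
read_count_matrix <- function(path) {
  vals <- .parse_matrix_body(.read_tsv(path), path)
  validate_count_matrix(vals)
}

#' Write a count matrix to TSV
#'
#' @param counts Validated count matrix.
#' @param path Output path.
#' @export
write_count_matrix <- function(counts, path) {
  .write_matrix(validate_count_matrix(counts), path, "gene_id")
}

## ---- abundance matrix -------------------------------------------------

#' Validate a relative abundance matrix
#'
#' @param values Numeric matrix (features x samples), entries >= 0.
#' @param relative If `TRUE`, additionally require every sample column to
#'   sum to 1 within `1e-9` (all-zero columns are forbidden).
#' @return The validated matrix.
#' @export
validate_abundance_matrix <- function(values, relative = FALSE) {
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values)))
    .stopf("abundance matrix must have feature rownames and sample colnames")
  .check_unique(rownames(values), "feature ids", "abundance matrix")
  .check_unique(colnames(values), "sample ids", "abundance matrix")
  if (anyNA(values) || any(values < 0))
    .stopf("abundance matrix entries must be non-negative and non-missing")
  if (relative) {
    cs <- colSums(values)
    off <- which(abs(cs - 1) > 1e-9)
    if (length(off) > 0)
      .stopf("sample column(s) do not sum to 1: %s",
             paste(utils::head(colnames(values)[off], 5), collapse = ", "))
  }
  values
}

#' Read an abundance matrix from TSV
#'
#' @inheritParams read_count_matrix
#' @param relative Enforce unit column sums (see
#'   [validate_abundance_matrix()]).
#' @return Numeric matrix (features x samples).
#' @export
read_abundance_matrix <- function(path, relative = FALSE) {
  vals <- .parse_matrix_body(.read_tsv(path), path)
  validate_abundance_matrix(vals, relative = relative)
}

#' Write an abundance matrix to TSV
#'
#' Values are written with full double precision so that a write/read
#' cycle is lossless.
#'
#' @param values Abundance matrix.
#' @param path Output path.
#' @export
write_abundance_matrix <- function(values, path) {
  .write_matrix(validate_abundance_matrix(values), path, "feature_id")
}

## ---- cohort labels ----------------------------------------------------

#' Validate cohort labels
#'
#' @param labels Named character vector mapping sample id to group label.
#' @param samples Optional sample ids that must all be labelled.
#' @param two_groups Require exactly two groups with >= 2 samples each
#'   (the precondition of all two-cohort stages).
#' @return The validated labels.
#' @export
validate_cohort_labels <- function(labels, samples = NULL, two_groups = TRUE) {
  if (is.null(names(labels)) || any(names(labels) == ""))
    .stopf("labels must be a named vector (names = sample ids)")
  .check_unique(names(labels), "sample ids", "cohort labels")
  if (!is.null(samples)) {
    missing <- setdiff(samples, names(labels))
    if (length(missing) > 0)
      .stopf("unlabelled sample(s): %s",
             paste(utils::head(missing, 5), collapse = ", "))
  }
  if (two_groups) {
    tab <- table(labels)
    if (length(tab) != 2L)
      .stopf("expected exactly 2 groups, found %d (%s)", length(tab),
             paste(names(tab), collapse = ", "))
    if (any(tab < 2L))
      .stopf("each group needs >= 2 samples")
  }
  labels
}

#' Read sample-to-cohort labels from a two-column TSV
#'
#' Columns: `sample_id`, `group`.
#'
#' @param path Path to the TSV file.
#' @return Named character vector of group labels.
#' @export
read_cohort_labels <- function(path) {
  tab <- .read_tsv(path)
  if (ncol(tab) < 2L) .stopf("label table needs columns sample_id, group")
  .check_unique(tab[[1L]], "sample ids", path)
  stats::setNames(as.character(tab[[2L]]), tab[[1L]])
}

#' Write cohort labels to TSV
#' @param labels Named character vector of group labels.
#' @param path Output path.
#' @export
write_cohort_labels <- function(labels, path) {
  writeLines(c("sample_id\tgroup",
               paste(names(labels), labels, sep = "\t")), path)
  invisible(path)
}

## ---- gene table -------------------------------------------------------

#' Read a gene length table
#'
#' Columns: `gene_id`, `length_bp`.  Lengths must be integers >= 100
#' (the minimum ORF length of the catalogue).
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with columns `gene_id`, `length_bp`.
#' @export
read_gene_table <- function(path) {
  tab <- .read_tsv(path)
  if (!all(c("gene_id", "length_bp") %in% colnames(tab)))
    .stopf("gene table needs columns gene_id, length_bp")
  out <- data.frame(gene_id = tab$gene_id,
                    length_bp = suppressWarnings(as.numeric(tab$length_bp)),
                    stringsAsFactors = FALSE)
  validate_gene_table(out)
}

#' Validate a gene length table
#' @param genes `data.frame` with `gene_id` and `length_bp`.
#' @return The validated table.
#' @export
validate_gene_table <- function(genes) {
  .check_unique(genes$gene_id, "gene ids", "gene table")
  if (anyNA(genes$length_bp) || any(genes$length_bp != round(genes$length_bp)))
    .stopf("gene lengths must be integers")
  if (any(genes$length_bp < 100))
    .stopf("gene length below the 100 bp catalogue minimum: %s",
           genes$gene_id[which(genes$length_bp < 100)[1]])
  genes
}

#' Write a gene length table to TSV
#' @param genes Gene table.
#' @param path Output path.
#' @export
write_gene_table <- function(genes, path) {
  writeLines(c("gene_id\tlength_bp",
               paste(genes$gene_id, format(genes$length_bp, trim = TRUE,
                                           scientific = FALSE), sep = "\t")),
             path)
  invisible(path)
}

## ---- best-hit taxonomy table ------------------------------------------

#' Parse semicolon-separated, rank-prefixed lineage strings
#'
#' Accepts strings such as
#' `"k__Bacteria;p__Firmicutes;...;s__F. prausnitzii;t__"`.  Missing
#' deeper ranks may be empty or absent.
#'
#' @param lineage Character vector of lineage strings.
#' @return Character matrix with one column per rank in [LINEAGE_RANKS]
#'   (empty string = unnamed at that rank).
#' @export
parse_lineage <- function(lineage) {
  out <- matrix("", nrow = length(lineage), ncol = length(LINEAGE_RANKS),
                dimnames = list(NULL, names(LINEAGE_RANKS)))
  fields <- strsplit(lineage, ";", fixed = TRUE)
  prefixes <- paste0(LINEAGE_RANKS, "__")
  for (i in seq_along(fields)) {
    for (f in fields[[i]]) {
      f <- trimws(f)
      hit <- which(startsWith(f, prefixes))
      if (length(hit) == 1L)
        out[i, hit] <- substring(f, 4L)
    }
  }
  out
}

#' Build a lineage string from rank names
#'
#' @param ranks Named character vector or list (names from
#'   [LINEAGE_RANKS]); omitted ranks are written empty.
#' @return A single semicolon-separated lineage string.
#' @export
make_lineage <- function(ranks) {
  vals <- stats::setNames(rep("", length(LINEAGE_RANKS)), names(LINEAGE_RANKS))
  ranks <- unlist(ranks)
  bad <- setdiff(names(ranks), names(LINEAGE_RANKS))
  if (length(bad) > 0) .stopf("unknown rank(s): %s", paste(bad, collapse = ", "))
  vals[names(ranks)] <- ranks
  paste0(LINEAGE_RANKS, "__", vals, collapse = ";")
}

#' Read a per-gene best-hit taxonomy table
#'
#' Columns: `gene_id`, `lineage` (rank-prefixed, semicolon-separated),
#' `pct_identity`, `pct_overlap` (percent of the query covered by the
#' alignment).  One row per gene (best hit only).
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with the four columns plus parsed per-rank name
#'   columns.
#' @export
read_gene_hits <- function(path) {
  tab <- .read_tsv(path)
  need <- c("gene_id", "lineage", "pct_identity", "pct_overlap")
  if (!all(need %in% colnames(tab)))
    .stopf("gene hit table needs columns %s", paste(need, collapse = ", "))
  out <- data.frame(gene_id = tab$gene_id, lineage = tab$lineage,
                    pct_identity = suppressWarnings(as.numeric(tab$pct_identity)),
                    pct_overlap = suppressWarnings(as.numeric(tab$pct_overlap)),
                    stringsAsFactors = FALSE)
  validate_gene_hits(out)
}

#' Validate a best-hit table
#' @param hits `data.frame` with columns `gene_id`, `lineage`,
#'   `pct_identity`, `pct_overlap`.
#' @return The table with per-rank name columns appended.
#' @export
validate_gene_hits <- function(hits) {
  .check_unique(hits$gene_id, "gene ids", "hit table")
  for (col in c("pct_identity", "pct_overlap")) {
    v <- hits[[col]]
    if (anyNA(v) || any(v < 0 | v > 100))
      .stopf("%s must lie in [0, 100]", col)
  }
  ranks <- parse_lineage(hits$lineage)
  cbind(hits[c("gene_id", "lineage", "pct_identity", "pct_overlap")],
        as.data.frame(ranks, stringsAsFactors = FALSE))
}

#' Write a best-hit table to TSV
#' @param hits Hit table (extra parsed columns are dropped).
#' @param path Output path.
#' @export
write_gene_hits <- function(hits, path) {
  writeLines(c("gene_id\tlineage\tpct_identity\tpct_overlap",
               paste(hits$gene_id, hits$lineage,
                     .fmt_num(hits$pct_identity), .fmt_num(hits$pct_overlap),
                     sep = "\t")), path)
  invisible(path)
}

## ---- annotation maps --------------------------------------------------

#' Read a gene-to-feature annotation map
#'
#' Columns: `gene_id`, `feature_ids` (comma-separated KO/OG identifiers;
#' a gene may carry zero, one, or several).  Genes with an empty feature
#' field are kept with zero annotations.
#'
#' @param path Path to the TSV file.
#' @return Named list mapping gene id to a character vector of feature
#'   ids.
#' @export
read_annotation_map <- function(path) {
  tab <- .read_tsv(path)
  if (ncol(tab) < 2L) .stopf("annotation table needs gene_id, feature_ids")
  .check_unique(tab[[1L]], "gene ids", path)
  feats <- strsplit(tab[[2L]], ",", fixed = TRUE)
  feats <- lapply(feats, function(f) f[nzchar(trimws(f))])
  stats::setNames(feats, tab[[1L]])
}

#' Write a gene-to-feature annotation map to TSV
#' @param ann Named list (gene id -> character vector of feature ids).
#' @param path Output path.
#' @export
write_annotation_map <- function(ann, path) {
  writeLines(c("gene_id\tfeature_ids",
               paste(names(ann), vapply(ann, paste, "", collapse = ","),
                     sep = "\t")), path)
  invisible(path)
}

#' Read KO module definitions
#'
#' Columns: `module_id`, `ko_ids` (comma-separated).  Modules must be
#' non-empty.
#'
#' @param path Path to the TSV file.
#' @return Named list mapping module id to a character vector of KO ids.
#' @export
read_module_map <- function(path) {
  mods <- read_annotation_map(path)
  empty <- names(mods)[lengths(mods) == 0L]
  if (length(empty) > 0)
    .stopf("empty module definition(s): %s",
           paste(utils::head(empty, 5), collapse = ", "))
  mods
}

## ---- nutrient table ---------------------------------------------------

#' Read a nutrient-by-sample table
#'
#' Rows are nutrients (e.g. protein, K, Zn, Fe, VB1, Se, Mg), columns are
#' samples; `NA` cells mark missing questionnaire values and are excluded
#' pairwise from downstream correlations.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix (nutrients x samples), possibly with `NA`s.
#' @export
read_nutrient_table <- function(path) {
  tab <- .read_tsv(path)
  vals <- .parse_matrix_body(tab, path, allow_na = TRUE)
  .check_unique(rownames(vals), "nutrient ids", path)
  vals
}

#' Write a nutrient table to TSV
#' @param nutrients Numeric matrix (nutrients x samples).
#' @param path Output path.
#' @export
write_nutrient_table <- function(nutrients, path) {
  .write_matrix(nutrients, path, "nutrient_id")
}

## ---- MGS co-occurrence network ----------------------------------------

#' Construct an MGS co-occurrence network object
#'
#' An undirected network whose nodes are MGS (annotated with mean
#' relative abundance and the taxonomic order used for colouring) and
#' whose edges carry the Spearman correlation of the MGS abundance
#' profiles; every edge correlation exceeds `rho_min` strictly.
#'
#' @param nodes `data.frame` with columns `mgs_id`, `mean_abundance`,
#'   `taxon_order`.
#' @param edges `data.frame` with columns `from`, `to`, `rho`.
#' @param rho_min Strict lower bound satisfied by all edges.
#' @return An object of class `mgs_network`.
#' @export
mgs_network <- function(nodes, edges, rho_min = 0.6) {
  stopifnot(all(c("mgs_id", "mean_abundance", "taxon_order") %in% names(nodes)))
  if (is.null(edges) || nrow(edges) == 0L)
    edges <- data.frame(from = character(), to = character(),
                        rho = numeric(), stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "rho") %in% names(edges)))
  .check_unique(nodes$mgs_id, "MGS ids", "network nodes")
  if (any(edges$from == edges$to)) .stopf("self-edges are not allowed")
  if (!all(c(edges$from, edges$to) %in% nodes$mgs_id))
    .stopf("edge endpoint not among network nodes")
  if (any(edges$rho <= rho_min))
    .stopf("edge rho must exceed %g strictly", rho_min)
  key <- ifelse(edges$from < edges$to, paste(edges$from, edges$to),
                paste(edges$to, edges$from))
  if (anyDuplicated(key)) .stopf("duplicate undirected edge")
  structure(list(nodes = nodes, edges = edges, rho_min = rho_min),
            class = "mgs_network")
}

#' @export
print.mgs_network <- function(x, ...) {
  cat(sprintf("MGS co-occurrence network: %d nodes, %d edges (rho > %g)\n",
              nrow(x$nodes), nrow(x$edges), x$rho_min))
  invisible(x)
}

#' Convert an MGS network to an igraph graph
#' @param net An `mgs_network`.
#' @return An undirected `igraph` graph with node attributes
#'   `mean_abundance`, `taxon_order` and edge attributes `rho`, `weight`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "mgs_network"))
  g <- igraph::graph_from_data_frame(
    net$edges[c("from", "to", "rho")], directed = FALSE,
    vertices = data.frame(name = net$nodes$mgs_id,
                          mean_abundance = net$nodes$mean_abundance,
                          taxon_order = net$nodes$taxon_order,
                          stringsAsFactors = FALSE))
  if (igraph::ecount(g) > 0)
    igraph::E(g)$weight <- igraph::E(g)$rho
  g
}

#' Write an MGS network to GraphML or a TSV edge list
#'
#' The edge list has a header line and one `source`, `target`, `rho`
#' (6 decimal places) row per edge; GraphML output is importable by
#' standard graph readers (e.g. Cytoscape, igraph).
#'
#' @param net An `mgs_network`.
#' @param path Output path.
#' @param format `"graphml"` or `"edgelist"`.
#' @export
write_network <- function(net, path, format = c("graphml", "edgelist")) {
  stopifnot(inherits(net, "mgs_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    writeLines(c("source\ttarget\trho",
                 if (nrow(net$edges) > 0)
                   paste(net$edges$from, net$edges$to,
                         sprintf("%.6f", net$edges$rho), sep = "\t")),
               path)
  }
  invisible(path)
}
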