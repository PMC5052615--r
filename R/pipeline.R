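## End-to-end pipeline: simulate (or load) -> profile -> differential ->
## MGS (cluster, taxonomy, network) -> KO reporter -> community ->
## diet associations, with a manifest and deterministic outputs.

.write_df <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Default pipeline configuration
#'
#' Thresholds default to the classical settings of the MGS workflow:
#' clustering at `rho > 0.8`, MGS with more than 25 genes, 25 tracer
#' genes, differential genes at `q < 0.001`, network edges at
#' `rho > 0.6`, module enrichment at reporter score `> 1.6`.
#'
#' @param seed Global seed (mandatory); stage seeds are derived from it.
#' @param sim Named list of overrides for [simulation_config()] (used
#'   when no `inputs` are supplied).
#' @param inputs Optional named list of file paths (`counts`, `genes`,
#'   `labels`, `hits`, `gene2ko`, `modules`, `nutrients`) to run on real
#'   data instead of a simulation.
#' @param q_threshold,rho_cluster,min_size,tracer_k,rho_network,
#'   reporter_threshold,n_background Stage parameters.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, sim = list(), inputs = NULL,
                            q_threshold = 0.001, rho_cluster = 0.8,
                            min_size = 25L, tracer_k = 25L,
                            rho_network = 0.6, reporter_threshold = 1.6,
                            n_background = 1000L) {
  if (missing(seed) || is.null(seed)) .stopf("seed is mandatory")
  structure(list(seed = as.integer(seed), sim = sim, inputs = inputs,
                 q_threshold = q_threshold, rho_cluster = rho_cluster,
                 min_size = as.integer(min_size),
                 tracer_k = as.integer(tracer_k),
                 rho_network = rho_network,
                 reporter_threshold = reporter_threshold,
                 n_background = as.integer(n_background)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

.load_inputs <- function(paths) {
  need <- c("counts", "genes", "labels")
  missing <- setdiff(need, names(paths))
  if (length(missing) > 0)
    .stopf("missing required input(s): %s", paste(missing, collapse = ", "))
  absent <- unlist(paths)[!file.exists(unlist(paths))]
  if (length(absent) > 0)
    .stopf("input file(s) not found: %s", paste(absent, collapse = ", "))
  out <- list(counts = read_count_matrix(paths$counts),
              genes = read_gene_table(paths$genes),
              labels = read_cohort_labels(paths$labels))
  if (!is.null(paths$hits)) out$hits <- read_gene_hits(paths$hits)
  if (!is.null(paths$gene2ko) && !is.null(paths$modules))
    out$annotations <- list(gene2ko = read_annotation_map(paths$gene2ko),
                            modules = read_module_map(paths$modules))
  if (!is.null(paths$nutrients))
    out$nutrients <- read_nutrient_table(paths$nutrients)
  out$truth <- NULL
  out
}

#' Run the full comparative-metagenomics pipeline
#'
#' Executes every stage in dependency order, writes each stage's output
#' as TSV (plus GraphML for the network) into `out_dir`, and records all
#' parameters and derived seeds in `manifest.yaml`.  A rerun with the
#' same configuration reproduces every output byte for byte.
#'
#' @param config A `pipeline_config`, or the path to a YAML file.
#' @param out_dir Output run directory (created if needed).
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name) message(sprintf("[%6.1fs] %s",
                                          proc.time()[["elapsed"]] - t0, name))
  warn_counts <- list()

  ## -- data ------------------------------------------------------------
  stage("data")
  if (is.null(config$inputs)) {
    sim_cfg <- do.call(simulation_config,
                       c(config$sim, list(seed = config$seed)))
    data <- simulate_dataset(sim_cfg)
    write_dataset(data, file.path(out_dir, "data"))
  } else {
    data <- .load_inputs(config$inputs)
  }
  labels <- data$labels
  groups <- sort(unique(unname(labels)))

  ## -- profiling -------------------------------------------------------
  stage("profile")
  abund <- gene_relative_abundance(data$counts, data$genes)
  write_abundance_matrix(abund, file.path(out_dir, "gene_abundance.tsv"))

  ## -- differential genes ----------------------------------------------
  stage("differential")
  diff <- withCallingHandlers(
    differential_features(abund, labels, q_threshold = config$q_threshold),
    message = function(m) invokeRestart("muffleMessage"))
  warn_counts$dropped_features <- attr(diff, "n_dropped")
  .write_df(diff, file.path(out_dir, "diff.tsv"))
  sig_genes <- diff$feature_id[diff$significant]

  ## -- MGS -------------------------------------------------------------
  stage("mgs")
  mgs_res <- NULL
  net <- NULL
  if (length(sig_genes) >= 2L) {
    mgs_res <- mgs_cluster(abund, sig_genes,
                           rho_cluster = config$rho_cluster,
                           min_size = config$min_size,
                           tracer_k = config$tracer_k,
                           hits = data$hits, labels = labels)
    bins <- mgs_res$mgs
    mgs_dir <- file.path(out_dir, "mgs")
    dir.create(mgs_dir, showWarnings = FALSE)
    .write_df(data.frame(
      mgs_id = rep(vapply(bins, `[[`, "", "mgs_id"),
                   vapply(bins, function(b) length(b$gene_ids), 0L)),
      gene_id = unlist(lapply(bins, `[[`, "gene_ids"), use.names = FALSE)),
      file.path(mgs_dir, "membership.tsv"))
    .write_df(data.frame(
      mgs_id = rep(vapply(bins, `[[`, "", "mgs_id"),
                   vapply(bins, function(b) length(b$tracer_gene_ids), 0L)),
      gene_id = unlist(lapply(bins, `[[`, "tracer_gene_ids"),
                       use.names = FALSE)),
      file.path(mgs_dir, "tracers.tsv"))
    .write_df(data.frame(
      mgs_id = vapply(bins, `[[`, "", "mgs_id"),
      n_genes = vapply(bins, function(b) length(b$gene_ids), 0L),
      taxon = vapply(bins, `[[`, "", "taxon"),
      taxon_rank = vapply(bins, function(b)
        if (is.na(b$taxon_rank)) "NA" else b$taxon_rank, ""),
      enriched_in = vapply(bins, function(b)
        if (is.na(b$enriched_in)) "NA" else b$enriched_in, "")),
      file.path(mgs_dir, "taxonomy.tsv"))
    .write_df(mgs_res$small, file.path(mgs_dir, "small_clusters.tsv"))
    if (nrow(mgs_res$profiles) > 0)
      write_abundance_matrix(mgs_res$profiles,
                             file.path(mgs_dir, "profiles.tsv"))
    tracer_genes <- unlist(lapply(bins, `[[`, "tracer_gene_ids"),
                           use.names = FALSE)
    if (length(tracer_genes) > 0)
      write_abundance_matrix(abund[tracer_genes, , drop = FALSE],
                             file.path(mgs_dir, "tracer_matrix.tsv"))
    warn_counts$unassigned_mgs <-
      sum(vapply(bins, `[[`, "", "taxon") == "unassigned")
    if (nrow(mgs_res$profiles) >= 2L) {
      net <- build_network(mgs_res$profiles, mgs_bins = bins,
                           hits = data$hits, rho_min = config$rho_network)
      write_network(net, file.path(out_dir, "network.graphml"), "graphml")
      write_network(net, file.path(out_dir, "network_edges.tsv"), "edgelist")
    }
  } else {
    message("mgs: fewer than 2 significant genes, stage skipped")
  }

  ## -- KO aggregation and reporter scores ------------------------------
  reporter <- NULL
  ko_abund <- NULL
  if (!is.null(data$annotations)) {
    stage("reporter")
    ko_abund <- aggregate_by_annotation(abund, data$annotations$gene2ko)
    write_abundance_matrix(ko_abund, file.path(out_dir, "ko_abundance.tsv"))
    koz <- suppressWarnings(
      ko_zscores(ko_abund, labels, focal_group = groups[1L]))
    .write_df(koz, file.path(out_dir, "ko_zscores.tsv"))
    reporter <- withCallingHandlers(
      reporter_scores(koz, data$annotations$modules,
                      n_background = config$n_background,
                      threshold = config$reporter_threshold,
                      focal_group = groups[1L], other_group = groups[2L],
                      seed = config$seed + 1000L),
      message = function(m) invokeRestart("muffleMessage"))
    warn_counts$skipped_modules <- length(attr(reporter, "skipped"))
    .write_df(reporter, file.path(out_dir, "reporter.tsv"))
  }

  ## -- community -------------------------------------------------------
  stage("community")
  species_abund <- if (!is.null(data$hits))
    aggregate_by_taxon(abund, data$hits, rank = "species") else abund
  if (!is.null(data$hits))
    write_abundance_matrix(species_abund,
                           file.path(out_dir, "species_abundance.tsv"))
  div <- data.frame(sample_id = colnames(species_abund),
                    group = unname(labels[colnames(species_abund)]),
                    shannon = shannon_index(species_abund),
                    gene_richness = richness(abund))
  .write_df(div, file.path(out_dir, "diversity.tsv"))
  bc <- bray_curtis(species_abund)
  ord <- pcoa(bc, n_axes = 2L)
  .write_df(cbind(data.frame(sample_id = rownames(ord$coordinates)),
                  as.data.frame(ord$coordinates)),
            file.path(out_dir, "pcoa_coords.tsv"))
  .write_df(data.frame(axis = seq_along(ord$eigenvalues),
                       eigenvalue = ord$eigenvalues),
            file.path(out_dir, "pcoa_eig.tsv"))

  ## -- diet associations -----------------------------------------------
  diet <- NULL
  if (!is.null(data$nutrients) && !is.null(mgs_res) &&
      nrow(mgs_res$profiles) > 0) {
    stage("diet")
    diet <- diet_correlation(mgs_res$profiles, data$nutrients)
    .write_df(diet, file.path(out_dir, "diet_correlation.tsv"))
  }

  ## -- recovery against planted truth ----------------------------------
  recovery <- NULL
  if (!is.null(data$truth) && !is.null(mgs_res)) {
    stage("recovery")
    recovery <- truth_recovery_report(data$truth, mgs_res$mgs,
                                      diff_result = diff,
                                      reporter_result = reporter)
    .write_df(recovery$summary, file.path(out_dir, "recovery.tsv"))
  }

  ## -- manifest ---------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.yaml"))
  manifest <- list(
    pipeline = "metamgs::run_pipeline",
    seed = config$seed,
    derived_seeds = list(simulation = config$seed,
                         reporter_background = config$seed + 1000L),
    parameters = list(q_threshold = config$q_threshold,
                      rho_cluster = config$rho_cluster,
                      min_size = config$min_size,
                      tracer_k = config$tracer_k,
                      rho_network = config$rho_network,
                      reporter_threshold = config$reporter_threshold,
                      n_background = config$n_background),
    n_significant_genes = length(sig_genes),
    n_mgs = if (is.null(mgs_res)) 0L else length(mgs_res$mgs),
    warnings = warn_counts,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  stage("done")

  invisible(list(config = config, data = data, abundance = abund,
                 differential = diff, mgs = mgs_res, network = net,
                 ko_abundance = ko_abund, reporter = reporter,
                 diversity = div, bray_curtis = bc, pcoa = ord,
                 diet = diet, recovery = recovery))
}
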