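## Seeded two-cohort synthetic metagenome generator with planted ground
## truth, plus the recovery report used to benchmark the pipeline.
##
## The generator emulates the statistical structure the downstream
## methods assume: genes of one species are strongly rank-correlated
## across samples (log-normal species trajectories with multiplicative
## log-normal gene noise), some species differ in abundance between the
## two cohorts, KOs of "shifted" modules ride on those differential
## species, and selected nutrients are rank-coupled to species profiles
## through a Gaussian copula.

#' Build a simulation configuration
#'
#' All sizes, effects and rates of the synthetic two-cohort dataset.
#' Defaults describe the benchmark conditions used throughout the test
#' suite: 20 species of 100 genes each, 30 + 30 samples, gene-level
#' log-noise 0.3, four species shifted by +/- 2 log2 units, two enriched
#' KO modules and two diet-coupled nutrients.
#'
#' @param n_species Number of species.
#' @param genes_per_species Genes per species (single integer or one
#'   value per species).
#' @param n_samples_per_group Integer pair, samples in groups "A" and
#'   "B".
#' @param gene_noise_sigma Standard deviation of the multiplicative
#'   log-normal gene noise (log scale).
#' @param species_lognormal_mu_sigma Pair (mu, sigma): species mean
#'   log-levels are drawn `N(mu, sigma)` once per species.
#' @param sample_sigma Between-sample standard deviation of each
#'   species' log abundance (log scale).
#' @param gene_factor_sigma Log-sd of the fixed per-gene factor (a
#'   copy-number/mappability surrogate drawn once per gene).
#' @param depth Read pairs sequenced per sample (multinomial size).
#' @param differential_species `data.frame(species, group, log2_effect)`:
#'   species multiplied by `2^log2_effect` in the target group.
#' @param enriched_modules `data.frame(module, group, shift)`: modules
#'   whose KOs are attached to genes of differential species of the
#'   matching group, so the module inherits a coherent abundance shift.
#' @param diet_correlated `data.frame(species, nutrient, rho)`: target
#'   Spearman correlations planted between nutrient intake and species
#'   abundance.
#' @param contamination_rate Fraction of genes whose best hit carries a
#'   wrong (other-species) lineage.
#' @param n_kos,n_modules,kos_per_module,genes_per_ko KO universe and
#'   module layout; modules are disjoint KO blocks.
#' @param nutrient_ids Nutrient variables to emit.
#' @param seed Mandatory integer seed; the generator is fully
#'   deterministic given the config.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 20L,
                              genes_per_species = 100L,
                              n_samples_per_group = c(30L, 30L),
                              gene_noise_sigma = 0.3,
                              species_lognormal_mu_sigma = c(0, 0.4),
                              sample_sigma = 0.7,
                              gene_factor_sigma = 0.5,
                              depth = 200000L,
                              differential_species = NULL,
                              enriched_modules = NULL,
                              diet_correlated = NULL,
                              contamination_rate = 0.02,
                              n_kos = 300L,
                              n_modules = 20L,
                              kos_per_module = 8L,
                              genes_per_ko = 5L,
                              nutrient_ids = c("protein", "K", "Zn", "Fe",
                                               "VB1", "Se", "Mg"),
                              seed) {
  if (missing(seed) || is.null(seed)) .stopf("seed is mandatory")
  if (n_species < 1L || any(genes_per_species < 1L) ||
      any(n_samples_per_group < 1L) || depth < 1L)
    .stopf("all counts must be >= 1")
  if (gene_noise_sigma < 0 || sample_sigma < 0)
    .stopf("noise sigmas must be >= 0")
  if (contamination_rate < 0 || contamination_rate > 1)
    .stopf("contamination_rate must lie in [0, 1]")
  if (n_kos < n_modules * kos_per_module)
    .stopf("KO universe smaller than the module layout")
  sp_ids <- sprintf("sp%03d", seq_len(n_species))
  if (is.null(differential_species))
    differential_species <- data.frame(
      species = sp_ids[seq_len(min(4L, n_species))],
      group = rep(c("A", "B"), length.out = min(4L, n_species)),
      log2_effect = 2,
      stringsAsFactors = FALSE)
  if (is.null(enriched_modules)) {
    grp <- unique(differential_species$group)
    grp <- grp[seq_len(min(2L, length(grp)))]
    enriched_modules <- data.frame(
      module = sprintf("M%04d", seq_along(grp)),
      group = grp,
      shift = 2,
      stringsAsFactors = FALSE)
  }
  if (is.null(diet_correlated))
    diet_correlated <- data.frame(
      species = differential_species$species[
        seq_len(min(2L, nrow(differential_species)))],
      nutrient = nutrient_ids[c(1L, min(6L, length(nutrient_ids)))],
      rho = 0.6,
      stringsAsFactors = FALSE)
  if (any(abs(diet_correlated$rho) > 1))
    .stopf("infeasible target rho (|rho| > 1)")
  if (!all(is.finite(differential_species$log2_effect)))
    .stopf("effects must be finite")
  if (!all(differential_species$species %in% sp_ids))
    .stopf("differential species not in the species set")
  structure(list(
    n_species = as.integer(n_species),
    genes_per_species = rep(as.integer(genes_per_species),
                            length.out = n_species),
    n_samples_per_group = as.integer(n_samples_per_group[1:2]),
    gene_noise_sigma = gene_noise_sigma,
    species_lognormal_mu_sigma = species_lognormal_mu_sigma,
    sample_sigma = sample_sigma,
    gene_factor_sigma = gene_factor_sigma,
    depth = as.integer(depth),
    differential_species = differential_species,
    enriched_modules = enriched_modules,
    diet_correlated = diet_correlated,
    contamination_rate = contamination_rate,
    n_kos = as.integer(n_kos),
    n_modules = as.integer(n_modules),
    kos_per_module = as.integer(kos_per_module),
    genes_per_ko = as.integer(genes_per_ko),
    nutrient_ids = nutrient_ids,
    seed = as.integer(seed)), class = "simulation_config")
}

#' Simulate a two-cohort gene-level metagenome with planted truth
#'
#' See [simulation_config()] for the generative model.  Per sample,
#' mapped read-pair counts are drawn `Multinomial(depth, p)` with
#' `p proportional to` gene abundance x gene length, so column sums equal the
#' configured depth exactly and length normalisation is genuinely
#' exercised downstream.
#'
#' @param cfg A `simulation_config`.
#' @return List with elements `counts` (gene x sample count matrix),
#'   `latent_abundance` (the noise-free-of-sequencing relative gene
#'   abundances underlying the counts), `genes` (gene length table),
#'   `labels` (cohort labels), `hits`
#'   (best-hit taxonomy table), `annotations` (list with `gene2ko` and
#'   `modules`), `nutrients` (nutrient x sample matrix), `truth`
#'   (planted ground truth) and `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  S <- cfg$n_species
  gps <- cfg$genes_per_species
  G <- sum(gps)
  n_a <- cfg$n_samples_per_group[1L]; n_b <- cfg$n_samples_per_group[2L]
  N <- n_a + n_b
  sp_ids <- sprintf("sp%03d", seq_len(S))
  gene_ids <- sprintf("g%05d", seq_len(G))
  gene_species <- rep(sp_ids, gps)
  sample_ids <- sprintf("s%03d", seq_len(N))
  labels <- stats::setNames(rep(c("A", "B"), c(n_a, n_b)), sample_ids)

  ## species log-abundance trajectories
  mu_sp <- stats::rnorm(S, cfg$species_lognormal_mu_sigma[1L],
                        cfg$species_lognormal_mu_sigma[2L])
  log_a <- matrix(stats::rnorm(S * N, 0, cfg$sample_sigma), S, N,
                  dimnames = list(sp_ids, sample_ids)) + mu_sp
  for (i in seq_len(nrow(cfg$differential_species))) {
    row <- cfg$differential_species[i, ]
    log_a[row$species, labels == row$group] <-
      log_a[row$species, labels == row$group] + row$log2_effect * log(2)
  }
  species_abund <- exp(log_a)

  ## gene-level abundance: species trajectory x fixed factor x noise
  gene_factor <- exp(stats::rnorm(G, 0, cfg$gene_factor_sigma))
  noise <- if (cfg$gene_noise_sigma > 0)
    matrix(exp(stats::rnorm(G * N, 0, cfg$gene_noise_sigma)), G, N)
  else matrix(1, G, N)
  gene_abund <- species_abund[gene_species, , drop = FALSE] *
    gene_factor * noise
  dimnames(gene_abund) <- list(gene_ids, sample_ids)

  ## lengths and multinomial read-pair counts (prob ~ abundance x length)
  lengths_bp <- sample(100:1500, G, replace = TRUE)
  counts <- matrix(0L, G, N, dimnames = list(gene_ids, sample_ids))
  wt <- gene_abund * lengths_bp
  for (j in seq_len(N))
    counts[, j] <- stats::rmultinom(1L, cfg$depth, wt[, j])[, 1L]

  ## best-hit taxonomy: species lineage, with a contaminated fraction
  orders <- sprintf("Order%02d", ((seq_len(S) - 1L) %% 6L) + 1L)
  lineages <- vapply(seq_len(S), function(i) make_lineage(c(
    superkingdom = "Bacteria",
    phylum = sprintf("Phylum%02d", ((i - 1L) %% 4L) + 1L),
    class = sprintf("Class%02d", ((i - 1L) %% 5L) + 1L),
    order = orders[i],
    family = sprintf("Family%02d", i),
    genus = sprintf("Genus%02d", i),
    species = sprintf("Species%02d", i),
    strain = sprintf("Strain%02d", i))), "")
  names(lineages) <- sp_ids
  hit_species <- gene_species
  n_contam <- floor(cfg$contamination_rate * G)
  if (n_contam > 0 && S > 1L) {
    contam <- sample.int(G, n_contam)
    hit_species[contam] <- vapply(gene_species[contam], function(sp)
      sample(setdiff(sp_ids, sp), 1L), "")
  }
  hits <- validate_gene_hits(data.frame(
    gene_id = gene_ids,
    lineage = unname(lineages[hit_species]),
    pct_identity = stats::runif(G, 96, 100),
    pct_overlap = stats::runif(G, 91, 100),
    stringsAsFactors = FALSE))

  ## KO universe, module layout, gene assignment
  ko_ids <- sprintf("K%05d", seq_len(cfg$n_kos))
  modules <- lapply(seq_len(cfg$n_modules), function(m)
    ko_ids[(m - 1L) * cfg$kos_per_module + seq_len(cfg$kos_per_module)])
  names(modules) <- sprintf("M%04d", seq_len(cfg$n_modules))
  host_genes <- function(group) {
    sp <- cfg$differential_species$species[
      cfg$differential_species$group == group]
    gene_ids[gene_species %in% sp]
  }
  ko2genes <- vector("list", cfg$n_kos)
  names(ko2genes) <- ko_ids
  enriched_kos <- character()
  for (i in seq_len(nrow(cfg$enriched_modules))) {
    row <- cfg$enriched_modules[i, ]
    if (!row$module %in% names(modules))
      .stopf("enriched module %s not in the module layout", row$module)
    pool <- host_genes(row$group)
    if (length(pool) == 0L)
      .stopf("no differential species in group %s to host module %s",
             row$group, row$module)
    for (ko in modules[[row$module]])
      ko2genes[[ko]] <- sample(pool, min(cfg$genes_per_ko, length(pool)))
    enriched_kos <- c(enriched_kos, modules[[row$module]])
  }
  for (ko in setdiff(ko_ids, enriched_kos))
    ko2genes[[ko]] <- sample(gene_ids, sample(3:max(3L, cfg$genes_per_ko), 1L))
  gene2ko <- stats::setNames(vector("list", G), gene_ids)
  for (ko in ko_ids)
    for (g in ko2genes[[ko]])
      gene2ko[[g]] <- c(gene2ko[[g]], ko)
  gene2ko <- lapply(gene2ko, function(x) if (is.null(x)) character() else x)

  ## nutrients: Gaussian copula on species ranks at the target Spearman
  nutrients <- matrix(stats::rnorm(length(cfg$nutrient_ids) * N, 50, 10),
                      length(cfg$nutrient_ids), N,
                      dimnames = list(cfg$nutrient_ids, sample_ids))
  for (i in seq_len(nrow(cfg$diet_correlated))) {
    row <- cfg$diet_correlated[i, ]
    if (!row$nutrient %in% cfg$nutrient_ids)
      .stopf("unknown nutrient %s", row$nutrient)
    ## Pearson r on normal scores giving Spearman rho for a Gaussian
    ## copula; couple to the species' RELATIVE abundance, the quantity
    ## the downstream analysis actually observes
    r <- 2 * sin(pi * row$rho / 6)
    rel_sp <- species_abund[row$species, ] / colSums(species_abund)
    z1 <- stats::qnorm((rank(rel_sp) - 0.5) / N)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(N)
    nutrients[row$nutrient, ] <- 50 + 10 * z2
  }

  truth <- list(
    species_genes = split(gene_ids, gene_species)[sp_ids],
    differential_species = cfg$differential_species,
    enriched_modules = cfg$enriched_modules,
    diet_correlated = cfg$diet_correlated,
    lineages = lineages)

  list(counts = counts,
       latent_abundance = sweep(gene_abund, 2L, colSums(gene_abund), "/"),
       genes = data.frame(gene_id = gene_ids, length_bp = lengths_bp,
                          stringsAsFactors = FALSE),
       labels = labels,
       hits = hits,
       annotations = list(gene2ko = gene2ko, modules = modules),
       nutrients = nutrients,
       truth = truth,
       config = cfg)
}

#' Write a simulated dataset to a run directory
#'
#' Emits all seven tables as TSV plus a `manifest.yaml` recording the
#' configuration (including the seed).
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(sim$counts, file.path(dir, "counts.tsv"))
  write_gene_table(sim$genes, file.path(dir, "genes.tsv"))
  write_cohort_labels(sim$labels, file.path(dir, "labels.tsv"))
  write_gene_hits(sim$hits, file.path(dir, "hits.tsv"))
  write_annotation_map(sim$annotations$gene2ko, file.path(dir, "gene2ko.tsv"))
  write_annotation_map(sim$annotations$modules, file.path(dir, "modules.tsv"))
  write_nutrient_table(sim$nutrients, file.path(dir, "nutrients.tsv"))
  truth_genes <- data.frame(
    gene_id = unlist(sim$truth$species_genes, use.names = FALSE),
    species = rep(names(sim$truth$species_genes),
                  lengths(sim$truth$species_genes)))
  utils::write.table(truth_genes, file.path(dir, "truth_species_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  cfg_list <- unclass(cfg)
  cfg_list$differential_species <- as.list(cfg$differential_species)
  cfg_list$enriched_modules <- as.list(cfg$enriched_modules)
  cfg_list$diet_correlated <- as.list(cfg$diet_correlated)
  yaml::write_yaml(list(generator = "metamgs::simulate_dataset",
                        seed = cfg$seed, config = cfg_list),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Adjusted Rand index between two labelings
#'
#' @param x,y Two partitions of the same objects (vectors of cluster
#'   labels, equal length).
#' @return The Hubert-Arabie adjusted Rand index.
#' @export
adjusted_rand_index <- function(x, y) {
  if (length(x) != length(y)) .stopf("partitions must have equal length")
  mclust::adjustedRandIndex(x, y)
}

#' Recovery report against planted ground truth
#'
#' Scores pipeline outputs against the `truth` record of a simulated
#' dataset: adjusted Rand index between the planted species partition
#' and the recovered MGS partition (restricted to clustered genes),
#' per-species enrichment direction accuracy, and module-enrichment
#' precision/recall.
#'
#' @param truth The `truth` element of [simulate_dataset()].
#' @param mgs_bins List of MGS bins (see [mgs_cluster()]), each with
#'   `gene_ids`, `enriched_in`.
#' @param diff_result Differential table from [differential_features()]
#'   (gene level), or `NULL`.
#' @param reporter_result Reporter table from [reporter_scores()], or
#'   `NULL`.
#' @return List with `ari`, `species` (per planted differential species:
#'   recovered flag and direction correctness), `modules`
#'   (precision/recall) and `summary` (long-format metric table).
#' @export
truth_recovery_report <- function(truth, mgs_bins, diff_result = NULL,
                                  reporter_result = NULL) {
  gene_species <- stats::setNames(
    rep(names(truth$species_genes), lengths(truth$species_genes)),
    unlist(truth$species_genes, use.names = FALSE))
  clustered <- unlist(lapply(mgs_bins, `[[`, "gene_ids"), use.names = FALSE)
  bin_of <- rep(vapply(mgs_bins, `[[`, "", "mgs_id"),
                vapply(mgs_bins, function(b) length(b$gene_ids), 0L))
  unknown <- setdiff(clustered, names(gene_species))
  if (length(unknown) > 0)
    .stopf("clustered gene(s) absent from truth: %s", unknown[1])
  ari <- if (length(clustered) > 0)
    adjusted_rand_index(unname(gene_species[clustered]), bin_of) else NA_real_

  species_rows <- lapply(seq_len(nrow(truth$differential_species)),
                         function(i) {
    row <- truth$differential_species[i, ]
    members <- truth$species_genes[[row$species]]
    ## MGS dominated by this species, if any
    frac <- vapply(mgs_bins, function(b)
      mean(b$gene_ids %in% members), 0)
    hit <- which(frac >= 0.5)
    recovered <- length(hit) > 0
    dir_ok <- recovered &&
      any(vapply(mgs_bins[hit], function(b)
        identical(b$enriched_in, row$group), FALSE))
    data.frame(species = row$species, group = row$group,
               recovered = recovered, direction_correct = dir_ok,
               stringsAsFactors = FALSE)
  })
  species_tab <- do.call(rbind, species_rows)

  modules_tab <- NULL
  precision <- recall <- NA_real_
  if (!is.null(reporter_result)) {
    called <- reporter_result$module_id[reporter_result$enriched]
    planted <- truth$enriched_modules$module
    precision <- if (length(called) > 0)
      mean(called %in% planted) else NA_real_
    recall <- if (length(planted) > 0) mean(planted %in% called) else NA_real_
    dir_ok <- vapply(seq_along(planted), function(i) {
      j <- match(planted[i], reporter_result$module_id)
      !is.na(j) && reporter_result$enriched[j] &&
        identical(reporter_result$direction[j],
                  truth$enriched_modules$group[i])
    }, FALSE)
    modules_tab <- data.frame(module = planted,
                              group = truth$enriched_modules$group,
                              recovered = planted %in% called,
                              direction_correct = dir_ok,
                              stringsAsFactors = FALSE)
  }

  summary <- data.frame(
    metric = c("ari", "n_mgs", "species_recovered", "species_direction_acc",
               "module_precision", "module_recall"),
    value = c(ari, length(mgs_bins), mean(species_tab$recovered),
              mean(species_tab$direction_correct), precision, recall))
  list(ari = ari, species = species_tab, modules = modules_tab,
       summary = summary)
}
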