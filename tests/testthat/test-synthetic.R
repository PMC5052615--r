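test_that("generator is deterministic under the seed", {
  s1 <- small_sim(seed = 5)
  s2 <- small_sim(seed = 5)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
  s3 <- small_sim(seed = 6)
  expect_false(identical(s1$counts, s3$counts))
})

test_that("count columns sum exactly to the configured depth", {
  sim <- small_sim(seed = 2)
  expect_true(all(colSums(sim$counts) == sim$config$depth))
  expect_true(all(sim$counts >= 0))
})

test_that("zero gene noise makes within-species genes perfectly rank-correlated", {
  cfg <- simulation_config(n_species = 4L, genes_per_species = 6L,
                           n_samples_per_group = c(8L, 8L),
                           gene_noise_sigma = 0, depth = 50000L, seed = 3)
  sim <- simulate_dataset(cfg)
  for (sp in names(sim$truth$species_genes)) {
    genes <- sim$truth$species_genes[[sp]]
    rho <- cor(t(sim$latent_abundance[genes, ]), method = "spearman")
    expect_equal(min(rho), 1)
  }
})

test_that("a +2 log2 species dominates in its target group gene by gene", {
  ## gene-level medians in the enriched group exceed the other group for
  ## >= 95% of the species' genes, across seeds
  frac <- vapply(1:20, function(seed) {
    cfg <- simulation_config(n_species = 10L, genes_per_species = 50L,
                             n_samples_per_group = c(30L, 30L),
                             gene_noise_sigma = 0.3,
                             differential_species = data.frame(
                               species = "sp001", group = "A",
                               log2_effect = 2),
                             diet_correlated = data.frame(
                               species = "sp001", nutrient = "protein",
                               rho = 0.6),
                             depth = 100000L, seed = seed)
    sim <- simulate_dataset(cfg)
    genes <- sim$truth$species_genes$sp001
    in_a <- sim$labels == "A"
    ab <- sim$latent_abundance[genes, ]
    mean(apply(ab[, in_a], 1, median) > apply(ab[, !in_a], 1, median))
  }, 0)
  expect_true(all(frac >= 0.95))
})

test_that("planted nutrient-species Spearman correlations hit their target", {
  cfg <- simulation_config(n_samples_per_group = c(60L, 60L),
                           depth = 100000L, seed = 11)
  sim <- simulate_dataset(cfg)
  for (i in seq_len(nrow(cfg$diet_correlated))) {
    row <- cfg$diet_correlated[i, ]
    sp_profile <- colSums(
      sim$latent_abundance[sim$truth$species_genes[[row$species]], ])
    obs <- cor(sp_profile, sim$nutrients[row$nutrient, ],
               method = "spearman")
    expect_lt(abs(obs - row$rho), 0.1)
  }
})

test_that("infeasible targets and bad configs are rejected", {
  expect_error(simulation_config(seed = 1, diet_correlated = data.frame(
    species = "sp001", nutrient = "protein", rho = 1.2)), "infeasible")
  expect_error(simulation_config(seed = 1, n_species = 0), ">= 1")
  expect_error(simulation_config(n_species = 5), "seed")
  expect_error(simulation_config(seed = 1, differential_species = data.frame(
    species = "sp099", group = "A", log2_effect = 2)), "not in the species")
})

test_that("contaminated best hits carry a wrong lineage at the set rate", {
  cfg <- simulation_config(n_species = 10L, genes_per_species = 50L,
                           contamination_rate = 0.1, depth = 50000L,
                           n_samples_per_group = c(5L, 5L), seed = 9)
  sim <- simulate_dataset(cfg)
  gene_sp <- rep(names(sim$truth$species_genes),
                 lengths(sim$truth$species_genes))
  true_lineage <- unname(sim$truth$lineages[gene_sp])
  expect_equal(sum(sim$hits$lineage != true_lineage), floor(0.1 * 500))
})

test_that("dataset writer emits all tables and a seeded manifest", {
  sim <- small_sim(seed = 4)
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "counts.tsv", "genes.tsv", "labels.tsv", "hits.tsv", "gene2ko.tsv",
    "modules.tsv", "nutrients.tsv", "truth_species_genes.tsv",
    "manifest.yaml")))))
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(man$seed, 4)
  expect_identical(read_count_matrix(file.path(dir, "counts.tsv")),
                   sim$counts + 0)
})

test_that("adjusted Rand index matches the contingency-table formula", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  ## one giant cluster against 10 equal planted species
  planted <- rep(1:10, each = 20)
  expect_lt(abs(adjusted_rand_index(planted, rep(1, 200))), 0.02)
  ## random partitions concentrate near zero and match the oracle
  set.seed(21)
  for (i in 1:50) {
    x <- sample(1:5, 60, replace = TRUE)
    y <- sample(1:5, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y), oracle_ari(x, y),
                 tolerance = 1e-12)
    expect_lt(abs(adjusted_rand_index(x, y)), 0.35)
  }
  aris <- vapply(1:50, function(i) {
    adjusted_rand_index(sample(rep(1:10, each = 10)), rep(1:10, each = 10))
  }, 0)
  expect_lt(mean(abs(aris)), 0.05)
})

test_that("recovery report scores a perfect and a degenerate clustering", {
  sim <- small_sim(seed = 8)
  ## perfect recovery: bins = planted species of the differential set
  bins <- lapply(seq_len(nrow(sim$truth$differential_species)), function(i) {
    sp <- sim$truth$differential_species$species[i]
    structure(list(mgs_id = sprintf("MGS%03d", i),
                   gene_ids = sim$truth$species_genes[[sp]],
                   enriched_in = sim$truth$differential_species$group[i]),
              class = "mgs_bin")
  })
  rec <- truth_recovery_report(sim$truth, bins)
  expect_equal(rec$ari, 1)
  expect_true(all(rec$species$recovered))
  expect_true(all(rec$species$direction_correct))
  ## one giant bin: ARI collapses to ~0
  giant <- list(structure(list(
    mgs_id = "MGS001",
    gene_ids = unlist(sim$truth$species_genes, use.names = FALSE),
    enriched_in = "A"), class = "mgs_bin"))
  expect_lt(abs(truth_recovery_report(sim$truth, giant)$ari), 0.02)
})
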