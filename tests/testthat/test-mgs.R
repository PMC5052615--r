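test_that("spearman_matrix matches closed forms and flags constants", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3), c = exp(c(1, 2, 3, 4)),
             k = rep(2, 4))
  colnames(x) <- sprintf("s%d", 1:4)
  expect_warning(rho <- spearman_matrix(x), "constant")
  expect_equal(rho["a", "a"], 1)
  expect_equal(rho["a", "b"], 0.6)           # 1 - 6*8/(4*15)
  expect_equal(rho["a", "c"], 1)             # monotone transform
  expect_equal(rho["a", "k"], 0)             # undefined -> 0
  expect_error(spearman_matrix(x[, 1:2]), ">= 3 samples")
  expect_error(spearman_matrix(x, c("a", "zz")), "zz")
})

test_that("threshold clustering equals connected components of the rho graph", {
  ids <- c("a", "b", "c", "d")
  rho <- diag(4)
  dimnames(rho) <- list(ids, ids)
  rho["a", "b"] <- rho["b", "a"] <- 0.9
  rho["b", "c"] <- rho["c", "b"] <- 0.85
  rho["c", "d"] <- rho["d", "c"] <- 0.5
  cl <- single_linkage_clusters(rho, threshold = 0.8)
  expect_equal(sort(lengths(cl), decreasing = TRUE), c(3L, 1L),
               ignore_attr = TRUE)
  expect_setequal(cl[[1]], c("a", "b", "c"))
  ## nothing above threshold -> all singletons
  low <- diag(4); dimnames(low) <- list(ids, ids)
  expect_length(single_linkage_clusters(low, 0.8), 4L)
})

test_that("threshold clustering equals a single-linkage dendrogram cut", {
  set.seed(31)
  for (i in 1:5) {
    x <- block_abundance(n_blocks = 4, genes_per_block = 10,
                         n_samples = 20, seed = 100 + i)
    x <- x * exp(matrix(rnorm(length(x), 0, 0.6), nrow(x)))
    rho <- suppressWarnings(spearman_matrix(x))
    cl <- single_linkage_clusters(rho, threshold = 0.8)
    memb <- setNames(rep(names(cl), lengths(cl)),
                     unlist(cl, use.names = FALSE))
    hc <- hclust(as.dist(1 - rho), method = "single")
    ## cut strictly below distance 1 - 0.8 (strict rho > 0.8)
    ref <- cutree(hc, h = 0.2 - 1e-9)
    expect_equal(adjusted_rand_index(memb[names(ref)], ref), 1)
  }
})

test_that("an artificially split species is re-fused into one MGS", {
  x <- block_abundance(n_blocks = 1, genes_per_block = 60, n_samples = 30,
                       seed = 55)
  x <- x * exp(matrix(rnorm(length(x), 0, 0.1), nrow(x)))
  part <- list(C0001 = rownames(x)[1:30], C0002 = rownames(x)[31:60])
  fused <- fuse_clusters(part, x, min_size = 25, threshold = 0.8)
  expect_length(fused$mgs, 1L)
  expect_setequal(fused$mgs[[1]]$gene_ids, rownames(x))
})

test_that("clusters of <= 25 genes are never reported as MGS", {
  x <- block_abundance(n_blocks = 2, genes_per_block = 30, n_samples = 20,
                       seed = 66)
  part <- list(C0001 = rownames(x)[1:10],    # small: never an MGS
               C0002 = rownames(x)[31:60])
  fused <- fuse_clusters(part, x, min_size = 25, threshold = 0.8)
  expect_length(fused$mgs, 1L)
  expect_equal(fused$small$cluster_id, "C0001")
  expect_equal(fused$small$size, 10L)
  ## exactly 25 genes is still too small (strict "> 25")
  part25 <- list(C0001 = rownames(x)[1:25])
  expect_length(fuse_clusters(part25, x, min_size = 25)$mgs, 0L)
})

test_that("independent species stay separate through fusion", {
  for (seed in 1:20) {
    set.seed(seed)
    base1 <- exp(rnorm(60, 0, 0.7)); base2 <- exp(rnorm(60, 0, 0.7))
    g1 <- t(replicate(30, base1 * exp(rnorm(60, 0, 0.3))))
    g2 <- t(replicate(30, base2 * exp(rnorm(60, 0, 0.3))))
    x <- rbind(g1, g2)
    dimnames(x) <- list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:60))
    part <- list(C0001 = rownames(x)[1:30], C0002 = rownames(x)[31:60])
    fused <- fuse_clusters(part, x, min_size = 25, threshold = 0.8)
    expect_length(fused$mgs, 2L)
  }
})

test_that("fusion never merges below the threshold and terminates", {
  ## three eligible clusters; a-b strongly coupled, c independent
  set.seed(77)
  base <- exp(rnorm(40))
  a <- t(replicate(30, base * exp(rnorm(40, 0, 0.05))))
  b <- t(replicate(30, base * exp(rnorm(40, 0, 0.05))))
  c_ <- t(replicate(30, exp(rnorm(40))))
  x <- rbind(a, b, c_)
  dimnames(x) <- list(sprintf("g%02d", 1:90), sprintf("s%02d", 1:40))
  part <- list(A = rownames(x)[1:30], B = rownames(x)[31:60],
               C = rownames(x)[61:90])
  fused <- fuse_clusters(part, x, min_size = 25, threshold = 0.8)
  expect_length(fused$mgs, 2L)
  sizes <- sort(vapply(fused$mgs, function(b) length(b$gene_ids), 0L))
  expect_equal(sizes, c(30L, 60L))
})

test_that("tracer selection is deterministic and order-invariant", {
  x <- block_abundance(n_blocks = 1, genes_per_block = 30, n_samples = 15,
                       seed = 88)
  x <- x * exp(matrix(rnorm(length(x), 0, 0.2), nrow(x)))
  genes <- rownames(x)
  t1 <- select_tracers(genes, x, k = 25)
  expect_length(t1, 25L)
  t2 <- select_tracers(sample(genes), x, k = 25)
  expect_identical(t1, t2)
  small <- select_tracers(genes[1:10], x, k = 25)
  expect_setequal(small, genes[1:10])
})

test_that("the MGS profile is the per-sample tracer median", {
  x <- rbind(g1 = c(0.1, 0.5), g2 = c(0.2, 0.4), g3 = c(0.6, 0.3))
  colnames(x) <- c("s1", "s2")
  expect_equal(mgs_profile(rownames(x), x), c(s1 = 0.2, s2 = 0.4))
  expect_equal(mgs_profile("g2", x), x["g2", ])
  expect_equal(mgs_profile(rownames(x), x * 3), 3 * mgs_profile(rownames(x), x))
})

test_that("consensus taxonomy walks ranks strictly from strain upward", {
  mk_hits <- function(n, lineages, identity = 99, overlap = 99) {
    data.frame(gene_id = sprintf("g%03d", seq_len(n)), lineage = lineages,
               pct_identity = identity, pct_overlap = overlap)
  }
  genes <- sprintf("g%03d", 1:100)
  ## 95/100 qualifying hits to species X -> (X, species)
  linX <- make_lineage(c(genus = "G", species = "X"))
  linY <- make_lineage(c(genus = "G", species = "Y"))
  hits <- mk_hits(100, c(rep(linX, 95), rep(linY, 5)))
  tax <- assign_taxonomy(genes, hits)
  expect_equal(tax$taxon, "X")
  expect_equal(tax$rank, "species")
  expect_equal(tax$support, 0.95)
  ## 85 X / 10 Y / 5 Z at species, all genus G -> (G, genus)
  linZ <- make_lineage(c(genus = "G", species = "Z"))
  hits2 <- mk_hits(100, c(rep(linX, 85), rep(linY, 10), rep(linZ, 5)))
  tax2 <- assign_taxonomy(genes, hits2)
  expect_equal(tax2$taxon, "G")
  expect_equal(tax2$rank, "genus")
  ## all identities below the strict 95 cutoff -> unassigned
  hits3 <- mk_hits(100, rep(linX, 100), identity = 94)
  expect_equal(assign_taxonomy(genes, hits3)$taxon, "unassigned")
  hits4 <- mk_hits(100, rep(linX, 100), identity = 95)
  expect_equal(assign_taxonomy(genes, hits4)$taxon, "unassigned")
  ## genes absent from the table count against the consensus
  tax5 <- assign_taxonomy(c(genes, sprintf("x%03d", 1:20)), hits)
  expect_equal(tax5$taxon, "unassigned")
})

test_that("the co-occurrence network uses a strict rho > 0.6 rule", {
  prof <- rbind(MGS001 = c(1, 2, 3, 4), MGS002 = c(2, 1, 4, 3),
                MGS003 = c(1.1, 2.2, 3.0, 4.4))
  colnames(prof) <- sprintf("s%d", 1:4)
  net <- build_network(prof, rho_min = 0.6)
  ## rho(1,2) = 0.6 exactly: excluded; rho(1,3) = 1: included
  key <- paste(net$edges$from, net$edges$to)
  expect_false("MGS001 MGS002" %in% key)
  expect_true("MGS001 MGS003" %in% key)
  expect_equal(net$edges$rho[net$edges$from == "MGS001" &
                               net$edges$to == "MGS003"], 1)
})

test_that("network edges equal a brute-force all-pairs scan", {
  set.seed(99)
  prof <- matrix(rlnorm(15 * 20), 15, 20,
                 dimnames = list(sprintf("MGS%03d", 1:15),
                                 sprintf("s%02d", 1:20)))
  prof[2, ] <- prof[1, ] * 2          # rho exactly 1
  prof[3, ] <- prof[1, ] + rlnorm(20, 0, 0.2)
  net <- build_network(prof, rho_min = 0.6)
  got <- sort(paste(net$edges$from, net$edges$to))
  want <- character()
  for (i in 1:14) for (j in (i + 1):15) {
    r <- oracle_spearman(prof[i, ], prof[j, ])
    if (r > 0.6) want <- c(want, paste(rownames(prof)[i], rownames(prof)[j]))
  }
  expect_identical(got, sort(want))
  for (k in seq_len(nrow(net$edges)))
    expect_equal(net$edges$rho[k],
                 oracle_spearman(prof[net$edges$from[k], ],
                                 prof[net$edges$to[k], ]))
})

test_that("mgs_cluster is invariant to gene and sample ordering", {
  sim <- small_sim(seed = 17)
  ab <- gene_relative_abundance(sim$counts, sim$genes)
  d <- suppressMessages(differential_features(ab, sim$labels))
  sig <- d$feature_id[d$significant]
  r1 <- suppressWarnings(mgs_cluster(ab, sig, labels = sim$labels))
  set.seed(1)
  perm <- ab[sample(nrow(ab)), sample(ncol(ab))]
  r2 <- suppressWarnings(mgs_cluster(perm, sample(sig), labels = sim$labels))
  m1 <- lapply(r1$mgs, `[[`, "gene_ids")
  m2 <- lapply(r2$mgs, `[[`, "gene_ids")
  expect_equal(length(m1), length(m2))
  for (i in seq_along(m1)) expect_setequal(m1[[i]], m2[[i]])
})
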