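make_ko_matrix <- function(n_ko = 40, n = 20, seed = 1) {
  set.seed(seed)
  x <- matrix(rlnorm(n_ko * n), n_ko, n,
              dimnames = list(sprintf("K%05d", seq_len(n_ko)),
                              sprintf("s%02d", seq_len(n))))
  x
}

test_that("KO z-scores invert two-sided p with the enrichment sign", {
  x <- make_ko_matrix()
  x[1, 1:10] <- x[1, 1:10] * 50      # strongly up in focal group
  labels <- setNames(rep(c("A", "B"), each = 10), colnames(x))
  z <- ko_zscores(x, labels, focal_group = "A")
  expect_gt(z$z[1], 3)
  expect_equal(z$direction[1], "A")
  ## z = qnorm(1 - p/2), signed
  expect_equal(abs(z$z), qnorm(1 - pmin(pmax(z$p_value, 1e-15),
                                        1 - 1e-15) / 2))
  ## p = 0.05 corresponds to |z| = 1.959964
  expect_equal(qnorm(1 - 0.05 / 2), 1.959964, tolerance = 1e-5)
  ## p = 1 (flat KO) gives z = 0
  flat <- x
  flat[2, ] <- 1
  zf <- suppressWarnings(ko_zscores(flat, labels, focal_group = "A"))
  expect_equal(zf$z[2], 0)
})

test_that("swapping the focal group negates every z-score", {
  x <- make_ko_matrix(seed = 5)
  labels <- setNames(rep(c("A", "B"), each = 10), colnames(x))
  za <- ko_zscores(x, labels, focal_group = "A")
  zb <- ko_zscores(x, labels, focal_group = "B")
  expect_equal(za$z, -zb$z, tolerance = 1e-12)
})

test_that("raw module aggregate is sum(z)/sqrt(k)", {
  z <- setNames(c(1, 1, 1, 1, rnorm(20)), sprintf("K%05d", 1:24))
  res <- reporter_scores(z, list(M1 = sprintf("K%05d", 1:4)),
                         n_background = 200, seed = 42)
  expect_equal(res$z_raw[res$module_id == "M1"], 2)
  ## module spanning the whole scored universe has a degenerate background
  expect_error(reporter_scores(z, list(Mall = names(z)), seed = 1),
               "degenerate|whole KO universe")
})

test_that("background standardisation centres and scales random modules", {
  ## random size-10 modules from a fixed z universe: reporter scores are
  ## approximately standard normal across seeds
  set.seed(50)
  z <- setNames(rnorm(120), sprintf("K%05d", 1:120))
  scores <- unlist(lapply(1:50, function(s) {
    set.seed(1000 + s)
    mods <- lapply(1:20, function(i) sample(names(z), 10))
    names(mods) <- sprintf("M%02d", 1:20)
    reporter_scores(z, mods, n_background = 400, seed = s)$z_reporter
  }))
  expect_lt(abs(mean(scores)), 0.1)
  expect_lt(abs(sd(scores) - 1), 0.15)
})

test_that("background sampling is reproducible under seed and skips empty modules", {
  z <- setNames(rnorm(60), sprintf("K%05d", 1:60))
  mods <- list(M1 = names(z)[1:6], M2 = c("KX", "KY"))
  expect_message(r1 <- reporter_scores(z, mods, seed = 7), "skipped 1")
  r2 <- suppressMessages(reporter_scores(z, mods, seed = 7))
  expect_identical(r1$z_reporter, r2$z_reporter)
  expect_equal(attr(r1, "skipped"), "M2")
  expect_equal(r1$module_id, "M1")
})

test_that("enrichment calls use a strict threshold in both directions", {
  res <- data.frame(module_id = c("a", "b", "c", "d"),
                    k = 4, z_raw = 0,
                    z_reporter = c(1.59, 1.61, -1.7, 0.2),
                    direction = c("A", "A", "B", "A"),
                    enriched = c(FALSE, TRUE, TRUE, FALSE))
  top <- enriched_modules(res, threshold = 1.6)
  expect_equal(top$module_id, c("c", "b"))
  none <- enriched_modules(res, threshold = 2)
  expect_equal(nrow(none), 0L)
})

test_that("under a permuted-label null the 1.6 exceedance rate is ~P(Z>1.6)", {
  ## score 5,000 random size-8 modules against a null z universe derived
  ## from permuted labels of a no-effect dataset
  set.seed(123)
  x <- make_ko_matrix(n_ko = 200, n = 40, seed = 321)
  labels <- setNames(sample(rep(c("A", "B"), 20)), colnames(x))
  z <- ko_zscores(x, labels, focal_group = "A")
  zv <- setNames(z$z, z$ko)
  draws <- replicate(5000, sum(zv[sample.int(200, 8)]) / sqrt(8))
  mu <- mean(replicate(2000, sum(zv[sample.int(200, 8)]) / sqrt(8)))
  sg <- sd(draws)
  frac <- mean((draws - mu) / sg > 1.6)
  expect_lt(abs(frac - pnorm(1.6, lower.tail = FALSE)), 0.03)
})

test_that("planted-shift modules are recovered with the right direction", {
  ## light version of the acceptance power run (fewer seeds)
  hits <- vapply(1:5, function(seed) {
    sim <- small_sim(seed = seed)
    ab <- gene_relative_abundance(sim$counts, sim$genes)
    ko <- aggregate_by_annotation(ab, sim$annotations$gene2ko)
    koz <- suppressWarnings(ko_zscores(ko, sim$labels, focal_group = "A"))
    res <- suppressMessages(
      reporter_scores(koz, sim$annotations$modules, seed = seed + 1000,
                      focal_group = "A", other_group = "B"))
    all(vapply(seq_len(nrow(sim$truth$enriched_modules)), function(i) {
      j <- match(sim$truth$enriched_modules$module[i], res$module_id)
      res$enriched[j] &&
        res$direction[j] == sim$truth$enriched_modules$group[i]
    }, FALSE))
  }, FALSE)
  expect_gte(sum(hits), 4L)
})
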