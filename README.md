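# metamgs

Gene-level comparative metagenomics for two-cohort studies, built around
a reference gene catalogue.

When two human cohorts are profiled by shotgun metagenomic sequencing,
the standard catalogue-based analysis asks: which catalogue genes differ
in abundance between the cohorts, which *metagenomic species* (MGS —
clusters of co-abundant genes interpreted as one microbial genome) those
genes belong to, which functional modules shift, how the communities
differ globally, and how the discriminating species relate to diet.
`metamgs` implements that analysis chain as tested, reusable R
functions, together with a seeded synthetic-cohort generator with
planted ground truth so every stage can be benchmarked end to end.

## The methods at a glance

* **Profiling** — relative gene abundance
  `a_g = (x_g/L_g) / Σ_j (x_j/L_j)` from mapped read-pair counts `x`
  and gene lengths `L`; aggregation to KO/OG profiles (sum over member
  genes) and to taxon profiles from best-hit lineages (identity > 95%,
  query overlap > 90%, strict).
* **Differential genes** — two-sided Wilcoxon rank-sum per feature
  (exact by enumeration for `min(n,m) ≤ 8`, normal approximation with
  tie/continuity correction otherwise), Benjamini–Hochberg step-up,
  significance at `q < 0.001`, direction = cohort with higher mean rank.
* **MGS** — single-linkage clustering of differential genes at Spearman
  `rho > 0.8` (connected components of the thresholded graph), fusion of
  clusters with more than 25 genes while their median representative
  profiles correlate above 0.8, 25 tracer genes per MGS, per-sample
  tracer-median abundance profile, consensus taxonomy (deepest rank
  where one taxon covers > 90% of member genes), and a co-occurrence
  network linking MGS at `rho > 0.6` (strict).
* **Reporter scores** — per-KO signed Z (`z = ±Φ⁻¹(1 − p/2)` from the
  rank-sum p), module aggregate `Σz/√k` standardised against 1000
  random same-size KO sets; enrichment at reporter score > 1.6.
* **Community** — Shannon diversity, richness, Bray–Curtis
  dissimilarity, classical PCoA (negative eigenvalues reported, not
  corrected).
* **Diet associations** — pairwise-complete Spearman correlation of MGS
  profiles with nutrient variables, t-approximation p-values, `+`/`*`
  flags at raw `P < 0.05` / `P < 0.01`.

The methods vignette (`vignettes/metamgs-methods.Rmd`) documents every
model, default and numerical choice in detail.

## Worked example

A full run on the default synthetic benchmark — 20 species × 100 genes,
30 + 30 samples, four species planted at ±2 log2 between cohorts A and
B, two planted 8-KO modules, two planted diet correlations (ρ = 0.6):

```r
library(metamgs)

cfg <- pipeline_config(seed = 1)          # 0.8 / >25 / q<0.001 / 0.6 / 1.6
res <- run_pipeline(cfg, file.path(tempdir(), "demo-run"))

d <- res$differential
cat(sum(d$significant), "of", nrow(d), "genes differential at q < 0.001\n")
for (b in res$mgs$mgs) print(b)
print(res$recovery$summary)
print(head(subset(res$reporter, enriched), 3))
print(head(subset(res$diet, flag != ""), 4))
```

```
398 of 2000 genes differential at q < 0.001
MGS001: 100 genes, taxon Strain01 (strain), enriched in A
MGS002: 100 genes, taxon Strain03 (strain), enriched in A
MGS003: 100 genes, taxon Strain04 (strain), enriched in B
MGS004: 98 genes, taxon Strain02 (strain), enriched in B
                 metric value
1                   ari   1.0
2                 n_mgs   4.0
3     species_recovered   1.0
4 species_direction_acc   1.0
5      module_precision   0.4
6         module_recall   1.0
  module_id k      z_raw z_reporter direction enriched
1     M0002 8 -18.002076  -6.152789         B     TRUE
2     M0001 8  17.076883   4.803653         A     TRUE
3     M0013 8   8.609007   2.158825         A     TRUE
   mgs_id nutrient_id  n        rho      p_value flag note      q_value
1  MGS001     protein 60  0.6301195 6.865735e-08    *      1.922406e-06
6  MGS001          Se 60 -0.3692137 3.695021e-03    *      1.960374e-02
8  MGS002     protein 60  0.3644346 4.200802e-03    *      1.960374e-02
13 MGS002          Se 60 -0.2930258 2.307759e-02    +      9.231035e-02
```

Reading the output: the ~400 significant genes are exactly the genes of
the four planted species; each species is recovered as one MGS with the
correct strain-level consensus taxon and enrichment direction (adjusted
Rand index 1 between the planted species partition and the recovered MGS
partition); both planted modules (`M0001` toward A, `M0002` toward B)
clear the 1.6 reporter threshold with the right sign; and the planted
protein–`sp001` correlation surfaces as a `*`-flagged ρ ≈ 0.63 for
`MGS001`.  The run directory holds every stage's table (`diff.tsv`,
`mgs/*.tsv`, `network.graphml`, `reporter.tsv`, `pcoa_coords.tsv`,
`diet_correlation.tsv`, `recovery.tsv`) plus a `manifest.yaml` with all
parameters, derived seeds and output checksums; rerunning the same
config reproduces every file byte for byte.

The same pipeline runs on real tables by passing file paths instead of a
simulation: see `?pipeline_config` (`inputs =`) and the reader functions
(`read_count_matrix`, `read_gene_table`, `read_cohort_labels`,
`read_gene_hits`, `read_annotation_map`, `read_module_map`,
`read_nutrient_table`).

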