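# rad2b

Species-level microbiome profiling from **type IIB restriction-site tags**,
plus the comparative analyses a two-group tissue-microbiome study needs.

Type IIB enzymes such as BcgI cleave both strands on both sides of their
bipartite recognition site CGA(N6)TGC, excising an iso-length fragment.
Sequencing only those fragments yields a reduced representation of a
community in which every species contributes a predictable set of
fixed-length tags. `rad2b` is for microbiome researchers who want this
low-biomass-friendly design as transparent, testable code: it digests
reference genomes in silico, keeps only tags unique to one species, filters
reads, and quantifies species with an explicit false-positive control.

## The model

For species *i* in a sample, with

- `s_i` — reads assigned to species *i*'s unique tags,
- `t_i` — distinct unique tags of *i* observed,
- `T_i` — theoretical number of distinct unique tags of *i* in the database,

the package computes

```
G_i   = sqrt(s_i * t_i)                  # false-positive control; keep G_i >= 5
cov_i = s_i / T_i                        # average marker coverage ~ genome copies
p_i   = cov_i / sum_j cov_j              # relative abundance, sums to 1
```

A spurious species typically collects many reads on a single tag (high
`s`, `t = 1`, low `G`); a genuine one spreads reads across its markers.
The `s/T` normalization makes abundances comparable between species with
very different marker counts.

Downstream: Chao1 / Shannon / Simpson alpha diversity with Wilcoxon group
tests; Bray–Curtis, binary Jaccard and Euclidean distances with PCoA and
PERMANOVA; per-taxon Kruskal–Wallis tests; a LEfSe-style LDA effect-size
screen (cutoff 4.0); and random-forest marker selection with
probability-of-disease (POD) scoring and AUC. A mock-community simulator
(`synth_config()`, `simulate_study()`) generates genomes, group-structured
compositions and tag-bearing FASTQ reads with exact ground truth, so the
whole pipeline is testable without downloading any reference data.

## Worked example

Simulate a 22-sample two-group study (15 MIBC vs 7 NMIBC) with two species
planted 16-fold higher in NMIBC, then run the full workflow:

```r
library(rad2b)

cfg <- synth_config(n_species = 12, genome_length = 6000, sites_per_genome = 8,
                    reads_per_sample = 2000,
                    planted_differentials = data.frame(
                      species = c(1L, 2L), log2fc = c(4, 4), group = "NMIBC"),
                    seed = 17)
res <- run_synthetic_study(cfg, n_perm = 199, n_trees = 300, folds = 3)

res$db
#> tag_db: 12 species, 96 unique 32-bp tags (0 shared tags removed)

prof <- as.data.frame(res$profiles[["NMIBC_01"]])   # one sample's profile
head(prof[order(-prof$rel_abundance), ], 4)
#>        species_id   s t T g_score coverage rel_abundance
#> 2 Genus01_sp00002 921 8 8    85.8    115.1        0.4860
#> 1 Genus01_sp00001 424 8 8    58.2     53.0        0.2237
#> 5 Genus03_sp00005 210 8 8    41.0     26.2        0.1108
#> 4 Genus02_sp00004  85 8 8    26.1     10.6        0.0449
```

Each row is one detected species: `s` reads landed on `t` of its `T`
database tags (here all 8, so `G = sqrt(s*t)` is far above 5), `coverage`
is `s/T`, and `rel_abundance` renormalizes coverage across survivors —
the planted NMIBC species dominate this NMIBC sample.

```r
s <- res$summary
s$species_detected                  # 12 — all simulated species recovered
unlist(s$venn)                      # shared 12, exclusives 0/0, total 12
unlist(s$alpha_p)                   # chao1 0.174, shannon 0.0029, simpson 0.014
unlist(s$beta_p)                    # bray_curtis 0.005, jaccard 0.27, euclidean 0.005
s$n_discriminative                  # 13 LEfSe hits across ranks
s$classifier[c("k", "auc", "pod_group_p")]
#> k = 1, auc = 0.981, pod_group_p = 6.8e-05

head(res$diff$lefse[res$diff$lefse$rank == "species", ], 3)
#>             taxon    rank enriched_in lda_score        p
#> 4 Genus01_sp00002 species       NMIBC      5.43 0.000215
#> 8 Genus01_sp00001 species       NMIBC      5.19 0.006650
#> 9 Genus06_sp00012 species        MIBC      4.98 0.008208
```

The two planted species head the LEfSe report, enriched in the right group
(MIBC-enriched hits are the compositional mirror image of planting two
large NMIBC effects). Richness (Chao1) does not differ — both groups carry
all 12 species — while evenness-sensitive indices and the abundance-aware
distances (Bray–Curtis, Euclidean) do; presence/absence Jaccard sees
nothing, as it should here. The classifier separates the groups with one
marker at AUC 0.98.

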