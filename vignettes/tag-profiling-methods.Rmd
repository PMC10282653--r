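---
title: "Methods: type IIB restriction-site tag profiling of microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: type IIB restriction-site tag profiling of microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The profiling model

Type IIB restriction endonucleases such as BcgI cut both strands on both
sides of a bipartite recognition site — CGA(N6)TGC for BcgI — excising an
iso-length fragment. Sequencing only these fragments gives a reduced
representation of a community: every genome contributes a predictable set of
fixed-length *tags*, and a tag found in exactly one species of the reference
set is a species-specific marker. `rad2b` implements this design end to end:

1. **In-silico digest** (`scan_recognition_sites()`, `extract_tags()`): every
   motif occurrence on either strand, overlapping matches included, yields
   the window of `arm5 + 12 + arm3` bases centred on the site. Windows are
   keyed in *canonical orientation* (the lexicographic minimum of the window
   and its reverse complement), which removes all strand bookkeeping between
   the genome digest and read-derived tags.
2. **Unique-tag database** (`build_tag_db()`): tags seen in two or more
   species are removed entirely; tags repeated at several loci of one genome
   count once. The per-species count of distinct unique tags is the
   theoretical tag count `T[i]`.
3. **Read QC** (`qc_filter()`): a clean read has at most 8% unknown bases, at
   most 20% of bases below Phred 30, and contains the recognition site.
4. **Profiling** (`profile_tags()`): reads are assigned by exact tag lookup.
   With `s[i]` reads on species *i*'s unique tags and `t[i]` distinct tags
   observed, the G score `sqrt(s[i] * t[i])` separates genuine detections
   (reads spread over many tags) from spurious ones (many reads piled on one
   tag); species with `G < 5` are discarded. Abundance is coverage
   normalized: `coverage[i] = s[i] / T[i]` estimates genome copies
   independently of how many markers a species happens to have, and relative
   abundance is `coverage[i] / sum(coverage)`.

Downstream, the package provides the comparative layer such a study needs:
alpha diversity (Chao1 on integer counts, Shannon and Simpson on
proportions) with Wilcoxon group tests; Bray–Curtis / binary Jaccard /
Euclidean distances with PCoA and PERMANOVA; per-taxon Kruskal–Wallis tests;
a LEfSe-style LDA effect-size screen; and a random-forest marker-selection
stage with probability-of-disease (POD) scoring.

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `arm5`, `arm3` | 10 bp each | flank retained around the 12-bp motif, so tags are 32 bp. Vendor pipelines do not publish the exact BcgI arm lengths; 10/10 matches the iso-length-fragment principle and is fully configurable, which isolates the assumption. |
| `max_unknown_frac` | 0.08 | strict `>` comparison: a 100-bp read with exactly 8 Ns is kept. |
| `q_threshold`, `max_lowq_frac` | Q30, 0.20 | strict `>` as above; Phred+33 only. |
| `g_threshold` | 5 | species with `G < 5` are removed; the boundary case `G = 5` is retained (threshold semantics are not otherwise specified, and keeping the boundary makes `g_score(5, 5)` a detection). |
| LEfSe `alpha`, `lda_cutoff` | 0.05, 4.0 | screen then effect size; scores are `log10` of a per-million-scale effect, so 4.0 corresponds to a ~10^4 per-million group difference. |
| forest settings | 500 trees, stratified bootstrap, √p features | standard random-forest defaults; none are critical at these sample sizes. |
| PERMANOVA `n_perm` | 999 | permutation count is a precision knob only; p-values use the `(1 + hits) / (1 + n_perm)` convention. |

## Decisions made where the design was open

- **QC order.** Whether the site-presence requirement applies before or
  after the two quality filters only affects which *reason* a doubly-bad
  read is labelled with, never the clean set. The fixed order is unknown
  bases → quality → site, and a conservation test asserts the keep-set is
  order-free.
- **One tag per read.** The library geometry yields one excised fragment per
  read. If several motifs occur, the leftmost plus-strand match wins, then
  the leftmost minus-strand match — a deterministic tie-break.
- **`T[i]` counts distinct markers.** A tag repeated at two loci of one
  genome is one marker: reads from either locus are indistinguishable, so
  counting it twice would deflate that species' coverage.
- **No read deduplication** before computing `t[i]`; `t` is the number of
  distinct unique tags seen at least once.
- **Alpha diversity inputs.** Chao1 needs singleton/doubleton frequencies
  and is computed on the integer read counts `s`; Shannon and Simpson are
  computed on relative abundances. Chao1 uses the bias-corrected form
  `S + F1(F1-1)/(2(F2+1))` (finite when `F2 = 0`), matching the behaviour of
  the standard ecology packages; the classic form is available by flag.
  No rarefaction is applied — depth differences are absorbed by the coverage
  normalization, and a rarefaction layer would add a parameter the profiling
  model does not need.
- **PERMANOVA** is implemented directly (Anderson's among/within partition
  of squared distances) so that permutation seeding is explicit;
  `vegan::adonis2` is used as an independent cross-check of the pseudo-F in
  the test suite, never as the implementation.
- **LEfSe internals.** The original tool's exact scoring is
  under-documented, so the scorer follows the published description: scale
  to per-million, subsample two thirds of each class 30 times, fit a
  two-class LDA with a ridge-regularized pooled covariance, and average the
  absolute discriminant-axis contribution with the absolute raw mean
  difference; the score is `log10(max(effect, 1))`. This is an
  approximation: rank order and cutoff behaviour are the contract, not
  decimal agreement with any particular LEfSe build.
- **POD** is the fraction of trees voting the positive class — bounded in
  [0, 1] — with out-of-bag trees only for training samples, avoiding
  resubstitution optimism. The marker count is chosen by the one-standard-
  error rule on the cross-validation error curve, the standard way to read
  such a curve without a cohort-specific choice.
- **Canonical sample order.** Random-forest fits depend on row order for a
  fixed seed, so all classifier entry points sort samples by id first;
  results are then invariant to the order in which samples are supplied.

## What the simulator emulates — and what it does not

`synth_config()` defaults describe a deliberately realistic small study:
30 species (two per genus, three genera per phylum), 20-kb single-contig
genomes with 30 recognition sites each, 15 vs 7 samples (mirroring an
imbalanced two-group clinical cohort), 100-bp reads carrying one tag each
inside motif-free padding, per-base substitution errors at 10^-3, `N` calls
at 5×10^-4, a two-state quality model (Phred ≈ 37 / ≈ 12, 5% low-quality
bases), log-normal species loadings with unit log-sd, and 1% contaminant
reads from a decoy genome that is excluded from the database. Group
structure is planted by multiplying selected species' loadings by `2^log2fc`
in one group before renormalization.

The generator is rejection-checked: genomes contain *exactly* the requested
sites (no spurious motifs), and each read contains exactly one site. That
makes ground truth exact, which is what the recovery tests need. It does
**not** model PCR duplicates, GC bias, quality-by-cycle decay, indels
(exact-match tag lookup makes an indel equivalent to a killing
substitution), strain-level variation within a species, or incomplete
reference databases. Passing the recovery tests therefore demonstrates that
the estimator chain is correct under its own assumptions — not that those
assumptions hold for any particular real library.

## Numerical and degenerate-input conventions

- Coordinates are 0-based half-open everywhere; FASTQ qualities are
  Phred+33 with values in [0, 60].
- Motif wildcards match `A/C/G/T` but never `N`: a genomic `N` cannot be
  matched exactly by a read, so windows containing `N` are discarded at
  digest time.
- Abundances of surviving species sum to 1 within 1e-9; a profile with no
  survivors is a zero-row profile, not an error.
- An all-zero count vector has Chao1 0; `0 log 0 = 0` in Shannon.
- A species surviving the G filter with `T = 0` is impossible from a
  consistent database and raises a hard error rather than an `Inf`.
- Ties in the Wilcoxon/Kruskal–Wallis tests fall back to the tie-corrected
  approximations of the underlying `stats` routines; the exact Wilcoxon
  distribution is used when both groups have ≤ 20 observations and no ties.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run everything at sizes chosen to
make the statistical checks sharp while staying desk-sized: 200 random
5–50 kb sequences for the scanner/brute-force equivalence; 100,000-read
single-sample communities for recovery (mean absolute error is compared to
the binomial sampling bound at that depth); 500 null communities of 22
samples for the PERMANOVA type-I rate at 99 permutations; 200 null
communities for the LEfSe false-positive rate and 20 seeds for each planted
benchmark; and a 22-sample synthetic study for the end-to-end workflow
test.

## Known limitations

- Exact-match tag lookup: a single substitution inside a 32-bp tag loses the
  read (it becomes unassigned). At a 1% per-base error rate ~27% of tag
  reads are lost roughly uniformly across species, which leaves relative
  abundances nearly unbiased but reduces effective depth.
- Shared tags are excluded at database build; there is no probabilistic
  reassignment, so closely related species pairs lose markers rather than
  sharing evidence. Species whose unique-tag count drops to zero are
  reported in the build report and can never be detected.
- The LDA effect size is a reimplementation faithful to the published
  description, not a byte-compatible port of any LEfSe release.
- POD is a vote fraction, not a calibrated probability.
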