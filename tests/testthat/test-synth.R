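test_that("generated genomes digest to exactly the requested tag counts", {
  cfg <- synth_config(n_species = 5, genome_length = 4000,
                      sites_per_genome = c(3L, 5L, 7L, 3L, 5L), seed = 31)
  ref <- generate_reference_set(cfg)
  got <- vapply(ref$genomes, function(g) length(extract_tags(g)), integer(1))
  expect_equal(got, c(3L, 5L, 7L, 3L, 5L))
  # tags are unique within each genome by construction
  for (g in ref$genomes) expect_false(anyDuplicated(extract_tags(g)) > 0)
  # taxonomy covers every species
  expect_setequal(ref$taxonomy$species_id,
                  vapply(ref$genomes, `[[`, "", "species_id"))
})

test_that("the generator is byte-deterministic for a fixed seed", {
  cfg <- synth_config(n_species = 3, genome_length = 3000,
                      sites_per_genome = 4, n_samples = c(A = 2L),
                      reads_per_sample = 200, seed = 59)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(vapply(s1$ref$genomes, `[[`, "", "contigs"),
                   vapply(s2$ref$genomes, `[[`, "", "contigs"))
  expect_identical(s1$truth$composition, s2$truth$composition)
  expect_identical(s1$samples, s2$samples)
  # and FASTA output is byte-identical
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_genomes(s1$ref$genomes, f1)
  write_genomes(s2$ref$genomes, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a planted shared tag is excluded from both species' T", {
  cfg0 <- synth_config(n_species = 4, genome_length = 4000,
                       sites_per_genome = 5, seed = 61)
  cfg1 <- synth_config(n_species = 4, genome_length = 4000,
                       sites_per_genome = 5, shared_tag_pair = c(1L, 2L),
                       seed = 61)
  db0 <- build_tag_db(generate_reference_set(cfg0)$genomes)
  db1 <- build_tag_db(generate_reference_set(cfg1)$genomes)
  expect_equal(unname(db0$T), rep(5L, 4))
  expect_equal(unname(db1$T[1:2]), c(4L, 4L))
  expect_equal(unname(db1$T[3:4]), c(5L, 5L))
  expect_equal(db1$report$n_shared_tags_removed, 1L)
})

test_that("compositions are normalized and differentials shift group means", {
  withr::with_seed(67, {
    up <- 0L
    for (i in 1:30) {
      cfg <- synth_config(
        n_species = 10, n_samples = c(A = 8L, B = 8L),
        planted_differentials = data.frame(species = 1L, log2fc = 3,
                                           group = "A"),
        seed = sample.int(1e6, 1))
      comp <- generate_composition(cfg)
      expect_equal(unname(rowSums(comp$composition)), rep(1, 16),
                   tolerance = 1e-12)
      mA <- mean(comp$composition[comp$groups == "A", 1])
      mB <- mean(comp$composition[comp$groups == "B", 1])
      if (mA > mB) up <- up + 1L
    }
    expect_gte(up, 28L)  # +3 log2fc lifts the group mean almost surely
  })
})

test_that("simulated reads carry full provenance and exact counts", {
  cfg <- synth_config(n_species = 4, genome_length = 3000,
                      sites_per_genome = 4, n_samples = c(A = 1L),
                      reads_per_sample = 750, seed = 71)
  ref <- generate_reference_set(cfg)
  comp <- generate_composition(cfg, ref$taxonomy$species_id)
  sim <- simulate_reads(ref, comp$composition[1, ], cfg, "sampleA", seed = 4)
  expect_equal(nrow(sim$reads), 750L)
  expect_identical(sim$provenance$read_id, sim$reads$read_id)
  expect_true(all(sim$provenance$species %in%
                    c(ref$taxonomy$species_id, "decoy")))
  expect_true(all(nchar(sim$reads$bases) == cfg$read_length))
  expect_true(all(nchar(sim$reads$quals) == cfg$read_length))
})

test_that("reads forced over the N threshold are exactly the QC casualties", {
  cfg <- synth_config(n_species = 3, genome_length = 3000,
                      sites_per_genome = 4, n_samples = c(A = 1L),
                      reads_per_sample = 300, base_error_rate = 0,
                      n_rate = 0, lowq_prob = 0, contaminant_rate = 0,
                      seed = 73)
  ref <- generate_reference_set(cfg)
  comp <- generate_composition(cfg, ref$taxonomy$species_id)
  sim <- simulate_reads(ref, comp$composition[1, ], cfg, "s", seed = 5)
  reads <- sim$reads
  # push a known subset over the 8% threshold (9 N's outside the tag zone:
  # reads always start with at least one pad base, use the first 9 positions
  # only when the tag starts later)
  victim <- which(!startsWith(reads$bases, "CGA") &
                    !startsWith(reads$bases, "GCA"))[1:40]
  tagged <- regexpr("CGA[ACGT]{6}TGC|GCA[ACGT]{6}TCG", reads$bases[victim])
  ok <- victim[tagged > 20]  # room for 9 Ns before the tag window
  reads$bases[ok] <- paste0(strrep("N", 9),
                            substring(reads$bases[ok], 10))
  res <- qc_filter(reads)
  expect_true(all(res$reason[ok] == "too_many_N"))
  expect_true(all(res$keep[setdiff(seq_len(300), ok)]))
})

test_that("error-free reads are assigned to the correct source species", {
  cfg <- synth_config(n_species = 5, genome_length = 4000,
                      sites_per_genome = 5, n_samples = c(A = 1L),
                      reads_per_sample = 2000, base_error_rate = 0,
                      n_rate = 0, lowq_prob = 0, contaminant_rate = 0,
                      seed = 79)
  ref <- generate_reference_set(cfg)
  db <- build_tag_db(ref$genomes)
  comp <- generate_composition(cfg, ref$taxonomy$species_id)
  sim <- simulate_reads(ref, comp$composition[1, ], cfg, "s", seed = 6)
  tag <- extract_read_tag(sim$reads$bases)
  hit <- db$tags$species_id[match(tag, db$tags$tag)]
  expect_gte(mean(hit == sim$provenance$species, na.rm = TRUE), 0.99)
  expect_gte(mean(!is.na(hit)), 0.99)
})

test_that("study simulation writes a complete, reloadable file set", {
  cfg <- synth_config(n_species = 3, genome_length = 3000,
                      sites_per_genome = 4, n_samples = c(A = 2L, B = 1L),
                      reads_per_sample = 150, seed = 83)
  dir <- withr::local_tempdir()
  sim <- simulate_study(cfg, out_dir = dir)
  expect_true(file.exists(sim$paths$fasta))
  expect_true(all(file.exists(sim$paths$fastq)))
  back <- read_fastq(sim$paths$fastq[[1]])
  expect_identical(back, sim$samples[[1]])
  genomes <- read_genomes(sim$paths$fasta)
  expect_equal(length(genomes), 4L)  # 3 species + decoy
  meta <- read.table(sim$paths$metadata, sep = "\t", header = TRUE)
  expect_equal(nrow(meta), 3L)
})
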