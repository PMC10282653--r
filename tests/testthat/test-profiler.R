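test_that("tag assignment counts reads and distinct tags per species", {
  tags <- ac_tags(6)
  db <- toy_db(list(spX = tags[1:3], spY = tags[4:5]))

  a <- assign_tags(character(0), db)
  expect_equal(sum(a$s), 0L)
  expect_equal(a$unassigned, 0L)

  a <- assign_tags(rep(canonical_tag(tags[1]), 3), db)
  expect_equal(a$s[["spX"]], 3L)
  expect_equal(a$t[["spX"]], 1L)
  expect_equal(a$s[["spY"]], 0L)

  a <- assign_tags(canonical_tag(tags[6]), db)  # not in db
  expect_equal(a$unassigned, 1L)
  expect_equal(sum(a$s), 0L)

  expect_error(assign_tags("ACGT", db), "scheme mismatch")
})

test_that("G score is the geometric mean of read and tag support", {
  expect_equal(g_score(0, 0), 0)
  expect_equal(g_score(25, 1), 5)
  expect_equal(g_score(5, 5), 5)
  expect_equal(g_score(16, 1), 4)
  # monotone in both arguments
  withr::with_seed(5, {
    s <- sample(0:100, 50, replace = TRUE)
    t <- pmin(s, sample(0:20, 50, replace = TRUE))
    expect_true(all(g_score(s + 1, t) >= g_score(s, t)))
    expect_true(all(g_score(s, t + 1) >= g_score(s, t)))
  })
})

test_that("G filter drops sub-threshold species and keeps the boundary", {
  prof <- data.frame(species_id = c("a", "b", "c"),
                     s = c(16L, 5L, 25L), t = c(1L, 5L, 1L),
                     T = c(10L, 10L, 10L))
  prof$g_score <- g_score(prof$s, prof$t)
  out <- apply_g_filter(prof, 5)
  expect_setequal(out$species_id, c("b", "c"))  # G=4 dropped, G=5 kept
  expect_equal(attr(out, "dropped")$species_id, "a")
  empty <- prof[0, ]
  expect_equal(nrow(apply_g_filter(empty, 5)), 0L)
})

test_that("relative abundance normalizes s/T coverage", {
  prof <- data.frame(species_id = c("a", "b"), s = c(10L, 30L),
                     t = c(5L, 9L), T = c(100L, 100L),
                     g_score = c(7.1, 16.4))
  out <- relative_abundance(prof)
  expect_equal(out$rel_abundance, c(0.25, 0.75))
  expect_equal(out$coverage, c(0.1, 0.3))

  one <- relative_abundance(prof[1, ])
  expect_equal(one$rel_abundance, 1.0)

  eq <- relative_abundance(data.frame(species_id = c("a", "b"),
                                      s = c(5L, 50L), t = c(2L, 3L),
                                      T = c(10L, 100L), g_score = c(9, 9)))
  expect_equal(eq$rel_abundance, c(0.5, 0.5))

  bad <- data.frame(species_id = "z", s = 5L, t = 1L, T = 0L, g_score = 9)
  expect_error(relative_abundance(bad), "T = 0")
})

test_that("abundances always normalize to one and scale out depth", {
  withr::with_seed(99, {
    for (i in 1:25) {
      k <- sample(2:12, 1)
      prof <- data.frame(species_id = paste0("sp", 1:k),
                         s = sample(1:500, k, replace = TRUE),
                         t = sample(1:5, k, replace = TRUE),
                         T = sample(5:50, k, replace = TRUE))
      prof$g_score <- g_score(prof$s, prof$t)
      out <- relative_abundance(prof)
      expect_lt(abs(sum(out$rel_abundance) - 1), 1e-9)
      doubled <- prof
      doubled$s <- prof$s * 2L
      expect_equal(relative_abundance(doubled)$rel_abundance,
                   out$rel_abundance)
    }
  })
})

test_that("profiling a pure single-species sample yields abundance 1", {
  tags <- ac_tags(8)
  db <- toy_db(list(spX = tags[1:4], spY = tags[5:8]))
  stream <- canonical_tag(rep(tags[1:4], times = c(10, 8, 6, 6)))
  prof <- profile_tags(stream, db)
  expect_equal(prof$species_id, "spX")
  expect_equal(prof$rel_abundance, 1.0)
  expect_equal(prof$s, 30L)
  expect_equal(prof$t, 4L)
})

test_that("a spiked false positive (10 reads on 1 tag) is suppressed", {
  tags <- ac_tags(8)
  db <- toy_db(list(spTrue = tags[1:4], spFalse = tags[5:8]))
  stream <- canonical_tag(c(rep(tags[1:4], times = c(7, 7, 6, 5)),
                            rep(tags[5], 10)))
  prof <- profile_tags(stream, db)
  expect_equal(prof$species_id, "spTrue")   # G(10,1)=3.16 < 5
  expect_equal(attr(prof, "dropped")$species_id, "spFalse")
  expect_equal(prof$rel_abundance, 1.0)
})

test_that("T-correction equalizes species with 10-fold tag-count difference", {
  # equal genome representation, T differing 10-fold: the s/T normalization
  # must recover equal abundances in expectation
  withr::with_seed(55, {
    ratios <- replicate(10, {
      cfg <- synth_config(n_species = 2, genome_length = 12000,
                          sites_per_genome = c(30L, 3L),
                          n_samples = c(A = 1L), reads_per_sample = 20000,
                          base_error_rate = 0, n_rate = 0, lowq_prob = 0,
                          contaminant_rate = 0,
                          seed = sample.int(1e6, 1))
      ref <- generate_reference_set(cfg)
      db <- build_tag_db(ref$genomes)
      comp <- c(0.5, 0.5)
      names(comp) <- ref$taxonomy$species_id
      sim <- simulate_reads(ref, comp, cfg, "s1", seed = sample.int(1e6, 1))
      prof <- profile_sample(sim$reads, db)
      ab <- setNames(prof$rel_abundance, prof$species_id)
      ab[[1]] / ab[[2]]
    })
    expect_gt(mean(ratios), 0.9)
    expect_lt(mean(ratios), 1.1)
  })
})

test_that("full per-sample pipeline recovers a 3-species composition", {
  cfg <- synth_config(n_species = 3, genome_length = 6000,
                      sites_per_genome = 8, n_samples = c(A = 1L),
                      reads_per_sample = 20000, base_error_rate = 0,
                      n_rate = 0, lowq_prob = 0, contaminant_rate = 0,
                      seed = 123)
  ref <- generate_reference_set(cfg)
  db <- build_tag_db(ref$genomes)
  truth <- c(0.6, 0.3, 0.1)
  names(truth) <- ref$taxonomy$species_id
  sim <- simulate_reads(ref, truth, cfg, "s1", seed = 9)
  prof <- profile_sample(sim$reads, db)
  ab <- setNames(prof$rel_abundance, prof$species_id)[names(truth)]
  expect_lt(mean(abs(ab - truth)), 0.02)
})
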