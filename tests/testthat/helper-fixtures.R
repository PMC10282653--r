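# Programmatic fixtures. Tags built over {A, C} arms and fillers carry the
# recognition motif exactly once (no G outside the motif's fixed bases), so
# toy databases have fully controlled content.

ac_chars <- c("A", "C")

ac_string <- function(n) paste(sample(ac_chars, n, replace = TRUE),
                               collapse = "")

# A 32-bp tag with the BcgI motif at offset 10 and single-motif guarantee.
ac_tag <- function(n6 = "AAAAAA", arm5 = strrep("A", 10),
                   arm3 = strrep("C", 10)) {
  tag <- paste0(arm5, "CGA", n6, "TGC", arm3)
  stopifnot(nrow(scan_recognition_sites(tag)) == 1L)
  tag
}

# Distinct single-motif tags, deterministically enumerated.
ac_tags <- function(n) {
  fill <- vapply(seq_len(n) - 1L, function(i) {
    paste(ac_chars[1 + (i %/% 2^(0:5)) %% 2], collapse = "")
  }, character(1))
  vapply(fill, function(f) ac_tag(n6 = f), character(1), USE.NAMES = FALSE)
}

# Build a tag_db from explicit per-species tag sets: each tag becomes one
# 32-bp contig, so the in-silico digest returns exactly these tags.
toy_db <- function(tag_sets, scheme = digest_scheme()) {
  genomes <- lapply(names(tag_sets), function(sp) {
    list(species_id = sp, contigs = tag_sets[[sp]])
  })
  build_tag_db(genomes, scheme)
}

# A read of length `len` carrying `tag` at 1-based offset `at`, padded with
# motif-free {A,C} sequence, with uniform quality `q`.
tag_read <- function(tag, id = "r1", at = 21L, len = 100L, q = 35L) {
  left <- strrep("A", at - 1L)
  right <- strrep("C", len - (at - 1L) - nchar(tag))
  bases <- paste0(left, tag, right)
  stopifnot(nchar(bases) == len)
  data.frame(read_id = id, bases = bases,
             quals = strrep(rawToChar(as.raw(33L + q)), len),
             stringsAsFactors = FALSE)
}

# Log-normal two-group abundance table without any planted signal.
null_table <- function(n1 = 15L, n2 = 7L, n_taxa = 30L, sdlog = 1,
                       group_names = c("MIBC", "NMIBC")) {
  n <- n1 + n2
  m <- matrix(rlnorm(n * n_taxa, 0, sdlog), n, n_taxa)
  m <- m / rowSums(m)
  rownames(m) <- sprintf("s%02d", seq_len(n))
  colnames(m) <- sprintf("taxon%02d", seq_len(n_taxa))
  groups <- setNames(rep(group_names, c(n1, n2)), rownames(m))
  abundance_table(m, counts = matrix(rpois(n * n_taxa, 20), n, n_taxa,
                                     dimnames = dimnames(m)),
                  groups = groups)
}
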