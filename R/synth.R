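BASES <- c("A", "C", "G", "T")

#' Configuration of the mock-community simulator
#'
#' The generator emulates the structure of a two-group tissue-microbiome
#' study profiled by type IIB tags: reference genomes carrying a controlled
#' number of recognition sites, log-normal community compositions with
#' planted differentially abundant species, and 100-bp tag-bearing reads with
#' substitution errors, unknown bases and a two-state base-quality model.
#' Group sizes default to 15 vs 7 to mirror a realistically imbalanced
#' clinical cohort.
#'
#' @param n_species Number of reference species.
#' @param genome_length Genome length in bp (single contig per species).
#' @param sites_per_genome Recognition sites planted per genome; scalar or
#'   one value per species.
#' @param n_samples Named integer vector of samples per group.
#' @param reads_per_sample Reads simulated per sample.
#' @param read_length Read length in bp.
#' @param base_error_rate Per-base substitution error probability.
#' @param n_rate Per-base probability of an `N` call.
#' @param quality_high,quality_low Mean Phred scores of the high- and
#'   low-quality base states.
#' @param lowq_prob Probability that a base is in the low-quality state.
#' @param planted_differentials Data frame with columns `species` (index or
#'   id), `log2fc`, `group`: the species' loading is multiplied by
#'   `2^log2fc` in that group.
#' @param lognormal_meanlog,lognormal_sdlog Log-normal parameters of the
#'   baseline species loadings.
#' @param contaminant_rate Fraction of reads drawn from an off-database decoy
#'   genome.
#' @param shared_tag_pair Optional integer pair: plant one identical tag in
#'   these two species to exercise the uniqueness filter.
#' @param seed Mandatory RNG seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_species = 30L,
                         genome_length = 20000L,
                         sites_per_genome = 30L,
                         n_samples = c(MIBC = 15L, NMIBC = 7L),
                         reads_per_sample = 20000L,
                         read_length = 100L,
                         base_error_rate = 0.001,
                         n_rate = 5e-4,
                         quality_high = 37,
                         quality_low = 12,
                         lowq_prob = 0.05,
                         planted_differentials = NULL,
                         lognormal_meanlog = 0,
                         lognormal_sdlog = 1.0,
                         contaminant_rate = 0.01,
                         shared_tag_pair = NULL,
                         seed) {
  if (missing(seed)) stop("synth_config requires an explicit seed")
  rates <- c(base_error_rate, n_rate, lowq_prob, contaminant_rate)
  stopifnot(all(rates >= 0), all(rates <= 1),
            all(sites_per_genome >= 1L), n_species >= 1L,
            read_length >= 1L, !is.null(names(n_samples)))
  cfg <- list(n_species = as.integer(n_species),
              genome_length = as.integer(genome_length),
              sites_per_genome = rep_len(as.integer(sites_per_genome),
                                         n_species),
              n_samples = n_samples,
              reads_per_sample = as.integer(reads_per_sample),
              read_length = as.integer(read_length),
              base_error_rate = base_error_rate,
              n_rate = n_rate,
              quality_high = quality_high,
              quality_low = quality_low,
              lowq_prob = lowq_prob,
              planted_differentials = planted_differentials,
              lognormal_meanlog = lognormal_meanlog,
              lognormal_sdlog = lognormal_sdlog,
              contaminant_rate = contaminant_rate,
              shared_tag_pair = shared_tag_pair,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

# Remove every recognition-site occurrence from a character vector of bases
# by point mutation, rescanning until clean.
erase_motifs <- function(chars, scheme) {
  for (iter in 1:100) {
    sites <- scan_recognition_sites(paste(chars, collapse = ""), scheme)
    if (nrow(sites) == 0L) return(chars)
    pos <- sites$offset + 2L  # 1-based index of the motif's 2nd base
    for (p in unique(pos)) {
      chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
    }
  }
  stop("failed to erase spurious recognition sites")
}

# One genome: motif-free random background with n_sites recognition sites
# planted at spaced positions, rejection-checked so that the in-silico
# digest recovers exactly n_sites distinct tags.
make_genome_seq <- function(len, n_sites, scheme) {
  ml <- scheme$motif_length
  block <- len %/% n_sites
  pad <- scheme$tag_length  # keeps neighbouring windows disjoint
  if (block < ml + 2L * pad) stop("genome_length too small for ", n_sites,
                                  " sites")
  motif_chars <- strsplit(scheme$motif, "")[[1]]
  wild <- motif_chars == "N"
  for (attempt in 1:25) {
    chars <- sample(BASES, len, replace = TRUE)
    chars <- erase_motifs(chars, scheme)
    starts <- integer(n_sites)  # 0-based motif offsets
    for (j in seq_len(n_sites)) {
      lo <- (j - 1L) * block + pad
      hi <- j * block - ml - pad
      starts[j] <- sample(lo:hi, 1L)
      fill <- motif_chars
      fill[wild] <- sample(BASES, sum(wild), replace = TRUE)
      chars[(starts[j] + 1L):(starts[j] + ml)] <- fill
    }
    seq <- paste(chars, collapse = "")
    sites <- scan_recognition_sites(seq, scheme)
    if (!identical(sort(sites$offset), sort(starts))) next  # spurious site
    tags <- contig_tags(seq, scheme)
    if (length(tags) == n_sites && !anyDuplicated(tags)) {
      return(list(seq = seq, sites = sort(starts)))
    }
  }
  stop("failed to generate a clean genome after 25 attempts")
}

#' Generate a mock reference set
#'
#' Produces `n_species` single-contig genomes with a controlled number of
#' recognition sites each, a synthetic taxonomy (two species per genus,
#' three genera per phylum), and one decoy genome that is kept out of the
#' database (its reads act as off-target contamination). Optionally one tag
#' is copied between a species pair so the shared tag is excluded from the
#' unique-tag database.
#'
#' @param config A [synth_config()].
#' @param scheme A [digest_scheme()].
#' @return List with `genomes`, `taxonomy` (data frame `species_id`, `genus`,
#'   `phylum`), `decoy` (a genome), and `windows` (per-species plus-strand
#'   tag windows, in genome order).
#' @export
generate_reference_set <- function(config, scheme = digest_scheme()) {
  withr::with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_species
    genus_i <- ceiling(seq_len(n) / 2)
    phylum_i <- ceiling(genus_i / 3)
    species_id <- sprintf("Genus%02d_sp%05d", genus_i, seq_len(n))
    taxonomy <- data.frame(species_id = species_id,
                           genus = sprintf("Genus%02d", genus_i),
                           phylum = sprintf("Phylum%02d", phylum_i),
                           stringsAsFactors = FALSE)
    raw <- lapply(seq_len(n), function(i) {
      make_genome_seq(config$genome_length, config$sites_per_genome[i], scheme)
    })
    genomes <- lapply(seq_len(n), function(i) {
      list(species_id = species_id[i], contigs = raw[[i]]$seq,
           sites = raw[[i]]$sites)
    })
    if (!is.null(config$shared_tag_pair)) {
      a <- config$shared_tag_pair[1]; b <- config$shared_tag_pair[2]
      ga <- genomes[[a]]; gb <- genomes[[b]]
      win_a <- substr(ga$contigs, ga$sites[1] - scheme$arm5 + 1L,
                      ga$sites[1] + scheme$motif_length + scheme$arm3)
      start_b <- gb$sites[1] - scheme$arm5 + 1L
      s <- gb$contigs
      substr(s, start_b, start_b + scheme$tag_length - 1L) <- win_a
      # accept only if the transplant did not disturb the site layout
      if (length(contig_tags(s, scheme)) == length(gb$sites)) {
        genomes[[b]]$contigs <- s
      } else {
        warning("shared-tag transplant rejected (spurious site); skipped")
      }
    }
    decoy_raw <- make_genome_seq(config$genome_length,
                                 max(config$sites_per_genome), scheme)
    decoy <- list(species_id = "decoy", contigs = decoy_raw$seq,
                  sites = decoy_raw$sites)
    windows <- lapply(c(genomes, list(decoy)), function(g) {
      sites <- scan_recognition_sites(g$contigs, scheme)
      plus_windows(g$contigs, sites$offset, sites$strand, scheme)
    })
    names(windows) <- c(species_id, "decoy")
    list(genomes = genomes, taxonomy = taxonomy, decoy = decoy,
         windows = windows, scheme = scheme)
  })
}

# Plus-strand tag windows at given motif offsets (all assumed fully flanked).
plus_windows <- function(seq, offsets, strands, scheme) {
  start0 <- ifelse(strands == "+", offsets - scheme$arm5,
                   offsets - scheme$arm3)
  substring(seq, start0 + 1L, start0 + scheme$tag_length)
}

#' Generate group-structured community compositions
#'
#' Baseline per-sample species loadings are drawn log-normal; each planted
#' differential multiplies its species' loading by `2^log2fc` in the
#' designated group; rows are normalized to sum to one.
#'
#' @param config A [synth_config()].
#' @param species_ids Species identifiers (column names); defaults to the
#'   ids that [generate_reference_set()] would assign.
#' @return List with `composition` (samples × species matrix, rows sum to 1),
#'   `groups` (named vector sample -> group), and `differentials`.
#' @export
generate_composition <- function(config, species_ids = NULL) {
  n <- config$n_species
  if (is.null(species_ids)) {
    genus_i <- ceiling(seq_len(n) / 2)
    species_ids <- sprintf("Genus%02d_sp%05d", genus_i, seq_len(n))
  }
  withr::with_seed(derive_seed(config$seed, 2L), {
    groups <- rep(names(config$n_samples), config$n_samples)
    sample_ids <- unlist(lapply(names(config$n_samples), function(g) {
      sprintf("%s_%02d", g, seq_len(config$n_samples[[g]]))
    }))
    m <- matrix(stats::rlnorm(length(groups) * n,
                              config$lognormal_meanlog,
                              config$lognormal_sdlog),
                nrow = length(groups), ncol = n,
                dimnames = list(sample_ids, species_ids))
    pd <- config$planted_differentials
    if (!is.null(pd)) {
      for (i in seq_len(nrow(pd))) {
        sp <- pd$species[i]
        j <- if (is.numeric(sp)) sp else match(sp, species_ids)
        m[groups == pd$group[i], j] <- m[groups == pd$group[i], j] *
          2^pd$log2fc[i]
      }
    }
    m <- m / rowSums(m)
    list(composition = m,
         groups = stats::setNames(groups, sample_ids),
         differentials = pd)
  })
}

# Collapse an n x L character matrix to n strings.
collapse_rows <- function(m) {
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Substitution errors / N-masking on a character matrix; returns the matrix
# plus the flat indices touched.
apply_substitutions <- function(m, rate) {
  idx <- which(stats::runif(length(m)) < rate)
  if (length(idx)) {
    repl <- sample(BASES, length(idx), replace = TRUE)
    same <- repl == m[idx]
    while (any(same)) {
      repl[same] <- sample(BASES, sum(same), replace = TRUE)
      same <- repl == m[idx]
    }
    m[idx] <- repl
  }
  list(m = m, idx = idx)
}

#' Simulate tag-bearing reads for one sample
#'
#' Each read is drawn by choosing a source species with probability
#' proportional to composition × tag count (genome copies times sites), one
#' of its tag windows uniformly, and a random orientation; the window is
#' embedded at a random offset in motif-free padding. Reads are
#' rejection-checked to contain exactly one recognition site, then
#' substitution errors, `N` calls and two-state qualities are applied.
#' A `contaminant_rate` fraction of reads comes from the decoy genome.
#'
#' @param ref Reference set from [generate_reference_set()].
#' @param composition One row of the composition matrix (named by species).
#' @param config A [synth_config()].
#' @param sample_id Sample label used in read ids.
#' @param n_reads Number of reads (defaults to `config$reads_per_sample`).
#' @param seed RNG seed for this sample.
#' @return List with `reads` (data frame `read_id`, `bases`, `quals`) and
#'   `provenance` (data frame `read_id`, `species`, `tag`, `n_errors`,
#'   `n_unknown`, `error_positions`).
#' @export
simulate_reads <- function(ref, composition, config, sample_id,
                           n_reads = config$reads_per_sample, seed) {
  scheme <- ref$scheme
  L <- config$read_length
  tl <- scheme$tag_length
  stopifnot(L >= tl + 2L)
  withr::with_seed(seed, {
    species_ids <- vapply(ref$genomes, `[[`, "", "species_id")
    all_sp <- c(species_ids, "decoy")
    n_tags <- lengths(ref$windows)[all_sp]
    w <- composition[species_ids] * n_tags[species_ids]
    is_cont <- stats::runif(n_reads) < config$contaminant_rate
    src <- character(n_reads)
    src[!is_cont] <- sample(species_ids, sum(!is_cont), replace = TRUE,
                            prob = w)
    src[is_cont] <- "decoy"
    flat_win <- unlist(ref$windows[all_sp], use.names = FALSE)
    first <- stats::setNames(cumsum(c(0L, n_tags[-length(n_tags)])), all_sp)
    tag_idx <- floor(stats::runif(n_reads) * n_tags[src]) + 1L
    win <- flat_win[first[src] + tag_idx]
    flip <- stats::runif(n_reads) < 0.5
    win[flip] <- revcomp(win[flip])
    # motif-free padding, then plant the window at a random offset
    max_off <- L - tl
    off <- sample.int(max_off - 1L, n_reads, replace = TRUE)  # 1..max_off-1
    m <- matrix(sample(BASES, n_reads * L, replace = TRUE),
                nrow = n_reads, ncol = L)
    tag_m <- matrix(unlist(strsplit(win, ""), use.names = FALSE),
                    nrow = n_reads, ncol = tl, byrow = TRUE)
    plant <- function(m) {
      for (k in seq_len(tl)) {
        m[cbind(seq_len(n_reads), off + k)] <- tag_m[, k]
      }
      m
    }
    m <- plant(m)
    # rejection: a read must contain its planted site and no spurious one
    reads_chr <- collapse_rows(m)
    bad <- which(site_counts(reads_chr, scheme) != 1L)
    iter <- 0L
    while (length(bad) && iter < 50L) {
      for (i in bad) {
        keep <- (off[i] + 1L):(off[i] + tl)
        m[i, -keep] <- sample(BASES, L - tl, replace = TRUE)
      }
      reads_chr <- collapse_rows(m[bad, , drop = FALSE])
      bad <- bad[site_counts(reads_chr, scheme) != 1L]
      iter <- iter + 1L
    }
    if (length(bad)) stop("failed to pad reads without spurious sites")
    sub <- apply_substitutions(m, config$base_error_rate)
    m <- sub$m
    idxN <- which(stats::runif(length(m)) < config$n_rate)
    m[idxN] <- "N"
    bases <- collapse_rows(m)
    err_pos <- flat_to_positions(sub$idx, n_reads)
    n_pos <- flat_to_positions(idxN, n_reads)
    # two-state quality model
    low <- stats::runif(n_reads * L) < config$lowq_prob
    phred <- round(stats::rnorm(n_reads * L,
                                ifelse(low, config$quality_low,
                                       config$quality_high), 2))
    phred <- pmin(pmax(phred, 2L), 40L)
    qchars <- strsplit(rawToChar(as.raw(33:93)), "")[[1]]
    qm <- matrix(qchars[phred + 1L], nrow = n_reads, ncol = L)
    quals <- collapse_rows(qm)
    read_id <- sprintf("%s_r%06d", sample_id, seq_len(n_reads))
    list(reads = data.frame(read_id = read_id, bases = bases, quals = quals,
                            stringsAsFactors = FALSE),
         provenance = data.frame(
           read_id = read_id,
           species = src,
           tag = canonical_tag(win),
           n_errors = lengths(err_pos),
           n_unknown = lengths(n_pos),
           error_positions = vapply(err_pos, paste, "", collapse = ","),
           stringsAsFactors = FALSE))
  })
}

# Number of recognition sites (both strands) per read.
site_counts <- function(reads, scheme) {
  count <- function(pat) {
    g <- gregexpr(sprintf("(?=%s)", motif_regex(pat)), reads, perl = TRUE)
    vapply(g, function(x) if (x[1] == -1L) 0L else length(x), integer(1))
  }
  n <- count(scheme$motif)
  rc <- revcomp(scheme$motif)
  if (!identical(rc, scheme$motif)) n <- n + count(rc)
  n
}

# Flat matrix indices -> per-row sorted column positions (1-based).
flat_to_positions <- function(idx, n_rows) {
  out <- vector("list", n_rows)
  if (length(idx)) {
    row <- (idx - 1L) %% n_rows + 1L
    col <- (idx - 1L) %/% n_rows + 1L
    hit <- split(col, row)
    out[as.integer(names(hit))] <- lapply(hit, sort)
  }
  out
}

#' Simulate a complete mock study
#'
#' Reference set, compositions and per-sample reads, with full ground truth.
#' With `out_dir` set, writes the reference FASTA (decoy included), one FASTQ
#' per sample, a sample metadata TSV, the true composition matrix and the
#' per-read provenance table.
#'
#' @param config A [synth_config()].
#' @param scheme A [digest_scheme()].
#' @param out_dir Optional output directory.
#' @return List with `ref`, `truth` (composition, groups, provenance,
#'   differentials), `samples` (per-sample read data frames) and, when
#'   written, `paths`.
#' @export
simulate_study <- function(config, scheme = digest_scheme(), out_dir = NULL) {
  ref <- generate_reference_set(config, scheme)
  comp <- generate_composition(config,
                               species_ids = ref$taxonomy$species_id)
  sample_ids <- rownames(comp$composition)
  samples <- vector("list", length(sample_ids))
  names(samples) <- sample_ids
  prov <- vector("list", length(sample_ids))
  for (i in seq_along(sample_ids)) {
    sim <- simulate_reads(ref, comp$composition[i, ], config,
                          sample_id = sample_ids[i],
                          seed = derive_seed(config$seed, 100L + i))
    samples[[i]] <- sim$reads
    sim$provenance$sample_id <- sample_ids[i]
    prov[[i]] <- sim$provenance
  }
  truth <- list(composition = comp$composition, groups = comp$groups,
                provenance = do.call(rbind, prov),
                differentials = comp$differentials)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fasta <- file.path(out_dir, "references.fasta")
    write_genomes(c(ref$genomes, list(ref$decoy)), fasta)
    fastq <- stats::setNames(
      file.path(out_dir, paste0(sample_ids, ".fastq")), sample_ids)
    for (s in sample_ids) write_fastq(samples[[s]], fastq[[s]])
    meta <- file.path(out_dir, "metadata.tsv")
    utils::write.table(
      data.frame(sample_id = sample_ids, fastq = unname(fastq),
                 group = unname(comp$groups[sample_ids])),
      meta, sep = "\t", quote = FALSE, row.names = FALSE)
    comp_path <- file.path(out_dir, "truth_composition.tsv")
    utils::write.table(data.frame(sample = sample_ids, comp$composition,
                                  check.names = FALSE),
                       comp_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    prov_path <- file.path(out_dir, "truth_provenance.tsv")
    utils::write.table(truth$provenance, prov_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tax_path <- file.path(out_dir, "taxonomy.tsv")
    utils::write.table(ref$taxonomy, tax_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
    paths <- list(fasta = fasta, fastq = fastq, metadata = meta,
                  truth_composition = comp_path, truth_provenance = prov_path,
                  taxonomy = tax_path)
  }
  list(ref = ref, truth = truth, samples = samples, paths = paths)
}
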