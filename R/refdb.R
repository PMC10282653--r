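#' Extract iso-length tags from a reference genome
#'
#' Performs the in-silico counterpart of a type IIB digest: every recognition
#' site that is fully flanked by `arm5`/`arm3` bases within a single contig
#' yields one tag of `scheme$tag_length` bases, reported in canonical
#' orientation. Windows containing `N` are discarded, as are sites too close
#' to a contig end.
#'
#' @param genome A list with elements `species_id` (string) and `contigs`
#'   (character vector of nucleotide strings).
#' @param scheme A [digest_scheme()].
#' @return Character vector of canonical tags (a multiset: repeated loci give
#'   repeated entries).
#' @export
extract_tags <- function(genome, scheme = digest_scheme()) {
  stopifnot(is.list(genome), !is.null(genome$contigs))
  out <- lapply(genome$contigs, contig_tags, scheme = scheme)
  unlist(out, use.names = FALSE)
}

contig_tags <- function(seq, scheme) {
  sites <- scan_recognition_sites(seq, scheme)
  if (nrow(sites) == 0L) return(character(0))
  n <- nchar(seq)
  plus <- sites$strand == "+"
  # in motif orientation the 5' arm of a minus-strand site lies downstream
  # on the plus strand; canonicalization makes the emitted key orientation-free
  start0 <- ifelse(plus, sites$offset - scheme$arm5, sites$offset - scheme$arm3)
  end0 <- start0 + scheme$tag_length
  ok <- start0 >= 0L & end0 <= n
  if (!any(ok)) return(character(0))
  w <- substring(seq, start0[ok] + 1L, end0[ok])
  w <- w[!grepl("N", w, fixed = TRUE)]
  canonical_tag(w)
}

#' Build a species-unique tag database
#'
#' Digests every reference genome in silico and keeps only tags that occur in
#' exactly one species. Tags repeated at several loci of one genome are stored
#' once; tags shared by two or more species are excluded entirely. The
#' per-species count of distinct unique tags is the theoretical tag count
#' \eqn{T_i} used for coverage normalization when profiling.
#'
#' @param genomes List of genomes, each a list with `species_id` and `contigs`.
#' @param scheme A [digest_scheme()].
#' @return An object of class `tag_db`: a list with elements
#'   \describe{
#'     \item{scheme}{the digest scheme used}
#'     \item{tags}{data frame `tag`, `species_id` (unique tags only)}
#'     \item{T}{named integer vector of theoretical tag counts per species
#'       (species with zero unique tags retained with value 0)}
#'     \item{report}{build report: species count, shared tags removed,
#'       species flagged with zero unique tags}
#'   }
#' @export
build_tag_db <- function(genomes, scheme = digest_scheme()) {
  stopifnot(length(genomes) >= 1L)
  ids <- vapply(genomes, function(g) as.character(g$species_id), character(1))
  if (any(!nzchar(ids))) stop("every genome needs a non-empty species_id")
  if (anyDuplicated(ids)) {
    stop("duplicate species_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  per <- lapply(genomes, function(g) unique(extract_tags(g, scheme)))
  tag <- unlist(per, use.names = FALSE)
  sp <- rep(ids, lengths(per))
  shared <- unique(tag[duplicated(tag)])  # within-species dups already removed
  keep <- !(tag %in% shared)
  tags <- data.frame(tag = tag[keep], species_id = sp[keep],
                     stringsAsFactors = FALSE)
  o <- order(tags$species_id, tags$tag)
  tags <- tags[o, , drop = FALSE]
  rownames(tags) <- NULL
  T_counts <- table(factor(tags$species_id, levels = ids))
  T_counts <- stats::setNames(as.integer(T_counts), ids)
  structure(
    list(scheme = scheme,
         tags = tags,
         T = T_counts,
         report = list(n_species = length(ids),
                       n_unique_tags = nrow(tags),
                       n_shared_tags_removed = length(shared),
                       zero_tag_species = ids[T_counts == 0L])),
    class = "tag_db"
  )
}

#' @export
print.tag_db <- function(x, ...) {
  cat(sprintf("tag_db: %d species, %d unique %d-bp tags (%d shared tags removed)\n",
              x$report$n_species, x$report$n_unique_tags,
              x$scheme$tag_length, x$report$n_shared_tags_removed))
  if (length(x$report$zero_tag_species)) {
    cat("species with zero unique tags:",
        paste(x$report$zero_tag_species, collapse = ", "), "\n")
  }
  invisible(x)
}

DB_SCHEMA_VERSION <- "1.0"

#' Write / read a tag database
#'
#' The database is stored as a plain TSV of (tag, species_id) pairs plus a
#' JSON sidecar carrying the digest scheme, the per-species theoretical tag
#' counts and the build report. `read_tag_db()` reproduces the database
#' bit-exactly and refuses sidecars with an unknown schema version.
#'
#' @param db A `tag_db`.
#' @param dir Output directory (created if missing).
#' @return `write_tag_db()` returns `dir` invisibly; `read_tag_db()` returns
#'   the `tag_db`.
#' @export
write_tag_db <- function(db, dir) {
  stopifnot(inherits(db, "tag_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(db$tags, file.path(dir, "tags.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(schema_version = DB_SCHEMA_VERSION,
               scheme = unclass(db$scheme),
               T = as.list(db$T),
               report = db$report)
  jsonlite::write_json(side, file.path(dir, "db.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_tag_db
#' @export
read_tag_db <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "db.json"), simplifyVector = TRUE)
  if (!identical(side$schema_version, DB_SCHEMA_VERSION)) {
    stop("unsupported tag_db schema version: ", side$schema_version)
  }
  scheme <- digest_scheme(arm5 = side$scheme$arm5, arm3 = side$scheme$arm3,
                          motif = side$scheme$motif)
  tags <- utils::read.table(file.path(dir, "tags.tsv"), sep = "\t",
                            header = TRUE, colClasses = "character")
  T_counts <- stats::setNames(as.integer(unlist(side$T)), names(side$T))
  report <- side$report
  report$zero_tag_species <- as.character(report$zero_tag_species)
  structure(list(scheme = scheme, tags = tags, T = T_counts, report = report),
            class = "tag_db")
}

#' Read reference genomes from FASTA
#'
#' Record IDs are parsed as `"<species_id>|<contig_id>"`; contigs sharing a
#' species id are grouped into one genome. Alternatively a two-column manifest
#' (`path`, `species_id`) can point at one FASTA file per species.
#'
#' @param fasta Path to a multi-record FASTA file.
#' @param manifest Optional data frame (or TSV path) with columns `path` and
#'   `species_id`; overrides `fasta`.
#' @return List of genomes (lists with `species_id`, `contigs`).
#' @export
read_genomes <- function(fasta = NULL, manifest = NULL) {
  if (!is.null(manifest)) {
    if (is.character(manifest)) {
      manifest <- utils::read.table(manifest, sep = "\t", header = TRUE,
                                    colClasses = "character")
    }
    stopifnot(all(c("path", "species_id") %in% names(manifest)))
    return(lapply(seq_len(nrow(manifest)), function(i) {
      x <- Biostrings::readDNAStringSet(manifest$path[i])
      list(species_id = manifest$species_id[i], contigs = as.character(x))
    }))
  }
  x <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(x))
  species <- sub("\\|.*$", "", ids)
  seqs <- as.character(x)
  out <- lapply(unique(species), function(sp) {
    list(species_id = sp, contigs = unname(seqs[species == sp]))
  })
  out
}

#' Write reference genomes to FASTA
#'
#' Records are named `"<species_id>|<contig_index>"` so that [read_genomes()]
#' round-trips the set.
#'
#' @param genomes List of genomes.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genomes <- function(genomes, path) {
  seqs <- unlist(lapply(genomes, `[[`, "contigs"), use.names = FALSE)
  nm <- unlist(lapply(genomes, function(g) {
    paste0(g$species_id, "|", seq_along(g$contigs))
  }), use.names = FALSE)
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- nm
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
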