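#' Quality-control policy for sequencing reads
#'
#' Clean reads must (1) contain at most `max_unknown_frac` unknown bases,
#' (2) have at most `max_lowq_frac` of their bases below Phred `q_threshold`,
#' and (3) when `require_site` is set, contain the recognition motif on either
#' strand. Both proportion cuts are strict: a read exactly at the boundary is
#' kept.
#'
#' @param max_unknown_frac Maximum tolerated fraction of `N` bases.
#' @param q_threshold Phred score below which a base counts as low-quality.
#' @param max_lowq_frac Maximum tolerated fraction of low-quality bases.
#' @param require_site Drop reads without a recognition site?
#' @return An object of class `qc_policy`.
#' @export
qc_policy <- function(max_unknown_frac = 0.08, q_threshold = 30L,
                      max_lowq_frac = 0.20, require_site = TRUE) {
  stopifnot(max_unknown_frac >= 0, max_unknown_frac <= 1,
            max_lowq_frac >= 0, max_lowq_frac <= 1, q_threshold >= 0)
  structure(list(max_unknown_frac = max_unknown_frac,
                 q_threshold = as.integer(q_threshold),
                 max_lowq_frac = max_lowq_frac,
                 require_site = isTRUE(require_site)),
            class = "qc_policy")
}

#' Read a FASTQ file into a data frame
#'
#' Phred+33 quality encoding is assumed. Gzip-compressed files are handled
#' transparently.
#'
#' @param path FASTQ path.
#' @return Data frame with columns `read_id`, `bases`, `quals`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             bases = unname(as.character(x)),
             quals = unname(as.character(S4Vectors::mcols(x)$qualities)),
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads Data frame with `read_id`, `bases`, `quals` (Phred+33).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$bases,
                           "+", reads$quals))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# Number of quality characters strictly below Phred `q` (Phred+33).
count_below_q <- function(quals, q) {
  if (q <= 0L) return(integer(length(quals)))
  hi <- min(33L + q - 1L, 126L)
  cls <- sprintf("[\\x21-\\x%02X]", hi)
  nchar(quals) - nchar(gsub(cls, "", quals, perl = TRUE))
}

#' Filter reads by unknown-base content, quality and site presence
#'
#' Applies the three clean-read conditions in a fixed order — unknown bases,
#' then base quality, then recognition-site presence — and reports the first
#' failing reason per read. The order affects only the reason labels, not
#' which reads are kept.
#'
#' @param reads Data frame with columns `read_id`, `bases`, `quals`.
#' @param policy A [qc_policy()].
#' @param scheme A [digest_scheme()] (for the site check).
#' @return Data frame `read_id`, `keep` (logical), `reason` (one of `pass`,
#'   `too_many_N`, `low_quality`, `no_site`).
#' @export
qc_filter <- function(reads, policy = qc_policy(), scheme = digest_scheme()) {
  n <- nrow(reads)
  len <- nchar(reads$bases)
  bad <- len != nchar(reads$quals)
  if (any(bad)) {
    stop("base/quality length mismatch for read(s): ",
         paste(utils::head(reads$read_id[bad], 5L), collapse = ", "))
  }
  reason <- rep("pass", n)
  if (policy$require_site) {
    has_site <- grepl(motif_regex(scheme$motif), reads$bases)
    rc <- revcomp(scheme$motif)
    if (!identical(rc, scheme$motif)) {
      has_site <- has_site | grepl(motif_regex(rc), reads$bases)
    }
    reason[!has_site] <- "no_site"
  }
  n_low <- count_below_q(reads$quals, policy$q_threshold)
  reason[n_low > policy$max_lowq_frac * len] <- "low_quality"
  n_unknown <- len - nchar(gsub("N", "", reads$bases, fixed = TRUE))
  reason[n_unknown > policy$max_unknown_frac * len] <- "too_many_N"
  data.frame(read_id = reads$read_id, keep = reason == "pass",
             reason = reason, stringsAsFactors = FALSE)
}

#' Extract the tag carried by each read
#'
#' Locates the first recognition motif (leftmost plus-strand match first,
#' then leftmost minus-strand match). If the read holds the full
#' `arm5`/`arm3` flanks around that motif (in motif orientation), the
#' canonical tag is returned; otherwise `NA`. One tag per read: the library
#' geometry puts a single excised fragment in each read.
#'
#' @param bases Character vector of read sequences (or a data frame with a
#'   `bases` column).
#' @param scheme A [digest_scheme()].
#' @return Character vector of canonical tags, `NA` where no complete tag is
#'   present.
#' @export
extract_read_tag <- function(bases, scheme = digest_scheme()) {
  if (is.data.frame(bases)) bases <- bases$bases
  n <- length(bases)
  if (n == 0L) return(character(0))
  plook <- sprintf("(?=%s)", motif_regex(scheme$motif))
  mlook <- sprintf("(?=%s)", motif_regex(revcomp(scheme$motif)))
  pp <- as.integer(regexpr(plook, bases, perl = TRUE))
  mp <- as.integer(regexpr(mlook, bases, perl = TRUE))
  use_plus <- pp > 0L
  off <- ifelse(use_plus, pp, mp)           # 1-based motif start
  start1 <- ifelse(use_plus, off - scheme$arm5, off - scheme$arm3)
  end1 <- start1 + scheme$tag_length - 1L
  ok <- off > 0L & start1 >= 1L & end1 <= nchar(bases)
  tag <- rep(NA_character_, n)
  if (any(ok)) tag[ok] <- canonical_tag(substr(bases[ok], start1[ok], end1[ok]))
  tag
}

#' QC and tag extraction for one sample
#'
#' Convenience composition of [qc_filter()] and [extract_read_tag()].
#'
#' @param reads FASTQ path or data frame from [read_fastq()].
#' @param policy A [qc_policy()].
#' @param scheme A [digest_scheme()].
#' @return List with `tags` (data frame `read_id`, `tag` for clean reads that
#'   yielded a complete tag) and `qc` (named counts per reason, plus `total`).
#' @export
qc_sample <- function(reads, policy = qc_policy(), scheme = digest_scheme()) {
  if (is.character(reads)) reads <- read_fastq(reads)
  res <- qc_filter(reads, policy, scheme)
  counts <- table(factor(res$reason,
                         levels = c("pass", "no_site", "too_many_N", "low_quality")))
  clean <- reads[res$keep, , drop = FALSE]
  tag <- extract_read_tag(clean$bases, scheme)
  keep <- !is.na(tag)
  list(tags = data.frame(read_id = clean$read_id[keep], tag = tag[keep],
                         stringsAsFactors = FALSE),
       qc = c(as.list(counts), total = nrow(reads)))
}
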