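#' Digest scheme for a type IIB restriction enzyme
#'
#' A type IIB enzyme such as BcgI cleaves both strands on both sides of a
#' bipartite recognition site, excising an iso-length fragment. The scheme
#' describes the recognition motif (fixed bases plus `N` wildcards) and the
#' number of flanking bases retained on each side of the motif, which together
#' fix the tag length. The default is the BcgI site CGA(N6)TGC with 10-bp arms,
#' i.e. 32-bp tags.
#'
#' @param arm5 Integer, bases retained upstream (5') of the motif.
#' @param arm3 Integer, bases retained downstream (3') of the motif.
#' @param motif Recognition motif over `A C G T N`; `N` positions match any
#'   unambiguous base (but never a literal `N` in the target sequence).
#' @return An object of class `digest_scheme`.
#' @examples
#' digest_scheme()            # BcgI, 32-bp tags
#' digest_scheme(arm5 = 12, arm3 = 12)
#' @export
digest_scheme <- function(arm5 = 10L, arm3 = 10L, motif = "CGANNNNNNTGC") {
  arm5 <- as.integer(arm5)
  arm3 <- as.integer(arm3)
  stopifnot(length(arm5) == 1L, length(arm3) == 1L, arm5 >= 0L, arm3 >= 0L,
            length(motif) == 1L, grepl("^[ACGTN]+$", motif))
  structure(
    list(motif = motif,
         motif_length = nchar(motif),
         arm5 = arm5,
         arm3 = arm3,
         tag_length = arm5 + nchar(motif) + arm3),
    class = "digest_scheme"
  )
}

#' @export
print.digest_scheme <- function(x, ...) {
  cat(sprintf("digest_scheme: %s (%d bp) + arms %d/%d -> %d-bp tags\n",
              x$motif, x$motif_length, x$arm5, x$arm3, x$tag_length))
  invisible(x)
}

#' Reverse complement of nucleotide strings
#'
#' Vectorized over a character vector of sequences over `A C G T N`.
#'
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical orientation of tags
#'
#' The canonical form of a tag is the lexicographic minimum of the sequence
#' and its reverse complement. Canonicalization removes the strand ambiguity
#' between genome digestion and read-derived tags: a fragment read in either
#' orientation maps to the same key.
#'
#' @param x Character vector of tag sequences.
#' @return Character vector of canonical tags.
#' @export
canonical_tag <- function(x) {
  if (length(x) == 0L) return(character(0))
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

# Regex for the motif on the plus strand; wildcards match unambiguous bases
# only (a genomic N can never be matched exactly by a read).
motif_regex <- function(motif) gsub("N", "[ACGT]", motif, fixed = TRUE)

# All 0-based start positions of `motif` in `seq`, overlapping matches
# included (zero-width lookahead).
motif_starts <- function(seq, motif) {
  if (nchar(seq) < nchar(motif)) return(integer(0))
  pat <- sprintf("(?=%s)", motif_regex(motif))
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Scan a sequence for recognition sites
#'
#' Reports every position where the plus strand matches the recognition motif
#' or its reverse complement, overlapping matches included. Offsets are
#' 0-based positions of the motif's first base on the plus strand.
#'
#' @param sequence A single nucleotide string over `A C G T N`.
#' @param scheme A [digest_scheme()].
#' @return A data frame with columns `offset` (0-based integer) and `strand`
#'   (`"+"` or `"-"`), sorted by offset.
#' @examples
#' scan_recognition_sites("CGAAAAAAATGC", digest_scheme())
#' @export
scan_recognition_sites <- function(sequence, scheme = digest_scheme()) {
  stopifnot(length(sequence) == 1L)
  plus <- motif_starts(sequence, scheme$motif)
  rc_motif <- revcomp(scheme$motif)
  minus <- if (identical(rc_motif, scheme$motif)) integer(0)
           else motif_starts(sequence, rc_motif)
  out <- data.frame(offset = c(plus, minus),
                    strand = rep(c("+", "-"), c(length(plus), length(minus))),
                    stringsAsFactors = FALSE)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
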