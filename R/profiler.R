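#' Assign canonical tags to species
#'
#' Exact-match lookup of tags against the species-unique database. For each
#' species, `s` counts tag occurrences (reads) and `t` counts distinct tags
#' seen at least once. Tags absent from the database are tallied as
#' unassigned.
#'
#' @param tags Character vector of canonical tags (scheme length).
#' @param db A `tag_db`.
#' @return List with integer vectors `s` and `t` (named by species, zeros for
#'   undetected species) and scalar `unassigned`.
#' @export
assign_tags <- function(tags, db) {
  stopifnot(inherits(db, "tag_db"))
  if (length(tags) && any(nchar(tags) != db$scheme$tag_length)) {
    stop("tag length differs from scheme tag_length (",
         db$scheme$tag_length, " bp): digest scheme mismatch?")
  }
  ids <- names(db$T)
  hit <- match(tags, db$tags$tag)
  sp <- db$tags$species_id[hit]
  s <- table(factor(sp, levels = ids))
  seen <- unique(tags[!is.na(hit)])
  sp_seen <- db$tags$species_id[match(seen, db$tags$tag)]
  t <- table(factor(sp_seen, levels = ids))
  list(s = stats::setNames(as.integer(s), ids),
       t = stats::setNames(as.integer(t), ids),
       unassigned = sum(is.na(hit)))
}

#' G score: geometric-mean false-positive control
#'
#' For species *i* with `s` reads on its unique tags and `t` distinct unique
#' tags observed, the G score is `sqrt(s * t)` — the geometric mean of read
#' support and tag breadth. A species hit many times on a single tag (likely
#' a spurious match) scores low; genuine presence spreads reads across many
#' tags.
#'
#' @param s Integer vector, reads assigned per species.
#' @param t Integer vector, distinct tags observed per species.
#' @param exponent Exponent of the mean; 0.5 is the geometric mean of `s*t`.
#' @return Numeric vector of G scores.
#' @examples
#' g_score(25, 1)  # 5
#' g_score(5, 5)   # 5
#' @export
g_score <- function(s, t, exponent = 0.5) {
  stopifnot(all(s >= 0), all(t >= 0))
  (as.numeric(s) * as.numeric(t))^exponent
}

#' Remove species below the G-score threshold
#'
#' Species with `g_score < threshold` are dropped as likely false positives;
#' a species exactly at the threshold is retained.
#'
#' @param profile Data frame with at least a `g_score` column.
#' @param threshold G-score threshold (default 5).
#' @return The filtered profile; removed rows are attached as
#'   `attr(, "dropped")`.
#' @export
apply_g_filter <- function(profile, threshold = 5) {
  keep <- profile$g_score >= threshold
  out <- profile[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- profile[!keep, , drop = FALSE]
  out
}

#' Coverage-normalized relative abundance
#'
#' Per surviving species, coverage is `s / T` — the average read depth over
#' its theoretical unique tags, a depth-independent proxy for the number of
#' genome copies present. Relative abundance divides each coverage by the sum
#' of coverages over all surviving species, so that abundances sum to one.
#' The `T` normalization is what distinguishes this estimator from naive read
#' counting: species with few unique tags are not penalized.
#'
#' @param profile Data frame with columns `s` and `T` (one row per surviving
#'   species).
#' @return The profile with `coverage` and `rel_abundance` columns added.
#' @export
relative_abundance <- function(profile) {
  if (nrow(profile) == 0L) {
    profile$coverage <- numeric(0)
    profile$rel_abundance <- numeric(0)
    return(profile)
  }
  if (any(profile$T <= 0L)) {
    stop("surviving species with T = 0: tag database inconsistency for ",
         paste(profile$species_id[profile$T <= 0L], collapse = ", "))
  }
  profile$coverage <- profile$s / profile$T
  profile$rel_abundance <- profile$coverage / sum(profile$coverage)
  profile
}

#' Profile a sample from its tag stream
#'
#' Composition of [assign_tags()], [g_score()], [apply_g_filter()] and
#' [relative_abundance()].
#'
#' @param tags Character vector of canonical tags.
#' @param db A `tag_db`.
#' @param g_threshold G-score threshold.
#' @param sample_id Optional sample label stored on the result.
#' @return A `species_profile`: data frame with columns `species_id`, `s`,
#'   `t`, `T`, `g_score`, `coverage`, `rel_abundance` (survivors only),
#'   with attributes `unassigned`, `n_tags`, `dropped` and `sample_id`.
#' @export
profile_tags <- function(tags, db, g_threshold = 5, sample_id = NA_character_) {
  a <- assign_tags(tags, db)
  detected <- a$s > 0L
  raw <- data.frame(species_id = names(db$T)[detected],
                    s = a$s[detected], t = a$t[detected],
                    T = unname(db$T[detected]),
                    stringsAsFactors = FALSE)
  raw$g_score <- g_score(raw$s, raw$t)
  prof <- apply_g_filter(raw, g_threshold)
  dropped <- attr(prof, "dropped")
  prof <- relative_abundance(prof)
  structure(prof,
            unassigned = a$unassigned,
            n_tags = length(tags),
            dropped = dropped,
            sample_id = sample_id,
            class = c("species_profile", "data.frame"))
}

#' Profile a sample from raw reads
#'
#' Full per-sample pipeline: FASTQ parsing, clean-read filtering, tag
#' extraction, database assignment, G-score filtering and abundance
#' estimation.
#'
#' @param reads FASTQ path or data frame from [read_fastq()].
#' @param db A `tag_db`.
#' @param policy A [qc_policy()].
#' @param g_threshold G-score threshold.
#' @param sample_id Sample label (defaults to the FASTQ basename).
#' @return A `species_profile` (see [profile_tags()]) with the QC reason
#'   counts attached as `attr(, "qc")`.
#' @export
profile_sample <- function(reads, db, policy = qc_policy(), g_threshold = 5,
                           sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- if (is.character(reads)) {
      sub("\\.(fastq|fq)(\\.gz)?$", "", basename(reads))
    } else NA_character_
  }
  qs <- qc_sample(reads, policy, db$scheme)
  prof <- profile_tags(qs$tags$tag, db, g_threshold, sample_id = sample_id)
  attr(prof, "qc") <- qs$qc
  prof
}

#' Write a species profile as TSV
#'
#' @param profile A `species_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
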