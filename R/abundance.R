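#' Samples-by-taxa abundance table
#'
#' Container for a study-level table of relative abundances: a samples × taxa
#' matrix whose rows sum to one (or are all zero), an optional parallel
#' integer matrix of read counts `s`, group labels, and a species taxonomy
#' (genus, phylum).
#'
#' @param values Numeric matrix, samples in rows, taxa in columns; rows must
#'   sum to 1 (within 1e-9) or be all zero.
#' @param counts Optional integer matrix of read counts, same shape.
#' @param groups Named character vector or factor mapping sample -> group.
#' @param taxonomy Optional data frame with columns `species_id`, `genus`,
#'   `phylum`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, counts = NULL, groups = NULL,
                            taxonomy = NULL) {
  values <- as.matrix(values)
  stopifnot(!is.null(rownames(values)), !is.null(colnames(values)),
            all(values >= 0))
  rs <- rowSums(values)
  if (any(rs > 0 & abs(rs - 1) > 1e-9)) {
    stop("abundance rows must sum to 1 (or be all zero)")
  }
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    stopifnot(identical(dim(counts), dim(values)), all(counts >= 0))
  }
  if (!is.null(groups)) {
    groups <- stats::setNames(as.character(groups), names(groups))
    stopifnot(all(rownames(values) %in% names(groups)))
    groups <- groups[rownames(values)]
  }
  structure(list(values = values, counts = counts, groups = groups,
                 taxonomy = taxonomy,
                 samples = rownames(values), taxa = colnames(values)),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$groups)) {
    tab <- table(x$groups)
    cat("; groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Merge per-sample profiles into an abundance table
#'
#' Species absent from a sample receive relative abundance 0 (not missing).
#'
#' @param profiles Named list of `species_profile` objects (names = sample
#'   ids; unnamed lists fall back to the profiles' `sample_id` attribute).
#' @param groups Named vector mapping sample -> group label.
#' @param taxonomy Optional taxonomy data frame (`species_id`, `genus`,
#'   `phylum`).
#' @return An `abundance_table` with both `values` (relative abundance) and
#'   `counts` (reads `s`).
#' @export
merge_profiles <- function(profiles, groups = NULL, taxonomy = NULL) {
  if (is.null(names(profiles))) {
    names(profiles) <- vapply(profiles, function(p) attr(p, "sample_id"),
                              character(1))
  }
  taxa <- sort(unique(unlist(lapply(profiles, function(p) p$species_id))))
  n <- length(profiles)
  values <- matrix(0, n, length(taxa),
                   dimnames = list(names(profiles), taxa))
  counts <- matrix(0L, n, length(taxa),
                   dimnames = list(names(profiles), taxa))
  for (i in seq_len(n)) {
    p <- profiles[[i]]
    j <- match(p$species_id, taxa)
    values[i, j] <- p$rel_abundance
    counts[i, j] <- p$s
  }
  abundance_table(values, counts = counts, groups = groups,
                  taxonomy = taxonomy)
}

#' Write / read an abundance table
#'
#' TSV with samples in rows; the group label is carried in a `group` column.
#'
#' @param table An `abundance_table`.
#' @param path TSV path.
#' @return `path` invisibly, or the re-read `abundance_table`.
#' @export
write_abundance_table <- function(table, path) {
  df <- data.frame(sample = table$samples,
                   group = if (is.null(table$groups)) NA else table$groups,
                   table$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_table
#' @export
read_abundance_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  values <- as.matrix(df[, setdiff(names(df), c("sample", "group")),
                         drop = FALSE])
  rownames(values) <- df$sample
  groups <- if (all(is.na(df$group))) NULL else
    stats::setNames(as.character(df$group), df$sample)
  abundance_table(values, groups = groups)
}
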