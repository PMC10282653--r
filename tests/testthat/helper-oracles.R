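# Independent oracles used to cross-check production code paths.

# Naive position-by-position motif scan over character vectors; no regex.
brute_scan <- function(seq, scheme = digest_scheme()) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  hits <- function(motif) {
    pat <- strsplit(motif, "")[[1]]
    ml <- length(pat)
    if (n < ml) return(integer(0))
    ok <- rep(TRUE, n - ml + 1L)
    for (k in seq_len(ml)) {
      w <- chars[k:(n - ml + k)]
      ok <- ok & if (pat[k] == "N") w %in% c("A", "C", "G", "T") else w == pat[k]
    }
    which(ok) - 1L
  }
  plus <- hits(scheme$motif)
  rcm <- revcomp(scheme$motif)
  minus <- if (identical(rcm, scheme$motif)) integer(0) else hits(rcm)
  out <- data.frame(offset = c(plus, minus),
                    strand = rep(c("+", "-"), c(length(plus), length(minus))),
                    stringsAsFactors = FALSE)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Pairwise-comparison AUC: fraction of (positive, negative) pairs where the
# positive scores higher, ties counted half.
auc_brute <- function(scores, is_pos) {
  p <- scores[is_pos]
  q <- scores[!is_pos]
  tot <- 0
  for (a in p) tot <- tot + sum(a > q) + 0.5 * sum(a == q)
  tot / (length(p) * length(q))
}

# All permutations of a vector (n <= 7).
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# PERMANOVA pseudo-F computed directly from the squared-distance matrix.
pseudo_f_direct <- function(d, groups) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  g <- factor(groups)
  a <- nlevels(g)
  sst <- sum(D2) / (2 * n)
  ssw <- 0
  for (lev in levels(g)) {
    m <- g == lev
    ssw <- ssw + sum(D2[m, m]) / (2 * sum(m))
  }
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
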