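#' Aggregate an abundance table to a taxonomic rank
#'
#' Sums species abundances (and counts) over shared genus or phylum labels;
#' rows still sum to one. `rank = "species"` returns the table unchanged.
#'
#' @param table An `abundance_table` whose taxonomy covers every taxon.
#' @param rank One of `"species"`, `"genus"`, `"phylum"`.
#' @return An `abundance_table` at the requested rank.
#' @export
aggregate_to_rank <- function(table, rank = c("species", "genus", "phylum")) {
  rank <- match.arg(rank)
  if (rank == "species") return(table)
  tax <- table$taxonomy
  if (is.null(tax)) stop("table has no taxonomy")
  lab <- tax[[rank]][match(table$taxa, tax$species_id)]
  if (anyNA(lab)) {
    stop("species missing from taxonomy: ",
         paste(utils::head(table$taxa[is.na(lab)], 10L), collapse = ", "))
  }
  agg <- function(m) t(rowsum(t(m), lab))
  values <- agg(table$values)
  counts <- if (is.null(table$counts)) NULL else agg(table$counts)
  abundance_table(values[, sort(colnames(values)), drop = FALSE],
                  counts = if (is.null(counts)) NULL else
                    counts[, sort(colnames(counts)), drop = FALSE],
                  groups = table$groups, taxonomy = tax)
}

#' Per-taxon Kruskal-Wallis tests
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square approximation
#' (df = groups - 1) for every taxon, with per-group mean relative abundances
#' attached. P-values are reported raw, without multiplicity adjustment.
#' A taxon constant across all samples gets `H = 0`, `p = 1`.
#'
#' @param table An `abundance_table` with group labels.
#' @param rank Label stored in the result (informational).
#' @return Data frame: `taxon`, `rank`, one `mean_<group>` column per group,
#'   `H`, `p`, `enriched_in` (group with the larger mean).
#' @export
kruskal_wallis_per_taxon <- function(table, rank = "species") {
  g <- factor(table$groups)
  stopifnot(nlevels(g) >= 2L)
  values <- table$values
  means <- apply(values, 2, function(v) tapply(v, g, mean))
  stat <- apply(values, 2, function(v) {
    if (length(unique(v)) == 1L) return(c(H = 0, p = 1))
    kw <- stats::kruskal.test(v, g)
    c(H = unname(kw$statistic), p = kw$p.value)
  })
  out <- data.frame(taxon = colnames(values), rank = rank,
                    t(means), H = stat["H", ], p = stat["p", ],
                    enriched_in = levels(g)[apply(means, 2, which.max)],
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[3:(2 + nlevels(g))] <- paste0("mean_", levels(g))
  rownames(out) <- NULL
  out
}

# Regularized two-class LDA discriminant direction (unit length).
lda_direction <- function(x1, x2) {
  d <- colMeans(x1) - colMeans(x2)
  n1 <- nrow(x1); n2 <- nrow(x2)
  sw <- ((n1 - 1) * stats::cov(x1) + (n2 - 1) * stats::cov(x2)) / (n1 + n2 - 2)
  p <- ncol(x1)
  ridge <- 0.01 * mean(diag(sw)) + 1e-8
  w <- solve(sw + diag(ridge, p), d)
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) return(rep(0, p))
  w / nrm
}

#' LDA effect size per taxon
#'
#' LEfSe-style effect-size scoring for two groups. Abundances are scaled to
#' per-million; over `n_boot` subsamples (a fraction of each class, sampled
#' without replacement) a regularized two-class LDA is fitted and each
#' feature's effect is the average of (a) the absolute between-class
#' difference along the discriminant axis attributed to the feature and
#' (b) the absolute raw between-class mean difference. The final score is
#' `log10(max(mean effect, 1))`, so a feature with no signal scores 0.
#'
#' @param table An `abundance_table` with exactly two groups, or a plain
#'   samples-by-taxa matrix (then `groups` must be given).
#' @param groups Group labels when `table` is a plain matrix.
#' @param n_boot Number of subsampling rounds (default 30).
#' @param subsample_frac Fraction of each class per round (default 0.67).
#' @param seed Optional RNG seed.
#' @return Data frame: `taxon`, `effect_size` (per-million scale),
#'   `lda_score` (log10), `enriched_in`.
#' @export
lda_effect_size <- function(table, groups = NULL, n_boot = 30L,
                            subsample_frac = 0.67, seed = NULL) {
  values <- if (inherits(table, "abundance_table")) table$values else
    as.matrix(table)
  if (is.null(groups)) groups <- table$groups
  g <- factor(groups)
  stopifnot(nlevels(g) == 2L, length(g) == nrow(values))
  run <- function() {
    x <- values * 1e6
    lv <- levels(g)
    i1 <- which(g == lv[1]); i2 <- which(g == lv[2])
    k1 <- ceiling(subsample_frac * length(i1))
    k2 <- ceiling(subsample_frac * length(i2))
    if (k1 < 2L || k2 < 2L) {
      stop("a class would have < 2 samples per subsample round")
    }
    p <- ncol(x)
    acc <- matrix(NA_real_, nrow = n_boot, ncol = p)
    ok <- 0L
    for (b in seq_len(4L * n_boot)) {
      if (ok >= n_boot) break
      s1 <- sample(i1, k1); s2 <- sample(i2, k2)
      eff <- tryCatch({
        x1 <- x[s1, , drop = FALSE]; x2 <- x[s2, , drop = FALSE]
        w <- lda_direction(x1, x2)
        d <- colMeans(x1) - colMeans(x2)
        axis_diff <- abs(sum(w * d))        # class-mean gap along the axis
        (abs(w) * axis_diff + abs(d)) / 2
      }, error = function(e) NULL)
      if (!is.null(eff)) {
        ok <- ok + 1L
        acc[ok, ] <- eff
      }
    }
    if (ok < 5L) stop("fewer than 5 successful LDA subsampling rounds")
    effect <- colMeans(acc[seq_len(ok), , drop = FALSE])
    overall_d <- colMeans(x[i1, , drop = FALSE]) -
      colMeans(x[i2, , drop = FALSE])
    data.frame(taxon = colnames(x),
               effect_size = effect,
               lda_score = log10(pmax(effect, 1)),
               enriched_in = ifelse(overall_d >= 0, lv[1], lv[2]),
               stringsAsFactors = FALSE)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  rownames(out) <- NULL
  out
}

#' LEfSe-style discriminative-taxon screen
#'
#' At each requested rank, taxa are screened by Kruskal-Wallis (`p < alpha`);
#' survivors get an LDA effect size, and taxa with `lda_score >= lda_cutoff`
#' are reported with the group they are enriched in.
#'
#' @param table An `abundance_table` with two groups and a taxonomy covering
#'   all species.
#' @param alpha Screening significance level (default 0.05).
#' @param lda_cutoff LDA score threshold (default 4.0).
#' @param ranks Ranks to scan.
#' @param n_boot,subsample_frac,seed Passed to [lda_effect_size()].
#' @return Data frame: `taxon`, `rank`, `enriched_in`, `lda_score`, `p`,
#'   sorted by decreasing score. Zero rows when nothing passes.
#' @export
lefse <- function(table, alpha = 0.05, lda_cutoff = 4.0,
                  ranks = c("phylum", "genus", "species"),
                  n_boot = 30L, subsample_frac = 0.67, seed = NULL) {
  res <- list()
  for (r in ranks) {
    tab_r <- aggregate_to_rank(table, r)
    kw <- kruskal_wallis_per_taxon(tab_r, rank = r)
    hit <- kw$taxon[kw$p < alpha]
    if (!length(hit)) next
    lda <- lda_effect_size(tab_r$values[, hit, drop = FALSE],
                           groups = tab_r$groups, n_boot = n_boot,
                           subsample_frac = subsample_frac, seed = seed)
    lda$p <- kw$p[match(lda$taxon, kw$taxon)]
    lda$rank <- r
    res[[r]] <- lda[lda$lda_score >= lda_cutoff,
                    c("taxon", "rank", "enriched_in", "lda_score", "p")]
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(taxon = character(0), rank = character(0),
               enriched_in = character(0), lda_score = numeric(0),
               p = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(-out$lda_score), , drop = FALSE]
  rownames(out) <- NULL
  out
}
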