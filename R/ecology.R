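#' Chao1 richness estimator
#'
#' Estimates total species richness from the observed counts using singleton
#' (`F1`) and doubleton (`F2`) frequencies. The default is the bias-corrected
#' form `S + F1*(F1-1) / (2*(F2+1))`, which stays finite when no doubletons
#' are observed; the classic form `S + F1^2/(2*F2)` is available by flag (and
#' falls back to the bias-corrected form when `F2 = 0`).
#'
#' @param counts Non-negative integer vector of per-taxon read counts.
#' @param bias_corrected Use the bias-corrected estimator (default)?
#' @return Estimated richness (0 for an all-zero vector).
#' @examples
#' chao1(c(1, 1, 2, 2, 5))  # 5.333...
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  stopifnot(all(counts >= 0))
  s_obs <- sum(counts > 0)
  if (s_obs == 0L) return(0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (!bias_corrected && f2 > 0) return(s_obs + f1^2 / (2 * f2))
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity index
#'
#' `-sum(p * log(p))` with `0*log(0) = 0`; natural log by default. Input is
#' renormalized to proportions.
#'
#' @param p Non-negative abundance vector.
#' @param base Logarithm base (default `exp(1)`).
#' @return Shannon index.
#' @export
shannon <- function(p, base = exp(1)) {
  stopifnot(all(p >= 0))
  p <- p[p > 0]
  if (!length(p)) return(0)
  p <- p / sum(p)
  -sum(p * log(p)) / log(base)
}

#' Simpson diversity index (Gini-Simpson form)
#'
#' `1 - sum(p^2)`: the probability that two random draws are different taxa.
#'
#' @param p Non-negative abundance vector.
#' @return Simpson index in `[0, 1 - 1/n]`.
#' @export
simpson <- function(p) {
  stopifnot(all(p >= 0))
  if (sum(p) == 0) return(0)
  p <- p / sum(p)
  1 - sum(p^2)
}

#' Per-sample alpha diversity
#'
#' Chao1 is computed on the integer read counts `s` (it needs singleton and
#' doubleton frequencies); Shannon and Simpson on relative abundances.
#'
#' @param table An `abundance_table` with a `counts` matrix.
#' @return Data frame with columns `sample`, `chao1`, `shannon`, `simpson`
#'   and `group` (if known).
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(table$counts)) {
    stop("alpha_diversity needs the integer count matrix (table$counts)")
  }
  data.frame(
    sample = table$samples,
    chao1 = apply(table$counts, 1, chao1),
    shannon = apply(table$values, 1, shannon),
    simpson = apply(table$values, 1, simpson),
    group = if (is.null(table$groups)) NA_character_ else unname(table$groups),
    stringsAsFactors = FALSE)
}

#' Two-group comparison of an alpha-diversity metric
#'
#' Wilcoxon rank-sum (Mann-Whitney) test, two-sided; exact when both groups
#' have at most 20 observations and no ties, otherwise the tie-corrected
#' normal approximation.
#'
#' @param values Numeric vector of per-sample metric values.
#' @param groups Group labels (exactly two levels), parallel to `values`.
#' @return Two-sided p-value.
#' @export
compare_alpha <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2L || any(table(g) == 0L)) {
    stop("compare_alpha needs exactly two non-empty groups")
  }
  x <- values[g == levels(g)[1]]
  y <- values[g == levels(g)[2]]
  exact <- length(x) <= 20 && length(y) <= 20 && !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact)$p.value)
}

#' Beta-diversity distance matrix
#'
#' Bray-Curtis on abundances, binary Jaccard on presence/absence, or
#' Euclidean on the abundance vectors.
#'
#' @param table An `abundance_table` (or plain samples-by-taxa matrix).
#' @param metric One of `"bray_curtis"`, `"binary_jaccard"`, `"euclidean"`.
#' @return A `dist` object with `attr(, "metric")` set.
#' @export
beta_distance <- function(table,
                          metric = c("bray_curtis", "binary_jaccard",
                                     "euclidean")) {
  metric <- match.arg(metric)
  values <- if (inherits(table, "abundance_table")) table$values else
    as.matrix(table)
  stopifnot(nrow(values) >= 2L)
  d <- switch(metric,
    bray_curtis = vegan::vegdist(values, method = "bray"),
    binary_jaccard = vegan::vegdist(values, method = "jaccard", binary = TRUE),
    euclidean = vegan::vegdist(values, method = "euclidean"))
  attr(d, "metric") <- metric
  d
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: double-centre `-0.5 * D^2`, eigendecompose, and
#' scale the top-`k` eigenvectors by the square root of their eigenvalues.
#' All eigenvalues (including negative ones, which arise for semi-metric
#' distances such as Bray-Curtis) are reported; only positive-eigenvalue axes
#' are returned as coordinates.
#'
#' @param dist A `dist` object.
#' @param k Number of axes requested (at most `n - 1`).
#' @return List with `points` (n × k' coordinate matrix, k' ≤ k),
#'   `eig` (all eigenvalues, non-increasing) and `var_explained`
#'   (positive-eigenvalue fractions).
#' @export
pcoa <- function(dist, k = 2L) {
  n <- attr(dist, "Size")
  stopifnot(k >= 1L, k <= n - 1L)
  res <- suppressWarnings(stats::cmdscale(dist, k = k, eig = TRUE))
  pts <- as.matrix(res$points)
  pos <- res$eig[res$eig > 1e-10]
  list(points = pts,
       eig = res$eig,
       var_explained = if (length(pos)) pos / sum(pos) else numeric(0))
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions the total sum of squared inter-point distances into among- and
#' within-group components and forms the pseudo-F ratio
#' `(SS_A / (a-1)) / (SS_W / (n-a))`. Significance is assessed by permuting
#' group labels; the p-value includes the observed statistic in both
#' numerator and denominator: `p = (1 + #[F* >= F]) / (1 + n_perm)`.
#'
#' @param dist A `dist` object over the samples.
#' @param groups Group labels, one per sample (>= 2 groups).
#' @param n_perm Number of label permutations.
#' @param seed Optional RNG seed for the permutations.
#' @return List with `pseudo_F`, `p`, `df` (among, within) and `n_perm`.
#'   A distance matrix with no variation at all (all entries zero) has
#'   nothing to partition: `pseudo_F` is `NA` and `p` is 1.
#' @export
permanova <- function(dist, groups, n_perm = 999L, seed = NULL) {
  D2 <- as.matrix(dist)^2
  n <- nrow(D2)
  g <- factor(groups)
  stopifnot(length(g) == n, n_perm >= 1L)
  if (nlevels(g) < 2L || any(table(g) == 0L)) {
    stop("permanova needs at least two non-empty groups")
  }
  a <- nlevels(g)
  sst <- sum(D2) / (2 * n)
  if (sst <= 0) {
    # all samples equidistant at zero (e.g. identical presence/absence
    # under a binary metric): no variation to partition
    return(list(pseudo_F = NA_real_, p = 1,
                df = c(among = a - 1L, within = n - a), n_perm = n_perm))
  }
  f_stat <- function(idx) {
    gg <- g[idx]
    ssw <- 0
    for (lev in levels(gg)) {
      m <- gg == lev
      ssw <- ssw + sum(D2[m, m]) / (2 * sum(m))
    }
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_stat(seq_len(n))
  run <- function() {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      if (f_stat(sample.int(n)) >= f_obs) hits <- hits + 1L
    }
    hits
  }
  hits <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(pseudo_F = f_obs, p = (1 + hits) / (1 + n_perm),
       df = c(among = a - 1L, within = n - a), n_perm = n_perm)
}
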