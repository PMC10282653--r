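#' Derive a stage sub-seed from a global seed
#'
#' Fixed Lehmer-style derivation so that every pipeline stage is
#' independently reproducible from the single study seed. Results stay in
#' `[1, 2^31 - 2]`.
#'
#' @param seed Global integer seed.
#' @param stage Stage index (any non-negative integer).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  m <- 2147483647
  x <- (as.numeric(seed) %% m) + 1
  for (i in seq_len(stage %% 64 + 1)) x <- (x * 48271) %% m
  as.integer((x + stage) %% (m - 1) + 1)
}

#' Venn partition of detected species between two groups
#'
#' A species is "in" a group when its relative abundance is positive in at
#' least one sample of that group. The union cardinality is the sum of the
#' shared and the two exclusive counts.
#'
#' @param table An `abundance_table` with two groups.
#' @return List with `shared`, one `only_<group>` entry per group, and
#'   `total` (the union cardinality).
#' @export
venn_species_counts <- function(table) {
  g <- factor(table$groups)
  stopifnot(nlevels(g) == 2L)
  lv <- levels(g)
  in_a <- colSums(table$values[g == lv[1], , drop = FALSE] > 0) > 0
  in_b <- colSums(table$values[g == lv[2], , drop = FALSE] > 0) > 0
  out <- list(shared = sum(in_a & in_b),
              only_a = sum(in_a & !in_b),
              only_b = sum(!in_a & in_b),
              total = sum(in_a | in_b))
  names(out)[2:3] <- paste0("only_", lv)
  out
}

#' Union cardinality from printed Venn counts
#'
#' For two sets summarized by their shared and exclusive member counts, the
#' size of the union is `shared + only_a + only_b`.
#'
#' @param shared Species found in both groups.
#' @param only_a,only_b Species exclusive to each group.
#' @return The union cardinality.
#' @examples
#' venn_union_total(165, 265, 97)  # 527
#' @export
venn_union_total <- function(shared, only_a, only_b) {
  stopifnot(shared >= 0, only_a >= 0, only_b >= 0)
  shared + only_a + only_b
}

#' Run the full study workflow
#'
#' Executes the complete analysis on profiled inputs: per-sample QC and
#' profiling, table merging, alpha/beta diversity with group tests,
#' Kruskal-Wallis and LEfSe-style differential abundance, and the
#' random-forest classifier. Writes per-stage TSVs and a machine-readable
#' `summary.json` into `out_dir`. Re-running with an identical configuration
#' and seed reproduces identical outputs.
#'
#' @param db A `tag_db` (or a directory written by [write_tag_db()]).
#' @param samples Data frame with columns `sample_id`, `fastq` (path or a
#'   list-column of read data frames), `group`.
#' @param taxonomy Taxonomy data frame (`species_id`, `genus`, `phylum`).
#' @param out_dir Output directory (created); `NULL` skips writing.
#' @param policy A [qc_policy()].
#' @param g_threshold G-score threshold.
#' @param metrics Beta-diversity metrics to compute.
#' @param n_perm PERMANOVA permutations.
#' @param alpha LEfSe screening level.
#' @param lda_cutoff LEfSe score cutoff.
#' @param positive Positive class for POD (default: the smaller group).
#' @param top_n,n_trees,folds Classifier settings.
#' @param seed Global seed, fanned out per stage via [derive_seed()].
#' @return List with `profiles`, `table`, `alpha`, `beta`, `diff`,
#'   `classifier` and `summary` (the content of `summary.json`).
#' @export
run_study <- function(db, samples, taxonomy = NULL, out_dir = NULL,
                      policy = qc_policy(), g_threshold = 5,
                      metrics = c("bray_curtis", "binary_jaccard",
                                  "euclidean"),
                      n_perm = 999L, alpha = 0.05, lda_cutoff = 4.0,
                      positive = NULL, top_n = 30L, n_trees = 500L,
                      folds = 5L, seed = 17L) {
  if (is.character(db)) db <- read_tag_db(db)
  stopifnot(all(c("sample_id", "fastq", "group") %in% names(samples)))
  stage <- "profiling"
  res <- tryCatch({
    profiles <- list()
    qc_counts <- list()
    for (i in seq_len(nrow(samples))) {
      sid <- samples$sample_id[i]
      reads <- samples$fastq[[i]]
      profiles[[sid]] <- profile_sample(reads, db, policy, g_threshold,
                                        sample_id = sid)
      qc_counts[[sid]] <- attr(profiles[[sid]], "qc")
    }
    groups <- stats::setNames(samples$group, samples$sample_id)
    tab <- merge_profiles(profiles, groups = groups, taxonomy = taxonomy)

    stage <- "alpha diversity"
    adiv <- alpha_diversity(tab)
    alpha_p <- vapply(c("chao1", "shannon", "simpson"), function(m) {
      compare_alpha(adiv[[m]], adiv$group)
    }, numeric(1))

    stage <- "beta diversity"
    beta <- lapply(stats::setNames(metrics, metrics), function(m) {
      d <- beta_distance(tab, m)
      pn <- permanova(d, tab$groups, n_perm = n_perm,
                      seed = derive_seed(seed, 10L))
      list(dist = d, pcoa = pcoa(d, k = min(3L, nrow(tab$values) - 1L)),
           permanova = pn)
    })

    stage <- "differential abundance"
    ranks <- if (is.null(taxonomy)) "species" else
      c("phylum", "genus", "species")
    kw <- do.call(rbind, lapply(ranks, function(r) {
      kruskal_wallis_per_taxon(aggregate_to_rank(tab, r), rank = r)
    }))
    disc <- lefse(tab, alpha = alpha, lda_cutoff = lda_cutoff, ranks = ranks,
                  seed = derive_seed(seed, 20L))

    stage <- "classifier"
    if (is.null(positive)) {
      counts <- table(samples$group)
      positive <- names(counts)[which.min(counts)]
    }
    cls <- classify_study(tab, positive, top_n = top_n, n_trees = n_trees,
                          folds = folds, seed = derive_seed(seed, 30L))

    venn <- venn_species_counts(tab)
    summary <- list(
      seed = seed,
      n_samples = nrow(samples),
      clean_reads = stats::setNames(
        vapply(qc_counts, function(q) as.integer(q$pass), integer(1)),
        names(qc_counts)),
      species_detected = length(tab$taxa),
      venn = venn,
      venn_identity = venn$total == Reduce(`+`, venn[1:3]),
      alpha_p = as.list(alpha_p),
      beta_p = lapply(beta, function(b) b$permanova$p),
      n_kw_significant = sum(kw$p < alpha),
      n_discriminative = nrow(disc),
      classifier = list(k = cls$k, markers = cls$markers, auc = cls$auc,
                        pod_group_p = cls$pod_group_p, positive = positive))
    list(profiles = profiles, table = tab, alpha = adiv, beta = beta,
         diff = list(kruskal_wallis = kw, lefse = disc), classifier = cls,
         summary = summary)
  }, error = function(e) {
    stop("study failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(out_dir)) write_study_outputs(res, out_dir)
  res
}

write_study_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_abundance_table(res$table, file.path(out_dir, "abundance.tsv"))
  tsv(res$alpha, "alpha_diversity.tsv")
  for (m in names(res$beta)) {
    dm <- as.matrix(res$beta[[m]]$dist)
    utils::write.table(data.frame(sample = rownames(dm), signif(dm, 6),
                                  check.names = FALSE),
                       file.path(out_dir, paste0("dist_", m, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tsv(res$diff$kruskal_wallis, "kruskal_wallis.tsv")
  tsv(res$diff$lefse, "lefse.tsv")
  tsv(res$classifier$ranking, "importance.tsv")
  tsv(res$classifier$cv_error_curve, "cv_error_curve.tsv")
  tsv(data.frame(sample = names(res$classifier$pod),
                 pod = signif(res$classifier$pod, 6)), "pod.tsv")
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 6)
  invisible(out_dir)
}

#' Simulate and analyse a complete synthetic study
#'
#' Convenience wrapper: generates the mock study from a [synth_config()],
#' builds the unique-tag database from the simulated references (decoy
#' excluded), and runs the full workflow.
#'
#' @param config A [synth_config()].
#' @param scheme A [digest_scheme()].
#' @param out_dir Optional output directory for the study outputs.
#' @param ... Passed to [run_study()].
#' @return As [run_study()], plus `sim` (the simulation, with truth) and
#'   `db`.
#' @export
run_synthetic_study <- function(config, scheme = digest_scheme(),
                                out_dir = NULL, ...) {
  sim <- simulate_study(config, scheme)
  db <- build_tag_db(sim$ref$genomes, scheme)
  samples <- data.frame(sample_id = names(sim$samples),
                        group = unname(sim$truth$groups[names(sim$samples)]),
                        stringsAsFactors = FALSE)
  samples$fastq <- unname(sim$samples)
  res <- run_study(db, samples, taxonomy = sim$ref$taxonomy,
                   out_dir = out_dir, seed = config$seed, ...)
  res$sim <- sim
  res$db <- db
  res
}
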