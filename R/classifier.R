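#' Random-forest importance ranking of abundant taxa
#'
#' Candidates are the `top_n` taxa by overall mean relative abundance; a
#' random forest (stratified bootstrap, permutation importance) is fitted on
#' them and taxa are ranked by out-of-bag mean decrease in accuracy.
#' Deterministic for a fixed seed.
#'
#' @param table An `abundance_table` with two groups.
#' @param top_n Number of most-abundant taxa to consider (default 30).
#' @param n_trees Trees in the forest (default 500).
#' @param seed Optional RNG seed.
#' @return Data frame `taxon`, `importance`, sorted by decreasing importance.
#' @export
rank_importance <- function(table, top_n = 30L, n_trees = 500L, seed = NULL) {
  table <- sort_samples(table)
  g <- factor(table$groups)
  if (nlevels(g) != 2L || any(tabulate(g) < 2L)) {
    stop("rank_importance needs two groups with >= 2 samples each")
  }
  top_n <- min(top_n, ncol(table$values))
  cand <- names(sort(colMeans(table$values), decreasing = TRUE))[seq_len(top_n)]
  x <- as.data.frame(table$values[, cand, drop = FALSE])
  fit <- function() {
    randomForest::randomForest(x = x, y = g, ntree = n_trees,
                               importance = TRUE,
                               strata = g, sampsize = tabulate(g))
  }
  rf <- if (is.null(seed)) fit() else withr::with_seed(seed, fit())
  imp <- randomForest::importance(rf, type = 1)[, 1]
  out <- data.frame(taxon = names(imp), importance = unname(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Canonical sample order (sorted ids) so that seeded forest fits do not
# depend on the input row order.
sort_samples <- function(table) {
  o <- order(table$samples)
  if (identical(o, seq_along(table$samples))) return(table)
  abundance_table(table$values[o, , drop = FALSE],
                  counts = if (is.null(table$counts)) NULL else
                    table$counts[o, , drop = FALSE],
                  groups = table$groups[o],
                  taxonomy = table$taxonomy)
}

# Stratified fold assignment: samples of each class are dealt round-robin.
stratified_folds <- function(g, folds) {
  fold <- integer(length(g))
  for (lev in levels(g)) {
    idx <- sample(which(g == lev))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Cross-validated marker-set selection
#'
#' For `k = 1, ..., nrow(ranking)` the stratified `folds`-fold
#' cross-validation error of a forest restricted to the top-`k` taxa is
#' measured. The selected marker count is the smallest `k` whose mean error
#' is within one standard error of the curve minimum (one-SE rule).
#'
#' @param table An `abundance_table` with two groups.
#' @param ranking Importance ranking from [rank_importance()] (computed with
#'   defaults when `NULL`).
#' @param folds Number of CV folds; silently reduced (with a warning) to the
#'   smaller group size when larger.
#' @param n_trees Trees per forest.
#' @param seed Optional RNG seed.
#' @return List with `markers` (selected taxa), `k`, and `cv_error_curve`
#'   (data frame `k`, `mean_error`, `se`).
#' @export
select_markers_cv <- function(table, ranking = NULL, folds = 5L,
                              n_trees = 500L, seed = NULL) {
  table <- sort_samples(table)
  g <- factor(table$groups)
  run <- function() {
    if (is.null(ranking)) ranking <- rank_importance(table, n_trees = n_trees)
    min_group <- min(tabulate(g))
    if (folds > min_group) {
      warning("folds reduced to the smaller group size (", min_group, ")")
      folds <- min_group
    }
    fold <- stratified_folds(g, folds)
    x <- as.data.frame(table$values[, ranking$taxon, drop = FALSE])
    ks <- seq_len(nrow(ranking))
    err <- matrix(NA_real_, nrow = length(ks), ncol = folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      for (k in ks) {
        xk <- x[, seq_len(k), drop = FALSE]
        rf <- randomForest::randomForest(x = xk[tr, , drop = FALSE],
                                         y = g[tr], ntree = n_trees)
        pred <- stats::predict(rf, xk[!tr, , drop = FALSE])
        err[k, f] <- mean(pred != g[!tr])
      }
    }
    mean_err <- rowMeans(err)
    se <- apply(err, 1, stats::sd) / sqrt(folds)
    kmin <- which.min(mean_err)
    k_sel <- min(ks[mean_err <= mean_err[kmin] + se[kmin]])
    list(markers = ranking$taxon[seq_len(k_sel)], k = k_sel,
         cv_error_curve = data.frame(k = ks, mean_error = mean_err, se = se))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Fit the marker-set random forest
#'
#' @param table An `abundance_table`.
#' @param taxa Taxa (markers) to use; all taxa when `NULL`.
#' @param n_trees Trees in the forest.
#' @param seed Optional RNG seed.
#' @return A `randomForest` classifier.
#' @export
fit_marker_forest <- function(table, taxa = NULL, n_trees = 500L,
                              seed = NULL) {
  table <- sort_samples(table)
  g <- factor(table$groups)
  if (is.null(taxa)) taxa <- table$taxa
  x <- as.data.frame(table$values[, taxa, drop = FALSE])
  fit <- function() {
    randomForest::randomForest(x = x, y = g, ntree = n_trees,
                               strata = g, sampsize = tabulate(g))
  }
  if (is.null(seed)) fit() else withr::with_seed(seed, fit())
}

#' Probability of disease (POD)
#'
#' The fraction of decision trees voting the designated positive class for a
#' sample. For the forest's own training samples, only out-of-bag trees are
#' counted (avoiding resubstitution optimism); new samples use all trees.
#'
#' @param model A fitted `randomForest`.
#' @param positive Positive class label.
#' @param newdata Optional data frame / matrix of new samples; `NULL` scores
#'   the training samples out-of-bag.
#' @return Named numeric vector of POD values in `[0, 1]`.
#' @export
pod_scores <- function(model, positive, newdata = NULL) {
  stopifnot(positive %in% colnames(model$votes) ||
            !is.null(newdata))
  if (is.null(newdata)) {
    v <- model$votes[, positive]
    if (anyNA(v) || any(is.nan(v))) {
      stop("some training samples have no out-of-bag trees; grow more trees")
    }
    return(v)
  }
  stats::predict(model, as.data.frame(newdata), type = "prob")[, positive]
}

#' Evaluate POD separation between groups
#'
#' AUC is the Mann-Whitney U statistic divided by `n1 * n2` (the probability
#' that a random positive-group sample outranks a random negative-group
#' sample, ties counted half); the group difference is tested with a
#' two-sided Wilcoxon rank-sum test.
#'
#' @param pods Numeric POD values.
#' @param groups Group labels parallel to `pods`.
#' @param positive Positive class label.
#' @return List with `auc` and `p`.
#' @export
evaluate_pod <- function(pods, groups, positive) {
  pos <- groups == positive
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0L || n2 == 0L) stop("both groups must be represented")
  r <- rank(pods)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  p <- if (length(unique(pods)) == 1L) 1 else suppressWarnings(
    stats::wilcox.test(pods[pos], pods[!pos])$p.value)
  list(auc = auc, p = p)
}

#' Cross-validated POD AUC
#'
#' Stratified k-fold cross-validation: each fold's samples are scored by a
#' forest trained on the remaining folds, and the held-out POD values are
#' pooled into a single AUC.
#'
#' @param table An `abundance_table` with two groups.
#' @param taxa Taxa to use (all when `NULL`).
#' @param positive Positive class label.
#' @param folds CV folds.
#' @param n_trees Trees per forest.
#' @param seed Optional RNG seed.
#' @return List with `auc`, `pods` (held-out POD per sample) and `p`.
#' @export
cv_pod_auc <- function(table, positive, taxa = NULL, folds = 5L,
                       n_trees = 500L, seed = NULL) {
  table <- sort_samples(table)
  g <- factor(table$groups)
  if (is.null(taxa)) taxa <- table$taxa
  x <- as.data.frame(table$values[, taxa, drop = FALSE])
  run <- function() {
    folds <- min(folds, min(tabulate(g)))
    fold <- stratified_folds(g, folds)
    pods <- rep(NA_real_, nrow(x))
    for (f in seq_len(folds)) {
      tr <- fold != f
      rf <- randomForest::randomForest(x = x[tr, , drop = FALSE], y = g[tr],
                                       ntree = n_trees)
      pods[!tr] <- stats::predict(rf, x[!tr, , drop = FALSE],
                                  type = "prob")[, positive]
    }
    ev <- evaluate_pod(pods, as.character(g), positive)
    list(auc = ev$auc, pods = stats::setNames(pods, rownames(x)), p = ev$p)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Full classifier stage: ranking, marker selection, POD and AUC
#'
#' @param table An `abundance_table` with two groups.
#' @param positive Positive class label (the class POD counts votes for).
#' @param top_n,n_trees,folds Forest and CV settings.
#' @param seed Optional RNG seed (fanned out internally).
#' @return List with `ranking`, `markers`, `k`, `cv_error_curve`, `pod`
#'   (out-of-bag POD of the final marker forest), `auc`, `pod_group_p`.
#' @export
classify_study <- function(table, positive, top_n = 30L, n_trees = 500L,
                           folds = 5L, seed = NULL) {
  s <- function(i) if (is.null(seed)) NULL else derive_seed(seed, i)
  ranking <- rank_importance(table, top_n = top_n, n_trees = n_trees,
                             seed = s(1L))
  sel <- select_markers_cv(table, ranking, folds = folds, n_trees = n_trees,
                           seed = s(2L))
  rf <- fit_marker_forest(table, sel$markers, n_trees = n_trees, seed = s(3L))
  pod <- pod_scores(rf, positive)
  ev <- evaluate_pod(pod, as.character(table$groups), positive)
  list(ranking = ranking, markers = sel$markers, k = sel$k,
       cv_error_curve = sel$cv_error_curve, pod = pod,
       auc = ev$auc, pod_group_p = ev$p)
}
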