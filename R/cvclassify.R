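#' Union of top pairwise t-test genes
#'
#' For every unordered pair of classes, genes are ranked by the two-sided
#' Welch t-test p-value and each pair contributes its `n_top` best genes; the
#' feature set is the union. This is the baseline feature-selection scheme
#' the CE-DEG signature is compared against.
#'
#' @param x Expression matrix (genes x samples).
#' @param labels Per-sample class labels (every class n >= 2).
#' @param n_top Genes per pair (default 100).
#' @return Character vector of gene ids (order: by first pair contributing).
#' @export
ttest_top_union <- function(x, labels, n_top = 100L) {
  validate_expression_matrix(x)
  gs <- group_stats(x, labels)
  if (length(gs$levels) < 2L) stop("need >= 2 classes")
  if (any(gs$n < 2L)) stop("every class needs n >= 2")
  pairs <- utils::combn(gs$levels, 2L)
  feats <- character(0)
  for (c_idx in seq_len(ncol(pairs))) {
    i <- pairs[1L, c_idx]; j <- pairs[2L, c_idx]
    vi <- gs$vars[, i] / gs$n[[i]]; vj <- gs$vars[, j] / gs$n[[j]]
    se2 <- vi + vj
    tt <- (gs$means[, i] - gs$means[, j]) / sqrt(se2)
    df <- se2^2 / (vi^2 / (gs$n[[i]] - 1) + vj^2 / (gs$n[[j]] - 1))
    p <- 2 * pt(-abs(tt), df)
    p[!is.finite(p)] <- 1
    top <- rownames(x)[order(p)][seq_len(min(n_top, nrow(x)))]
    feats <- union(feats, top)
  }
  feats
}

#' Greedy decorrelation of a ranked feature list
#'
#' Scans candidates in priority order and keeps a gene only if its absolute
#' Pearson correlation with every already-kept gene is below `r_threshold`
#' (|r| >= 0.5 being the conventional large effect size for correlations).
#' Output preserves the input priority order.
#'
#' @param candidates Gene ids ordered by priority (best first).
#' @param x Expression matrix containing the candidate rows.
#' @param r_threshold Correlation cutoff (default 0.5).
#' @return Subset of `candidates`, in order.
#' @export
decorrelate_features <- function(candidates, x, r_threshold = 0.5) {
  if (!all(candidates %in% rownames(x)))
    stop("candidates missing from the matrix")
  kept <- character(0)
  kept_mat <- NULL
  for (g in candidates) {
    v <- x[g, ]
    if (is.null(kept_mat)) {
      kept <- g; kept_mat <- matrix(v, nrow = 1L)
      next
    }
    if (sd(v) == 0) next                       # constant gene: undefined r, drop
    r <- suppressWarnings(as.numeric(cor(t(kept_mat), v)))
    r[is.na(r)] <- 1
    if (all(abs(r) < r_threshold)) {
      kept <- c(kept, g)
      kept_mat <- rbind(kept_mat, v)
    }
  }
  kept
}

#' Choose the feature count minimising cross-validated error
#'
#' Evaluates prefixes of a ranked feature list over a size grid by stratified
#' k-fold cross-validation with a linear SVM and returns the smallest size
#' attaining the minimum misclassification error.
#'
#' @param ranked Gene ids ordered by priority.
#' @param x Expression matrix.
#' @param labels Per-sample class labels.
#' @param grid Candidate prefix sizes; default a log-spaced grid
#'   `{1, 2, 5, 10, 20, 50, 100, 200, 500, ...}` capped at
#'   `length(ranked)` (which is always included).
#' @param k Folds for the inner cross-validation (default 5).
#' @param seed Integer seed.
#' @return List with `n_features`, `error` and `curve`
#'   (data frame `size`, `error` in `[0, 1]`).
#' @export
min_error_feature_count <- function(ranked, x, labels, grid = NULL, k = 5L,
                                    seed = 1L) {
  if (!length(ranked)) stop("ranked feature list is empty")
  if (is.null(grid)) {
    grid <- c(1L, 2L, 5L, 10L, 20L, 50L, 100L, 200L, 500L, 1000L)
    grid <- grid[grid < length(ranked)]
    grid <- unique(c(grid, length(ranked)))
  }
  grid <- sort(unique(as.integer(grid)))
  if (!length(grid)) stop("empty size grid")
  if (max(grid) > length(ranked)) stop("grid exceeds the number of ranked features")
  labels <- droplevels(as.factor(labels))
  set.seed(seed)
  folds <- stratified_folds(labels, k)
  err <- vapply(grid, function(sz) {
    feats <- ranked[seq_len(sz)]
    wrong <- 0L; total <- 0L
    for (f in seq_len(k)) {
      test <- folds == f
      if (!any(test) || length(unique(labels[!test])) < 2L) next
      pred <- svm_predict(x[feats, !test, drop = FALSE], labels[!test],
                          x[feats, test, drop = FALSE])
      wrong <- wrong + sum(pred != labels[test])
      total <- total + sum(test)
    }
    wrong / max(total, 1L)
  }, numeric(1))
  best <- grid[which.min(err)]                 # ties -> smallest size
  list(n_features = best, error = min(err),
       curve = data.frame(size = grid, error = err))
}

# stratified fold ids: within each class, samples are spread over folds;
# classes smaller than k occupy a random subset of folds.
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    folds[idx] <- sample(rep_len(sample.int(k), length(idx)))
  }
  folds
}

svm_predict <- function(train_x, train_y, test_x) {
  fit <- e1071::svm(x = t(train_x), y = droplevels(train_y),
                    kernel = "linear", cost = 1, scale = FALSE)
  predict(fit, t(test_x))
}

#' Repeated stratified cross-validation with a linear SVM
#'
#' Stratified k-fold cross-validation repeated `reps` times with fresh fold
#' assignments. Feature selection is re-run inside every training fold (no
#' information from the test fold leaks into selection), a linear-kernel
#' C = 1 SVM with one-vs-one multiclass voting is trained, and per-repetition
#' integer confusion counts are accumulated and finally divided by `reps`,
#' yielding fractional cells. Classes smaller than `k` appear in only some
#' folds.
#'
#' @param x Expression matrix (genes x samples).
#' @param labels Per-sample class labels (every class n >= 2).
#' @param feature_selector Function `(train_x, train_labels) -> gene ids`;
#'   default keeps all genes.
#' @param k Folds (default 30).
#' @param reps Repetitions (default 3).
#' @param seed Integer seed.
#' @param max_redraw Maximum fold redraws when a fold leaves a training
#'   class empty.
#' @return Object of class `"confusion_table"`: list with `counts`
#'   (class x class averaged counts; rows = truth), `totals`, `sensitivity`,
#'   `reps`, `classes`.
#' @export
repeated_stratified_cv <- function(x, labels, feature_selector = NULL,
                                   k = 30L, reps = 3L, seed = 1L,
                                   max_redraw = 10L) {
  validate_expression_matrix(x)
  labels <- droplevels(as.factor(labels))
  if (length(labels) != ncol(x)) stop("labels must have one entry per sample")
  if (nlevels(labels) < 2L) stop("need >= 2 classes")
  if (any(table(labels) < 2L)) stop("every class needs >= 2 samples")
  if (is.null(feature_selector))
    feature_selector <- function(train_x, train_labels) rownames(train_x)
  classes <- levels(labels)
  counts <- matrix(0, length(classes), length(classes),
                   dimnames = list(truth = classes, predicted = classes))
  set.seed(seed)
  for (r in seq_len(reps)) {
    folds <- stratified_folds(labels, k)
    for (attempt in seq_len(max_redraw)) {
      ok <- all(vapply(seq_len(k), function(f)
        all(table(labels[folds != f]) > 0L), logical(1)))
      if (ok) break
      warning("fold left a training class empty; redrawing folds")
      folds <- stratified_folds(labels, k)
    }
    for (f in seq_len(k)) {
      test <- folds == f
      if (!any(test)) next
      feats <- feature_selector(x[, !test, drop = FALSE], labels[!test])
      if (!length(feats)) feats <- rownames(x)
      pred <- svm_predict(x[feats, !test, drop = FALSE], labels[!test],
                          x[feats, test, drop = FALSE])
      counts <- counts + table(factor(labels[test], levels = classes),
                               factor(pred, levels = classes))
    }
  }
  counts <- counts / reps
  totals <- as.numeric(table(labels))
  structure(list(counts = counts, totals = setNames(totals, classes),
                 sensitivity = setNames(diag(counts) / totals, classes),
                 reps = reps, classes = classes),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("Cross-validation confusion table (%d classes, averaged over %d repetitions)\n",
              length(x$classes), x$reps))
  print(round(x$counts, 1))
  print(data.frame(class = x$classes, total = x$totals,
                   sensitivity = round(x$sensitivity, 3), row.names = NULL))
  invisible(x)
}

#' Sensitivity metrics of a confusion table
#'
#' Per-class sensitivity (diagonal over class total), the weighted average
#' sensitivity \eqn{\sum_c n_c s_c / \sum_c n_c}, and its normal-approximation
#' confidence interval treating the `reps * sum(n_c)` cross-validated
#' predictions as Bernoulli trials.
#'
#' @param ct A `"confusion_table"` (or a list with `counts`, `totals`,
#'   `reps`).
#' @param conf Confidence level (default 0.95).
#' @return List with `sensitivity` (named), `weighted` and `ci`
#'   (length-2 vector).
#' @export
confusion_metrics <- function(ct, conf = 0.95) {
  if (any(ct$totals <= 0)) stop("zero class total")
  sens <- diag(ct$counts) / ct$totals
  w <- weighted_sensitivity(sens, ct$totals)
  n_eff <- ct$reps * sum(ct$totals)
  z <- qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(w * (1 - w) / n_eff)
  list(sensitivity = setNames(sens, names(ct$totals)), weighted = w,
       ci = c(lower = max(0, w - half), upper = min(1, w + half)))
}

#' Feature selector: CE-DEGs from Games-Howell pairwise testing
#'
#' Returns a closure suitable for [repeated_stratified_cv()]: on each
#' training fold it gates genes by Kruskal-Wallis, runs Games-Howell pairwise
#' comparisons, and returns the union of per-class CE-DEG sets (falling back
#' to the gate survivors if no CE-DEG is found).
#'
#' @param alpha Significance level.
#' @return Function `(train_x, train_labels) -> gene ids`.
#' @export
cedeg_feature_selector <- function(alpha = 0.05) {
  function(train_x, train_labels) {
    gate <- kruskal_wallis_gate(train_x, train_labels, alpha)
    if (!length(gate$retained)) return(rownames(train_x))
    pw <- pairwise_significance(train_x[gate$retained, , drop = FALSE],
                                train_labels)
    feats <- unique(unlist(ce_deg_sets(pw, alpha)))
    if (!length(feats)) gate$retained else feats
  }
}

#' Feature selector: union of top pairwise t-test genes
#'
#' Closure for [repeated_stratified_cv()] applying [ttest_top_union()] and,
#' optionally, greedy decorrelation on each training fold.
#'
#' @param n_top Genes per class pair.
#' @param r_threshold Optional decorrelation cutoff (NULL to skip).
#' @return Function `(train_x, train_labels) -> gene ids`.
#' @export
top_union_selector <- function(n_top = 100L, r_threshold = NULL) {
  function(train_x, train_labels) {
    feats <- ttest_top_union(train_x, train_labels, n_top)
    if (!is.null(r_threshold))
      feats <- decorrelate_features(feats, train_x, r_threshold)
    feats
  }
}
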