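#' Stratified 10-fold cross-validation plan with validation rotation
#'
#' Splits participants into `k` near-equal subsets stratified by group. In
#' fold i the i-th subset is the test set, subset `(i mod k) + 1` is the
#' validation set, and the remaining `k - 2` subsets form the training set,
#' so every subset serves each role exactly once across the rotation and
#' every participant is tested exactly once.
#'
#' @param labels factor or character group labels.
#' @param k folds (default 10).
#' @param seed integer seed for the stratified shuffle.
#' @return Object of class `cv_plan`: list with `k`, `assignments`
#'   (participant -> subset), `folds` (per fold: `test`, `validation`,
#'   `train` index vectors), `seed`.
#' @export
make_cv_plan <- function(labels, k = 10L, seed = 1L) {
  n <- length(labels)
  if (n < 2 * k) stop("need at least 2 participants per fold")
  labels <- as.character(labels)
  set.seed(seed)
  assignments <- integer(n)
  counts <- integer(k)
  for (g in unique(labels)) {
    idx <- sample(which(labels == g))
    # hand each group's remainder to the currently least-filled subsets so
    # total subset sizes stay within one of each other
    ord <- order(counts, seq_len(k))
    assignments[idx] <- rep_len(ord, length(idx))
    counts <- counts + tabulate(assignments[idx], k)
  }
  for (s in seq_len(k)) {
    if (length(unique(labels[assignments == s])) < length(unique(labels))) {
      stop("subset ", s, " lacks a class; too few participants to stratify")
    }
  }
  folds <- lapply(seq_len(k), function(i) {
    val <- (i %% k) + 1L
    list(test = which(assignments == i),
         validation = which(assignments == val),
         train = which(!assignments %in% c(i, val)))
  })
  structure(list(k = as.integer(k), assignments = assignments, folds = folds,
                 seed = as.integer(seed)),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  sizes <- table(x$assignments)
  cat(sprintf("CV plan: %d folds, subset sizes %s (seed %d)\n",
              x$k, paste(range(sizes), collapse = "-"), x$seed))
  invisible(x)
}

#' Random-forest hyper-parameter grid
#'
#' Default grid: trees 10-150 by 10, minimum leaf size 1-11, bootstrap
#' fraction 0.5-1.0 by 0.1 (990 configurations).
#'
#' @param n_trees,min_leaf,bootstrap_fraction candidate values.
#' @return data frame, one row per configuration.
#' @export
rf_grid <- function(n_trees = seq(10L, 150L, 10L), min_leaf = 1:11,
                    bootstrap_fraction = seq(0.5, 1.0, 0.1)) {
  expand.grid(n_trees = as.integer(n_trees), min_leaf = as.integer(min_leaf),
              bootstrap_fraction = bootstrap_fraction, KEEP.OUT.ATTRS = FALSE)
}

# one deterministic forest fit (Gini splitting; per-tree bootstrap WITH
# replacement of round(fraction * n_train) cases)
fit_rf <- function(x, y, config, seed, importance = FALSE) {
  set.seed(seed)
  randomForest::randomForest(
    x = x, y = y,
    ntree = config$n_trees,
    nodesize = config$min_leaf,
    sampsize = max(2L, round(config$bootstrap_fraction * nrow(x))),
    replace = TRUE,
    importance = importance
  )
}

rf_levels <- c("HC", "MDD")

as_rf_factor <- function(labels) factor(as.character(labels), levels = rf_levels)

#' Grid search over the cross-validation rotation
#'
#' Trains each configuration on every fold's training subsets and scores it
#' on the fold's validation subset; the configuration with the highest mean
#' validation accuracy wins, ties broken deterministically towards fewer
#' trees, then larger minimum leaf, then smaller bootstrap fraction.
#'
#' @param x participants x features numeric matrix.
#' @param labels group labels (`"MDD"` / `"HC"`).
#' @param plan a `cv_plan`.
#' @param grid data frame from [rf_grid()].
#' @param seed integer seed controlling forest randomness.
#' @return the chosen configuration (one-row data frame) with
#'   `mean_val_accuracy`; `attr(, "grid_scores")` holds all scores.
#' @export
grid_search <- function(x, labels, plan, grid = rf_grid(), seed = 1L) {
  stopifnot(inherits(plan, "cv_plan"), nrow(grid) >= 1)
  if (any(!is.finite(as.matrix(x)))) stop("features must be finite")
  y <- as_rf_factor(labels)
  scores <- numeric(nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    cfg <- grid[ci, ]
    acc <- numeric(plan$k)
    for (fi in seq_len(plan$k)) {
      f <- plan$folds[[fi]]
      fit <- fit_rf(x[f$train, , drop = FALSE], y[f$train], cfg,
                    seed = seed * 1000L + fi)
      pred <- stats::predict(fit, x[f$validation, , drop = FALSE])
      acc[fi] <- mean(pred == y[f$validation])
    }
    scores[ci] <- mean(acc)
  }
  ord <- order(-scores, grid$n_trees, -grid$min_leaf, grid$bootstrap_fraction)
  best <- grid[ord[1], , drop = FALSE]
  best$mean_val_accuracy <- scores[ord[1]]
  rownames(best) <- NULL
  attr(best, "grid_scores") <- cbind(grid, mean_val_accuracy = scores)
  best
}

binary_auc <- function(score, truth_pos) {
  n1 <- sum(truth_pos); n0 <- sum(!truth_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[truth_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

classification_metrics <- function(pred, score, truth) {
  pos <- truth == "MDD"
  tp <- sum(pred == "MDD" & pos); fp <- sum(pred == "MDD" & !pos)
  fn <- sum(pred != "MDD" & pos)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  c(accuracy = 100 * mean(pred == truth),
    f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec),
    auc = binary_auc(score, pos))
}

#' Cross-validated random-forest evaluation
#'
#' Retrains the chosen configuration on each fold's training subsets,
#' predicts that fold's test subset, and pools the test predictions:
#' accuracy (percent), F1 (clinical group positive) and AUC (score = the
#' fraction of trees voting for the clinical group). 95% confidence
#' intervals come from 1000 percentile-bootstrap resamples of the pooled
#' test predictions. Out-of-bag permutation importance is computed per fold,
#' averaged, floored at zero and normalized to a maximum of one. To avoid
#' information leakage the dynamic-feature shift constant is re-derived from
#' the training subsets within each fold when unshifted score matrices are
#' supplied (a constant shift common to all features leaves forest splits,
#' and hence all reported metrics, unchanged; it is recomputed for
#' protocol fidelity).
#'
#' @param x participants x features matrix, or a `cohort_features`.
#' @param labels group labels (ignored when `x` is a `cohort_features`).
#' @param plan a `cv_plan`.
#' @param config configuration row (from [grid_search()] or [rf_grid()]).
#' @param seed integer seed.
#' @param n_boot bootstrap iterations for the CIs (default 1000).
#' @return Object of class `rf_cv`: chosen config, pooled and per-fold
#'   metrics, bootstrap CIs, normalized importances, pooled predictions.
#' @export
evaluate_rf <- function(x, labels = NULL, plan, config, seed = 1L,
                        n_boot = 1000L) {
  unshifted <- NULL
  if (inherits(x, "cohort_features")) {
    labels <- x$groups
    unshifted <- x$unshifted
    static_labels <- x$static_labels
    feats <- x$features
  } else {
    feats <- as.matrix(x)
  }
  y <- as_rf_factor(labels)
  n <- length(y)
  pred <- factor(rep(NA_character_, n), levels = rf_levels)
  score <- numeric(n)
  per_fold <- matrix(NA_real_, plan$k, 3,
                     dimnames = list(NULL, c("accuracy", "f1", "auc")))
  imp_sum <- NULL
  for (fi in seq_len(plan$k)) {
    f <- plan$folds[[fi]]
    xf <- feats
    if (!is.null(unshifted)) {
      sh_tr <- min(vapply(unshifted[f$train], min, numeric(1)))
      resh <- shift_nonnegative(unshifted, shift = sh_tr)
      dyn <- t(vapply(resh$matrices, as.vector,
                      numeric(length(as.vector(resh$matrices[[1]])))))
      xf <- cbind(feats[, static_labels, drop = FALSE], dyn)
      colnames(xf) <- colnames(feats)
    }
    fit <- fit_rf(xf[f$train, , drop = FALSE], y[f$train], config,
                  seed = seed * 1000L + fi, importance = TRUE)
    prob <- stats::predict(fit, xf[f$test, , drop = FALSE], type = "prob")[, "MDD"]
    pr <- stats::predict(fit, xf[f$test, , drop = FALSE])
    pred[f$test] <- pr
    score[f$test] <- prob
    per_fold[fi, ] <- classification_metrics(pr, prob, y[f$test])
    im <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
    imp_sum <- if (is.null(imp_sum)) im else imp_sum + im
  }
  pooled <- classification_metrics(pred, score, y)

  set.seed(seed + 777L)
  boot <- matrix(NA_real_, n_boot, 3, dimnames = list(NULL, names(pooled)))
  for (b in seq_len(n_boot)) {
    idx <- sample(n, n, replace = TRUE)
    boot[b, ] <- classification_metrics(pred[idx], score[idx], y[idx])
  }
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)

  imp <- pmax(imp_sum / plan$k, 0)
  if (max(imp) > 0) imp <- imp / max(imp)
  imp <- sort(imp, decreasing = TRUE)

  structure(
    list(config = config, pooled = pooled, per_fold = per_fold,
         per_fold_mean = colMeans(per_fold, na.rm = TRUE),
         ci = ci, importances = imp,
         predictions = data.frame(truth = y, pred = pred, score = score),
         majority_baseline = 100 * max(table(y)) / n,
         seed = seed),
    class = "rf_cv"
  )
}

#' @export
print.rf_cv <- function(x, ...) {
  cat(sprintf(
    "Random-forest CV (trees = %d, min leaf = %d, bootstrap fraction = %.1f)\n",
    x$config$n_trees, x$config$min_leaf, x$config$bootstrap_fraction))
  cat(sprintf("  pooled test accuracy %.2f%% [%.2f, %.2f]\n",
              x$pooled["accuracy"], x$ci[1, "accuracy"], x$ci[2, "accuracy"]))
  cat(sprintf("  F1 %.3f [%.3f, %.3f]; AUC %.3f [%.3f, %.3f]\n",
              x$pooled["f1"], x$ci[1, "f1"], x$ci[2, "f1"],
              x$pooled["auc"], x$ci[1, "auc"], x$ci[2, "auc"]))
  cat(sprintf("  per-fold mean accuracy %.2f%%; majority baseline %.2f%%\n",
              x$per_fold_mean["accuracy"], x$majority_baseline))
  invisible(x)
}

#' @export
summary.rf_cv <- function(object, top = 12L, ...) {
  print(object)
  cat("Top", top, "normalized feature importances:\n")
  print(round(utils::head(object$importances, top), 3))
  invisible(object)
}
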