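test_that("the cross-validation plan is stratified with a full role rotation", {
  labels <- rep(c("MDD", "HC"), c(83, 78))
  plan <- make_cv_plan(labels, k = 10, seed = 3)
  sizes <- table(plan$assignments)
  expect_true(all(sizes %in% c(16, 17)))
  tested <- sort(unlist(lapply(plan$folds, `[[`, "test")))
  expect_equal(tested, seq_along(labels))  # everyone tested exactly once
  for (f in plan$folds) {
    expect_length(intersect(f$test, f$validation), 0L)
    expect_length(intersect(f$train, union(f$test, f$validation)), 0L)
    expect_setequal(c(f$test, f$validation, f$train), seq_along(labels))
  }
  # each subset serves as validation exactly once
  vals <- vapply(seq_len(10), function(i)
    plan$assignments[plan$folds[[i]]$validation[1]], integer(1))
  expect_setequal(vals, 1:10)
  # determinism
  expect_identical(plan, make_cv_plan(labels, k = 10, seed = 3))
  expect_error(make_cv_plan(rep(c("MDD", "HC"), 5), k = 10), "at least 2")
})

test_that("the hyper-parameter grid enumerates 990 configurations", {
  g <- rf_grid()
  expect_equal(nrow(g), 990L)
  expect_equal(nrow(unique(g)), 990L)
  expect_equal(range(g$n_trees), c(10L, 150L))
  expect_equal(range(g$min_leaf), c(1L, 11L))
  expect_equal(range(g$bootstrap_fraction), c(0.5, 1.0))
  expect_equal(nrow(rf_grid_reduced()), 18L)
})

test_that("grid search breaks validation-accuracy ties towards simpler forests", {
  set.seed(5)
  n <- 60
  labels <- rep(c("MDD", "HC"), each = n / 2)
  x <- matrix(rnorm(n * 4), n, 4)
  x[labels == "MDD", 1] <- x[labels == "MDD", 1] + 8  # trivially separable
  plan <- make_cv_plan(labels, k = 5, seed = 1)
  grid <- rf_grid(n_trees = c(100L, 20L), min_leaf = c(1L, 5L),
                  bootstrap_fraction = 0.8)
  best <- grid_search(x, labels, plan, grid, seed = 2)
  expect_equal(best$mean_val_accuracy, 1)
  expect_equal(best$n_trees, 20L)   # fewer trees preferred on a tie
  expect_equal(best$min_leaf, 5L)   # then the larger leaf
  scores <- attr(best, "grid_scores")
  expect_equal(nrow(scores), 4L)
})

test_that("evaluation separates separable classes and stays at chance on permuted labels", {
  set.seed(6)
  n <- 80
  labels <- rep(c("MDD", "HC"), each = n / 2)
  x <- matrix(rnorm(n * 6), n, 6)
  x[labels == "MDD", 1] <- x[labels == "MDD", 1] + 6
  plan <- make_cv_plan(labels, k = 5, seed = 2)
  cfg <- data.frame(n_trees = 60L, min_leaf = 1L, bootstrap_fraction = 0.8)
  res <- evaluate_rf(x, labels, plan, cfg, seed = 4, n_boot = 200)
  expect_gt(res$pooled["accuracy"], 95)
  expect_gt(res$pooled["auc"], 0.99)
  expect_true(all(res$ci[1, ] <= res$pooled & res$pooled <= res$ci[2, ]))
  # permuted labels: accuracy within the binomial null band around 50%
  set.seed(11)
  perm <- sample(labels)
  plan_p <- make_cv_plan(perm, k = 5, seed = 2)
  res_p <- evaluate_rf(x, perm, plan_p, cfg, seed = 4, n_boot = 100)
  band <- 100 * (0.5 + c(-1, 1) * 3 * sqrt(0.25 / n))
  expect_gt(res_p$pooled["accuracy"], band[1])
  expect_lt(res_p$pooled["accuracy"], band[2])
})

test_that("out-of-bag importance ranks a single predictive feature first", {
  set.seed(7)
  n <- 80
  labels <- rep(c("MDD", "HC"), each = n / 2)
  x <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  x[labels == "MDD", 3] <- x[labels == "MDD", 3] + 4
  plan <- make_cv_plan(labels, k = 5, seed = 1)
  cfg <- data.frame(n_trees = 100L, min_leaf = 1L, bootstrap_fraction = 0.8)
  res <- evaluate_rf(x, labels, plan, cfg, seed = 5, n_boot = 100)
  expect_equal(names(res$importances)[1], "f3")
  expect_equal(unname(res$importances[1]), 1)
  expect_true(all(res$importances >= 0))
  # label-independent features have near-zero normalized importance
  expect_lt(max(res$importances[names(res$importances) != "f3"]), 0.2)
  # a duplicated predictive column splits importance but stays on top
  x2 <- cbind(x, f3b = x[, 3])
  res2 <- evaluate_rf(x2, labels, plan, cfg, seed = 5, n_boot = 100)
  expect_true(all(c("f3", "f3b") %in% names(res2$importances)[1:2]))
})

test_that("fixed seeds reproduce configuration, metrics and importances", {
  set.seed(8)
  n <- 40
  labels <- rep(c("MDD", "HC"), each = n / 2)
  x <- matrix(rnorm(n * 5), n, 5)
  x[labels == "MDD", 2] <- x[labels == "MDD", 2] + 1
  plan <- make_cv_plan(labels, k = 4, seed = 9)
  grid <- rf_grid(n_trees = c(30L, 60L), min_leaf = 1L, bootstrap_fraction = 0.8)
  b1 <- grid_search(x, labels, plan, grid, seed = 3)
  b2 <- grid_search(x, labels, plan, grid, seed = 3)
  expect_equal(b1$n_trees, b2$n_trees)
  r1 <- evaluate_rf(x, labels, plan, b1, seed = 3, n_boot = 100)
  r2 <- evaluate_rf(x, labels, plan, b2, seed = 3, n_boot = 100)
  expect_identical(r1$pooled, r2$pooled)
  expect_identical(r1$importances, r2$importances)
  expect_identical(r1$ci, r2$ci)
})
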