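test_that("test selection follows the normality screen", {
  set.seed(1)
  expect_equal(choose_test(rnorm(80), rnorm(80)), "student_t")
  # strongly skewed samples are routed to the rank-sum test
  skew_picks <- vapply(1:5, function(i) {
    set.seed(i)
    choose_test(rexp(80), rexp(80))
  }, character(1))
  expect_true(all(skew_picks == "wilcoxon_ranksum"))
  expect_equal(choose_test(rep(1, 10), rnorm(10)), "wilcoxon_ranksum")
  expect_error(choose_test(1:2, rnorm(10)), "at least 3")
})

test_that("2x2 chi-square without continuity correction matches closed forms", {
  sex <- matrix(c(37, 36, 46, 42), 2, 2)
  res <- chi_square_2x2(sex)
  expect_equal(round(res$statistic, 3), 0.040)
  expect_equal(round(res$p, 3), 0.841)
  expect_equal(res$df, 1)
  # transpose invariance
  expect_equal(chi_square_2x2(t(sex))$statistic, res$statistic)
  # proportional table -> 0; diagonal table -> n
  expect_equal(chi_square_2x2(matrix(c(10, 20, 20, 40), 2))$statistic, 0)
  expect_equal(chi_square_2x2(matrix(c(20, 0, 0, 20), 2))$statistic, 40)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "marginal")
  expect_error(chi_square_2x2(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("BH adjustment matches a hand-rolled step-up on random vectors", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_fdr(rep(0.2, 4)), rep(0.2, 4))
  step_up <- function(p) {
    m <- length(p); o <- order(p)
    q <- p[o] * m / seq_len(m)
    for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
    pmin(1, q)[order(o)]
  }
  for (i in 1:5) {
    set.seed(i)
    p <- runif(20)
    expect_equal(bh_fdr(p), step_up(p))
  }
  set.seed(9); p <- runif(30)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("fluoxetine equivalents follow the published table", {
  expect_equal(fluoxetine_equivalent("sertraline", 98.5), 40)
  expect_equal(fluoxetine_equivalent("fluoxetine", 20), 20)
  expect_equal(fluoxetine_equivalent("venlafaxine", 74.7), 20)
  # multiple medications sum
  expect_equal(fluoxetine_equivalent(c("fluoxetine", "paroxetine"), c(20, 34)),
               60)
  expect_error(fluoxetine_equivalent("prozac", 20), "supported")
  expect_error(fluoxetine_equivalent("sertraline", -5), ">= 0")
})

test_that("the score inclusion screen applies the majority rule", {
  cl <- data.frame(
    group = rep("MDD", 83),
    dass_d = rep(16, 83),                      # all above 14
    dass_a = c(rep(9, 76), rep(5, 7)),         # 76 above 7
    dass_s = c(rep(15, 19), rep(10, 64)),      # only 19 above 14
    shaps = rep(33, 83)
  )
  expect_setequal(include_scores(cl), c("dass_d", "dass_a", "shaps"))
})

test_that("Spearman feature-symptom screening works on the clinical group", {
  set.seed(2)
  n <- 40
  ids <- sprintf("MDD%03d", 1:n)
  f <- matrix(cbind(sort(rnorm(n)), rnorm(n)), n, 2,
              dimnames = list(ids, c("static|A~B", "static|C~D")))
  cl <- data.frame(id = ids, group = "MDD", dass_d = seq_len(n) + 0,
                   shaps = sample(0:42, n, TRUE))
  res <- spearman_feature_symptoms(f, cl, scores = c("dass_d", "shaps"))
  r1 <- res$r[res$feature == "static|A~B" & res$score == "dass_d"]
  expect_equal(r1, 1)  # strictly increasing feature
  # permuted score stays in the null band with q near 1
  r2 <- res[res$feature == "static|C~D" & res$score == "dass_d", ]
  expect_lt(abs(r2$r), 3 / sqrt(n))
  expect_gt(r2$q, 0.5)
  # constant feature reported as missing
  f2 <- cbind(f, "static|E~F" = 1)
  res2 <- spearman_feature_symptoms(f2, cl, scores = "dass_d")
  expect_true(is.na(res2$r[res2$feature == "static|E~F"]))
})

test_that("regression recovers planted standardized coefficients", {
  mk_clinical <- function(n, y) {
    data.frame(id = sprintf("MDD%03d", 1:n), group = "MDD",
               age = runif(n, 12, 18), sex = sample(c("male", "female"), n, TRUE),
               duration_months = runif(n, 1, 36),
               medication = "fluoxetine", dose_mg_day = 20,
               dass_d = y)
  }
  set.seed(3)
  n <- 83
  x <- rnorm(n)
  f <- matrix(x, n, 1, dimnames = list(sprintf("MDD%03d", 1:n), "static|A~B"))
  # exact linear outcome: R^2 = 1
  res <- suppressWarnings(
    regress_clinical("dass_d", f, mk_clinical(n, 2 * x + 5), "static|A~B"))
  expect_equal(res$r_squared, 1, tolerance = 1e-9)
  expect_equal(res$adj_r_squared, 1, tolerance = 1e-9)
  # independent outcome: adjusted R^2 near zero (may be negative)
  res0 <- regress_clinical("dass_d", f, mk_clinical(n, rnorm(n)), "static|A~B")
  expect_lt(abs(res0$adj_r_squared), 0.15)
  # planted beta = -0.5 with noise tuned to R^2 ~ 0.3
  y <- -0.5 * x + rnorm(n, sd = 0.76)
  res1 <- regress_clinical("dass_d", f, mk_clinical(n, y), "static|A~B")
  b <- res1$coefficients["`static|A~B`", "Estimate"]
  if (is.na(b)) b <- res1$coefficients["static|A~B", "Estimate"]
  expect_lt(abs(b - (-0.5)), 0.2)
  expect_true(all(res1$vif >= 1))
  expect_lte(res1$adj_r_squared, res1$r_squared)
  # collinear design is refused with the offending column named
  f2 <- cbind(f, "static|A~C" = x)
  expect_error(regress_clinical("dass_d", f2, mk_clinical(n, y),
                                c("static|A~B", "static|A~C")), "singular")
})

test_that("group comparison applies family-wise BH and flags planted effects", {
  set.seed(4)
  n <- 60
  g <- rep(c("MDD", "HC"), each = n / 2)
  f <- matrix(rnorm(n * 6), n,
              dimnames = list(NULL, c(paste0("static|P", 1:3),
                                      paste0("PC1|P", 1:3))))
  f[g == "MDD", "static|P1"] <- f[g == "MDD", "static|P1"] + 1.5
  gs <- group_compare(f, g)
  expect_s3_class(gs, "group_stats")
  expect_equal(sort(unique(gs$family)), c("PC1", "static"))
  expect_lt(gs$q[gs$feature == "static|P1"], 0.05)
  expect_equal(gs$direction[gs$feature == "static|P1"], 1)
  # q >= p always
  expect_true(all(gs$q >= gs$p - 1e-12))
})
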