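#' Choose the two-group test for a continuous feature
#'
#' Lilliefors-corrected one-sample Kolmogorov-Smirnov normality test per
#' group at alpha = 0.05: if both groups look normal, the two-sided
#' pooled-variance Student t-test; otherwise the Wilcoxon rank-sum test.
#' Degenerate (constant) samples fall back to the rank-sum test.
#'
#' @param x,y numeric vectors (>= 3 values each).
#' @param alpha normality-test level.
#' @return `"student_t"` or `"wilcoxon_ranksum"`.
#' @export
choose_test <- function(x, y, alpha = 0.05) {
  if (length(x) < 3 || length(y) < 3) stop("need at least 3 values per group")
  normal <- function(v) {
    if (length(unique(v)) < 2) return(FALSE)
    if (length(v) < 5) return(FALSE)  # Lilliefors needs n >= 5
    nortest::lillie.test(v)$p.value >= alpha
  }
  if (normal(x) && normal(y)) "student_t" else "wilcoxon_ranksum"
}

#' Pearson chi-square test on a 2 x 2 count table
#'
#' Without continuity correction, df = 1.
#'
#' @param tab 2 x 2 matrix of non-negative integer counts.
#' @return list with `statistic`, `p`, `df`.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) stop("zero marginal in count table")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), p = unname(ct$p.value),
       df = unname(ct$parameter))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up q-values `q_i = min_(j >= rank(i)) p_(j) * m / j`, capped at 1,
#' returned in the input order (delegates to `stats::p.adjust`).
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Between-group comparison of every feature with family-wise BH correction
#'
#' For each feature column the test chosen by [choose_test()] is run
#' two-sided; q-values are computed within feature families: all static
#' features form one family and each principal-component order forms its own
#' (the `"PC<k>|"` label prefix), matching per-map presentation. Set
#' `family = "all"` to correct across every feature at once.
#'
#' @param features a `cohort_features` or a participants x features matrix.
#' @param groups group labels (taken from the object if omitted); the first
#'   level of `c("MDD","HC")` ordering is the clinical group.
#' @param family `"prefix"` (default) or `"all"`.
#' @return data frame of class `group_stats`: `feature`, `family`,
#'   `test_name`, `statistic`, `p`, `q`, `direction` (sign of clinical minus
#'   control mean).
#' @export
group_compare <- function(features, groups = NULL, family = c("prefix", "all")) {
  family <- match.arg(family)
  if (inherits(features, "cohort_features")) {
    if (is.null(groups)) groups <- features$groups
    features <- features$features
  }
  stopifnot(!is.null(groups), nrow(features) == length(groups))
  g1 <- groups == "MDD"
  fam <- sub("\\|.*$", "", colnames(features))
  if (family == "all") fam <- rep("all", ncol(features))
  out <- data.frame(feature = colnames(features), family = fam,
                    test_name = NA_character_, statistic = NA_real_,
                    p = NA_real_, q = NA_real_, direction = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(features))) {
    x <- features[g1, j]; y <- features[!g1, j]
    tn <- choose_test(x, y)
    if (tn == "student_t") {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      out$statistic[j] <- unname(tt$statistic); out$p[j] <- tt$p.value
    } else {
      wt <- stats::wilcox.test(x, y, exact = FALSE)
      out$statistic[j] <- unname(wt$statistic); out$p[j] <- wt$p.value
    }
    out$test_name[j] <- tn
    out$direction[j] <- sign(mean(x) - mean(y))
  }
  for (f in unique(out$family)) {
    idx <- out$family == f
    out$q[idx] <- bh_fdr(out$p[idx])
  }
  class(out) <- c("group_stats", "data.frame")
  out
}

#' @export
print.group_stats <- function(x, ...) {
  cols <- c("feature", "test_name", "statistic", "p", "q")
  if (!all(cols %in% names(x))) return(NextMethod())
  sig <- x[!is.na(x$q) & x$q < 0.05, ]
  cat(sprintf("Group comparison: %d features, %d significant at q < 0.05\n",
              nrow(x), nrow(sig)))
  if (nrow(sig) > 0) print.data.frame(sig[, cols], row.names = FALSE, digits = 3)
  invisible(x)
}

#' Clinical-score inclusion screen
#'
#' A symptom score enters the correlation analyses when a cohort majority of
#' the clinical group exceeds its clinical threshold (defaults: depression
#' subscale 14, anxiety 7, stress 14); the anhedonia score is always
#' included.
#'
#' @param clinical a `clinical_table` (clinical-group rows are used).
#' @param thresholds named list of clinical cut-offs.
#' @return character vector of included score columns.
#' @export
include_scores <- function(clinical,
                           thresholds = list(dass_d = 14, dass_a = 7, dass_s = 14)) {
  cl <- clinical[clinical$group == "MDD", , drop = FALSE]
  keep <- character(0)
  for (sc in names(thresholds)) {
    if (sum(cl[[sc]] > thresholds[[sc]], na.rm = TRUE) > nrow(cl) / 2) {
      keep <- c(keep, sc)
    }
  }
  c(keep, "shaps")
}

#' Spearman correlations between features and symptom scores
#'
#' Clinical-group rows only; tie-corrected Spearman rank correlation of
#' every feature x score combination, with BH correction across the full
#' grid (one family).
#'
#' @param features a `cohort_features` or matrix with participant row names.
#' @param clinical a `clinical_table` aligned by `id`.
#' @param scores score columns to use; default [include_scores()].
#' @param feature_subset optional character vector of feature columns.
#' @return data frame of class `fc_correlations`: `feature`, `score`, `r`,
#'   `p`, `q`.
#' @export
spearman_feature_symptoms <- function(features, clinical, scores = NULL,
                                      feature_subset = NULL) {
  if (inherits(features, "cohort_features")) {
    groups <- features$groups
    fm <- features$features
  } else {
    fm <- as.matrix(features)
    groups <- clinical$group[match(rownames(fm), clinical$id)]
  }
  if (is.null(scores)) scores <- include_scores(clinical)
  cl <- clinical[match(rownames(fm), clinical$id), , drop = FALSE]
  keep <- which(groups == "MDD")
  fm <- fm[keep, , drop = FALSE]
  cl <- cl[keep, , drop = FALSE]
  if (!is.null(feature_subset)) fm <- fm[, feature_subset, drop = FALSE]
  grid <- expand.grid(feature = colnames(fm), score = scores,
                      stringsAsFactors = FALSE)
  grid$r <- NA_real_; grid$p <- NA_real_
  for (i in seq_len(nrow(grid))) {
    x <- fm[, grid$feature[i]]
    y <- cl[[grid$score[i]]]
    if (stats::sd(x) == 0 || stats::sd(y, na.rm = TRUE) == 0) next
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    grid$r[i] <- unname(ct$estimate); grid$p[i] <- ct$p.value
  }
  grid$q <- NA_real_
  ok <- !is.na(grid$p)
  grid$q[ok] <- bh_fdr(grid$p[ok])
  class(grid) <- c("fc_correlations", "data.frame")
  grid
}

#' Fluoxetine-equivalent antidepressant dose
#'
#' Converts a daily dose of one of the five supported antidepressants to the
#' equivalent fluoxetine dose: `dose * 40 / equivalent_dose`, where the
#' equivalence table is fluoxetine 40, sertraline 98.5, paroxetine 34,
#' clomipramine 116.1, venlafaxine 149.4 mg/day. Vectors of several
#' medications for one participant sum.
#'
#' @param drug drug name(s), case-insensitive.
#' @param dose_mg_day daily dose(s), mg.
#' @return fluoxetine-equivalent mg/day (sum over entries).
#' @export
fluoxetine_equivalent <- function(drug, dose_mg_day) {
  tab <- fluoxetine_equivalence_table()
  drug <- tolower(drug)
  unknown <- setdiff(drug, names(tab))
  if (length(unknown) > 0) {
    stop("unknown drug(s): ", paste(unknown, collapse = ", "),
         "; supported: ", paste(names(tab), collapse = ", "))
  }
  if (any(dose_mg_day < 0)) stop("dose must be >= 0")
  sum(dose_mg_day * 40 / tab[drug])
}

#' @rdname fluoxetine_equivalent
#' @export
fluoxetine_equivalence_table <- function() {
  c(fluoxetine = 40, sertraline = 98.5, paroxetine = 34,
    clomipramine = 116.1, venlafaxine = 149.4)
}

#' Covariate-adjusted multiple linear regression on a symptom score
#'
#' Ordinary least squares of one clinical-group symptom score on selected
#' features plus the four covariates (age, sex as 0/1, illness duration,
#' fluoxetine-equivalent dose). Continuous variables are z-scored so slopes
#' are standardized betas. Reports adjusted R-squared, per-predictor t and
#' p, variance-inflation factors, a Breusch-Pagan homoscedasticity flag and
#' a Shapiro-Wilk residual-normality flag.
#'
#' @param outcome score column name.
#' @param features a `cohort_features` or matrix.
#' @param clinical a `clinical_table`.
#' @param feature_cols feature columns to enter as predictors.
#' @return Object of class `fc_regression`.
#' @export
regress_clinical <- function(outcome, features, clinical, feature_cols) {
  if (inherits(features, "cohort_features")) {
    groups <- features$groups
    fm <- features$features
  } else {
    fm <- as.matrix(features)
    groups <- clinical$group[match(rownames(fm), clinical$id)]
  }
  cl <- clinical[match(rownames(fm), clinical$id), , drop = FALSE]
  keep <- which(groups == "MDD")
  fm <- fm[keep, feature_cols, drop = FALSE]
  cl <- cl[keep, , drop = FALSE]
  fluox <- mapply(function(d, x) if (is.na(d)) 0 else fluoxetine_equivalent(d, x),
                  cl$medication, cl$dose_mg_day)
  zs <- function(v) if (stats::sd(v) == 0) v * 0 else (v - mean(v)) / stats::sd(v)
  df <- data.frame(
    y = zs(cl[[outcome]]),
    apply(fm, 2, zs),
    age = zs(cl$age),
    sex = as.numeric(cl$sex == "male"),
    duration = zs(cl$duration_months),
    fluox_eq = zs(fluox),
    check.names = FALSE
  )
  # zero-variance covariates (e.g. a uniform dose) carry no information
  keep_cols <- c(TRUE, vapply(df[-1], function(v) stats::sd(v) > 0, logical(1)))
  df <- df[, keep_cols, drop = FALSE]
  n <- nrow(df); p <- ncol(df) - 1
  if (n <= p + 1) stop("need n > number of predictors + 1")
  qrX <- qr(as.matrix(df[, -1]))
  if (qrX$rank < p) {
    stop("singular design; collinear column(s): ",
         paste(colnames(df)[-1][qrX$pivot[(qrX$rank + 1):p]], collapse = ", "))
  }
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)
  vifs <- if (p > 1) car::vif(fit) else stats::setNames(1, colnames(df)[2])
  bp <- lmtest::bptest(fit)
  swp <- tryCatch(stats::shapiro.test(stats::residuals(fit))$p.value,
                  error = function(e) NA_real_)
  fstat <- sm$fstatistic
  structure(
    list(outcome = outcome,
         coefficients = sm$coefficients,
         r_squared = sm$r.squared,
         adj_r_squared = sm$adj.r.squared,
         model_p = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                    lower.tail = FALSE)),
         vif = vifs,
         homoscedastic = bp$p.value >= 0.05,
         bp_p = unname(bp$p.value),
         residuals_normal = is.na(swp) || swp >= 0.05,
         shapiro_p = swp,
         n = n, fit = fit),
    class = "fc_regression"
  )
}

#' @export
print.fc_regression <- function(x, ...) {
  cat(sprintf("Regression of %s (n = %d): adj R^2 = %.3f, model p = %.4f\n",
              x$outcome, x$n, x$adj_r_squared, x$model_p))
  print(round(x$coefficients, 4))
  cat(sprintf("  homoscedastic: %s (BP p = %.3f); residuals normal: %s\n",
              x$homoscedastic, x$bp_p, x$residuals_normal))
  invisible(x)
}
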