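#' Reduced hyper-parameter grid
#'
#' A 3 x 3 x 2 sub-grid of the full 990-configuration search space, spanning
#' its corners; the full grid ([rf_grid()]) remains available where the
#' compute budget allows.
#'
#' @return data frame of 18 configurations.
#' @export
rf_grid_reduced <- function() {
  rf_grid(n_trees = c(50L, 100L, 150L), min_leaf = c(1L, 5L, 9L),
          bootstrap_fraction = c(0.6, 0.8))
}

#' Run the complete analysis pipeline on a cohort
#'
#' Stages, in order: channel quality control (baseline SNR, 40-dB rule),
#' preprocessing to ROI oxyhemoglobin traces, static and sliding-window
#' connectivity, principal-component feature extraction with CCR-based
#' selection and cohort shifting, between-group statistics with BH
#' correction, feature-symptom Spearman correlations and covariate-adjusted
#' regressions (clinical group), and cross-validated random-forest
#' classification.
#'
#' @param cohort a `synthetic_cohort`, or a list with `recordings`,
#'   `clinical` and `montage` built from files.
#' @param threshold_db QC threshold (dB).
#' @param params a `preprocess_params`.
#' @param window_s,step_s sliding-window parameters (s).
#' @param grid hyper-parameter grid (default [rf_grid_reduced()]); `NULL`
#'   skips the search and uses `config`.
#' @param config forest configuration used when `grid` is `NULL`.
#' @param k cross-validation folds.
#' @param cv_seed,rf_seed seeds for the fold assignment and the forests.
#' @param run_classifier,run_stats stage switches.
#' @return Object of class `fnirs_pipeline` with elements `qc`, `features`,
#'   `group_stats`, `correlations`, `regressions`, `cv`, `chosen_config`.
#' @export
run_pipeline <- function(cohort, threshold_db = 40,
                         params = preprocess_params(),
                         window_s = 20, step_s = 1,
                         grid = rf_grid_reduced(), config = NULL,
                         k = 10L, cv_seed = 1L, rf_seed = 1L,
                         run_classifier = TRUE, run_stats = TRUE) {
  feats <- extract_cohort_features(cohort$recordings, cohort$montage,
                                   threshold_db = threshold_db,
                                   params = params,
                                   window_s = window_s, step_s = step_s)
  out <- list(qc = attr(feats, "qc"), features = feats)

  if (run_stats) {
    out$group_stats <- group_compare(feats)
    scores <- include_scores(cohort$clinical)
    out$included_scores <- scores
    out$correlations <- spearman_feature_symptoms(feats, cohort$clinical,
                                                  scores = scores)
    out$regressions <- list()
    for (sc in scores) {
      sig <- out$correlations
      sig <- sig$feature[sig$score == sc & !is.na(sig$q) & sig$q < 0.05]
      if (length(sig) == 0) next
      reg <- tryCatch(
        regress_clinical(sc, feats, cohort$clinical, feature_cols = sig),
        error = function(e) {
          warning("regression for ", sc, " skipped: ", conditionMessage(e))
          NULL
        })
      if (!is.null(reg)) out$regressions[[sc]] <- reg
    }
  }

  if (run_classifier) {
    plan <- make_cv_plan(feats$groups, k = k, seed = cv_seed)
    chosen <- if (is.null(grid)) config else
      grid_search(feats$features, feats$groups, plan, grid, seed = rf_seed)
    out$chosen_config <- chosen
    out$cv <- evaluate_rf(feats, plan = plan, config = chosen, seed = rf_seed)
    out$cv_plan <- plan
  }
  class(out) <- "fnirs_pipeline"
  out
}

#' @export
print.fnirs_pipeline <- function(x, ...) {
  cat("fNIRS connectivity pipeline result\n")
  print(x$features)
  if (!is.null(x$group_stats)) {
    cat(sprintf("  %d feature(s) differ between groups at q < 0.05\n",
                sum(x$group_stats$q < 0.05, na.rm = TRUE)))
  }
  if (!is.null(x$cv)) print(x$cv)
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' `features.csv`, `qc_report.tsv`, `group_stats.tsv`, `correlations.tsv`,
#' `regression.json`, `cv_result.json`, `importances.tsv`,
#' `predictions.csv` and a `manifest.json` provenance block (stage
#' parameters and seeds).
#'
#' @param result an `fnirs_pipeline`.
#' @param dir output directory.
#' @param params the `preprocess_params` used (stored in the manifest).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(result, dir, params = preprocess_params()) {
  stopifnot(inherits(result, "fnirs_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fe <- result$features
  utils::write.csv(
    data.frame(id = fe$ids, group = fe$groups, fe$features,
               check.names = FALSE),
    file.path(dir, "features.csv"), row.names = FALSE)
  qc <- result$qc
  utils::write.table(
    data.frame(channel = rownames(qc$snr_db), qc$snr_db,
               pass = !rownames(qc$snr_db) %in% as.character(qc$excluded_channels),
               check.names = FALSE),
    file.path(dir, "qc_report.tsv"), sep = "\t", row.names = FALSE)
  if (!is.null(result$group_stats)) {
    utils::write.table(result$group_stats, file.path(dir, "group_stats.tsv"),
                       sep = "\t", row.names = FALSE)
    utils::write.table(result$correlations, file.path(dir, "correlations.tsv"),
                       sep = "\t", row.names = FALSE)
    jsonlite::write_json(
      lapply(result$regressions, function(r) list(
        outcome = r$outcome, adj_r_squared = r$adj_r_squared,
        model_p = r$model_p,
        coefficients = as.data.frame(r$coefficients),
        vif = as.list(r$vif), homoscedastic = r$homoscedastic,
        residuals_normal = r$residuals_normal, n = r$n)),
      file.path(dir, "regression.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(result$cv)) {
    cv <- result$cv
    jsonlite::write_json(
      list(config = as.list(cv$config), pooled = as.list(cv$pooled),
           per_fold_mean = as.list(cv$per_fold_mean),
           ci = as.data.frame(cv$ci), majority_baseline = cv$majority_baseline,
           seed = cv$seed),
      file.path(dir, "cv_result.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(
      data.frame(feature = names(cv$importances),
                 importance = unname(cv$importances)),
      file.path(dir, "importances.tsv"), sep = "\t", row.names = FALSE)
    utils::write.csv(cv$predictions, file.path(dir, "predictions.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    package = "fnirsdfc",
    version = as.character(utils::packageVersion("fnirsdfc")),
    n_components = fe$n_components, shift_constant = fe$shift_constant,
    qc_threshold_db = qc$threshold_db,
    preprocess = unclass(params),
    artifacts = list.files(dir)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a per-participant time-series CSV
#'
#' Header row required; first column `time_s`, remaining columns channels.
#' Ragged rows, non-numeric cells and decimal-comma files are rejected with
#' the offending row/column named.
#'
#' @param path CSV path.
#' @return list with `time_s` and `data` (time x channel matrix).
#' @export
read_timeseries <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("expected a time column plus at least one channel")
  for (j in seq_len(ncol(raw))) {
    v <- raw[[j]]
    if (any(grepl(",", v, fixed = TRUE))) {
      stop("decimal-comma value in column '", colnames(raw)[j],
           "'; use '.' as the decimal separator")
    }
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num) & !is.na(v) & nzchar(v))) {
      stop(sprintf("non-numeric cell at row %d, column '%s'",
                   which(is.na(num))[1], colnames(raw)[j]))
    }
    raw[[j]] <- num
  }
  m <- as.matrix(raw[, -1, drop = FALSE])
  list(time_s = raw[[1]], data = m)
}

#' Write / read a labelled numeric matrix as CSV
#'
#' Round-trip stable to better than 1e-12 (full precision serialisation);
#' row and column labels preserved.
#'
#' @param m numeric matrix with dimnames.
#' @param path CSV path.
#' @return `write_matrix`: `path` invisibly; `read_matrix`: the matrix.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(label = rownames(m) %||% as.character(seq_len(nrow(m))),
                   m, check.names = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
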