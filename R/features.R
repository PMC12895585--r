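#' Build the cohort feature table from ROI time series
#'
#' For every participant: the 15 static Fisher-z pair values, and the 15 x N
#' principal-component scores of the window-wise connectivity matrix,
#' flattened with labels `"PC<k>|<pair>"`. One N is selected on the
#' cohort-mean cumulative-contribution-rate curve; the component scores are
#' shifted by the global cohort minimum so all dynamic features are
#' non-negative.
#'
#' @param roi_list list of `roi_timeseries` objects.
#' @param window_s,step_s sliding-window parameters (seconds).
#' @param ccr_lo,ccr_hi component-selection band in percent.
#' @param n_components optional fixed N (overrides CCR selection).
#' @return Object of class `cohort_features`: list with `features`
#'   (participants x (15 + 15N) matrix, row names = participant ids),
#'   `groups`, `ids`, `n_components`, `shift_constant`, `mean_ccr`,
#'   `unshifted` (list of raw D matrices, used for leakage-free shifting
#'   inside cross-validation), `static_labels`, `dynamic_labels`.
#' @export
build_features <- function(roi_list, window_s = 20, step_s = 1,
                           ccr_lo = 90, ccr_hi = 95, n_components = NULL) {
  stopifnot(length(roi_list) >= 1)
  ids <- vapply(roi_list, function(r) r$id %||% NA_character_, character(1))
  if (any(is.na(ids))) ids <- paste0("P", seq_along(roi_list))
  groups <- vapply(roi_list, function(r) r$group %||% NA_character_, character(1))

  statics <- lapply(roi_list, static_fc)
  dynamics <- lapply(roi_list, dynamic_fc, window_s = window_s, step_s = step_s)
  decomps <- lapply(dynamics, pca_decompose)
  if (is.null(n_components)) {
    N <- select_n_components(decomps, ccr_lo, ccr_hi)
    mean_ccr <- attr(N, "mean_ccr")
  } else {
    N <- as.integer(n_components)
    mean_ccr <- rowMeans(vapply(decomps, function(d) d$ccr_curve,
                                numeric(length(decomps[[1]]$ccr_curve))))
  }
  d_list <- lapply(decomps, project_components, N = N)
  sh <- shift_nonnegative(d_list)

  pairs <- roi_pair_names()
  static_labels <- paste0("static|", pairs)
  dynamic_labels <- as.vector(vapply(
    seq_len(N), function(k) paste0("PC", k, "|", pairs), character(length(pairs))
  ))
  feat <- matrix(NA_real_, length(roi_list), length(static_labels) + length(dynamic_labels),
                 dimnames = list(ids, c(static_labels, dynamic_labels)))
  for (i in seq_along(roi_list)) {
    dvec <- as.vector(sh$matrices[[i]])  # column-major: PC1 pairs, PC2 pairs, ...
    feat[i, ] <- c(statics[[i]]$pair_vector, dvec)
  }
  structure(
    list(features = feat, groups = groups, ids = ids,
         n_components = as.integer(N), shift_constant = sh$shift_constant,
         mean_ccr = mean_ccr, unshifted = d_list,
         static_labels = static_labels, dynamic_labels = dynamic_labels),
    class = "cohort_features"
  )
}

#' @export
print.cohort_features <- function(x, ...) {
  cat(sprintf(
    "Cohort feature table: %d participants x %d features (15 static + 15 x %d dynamic)\n",
    nrow(x$features), ncol(x$features), x$n_components
  ))
  cat(sprintf("  shift constant %.4f, mean CCR(N) %.1f%%\n",
              x$shift_constant, x$mean_ccr[x$n_components]))
  invisible(x)
}

#' @export
summary.cohort_features <- function(object, ...) {
  print(object)
  tab <- table(object$groups)
  cat("  groups:", paste(sprintf("%s = %d", names(tab), tab), collapse = ", "), "\n")
  invisible(object)
}

#' Run QC + preprocessing + feature extraction on a cohort of recordings
#'
#' Convenience wrapper: cohort-wide channel QC, per-participant
#' preprocessing to ROI traces, then [build_features()].
#'
#' @param recordings list of `fnirs_recording` objects.
#' @param montage the full acquisition `montage`.
#' @param threshold_db QC retention threshold (dB).
#' @param params a `preprocess_params`.
#' @param ... passed to [build_features()].
#' @return a `cohort_features`; `attr(, "qc")` holds the `qc_report`.
#' @export
extract_cohort_features <- function(recordings, montage, threshold_db = 40,
                                    params = preprocess_params(), ...) {
  qc <- qc_cohort(recordings, threshold_db)
  montage_qc <- suppressMessages(apply_channel_filter(qc, montage))
  roi_list <- lapply(recordings, preprocess_recording, montage = montage_qc,
                     params = params)
  out <- build_features(roi_list, ...)
  attr(out, "qc") <- qc
  out
}
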