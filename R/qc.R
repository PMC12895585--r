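#' Baseline signal-to-noise ratio per channel and wavelength
#'
#' SNR in decibels of the quiet baseline segment, `20 * log10(mean / sd)`
#' per channel, with the sample (n-1) standard deviation. A non-positive
#' baseline mean leaves the SNR undefined (`NaN`, flagged downstream); a zero
#' sd gives `+Inf` and counts as passing.
#'
#' @param baseline time x channel matrix of baseline intensity samples.
#' @return Named numeric vector of SNR values (dB) per channel.
#' @export
compute_snr <- function(baseline) {
  baseline <- as.matrix(baseline)
  if (nrow(baseline) < 2) stop("baseline needs at least 2 samples per channel")
  if (any(!is.finite(baseline))) stop("baseline contains non-finite values")
  mu <- colMeans(baseline)
  sdv <- apply(baseline, 2, stats::sd)
  snr <- rep(NaN, length(mu))
  ok <- mu > 0
  snr[ok & sdv == 0] <- Inf
  idx <- ok & sdv > 0
  snr[idx] <- 20 * log10(mu[idx] / sdv[idx])
  names(snr) <- colnames(baseline)
  snr
}

#' Channel quality control over a cohort of recordings
#'
#' Computes the baseline SNR of every channel at both wavelengths for every
#' recording and applies the retention rule: a channel is kept only if its
#' SNR is at or above `threshold_db` at *both* wavelengths (equivalently, it
#' is excluded if it falls below threshold in at least one wavelength). In
#' the default cohort-wide mode a channel failing in any participant is
#' excluded for all participants, so every analysis uses one common montage;
#' `mode = "per_participant"` reports failures participant by participant
#' instead.
#'
#' @param recordings list of `fnirs_recording` objects (or a single one).
#' @param threshold_db retention threshold in dB (default 40).
#' @param mode `"cohort"` (default) or `"per_participant"`.
#' @return Object of class `qc_report`: list with `snr_db` (channel x
#'   wavelength matrix of the cohort minimum SNR), `threshold_db`,
#'   `excluded_channels`, `retained_channels`, `undefined` (channels with
#'   non-positive baseline mean anywhere), `mode`, and in per-participant
#'   mode a `per_participant` list of excluded sets.
#' @export
qc_cohort <- function(recordings, threshold_db = 40, mode = c("cohort", "per_participant")) {
  mode <- match.arg(mode)
  if (inherits(recordings, "fnirs_recording")) recordings <- list(recordings)
  stopifnot(length(recordings) > 0)
  wl <- names(recordings[[1]]$intensity)
  ch <- colnames(recordings[[1]]$intensity[[1]])
  min_snr <- matrix(Inf, length(ch), length(wl), dimnames = list(ch, wl))
  undefined <- character(0)
  per_part <- list()
  for (rec in recordings) {
    excl_i <- character(0)
    for (w in wl) {
      base <- rec$intensity[[w]][seq_len(rec$baseline_n), , drop = FALSE]
      snr <- compute_snr(base)
      undefined <- union(undefined, ch[is.nan(snr)])
      min_snr[, w] <- pmin(min_snr[, w], ifelse(is.nan(snr), -Inf, snr))
      excl_i <- union(excl_i, ch[is.nan(snr) | snr < threshold_db])
    }
    per_part[[rec$id]] <- sort(as.integer(excl_i))
  }
  fails <- apply(min_snr, 1, min) < threshold_db
  excluded <- ch[fails]
  structure(
    list(
      snr_db = min_snr, threshold_db = threshold_db,
      excluded_channels = sort(as.integer(excluded)),
      retained_channels = sort(as.integer(setdiff(ch, excluded))),
      undefined = sort(as.integer(undefined)),
      mode = mode,
      per_participant = if (mode == "per_participant") per_part else NULL
    ),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "QC report (%s mode, threshold %g dB): %d retained, %d excluded\n",
    x$mode, x$threshold_db, length(x$retained_channels),
    length(x$excluded_channels)
  ))
  if (length(x$excluded_channels) > 0) {
    cat("  excluded:", paste(x$excluded_channels, collapse = ", "), "\n")
  }
  if (length(x$undefined) > 0) {
    cat("  undefined SNR (non-positive baseline mean):",
        paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Restrict a montage to the channels passing quality control
#'
#' @param report a `qc_report` covering every montage channel.
#' @param montage a `montage`.
#' @return The montage restricted to retained channels. Errors if an entire
#'   ROI loses all channels (ROI aggregation would be impossible).
#' @export
apply_channel_filter <- function(report, montage) {
  stopifnot(inherits(report, "qc_report"), inherits(montage, "montage"))
  all_ch <- montage$channels$channel
  covered <- union(report$retained_channels, report$excluded_channels)
  if (!all(all_ch %in% covered)) {
    stop("QC report does not cover montage channel(s): ",
         paste(setdiff(all_ch, covered), collapse = ", "))
  }
  keep <- intersect(all_ch, report$retained_channels)
  message(sprintf("QC: retaining %d of %d channels", length(keep), length(all_ch)))
  subset_montage(montage, keep)
}
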