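#' Fisher z-transformation of a correlation coefficient
#'
#' `z = atanh(r)` with `|r|` clipped to `1 - 1e-7` first, so degenerate
#' perfectly correlated inputs stay finite.
#'
#' @param r correlation value(s), `|r| <= 1`.
#' @return Fisher-z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must be <= 1")
  out <- atanh(pmin(1 - 1e-7, pmax(-(1 - 1e-7), as.numeric(r))))
  attributes(out) <- attributes(r)
  out
}

# upper-triangle (row-major) flattening of a symmetric ROI matrix into the
# fixed 15-element pair order
pair_vector <- function(m, rois = roi_names()) {
  n <- nrow(m)
  out <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) out <- c(out, m[i, j])
  }
  stats::setNames(out, roi_pair_names(rois))
}

#' Static functional connectivity over the whole analysis period
#'
#' Pairwise Pearson correlation of the six ROI traces over all samples,
#' Fisher z-transformed; one 6 x 6 symmetric matrix and its fixed-order
#' 15-element pair vector.
#'
#' @param roi_ts a `roi_timeseries`.
#' @return Object of class `static_fc`: list with `z` (6 x 6 matrix, zero
#'   diagonal), `pair_vector` (length 15), `id`, `group`.
#' @export
static_fc <- function(roi_ts) {
  stopifnot(inherits(roi_ts, "roi_timeseries"))
  x <- t(roi_ts$traces)
  if (nrow(x) < 3) stop("need at least 3 samples")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant ROI trace: ", paste(colnames(x)[sds == 0], collapse = ", "))
  }
  z <- fisher_z(stats::cor(x))
  diag(z) <- 0
  structure(list(z = z, pair_vector = pair_vector(z, roi_ts$roi_order),
                 id = roi_ts$id, group = roi_ts$group),
            class = "static_fc")
}

#' @export
print.static_fc <- function(x, ...) {
  cat("Static Fisher-z FC matrix (15 pairs), mean z =",
      round(mean(x$pair_vector), 3), "\n")
  invisible(x)
}

#' Sliding-window sample indices
#'
#' Half-open, sample-aligned windows `[s, s + window * rate)` advancing by
#' `step * rate` samples; no partial final window. A 150-s recording at
#' 10 Hz with a 20-s window and 1-s step gives 131 windows.
#'
#' @param n_samples total sample count.
#' @param rate sampling rate (Hz).
#' @param window_s window length (s).
#' @param step_s step (s).
#' @return list of integer index vectors; `attr(, "onset_s")` gives window
#'   onset times in seconds.
#' @export
sliding_windows <- function(n_samples, rate, window_s = 20, step_s = 1) {
  w <- round(window_s * rate)
  s <- round(step_s * rate)
  if (w > n_samples) stop("window longer than the recording")
  if (s < 1) stop("step must be at least one sample")
  starts <- seq(0L, n_samples - w, by = s)
  out <- lapply(starts, function(s0) (s0 + 1L):(s0 + w))
  attr(out, "onset_s") <- starts / rate
  out
}

#' Dynamic (sliding-window) functional connectivity
#'
#' Window-wise Pearson correlation of every ROI pair, Fisher z-transformed:
#' the K x M matrix X with K = 15 pairs (rows, fixed order) and M windows
#' (columns); M = 131 on the standard 150-s, 10-Hz recording.
#'
#' @param roi_ts a `roi_timeseries`.
#' @param window_s,step_s window length and increment in seconds.
#' @return Object of class `dynamic_fc`: list with `X` (K x M), `window_s`,
#'   `step_s`, `window_starts` (s), `id`, `group`.
#' @export
dynamic_fc <- function(roi_ts, window_s = 20, step_s = 1) {
  stopifnot(inherits(roi_ts, "roi_timeseries"))
  x <- t(roi_ts$traces)
  wins <- sliding_windows(nrow(x), roi_ts$sampling_rate, window_s, step_s)
  pairs <- roi_pair_names(roi_ts$roi_order)
  # row-major upper-triangle linear indices into the 6 x 6 matrix
  nr <- ncol(x)
  ut <- unlist(lapply(seq_len(nr - 1L), function(i)
    i + (seq(i + 1L, nr) - 1L) * nr))
  clip <- 1 - 1e-7
  X <- matrix(NA_real_, length(pairs), length(wins),
              dimnames = list(pairs, NULL))
  for (m in seq_along(wins)) {
    xw <- x[wins[[m]], , drop = FALSE]
    cw <- suppressWarnings(stats::cor(xw))
    if (any(is.na(cw))) {
      bad <- colnames(xw)[apply(xw, 2, stats::sd) == 0]
      stop("constant ROI trace within window ", m, ": ",
           paste(bad, collapse = ", "))
    }
    X[, m] <- atanh(pmin(clip, pmax(-clip, cw[ut])))
  }
  structure(list(X = X, window_s = window_s, step_s = step_s,
                 window_starts = attr(wins, "onset_s"),
                 id = roi_ts$id, group = roi_ts$group),
            class = "dynamic_fc")
}

#' @export
print.dynamic_fc <- function(x, ...) {
  cat(sprintf("Dynamic Fisher-z FC: %d pairs x %d windows (%g s window, %g s step)\n",
              nrow(x$X), ncol(x$X), x$window_s, x$step_s))
  invisible(x)
}
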