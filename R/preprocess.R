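#' Molar extinction coefficients for oxy-/deoxyhemoglobin
#'
#' Standard published extinction coefficients at the two measurement
#' wavelengths, in cm^-1 per mM. Configurable wherever used; connectivity is
#' insensitive to these scalars, they matter only for absolute concentration
#' scaling and round-trip checks.
#'
#' @return 2 x 2 matrix, rows `"695"`/`"830"` (nm), columns `HbO`/`HbR`.
#' @export
extinction_coefficients <- function() {
  matrix(c(0.3208, 1.7943,
           0.9740, 0.6930),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("695", "830"), c("HbO", "HbR")))
}

#' Convert raw intensity to optical density change
#'
#' `OD(t) = -log10(I(t) / mean(I))` per channel; the within-series mean is
#' the reference intensity, so a constant series maps to zero OD and overall
#' intensity scaling drops out.
#'
#' @param intensity time x channel matrix of strictly positive intensities.
#' @return time x channel matrix of optical density changes.
#' @export
intensity_to_od <- function(intensity) {
  intensity <- as.matrix(intensity)
  bad <- which(intensity <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-positive intensity at channel %s, sample %s",
                 colnames(intensity)[bad[1, 2]] %||% bad[1, 2], bad[1, 1]))
  }
  ref <- colMeans(intensity)
  -log10(sweep(intensity, 2, ref, `/`))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Modified Beer-Lambert conversion to hemoglobin concentration changes
#'
#' Per sample and channel, solves the 2 x 2 linear system
#' `dOD_lambda = d * DPF_lambda * (eps_HbO,lambda * dHbO + eps_HbR,lambda * dHbR)`
#' for the oxy- and deoxyhemoglobin concentration changes.
#'
#' @param od list of two time x channel OD matrices named by wavelength.
#' @param distance_cm source-detector distance (cm).
#' @param dpf differential pathlength factor per wavelength (default 6 both).
#' @param extinction extinction matrix as [extinction_coefficients()].
#' @return Object of class `hemo_series`: list with `dHbO`, `dHbR` (time x
#'   channel, mM) and the conversion parameters.
#' @export
mbll <- function(od, distance_cm = 3, dpf = c(6, 6),
                 extinction = extinction_coefficients()) {
  wl <- names(od)
  stopifnot(length(wl) == 2, all(wl %in% rownames(extinction)))
  A <- extinction[wl, , drop = FALSE] * distance_cm * dpf
  if (abs(det(A)) < 1e-12) stop("singular extinction system; check coefficients")
  Ainv <- solve(A)
  # concentrations = Ainv %*% OD, vectorized over all samples/channels
  dHbO <- Ainv[1, 1] * od[[1]] + Ainv[1, 2] * od[[2]]
  dHbR <- Ainv[2, 1] * od[[1]] + Ainv[2, 2] * od[[2]]
  structure(list(dHbO = dHbO, dHbR = dHbR, distance_cm = distance_cm,
                 dpf = dpf, wavelengths = wl),
            class = "hemo_series")
}

#' Forward Beer-Lambert model
#'
#' Maps hemoglobin concentration changes to dual-wavelength optical density;
#' the exact inverse of [mbll()]. Used by the synthetic generator and by
#' round-trip tests.
#'
#' @inheritParams mbll
#' @param dHbO,dHbR time x channel concentration matrices (mM).
#' @return list of OD matrices named by wavelength.
#' @export
beer_lambert_forward <- function(dHbO, dHbR, distance_cm = 3, dpf = c(6, 6),
                                 extinction = extinction_coefficients()) {
  wl <- rownames(extinction)
  out <- list()
  for (k in seq_along(wl)) {
    out[[wl[k]]] <- distance_cm * dpf[k] *
      (extinction[k, "HbO"] * dHbO + extinction[k, "HbR"] * dHbR)
  }
  out
}

# zero-phase IIR filtering of matrix columns: forward-backward application
# with odd reflection padding at both ends and steady-state initial
# conditions (filtfilt semantics, vectorized across columns)
filtfilt_matrix <- function(b, a, x) {
  x <- as.matrix(x)
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b)))
  a <- c(a, rep(0, nf - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  # pad far enough for the slowest pole's transient to die out
  r <- max(abs(polyroot(rev(a))))
  tau <- if (r < 1) -1 / log(r) else Inf
  n_ext <- max(3L * (nf - 1L), ceiling(6 * tau))
  n_ext <- as.integer(min(nrow(x) - 1L, n_ext))
  if (nrow(x) <= 3L * (nf - 1L)) stop("signal too short for the filter order")
  # steady-state filter state for a unit step input
  kdc <- sum(b) / sum(a)
  si <- rev(cumsum(rev(b - kdc * a)))[-1]
  top <- 2 * matrix(x[1, ], n_ext, ncol(x), byrow = TRUE) -
    x[n_ext + 1 - seq_len(n_ext) + 1, , drop = FALSE]
  bot <- 2 * matrix(x[nrow(x), ], n_ext, ncol(x), byrow = TRUE) -
    x[nrow(x) - seq_len(n_ext), , drop = FALSE]
  xe <- rbind(top, x, bot)
  y <- iir_filter_cpp(b, a, xe, si)
  y <- iir_filter_cpp(b, a, y[rev(seq_len(nrow(y))), , drop = FALSE], si)
  y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
  y[n_ext + seq_len(nrow(x)), , drop = FALSE]
}

#' Butterworth band-pass filter, zero phase
#'
#' Third-order Butterworth band-pass (default 0.01-0.2 Hz) applied forward
#' and backward (zero phase) to each column.
#'
#' @param x numeric vector or time x channel matrix.
#' @param rate sampling rate (Hz).
#' @param low,high corner frequencies (Hz).
#' @param order filter order (default 3).
#' @return filtered signal with the shape of `x`.
#' @export
bandpass_filter <- function(x, rate, low = 0.01, high = 0.2, order = 3) {
  nyq <- rate / 2
  if (low <= 0 || high >= nyq || low >= high) {
    stop("corner frequencies must satisfy 0 < low < high < Nyquist")
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  out <- filtfilt_matrix(bf$b, bf$a, m)
  dimnames(out) <- if (vec) NULL else dimnames(x)
  if (vec) as.numeric(out) else out
}

#' Hemodynamic modality separation
#'
#' Decomposes paired (dHbO, dHbR) signals into a functional component, on
#' which deoxy change is a fixed negative ratio `k` of oxy change, and a
#' systemic component on the positively correlated direction
#' (`dHbR = k_systemic * dHbO`). Physiological interference (Mayer waves,
#' respiration) rides on the systemic direction and is removed; the
#' functional oxyhemoglobin component is returned as the backbone signal.
#'
#' @param hemo a `hemo_series` (aligned `dHbO`, `dHbR`).
#' @param k functional HbR/HbO ratio, must be negative (default -0.6).
#' @param k_systemic systemic HbR/HbO ratio, must be positive (default 1).
#' @return a `hemo_series` holding the functional component.
#' @export
hemodynamic_separation <- function(hemo, k = -0.6, k_systemic = 1) {
  stopifnot(inherits(hemo, "hemo_series"))
  if (k >= 0) stop("functional ratio k must be negative")
  if (k_systemic <= 0) stop("systemic ratio must be positive")
  # [dHbO; dHbR] = [1 1; k k_s] [f; s]  =>  invert the mixing matrix
  det_m <- k_systemic - k
  f <- (k_systemic * hemo$dHbO - hemo$dHbR) / det_m
  hemo$dHbO <- f
  hemo$dHbR <- k * f
  hemo$separation <- list(k = k, k_systemic = k_systemic)
  hemo
}

#' Aggregate channel hemoglobin signals into ROI traces
#'
#' ROI trace = linear summation of the dHbO signals of the channels the ROI
#' covers, in the fixed ROI order. Pearson correlations downstream are
#' invariant to the sum-versus-mean choice; `fun = "mean"` is available.
#'
#' @param hemo a `hemo_series` whose columns are named by channel id.
#' @param montage a post-QC `montage`; every ROI must keep >= 1 channel.
#' @param fun `"sum"` (default) or `"mean"`.
#' @return Object of class `roi_timeseries`: list with `traces` (6 x T
#'   matrix), `roi_order`, `sampling_rate` (taken from `attr(hemo,
#'   "sampling_rate")` if present, else `NA`).
#' @export
aggregate_rois <- function(hemo, montage, fun = c("sum", "mean")) {
  fun <- match.arg(fun)
  stopifnot(inherits(hemo, "hemo_series"), inherits(montage, "montage"))
  rois <- roi_names()
  ch_names <- colnames(hemo$dHbO)
  traces <- matrix(0, length(rois), nrow(hemo$dHbO),
                   dimnames = list(rois, NULL))
  for (r in rois) {
    ch_r <- names(montage$roi_map)[montage$roi_map == r]
    ch_r <- intersect(ch_r, ch_names)
    if (length(ch_r) == 0) stop("ROI without channels after QC: ", r)
    block <- hemo$dHbO[, ch_r, drop = FALSE]
    traces[r, ] <- if (fun == "sum") rowSums(block) else rowMeans(block)
  }
  structure(
    list(traces = traces, roi_order = rois,
         sampling_rate = attr(hemo, "sampling_rate") %||% NA_real_),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI time series: %d ROIs x %d samples at %s Hz\n",
              nrow(x$traces), ncol(x$traces),
              format(x$sampling_rate)))
  invisible(x)
}

#' Preprocessing parameters
#'
#' @param band band-pass corners in Hz.
#' @param butter_order Butterworth order.
#' @param wavelet_threshold tail-probability threshold of the wavelet
#'   correction.
#' @param k,k_systemic hemodynamic separation ratios.
#' @param dpf differential pathlength factors.
#' @param roi_fun `"sum"` or `"mean"` ROI aggregation.
#' @return list of class `preprocess_params`.
#' @export
preprocess_params <- function(band = c(0.01, 0.2), butter_order = 3,
                              wavelet_threshold = 0.1, k = -0.6,
                              k_systemic = 1, dpf = c(6, 6),
                              roi_fun = "sum") {
  structure(list(band = band, butter_order = butter_order,
                 wavelet_threshold = wavelet_threshold, k = k,
                 k_systemic = k_systemic, dpf = dpf, roi_fun = roi_fun),
            class = "preprocess_params")
}

#' Preprocess one raw recording to ROI hemoglobin traces
#'
#' The fixed stage order: intensity to optical density, modified
#' Beer-Lambert conversion, Butterworth band-pass (0.01-0.2 Hz), wavelet
#' motion correction (Daubechies-5, threshold 0.1), hemodynamic modality
#' separation, then ROI aggregation of the functional oxyhemoglobin signal.
#' The 10-s quiet baseline segment is used for QC only and is dropped before
#' conversion.
#'
#' @param recording an `fnirs_recording`.
#' @param montage post-QC `montage` restricted to retained channels.
#' @param params a `preprocess_params`.
#' @return a `roi_timeseries` (6 x T, T the analysis-period sample count).
#' @export
preprocess_recording <- function(recording, montage,
                                 params = preprocess_params()) {
  stopifnot(inherits(recording, "fnirs_recording"))
  keep <- as.character(montage$channels$channel)
  task_rows <- (recording$baseline_n + 1):nrow(recording$intensity[[1]])
  od <- lapply(recording$intensity, function(m) {
    intensity_to_od(m[task_rows, keep, drop = FALSE])
  })
  hemo <- mbll(od, distance_cm = montage$distance_cm, dpf = params$dpf)
  rate <- recording$sampling_rate
  nc <- length(keep)
  both <- cbind(hemo$dHbO, hemo$dHbR)  # one pass through both filters
  both <- bandpass_filter(both, rate, params$band[1], params$band[2],
                          params$butter_order)
  both <- wavelet_motion_correct(both, params$wavelet_threshold)
  hemo$dHbO <- both[, seq_len(nc), drop = FALSE]
  hemo$dHbR <- both[, nc + seq_len(nc), drop = FALSE]
  colnames(hemo$dHbO) <- keep
  colnames(hemo$dHbR) <- keep
  hemo <- hemodynamic_separation(hemo, params$k, params$k_systemic)
  attr(hemo, "sampling_rate") <- rate
  out <- aggregate_rois(hemo, montage, params$roi_fun)
  out$sampling_rate <- rate
  out$id <- recording$id
  out$group <- recording$group
  out
}
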