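#' Region-of-interest labels in their fixed analysis order
#'
#' Six frontotemporal regions of interest: right/left dorsolateral prefrontal
#' cortex, right/left medial prefrontal cortex, right/left temporal lobe. All
#' ROI-level containers in the package (ROI time series, connectivity
#' matrices, feature labels) use this order, so features are comparable across
#' participants.
#'
#' @return Character vector of the 6 ROI labels.
#' @export
roi_names <- function() {
  c("DLPFC(R)", "DLPFC(L)", "mPFC(R)", "mPFC(L)", "TL(R)", "TL(L)")
}

#' Ordered ROI pair labels
#'
#' Row-major upper triangle of the fixed ROI order; 6 ROIs give 15 pairs.
#'
#' @param rois character vector of ROI labels (default [roi_names()]).
#' @return Character vector of `"<roi_i>~<roi_j>"` labels, i < j.
#' @export
roi_pair_names <- function(rois = roi_names()) {
  n <- length(rois)
  out <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      out <- c(out, paste0(rois[i], "~", rois[j]))
    }
  }
  out
}

#' Build the standard 3 x 11 frontotemporal probe grid montage
#'
#' Optodes are laid out on a `rows x cols` checkerboard of alternating sources
#' and detectors (3 x 11 gives 33 optodes: 17 sources, 16 detectors, 3 cm
#' spacing). A measurement channel is formed by every horizontally or
#' vertically adjacent source-detector pair; the 3 x 11 band yields 52
#' channels. Channels are numbered row-major by the midpoint of the pair, and
#' each channel is assigned to one of the six frontotemporal ROIs by its
#' lateral position (right hemisphere at low column numbers, frontal view).
#'
#' @param rows,cols grid dimensions (defaults 3 and 11).
#' @param distance_cm inter-optode distance in cm (default 3).
#' @return An object of class `montage`: list with `channels` (data frame:
#'   `channel`, `source_id`, `detector_id`, `row`, `col` midpoint position),
#'   `roi_map` (named integer vector channel -> ROI label), `n_sources`,
#'   `n_detectors`, `distance_cm`.
#' @export
build_montage <- function(rows = 3L, cols = 11L, distance_cm = 3) {
  # checkerboard: (row + col) even -> source, else detector
  pos <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  pos$is_source <- (pos$row + pos$col) %% 2L == 0L
  pos$optode_id <- seq_len(nrow(pos))
  src <- pos[pos$is_source, ]
  det <- pos[!pos$is_source, ]
  src$source_id <- seq_len(nrow(src))
  det$detector_id <- seq_len(nrow(det))

  # adjacent pairs (|dr| + |dc| = 1); each pair is one source + one detector
  edges <- list()
  for (k in seq_len(nrow(pos))) {
    r <- pos$row[k]; c0 <- pos$col[k]
    if (c0 < cols) edges[[length(edges) + 1L]] <- c(k, which(pos$row == r & pos$col == c0 + 1L))
    if (r < rows) edges[[length(edges) + 1L]] <- c(k, which(pos$row == r + 1L & pos$col == c0))
  }
  ed <- do.call(rbind, edges)
  mid_row <- (pos$row[ed[, 1]] + pos$row[ed[, 2]]) / 2
  mid_col <- (pos$col[ed[, 1]] + pos$col[ed[, 2]]) / 2
  ord <- order(mid_row, mid_col)
  ed <- ed[ord, , drop = FALSE]
  mid_row <- mid_row[ord]; mid_col <- mid_col[ord]

  get_src <- function(k) if (pos$is_source[k]) src$source_id[match(k, src$optode_id)] else NA_integer_
  get_det <- function(k) if (!pos$is_source[k]) det$detector_id[match(k, det$optode_id)] else NA_integer_
  source_id <- detector_id <- integer(nrow(ed))
  for (i in seq_len(nrow(ed))) {
    a <- ed[i, 1]; b <- ed[i, 2]
    source_id[i] <- if (pos$is_source[a]) get_src(a) else get_src(b)
    detector_id[i] <- if (!pos$is_source[a]) get_det(a) else get_det(b)
  }

  channels <- data.frame(
    channel = seq_len(nrow(ed)),
    source_id = source_id,
    detector_id = detector_id,
    row = mid_row,
    col = mid_col
  )

  # lateral ROI bands over the 11 columns (frontal view: right hemisphere left)
  roi_of <- function(mc) {
    if (mc <= 2.5) "TL(R)"
    else if (mc <= 4.5) "DLPFC(R)"
    else if (mc <= 6) "mPFC(R)"
    else if (mc <= 7.5) "mPFC(L)"
    else if (mc <= 9.5) "DLPFC(L)"
    else "TL(L)"
  }
  roi_map <- vapply(channels$col, roi_of, character(1))
  names(roi_map) <- as.character(channels$channel)

  structure(
    list(
      channels = channels,
      roi_map = roi_map,
      n_sources = nrow(src),
      n_detectors = nrow(det),
      distance_cm = distance_cm
    ),
    class = "montage"
  )
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf(
    "fNIRS montage: %d channels (%d sources, %d detectors, %g cm)\n",
    nrow(x$channels), x$n_sources, x$n_detectors, x$distance_cm
  ))
  print(table(x$roi_map))
  invisible(x)
}

#' Restrict a montage to a channel subset
#'
#' @param montage a `montage` object.
#' @param keep integer channel ids to retain.
#' @return The montage restricted to `keep`; errors if any ROI would lose all
#'   of its channels (downstream ROI aggregation would be impossible).
#' @export
subset_montage <- function(montage, keep) {
  stopifnot(inherits(montage, "montage"))
  keep <- sort(unique(as.integer(keep)))
  if (!all(keep %in% montage$channels$channel)) {
    stop("unknown channel id(s): ",
         paste(setdiff(keep, montage$channels$channel), collapse = ", "))
  }
  new_map <- montage$roi_map[as.character(keep)]
  lost <- setdiff(unique(montage$roi_map), unique(new_map))
  if (length(lost) > 0) {
    stop("channel filter removes every channel of ROI(s): ",
         paste(lost, collapse = ", "))
  }
  montage$channels <- montage$channels[montage$channels$channel %in% keep, , drop = FALSE]
  montage$roi_map <- new_map
  montage
}

#' Read / write a montage as JSON
#'
#' The channel-to-ROI map is configuration, not code: montages are serialized
#' to an editable JSON file.
#'
#' @param montage a `montage` object.
#' @param path file path.
#' @return `write_montage` returns `path` invisibly; `read_montage` a
#'   `montage`.
#' @export
write_montage <- function(montage, path) {
  stopifnot(inherits(montage, "montage"))
  obj <- list(
    channels = montage$channels,
    roi_map = as.list(montage$roi_map),
    n_sources = montage$n_sources,
    n_detectors = montage$n_detectors,
    distance_cm = montage$distance_cm
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      channels = as.data.frame(obj$channels),
      roi_map = unlist(obj$roi_map),
      n_sources = as.integer(obj$n_sources),
      n_detectors = as.integer(obj$n_detectors),
      distance_cm = as.numeric(obj$distance_cm)
    ),
    class = "montage"
  )
}
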