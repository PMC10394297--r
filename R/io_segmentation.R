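# Segmentation of multichannel EEG into overlapping labeled windows.

#' Construct a multichannel EEG signal
#'
#' @param samples numeric matrix, channels x time, in microvolts (or
#'   unitless after normalization).
#' @param sampling_rate_hz positive sampling rate.
#' @param channel_names optional channel labels (default Ch1..ChC).
#' @param patient_id identifier of the recording's subject.
#' @return an object of class `multichannel_signal`.
#' @export
multichannel_signal <- function(samples, sampling_rate_hz,
                                channel_names = NULL, patient_id = "unknown") {
  samples <- as.matrix(samples)
  if (nrow(samples) < 1L || ncol(samples) < 1L) {
    stop_seizdg("signal needs at least one channel and one sample",
                class = "seizdg_validation_error")
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop_seizdg("sampling_rate_hz must be positive", class = "seizdg_validation_error")
  }
  channel_names <- channel_names %||% paste0("Ch", seq_len(nrow(samples)))
  if (length(channel_names) != nrow(samples)) {
    stop_seizdg("channel_names length must equal channel count",
                class = "seizdg_validation_error")
  }
  structure(list(samples = samples, sampling_rate_hz = sampling_rate_hz,
                 channel_names = as.character(channel_names),
                 patient_id = patient_id),
            class = "multichannel_signal")
}

#' @export
print.multichannel_signal <- function(x, ...) {
  cat(sprintf("<multichannel_signal> patient=%s  %d ch x %d samples @ %g Hz\n",
              x$patient_id, nrow(x$samples), ncol(x$samples), x$sampling_rate_hz))
  invisible(x)
}

#' Min-max normalization per channel
#'
#' Rescales each channel to `[0, 1]` using that channel's minimum and
#' maximum over the whole input (per channel, per recording — computed
#' before segmentation so adjacent overlapping windows stay consistent).
#' Constant channels map to all zeros.
#'
#' @param x a `multichannel_signal`, or a numeric matrix (channels x time),
#'   or a numeric vector (one channel).
#' @return same type as the input, values in `[0, 1]`.
#' @export
#' @examples
#' minmax_normalize(c(0, 5, 10))  # 0 0.5 1
minmax_normalize <- function(x) {
  if (inherits(x, "multichannel_signal")) {
    x$samples <- minmax_normalize(x$samples)
    return(x)
  }
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, 1L) else as.matrix(x)
  assert_finite(m, "signal")
  rng_min <- apply(m, 1, min)
  rng <- apply(m, 1, max) - rng_min
  rng[rng <= 0] <- 1
  out <- (m - rng_min) / rng
  if (vec) drop(out) else out
}

#' Cut a recording into overlapping fixed-length segments
#'
#' Windows are half-open `[start, start + window_len)` with 0-based start
#' indices advancing by `hop = window_len * (1 - overlap_fraction)`; a
#' trailing remainder shorter than the window is dropped, giving
#' `floor((T - window_len)/hop) + 1` segments.
#'
#' @param x a `multichannel_signal` (normalize first; see
#'   [minmax_normalize()]).
#' @param window_len window length in samples (default 250, i.e. 1 s at
#'   250 Hz).
#' @param overlap_fraction fraction of overlap between adjacent windows in
#'   `[0, 1)`; default 0.5.
#' @return a `segment_batch`: list with array `x` of dim
#'   `[n_segments, channels, window_len]`, integer `segment_index`
#'   (0-based), `start` sample indices (0-based), and metadata. Labels are
#'   attached later by [label_segments()].
#' @export
segment_signal <- function(x, window_len = 250L, overlap_fraction = 0.5) {
  stopifnot(inherits(x, "multichannel_signal"))
  Tn <- ncol(x$samples)
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop_seizdg("overlap_fraction must be in [0, 1)", class = "seizdg_validation_error")
  }
  if (window_len > Tn) {
    stop_seizdg("signal (", Tn, " samples) shorter than window (", window_len, ")",
                class = "seizdg_empty_batch_error")
  }
  hop <- window_len * (1 - overlap_fraction)
  n_seg <- as.integer(floor((Tn - window_len) / hop) + 1)
  starts <- round(hop * (seq_len(n_seg) - 1))   # 0-based
  C <- nrow(x$samples)
  arr <- array(0, dim = c(n_seg, C, window_len))
  for (i in seq_len(n_seg)) {
    arr[i, , ] <- x$samples[, (starts[i] + 1L):(starts[i] + window_len), drop = FALSE]
  }
  structure(list(
    x = arr, n = n_seg, segment_index = seq_len(n_seg) - 1L, start = starts,
    window_len = as.integer(window_len),
    sampling_rate_hz = x$sampling_rate_hz,
    channel_names = x$channel_names, patient_id = x$patient_id,
    y = NULL, patient_label = NULL
  ), class = "segment_batch")
}

#' @export
print.segment_batch <- function(x, ...) {
  lab <- if (is.null(x$y)) "unlabeled" else
    sprintf("%d seizure / %d normal", sum(x$y == 1L), sum(x$y == 0L))
  cat(sprintf("<segment_batch> %d segments x %d ch x %d samples (%s)\n",
              x$n, dim(x$x)[2], x$window_len, lab))
  invisible(x)
}

#' Label segments from a seizure/background annotation
#'
#' Annotations follow the term/time CSV dialect: columns `patient_id`,
#' `start_s`, `stop_s`, `label` with `label` in `{seiz, bckg}` and
#' intervals `[start_s, stop_s)`. Each window is labeled by the majority
#' state of its samples (ties go to seizure). The annotation must cover
#' every sample of every window.
#'
#' @param batch a `segment_batch` from [segment_signal()].
#' @param annotation data frame as above (rows for other patients are
#'   ignored if `patient_id` matches none/several, the batch's own id is
#'   used).
#' @param patient_label integer patient index attached to every segment.
#' @return the batch with `y` (0 normal / 1 seizure) and `patient_label`
#'   filled in; segment count and order are preserved.
#' @export
label_segments <- function(batch, annotation, patient_label = 1L) {
  stopifnot(inherits(batch, "segment_batch"))
  ann <- annotation
  if (!is.null(ann$patient_id) && batch$patient_id %in% ann$patient_id) {
    ann <- ann[ann$patient_id == batch$patient_id, , drop = FALSE]
  }
  if (nrow(ann) == 0L) {
    stop_seizdg("no annotation rows for patient ", batch$patient_id,
                class = "seizdg_label_error")
  }
  fs <- batch$sampling_rate_hz
  total <- max(batch$start) + batch$window_len
  mask <- rep(NA_integer_, total)          # per-sample state over covered span
  for (r in seq_len(nrow(ann))) {
    a <- floor(ann$start_s[r] * fs) + 1L
    b <- min(ceiling(ann$stop_s[r] * fs), total)
    if (a > total || b < a) next
    mask[a:b] <- if (ann$label[r] == "seiz") 1L else 0L
  }
  y <- integer(batch$n)
  for (i in seq_len(batch$n)) {
    w <- mask[(batch$start[i] + 1L):(batch$start[i] + batch$window_len)]
    if (anyNA(w)) {
      stop_seizdg("annotation gap overlaps window at segment ", i - 1L,
                  class = "seizdg_label_error")
    }
    y[i] <- as.integer(mean(w) >= 0.5)     # majority of window
  }
  batch$y <- y
  batch$patient_label <- rep(as.integer(patient_label), batch$n)
  batch
}

#' Extract one segment from a batch
#'
#' @param batch a `segment_batch`.
#' @param i segment number (1-based position in the batch).
#' @return list with `samples` (channels x window_len matrix),
#'   `category_label`, `patient_label`, `segment_index`.
#' @export
get_segment <- function(batch, i) {
  stopifnot(i >= 1L, i <= batch$n)
  list(samples = matrix(batch$x[i, , ], dim(batch$x)[2], batch$window_len),
       category_label = if (is.null(batch$y)) NA_integer_ else batch$y[i],
       patient_label = if (is.null(batch$patient_label)) NA_integer_
                       else batch$patient_label[i],
       segment_index = batch$segment_index[i])
}

# Stack several per-patient batches into one training design:
# X [N, C, L], y in {0,1}, d re-indexed to 1..P in batch order.
bind_batches <- function(batches) {
  stopifnot(length(batches) >= 1L)
  C <- dim(batches[[1]]$x)[2]
  L <- batches[[1]]$window_len
  for (b in batches) {
    if (dim(b$x)[2] != C || b$window_len != L) {
      stop_seizdg("batches have incompatible shapes", class = "seizdg_validation_error")
    }
    if (is.null(b$y)) stop_seizdg("batches must be labeled", class = "seizdg_validation_error")
  }
  N <- sum(vapply(batches, function(b) as.integer(b$n), 0L))
  X <- array(0, dim = c(N, C, L))
  y <- integer(N); d <- integer(N)
  at <- 0L
  for (p in seq_along(batches)) {
    b <- batches[[p]]
    X[(at + 1L):(at + b$n), , ] <- b$x
    y[(at + 1L):(at + b$n)] <- b$y
    d[(at + 1L):(at + b$n)] <- p
    at <- at + b$n
  }
  list(X = X, y = y, d = d, n_patients = length(batches))
}

#' Serialize a segment batch to disk
#'
#' Writes the segment array as a gzip-compressed CSV (one row per
#' segment-channel) plus a JSON sidecar holding labels, patient ids and
#' provenance.
#'
#' @param batch a labeled `segment_batch`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_segment_batch <- function(batch, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dims <- dim(batch$x)
  # rows ordered segment-major, channel-minor; one window per row
  flat <- t(matrix(aperm(batch$x, c(3, 2, 1)), nrow = dims[3]))
  con <- gzfile(file.path(dir, "segments.csv.gz"), "w")
  utils::write.table(flat, con, sep = ",", row.names = FALSE, col.names = FALSE)
  close(con)
  meta <- list(
    n = batch$n, channels = dims[2], window_len = batch$window_len,
    sampling_rate_hz = batch$sampling_rate_hz,
    channel_names = batch$channel_names, patient_id = batch$patient_id,
    segment_index = batch$segment_index, start = batch$start,
    y = batch$y, patient_label = batch$patient_label
  )
  jsonlite::write_json(meta, file.path(dir, "segments.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a segment batch written by [write_segment_batch()]
#' @param dir directory holding `segments.csv.gz` and `segments.json`.
#' @return a `segment_batch`.
#' @export
read_segment_batch <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "segments.json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(
    gzfile(file.path(dir, "segments.csv.gz")), sep = ","))
  arr <- array(0, dim = c(meta$n, meta$channels, meta$window_len))
  row <- 1L
  for (i in seq_len(meta$n)) for (c_i in seq_len(meta$channels)) {
    arr[i, c_i, ] <- flat[row, ]
    row <- row + 1L
  }
  structure(list(
    x = arr, n = meta$n, segment_index = meta$segment_index, start = meta$start,
    window_len = meta$window_len, sampling_rate_hz = meta$sampling_rate_hz,
    channel_names = meta$channel_names, patient_id = meta$patient_id,
    y = meta$y, patient_label = meta$patient_label
  ), class = "segment_batch")
}
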