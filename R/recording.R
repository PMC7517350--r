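#' Construct a multichannel EEG recording
#'
#' An \code{eeg_recording} holds a channels-by-samples amplitude matrix
#' (microvolts), the sampling rate in Hz, unique channel labels, and an
#' optional frequency-band tag \code{c(low, high)} in Hz marking band-limited
#' data.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz, positive scalar.
#' @param labels character vector of unique channel labels, one per row.
#' @param band optional numeric length-2 vector \code{c(low, high)} in Hz.
#' @return An object of class \code{eeg_recording}.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(20), 2, 10), fs = 500,
#'                      labels = c("Fp1", "O2"))
#' rec
#' @export
eeg_recording <- function(data, fs, labels, band = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric", call. = FALSE)
  if (anyNA(data)) stop("data contains missing values", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive number", call. = FALSE)
  labels <- canonical_labels(labels)
  if (length(labels) != nrow(data))
    stop("number of labels (", length(labels),
         ") does not match number of channels (", nrow(data), ")",
         call. = FALSE)
  if (anyDuplicated(labels))
    stop("duplicate channel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(band)) {
    stopifnot(is.numeric(band), length(band) == 2L, band[1] < band[2])
    band <- as.numeric(band)
  }
  rownames(data) <- labels
  structure(list(labels = labels, fs = as.numeric(fs), data = data,
                 band = band),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", length(x$labels), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (",
      round(ncol(x$data) / x$fs, 2), " s)\n", sep = "")
  if (!is.null(x$band))
    cat("  band: ", x$band[1], "-", x$band[2], " Hz\n", sep = "")
  cat("  channels: ", paste(x$labels, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.eeg_recording <- function(x, ...) x$data

n_samples <- function(rec) ncol(rec$data)

#' Extract a channel subset of a recording
#'
#' @param rec an [eeg_recording()].
#' @param channels character vector of labels (or a \code{region_spec}).
#' @return An \code{eeg_recording} restricted to the requested channels, in
#'   the requested order.
#' @export
select_channels <- function(rec, channels) {
  if (inherits(channels, "region_spec")) channels <- channels$channels
  channels <- canonical_labels(channels)
  idx <- match(channels, rec$labels)
  if (anyNA(idx))
    stop("channels not present in recording: ",
         paste(channels[is.na(idx)], collapse = ", "), call. = FALSE)
  eeg_recording(rec$data[idx, , drop = FALSE], rec$fs, channels, rec$band)
}

#' Split a recording into equal-length contiguous segments
#'
#' The recording is divided into consecutive non-overlapping slices of
#' \code{seconds} duration (default 600 s, i.e. 10 minutes, so a one-hour
#' recording yields segments 1-6).  A trailing remainder shorter than one
#' segment is discarded.
#'
#' @param rec an [eeg_recording()].
#' @param seconds segment duration in seconds, positive.
#' @return A list of class \code{segment_set}: \code{segments} (list of
#'   \code{eeg_recording}), \code{segment_seconds}, and \code{indices}.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 5000), 2, 5000), 100, c("C3", "C4"))
#' length(segment_recording(rec, seconds = 10)$segments)  # 5
#' @export
segment_recording <- function(rec, seconds = 600) {
  stopifnot(inherits(rec, "eeg_recording"),
            is.numeric(seconds), length(seconds) == 1L, seconds > 0)
  len <- as.integer(round(seconds * rec$fs))
  n <- n_samples(rec)
  if (n < len)
    stop("recording (", n, " samples) shorter than one segment of ",
         len, " samples", call. = FALSE)
  k <- n %/% len
  segments <- lapply(seq_len(k), function(i) {
    cols <- ((i - 1L) * len + 1L):(i * len)
    eeg_recording(rec$data[, cols, drop = FALSE], rec$fs, rec$labels,
                  rec$band)
  })
  structure(list(segments = segments, segment_seconds = seconds,
                 indices = seq_len(k)),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat("<segment_set> ", length(x$segments), " segments of ",
      x$segment_seconds, " s\n", sep = "")
  invisible(x)
}
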