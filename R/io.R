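#' Read a multichannel EEG recording from disk
#'
#' Two storage formats are supported: EDF (European Data Format, 16-bit) and
#' plain delimited numeric tables (TSV/CSV) with one column per channel and a
#' header row of channel labels.  For tables the sampling rate comes either
#' from the \code{fs} argument or from a JSON sidecar \code{<path>.json}
#' written by [write_recording()].  Channel labels are matched against the
#' 10-20 montage case-insensitively with surrounding whitespace stripped.
#'
#' @param path path to the file.
#' @param format \code{"auto"} (by extension), \code{"edf"} or \code{"table"}.
#' @param fs sampling rate in Hz; required for tables without a sidecar,
#'   ignored for EDF.
#' @return An [eeg_recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format = c("auto", "edf", "table"),
                           fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot read '", path, "': no such file", call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "table"
  if (format == "edf") read_edf(path) else read_table_recording(path, fs)
}

#' Write a recording to disk
#'
#' @param rec an [eeg_recording()].
#' @param path destination file path.
#' @param format \code{"auto"} (by extension), \code{"edf"} or \code{"table"}.
#'   EDF stores amplitudes as 16-bit integers scaled to the per-channel
#'   physical range (microvolts assumed), so a round trip is exact only up to
#'   that quantisation; tables store full-precision text plus a JSON sidecar
#'   \code{<path>.json} carrying the sampling rate and band tag.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "table")) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(rec$labels) == 0L)
    stop("recording has no channels", call. = FALSE)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "table"
  if (format == "edf") write_edf(rec, path) else write_table_recording(rec, path)
  invisible(path)
}

read_table_recording <- function(path, fs = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  labels <- canonical_labels(header)
  if (anyDuplicated(labels))
    stop("duplicate channel labels in header of '", path, "'", call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE)
  band <- NULL
  sidecar <- paste0(path, ".json")
  if (is.null(fs) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    fs <- meta$fs
    if (!is.null(meta$band) && length(meta$band) == 2L) band <- meta$band
  }
  if (is.null(fs))
    stop("sampling rate unknown: pass fs= or provide a '", sidecar,
         "' sidecar", call. = FALSE)
  eeg_recording(t(as.matrix(tab)), fs = fs, labels = labels, band = band)
}

write_table_recording <- function(rec, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- as.data.frame(t(rec$data))
  names(tab) <- rec$labels
  utils::write.table(tab, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  meta <- list(fs = rec$fs)
  if (!is.null(rec$band)) meta$band <- rec$band
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# --- Minimal EDF (European Data Format) support -----------------------------
# Continuous recordings only: one-second data records, 16-bit little-endian
# samples, physical units microvolts.  Annotation channels are out of scope.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, width = 1, format = "g", digits = 7)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  edf_pad(s, width)
}

write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  ns <- length(rec$labels)
  n <- ncol(rec$data)
  nrec <- n %/% fs
  if (nrec < 1L)
    stop("recording shorter than one second cannot be stored as EDF",
         call. = FALSE)
  if (n %% fs != 0L) {
    warning("EDF writer truncating ", n %% fs,
            " trailing samples (incomplete final 1-s record)")
    n <- nrec * fs
  }
  x <- rec$data[, seq_len(n), drop = FALSE]
  pmin <- apply(x, 1, min)
  pmax <- apply(x, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8),
    edf_pad("00.00.00", 8),
    edf_pad(256L * (1L + ns), 8),
    edf_pad("", 44),
    edf_pad(nrec, 8),
    edf_pad(1, 8),
    edf_pad(ns, 4),
    paste(vapply(rec$labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(pmin, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  scale <- (dmax - dmin) / (pmax - pmin)
  dig <- round(sweep(sweep(x, 1, pmin, "-"), 1, scale, "*")) + dmin
  dig <- pmin(pmax(dig, dmin), dmax)
  for (r in seq_len(nrec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    block <- t(dig[, cols, drop = FALSE])     # samples x channels
    writeBin(as.integer(block), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                         # version
  rd(80); rd(80); rd(8); rd(8)  # patient, recording, date, time
  rd(8)                         # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L)
    stop("'", path, "' is not a readable EDF file", call. = FALSE)
  field <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- field(16)
  field(80)                     # transducer
  field(8)                      # physical dimension
  pmin <- as.numeric(field(8))
  pmax <- as.numeric(field(8))
  dmin <- as.numeric(field(8))
  dmax <- as.numeric(field(8))
  field(80)                     # prefiltering
  spr <- as.integer(field(8))
  field(32)
  if (length(unique(spr)) != 1L)
    stop("EDF reader supports a single common sampling rate only",
         call. = FALSE)
  spr1 <- spr[1]
  fs <- spr1 / dur
  dig <- matrix(0, nrow = ns, ncol = nrec * spr1)
  for (r in seq_len(nrec)) {
    vals <- readBin(con, "integer", n = ns * spr1, size = 2L,
                    endian = "little", signed = TRUE)
    dig[, ((r - 1L) * spr1 + 1L):(r * spr1)] <-
      t(matrix(vals, nrow = spr1, ncol = ns))
  }
  scale <- (pmax - pmin) / (dmax - dmin)
  phys <- sweep(sweep(dig, 1, dmin, "-"), 1, scale, "*")
  phys <- sweep(phys, 1, pmin, "+")
  eeg_recording(phys, fs = fs, labels = labels)
}

#' Write a labelled square matrix as TSV
#'
#' Used for connectivity matrices and other node-by-node tables: channel
#' labels appear as both the header row and the first column.
#'
#' @param m numeric matrix (or [connectivity_matrix()]).
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  if (inherits(m, "connectivity_matrix")) {
    labels <- m$labels
    m <- m$values
  } else {
    labels <- rownames(m)
    if (is.null(labels)) labels <- paste0("V", seq_len(nrow(m)))
  }
  df <- data.frame(node = labels, m, check.names = FALSE)
  colnames(df) <- c("node", labels)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labelled square matrix written by [write_matrix_tsv()]
#'
#' @param path path to the TSV file.
#' @return A numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
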