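#' Normalised zero-lag cross-correlation of two signals
#'
#' The connectivity strength between channels i and j is
#' \deqn{\gamma_{ij} = \frac{|\sum_t s_i(t) s_j(t)|}
#'   {\sqrt{\sum_t s_i(t)^2 \; \sum_t s_j(t)^2}},}
#' the absolute normalised cross-correlation evaluated at lag zero, with no
#' mean-centering.  By Cauchy-Schwarz \eqn{\gamma \in [0, 1]}; it is
#' invariant to rescaling either signal.  Band-limited alpha oscillations
#' are near zero-mean, so the uncentered value closely tracks the Pearson
#' correlation magnitude; a centered variant is available.
#'
#' @param si,sj numeric vectors of equal length (at least 2), each with
#'   nonzero energy.
#' @param center subtract each signal's mean first (default \code{FALSE}).
#' @return Scalar \eqn{\gamma} in \code{[0, 1]}.
#' @examples
#' zero_lag_correlation(sin(1:100), sin(1:100))  # 1
#' @export
zero_lag_correlation <- function(si, sj, center = FALSE) {
  if (length(si) != length(sj))
    stop("signals have different lengths (", length(si), " vs ",
         length(sj), ")", call. = FALSE)
  if (length(si) < 2L)
    stop("signals must have at least 2 samples", call. = FALSE)
  if (center) {
    si <- si - mean(si)
    sj <- sj - mean(sj)
  }
  ei <- sum(si^2)
  ej <- sum(sj^2)
  if (ei <= 0 || ej <= 0)
    stop("zero-energy signal: correlation undefined", call. = FALSE)
  abs(sum(si * sj)) / sqrt(ei * ej)
}

#' Build the functional connectivity matrix of a recording
#'
#' Every channel pair is scored by [zero_lag_correlation()]; the diagonal is
#' set to zero to exclude self-connections and the matrix is symmetric by
#' construction.  The intended input is the band-limited alpha recording
#' produced by [extract_alpha()], one matrix per 10-minute segment.
#'
#' @param rec an [eeg_recording()] (typically band-limited), N >= 2 channels.
#' @param segment_index optional integer tag.
#' @param center passed to [zero_lag_correlation()].
#' @return An object of class \code{connectivity_matrix}: \code{labels},
#'   \code{values} (N x N, zero diagonal, entries in \code{[0, 1]}),
#'   \code{segment_index}.
#' @export
build_connectivity <- function(rec, segment_index = NA_integer_,
                               center = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$data
  if (nrow(x) < 2L)
    stop("need at least 2 channels to build a connectivity matrix",
         call. = FALSE)
  if (center) x <- x - rowMeans(x)
  energy <- rowSums(x^2)
  if (any(energy <= 0)) {
    bad <- rec$labels[energy <= 0]
    stop("zero-energy channel(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cp <- tcrossprod(x)                      # sum_t si(t) sj(t)
  vals <- abs(cp) / sqrt(outer(energy, energy))
  vals <- (vals + t(vals)) / 2             # remove float asymmetry
  diag(vals) <- 0
  connectivity_matrix(vals, rec$labels, segment_index)
}

#' Construct a connectivity matrix object
#'
#' @param values symmetric numeric N x N matrix with zero diagonal and
#'   off-diagonal entries in \code{[0, 1]}.
#' @param labels channel labels, length N.
#' @param segment_index optional integer tag.
#' @return An object of class \code{connectivity_matrix}.
#' @export
connectivity_matrix <- function(values, labels,
                                segment_index = NA_integer_) {
  values <- as.matrix(values)
  n <- nrow(values)
  stopifnot(ncol(values) == n, length(labels) == n)
  if (any(abs(values - t(values)) > 1e-10))
    stop("connectivity matrix must be symmetric", call. = FALSE)
  if (any(diag(values) != 0))
    stop("connectivity matrix diagonal must be zero", call. = FALSE)
  if (any(values < 0) || any(values > 1 + 1e-12))
    stop("connectivity strengths must lie in [0, 1]", call. = FALSE)
  dimnames(values) <- list(labels, labels)
  structure(list(labels = as.character(labels), values = values,
                 segment_index = segment_index),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat("<connectivity_matrix> ", length(x$labels), " nodes",
      if (!is.na(x$segment_index)) paste0(", segment ", x$segment_index),
      "\n  off-diagonal gamma: min ", format(min(off), digits = 3),
      ", median ", format(stats::median(off), digits = 3),
      ", max ", format(max(off), digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.connectivity_matrix <- function(x, ...) x$values

#' @export
plot.connectivity_matrix <- function(x, main = NULL, ...) {
  n <- length(x$labels)
  graphics::image(seq_len(n), seq_len(n),
                  t(x$values[n:1, , drop = FALSE]),
                  zlim = c(0, 1), axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  main = main %||% "functional connectivity", ...)
  graphics::axis(1, at = seq_len(n), labels = x$labels, las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(n), labels = rev(x$labels), las = 2,
                 cex.axis = 0.6)
  invisible(x)
}

#' Global connectivity energy of a network
#'
#' The total energy of the connectivity matrix elements,
#' \eqn{\sum_{i,j} F(i,j)^2} (the zero diagonal contributes nothing), an
#' overall coupling-strength summary of the network.  An absolute-value
#' variant \eqn{\sum |F(i,j)|} is available.
#'
#' @param F a [connectivity_matrix()] (or plain matrix).
#' @param type \code{"squared"} (default) or \code{"absolute"}.
#' @return Non-negative scalar.
#' @export
global_connectivity_energy <- function(F, type = c("squared", "absolute")) {
  type <- match.arg(type)
  m <- if (inherits(F, "connectivity_matrix")) F$values else as.matrix(F)
  if (type == "squared") sum(m^2) else sum(abs(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
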