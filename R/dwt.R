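#' @name dwt
#' @title Orthonormal discrete wavelet decomposition
#'
#' @description
#' The band decomposition used throughout the package is a periodised
#' orthonormal Daubechies DWT.  At sampling rate \code{fs}, detail level
#' \code{L} spans the dyadic band \code{[fs/2^(L+1), fs/2^L]} Hz; at the
#' 500 Hz rate of standard clinical EEG, level 5 of a 9-level decomposition
#' spans 7.8125-15.625 Hz and is used to reconstruct alpha oscillations.
#'
#' Signals are zero-padded internally to a multiple of \code{2^levels}, so
#' arbitrary lengths are accepted while the transform stays orthonormal:
#' reconstruction from the full pyramid is exact to machine precision and
#' total coefficient energy equals signal energy.
NULL

# Daubechies decomposition filters (orthonormal; standard published values).
wavelet_filters <- function(wavelet = "db8") {
  lo <- switch(wavelet,
    haar = c(0.7071067811865476, 0.7071067811865476),
    db2 = c(-0.12940952255126037, 0.2241438680420134,
            0.8365163037378079, 0.48296291314453416),
    db4 = c(-0.010597401785069032, 0.0328830116668852,
            0.030841381835560764, -0.18703481171909309,
            -0.027983769416859854, 0.6308807679298589,
            0.7148465705529157, 0.2303778133088965),
    db8 = c(-0.00011747678412476953, 0.0006754494064505693,
            -0.00039174037337694705, -0.004870352993451574,
            0.008746094047405777, 0.013981027917398282,
            -0.044088253930794755, -0.017369301001807547,
            0.12874742662047847, 0.0004724845739132828,
            -0.2840155429615469, -0.015829105256349306,
            0.5853546836542067, 0.6756307362972898,
            0.31287159091429995, 0.05441584224310401),
    stop("unknown wavelet '", wavelet, "' (available: haar, db2, db4, db8)",
         call. = FALSE)
  )
  L <- length(lo)
  # quadrature mirror: hi[j] = (-1)^j * lo[L-1-j]  (0-based j)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1L)
  list(lo = lo, hi = hi)
}

# One circular analysis step; n must be even.
# cA[k] = sum_j lo[j] x[(2k+j) mod n],  k = 0..n/2-1  (0-based)
dwt_step <- function(x, flt) {
  n <- length(x)
  half <- n %/% 2L
  k2 <- 2L * (seq_len(half) - 1L)
  cA <- numeric(half)
  cD <- numeric(half)
  for (j in seq_along(flt$lo)) {
    xs <- x[((k2 + (j - 1L)) %% n) + 1L]
    cA <- cA + flt$lo[j] * xs
    cD <- cD + flt$hi[j] * xs
  }
  list(cA = cA, cD = cD)
}

# Adjoint (= inverse, the transform is orthonormal) of dwt_step.
idwt_step <- function(cA, cD, flt) {
  half <- length(cA)
  n <- 2L * half
  k2 <- 2L * (seq_len(half) - 1L)
  x <- numeric(n)
  for (j in seq_along(flt$lo)) {
    p <- ((k2 + (j - 1L)) %% n) + 1L
    x[p] <- x[p] + flt$lo[j] * cA + flt$hi[j] * cD
  }
  x
}

#' Decompose a single-channel signal into a wavelet pyramid
#'
#' @param signal numeric vector, length at least \code{2^levels}.
#' @param levels decomposition depth (default 9).
#' @param wavelet basis identifier: \code{"haar"}, \code{"db2"}, \code{"db4"} or
#'   \code{"db8"} (default).
#' @return An object of class \code{wavelet_pyramid} with components
#'   \code{details} (list of per-level detail coefficients, level 1 finest),
#'   \code{approx} (final approximation), \code{levels}, \code{wavelet},
#'   and \code{n} (original signal length).
#' @examples
#' p <- dwt_decompose(sin(2 * pi * 10 * (0:4095) / 500), levels = 9)
#' length(p$details)  # 9
#' @export
dwt_decompose <- function(signal, levels = 9L, wavelet = "db8") {
  stopifnot(is.numeric(signal), length(levels) == 1L, levels >= 1L)
  levels <- as.integer(levels)
  n <- length(signal)
  if (n < 2^levels)
    stop("signal of length ", n, " too short for ", levels,
         " decomposition levels (need >= ", 2^levels, ")", call. = FALSE)
  block <- 2^levels
  padded <- as.integer(ceiling(n / block) * block)
  x <- c(as.numeric(signal), numeric(padded - n))
  flt <- wavelet_filters(wavelet)
  details <- vector("list", levels)
  for (l in seq_len(levels)) {
    s <- dwt_step(x, flt)
    details[[l]] <- s$cD
    x <- s$cA
  }
  structure(list(details = details, approx = x, levels = levels,
                 wavelet = wavelet, n = n),
            class = "wavelet_pyramid")
}

#' @export
print.wavelet_pyramid <- function(x, ...) {
  cat("<wavelet_pyramid> ", x$wavelet, ", ", x$levels,
      " levels, signal length ", x$n, "\n", sep = "")
  invisible(x)
}

#' Reconstruct a signal from (a subset of) a wavelet pyramid
#'
#' @param pyr a [dwt_decompose()] pyramid.
#' @param keep_details integer vector of detail levels to retain (default
#'   all); coefficients at other levels are zeroed.
#' @param keep_approx retain the final approximation (default \code{TRUE}).
#' @return Numeric vector of the original signal length.
#' @export
dwt_reconstruct <- function(pyr, keep_details = seq_len(pyr$levels),
                            keep_approx = TRUE) {
  stopifnot(inherits(pyr, "wavelet_pyramid"))
  if (length(keep_details) > 0L)
    stopifnot(all(keep_details >= 1L), all(keep_details <= pyr$levels))
  flt <- wavelet_filters(pyr$wavelet)
  x <- if (keep_approx) pyr$approx else numeric(length(pyr$approx))
  for (l in rev(seq_len(pyr$levels))) {
    cD <- if (l %in% keep_details) pyr$details[[l]]
          else numeric(length(pyr$details[[l]]))
    x <- idwt_step(x, cD, flt)
  }
  x[seq_len(pyr$n)]
}

#' Soft-threshold the detail coefficients of a pyramid
#'
#' Universal soft thresholding: every detail coefficient \code{c} is replaced
#' by \code{sign(c) * max(|c| - lambda, 0)} with
#' \code{lambda = sigma * sqrt(2 * log(n))}, where the noise scale
#' \code{sigma} is the median absolute level-1 detail coefficient divided by
#' 0.6745 and \code{n} is the signal length.
#'
#' @param pyr a [dwt_decompose()] pyramid.
#' @param rule \code{"universal_soft"} or \code{"none"} (identity).
#' @return A \code{wavelet_pyramid} with thresholded details.
#' @export
threshold_denoise <- function(pyr, rule = c("universal_soft", "none")) {
  stopifnot(inherits(pyr, "wavelet_pyramid"))
  rule <- match.arg(rule)
  if (rule == "none") return(pyr)
  sigma <- stats::median(abs(pyr$details[[1]])) / 0.6745
  lambda <- sigma * sqrt(2 * log(pyr$n))
  pyr$details <- lapply(pyr$details, function(c)
    sign(c) * pmax(abs(c) - lambda, 0))
  pyr
}

#' Dyadic detail level covering the alpha band
#'
#' Returns the detail level \code{L} whose band \code{[fs/2^(L+1), fs/2^L]}
#' contains 10 Hz, the centre of the alpha rhythm.  At \code{fs = 500} this
#' is level 5 (7.8125-15.625 Hz).
#'
#' @param fs sampling rate in Hz.
#' @param levels available decomposition depth.
#' @return Integer level.
#' @export
alpha_band_level <- function(fs, levels = 9L) {
  stopifnot(fs > 0)
  L <- floor(log2(fs / 10))
  if (L < 1 || L > levels)
    stop("no dyadic detail level within depth ", levels,
         " contains 10 Hz at fs = ", fs, " Hz", call. = FALSE)
  as.integer(L)
}

#' Extract alpha oscillations from a recording
#'
#' Each channel is decomposed to \code{levels} wavelet levels, optionally
#' denoised, and reconstructed from only the detail coefficients of the
#' dyadic level containing 10 Hz (level 5 at 500 Hz, spanning
#' 7.8125-15.625 Hz).  The output is band-tagged with that dyadic interval
#' and has the same length as the input.
#'
#' @param rec an [eeg_recording()].
#' @param levels decomposition depth (default 9).
#' @param wavelet basis identifier (default \code{"db8"}).
#' @param denoise threshold rule applied before band reconstruction:
#'   \code{"none"} (default) or \code{"universal_soft"}.
#' @return A band-tagged \code{eeg_recording} of alpha oscillations.
#' @export
extract_alpha <- function(rec, levels = 9L, wavelet = "db8",
                          denoise = c("none", "universal_soft")) {
  stopifnot(inherits(rec, "eeg_recording"))
  denoise <- match.arg(denoise)
  L <- alpha_band_level(rec$fs, levels)
  out <- t(apply(rec$data, 1, function(x) {
    pyr <- dwt_decompose(x, levels = levels, wavelet = wavelet)
    if (denoise != "none") pyr <- threshold_denoise(pyr, denoise)
    dwt_reconstruct(pyr, keep_details = L, keep_approx = FALSE)
  }))
  band <- c(rec$fs / 2^(L + 1), rec$fs / 2^L)
  eeg_recording(out, rec$fs, rec$labels, band = band)
}

#' Alpha energy ratio of a recording
#'
#' Per channel, the ratio of the squared detail coefficients at the alpha
#' level to the total squared coefficients over all levels (details plus
#' approximation); by orthonormality the denominator equals the signal
#' energy, so the ratio is the fraction of signal energy in the alpha band
#' and lies in \code{[0, 1]}.  The reported value is the mean over the
#' region's channels (all channels when \code{region} is \code{NULL}).  A
#' zero-energy channel is assigned ratio 0 with a warning.
#'
#' @param rec an [eeg_recording()] of raw (broadband) EEG.
#' @param region optional \code{region_spec} restricting and averaging.
#' @param levels,wavelet decomposition parameters, as in [dwt_decompose()].
#' @param segment_index optional integer tag carried through to the result.
#' @return An object of class \code{alpha_ratio}: \code{value} (region
#'   mean), \code{per_channel} (named vector), \code{region},
#'   \code{segment_index}, \code{level}.
#' @export
alpha_ratio <- function(rec, region = NULL, levels = 9L, wavelet = "db8",
                        segment_index = NA_integer_) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.null(region)) rec <- select_channels(rec, region)
  L <- alpha_band_level(rec$fs, levels)
  per <- apply(rec$data, 1, function(x) {
    pyr <- dwt_decompose(x, levels = levels, wavelet = wavelet)
    total <- sum(pyr$approx^2) + sum(vapply(pyr$details,
                                            function(d) sum(d^2), 0))
    if (total <= 0) {
      warning("zero-energy channel: alpha ratio reported as 0")
      return(0)
    }
    sum(pyr$details[[L]]^2) / total
  })
  structure(list(value = mean(per), per_channel = per,
                 region = if (is.null(region)) NULL else region$name,
                 segment_index = segment_index, level = L),
            class = "alpha_ratio")
}

#' @export
print.alpha_ratio <- function(x, ...) {
  cat("<alpha_ratio> ", format(x$value, digits = 4),
      if (!is.null(x$region)) paste0(" (region: ", x$region, ")"),
      "\n", sep = "")
  invisible(x)
}
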