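#' Standard 19-channel 10-20 montage and scalp regions
#'
#' The canonical node order used throughout the package is the 19 standard
#' 10-20 electrodes Fp1, Fp2, F7, F3, Fz, F4, F8, T3, C3, Cz, C4, T4, T5,
#' P3, Pz, P4, T6, O1, O2, numbered 1-19.  Two 7-channel scalp regions are
#' defined on top of it: the frontal region (Fp1, Fp2, F7, F3, Fz, F4, F8)
#' and the parieto-occipital region (T5, P3, Pz, P4, T6, O1, O2).  Central
#' and mid-temporal channels (T3, C3, Cz, C4, T4) belong to neither.
#'
#' @return A list with components:
#' \describe{
#'   \item{channels}{character vector of the 19 labels in canonical order.}
#'   \item{frontal}{a \code{region_spec} for the frontal channels.}
#'   \item{parieto_occipital}{a \code{region_spec} for the parieto-occipital
#'     channels.}
#' }
#' @examples
#' m <- default_montage()
#' m$channels[c(1, 19)]     # "Fp1" "O2"
#' intersect(m$frontal$channels, m$parieto_occipital$channels)  # empty
#' @export
default_montage <- function() {
  channels <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                "T3", "C3", "Cz", "C4", "T4",
                "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
  list(
    channels = channels,
    frontal = region_spec("frontal",
                          c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8")),
    parieto_occipital = region_spec("parieto_occipital",
                                    c("T5", "P3", "Pz", "P4", "T6", "O1", "O2"))
  )
}

#' Define a named set of montage channels
#'
#' @param name region label, e.g. \code{"frontal"}.
#' @param channels non-empty character vector of 10-20 channel labels.
#' @return An object of class \code{region_spec}.
#' @export
region_spec <- function(name, channels) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(channels) == 0L)
    stop("region '", name, "' has no channels", call. = FALSE)
  if (anyDuplicated(channels))
    stop("region '", name, "' has duplicated channels", call. = FALSE)
  structure(list(name = name, channels = as.character(channels)),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat("<region_spec> ", x$name, ": ",
      paste(x$channels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Approximate 2-D positions of the 10-20 electrodes on a unit head disc.
# Used only to parameterise the distance decay of the synthetic leakage
# kernel; not an anatomical coordinate system.
montage_coordinates <- function() {
  xy <- rbind(
    Fp1 = c(-0.31, 0.95), Fp2 = c(0.31, 0.95),
    F7  = c(-0.81, 0.59), F3  = c(-0.55, 0.48), Fz = c(0, 0.50),
    F4  = c(0.55, 0.48),  F8  = c(0.81, 0.59),
    T3  = c(-1.00, 0.00), C3  = c(-0.50, 0.00), Cz = c(0, 0.00),
    C4  = c(0.50, 0.00),  T4  = c(1.00, 0.00),
    T5  = c(-0.81, -0.59), P3 = c(-0.55, -0.48), Pz = c(0, -0.50),
    P4  = c(0.55, -0.48), T6  = c(0.81, -0.59),
    O1  = c(-0.31, -0.95), O2 = c(0.31, -0.95)
  )
  colnames(xy) <- c("x", "y")
  xy
}

# Case-insensitive, whitespace-tolerant match of labels against the montage.
# Returns labels in their canonical spelling; unknown labels pass through
# unchanged (recordings are not restricted to the 19-channel montage).
canonical_labels <- function(labels) {
  labels <- trimws(labels)
  montage <- default_montage()$channels
  hit <- match(toupper(labels), toupper(montage))
  out <- ifelse(is.na(hit), labels, montage[hit])
  as.character(out)
}
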