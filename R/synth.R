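#' Scenario configuration for synthetic EEG cohorts
#'
#' Describes a cohort of multichannel EEG recordings with region-localised
#' alpha sources whose spatial distribution drifts across recording stages,
#' time-invariant linear leakage mixing between channels, and broadband
#' background noise.  Alpha sources are sinusoids with per-subject frequency
#' jitter and slow amplitude modulation; each driven region is fed by two
#' phase-offset sub-sources so that within-region coherence is graded rather
#' than perfect.
#'
#' @param name scenario label (also used as the group label).
#' @param n_subjects subjects in the cohort (default 14).
#' @param fs sampling rate in Hz (default 500).
#' @param segment_seconds duration of each stage in seconds (default 60; a
#'   full-length study stage is 600).
#' @param n_segments number of stages (default 6).
#' @param channels channel labels (default the 19-channel 10-20 montage).
#' @param source_amplitudes numeric matrix, \code{n_segments} rows by 3
#'   columns \code{frontal}, \code{parieto_occipital}, \code{auditory}: the
#'   per-stage alpha source amplitude of each region in microvolts.
#' @param alpha_freq nominal alpha frequency in Hz (default 10).
#' @param freq_jitter_sd per-subject SD of the alpha frequency in Hz
#'   (default 0.4).
#' @param region_rho within-region correlation of the two sub-sources,
#'   named vector for \code{frontal} and \code{parieto_occipital}.
#' @param mixing_spread leakage kernel width in inter-electrode distance
#'   units; \code{0} disables mixing (default 0.15).
#' @param noise_sd background white-noise SD in microvolts (default 10).
#' @param amp_scale global amplitude scale applied to the mixed recording
#'   (sources and noise alike); affects entropy but not correlation.
#' @param seed integer cohort seed.
#' @return An object of class \code{scenario_config}.
#' @seealso [scenario_presets()], [simulate_recording()]
#' @export
scenario_config <- function(name,
                            n_subjects = 14L,
                            fs = 500,
                            segment_seconds = 60,
                            n_segments = 6L,
                            channels = default_montage()$channels,
                            source_amplitudes,
                            alpha_freq = 10,
                            freq_jitter_sd = 0.4,
                            region_rho = c(frontal = 0.95,
                                           parieto_occipital = 0.7),
                            mixing_spread = 0.15,
                            noise_sd = 10,
                            amp_scale = 1,
                            seed = 1L) {
  source_amplitudes <- as.matrix(source_amplitudes)
  if (nrow(source_amplitudes) != n_segments || ncol(source_amplitudes) != 3L)
    stop("source_amplitudes must be n_segments x 3 (frontal, ",
         "parieto_occipital, auditory)", call. = FALSE)
  colnames(source_amplitudes) <- c("frontal", "parieto_occipital", "auditory")
  if (any(source_amplitudes < 0))
    stop("source amplitudes must be non-negative", call. = FALSE)
  stopifnot(n_subjects >= 1L, fs > 0, segment_seconds > 0, n_segments >= 1L,
            noise_sd >= 0, amp_scale > 0, mixing_spread >= 0)
  structure(list(name = name, n_subjects = as.integer(n_subjects), fs = fs,
                 segment_seconds = segment_seconds,
                 n_segments = as.integer(n_segments),
                 channels = canonical_labels(channels),
                 source_amplitudes = source_amplitudes,
                 alpha_freq = alpha_freq, freq_jitter_sd = freq_jitter_sd,
                 region_rho = region_rho, mixing_spread = mixing_spread,
                 noise_sd = noise_sd, amp_scale = amp_scale,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> '", x$name, "': ", x$n_subjects, " subjects, ",
      x$n_segments, " x ", x$segment_seconds, " s @ ", x$fs, " Hz, ",
      length(x$channels), " channels, seed ", x$seed, "\n", sep = "")
  print(round(x$source_amplitudes, 2))
  invisible(x)
}

#' Control and radio scenario presets
#'
#' Two cohorts of 14 subjects, 6 stages, 500 Hz, 19 channels:
#' \describe{
#'   \item{control}{prolonged monotonous driving with no countermeasure:
#'     frontal alpha amplitude strictly decreasing and parieto-occipital
#'     amplitude strictly increasing over the six stages, emulating the
#'     drift of strong alpha coupling from frontal to parieto-occipital
#'     sites as fatigue accumulates.}
#'   \item{radio}{the same task with an auditory countermeasure: strong
#'     frontal amplitude retained in every stage, an initial auditory
#'     (T3/T4) source boost in stage 1, and a larger overall amplitude
#'     scale, emulating the preserved frontal activity and higher regional
#'     information content of the stimulated group.}
#' }
#'
#' @param seed base cohort seed; the radio cohort uses \code{seed + 1}.
#' @param segment_seconds stage duration (default 60 s).
#' @return Named list of two [scenario_config()] objects, \code{control}
#'   and \code{radio}.
#' @export
scenario_presets <- function(seed = 1L, segment_seconds = 60) {
  control <- scenario_config(
    name = "control",
    segment_seconds = segment_seconds,
    source_amplitudes = cbind(
      frontal = c(30, 12, 4, 0.9, 0.7, 0.5),
      parieto_occipital = c(2, 8, 15, 22, 26, 30),
      auditory = c(0, 0, 0, 0, 0, 0)),
    amp_scale = 1,
    seed = seed)
  radio <- scenario_config(
    name = "radio",
    segment_seconds = segment_seconds,
    source_amplitudes = cbind(
      frontal = c(30, 26, 26, 26, 26, 26),
      parieto_occipital = c(2, 4, 4.5, 5, 5.5, 6),
      auditory = c(35, 5, 5, 5, 5, 5)),
    amp_scale = 2,
    seed = seed + 1L)
  list(control = control, radio = radio)
}

# Region -> sub-source channel groups (montage names).
synth_subgroups <- function() {
  list(
    frontal_a = list(region = "frontal",
                     channels = c("Fp1", "Fp2", "F7", "F3")),
    frontal_b = list(region = "frontal", channels = c("Fz", "F4", "F8")),
    po_a = list(region = "parieto_occipital",
                channels = c("T5", "P3", "Pz", "P4")),
    po_b = list(region = "parieto_occipital",
                channels = c("T6", "O1", "O2")),
    aud = list(region = "auditory", channels = c("T3", "T4"))
  )
}

#' Leakage mixing matrix of a scenario
#'
#' Gaussian distance-decay kernel over the 2-D 10-20 electrode layout:
#' \code{W[i, j] = exp(-(d_ij / spread)^2)} with unit diagonal; a spread of
#' 0 yields the identity (no leakage).  The matrix is a pure function of
#' the geometry, hence identical across segments and subjects - the
#' time-invariant signal-mixing assumption.
#'
#' @param cfg a [scenario_config()].
#' @return Numeric mixing matrix, channels x channels.
#' @export
leakage_matrix <- function(cfg) {
  xy <- montage_coordinates()
  idx <- match(cfg$channels, rownames(xy))
  if (anyNA(idx))
    stop("leakage geometry undefined for channels: ",
         paste(cfg$channels[is.na(idx)], collapse = ", "), call. = FALSE)
  d <- as.matrix(stats::dist(xy[idx, , drop = FALSE]))
  if (cfg$mixing_spread <= 0) {
    W <- diag(length(cfg$channels))
  } else {
    W <- exp(-(d / cfg$mixing_spread)^2)
  }
  dimnames(W) <- list(cfg$channels, cfg$channels)
  W
}

#' Simulate one subject's multichannel recording
#'
#' Each driven region's channels receive that region's alpha sub-source
#' (sinusoid at the subject's jittered alpha frequency with slow amplitude
#' modulation) scaled by the stage's amplitude, plus independent broadband
#' white noise; all channels are then mixed by the fixed leakage matrix and
#' the stages are concatenated into one continuous recording.  The output
#' is a deterministic function of (config, subject index).
#'
#' @param cfg a [scenario_config()].
#' @param subject subject index, 1-based.
#' @return An [eeg_recording()] of
#'   \code{n_segments * segment_seconds * fs} samples.
#' @export
simulate_recording <- function(cfg, subject) {
  stopifnot(inherits(cfg, "scenario_config"),
            subject >= 1L, subject <= cfg$n_subjects)
  with_seed((cfg$seed %% 100000L) * 10000L + as.integer(subject), {
    fs <- cfg$fs
    seg_len <- as.integer(round(cfg$segment_seconds * fs))
    n <- seg_len * cfg$n_segments
    tt <- (seq_len(n) - 1) / fs
    seg_of <- rep(seq_len(cfg$n_segments), each = seg_len)
    nch <- length(cfg$channels)
    f_subj <- cfg$alpha_freq + stats::rnorm(1, 0, cfg$freq_jitter_sd)
    subj_amp <- exp(stats::rnorm(1, 0, 0.05))
    # small fixed frequency offsets keep different regions near-orthogonal
    region_freq <- c(frontal = f_subj, parieto_occipital = f_subj + 0.63,
                     auditory = f_subj - 0.57)
    region_phase <- stats::setNames(stats::runif(3, 0, 2 * pi),
                                    names(region_freq))
    X <- matrix(0, nch, n, dimnames = list(cfg$channels, NULL))
    groups <- synth_subgroups()
    for (gname in names(groups)) {
      g <- groups[[gname]]
      r <- g$region
      rho <- if (r %in% names(cfg$region_rho)) cfg$region_rho[[r]] else 1
      # the second sub-source of a region is phase-offset by acos(rho), so
      # the zero-lag correlation between the two sub-sources is about rho
      offset <- if (endsWith(gname, "_b")) acos(min(max(rho, -1), 1)) else 0
      am <- 1 + 0.25 * sin(2 * pi * stats::runif(1, 0.05, 0.15) * tt +
                           stats::runif(1, 0, 2 * pi))
      src <- am * sin(2 * pi * region_freq[[r]] * tt +
                      region_phase[[r]] + offset)
      gains <- cfg$source_amplitudes[seg_of, r]
      for (ch in g$channels) {
        if (!(ch %in% cfg$channels)) next
        jit <- 1 + stats::rnorm(1, 0, 0.1)
        X[ch, ] <- X[ch, ] + gains * jit * src
      }
    }
    if (cfg$noise_sd > 0)
      X <- X + matrix(stats::rnorm(nch * n, 0, cfg$noise_sd), nch, n)
    W <- leakage_matrix(cfg)
    Y <- cfg$amp_scale * subj_amp * (W %*% X)
    eeg_recording(Y, fs, cfg$channels)
  })
}

#' Simulate a whole cohort
#'
#' @param cfg a [scenario_config()].
#' @return A list with one element per subject, each a list
#'   \code{(subject, group, recording)}; subject ids are
#'   \code{<name>_S01 ...}.
#' @export
simulate_cohort <- function(cfg) {
  lapply(seq_len(cfg$n_subjects), function(i) {
    list(subject = sprintf("%s_S%02d", cfg$name, i), group = cfg$name,
         recording = simulate_recording(cfg, i))
  })
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
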